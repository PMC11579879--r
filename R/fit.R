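#' Fit all applicable MR estimators to a harmonized dataset
#'
#' The standard analysis sequence for one exposure-outcome pair: with a
#' single instrument the Wald ratio is the only estimate; with two or more,
#' Cochran's Q decides between fixed- and random-effects IVW (see
#' [select_effects_model()]); with three or more, MR-Egger, the weighted
#' median and both mode estimators are added, and the full sensitivity
#' report (heterogeneity, Egger intercept, Steiger direction) is attached.
#'
#' @param dat Harmonized dataset from [harmonize()].
#' @param n_boot Bootstrap resamples for median/mode standard errors; `0`
#'   skips them (point estimates only).
#' @param seed Integer seed for the bootstraps (required when `n_boot > 0`
#'   and more than two SNPs are available).
#' @param bandwidth_factor Kernel bandwidth multiplier for [mr_modes()].
#' @return An object of class `mr_fit` with elements `estimates` (tidy
#'   per-method rows), `sensitivity` (one row, `NULL` when fewer than two
#'   SNPs), `data`, `exposure`, `outcome`. Use [tidy()][generics::tidy] /
#'   [glance()][generics::glance] to extract the tables.
#' @export
#' @examples
#' sim <- sim_study(n_snps = 20, theta = 0.3, seed = 7)
#' fit <- mr_fit(harmonize(sim$exposure, sim$outcome), n_boot = 100, seed = 1)
#' tidy(fit)
#' glance(fit)
mr_fit <- function(dat, n_boot = 1000, seed = NULL, bandwidth_factor = 1) {
  n <- nrow(dat)
  if (n == 0) stop("no SNPs in harmonized dataset", call. = FALSE)

  if (n == 1) {
    est <- mr_wald_ratio(dat)
    sens <- NULL
  } else {
    qres <- .cochran_q(dat)
    model <- select_effects_model(qres$p_q, qres$i2)
    est <- mr_ivw(dat, model)
    if (n >= 3) {
      est <- dplyr::bind_rows(
        est,
        mr_egger(dat),
        mr_weighted_median(dat, n_boot = n_boot, seed = seed),
        mr_modes(dat, bandwidth_factor = bandwidth_factor,
                 n_boot = n_boot, seed = if (is.null(seed)) NULL else seed + 2L)
      )
    }
    sens <- sensitivity_report(dat)
  }
  structure(
    list(estimates = est, sensitivity = sens, data = dat,
         exposure = attr(dat, "exposure") %||% "exposure",
         outcome = attr(dat, "outcome") %||% "outcome"),
    class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, ...) {
  cat("<mr_fit>", x$exposure, "->", x$outcome, "|", nrow(x$data), "SNPs\n")
  print(x$estimates)
  invisible(x)
}

#' Tidy the per-method estimates of an MR fit
#'
#' @param x An `mr_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per estimator: `exposure`, `outcome`,
#'   `method`, `nsnp`, `beta`, `se`, `ci_low`, `ci_high`, `pvalue`, plus
#'   Egger intercept columns where applicable.
#' @method tidy mr_fit
#' @export
tidy.mr_fit <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(exposure = x$exposure, outcome = x$outcome),
                   x$estimates)
}

#' One-row model-level summary of an MR fit
#'
#' @param x An `mr_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: primary estimate (`beta`, `se`, `pvalue`,
#'   `method`, `nsnp`) joined with the sensitivity report columns (all `NA`
#'   for single-instrument fits).
#' @method glance mr_fit
#' @export
glance.mr_fit <- function(x, ...) {
  primary <- x$estimates[1, c("method", "nsnp", "beta", "se", "pvalue")]
  sens <- x$sensitivity %||% tibble::tibble(
    q = NA_real_, df = NA_integer_, p_q = NA_real_, i2 = NA_real_,
    effects_model_chosen = NA_character_,
    egger_intercept = NA_real_, egger_intercept_se = NA_real_,
    egger_intercept_pvalue = NA_real_,
    steiger_direction_ok = NA, p_steiger = NA_real_,
    r2_exposure = NA_real_, r2_outcome = NA_real_)
  dplyr::bind_cols(
    tibble::tibble(exposure = x$exposure, outcome = x$outcome),
    primary, sens)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
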