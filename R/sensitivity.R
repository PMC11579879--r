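# Q over per-SNP Wald ratios with first-order SEs; weights 1/se_ratio^2
# (the same weights the IVW estimator uses, so the two agree on beta_ivw).
.cochran_q <- function(dat) {
  r <- .ratios(dat)
  w <- 1 / r$se^2
  beta_ivw <- sum(w * r$b) / sum(w)
  q <- sum(w * (r$b - beta_ivw)^2)
  df <- nrow(dat) - 1L
  list(q = q, df = df, p_q = stats::pchisq(q, df, lower.tail = FALSE),
       i2 = if (q > 0) max(0, (q - df) / q) else 0)
}

#' Cochran's Q heterogeneity test
#'
#' `Q = sum(w_i * (b_i - b_IVW)^2)` over per-SNP Wald ratios `b_i` with
#' inverse-variance weights `w_i = 1/se_ratio_i^2`, compared against a
#' chi-square with `nsnp - 1` degrees of freedom. `I2 = max(0, (Q - df)/Q)`
#' expresses the fraction of variability beyond chance.
#'
#' @param dat Harmonized dataset with at least 2 SNPs.
#' @return A one-row tibble: `q`, `df`, `p_q`, `i2`.
#' @export
cochran_q <- function(dat) {
  if (nrow(dat) < 2) {
    return(tibble::tibble(q = NA_real_, df = NA_integer_, p_q = NA_real_,
                          i2 = NA_real_, note = "not applicable"))
  }
  tibble::as_tibble(.cochran_q(dat))
}

#' Choose the IVW effects model from heterogeneity diagnostics
#'
#' Random effects if and only if heterogeneity is both statistically
#' significant and substantial: `p_q < p_threshold` AND `i2 > i2_threshold`
#' (defaults 0.05 and 0.25, strict inequalities). Many tools condition on
#' the p-value alone; both thresholds are exposed so that convention can be
#' recovered (`i2_threshold = 0`).
#'
#' @param p_q Cochran's Q p-value.
#' @param i2 I-squared, in `[0, 1]`.
#' @param p_threshold,i2_threshold Decision thresholds.
#' @return `"random"` or `"fixed"`.
#' @export
select_effects_model <- function(p_q, i2, p_threshold = 0.05,
                                 i2_threshold = 0.25) {
  stopifnot(is.finite(p_q), is.finite(i2))
  if (p_q < p_threshold && i2 > i2_threshold) "random" else "fixed"
}

#' Steiger directionality test
#'
#' Checks that the instruments explain more variance in the exposure than
#' in the outcome, supporting the assumed causal direction. Per-trait R2 is
#' summed over instruments via [snp_r2()]; the two correlation magnitudes
#' `|r| = sqrt(R2)` are compared on the Fisher-z scale with a normal test
#' using variances `1/(n - 3)`.
#'
#' @param dat Harmonized dataset (>= 1 SNP) with `eaf`/`n` columns on both
#'   sides; both sample sizes must exceed 3.
#' @return A one-row tibble: `steiger_direction_ok` (`r2_exposure >
#'   r2_outcome`), `p_steiger`, `r2_exposure`, `r2_outcome`.
#' @export
steiger_test <- function(dat) {
  stopifnot(nrow(dat) >= 1)
  n_exp <- max(dat$n_exp)
  n_out <- max(dat$n_out)
  if (n_exp <= 3 || n_out <= 3) stop("sample sizes must exceed 3", call. = FALSE)
  r2_exp <- min(sum(snp_r2(dat$beta_exp, dat$se_exp, dat$eaf_exp, dat$n_exp)),
                1 - 1e-15)
  r2_out <- min(sum(snp_r2(dat$beta_out, dat$se_out, dat$eaf_out, dat$n_out)),
                1 - 1e-15)
  z <- (atanh(sqrt(r2_exp)) - atanh(sqrt(r2_out))) /
    sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  tibble::tibble(
    steiger_direction_ok = r2_exp > r2_out,
    p_steiger = 2 * stats::pnorm(-abs(z)),
    r2_exposure = r2_exp, r2_outcome = r2_out
  )
}

#' Full sensitivity report for a harmonized dataset
#'
#' Combines heterogeneity (Cochran's Q, I-squared), the resulting
#' fixed/random effects-model choice, the MR-Egger intercept test for
#' directional pleiotropy, and the Steiger directionality test into one
#' row. Components whose SNP-count preconditions fail (Q needs 2, Egger 3)
#' are reported as `NA`.
#'
#' @param dat Harmonized dataset.
#' @return A one-row tibble: `q`, `df`, `p_q`, `i2`,
#'   `effects_model_chosen`, `egger_intercept`, `egger_intercept_se`,
#'   `egger_intercept_pvalue`, `steiger_direction_ok`, `p_steiger`,
#'   `r2_exposure`, `r2_outcome`.
#' @export
sensitivity_report <- function(dat) {
  qres <- cochran_q(dat)
  model <- if (is.na(qres$q)) {
    NA_character_
  } else {
    select_effects_model(qres$p_q, qres$i2)
  }
  eg <- mr_egger(dat)
  st <- steiger_test(dat)
  tibble::tibble(
    q = qres$q, df = qres$df, p_q = qres$p_q, i2 = qres$i2,
    effects_model_chosen = model,
    egger_intercept = eg$egger_intercept,
    egger_intercept_se = eg$egger_intercept_se,
    egger_intercept_pvalue = eg$egger_intercept_pvalue,
    steiger_direction_ok = st$steiger_direction_ok,
    p_steiger = st$p_steiger,
    r2_exposure = st$r2_exposure, r2_outcome = st$r2_outcome
  )
}
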