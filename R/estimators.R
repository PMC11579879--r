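Z95 <- stats::qnorm(0.975)

#' Construct an MR result row
#'
#' Builds the one-row tibble all estimators return, from a point estimate
#' and standard error — useful for feeding externally published estimates
#' (e.g. step odds ratios, as `log(OR)`) into [two_step_mediation()]. The
#' 95% CI is normal-based and the p-value is the two-sided normal
#' `2*pnorm(-|beta/se|)`, the same identities every estimator satisfies.
#'
#' @param method Method label (e.g. `"wald_ratio"`, `"ivw_random"`).
#' @param beta,se Estimate and standard error on the beta (log-OR) scale.
#' @param nsnp Number of SNPs behind the estimate.
#' @param ... Additional columns (e.g. Egger intercept fields).
#' @return A one-row tibble: `method`, `nsnp`, `beta`, `se`, `ci_low`,
#'   `ci_high`, `pvalue`, plus any extra columns.
#' @export
mr_result <- function(method, beta, se, nsnp, ...) {
  tibble::tibble(
    method = method, nsnp = as.integer(nsnp),
    beta = beta, se = se,
    ci_low = beta - Z95 * se, ci_high = beta + Z95 * se,
    pvalue = 2 * stats::pnorm(-abs(beta / se)),
    ...
  )
}

mr_not_applicable <- function(method, nsnp, ...) {
  tibble::tibble(
    method = method, nsnp = as.integer(nsnp),
    beta = NA_real_, se = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
    pvalue = NA_real_, note = "not applicable", ...
  )
}

# per-SNP Wald ratios and their first-order delta SEs
.ratios <- function(d) {
  list(b = d$beta_out / d$beta_exp, se = d$se_out / abs(d$beta_exp))
}

#' Wald ratio causal estimate from a single variant
#'
#' `beta = beta_out / beta_exp`, with the first-order delta-method standard
#' error `se_out / |beta_exp|`. The single-variant estimate used when an
#' exposure has exactly one instrument.
#'
#' @param dat A one-row harmonized dataset (columns `beta_exp`, `se_exp`,
#'   `beta_out`, `se_out`).
#' @return A one-row results tibble (`method = "wald_ratio"`).
#' @export
mr_wald_ratio <- function(dat) {
  stopifnot(nrow(dat) == 1)
  if (dat$beta_exp == 0) stop("undefined ratio: beta_exp is zero", call. = FALSE)
  r <- .ratios(dat)
  mr_result("wald_ratio", r$b, r$se, 1L)
}

#' Inverse-variance-weighted causal estimate
#'
#' Weighted least squares of outcome betas on exposure betas through the
#' origin with weights `1/se_out^2`; equivalently the inverse-variance
#' weighted mean of per-SNP Wald ratios. Under the fixed-effects model
#' `se = sqrt(1 / sum(w * beta_exp^2))`; the random-effects model inflates
#' it multiplicatively by `sqrt(max(1, Q/(nsnp - 1)))`, reducing to fixed
#' effects when Cochran's Q does not exceed its degrees of freedom.
#'
#' @param dat Harmonized dataset (>= 1 SNP).
#' @param effects_model `"fixed"` or `"random"`.
#' @return A one-row results tibble (`method = "ivw_fixed"` or
#'   `"ivw_random"`).
#' @export
mr_ivw <- function(dat, effects_model = c("fixed", "random")) {
  effects_model <- match.arg(effects_model)
  n <- nrow(dat)
  if (n == 0) stop("no SNPs in harmonized dataset", call. = FALSE)
  w <- 1 / dat$se_out^2
  beta <- sum(w * dat$beta_exp * dat$beta_out) / sum(w * dat$beta_exp^2)
  se <- sqrt(1 / sum(w * dat$beta_exp^2))
  if (effects_model == "random" && n >= 2) {
    q <- .cochran_q(dat)$q
    se <- se * sqrt(max(1, q / (n - 1)))
  }
  mr_result(paste0("ivw_", effects_model), beta, se, n)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome betas on exposure betas with an
#' unconstrained intercept, weights `1/se_out^2`. Records are first
#' re-signed so every exposure beta is non-negative (the intercept is not
#' orientation-invariant without this convention). The slope is the
#' pleiotropy-adjusted causal estimate; the intercept estimates average
#' directional pleiotropy, and its two-sided test is reported in the
#' `egger_intercept*` columns. Standard errors use the multiplicative
#' residual scale floored at 1.
#'
#' @param dat Harmonized dataset; requires at least 3 SNPs, otherwise a
#'   structured not-applicable row is returned.
#' @return A one-row results tibble (`method = "egger"`) with extra columns
#'   `egger_intercept`, `egger_intercept_se`, `egger_intercept_pvalue`.
#' @export
mr_egger <- function(dat) {
  n <- nrow(dat)
  if (n < 3) {
    return(mr_not_applicable("egger", n,
                             egger_intercept = NA_real_,
                             egger_intercept_se = NA_real_,
                             egger_intercept_pvalue = NA_real_))
  }
  sgn <- ifelse(dat$beta_exp < 0, -1, 1)
  bx <- sgn * dat$beta_exp
  by <- sgn * dat$beta_out
  w <- 1 / dat$se_out^2

  x <- cbind(1, bx)
  xtwx <- crossprod(x, w * x)
  coefs <- unname(drop(solve(xtwx, crossprod(x, w * by))))
  resid <- by - drop(x %*% coefs)
  sigma2 <- sum(w * resid^2) / (n - 2)
  ses <- unname(sqrt(diag(solve(xtwx))) * sqrt(max(1, sigma2)))

  res <- mr_result("egger", coefs[2], ses[2], n)
  res$egger_intercept <- coefs[1]
  res$egger_intercept_se <- ses[1]
  res$egger_intercept_pvalue <- 2 * stats::pnorm(-abs(coefs[1] / ses[1]))
  res
}

# cumulative-weight median of per-SNP ratios with linear interpolation
.weighted_median_point <- function(b, w) {
  o <- order(b)
  b <- b[o]
  w <- w[o] / sum(w)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(b[1])
  k <- max(which(s < 0.5))
  if (k == length(b)) return(b[k])
  b[k] + (b[k + 1] - b[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
}

# parametric bootstrap SE: redraw per-SNP betas from their sampling
# distributions, recompute the point estimate
.boot_se <- function(dat, point_fun, n_boot, seed) {
  n <- nrow(dat)
  withr::with_seed(seed, {
    est <- vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(n, dat$beta_exp, dat$se_exp)
      by <- stats::rnorm(n, dat$beta_out, dat$se_out)
      point_fun(bx, by, dat$se_out)
    }, numeric(1))
  })
  stats::sd(est)
}

#' Weighted median causal estimate
#'
#' The inverse-variance weighted median of per-SNP Wald ratios: ratios are
#' ordered, weights (`1 / se_ratio^2`, normalized to sum 1) accumulated,
#' and the estimate taken at cumulative weight 0.5 with linear
#' interpolation between the bracketing ratios. Consistent when at least
#' half the weight lies on valid instruments. The standard error comes from
#' a seeded parametric bootstrap (per-SNP betas redrawn from their normal
#' sampling distributions).
#'
#' @param dat Harmonized dataset; requires >= 3 SNPs.
#' @param n_boot Bootstrap resamples for the SE (default 1000). `0` skips
#'   the bootstrap and reports `se = NA` (point estimate only).
#' @param seed Integer seed for the bootstrap (required when `n_boot > 0`).
#' @return A one-row results tibble (`method = "weighted_median"`).
#' @export
mr_weighted_median <- function(dat, n_boot = 1000, seed = NULL) {
  n <- nrow(dat)
  if (n < 3) return(mr_not_applicable("weighted_median", n))
  point <- function(bx, by, sy) {
    .weighted_median_point(by / bx, (bx / sy)^2)
  }
  beta <- point(dat$beta_exp, dat$beta_out, dat$se_out)
  se <- NA_real_
  if (n_boot > 0) {
    if (is.null(seed)) stop("seed is required when n_boot > 0", call. = FALSE)
    se <- .boot_se(dat, point, n_boot, seed)
  }
  mr_result("weighted_median", beta, se, n)
}

# argmax of a normal-kernel-smoothed density of the ratios over a fine grid;
# ties resolve to the smallest ratio (ascending grid, first maximum)
.mode_point <- function(b, w, bandwidth_factor, grid_n = 512) {
  h <- bandwidth_factor * stats::mad(b)
  if (!is.finite(h) || h <= 0) {
    # zero spread in the majority: the kernel degenerates to point masses,
    # so take the discrete weighted mode (smallest value on ties)
    vals <- sort(unique(b))
    ws <- vapply(vals, function(v) sum(w[b == v]), numeric(1))
    return(vals[which.max(ws)])
  }
  grid <- seq(min(b) - 3 * h, max(b) + 3 * h, length.out = grid_n)
  dens <- colSums((w / sum(w)) * stats::dnorm(outer(b, grid, "-") / h))
  grid[which.max(dens)]
}

#' Mode-based causal estimates
#'
#' Smooths the per-SNP Wald ratios with a normal kernel of bandwidth
#' `bandwidth_factor * 1.4826 * MAD(ratios)` and takes the density argmax:
#' the simple mode uses equal weights, the weighted mode inverse-variance
#' weights (`1 / se_ratio^2`). Consistent when the largest group of
#' instruments sharing a ratio value is valid. Standard errors by seeded
#' parametric bootstrap.
#'
#' @inheritParams mr_weighted_median
#' @param bandwidth_factor Multiplier on the robust spread (default 1).
#' @return A two-row results tibble (`method = "simple_mode"`,
#'   `"weighted_mode"`).
#' @export
mr_modes <- function(dat, bandwidth_factor = 1, n_boot = 1000, seed = NULL) {
  n <- nrow(dat)
  if (n < 3) {
    return(dplyr::bind_rows(mr_not_applicable("simple_mode", n),
                            mr_not_applicable("weighted_mode", n)))
  }
  simple <- function(bx, by, sy) {
    .mode_point(by / bx, rep(1, length(bx)), bandwidth_factor)
  }
  weighted <- function(bx, by, sy) {
    .mode_point(by / bx, (bx / sy)^2, bandwidth_factor)
  }
  b_s <- simple(dat$beta_exp, dat$beta_out, dat$se_out)
  b_w <- weighted(dat$beta_exp, dat$beta_out, dat$se_out)
  se_s <- se_w <- NA_real_
  if (n_boot > 0) {
    if (is.null(seed)) stop("seed is required when n_boot > 0", call. = FALSE)
    se_s <- .boot_se(dat, simple, n_boot, seed)
    se_w <- .boot_se(dat, weighted, n_boot, seed + 1L)
  }
  dplyr::bind_rows(mr_result("simple_mode", b_s, se_s, n),
                   mr_result("weighted_mode", b_w, se_w, n))
}
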