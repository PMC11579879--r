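#' Two-step mediation MR from three GWAS summary-statistics tables
#'
#' Runs the full mediation decomposition for one exposure-mediator-outcome
#' triple: the total effect (exposure -> outcome), step 1 (exposure ->
#' mediator) and step 2 (mediator -> outcome) are each estimated with
#' instrument selection, harmonization and the standard estimator sequence
#' (Wald ratio for one instrument, otherwise IVW with the effects model
#' chosen from Cochran's Q), then combined with [two_step_mediation()].
#'
#' Step-2 instruments are selected from the mediator's GWAS and SNPs
#' associated with the exposure (exposure p-value below `exclude_p`) are
#' excluded: such variants reach the outcome through the exposure's direct
#' path as well, which would contaminate the mediator -> outcome estimate.
#'
#' @param exposure,mediator,outcome Summary-statistics tibbles.
#' @param config A [screen_config()] providing instrument-selection and
#'   harmonization settings plus the seed.
#' @param exclude_p Exposure-association p-value below which a SNP is
#'   barred from the step-2 instrument set (default 0.05).
#' @return A one-row tibble as from [two_step_mediation()], with the three
#'   step estimates and instrument counts as extra columns.
#' @export
#' @examples
#' sim <- sim_study(theta = 0.3, b2 = 0.4, b3 = 0.5, seed = 2)
#' mr_mediation(sim$exposure, sim$mediator, sim$outcome,
#'              config = screen_config(n_boot = 0, seed = 2))
mr_mediation <- function(exposure, mediator, outcome,
                         config = screen_config(), exclude_p = 0.05) {
  tot <- .screen_one(exposure, outcome, config, seed = config$seed)
  s1 <- .screen_one(exposure, mediator, config, seed = config$seed + 1L)
  exp_assoc <- exposure$snp_id[exposure$pvalue < exclude_p]
  s2 <- .screen_one(mediator, outcome, config, seed = config$seed + 2L,
                    exclude_snps = exp_assoc)
  failed <- c(total = tot$reason, step1 = s1$reason, step2 = s2$reason)
  if (any(failed != "")) {
    stop("mediation step(s) not estimable: ",
         paste(names(failed)[failed != ""], failed[failed != ""],
               sep = ": ", collapse = "; "), call. = FALSE)
  }
  res <- two_step_mediation(tot$fit$estimates[1, ], s1$fit$estimates[1, ],
                            s2$fit$estimates[1, ])
  res$nsnp_total <- tot$fit$estimates$nsnp[1]
  res$nsnp_step1 <- s1$fit$estimates$nsnp[1]
  res$nsnp_step2 <- s2$fit$estimates$nsnp[1]
  res
}

#' Combine three MR estimates into a mediation decomposition
#'
#' Decomposes the total effect of an exposure on an outcome into the part
#' transmitted through a mediator and the remainder, from three MR fits on
#' the log-odds (beta) scale:
#'
#' * `total`: exposure -> outcome (the total effect, `beta1`);
#' * `step1`: exposure -> mediator (`beta2`);
#' * `step2`: mediator -> outcome (`beta3`).
#'
#' The indirect effect is the product of coefficients `beta2 * beta3`, with
#' the first-order Delta-method standard error
#' `sqrt(beta3^2 * se2^2 + beta2^2 * se3^2)` and a normal-based 95% CI. The
#' direct effect is `beta1 - beta2*beta3`, and the proportion mediated
#' `beta2*beta3 / beta1`. Proportions outside `[0, 1]` (inconsistent
#' mediation) are reported as-is and flagged, never clamped; a zero total
#' effect leaves the proportion `NA` with a flag while the indirect effect
#' is still reported.
#'
#' @param total,step1,step2 One-row MR results tibbles (as returned by the
#'   estimators), or any objects with `beta`, `se` and `method` fields.
#' @return A one-row tibble: `beta_total`, `se_total`, `beta_exp_to_med`,
#'   `beta_med_to_out`, `beta_indirect`, `se_indirect`, `ci_indirect_low`,
#'   `ci_indirect_high`, `pvalue_indirect`, `beta_direct`,
#'   `proportion_mediated`, `flag` (`""`, `"proportion outside [0,1]"` or
#'   `"total effect zero"`), and the estimator labels
#'   `method_total`, `method_step1`, `method_step2`.
#' @export
#' @examples
#' # step estimates quoted as odds ratios: OR 2.40 and OR 1.66
#' s1 <- mr_result("wald_ratio", log(2.40), 0.28, 1)
#' s2 <- mr_result("ivw_random", log(1.66), 0.11, 8)
#' tot <- mr_result("wald_ratio", 0.9, 0.3, 1)
#' two_step_mediation(tot, s1, s2)
two_step_mediation <- function(total, step1, step2) {
  b1 <- total$beta
  b2 <- step1$beta
  b3 <- step2$beta
  stopifnot(is.finite(b1), is.finite(b2), is.finite(b3),
            step1$se > 0, step2$se > 0)
  ind <- b2 * b3
  se_ind <- sqrt(b3^2 * step1$se^2 + b2^2 * step2$se^2)
  prop <- if (b1 == 0) NA_real_ else ind / b1
  flag <- if (b1 == 0) {
    "total effect zero"
  } else if (prop < 0 || prop > 1) {
    "proportion outside [0,1]"
  } else ""
  tibble::tibble(
    beta_total = b1, se_total = total$se,
    beta_exp_to_med = b2, beta_med_to_out = b3,
    beta_indirect = ind, se_indirect = se_ind,
    ci_indirect_low = ind - Z95 * se_ind,
    ci_indirect_high = ind + Z95 * se_ind,
    pvalue_indirect = 2 * stats::pnorm(-abs(ind / se_ind)),
    beta_direct = b1 - ind,
    proportion_mediated = prop,
    flag = flag,
    method_total = total$method %||% NA_character_,
    method_step1 = step1$method %||% NA_character_,
    method_step2 = step2$method %||% NA_character_
  )
}
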