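# SNP metadata: positions spaced >20 Mb apart (beyond any clumping window
# used here) across chromosomes so simulated instruments are independent
# even under distance-only clumping.
.sim_snp_meta <- function(n_snps, maf_range, frac_palindromic, prefix = "rs",
                          pos_offset = 0L) {
  pal_pairs <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
  nonpal_pairs <- list(c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
                       c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))
  is_pal <- stats::runif(n_snps) < frac_palindromic
  pick <- function(pairs, k) pairs[sample.int(length(pairs), k, replace = TRUE)]
  alle <- vector("list", n_snps)
  alle[is_pal] <- pick(pal_pairs, sum(is_pal))
  alle[!is_pal] <- pick(nonpal_pairs, sum(!is_pal))
  chrom <- as.character(rep_len(1:22, n_snps))
  # 21 Mb spacing keeps SNPs outside any clumping window used here; beyond
  # ~2200 SNPs positions wrap (such panels are used for distributional
  # checks, not clumping)
  idx <- (ceiling(seq_len(n_snps) / 22) - 1L) %% 100L + 1L
  pos <- as.integer(21e6 * idx) + as.integer(pos_offset)
  tibble::tibble(
    snp_id = paste0(prefix, seq_len(n_snps)),
    chrom = chrom, pos = pos,
    effect_allele = vapply(alle, `[`, "", 1),
    other_allele = vapply(alle, `[`, "", 2),
    maf = stats::runif(n_snps, maf_range[1], maf_range[2])
  )
}

# observed summary stats for one trait: true per-allele effects plus normal
# sampling noise with SE = 1/sqrt(2p(1-p)n) (standardized-trait scale)
.sim_trait_stats <- function(meta, true_beta, n, trait_name,
                             trait_type = "quantitative") {
  v <- 2 * meta$maf * (1 - meta$maf)
  se <- 1 / sqrt(v * n)
  beta <- stats::rnorm(nrow(meta), true_beta, se)
  eaf <- meta$maf + stats::rnorm(nrow(meta), 0, sqrt(meta$maf * (1 - meta$maf) / (2 * n)))
  eaf <- pmin(pmax(eaf, 0.005), 0.995)
  new_sumstats(tibble::tibble(
    snp_id = meta$snp_id, chrom = meta$chrom, pos = meta$pos,
    effect_allele = meta$effect_allele, other_allele = meta$other_allele,
    eaf = eaf, beta = beta, se = se,
    pvalue = 2 * stats::pnorm(-abs(beta / se)),
    n = as.integer(n)
  ), trait_name = trait_name, trait_type = trait_type)
}

# allele-coding corruption: swapping effect/other alleles negates the beta
# and complements the EAF; a strand flip only relabels the alleles. Both are
# exactly invertible, which is what makes the harmonization oracle exact.
.corrupt_coding <- function(stats, frac_swapped, frac_flipped) {
  n <- nrow(stats)
  swap <- stats::runif(n) < frac_swapped
  flip <- stats::runif(n) < frac_flipped
  out <- stats
  out$effect_allele[swap] <- stats$other_allele[swap]
  out$other_allele[swap] <- stats$effect_allele[swap]
  out$beta[swap] <- -stats$beta[swap]
  out$eaf[swap] <- 1 - stats$eaf[swap]
  out$effect_allele[flip] <- unname(.complement[out$effect_allele[flip]])
  out$other_allele[flip] <- unname(.complement[out$other_allele[flip]])
  out
}

.sim_pleiotropy <- function(n_snps, model, mean, sd, frac) {
  alpha <- numeric(n_snps)
  if (model == "none") return(alpha)
  # exactly frac * n_snps invalid instruments (random subset)
  k <- round(frac * n_snps)
  affected <- sample.int(n_snps, k)
  alpha[affected] <- switch(model,
    balanced = stats::rnorm(k, 0, sd),
    directional = stats::rnorm(k, mean, sd))
  alpha
}

#' Simulate a three-trait GWAS summary-statistics study
#'
#' Generates per-SNP summary statistics for an exposure, a mediator and an
#' outcome under the causal chain exposure -> mediator -> outcome with an
#' additional direct exposure -> outcome path. Per SNP `i`: a minor-allele
#' frequency is drawn from `maf_range`; the true exposure effect `gamma_i`
#' is scaled (with random sign) so each SNP explains
#' `exposure_r2_per_snp` of the exposure variance; the mediator effect is
#' `b2 * gamma_i`; the outcome effect is `(theta + b2*b3) * gamma_i +
#' sign(gamma_i) * alpha_i`, where `alpha_i` is the horizontal-pleiotropy
#' term, defined per exposure-increasing allele so a directional model
#' shifts every affected SNP the same way in the causal frame. Reported
#' betas add normal sampling noise with `SE = 1/sqrt(2p(1-p)n)` per trait
#' (traits standardized; binary traits are emulated identically on the
#' log-OR scale), p-values follow from the normal z-statistic, and the
#' three samples are non-overlapping (independent noise).
#'
#' Allele codings of the mediator and outcome tables are then corrupted at
#' the requested rates (allele swaps and strand flips) to exercise
#' harmonization; the uncorrupted tables are kept in `$clean` so estimates
#' after harmonization can be compared against the uncorrupted truth.
#'
#' @param n_snps Number of independent SNPs (default 30).
#' @param n_exp,n_med,n_out GWAS sample sizes (default 10000 each).
#' @param maf_range Minor-allele-frequency range (default `c(0.05, 0.40)`,
#'   keeping palindromic SNPs orientable by frequency).
#' @param exposure_r2_per_snp Per-SNP explained variance of the exposure
#'   (default 0.01); `exposure_r2_per_snp * n_snps` must stay below 1.
#' @param n_snps_med Number of SNPs acting directly on the mediator
#'   (default: `n_snps` when the mediated path is active, i.e. `b2` and
#'   `b3` both non-zero, else 0). These SNPs are independent of the
#'   exposure, appear in all three tables (zero true effect on the
#'   exposure, effect `b3 * delta_i` on the outcome), and are what makes
#'   the mediator -> outcome step of two-step MR identifiable: the
#'   exposure's instruments act on the mediator only through the exposure
#'   and would conflate the direct path.
#' @param theta Direct causal effect exposure -> outcome (default 0.3).
#' @param b2,b3 Exposure -> mediator and mediator -> outcome effects
#'   (default 0: no mediated path).
#' @param pleiotropy `"none"`, `"balanced"` (mean-zero) or `"directional"`.
#' @param pleiotropy_mean,pleiotropy_sd Parameters of the pleiotropic
#'   effect distribution (defaults 0.02 and 0.01).
#' @param pleiotropy_frac Fraction of SNPs carrying pleiotropic effects
#'   when the model is not `"none"` (default 1).
#' @param frac_palindromic Fraction of SNPs given A/T or C/G allele pairs
#'   (default 0.2).
#' @param frac_allele_swapped,frac_strand_flipped Allele-coding corruption
#'   rates applied to the mediator and outcome tables (default 0).
#' @param seed Integer seed; the output is fully reproducible from it.
#' @return A list of class `mr_simulation`: `exposure`, `mediator`,
#'   `outcome` (summary-statistics tibbles, possibly corrupted), `clean`
#'   (the uncorrupted mediator/outcome twins), `truth` (`theta_total =
#'   theta + b2*b3`, `theta_direct`, `b2`, `b3`, `proportion_mediated =
#'   b2*b3 / theta_total`), and the generating parameters in `params`.
#' @export
#' @examples
#' sim <- sim_study(theta = 0.3, b2 = 0.4, b3 = 0.5, seed = 1)
#' sim$truth$proportion_mediated # 0.2 / 0.5
sim_study <- function(n_snps = 30, n_snps_med = NULL,
                      n_exp = 10000, n_med = 10000,
                      n_out = 10000, maf_range = c(0.05, 0.40),
                      exposure_r2_per_snp = 0.01, theta = 0.3,
                      b2 = 0, b3 = 0,
                      pleiotropy = c("none", "balanced", "directional"),
                      pleiotropy_mean = 0.02, pleiotropy_sd = 0.01,
                      pleiotropy_frac = 1,
                      frac_palindromic = 0.2, frac_allele_swapped = 0,
                      frac_strand_flipped = 0, seed) {
  pleiotropy <- match.arg(pleiotropy)
  stopifnot(maf_range[1] > 0, maf_range[2] < 1, maf_range[1] <= maf_range[2],
            frac_palindromic >= 0, frac_palindromic <= 1,
            frac_allele_swapped >= 0, frac_allele_swapped <= 1,
            frac_strand_flipped >= 0, frac_strand_flipped <= 1)
  if (exposure_r2_per_snp * n_snps >= 1) {
    stop("exposure_r2_per_snp * n_snps must be < 1 (total variance over-explained)",
         call. = FALSE)
  }
  if (missing(seed)) stop("seed is required", call. = FALSE)
  n_snps_med <- n_snps_med %||% (if (b2 != 0 && b3 != 0) n_snps else 0L)
  if (n_snps_med > 0 && exposure_r2_per_snp * n_snps_med >= 1) {
    stop("exposure_r2_per_snp * n_snps_med must be < 1", call. = FALSE)
  }

  withr::with_seed(seed, {
    meta <- .sim_snp_meta(n_snps, maf_range, frac_palindromic)
    gamma <- sample(c(-1, 1), n_snps, replace = TRUE) *
      sqrt(exposure_r2_per_snp / (2 * meta$maf * (1 - meta$maf)))
    alpha <- .sim_pleiotropy(n_snps, pleiotropy, pleiotropy_mean,
                             pleiotropy_sd, pleiotropy_frac)
    theta_total <- theta + b2 * b3

    # true per-allele effects on each trait, exposure's instruments first,
    # then the mediator's own instruments (independent of the exposure)
    beta_exp_true <- gamma
    beta_med_true <- b2 * gamma
    # pleiotropic effects are defined per exposure-increasing allele, so
    # they follow the orientation of the exposure effect; without sign(gamma)
    # a nonzero-mean alpha would cancel across randomly oriented SNPs and
    # "directional" pleiotropy would be indistinguishable from balanced
    beta_out_true <- theta_total * gamma + sign(gamma) * alpha
    if (n_snps_med > 0) {
      meta_med <- .sim_snp_meta(n_snps_med, maf_range, frac_palindromic,
                                prefix = "rsm", pos_offset = 10500000L)
      delta <- sample(c(-1, 1), n_snps_med, replace = TRUE) *
        sqrt(exposure_r2_per_snp / (2 * meta_med$maf * (1 - meta_med$maf)))
      meta <- dplyr::bind_rows(meta, meta_med)
      beta_exp_true <- c(beta_exp_true, numeric(n_snps_med))
      beta_med_true <- c(beta_med_true, delta)
      beta_out_true <- c(beta_out_true, b3 * delta)
    }

    exposure <- .sim_trait_stats(meta, beta_exp_true, n_exp, "exposure")
    med_clean <- .sim_trait_stats(meta, beta_med_true, n_med, "mediator")
    out_clean <- .sim_trait_stats(meta, beta_out_true, n_out,
                                  "outcome", trait_type = "binary")
    mediator <- .corrupt_coding(med_clean, frac_allele_swapped, frac_strand_flipped)
    outcome <- .corrupt_coding(out_clean, frac_allele_swapped, frac_strand_flipped)
  })

  structure(list(
    exposure = exposure, mediator = mediator, outcome = outcome,
    clean = list(mediator = med_clean, outcome = out_clean),
    truth = list(theta_total = theta_total, theta_direct = theta,
                 b2 = b2, b3 = b3,
                 proportion_mediated = if (theta_total == 0) NA_real_ else
                   b2 * b3 / theta_total),
    params = list(n_snps = n_snps, n_snps_med = n_snps_med,
                  n_exp = n_exp, n_med = n_med,
                  n_out = n_out, maf_range = maf_range,
                  exposure_r2_per_snp = exposure_r2_per_snp, theta = theta,
                  b2 = b2, b3 = b3, pleiotropy = pleiotropy,
                  pleiotropy_mean = pleiotropy_mean,
                  pleiotropy_sd = pleiotropy_sd,
                  pleiotropy_frac = pleiotropy_frac,
                  frac_palindromic = frac_palindromic,
                  frac_allele_swapped = frac_allele_swapped,
                  frac_strand_flipped = frac_strand_flipped, seed = seed)
  ), class = "mr_simulation")
}

#' @export
print.mr_simulation <- function(x, ...) {
  p <- x$params
  cat("<mr_simulation>", p$n_snps, "SNPs | theta =", p$theta,
      "b2 =", p$b2, "b3 =", p$b3, "| pleiotropy:", p$pleiotropy,
      "| seed", p$seed, "\n")
  invisible(x)
}

#' Simulate an LD block
#'
#' Builds a pairwise LD r-squared matrix for a set of SNPs, for testing
#' clumping behaviour. `r2_profile` is either a single value applied to
#' every off-diagonal pair or a full symmetric matrix.
#'
#' @param snp_ids Character vector of SNP IDs.
#' @param r2_profile Scalar in `[0, 1]` or an `n x n` matrix of pairwise
#'   r-squared values (diagonal forced to 1).
#' @return An LD matrix as accepted by [select_instruments()]: a list with
#'   `snp_ids` and the symmetric `r2` matrix.
#' @export
sim_ld_block <- function(snp_ids, r2_profile = 0) {
  n <- length(snp_ids)
  if (is.matrix(r2_profile)) {
    if (nrow(r2_profile) != n || ncol(r2_profile) != n) {
      stop("r2_profile dimensions do not match snp_ids", call. = FALSE)
    }
    m <- r2_profile
  } else {
    stopifnot(length(r2_profile) == 1, r2_profile >= 0, r2_profile <= 1)
    m <- matrix(r2_profile, n, n)
  }
  diag(m) <- 1
  ld_matrix(snp_ids, m)
}

#' Simulate a multi-exposure screening panel
#'
#' Generates one summary-statistics table per exposure (each with its own
#' disjoint set of instruments), a discovery outcome covering every SNP, an
#' optional independent replication outcome (same true effects, fresh
#' sampling noise), and an optional mediator, for exercising the screening
#' pipeline end to end.
#'
#' @param n_exposures Number of exposures in the panel.
#' @param theta Vector of causal effects, recycled to `n_exposures`.
#' @param snps_per_exposure Instruments per exposure (default 1, echoing
#'   metabolite GWAS where most exposures have a single instrument).
#' @param b2,b3 Mediated-path effects shared by all exposures: the mediator
#'   responds to each exposure's instruments with slope `b2`, and the
#'   outcome's true effects include the `b2 * b3` mediated contribution.
#' @param replication Generate a replication outcome cohort?
#' @param seed Integer seed.
#' @inheritParams sim_study
#' @return A list: `exposures` (list of summary-stat tibbles), `outcome`,
#'   `replication` (or `NULL`), `mediator`, `truth` (per-exposure theta).
#' @export
sim_screen <- function(n_exposures = 20, theta = 0, snps_per_exposure = 1,
                       n_exp = 10000, n_out = 10000,
                       exposure_r2_per_snp = 0.02,
                       b2 = 0, b3 = 0, maf_range = c(0.05, 0.40),
                       replication = FALSE, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  theta <- rep_len(theta, n_exposures)
  withr::with_seed(seed, {
    exposures <- vector("list", n_exposures)
    out_rows <- med_rows <- rep_rows <- vector("list", n_exposures)
    for (e in seq_len(n_exposures)) {
      meta <- .sim_snp_meta(snps_per_exposure, maf_range, 0.2,
                            prefix = paste0("rs", e, "_"))
      gamma <- sample(c(-1, 1), snps_per_exposure, replace = TRUE) *
        sqrt(exposure_r2_per_snp / (2 * meta$maf * (1 - meta$maf)))
      exposures[[e]] <- .sim_trait_stats(meta, gamma, n_exp,
                                         paste0("exposure_", e))
      beta_out <- (theta[e] + b2 * b3) * gamma
      out_rows[[e]] <- .sim_trait_stats(meta, beta_out, n_out, "outcome",
                                        trait_type = "binary")
      med_rows[[e]] <- .sim_trait_stats(meta, b2 * gamma, n_out, "mediator")
      if (replication) {
        rep_rows[[e]] <- .sim_trait_stats(meta, beta_out, n_out,
                                          "outcome_replication",
                                          trait_type = "binary")
      }
    }
  })
  bind_set <- function(rows, name, type = "quantitative") {
    new_sumstats(dplyr::bind_rows(lapply(rows, tibble::as_tibble)),
                 trait_name = name, trait_type = type)
  }
  list(
    exposures = exposures,
    outcome = bind_set(out_rows, "outcome", "binary"),
    replication = if (replication) bind_set(rep_rows, "outcome_replication", "binary") else NULL,
    mediator = bind_set(med_rows, "mediator"),
    truth = tibble::tibble(exposure = paste0("exposure_", seq_len(n_exposures)),
                           theta = theta)
  )
}
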