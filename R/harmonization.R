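.complement <- c(A = "T", C = "G", G = "C", T = "A")

.is_palindromic <- function(a1, a2) .complement[a1] == a2

#' Harmonize exposure and outcome summary statistics
#'
#' Merges two summary-statistics tables on shared SNP IDs and aligns the
#' outcome associations to the exposure's effect-allele coding. For each
#' shared SNP:
#'
#' * alleles already match: kept unchanged (`action = "none"`);
#' * outcome alleles swapped relative to the exposure: outcome beta negated
#'   and its EAF complemented (`"outcome_flipped"`);
#' * outcome alleles on the opposite strand (A<->T, C<->G), possibly also
#'   swapped: relabelled, and negated/complemented if swapped
#'   (`"strand_complemented"`, `"strand_complemented_and_flipped"`);
#' * palindromic SNPs (A/T or C/G pairs), where swap and strand flip are
#'   indistinguishable from the alleles alone: oriented by allele frequency,
#'   kept only when both EAFs lie outside the ambiguity window
#'   `[0.5 - w, 0.5 + w]`; the outcome is flipped when the two frequencies
#'   disagree on which allele is minor. Ambiguous palindromes are dropped;
#' * irreconcilable allele pairs are dropped.
#'
#' Records sharing a SNP ID but mapped to different (chrom, pos) are dropped
#' rather than errored.
#'
#' @param exposure,outcome Summary-statistics tibbles (canonical columns).
#' @param palindrome_eaf_window Half-width `w` of the EAF ambiguity window
#'   around 0.5 for palindromic SNPs. Default `0.08` (ambiguous when EAF is
#'   in \[0.42, 0.58\]); `0.5` drops every palindrome.
#' @return A tibble of class `mr_harmonized` with one row per retained SNP:
#'   `snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `beta_exp`,
#'   `se_exp`, `eaf_exp`, `n_exp`, `beta_out`, `se_out`, `eaf_out`, `n_out`,
#'   `action`, `palindromic`. Attributes: `exposure`, `outcome` (trait
#'   names), `n_dropped_palindromic`, `n_dropped_unmatched`.
#' @export
#' @examples
#' sim <- sim_study(n_snps = 10, frac_allele_swapped = 0.5, seed = 1)
#' harmonize(sim$exposure, sim$outcome)
harmonize <- function(exposure, outcome, palindrome_eaf_window = 0.08) {
  w <- palindrome_eaf_window
  stopifnot(w >= 0, w <= 0.5, nrow(exposure) > 0, nrow(outcome) > 0)

  m <- dplyr::inner_join(
    tibble::as_tibble(exposure), tibble::as_tibble(outcome),
    by = "snp_id", suffix = c("_exp", "_out"))
  if (nrow(m) == 0) stop("no shared SNPs between exposure and outcome", call. = FALSE)

  n_dropped_palindromic <- 0L
  n_dropped_unmatched <- 0L

  # positional consistency: same snp_id must map to the same locus
  pos_ok <- m$chrom_exp == m$chrom_out & m$pos_exp == m$pos_out
  n_dropped_unmatched <- n_dropped_unmatched + sum(!pos_ok)
  m <- m[pos_ok, , drop = FALSE]

  a1x <- m$effect_allele_exp
  a2x <- m$other_allele_exp
  a1y <- m$effect_allele_out
  a2y <- m$other_allele_out
  pal <- .is_palindromic(a1x, a2x)

  action <- rep(NA_character_, nrow(m))
  flip <- rep(FALSE, nrow(m))
  keep <- rep(TRUE, nrow(m))
  drop_reason <- rep("", nrow(m))

  same <- a1y == a1x & a2y == a2x
  swapped <- a1y == a2x & a2y == a1x
  comp <- a1y == unname(.complement[a1x]) & a2y == unname(.complement[a2x])
  comp_swapped <- a1y == unname(.complement[a2x]) & a2y == unname(.complement[a1x])

  # non-palindromic: allele labels identify the transformation uniquely
  np <- !pal
  action[np & same] <- "none"
  action[np & swapped] <- "outcome_flipped"
  flip[np & swapped] <- TRUE
  action[np & comp] <- "strand_complemented"
  action[np & comp_swapped] <- "strand_complemented_and_flipped"
  flip[np & comp_swapped] <- TRUE
  bad <- np & !(same | swapped | comp | comp_swapped)
  keep[bad] <- FALSE
  drop_reason[bad] <- "incompatible alleles"

  # palindromic: labels cannot distinguish swap from strand flip; orient by
  # which allele is minor, and only when both EAFs are unambiguous
  if (any(pal)) {
    pal_match <- pal & (same | swapped | comp | comp_swapped)
    keep[pal & !pal_match] <- FALSE
    drop_reason[pal & !pal_match] <- "incompatible alleles"
    idx <- which(pal_match)
    ex <- m$eaf_exp[idx]
    ey <- m$eaf_out[idx]
    ambiguous <- is.na(ex) | is.na(ey) |
      (ex >= 0.5 - w & ex <= 0.5 + w) | (ey >= 0.5 - w & ey <= 0.5 + w)
    keep[idx[ambiguous]] <- FALSE
    drop_reason[idx[ambiguous]] <- "ambiguous palindrome"
    ok <- idx[!ambiguous]
    disagree <- (ex[!ambiguous] < 0.5) != (ey[!ambiguous] < 0.5)
    action[ok] <- ifelse(disagree, "outcome_flipped", "none")
    flip[ok] <- disagree
  }

  n_dropped_palindromic <- sum(drop_reason == "ambiguous palindrome")
  n_dropped_unmatched <- n_dropped_unmatched + sum(drop_reason == "incompatible alleles")

  out <- tibble::tibble(
    snp_id = m$snp_id,
    chrom = m$chrom_exp,
    pos = m$pos_exp,
    effect_allele = a1x,
    other_allele = a2x,
    beta_exp = m$beta_exp, se_exp = m$se_exp,
    eaf_exp = m$eaf_exp, n_exp = m$n_exp,
    beta_out = ifelse(flip, -m$beta_out, m$beta_out),
    se_out = m$se_out,
    eaf_out = ifelse(flip, 1 - m$eaf_out, m$eaf_out),
    n_out = m$n_out,
    action = action,
    palindromic = pal
  )[keep, , drop = FALSE]

  structure(out,
            exposure = attr(exposure, "trait_name") %||% "exposure",
            outcome = attr(outcome, "trait_name") %||% "outcome",
            n_dropped_palindromic = n_dropped_palindromic,
            n_dropped_unmatched = n_dropped_unmatched,
            class = c("mr_harmonized", class(tibble::tibble())))
}

#' Harmonization audit table
#'
#' Per-SNP record of the action harmonization took, suitable for writing as
#' a TSV audit trail.
#'
#' @param hd A harmonized dataset from [harmonize()].
#' @return A tibble with `snp_id`, `action`, `palindromic`.
#' @export
harmonization_audit <- function(hd) {
  tibble::tibble(snp_id = hd$snp_id, action = hd$action,
                 palindromic = hd$palindromic)
}

#' @export
print.mr_harmonized <- function(x, ...) {
  cat("<mr_harmonized>", attr(x, "exposure"), "->", attr(x, "outcome"),
      "|", nrow(x), "SNPs retained,",
      attr(x, "n_dropped_palindromic"), "ambiguous palindromes dropped,",
      attr(x, "n_dropped_unmatched"), "unmatched dropped\n")
  NextMethod()
}
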