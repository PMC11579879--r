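#' Per-SNP explained variance
#'
#' Approximates the fraction of trait variance explained by one SNP from
#' summary statistics alone, as `2p(1-p)beta^2 / (2p(1-p)beta^2 +
#' 2p(1-p)se^2 n)`, which simplifies to `z^2 / (z^2 + n)` with
#' `z = beta/se`. The result is clipped to `[0, 1)`.
#'
#' @param beta,se,eaf,n Vectors of per-SNP effect, standard error,
#'   effect-allele frequency and GWAS sample size (recycled).
#' @return Numeric vector of per-SNP R-squared values in `[0, 1)`.
#' @export
#' @examples
#' snp_r2(beta = 0.1, se = 0.01, eaf = 0.5, n = 10000) # 100/10100
snp_r2 <- function(beta, se, eaf, n) {
  if (any(n <= 2)) stop("sample size n must exceed 2", call. = FALSE)
  stopifnot(all(se > 0), all(eaf > 0 & eaf < 1))
  v <- 2 * eaf * (1 - eaf)
  r2 <- (v * beta^2) / (v * beta^2 + v * se^2 * n)
  pmin(pmax(r2, 0), 1 - 1e-15)
}

#' Instrument-strength F-statistic
#'
#' `F = ((N - K - 1) / K) * (R2 / (1 - R2))`, where `N` is the exposure GWAS
#' sample size, `K` the number of instruments and `R2` their total explained
#' variance. Values below 10 conventionally flag weak instruments.
#'
#' @param n Exposure GWAS sample size (`> k + 1`).
#' @param k Number of instruments (`>= 1`).
#' @param r2_total Total explained variance in `[0, 1)`.
#' @return The F-statistic (scalar).
#' @export
#' @examples
#' f_statistic(n = 1001, k = 1, r2_total = 0.01) # 999 * (0.01/0.99)
f_statistic <- function(n, k, r2_total) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (n <= k + 1) stop("n must exceed k + 1", call. = FALSE)
  if (r2_total < 0 || r2_total >= 1) stop("r2_total must be in [0, 1)", call. = FALSE)
  ((n - k - 1) / k) * (r2_total / (1 - r2_total))
}

#' Read a pairwise LD matrix
#'
#' Reads a square TSV of pairwise LD r-squared values with SNP IDs as both
#' header row and first column.
#'
#' @param path TSV path.
#' @return A list with `snp_ids` (character) and `r2` (symmetric numeric
#'   matrix, unit diagonal), as accepted by [select_instruments()].
#' @export
read_ld_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1])
  rownames(m) <- ids
  ld_matrix(ids, m)
}

# Validating constructor shared by read_ld_matrix() and sim_ld_block().
ld_matrix <- function(snp_ids, r2) {
  r2 <- as.matrix(r2)
  stopifnot(nrow(r2) == length(snp_ids), ncol(r2) == length(snp_ids))
  if (max(abs(r2 - t(r2))) > 1e-12) stop("LD matrix must be symmetric", call. = FALSE)
  if (max(abs(diag(r2) - 1)) > 1e-12) stop("LD matrix diagonal must be 1", call. = FALSE)
  if (any(r2 < 0 | r2 > 1)) stop("LD r2 values must lie in [0, 1]", call. = FALSE)
  dimnames(r2) <- list(snp_ids, snp_ids)
  list(snp_ids = snp_ids, r2 = r2)
}

#' Select genetic instruments for an exposure
#'
#' Filters a summary-statistics table to genome-wide-significant SNPs and
#' prunes them to approximate independence by greedy LD clumping:
#' candidates are ranked by ascending p-value (ties broken by chromosome,
#' position, then SNP ID) and each is retained unless it lies within
#' `window_kb` of an already-retained SNP on the same chromosome and either
#' (a) their LD r-squared in `ld` is at or above `r2_threshold`, or (b) no
#' LD matrix was supplied, in which case co-location within the window alone
#' removes it (a conservative rule, noted in the result).
#'
#' @param stats Summary-statistics tibble (canonical columns, see
#'   [read_summary_stats()]).
#' @param p_threshold Significance threshold for candidacy (default `5e-8`).
#' @param r2_threshold Clumping r-squared threshold (default `0.001`).
#' @param window_kb Clumping window in kilobases (default `10000`).
#' @param ld Optional LD matrix from [read_ld_matrix()] or [sim_ld_block()].
#'   SNP pairs absent from the matrix are treated as uncorrelated.
#' @return A list of class `mr_instruments`: `exposure_name`, `snps` (the
#'   retained rows, a tibble), `k`, `r2_total` (sum of [snp_r2()] over
#'   retained SNPs), `f_statistic`, `no_instruments` (flag: nothing passed
#'   `p_threshold`), `weak` (flag: F < 10), `distance_only` (flag: clumped
#'   without LD information).
#' @export
select_instruments <- function(stats, p_threshold = 5e-8,
                               r2_threshold = 0.001, window_kb = 10000,
                               ld = NULL) {
  stopifnot(p_threshold > 0, p_threshold < 1,
            r2_threshold >= 0, r2_threshold <= 1, window_kb > 0)
  exposure_name <- attr(stats, "trait_name") %||% "exposure"

  cand <- dplyr::filter(stats, .data$pvalue < p_threshold)
  if (nrow(cand) == 0) {
    return(structure(
      list(exposure_name = exposure_name,
           snps = tibble::as_tibble(stats)[0, ], k = 0L, r2_total = 0,
           f_statistic = NA_real_, no_instruments = TRUE, weak = NA,
           distance_only = is.null(ld)),
      class = "mr_instruments"))
  }
  cand <- dplyr::arrange(cand, .data$pvalue, .data$chrom, .data$pos,
                         .data$snp_id)

  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    kept <- which(keep)
    clash <- FALSE
    for (j in kept) {
      if (cand$chrom[j] != cand$chrom[i]) next
      if (abs(cand$pos[j] - cand$pos[i]) > window_kb * 1000) next
      if (is.null(ld)) { clash <- TRUE; break }
      r2 <- 0
      if (cand$snp_id[i] %in% ld$snp_ids && cand$snp_id[j] %in% ld$snp_ids) {
        r2 <- ld$r2[cand$snp_id[i], cand$snp_id[j]]
      }
      if (r2 >= r2_threshold) { clash <- TRUE; break }
    }
    keep[i] <- !clash
  }
  snps <- cand[keep, , drop = FALSE]

  r2_total <- sum(snp_r2(snps$beta, snps$se, snps$eaf, snps$n))
  r2_total <- min(r2_total, 1 - 1e-15)
  k <- nrow(snps)
  n_exp <- max(snps$n)
  f <- if (n_exp > k + 1) f_statistic(n_exp, k, r2_total) else NA_real_

  structure(
    list(exposure_name = exposure_name, snps = tibble::as_tibble(snps),
         k = k, r2_total = r2_total, f_statistic = f,
         no_instruments = FALSE, weak = isTRUE(f < 10),
         distance_only = is.null(ld)),
    class = "mr_instruments")
}

#' @export
print.mr_instruments <- function(x, ...) {
  if (x$no_instruments) {
    cat("<mr_instruments>", x$exposure_name, "- no instruments\n")
  } else {
    cat("<mr_instruments>", x$exposure_name, "- k =", x$k,
        sprintf("R2 = %.4g, F = %.4g%s", x$r2_total, x$f_statistic,
                if (isTRUE(x$weak)) " (weak, F < 10)" else ""), "\n")
  }
  invisible(x)
}
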