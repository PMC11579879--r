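#' Column dialects for GWAS summary-statistics tables
#'
#' A dialect maps the canonical column names used throughout this package to
#' the header names found in a particular GWAS release. Two dialects ship:
#' `"generic"` (the package's own canonical names) and `"gwas"`, mirroring
#' headers common in public GWAS downloads (`SNP`, `CHR`, `BP`, `A1`, `A2`,
#' `FREQ`, `BETA`, `SE`, `P`, `N`). Pass a named character vector to
#' [read_summary_stats()] to define your own: names are canonical fields,
#' values are the file's header names.
#'
#' @format A named list of named character vectors.
#' @export
sumstats_dialects <- list(
  generic = c(
    snp_id = "snp_id", chrom = "chrom", pos = "pos",
    effect_allele = "effect_allele", other_allele = "other_allele",
    eaf = "eaf", beta = "beta", se = "se", pvalue = "pvalue", n = "n"
  ),
  gwas = c(
    snp_id = "SNP", chrom = "CHR", pos = "BP",
    effect_allele = "A1", other_allele = "A2",
    eaf = "FREQ", beta = "BETA", se = "SE", pvalue = "P", n = "N"
  )
)

.sumstats_fields <- names(sumstats_dialects$generic)

# Row-level validity for single-nucleotide variants; returns a reason string
# per row ("" = valid). Harmonization rules are defined for SNVs only, so
# indels / multi-allelic codes are dropped here.
.sumstats_row_problems <- function(df) {
  bases <- c("A", "C", "G", "T")
  reason <- rep("", nrow(df))
  bad <- !(df$effect_allele %in% bases) | !(df$other_allele %in% bases)
  reason[bad & reason == ""] <- "allele not a single base in {A,C,G,T}"
  same <- !bad & df$effect_allele == df$other_allele
  reason[same & reason == ""] <- "effect and other allele identical"
  reason[(is.na(df$se) | df$se <= 0) & reason == ""] <- "se not positive"
  reason[(is.na(df$eaf) | df$eaf <= 0 | df$eaf >= 1) & reason == ""] <-
    "eaf outside (0,1)"
  reason[(is.na(df$pvalue) | df$pvalue <= 0 | df$pvalue > 1) & reason == ""] <-
    "pvalue outside (0,1]"
  reason[(is.na(df$n) | df$n <= 0) & reason == ""] <- "n not positive"
  reason[is.na(df$beta) & reason == ""] <- "beta missing"
  reason
}

#' Read a GWAS summary-statistics table
#'
#' Reads a delimited table of per-SNP association statistics (one row per
#' SNP) and returns a validated tibble in the package's canonical layout:
#' `snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`,
#' `se`, `pvalue`, `n`. The delimiter (tab or comma) is auto-detected from
#' the header line; gzip-compressed files are handled transparently by readr.
#'
#' Rows violating the per-SNP invariants (non-SNV alleles, `se <= 0`, `eaf`
#' outside (0,1), `pvalue` outside (0,1], non-positive `n`) are dropped with
#' a message reporting the count. Alleles are upper-cased. When both `beta`,
#' `se` and `pvalue` are present, rows whose reported p-value disagrees with
#' the normal approximation `2*pnorm(-|beta/se|)` by more than a factor of
#' 10 on the log10 scale trigger a warning (the rows are kept).
#'
#' @param path Path to a TSV/CSV file, optionally gzip-compressed.
#' @param dialect Either the name of a built-in dialect (see
#'   [sumstats_dialects]) or a named character vector mapping canonical
#'   field names to the file's column headers.
#' @param trait_name Optional trait label stored in the `trait_name`
#'   attribute (defaults to the file name without extension).
#' @param trait_type `"quantitative"` or `"binary"` (log-OR scale betas).
#' @return A tibble of class `mr_sumstats` with one row per valid SNP, in
#'   file order. Attributes: `trait_name`, `trait_type`, `n_dropped`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' readr::write_tsv(sim_study(n_snps = 5, seed = 1)$exposure, f)
#' read_summary_stats(f)
read_summary_stats <- function(path, dialect = "generic",
                               trait_name = NULL,
                               trait_type = c("quantitative", "binary")) {
  trait_type <- match.arg(trait_type)
  stopifnot(file.exists(path))
  map <- if (is.character(dialect) && length(dialect) == 1) {
    if (!dialect %in% names(sumstats_dialects)) {
      stop("unknown dialect '", dialect, "'; see sumstats_dialects", call. = FALSE)
    }
    sumstats_dialects[[dialect]]
  } else {
    dialect
  }
  missing_map <- setdiff(.sumstats_fields, names(map))
  if (length(missing_map) > 0) {
    stop("dialect does not map required column(s): ",
         paste(missing_map, collapse = ", "), call. = FALSE)
  }

  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  missing_cols <- setdiff(unname(map[.sumstats_fields]), names(raw))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }

  df <- tibble::tibble(
    snp_id = as.character(raw[[map[["snp_id"]]]]),
    chrom = as.character(raw[[map[["chrom"]]]]),
    pos = as.integer(raw[[map[["pos"]]]]),
    effect_allele = toupper(as.character(raw[[map[["effect_allele"]]]])),
    other_allele = toupper(as.character(raw[[map[["other_allele"]]]])),
    eaf = as.numeric(raw[[map[["eaf"]]]]),
    beta = as.numeric(raw[[map[["beta"]]]]),
    se = as.numeric(raw[[map[["se"]]]]),
    pvalue = as.numeric(raw[[map[["pvalue"]]]]),
    n = as.integer(raw[[map[["n"]]]])
  )

  reason <- .sumstats_row_problems(df)
  n_dropped <- sum(reason != "")
  if (n_dropped > 0) {
    tab <- table(reason[reason != ""])
    message("read_summary_stats: dropped ", n_dropped, " row(s): ",
            paste(names(tab), unname(tab), sep = " x ", collapse = "; "))
    df <- df[reason == "", , drop = FALSE]
  }
  if (nrow(df) == 0) stop("no valid rows in ", path, call. = FALSE)

  # warn-only consistency check of p against |beta/se|
  p_norm <- 2 * stats::pnorm(-abs(df$beta / df$se))
  incons <- abs(log10(pmax(df$pvalue, 1e-300)) - log10(pmax(p_norm, 1e-300))) > 1
  if (any(incons)) {
    warning(sum(incons), " row(s) have p-values inconsistent with |beta/se| ",
            "under the normal approximation", call. = FALSE)
  }
  if (anyDuplicated(df$snp_id)) {
    stop("duplicate snp_id in ", path, call. = FALSE)
  }

  new_sumstats(df,
               trait_name = trait_name %||%
                 sub("\\.(tsv|csv)(\\.gz)?$", "", basename(path)),
               trait_type = trait_type, n_dropped = n_dropped)
}

new_sumstats <- function(df, trait_name, trait_type = "quantitative",
                         n_dropped = 0L) {
  structure(tibble::as_tibble(df),
            trait_name = trait_name, trait_type = trait_type,
            n_dropped = n_dropped,
            class = c("mr_sumstats", class(tibble::tibble())))
}

#' @export
print.mr_sumstats <- function(x, ...) {
  cat("<mr_sumstats> trait:", attr(x, "trait_name") %||% "?",
      paste0("(", attr(x, "trait_type") %||% "quantitative", "),"),
      nrow(x), "SNPs\n")
  NextMethod()
}

#' Write a GWAS summary-statistics table
#'
#' Inverse of [read_summary_stats()]: writes the canonical columns as TSV
#' (or gzip TSV if the path ends in `.gz`).
#'
#' @param stats A summary-statistics tibble (canonical columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(stats, path) {
  readr::write_tsv(stats[, .sumstats_fields], path, progress = FALSE)
  invisible(path)
}

#' Write an MR results table
#'
#' Writes causal-effect estimates as a tab-delimited report with a fixed
#' column order: `exposure`, `outcome`, `method`, `nsnp`, `beta`, `se`,
#' `or` (`exp(beta)`), `ci_low`, `ci_high`, `or_ci_low`, `or_ci_high`,
#' `pvalue`, then any additional columns present (Egger intercept fields,
#' sensitivity columns, mediation fields, ...). This is the tabular
#' counterpart of the forest-plot figures MR studies usually print.
#'
#' @param results A non-empty data frame of MR results containing at least
#'   `method`, `nsnp`, `beta`, `se`, `ci_low`, `ci_high`, `pvalue`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path) {
  if (is.null(results) || nrow(results) == 0) {
    stop("results must be non-empty", call. = FALSE)
  }
  res <- tibble::as_tibble(results)
  for (col in c("exposure", "outcome")) {
    if (!col %in% names(res)) res[[col]] <- NA_character_
  }
  res$or <- exp(res$beta)
  res$or_ci_low <- exp(res$ci_low)
  res$or_ci_high <- exp(res$ci_high)
  lead <- c("exposure", "outcome", "method", "nsnp", "beta", "se", "or",
            "ci_low", "ci_high", "or_ci_low", "or_ci_high", "pvalue")
  res <- res[, c(lead, setdiff(names(res), lead))]
  readr::write_tsv(res, path, progress = FALSE)
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
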