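#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param m Number of tests (`>= 1`).
#' @return `alpha / m`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 191) # 2.62e-4
#' bonferroni_threshold(0.05, 3)   # 0.0167
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  stopifnot(alpha > 0, alpha < 1)
  alpha / m
}

#' Screening-pipeline configuration
#'
#' Bundles the instrument-selection, harmonization and multiple-testing
#' settings consumed by [run_screen()].
#'
#' @param alpha Family-wise error rate for the Bonferroni correction
#'   (default 0.05).
#' @param p_threshold,clump_r2,clump_kb,ld Instrument-selection settings,
#'   see [select_instruments()].
#' @param palindrome_eaf_window See [harmonize()].
#' @param m_nominal Bonferroni denominator: the nominal panel size. Default
#'   `NULL` uses the number of exposures supplied to [run_screen()] (e.g.
#'   191 when screening a 191-metabolite panel, regardless of how many turn
#'   out to be analyzable).
#' @param use_m_tested If `TRUE`, divide by the number of analyzable
#'   exposures instead of the nominal panel size.
#' @param min_f Instrument sets with F below this are flagged (never
#'   auto-dropped; default 10).
#' @param n_boot Bootstrap resamples for median/mode SEs in multi-SNP fits.
#' @param seed Integer seed driving every stochastic step (bootstraps).
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(alpha = 0.05, p_threshold = 5e-8, clump_r2 = 0.001,
                          clump_kb = 10000, ld = NULL,
                          palindrome_eaf_window = 0.08, m_nominal = NULL,
                          use_m_tested = FALSE, min_f = 10, n_boot = 1000,
                          seed = 1L) {
  stopifnot(alpha > 0, alpha < 1)
  structure(list(alpha = alpha, p_threshold = p_threshold,
                 clump_r2 = clump_r2, clump_kb = clump_kb, ld = ld,
                 palindrome_eaf_window = palindrome_eaf_window,
                 m_nominal = m_nominal, use_m_tested = use_m_tested,
                 min_f = min_f, n_boot = n_boot, seed = as.integer(seed)),
            class = "screen_config")
}

# one exposure through instruments -> harmonization -> mr_fit;
# returns list(fit=..., reason="") or list(fit=NULL, reason=...)
.screen_one <- function(exposure, outcome, config, seed, exclude_snps = NULL) {
  if (!is.null(exclude_snps)) {
    keep <- !exposure$snp_id %in% exclude_snps
    exposure <- new_sumstats(tibble::as_tibble(exposure)[keep, ],
                             attr(exposure, "trait_name"),
                             attr(exposure, "trait_type") %||% "quantitative")
    if (nrow(exposure) == 0) {
      return(list(fit = NULL, instruments = NULL,
                  reason = "no instruments after exclusion"))
    }
  }
  ins <- select_instruments(exposure, p_threshold = config$p_threshold,
                            r2_threshold = config$clump_r2,
                            window_kb = config$clump_kb, ld = config$ld)
  if (ins$no_instruments) {
    return(list(fit = NULL, instruments = ins, reason = "no instruments"))
  }
  hd <- tryCatch(
    harmonize(new_sumstats(ins$snps, attr(exposure, "trait_name"),
                           attr(exposure, "trait_type") %||% "quantitative"),
              outcome,
              palindrome_eaf_window = config$palindrome_eaf_window),
    error = function(e) NULL)
  if (is.null(hd) || nrow(hd) == 0) {
    return(list(fit = NULL, instruments = ins,
                reason = "no instruments shared with outcome"))
  }
  fit <- mr_fit(hd, n_boot = config$n_boot, seed = seed)
  list(fit = fit, instruments = ins, reason = "")
}

#' Screen many exposures against an outcome
#'
#' Runs the full study design at any scale. For each exposure: select
#' instruments ([select_instruments()]), harmonize with the outcome
#' ([harmonize()]), estimate the causal effect (Wald ratio for a single
#' instrument, otherwise IVW with the effects model chosen from Cochran's
#' Q), and attach sensitivity diagnostics where the SNP count permits.
#' Exposures losing all instruments along the way are skipped with a
#' recorded reason, never fatal. The Bonferroni threshold is
#' `alpha / m_nominal` by default (the nominal panel size); hits are the
#' exposures whose primary p-value falls below it.
#'
#' When a replication outcome is supplied, each hit is re-estimated in the
#' second cohort and declared replicated if its p-value is below
#' `alpha / (number of hits)` with the same direction of effect. When a
#' mediator is supplied, two-step mediation MR runs for every hit that
#' survived replication (or every hit when no replication cohort is given):
#' step 1 re-targets the exposure's instruments at the mediator, step 2
#' estimates mediator -> outcome from the mediator's own instruments, and
#' [two_step_mediation()] combines them with the discovery estimate as the
#' total effect.
#'
#' The report is reproducible given the config seed.
#'
#' @param exposures A named list of exposure summary-statistics tibbles (or
#'   a single tibble).
#' @param outcome Outcome summary statistics.
#' @param replication Optional replication-cohort outcome summary stats.
#' @param mediator Optional mediator summary stats.
#' @param config A [screen_config()].
#' @return An object of class `mr_screen`: `results` (per-exposure tibble
#'   with primary estimate, sensitivity columns, instrument strength and
#'   skip reasons), `m_tested`, `m_nominal`, `bonferroni_threshold`,
#'   `hits`, `replication`, `mediation`, `config`.
#' @export
run_screen <- function(exposures, outcome, replication = NULL,
                       mediator = NULL, config = screen_config()) {
  if (is.data.frame(exposures)) exposures <- list(exposures)
  stopifnot(length(exposures) >= 1)
  names(exposures) <- purrr::imap_chr(
    exposures, ~ attr(.x, "trait_name") %||% paste0("exposure_", .y))

  runs <- purrr::imap(exposures, function(exp, nm) {
    .screen_one(exp, outcome, config, seed = config$seed + match(nm, names(exposures)))
  })

  if (all(purrr::map_lgl(runs, ~ is.null(.x$fit)))) {
    diag <- paste(names(runs), purrr::map_chr(runs, "reason"),
                  sep = ": ", collapse = "; ")
    stop("no exposure yields analyzable instruments [", diag, "]", call. = FALSE)
  }

  results <- purrr::imap_dfr(runs, function(r, nm) {
    if (is.null(r$fit)) {
      return(tibble::tibble(exposure = nm, skipped = TRUE,
                            skip_reason = r$reason))
    }
    g <- glance(r$fit)
    g$exposure <- nm
    g$skipped <- FALSE
    g$skip_reason <- ""
    g$f_statistic <- r$instruments$f_statistic
    g$weak_instruments <- isTRUE(r$instruments$f_statistic < config$min_f)
    g
  })

  m_tested <- sum(!results$skipped)
  m_nominal <- config$m_nominal %||% length(exposures)
  m <- if (config$use_m_tested) m_tested else m_nominal
  thr <- bonferroni_threshold(config$alpha, m)
  hits <- results$exposure[!results$skipped & !is.na(results$pvalue) &
                             results$pvalue < thr]

  replication_tbl <- NULL
  surviving <- hits
  if (!is.null(replication) && length(hits) > 0) {
    rep_thr <- bonferroni_threshold(config$alpha, length(hits))
    replication_tbl <- purrr::map_dfr(hits, function(h) {
      disc_beta <- results$beta[results$exposure == h]
      r <- .screen_one(exposures[[h]], replication, config,
                       seed = config$seed + 10000L + match(h, hits))
      if (is.null(r$fit)) {
        return(tibble::tibble(exposure = h, beta = NA_real_, se = NA_real_,
                              pvalue = NA_real_, replicated = FALSE,
                              direction_consistent = NA))
      }
      p <- r$fit$estimates[1, ]
      tibble::tibble(
        exposure = h, beta = p$beta, se = p$se, pvalue = p$pvalue,
        direction_consistent = sign(p$beta) == sign(disc_beta),
        replicated = p$pvalue < rep_thr & sign(p$beta) == sign(disc_beta))
    })
    surviving <- replication_tbl$exposure[replication_tbl$replicated]
  }

  mediation_tbl <- NULL
  if (!is.null(mediator) && length(surviving) > 0) {
    mediation_tbl <- purrr::map_dfr(surviving, function(h) {
      cfg_h <- config
      cfg_h$seed <- config$seed + 30000L + match(h, surviving)
      med <- tryCatch(
        mr_mediation(exposures[[h]], mediator, outcome, config = cfg_h),
        error = function(e) tibble::tibble(flag = conditionMessage(e)))
      dplyr::bind_cols(tibble::tibble(exposure = h), med)
    })
  }

  structure(list(results = results, m_tested = m_tested,
                 m_nominal = m_nominal, bonferroni_threshold = thr,
                 hits = hits, replication = replication_tbl,
                 mediation = mediation_tbl, config = config),
            class = "mr_screen")
}

#' @export
print.mr_screen <- function(x, ...) {
  cat("<mr_screen>", nrow(x$results), "exposures (", x$m_tested, "analyzable ),",
      "Bonferroni threshold", signif(x$bonferroni_threshold, 3), "\n")
  cat("hits:", if (length(x$hits)) paste(x$hits, collapse = ", ") else "none", "\n")
  if (!is.null(x$replication)) {
    cat("replicated:", sum(x$replication$replicated), "of", nrow(x$replication), "\n")
  }
  if (!is.null(x$mediation)) cat("mediation rows:", nrow(x$mediation), "\n")
  invisible(x)
}

#' Tidy the per-exposure screening results
#'
#' @param x An `mr_screen` object.
#' @param ... Unused.
#' @return The per-exposure results tibble with a logical `hit` column.
#' @method tidy mr_screen
#' @export
tidy.mr_screen <- function(x, ...) {
  dplyr::mutate(x$results, hit = .data$exposure %in% x$hits)
}

#' One-row summary of a screening run
#'
#' @param x An `mr_screen` object.
#' @param ... Unused.
#' @return A one-row tibble: `m_nominal`, `m_tested`,
#'   `bonferroni_threshold`, `n_hits`, `n_replicated`, `n_mediated`.
#' @method glance mr_screen
#' @export
glance.mr_screen <- function(x, ...) {
  tibble::tibble(
    m_nominal = x$m_nominal, m_tested = x$m_tested,
    bonferroni_threshold = x$bonferroni_threshold,
    n_hits = length(x$hits),
    n_replicated = if (is.null(x$replication)) NA_integer_ else
      sum(x$replication$replicated),
    n_mediated = if (is.null(x$mediation)) NA_integer_ else
      nrow(x$mediation))
}
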