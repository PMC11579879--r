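#' Scatter plot of an MR fit
#'
#' Per-SNP exposure effects against outcome effects with +/- 1 SE error
#' bars, overlaid with the fitted slope of each multi-SNP estimator (the
#' IVW line through the origin, the Egger line with its intercept, and the
#' weighted-median slope where available).
#'
#' @param object An `mr_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mr_fit
#' @export
autoplot.mr_fit <- function(object, ...) {
  d <- tibble::as_tibble(object$data)
  sgn <- ifelse(d$beta_exp < 0, -1, 1)
  d$bx <- sgn * d$beta_exp
  d$by <- sgn * d$beta_out
  est <- object$estimates
  lines <- dplyr::filter(
    est, !is.na(.data$beta),
    .data$method %in% c("ivw_fixed", "ivw_random", "egger", "weighted_median"))
  lines$intercept <- ifelse(lines$method == "egger", lines$egger_intercept, 0)
  lines$intercept[is.na(lines$intercept)] <- 0

  ggplot2::ggplot(d, ggplot2::aes(x = .data$bx, y = .data$by)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$by - .data$se_out,
                                        ymax = .data$by + .data$se_out),
                           linewidth = 0.3, colour = "grey60", width = 0) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$bx - .data$se_exp,
                                         xmax = .data$bx + .data$se_exp),
                            linewidth = 0.3, colour = "grey60", height = 0) +
    ggplot2::geom_point(size = 1.8) +
    ggplot2::geom_abline(
      data = lines,
      ggplot2::aes(slope = .data$beta, intercept = .data$intercept,
                   colour = .data$method)) +
    ggplot2::labs(x = "SNP effect on exposure", y = "SNP effect on outcome",
                  colour = "method",
                  title = paste(object$exposure, "→", object$outcome)) +
    ggplot2::theme_minimal()
}

#' Forest plot of per-exposure causal estimates
#'
#' The screening analogue of a forest plot: one row per analyzable
#' exposure, the primary estimate (Wald ratio or IVW) with its 95% CI on
#' the log-odds scale, hits highlighted.
#'
#' @param screen An `mr_screen` object from [run_screen()].
#' @return A ggplot object.
#' @export
plot_screen_forest <- function(screen) {
  d <- dplyr::filter(tidy(screen), !.data$skipped)
  d$ci_low <- d$beta - Z95 * d$se
  d$ci_high <- d$beta + Z95 * d$se
  ggplot2::ggplot(d, ggplot2::aes(x = .data$beta,
                                  y = stats::reorder(.data$exposure, .data$beta),
                                  colour = .data$hit)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high), height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "causal estimate (log-odds per unit exposure)",
                  y = NULL, colour = "Bonferroni hit") +
    ggplot2::theme_minimal()
}

#' @rdname plot_screen_forest
#' @param object An `mr_screen` object.
#' @param ... Unused.
#' @method autoplot mr_screen
#' @export
autoplot.mr_screen <- function(object, ...) plot_screen_forest(object)
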