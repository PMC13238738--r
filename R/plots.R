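#' Plot a region-call table
#'
#' Volcano-style view of one sample: enrichment score against
#' `-log10(padj)`, coloured by the presence call, with the calling
#' thresholds drawn as dashed lines. Blacklisted regions (call `NA`) are
#' shown in grey.
#'
#' @param object A `region_calls` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.region_calls <- function(object, ...) {
  params <- attr(object, "params") %||% list(score_min = 1.5, fdr_max = 0.25)
  df <- as_tibble(object)
  df$status <- factor(
    dplyr::case_when(is.na(df$call) ~ "blacklisted",
                     df$call == 1L ~ "present",
                     TRUE ~ "absent"),
    levels = c("absent", "present", "blacklisted"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score,
                                   y = -log10(pmax(.data$padj, 1e-300)),
                                   colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.6, size = 1, na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = params$score_min, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(params$fdr_max), linetype = "dashed") +
    ggplot2::scale_colour_manual(
      values = c(absent = "grey40", present = "firebrick", blacklisted = "grey80"),
      drop = FALSE) +
    ggplot2::labs(x = "enrichment score (log2 obs/exp)",
                  y = expression(-log[10] ~ "FDR-adjusted p"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a two-sample comparison
#'
#' Scatter of per-region enrichment scores, sample A against baseline B,
#' coloured by state transition when present.
#'
#' @param object A `region_comparison` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.region_comparison <- function(object, ...) {
  df <- as_tibble(object)
  aes <- if ("transition" %in% names(df)) {
    ggplot2::aes(x = .data$score_b, y = .data$score_a, colour = .data$transition)
  } else {
    ggplot2::aes(x = .data$score_b, y = .data$score_a)
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6, size = 1, na.rm = TRUE) +
    ggplot2::labs(x = "enrichment score (baseline B)",
                  y = "enrichment score (A)") +
    ggplot2::theme_minimal()
}

#' Plot a fitted background model
#'
#' Histogram of genome-tile counts with the fitted Negative Binomial (or
#' Poisson, in the infinite-dispersion limit) probability mass overlaid.
#'
#' @param object A `background_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.background_model <- function(object, ...) {
  tab <- object$count_table
  df <- tibble(count = as.integer(names(tab)),
               freq = as.integer(tab) / sum(tab))
  grid <- tibble(count = seq(min(df$count), max(df$count)))
  grid$pmf <- if (is.infinite(object$theta)) {
    stats::dpois(grid$count, object$lambda_g)
  } else {
    stats::dnbinom(grid$count, mu = object$lambda_g, size = object$theta)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$count, y = .data$freq)) +
    ggplot2::geom_col(fill = "grey70", width = 0.9) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$pmf),
                       colour = "firebrick") +
    ggplot2::labs(x = "midpoints per tile", y = "frequency") +
    ggplot2::theme_minimal()
}
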