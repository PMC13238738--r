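#' One-sided Negative Binomial tail probability
#'
#' The enrichment p-value for a region: `p = P(Y >= y)` with
#' `Y ~ NB(mu = lambda_t, size = theta)`, computed via the survival function
#' at `y - 1` for numerical accuracy. `theta = Inf` uses the Poisson tail
#' (the NB model's limiting case). Degenerate expectations follow the
#' convention `lambda_t = 0, y > 0 -> p = 0`; `y = 0 -> p = 1` (the whole
#' support).
#'
#' @param y Observed counts (non-negative integers; vectorized).
#' @param lambda_t Expected counts under the null (>= 0; recycled).
#' @param theta NB size parameter (> 0) or `Inf` for Poisson.
#' @return p-values in `[0, 1]`.
#' @export
nb_tail_pvalue <- function(y, lambda_t, theta) {
  if (any(y < 0) || any(lambda_t < 0)) abort("y and lambda_t must be non-negative")
  if (length(theta) != 1L || is.na(theta) || theta <= 0) {
    abort("theta must be a single positive value or Inf")
  }
  n <- max(length(y), length(lambda_t))
  y <- rep_len(y, n)
  mu <- rep_len(lambda_t, n)
  p <- numeric(n)
  zero_mu <- mu == 0
  p[zero_mu] <- ifelse(y[zero_mu] == 0, 1, 0)
  if (any(!zero_mu)) {
    yy <- y[!zero_mu]
    mm <- mu[!zero_mu]
    p[!zero_mu] <- if (is.infinite(theta)) {
      ppois(yy - 1, lambda = mm, lower.tail = FALSE)
    } else {
      pnbinom(yy - 1, mu = mm, size = theta, lower.tail = FALSE)
    }
  }
  p[y == 0] <- 1
  p
}

#' Benjamini-Hochberg adjustment in input order
#'
#' Step-up FDR adjustment across all testable regions of one experiment.
#' `NA` entries (blacklisted regions) are excluded from the correction --
#' they neither receive an adjusted value nor inflate the number of tests --
#' and stay `NA` in the output.
#'
#' @param p Numeric p-values in `[0, 1]`, `NA` allowed.
#' @return Adjusted p-values, same length and order, clamped to `[0, 1]`.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) abort("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Log2 enrichment score
#'
#' `s = log2((y + epsilon) / (lambda_t + epsilon))`: the observed/expected
#' log-ratio, finite for all counts thanks to the pseudo-count. With the
#' default `epsilon = 1` the score of an empty region against an empty
#' expectation is exactly 0.
#'
#' @param y Observed counts.
#' @param lambda_t Expected counts.
#' @param epsilon Pseudo-count (> 0, default 1).
#' @return Scores in log2 units.
#' @export
enrichment_score <- function(y, lambda_t, epsilon = 1) {
  if (epsilon <= 0) abort("epsilon must be positive")
  log2((y + epsilon) / (lambda_t + epsilon))
}

#' Standardised deviation from the expected background
#'
#' z-score under the NB mean-variance relation:
#' `z = (y - lambda_t) / sqrt(lambda_t + lambda_t^2 / theta)`, reducing to
#' `(y - lambda_t) / sqrt(lambda_t)` in the Poisson limit. `NA` when
#' `lambda_t = 0` (no finite standardisation exists).
#'
#' @inheritParams nb_tail_pvalue
#' @return z-scores (sign follows `y - lambda_t`).
#' @export
nb_z_score <- function(y, lambda_t, theta) {
  v <- if (is.infinite(theta)) lambda_t else lambda_t + lambda_t^2 / theta
  z <- (y - lambda_t) / sqrt(v)
  z[lambda_t == 0] <- NA_real_
  z
}

#' Binary presence call
#'
#' A mark is called present (1) in a region when the enrichment score
#' strictly exceeds `score_min` and the BH-adjusted p-value is strictly below
#' `fdr_max`; otherwise absent (0). Blacklisted regions are `NA`. Defaults
#' (`score_min = 1.5`, `fdr_max = 0.25`) balance sensitivity and specificity
#' for broad promoter-associated marks.
#'
#' @param score Enrichment scores.
#' @param padj BH-adjusted p-values.
#' @param blacklisted Logical flags.
#' @param score_min Score threshold (strict `>`).
#' @param fdr_max FDR threshold (strict `<`).
#' @return Integer vector in `{0, 1, NA}`.
#' @export
call_presence <- function(score, padj, blacklisted = FALSE,
                          score_min = 1.5, fdr_max = 0.25) {
  n <- max(length(score), length(padj), length(blacklisted))
  score <- rep_len(score, n)
  padj <- rep_len(padj, n)
  blacklisted <- rep_len(blacklisted, n)
  call <- as.integer(score > score_min & padj < fdr_max)
  call[blacklisted] <- NA_integer_
  call
}

#' Call chromatin status over a region set
#'
#' End-to-end single-sample inference: count fragment midpoints in genome
#' tiles and target windows, fit the global NB background for the experiment
#' (and the control, when supplied), derive per-region modulation factors and
#' expected counts, then test, score and call every region.
#'
#' @param regions Region tibble from [read_regions_bed()] (optionally already
#'   flagged via [flag_blacklisted()]).
#' @param treatment Path to the experiment alignment file, or a midpoint
#'   track from [extract_fragment_midpoints()].
#' @param sizes Chromosome-sizes tibble.
#' @param control Optional matched control: path or midpoint track. Without
#'   it, all modulation factors are 1.
#' @param blacklist Optional blacklist tibble; applied to both the region
#'   flags and the background tiling.
#' @param tile_width Background tile width in bp; defaults to the region
#'   width W so the background mean is directly comparable to window counts.
#' @param epsilon Pseudo-count for the enrichment score (default 1).
#' @param score_min,fdr_max Calling thresholds (defaults 1.5 and 0.25).
#' @param mode Alignment mode passed to [extract_fragment_midpoints()].
#' @param min_mapq Minimum mapping quality for fragments.
#'
#' @return A tibble of class `region_calls` with one row per region, in
#'   region order: `chrom`, `start`, `end`, `name`, `blacklisted`, `y`,
#'   `y_ctrl`, `m`, `lambda_t`, `p`, `padj`, `score`, `z`, `call`.
#'   Blacklisted regions carry `NA` in `p`, `padj` and `call`. Attributes:
#'   `background` (the treatment `background_model`), `background_control`
#'   (or `NULL`), `params`.
#' @export
call_regions <- function(regions, treatment, sizes, control = NULL,
                         blacklist = NULL, tile_width = NULL, epsilon = 1,
                         score_min = 1.5, fdr_max = 0.25,
                         mode = "auto", min_mapq = 0) {
  width <- unique(regions$end - regions$start)
  if (length(width) != 1L) abort("regions must all have the same width")
  tile_width <- tile_width %||% width

  if (!is.null(blacklist)) regions <- flag_blacklisted(regions, blacklist)
  if (is.null(regions$blacklisted)) regions$blacklisted <- FALSE

  trt <- as_midpoint_track(treatment, mode = mode, min_mapq = min_mapq)
  check_track_chromosomes(trt, regions)
  tiles <- tile_genome(sizes, tile_width, blacklist)

  bg <- fit_background(count_midpoints(tiles, trt), role = "treatment",
                       source = attr(trt, "source") %||% "treatment")

  out <- count_midpoints(regions, trt, col = "y")
  if (!is.null(control)) {
    ctrl <- as_midpoint_track(control, mode = mode, min_mapq = min_mapq)
    bg_ctrl <- fit_background(count_midpoints(tiles, ctrl), role = "control",
                              source = attr(ctrl, "source") %||% "control")
    out <- count_midpoints(out, ctrl, col = "y_ctrl")
    out$m <- compute_modulation(out$y_ctrl, bg_ctrl$lambda_g)
  } else {
    bg_ctrl <- NULL
    out$y_ctrl <- NA_integer_
    out$m <- 1
  }
  out$lambda_t <- expected_signal(out$m, bg)
  out$p <- nb_tail_pvalue(out$y, out$lambda_t, bg$theta)
  out$p[out$blacklisted] <- NA_real_
  out$padj <- bh_adjust(out$p)
  out$score <- enrichment_score(out$y, out$lambda_t, epsilon)
  out$z <- nb_z_score(out$y, out$lambda_t, bg$theta)
  out$call <- call_presence(out$score, out$padj, out$blacklisted,
                            score_min, fdr_max)
  attr(out, "background") <- bg
  attr(out, "background_control") <- bg_ctrl
  attr(out, "params") <- list(width = width, tile_width = tile_width,
                              epsilon = epsilon, score_min = score_min,
                              fdr_max = fdr_max, min_mapq = min_mapq)
  class(out) <- c("region_calls", class(out))
  out
}

as_midpoint_track <- function(x, mode = "auto", min_mapq = 0) {
  if (is.character(x) && length(x) == 1L) {
    return(extract_fragment_midpoints(x, mode = mode, min_mapq = min_mapq))
  }
  if (is.data.frame(x) && all(c("chrom", "pos") %in% names(x))) return(x)
  abort("treatment/control must be an alignment file path or a midpoint track")
}

check_track_chromosomes <- function(track, regions) {
  missing <- setdiff(unique(regions$chrom), unique(track$chrom))
  if (length(missing) > 0L && nrow(track) > 0L) {
    warn(paste0("no fragments on chromosome(s) ", paste(missing, collapse = ", "),
                "; their regions get zero counts"))
  }
  invisible(TRUE)
}

#' Summarise a region-call table
#'
#' @param x A `region_calls` tibble.
#' @param ... Unused.
#' @return One-row tibble: region counts, presence calls, blacklist count,
#'   background parameters.
#' @exportS3Method generics::glance
glance.region_calls <- function(x, ...) {
  bg <- attr(x, "background")
  tibble(
    n_regions = nrow(x),
    n_blacklisted = sum(x[["blacklisted"]] %||% logical()),
    n_called = sum(x[["call"]] == 1L, na.rm = TRUE),
    lambda_g = bg$lambda_g %||% NA_real_,
    theta = bg$theta %||% NA_real_,
    with_control = !is.null(attr(x, "background_control"))
  )
}

#' @export
print.region_calls <- function(x, ...) {
  g <- glance.region_calls(x)
  cat(sprintf("Region calls: %d regions (%d blacklisted), %d called present\n",
              g$n_regions, g$n_blacklisted, g$n_called))
  if (!is.na(g$lambda_g)) {
    cat(sprintf("Background: lambda_g = %.3f, theta = %s, control %s\n",
                g$lambda_g,
                if (is.infinite(g$theta)) "Inf (Poisson)" else sprintf("%.3f", g$theta),
                if (g$with_control) "used" else "absent"))
  }
  NextMethod()
}

#' Write a region-call table to TSV
#'
#' Columns: `chrom`, `start`, `end`, `name`, `y`, `y_ctrl`, `m`, `lambda_t`,
#' `p`, `padj`, `score`, `z`, `call`, and `expression` when present. The
#' first three columns are BED-compatible; `NA` is written literally; floats
#' are formatted at 6 significant digits.
#'
#' @param calls A `region_calls` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  cols <- intersect(
    c("chrom", "start", "end", "name", "y", "y_ctrl", "m", "lambda_t",
      "p", "padj", "score", "z", "call", "expression"),
    names(calls))
  out <- as_tibble(calls)[, cols]
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(v) signif(v, 6))
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read back a region-call TSV
#'
#' @param path Path written by [write_calls_tsv()].
#' @return A tibble (class `region_calls`, without background attributes).
#' @export
read_calls_tsv <- function(path) {
  out <- readr::read_tsv(path, na = "NA", show_col_types = FALSE, progress = FALSE)
  class(out) <- c("region_calls", class(out))
  out
}
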