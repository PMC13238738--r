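#' Estimate the genome-wide background rate
#'
#' The background rate lambda_g is the arithmetic mean fragment-midpoint
#' count per non-blacklisted genome tile, zero-count tiles included (dropping
#' them would bias the rate upward in sparse libraries).
#'
#' @param counts Integer vector of per-tile counts (non-blacklisted tiles
#'   only; [tile_genome()] already removes blacklisted tiles).
#' @param role `"treatment"` or `"control"`. A rate of zero is an error for a
#'   control (it would divide the modulation factor) and a warning for a
#'   treatment.
#' @return The mean count per tile (double).
#' @export
estimate_lambda_g <- function(counts, role = c("treatment", "control")) {
  role <- match.arg(role)
  if (length(counts) == 0L) abort("no tiles: cannot estimate background rate")
  if (any(counts < 0)) abort("negative tile counts")
  lg <- mean(counts)
  if (lg == 0) {
    if (role == "control") {
      abort("control background rate is zero; modulation factors are undefined")
    }
    warn("treatment background rate is zero: no fragments in any tile")
  }
  lg
}

#' Estimate the global Negative Binomial dispersion
#'
#' Method-of-moments estimate of the NB size parameter theta from genome-wide
#' tile counts: `theta = mu^2 / (s^2 - mu)` with `mu` the tile mean and `s^2`
#' the unbiased sample variance. When the counts are not overdispersed
#' (`s^2 <= mu`) the estimate diverges and `Inf` is returned, under which the
#' downstream tail test reduces to a Poisson test. Estimates above `1e6` are
#' clamped to `Inf` for numerical stability of the NB tail.
#'
#' A single global theta is shared across regions within an experiment: with
#' no replicates, overdispersion is attributed to library-wide technical
#' variability rather than estimated per region.
#'
#' @param counts Integer vector of per-tile counts, length >= 2.
#' @return `theta` (double > 0) or `Inf` for the Poisson limit.
#' @export
estimate_dispersion <- function(counts) {
  if (length(counts) < 2L) abort("need at least 2 tiles to estimate dispersion")
  mu <- mean(counts)
  s2 <- var(counts)
  if (s2 <= mu || mu == 0) return(Inf)
  theta <- mu^2 / (s2 - mu)
  if (theta > 1e6) Inf else theta
}

#' Fit the global background model from tile counts
#'
#' Convenience wrapper combining [estimate_lambda_g()] and
#' [estimate_dispersion()] on a counted genome tiling.
#'
#' @param tiles Tibble of tiles with a count column (see [count_midpoints()]).
#' @param count_col Name of the count column (default `"count"`).
#' @param role `"treatment"` or `"control"` (zero-rate policy; see
#'   [estimate_lambda_g()]).
#' @param source Experiment label recorded in the model.
#' @return An object of class `background_model`: a list with `lambda_g`,
#'   `theta` (`Inf` = Poisson), `tile_width`, `n_tiles`, `source`, and
#'   `count_table` (the tile-count frequency table, kept for diagnostics and
#'   plotting).
#' @export
fit_background <- function(tiles, count_col = "count",
                           role = c("treatment", "control"), source = NA_character_) {
  role <- match.arg(role)
  counts <- tiles[[count_col]]
  if (is.null(counts)) abort(paste0("no column '", count_col, "' in tiles"))
  model <- structure(
    list(
      lambda_g = estimate_lambda_g(counts, role = role),
      theta = estimate_dispersion(counts),
      tile_width = attr(tiles, "tile_width") %||% NA_integer_,
      n_tiles = length(counts),
      source = source,
      count_table = table(counts)
    ),
    class = "background_model"
  )
  model
}

#' @export
print.background_model <- function(x, ...) {
  cat("Global background model", if (!is.na(x$source)) paste0("(", x$source, ")"), "\n")
  cat(sprintf("  lambda_g: %.4f midpoints per %s-bp tile (N = %d tiles)\n",
              x$lambda_g, format(x$tile_width), x$n_tiles))
  cat(sprintf("  theta:    %s\n",
              if (is.infinite(x$theta)) "Inf (Poisson)" else sprintf("%.4f", x$theta)))
  invisible(x)
}

#' Tidy a background model
#'
#' @param x A `background_model`.
#' @param ... Unused.
#' @return A one-row tibble with `lambda_g`, `theta`, `poisson_limit`,
#'   `tile_width`, `n_tiles`, `source`.
#' @exportS3Method generics::tidy
tidy.background_model <- function(x, ...) {
  tibble(lambda_g = x$lambda_g, theta = x$theta,
         poisson_limit = is.infinite(x$theta),
         tile_width = as.integer(x$tile_width), n_tiles = x$n_tiles,
         source = x$source)
}

#' @rdname tidy.background_model
#' @exportS3Method generics::glance
glance.background_model <- function(x, ...) tidy.background_model(x, ...)

#' Serialize a background model to JSON
#'
#' Writes a small provenance sidecar (`lambda_g`, `theta` or `"inf"`,
#' `tile_width`, `n_tiles`, `source`).
#'
#' @param model A `background_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_background_json <- function(model, path) {
  obj <- list(
    lambda_g = model$lambda_g,
    theta = if (is.infinite(model$theta)) "inf" else model$theta,
    tile_width = as.integer(model$tile_width),
    n_tiles = model$n_tiles,
    source = model$source
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Control-based modulation factors
#'
#' Scales the global background into a region-local expectation using the
#' matched control: `m_i = max(1, y_ctrl_i / lambda_g_ctrl)`. The lower bound
#' of one prevents deflation of the expected background in regions with low
#' control coverage; without a control every `m_i` is 1 and inference falls
#' back to the global background alone.
#'
#' @param control_counts Integer vector of per-region control counts, or
#'   `NULL` when no control is available.
#' @param lambda_g_ctrl Control background rate (> 0), or `NULL`.
#' @param n Number of regions (required when `control_counts` is `NULL`).
#' @return Numeric vector of modulation factors, all >= 1.
#' @export
compute_modulation <- function(control_counts, lambda_g_ctrl, n = NULL) {
  if (is.null(control_counts)) {
    if (is.null(n)) abort("n is required when no control counts are given")
    return(rep(1, n))
  }
  if (is.null(lambda_g_ctrl) || lambda_g_ctrl <= 0) {
    abort("control background rate must be positive for modulation")
  }
  pmax(1, control_counts / lambda_g_ctrl)
}

#' Locally adjusted expected background
#'
#' `lambda_t_i = m_i * lambda_g`: the expected count in region i under the
#' null, integrating global library intensity with region-specific control
#' modulation.
#'
#' @param m Modulation factors from [compute_modulation()].
#' @param model A `background_model` (or a plain lambda_g scalar).
#' @return Numeric vector of expected counts, same length as `m`.
#' @export
expected_signal <- function(m, model) {
  lg <- if (inherits(model, "background_model")) model$lambda_g else model
  m * lg
}
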