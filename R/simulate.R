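#' Specify a synthetic chromatin profiling dataset
#'
#' Describes a toy genome with known ground truth: uniform background
#' fragments at a stated rate, enriched windows at stated fold-changes, and
#' an optional matched control whose coverage can be regionally distorted
#' (emulating copy-number bias). All randomness flows from the single seed.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths (bp).
#' @param width Region/tile width W in bp (default 2000, the promoter
#'   TSS +/- 1 kb geometry).
#' @param n_regions Number of target windows to place.
#' @param enriched Integer indices (into the region set) of enriched windows.
#' @param fold Fold-changes (>= 1) for the enriched windows, recycled to
#'   `length(enriched)`. The expected midpoint count of an enriched window is
#'   `fold * background_rate`.
#' @param background_rate Expected background midpoints per W-bp tile (> 0).
#' @param distortion Optional tibble (`chrom`, `start`, `end`, `multiplier`)
#'   of control-coverage distortion intervals; within each, control coverage
#'   is multiplied by `multiplier`.
#' @param distort_treatment If `TRUE`, the same distortion multipliers are
#'   also applied to the experiment library, as a genomic copy-number gain
#'   would inflate both libraries (default `FALSE`).
#' @param frag_len_mean,frag_len_sd Fragment length distribution (bp).
#' @param paired Emit proper read pairs (`TRUE`) or single-end reads.
#' @param overdispersion NB size parameter theta for gamma-mixed background
#'   rates (tile counts then follow NB(mu, theta)); `NULL` for plain Poisson
#'   backgrounds.
#' @param expression If `TRUE`, write an expression table correlated with
#'   enrichment (baseline noise plus `2 * log2(fold)`).
#' @param seed Integer random seed, recorded in the output manifest.
#' @return A validated list of class `simulation_spec`.
#' @export
simulation_spec <- function(chrom_lengths, width = 2000, n_regions = 100,
                            enriched = integer(), fold = numeric(),
                            background_rate = 20, distortion = NULL,
                            distort_treatment = FALSE,
                            frag_len_mean = 200, frag_len_sd = 20,
                            paired = TRUE, overdispersion = NULL,
                            expression = FALSE, seed = 1L) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    abort("chrom_lengths must be a named vector")
  }
  if (background_rate <= 0) abort("background_rate must be positive")
  fold <- rep_len(as.numeric(fold), length(enriched))
  if (any(fold < 1)) abort("fold-changes must be >= 1")
  if (length(enriched) > 0 && (any(enriched < 1) || any(enriched > n_regions))) {
    abort("enriched indices out of range")
  }
  if (!is.null(distortion)) {
    stopifnot(all(c("chrom", "start", "end", "multiplier") %in% names(distortion)),
              all(distortion$multiplier >= 1))
  }
  structure(list(
    chrom_lengths = chrom_lengths, width = as.integer(width),
    n_regions = as.integer(n_regions),
    enriched = as.integer(enriched), fold = fold,
    background_rate = background_rate, distortion = distortion,
    distort_treatment = isTRUE(distort_treatment),
    frag_len_mean = frag_len_mean, frag_len_sd = frag_len_sd,
    paired = isTRUE(paired), overdispersion = overdispersion,
    expression = isTRUE(expression), seed = as.integer(seed)
  ), class = "simulation_spec")
}

#' Place non-overlapping toy promoter windows
#'
#' Places `n` width-W windows at randomly sampled non-overlapping slots
#' (each slot is separated by at least W bp from its neighbours), named
#' `GENE0001`, `GENE0002`, ... in coordinate order. Deterministic under
#' `seed`.
#'
#' @param sizes Chromosome-sizes tibble (or named length vector).
#' @param width Window width W in bp.
#' @param n Number of windows.
#' @param seed Integer seed.
#' @return A region tibble (`chrom`, `start`, `end`, `name`, `blacklisted`).
#' @export
make_toy_promoters <- function(sizes, width, n, seed = 1L) {
  if (!is.data.frame(sizes)) {
    sizes <- tibble(chrom = names(sizes), length = as.integer(sizes))
  }
  slots <- bind_rows(lapply(seq_len(nrow(sizes)), function(i) {
    k <- sizes$length[i] %/% (2L * width)
    if (k == 0L) return(NULL)
    start <- (2L * width) * (seq_len(k) - 1L)
    tibble(chrom = sizes$chrom[i], start = start, end = start + as.integer(width))
  }))
  if (nrow(slots) < n) {
    abort(sprintf("cannot place %d non-overlapping windows of width %d: only %d slots",
                  n, width, nrow(slots)))
  }
  set.seed(seed)
  pick <- sort(sample.int(nrow(slots), n))
  out <- slots[pick, , drop = FALSE]
  out <- arrange(out, .data$chrom, .data$start)
  out$name <- sprintf("GENE%04d", seq_len(n))
  out$blacklisted <- FALSE
  out
}

#' Simulate a complete dataset with known ground truth
#'
#' Writes to `outdir`: `chrom.sizes`, `regions.bed` (fixed width W),
#' sorted+indexed experiment and control BAMs, a truth table TSV
#' (region, enriched flag, fold), an optional expression TSV, and a
#' `manifest.json` recording the spec and seed.
#'
#' Background fragments are placed uniformly at the stated per-tile rate
#' (gamma-mixed per tile when `overdispersion` is set, giving genuinely
#' NB-distributed tile counts). Each enriched region receives additional
#' fragments so its expected midpoint count is `fold * background_rate`. The
#' control receives background only, plus the distortion multipliers over
#' the stated intervals. Paired-end records are proper pairs whose outer
#' span equals the simulated fragment length; MAPQ is fixed at 60.
#'
#' @param spec A [simulation_spec()].
#' @param outdir Output directory (created if missing).
#' @param control Write a control library (default `TRUE`).
#' @return A named list manifest of written file paths, plus `regions`
#'   (tibble), `truth` (tibble) and `spec`.
#' @export
simulate_dataset <- function(spec, outdir, control = TRUE) {
  stopifnot(inherits(spec, "simulation_spec"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sizes <- tibble(chrom = names(spec$chrom_lengths),
                  length = as.integer(spec$chrom_lengths))

  regions <- make_toy_promoters(sizes, spec$width, spec$n_regions, spec$seed)
  truth <- tibble(name = regions$name, enriched = FALSE, fold = 1)
  truth$enriched[spec$enriched] <- TRUE
  truth$fold[spec$enriched] <- spec$fold

  # regions were placed under spec$seed; continue the stream for fragments
  set.seed(spec$seed + 1L)
  mids_exp <- simulate_background_midpoints(sizes, spec)
  if (spec$distort_treatment && !is.null(spec$distortion)) {
    mids_exp <- bind_rows(mids_exp, simulate_distortion_midpoints(spec))
  }
  if (length(spec$enriched) > 0L) {
    enr <- regions[spec$enriched, , drop = FALSE]
    extra <- rpois(nrow(enr), (truth$fold[spec$enriched] - 1) * spec$background_rate)
    mids_exp <- bind_rows(mids_exp, uniform_midpoints(enr, extra))
  }
  mids_ctrl <- NULL
  if (control) {
    mids_ctrl <- simulate_background_midpoints(sizes, spec)
    if (!is.null(spec$distortion)) {
      mids_ctrl <- bind_rows(mids_ctrl, simulate_distortion_midpoints(spec))
    }
  }

  sizes_path <- file.path(outdir, "chrom.sizes")
  readr::write_tsv(sizes, sizes_path, col_names = FALSE, progress = FALSE)
  regions_path <- file.path(outdir, "regions.bed")
  write_bed(regions, regions_path)
  truth_path <- file.path(outdir, "truth.tsv")
  readr::write_tsv(truth, truth_path, progress = FALSE)

  exp_path <- write_alignments(mids_exp, sizes, spec,
                               file.path(outdir, "experiment"))
  ctrl_path <- if (control) {
    write_alignments(mids_ctrl, sizes, spec, file.path(outdir, "control"))
  } else NULL

  expr_path <- NULL
  if (spec$expression) {
    expr <- tibble(name = truth$name,
                   expression = rnorm(nrow(truth), 5, 1) + 2 * log2(truth$fold))
    expr_path <- file.path(outdir, "expression.tsv")
    readr::write_tsv(expr, expr_path, progress = FALSE)
  }

  manifest <- list(
    chrom_sizes = sizes_path, regions = regions_path, truth = truth_path,
    experiment = exp_path, control = ctrl_path, expression = expr_path,
    n_fragments_experiment = nrow(mids_exp),
    n_fragments_control = if (control) nrow(mids_ctrl) else NA_integer_,
    seed = spec$seed
  )
  jsonlite::write_json(
    c(manifest[!vapply(manifest, is.null, logical(1))],
      list(spec = unclass(spec)[setdiff(names(spec), "distortion")])),
    file.path(outdir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
  c(manifest, list(regions_tbl = regions, truth_tbl = truth, spec = spec))
}

# background midpoints over whole chromosomes: per-tile counts (Poisson or
# gamma-mixed -> NB), positions uniform within the tile; the trailing
# partial tile is filled at the same rate scaled by its length
simulate_background_midpoints <- function(sizes, spec) {
  W <- spec$width
  mu <- spec$background_rate
  th <- spec$overdispersion
  out <- lapply(seq_len(nrow(sizes)), function(i) {
    L <- sizes$length[i]
    starts <- seq(0L, L - 1L, by = W)
    lens <- pmin(starts + W, L) - starts
    rate <- mu * lens / W
    if (!is.null(th)) rate <- rgamma(length(rate), shape = th, rate = th) * rate
    cnt <- rpois(length(rate), rate)
    pos <- unlist(lapply(which(cnt > 0L), function(k) {
      starts[k] + floor(runif(cnt[k]) * lens[k])
    }), use.names = FALSE)
    if (is.null(pos)) pos <- integer()
    tibble(chrom = sizes$chrom[i], pos = as.integer(pos))
  })
  bind_rows(out)
}

simulate_distortion_midpoints <- function(spec) {
  d <- spec$distortion
  W <- spec$width
  out <- lapply(seq_len(nrow(d)), function(i) {
    len <- d$end[i] - d$start[i]
    extra <- rpois(1, (d$multiplier[i] - 1) * spec$background_rate * len / W)
    tibble(chrom = d$chrom[i],
           pos = as.integer(d$start[i] + floor(runif(extra) * len)))
  })
  bind_rows(out)
}

uniform_midpoints <- function(intervals, counts) {
  out <- lapply(seq_len(nrow(intervals)), function(i) {
    len <- intervals$end[i] - intervals$start[i]
    tibble(chrom = intervals$chrom[i],
           pos = as.integer(intervals$start[i] + floor(runif(counts[i]) * len)))
  })
  bind_rows(out)
}

# Fragments around each midpoint are written as SAM then converted to a
# coordinate-sorted, indexed BAM. Paired mode emits one proper pair per
# fragment (flags 99/147, TLEN = +/- fragment length); single mode one read
# spanning the fragment. Midpoints are exactly recoverable: the fragment
# starts at mid - floor(len/2).
write_alignments <- function(mids, sizes, spec, stem) {
  chrom_len <- setNames(sizes$length, sizes$chrom)
  n <- nrow(mids)
  len <- pmax(20L, as.integer(round(rnorm(n, spec$frag_len_mean, spec$frag_len_sd))))
  len <- pmin(len, as.integer(chrom_len[mids$chrom]))
  start <- mids$pos - len %/% 2L
  start <- pmax(0L, pmin(start, as.integer(chrom_len[mids$chrom]) - len))
  rl <- pmin(50L, len)

  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", sizes$chrom, sizes$length))
  sam_path <- paste0(stem, ".sam")
  if (n == 0L) {
    writeLines(header, sam_path)
  } else if (spec$paired) {
    qname <- sprintf("frag%07d", seq_len(n))
    pos1 <- start + 1L
    pos2 <- start + len - rl + 1L
    r1 <- sprintf("%s\t99\t%s\t%d\t60\t%dM\t=\t%d\t%d\t*\t*",
                  qname, mids$chrom, pos1, rl, pos2, len)
    r2 <- sprintf("%s\t147\t%s\t%d\t60\t%dM\t=\t%d\t-%d\t*\t*",
                  qname, mids$chrom, pos2, rl, pos1, len)
    writeLines(c(header, rbind(r1, r2)), sam_path)
  } else {
    qname <- sprintf("read%07d", seq_len(n))
    rec <- sprintf("%s\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*",
                   qname, mids$chrom, start + 1L, len)
    writeLines(c(header, rec), sam_path)
  }
  bam <- Rsamtools::asBam(sam_path, destination = stem, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam_path)
  bam
}
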