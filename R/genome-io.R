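#' Read a chromosome-sizes table
#'
#' Reads the standard two-column `chrom.sizes` format (chromosome name,
#' length in bp, whitespace- or tab-delimited, no header) used throughout
#' genomics tooling.
#'
#' @param path Path to a two-column text file.
#'
#' @return A tibble with columns `chrom` (character) and `length` (integer bp),
#'   preserving file order.
#'
#' @examples
#' f <- tempfile(fileext = ".sizes")
#' writeLines(c("chr1\t5000", "chr2\t3000"), f)
#' read_chrom_sizes(f)
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("chromosome-sizes file not found: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    abort("chromosome-sizes file is empty")
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(fields) != 2L)
  if (length(bad) > 0L) {
    abort(paste0("malformed chromosome-sizes line ", bad[1], ": expected 2 columns, got ",
                 lengths(fields)[bad[1]]))
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  len <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  if (anyNA(len) || any(len != floor(len))) {
    abort("chromosome lengths must be integers")
  }
  if (any(len <= 0)) {
    abort(paste0("non-positive chromosome length for: ",
                 paste(chrom[len <= 0], collapse = ", ")))
  }
  if (anyDuplicated(chrom)) {
    abort(paste0("duplicate chromosome name: ",
                 paste(unique(chrom[duplicated(chrom)]), collapse = ", ")))
  }
  tibble(chrom = chrom, length = as.integer(len))
}

#' Read fixed-width target regions from a BED file
#'
#' Reads a BED3/BED4 file of target windows (for example promoters defined as
#' TSS +/- 1 kb) and enforces the fixed-width contract: every region must be
#' exactly `width` bp. Coordinates are kept in BED convention (0-based,
#' half-open) throughout the package.
#'
#' Regions on chromosomes absent from `sizes`, or extending past a chromosome
#' end, are dropped with a warning rather than clipped, since clipping would
#' break the fixed-width invariant. Any region whose width differs from
#' `width` is an error. Duplicate names receive a numeric suffix so names are
#' unique; missing names default to `region_<k>`.
#'
#' @param path Path to a BED3+ file (track/browser lines are skipped).
#' @param width Required region width W in bp.
#' @param sizes Chromosome-sizes tibble from [read_chrom_sizes()].
#'
#' @return A tibble with columns `chrom`, `start`, `end`, `name`,
#'   `blacklisted` (all `FALSE`; see [flag_blacklisted()]).
#' @export
read_regions_bed <- function(path, width, sizes) {
  stopifnot(is.numeric(width), width > 0)
  gr <- read_bed_intervals(path)
  if (nrow(gr) == 0L) {
    abort(paste0("region BED file contains no intervals: ", path))
  }
  w <- gr$end - gr$start
  if (any(w != width)) {
    k <- which(w != width)[1]
    abort(sprintf(
      "region %d (%s:%d-%d) has width %d; all regions must have width %d",
      k, gr$chrom[k], gr$start[k], gr$end[k], w[k], as.integer(width)))
  }
  if (is.null(gr$name)) gr$name <- NA_character_
  gr$name <- ifelse(is.na(gr$name) | gr$name == "" | gr$name == ".",
                    paste0("region_", seq_len(nrow(gr))), gr$name)

  len <- setNames(sizes$length, sizes$chrom)
  known <- gr$chrom %in% sizes$chrom
  inb <- known & gr$end <= len[gr$chrom] & gr$start >= 0
  inb[is.na(inb)] <- FALSE
  if (any(!inb)) {
    warn(sprintf("dropped %d region(s) on unknown chromosomes or out of bounds (e.g. %s)",
                 sum(!inb), gr$name[which(!inb)[1]]))
    gr <- gr[inb, , drop = FALSE]
  }
  if (nrow(gr) == 0L) {
    abort("no regions remain after bounds filtering")
  }
  gr$name <- make_unique_names(gr$name)
  tibble(chrom = gr$chrom, start = as.integer(gr$start), end = as.integer(gr$end),
         name = gr$name, blacklisted = FALSE)
}

#' Read a blacklist BED file
#'
#' @param path Path to a BED3+ file of intervals to exclude (e.g. the ENCODE
#'   blacklist). Coordinates are 0-based half-open.
#' @return A tibble with columns `chrom`, `start`, `end` (may have zero rows).
#' @export
read_blacklist_bed <- function(path) {
  gr <- read_bed_intervals(path)
  tibble(chrom = gr$chrom, start = as.integer(gr$start), end = as.integer(gr$end))
}

# rtracklayer does the BED parsing (track-line skipping, 1-based GRanges);
# convert back to the BED 0-based half-open convention used internally.
read_bed_intervals <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("BED file not found: ", path))
  }
  path <- normalise_bed_columns(path)
  gr <- tryCatch(
    rtracklayer::import(path, format = "BED"),
    error = function(e) abort(paste0("failed to parse BED file ", path, ": ",
                                     conditionMessage(e)))
  )
  df <- as.data.frame(gr)
  out <- tibble(
    chrom = as.character(df$seqnames),
    start = as.integer(df$start) - 1L,
    end = as.integer(df$end)
  )
  if (!is.null(df$name)) out$name <- as.character(df$name)
  out
}

# BED files mixing 3- and 4-column records are pad-normalised (name ".")
# so the parser sees a rectangular file
normalise_bed_columns <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (length(unique(nf)) <= 1L) return(path)
  pad_to <- min(max(nf), 4L)
  lines[body] <- vapply(strsplit(lines[body], "\t", fixed = TRUE), function(f) {
    f <- head(f, 4L)
    paste(c(f, rep(".", max(0L, pad_to - length(f)))), collapse = "\t")
  }, character(1))
  tmp <- tempfile(fileext = ".bed")
  writeLines(lines, tmp)
  tmp
}

make_unique_names <- function(nm) {
  if (!anyDuplicated(nm)) return(nm)
  dup <- nm %in% nm[duplicated(nm)]
  idx <- stats::ave(seq_along(nm), nm, FUN = seq_along)
  nm[dup] <- paste0(nm[dup], "_", idx[dup])
  nm
}

#' Write regions or calls back to BED
#'
#' Writes the first three (or four, when a `name` column is present) columns
#' in BED convention, tab-separated without header.
#'
#' @param x A tibble with `chrom`, `start`, `end` and optionally `name`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "name"), names(x))
  readr::write_tsv(x[, cols], path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Flag target regions overlapping a blacklist
#'
#' Sets the `blacklisted` flag to `TRUE` for every region sharing at least
#' one bp (half-open semantics) with any blacklist interval. Region order and
#' coordinates are unchanged; the operation is idempotent. Blacklisted
#' regions are excluded from statistical testing downstream and their
#' p-values, adjusted p-values and calls are reported as `NA`.
#'
#' @param regions Region tibble from [read_regions_bed()].
#' @param blacklist Tibble with `chrom`, `start`, `end` (0-based half-open),
#'   or `NULL` for no blacklist.
#' @return `regions` with its `blacklisted` column updated.
#' @export
flag_blacklisted <- function(regions, blacklist) {
  regions$blacklisted <- overlaps_any(regions, blacklist)
  regions
}

# TRUE for each interval in x overlapping >=1 bp of any interval in y
overlaps_any <- function(x, y) {
  if (is.null(y) || nrow(y) == 0L) return(rep(FALSE, nrow(x)))
  hit <- rep(FALSE, nrow(x))
  for (ch in intersect(unique(x$chrom), unique(y$chrom))) {
    xi <- which(x$chrom == ch)
    yi <- which(y$chrom == ch)
    # half-open [start, end) -> closed IRanges [start+1, end]
    q <- IRanges::IRanges(start = x$start[xi] + 1L, end = x$end[xi])
    s <- IRanges::IRanges(start = y$start[yi] + 1L, end = y$end[yi])
    hit[xi] <- IRanges::overlapsAny(q, s)
  }
  hit
}

#' Tile the genome for background estimation
#'
#' Partitions every chromosome into consecutive non-overlapping tiles of
#' exactly `tile_width` bp starting at 0. A trailing partial tile is dropped
#' (a per-tile mean over unequal widths would be biased). Tiles overlapping
#' any blacklist interval are removed entirely; their number is recorded in
#' the `n_excluded` attribute.
#'
#' @param sizes Chromosome-sizes tibble from [read_chrom_sizes()].
#' @param tile_width Tile width in bp (> 0); conventionally equal to the
#'   target-region width W so the background mean is directly commensurable
#'   with window counts.
#' @param blacklist Optional blacklist tibble (`chrom`, `start`, `end`).
#'
#' @return A tibble of tiles (`chrom`, `start`, `end`) with attributes
#'   `tile_width` and `n_excluded`.
#' @export
tile_genome <- function(sizes, tile_width, blacklist = NULL) {
  stopifnot(is.numeric(tile_width), tile_width > 0)
  tile_width <- as.integer(tile_width)
  per_chrom <- lapply(seq_len(nrow(sizes)), function(i) {
    n <- sizes$length[i] %/% tile_width
    if (n == 0L) return(NULL)
    start <- tile_width * (seq_len(n) - 1L)
    tibble(chrom = sizes$chrom[i], start = start, end = start + tile_width)
  })
  tiles <- bind_rows(per_chrom)
  if (nrow(tiles) == 0L) {
    abort("tile width exceeds every chromosome length: no tiles")
  }
  excl <- overlaps_any(tiles, blacklist)
  out <- tiles[!excl, , drop = FALSE]
  if (nrow(out) == 0L) {
    abort("all tiles removed by blacklist: no background tiles remain")
  }
  attr(out, "tile_width") <- tile_width
  attr(out, "n_excluded") <- sum(excl)
  out
}
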