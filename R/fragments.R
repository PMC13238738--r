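#' Extract fragment midpoints from an alignment file
#'
#' Reduces each sequenced DNA fragment to its central genomic position, the
#' point representation used for window counting. Paired-end proper pairs are
#' combined into a single fragment spanning the outer mapped coordinates of
#' the two mates; single-end reads are treated as individual fragments
#' covering their own aligned span. The midpoint of a fragment `[start, end)`
#' is `start + floor((end - start) / 2)` (0-based).
#'
#' Unmapped, secondary, supplementary and duplicate-flagged records are always
#' skipped. In paired mode only properly paired primary alignments contribute,
#' each pair exactly once (keyed on the leftmost mate); improper pairs are not
#' salvaged as single-end fragments. In `"auto"` mode the paired flag of the
#' first mapped record selects the mode.
#'
#' @param path Path to a coordinate-sorted BAM (indexed; an index is created
#'   if missing). A SAM file is accepted and converted on the fly.
#' @param mode One of `"auto"`, `"paired"`, `"single"`.
#' @param min_mapq Minimum mapping quality (default 0; alignment-confidence
#'   filtering is normally done upstream).
#'
#' @return A tibble with columns `chrom` (character) and `pos` (integer,
#'   0-based midpoint), sorted by chromosome then position, with attributes
#'   `total_fragments`, `source` (file basename) and `mode`.
#' @export
extract_fragment_midpoints <- function(path, mode = c("auto", "paired", "single"),
                                       min_mapq = 0) {
  mode <- match.arg(mode)
  bam <- as_indexed_bam(path)
  if (mode == "auto") {
    mode <- detect_alignment_mode(bam)
  }
  flags <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE,
    isDuplicate = FALSE,
    isProperPair = if (mode == "paired") TRUE else NA,
    isPaired = if (mode == "paired") TRUE else NA
  )
  mq <- if (min_mapq > 0) as.integer(min_mapq) else NA_integer_

  if (mode == "paired") {
    param <- Rsamtools::ScanBamParam(flag = flags, mapqFilter = mq,
                                     what = c("rname", "pos", "isize"))
    rec <- Rsamtools::scanBam(bam, param = param)[[1]]
    keep <- !is.na(rec$isize) & rec$isize > 0L
    if (!any(keep)) {
      warn(paste0("no proper pairs found in ", path, "; empty midpoint track"))
      return(empty_track(path, mode))
    }
    start0 <- rec$pos[keep] - 1L          # SAM is 1-based
    frag_len <- rec$isize[keep]           # TLEN of leftmost mate = outer span
    chrom <- as.character(rec$rname[keep])
    pos <- start0 + frag_len %/% 2L
  } else {
    param <- Rsamtools::ScanBamParam(flag = flags, mapqFilter = mq)
    ga <- GenomicAlignments::readGAlignments(bam, param = param)
    if (length(ga) == 0L) {
      return(empty_track(path, mode))
    }
    df <- as.data.frame(ga)
    start0 <- df$start - 1L
    end0 <- df$end                        # closed 1-based end == half-open 0-based end
    chrom <- as.character(df$seqnames)
    pos <- start0 + (end0 - start0) %/% 2L
  }
  track <- tibble(chrom = chrom, pos = as.integer(pos))
  track <- arrange(track, .data$chrom, .data$pos)
  attr(track, "total_fragments") <- nrow(track)
  attr(track, "source") <- basename(path)
  attr(track, "mode") <- mode
  track
}

empty_track <- function(path, mode) {
  track <- tibble(chrom = character(), pos = integer())
  attr(track, "total_fragments") <- 0L
  attr(track, "source") <- basename(path)
  attr(track, "mode") <- mode
  track
}

# SAM input is converted; BAM without a .bai is indexed in place next to the
# file when writable, otherwise via a temp copy.
as_indexed_bam <- function(path) {
  if (!file.exists(path)) abort(paste0("alignment file not found: ", path))
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = TRUE)
    return(bam)
  }
  if (!file.exists(paste0(path, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", path))) {
    ok <- tryCatch({ Rsamtools::indexBam(path); TRUE },
                   error = function(e) FALSE)
    if (!ok) {
      sorted <- Rsamtools::sortBam(path, tempfile())
      Rsamtools::indexBam(sorted)
      return(sorted)
    }
  }
  path
}

detect_alignment_mode <- function(bam) {
  bf <- Rsamtools::BamFile(bam, yieldSize = 1000L)
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE),
    what = "flag")
  fl <- Rsamtools::scanBam(bf, param = param)[[1]]$flag
  if (length(fl) == 0L) return("single")
  if (bitwAnd(fl[1], 1L) > 0L) "paired" else "single"
}

#' Count fragment midpoints in intervals
#'
#' Counts, for each interval, the midpoints `p` with
#' `start <= p < end` on the matching chromosome (half-open, so a midpoint
#' exactly at `end` is not counted). Intervals may overlap each other, in
#' which case a midpoint can be counted in several intervals. Chromosomes
#' absent from the track contribute zero.
#'
#' @param intervals Tibble with `chrom`, `start`, `end` (tiles or target
#'   regions), in any order.
#' @param track Midpoint track from [extract_fragment_midpoints()].
#' @param col Name of the count column added to `intervals` (default
#'   `"count"`).
#' @return `intervals` with an added integer count column.
#' @export
count_midpoints <- function(intervals, track, col = "count") {
  counts <- integer(nrow(intervals))
  if (nrow(track) > 0L) {
    by_chrom <- split(track$pos, track$chrom)
    for (ch in intersect(names(by_chrom), unique(intervals$chrom))) {
      p <- sort(by_chrom[[ch]])
      idx <- which(intervals$chrom == ch)
      # midpoints <= x via findInterval on the sorted positions
      counts[idx] <- findInterval(intervals$end[idx] - 1L, p) -
        findInterval(intervals$start[idx] - 1L, p)
    }
  }
  intervals[[col]] <- as.integer(counts)
  intervals
}

#' Write a midpoint track as BED3 (debugging aid)
#'
#' @param track Midpoint track tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_midpoints_bed <- function(track, path) {
  out <- tibble(chrom = track$chrom, start = track$pos, end = track$pos + 1L)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
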