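# Hand-built SAM files for fragment-extraction tests, and the standard
# simulated study datasets used by the end-to-end tests.

sam_header <- function(sizes) {
  c("@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", names(sizes), as.integer(sizes)))
}

# records: character vector of tab-joined SAM body lines
write_sam <- function(records, sizes = c(chr1 = 10000L), dir = tempdir()) {
  path <- tempfile(tmpdir = dir, fileext = ".sam")
  writeLines(c(sam_header(sizes), records), path)
  path
}

sam_rec <- function(qname, flag, rname, pos, cigar, rnext = "*", pnext = 0,
                    tlen = 0, mapq = 60) {
  paste(qname, flag, rname, pos, mapq, cigar, rnext, pnext, tlen, "*", "*",
        sep = "\t")
}

# a proper pair covering the half-open fragment [start, start + len)
sam_pair <- function(qname, chrom, start0, len, read_len = 50L, mapq = 60) {
  read_len <- min(read_len, len)
  pos1 <- start0 + 1L
  pos2 <- start0 + len - read_len + 1L
  c(sam_rec(qname, 99, chrom, pos1, paste0(read_len, "M"), "=", pos2, len,
            mapq = mapq),
    sam_rec(qname, 147, chrom, pos2, paste0(read_len, "M"), "=", pos1, -len,
            mapq = mapq))
}

# The study conditions used across the end-to-end tests: 500 promoter-like
# 2-kb windows on a three-chromosome toy genome, background 20 midpoints per
# window-width tile (the simulator's defaults for this geometry).
study_genome <- c(chr1 = 840000L, chr2 = 840000L, chr3 = 840000L)

study_spec <- function(seed, enriched = integer(), fold = numeric(),
                       distortion = NULL, distort_treatment = FALSE, ...) {
  simulation_spec(
    chrom_lengths = study_genome, width = 2000, n_regions = 500,
    enriched = enriched, fold = fold, background_rate = 20,
    distortion = distortion, distort_treatment = distort_treatment,
    seed = seed, ...)
}

run_study <- function(manifest, control = NULL, ...) {
  sizes <- read_chrom_sizes(manifest$chrom_sizes)
  regions <- read_regions_bed(manifest$regions, 2000, sizes)
  call_regions(regions, manifest$experiment, sizes, control = control, ...)
}
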