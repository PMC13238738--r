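#' Classify promoter chromatin states from two marks
#'
#' Combines the presence calls of an active-mark experiment (e.g. H3K4me3)
#' and a repressive-mark experiment (e.g. H3K27me3) over the identical
#' region set into four discrete chromatin states:
#'
#' * `N` -- neither mark
#' * `A` -- active only
#' * `R` -- repressed only
#' * `B` -- bivalent (both marks)
#'
#' Any `NA` contributing call (blacklisted region) yields state `NA`.
#'
#' @param active_calls,repressive_calls `region_calls` tibbles over the same
#'   regions (same names, intervals, order -- enforced).
#' @return A tibble of class `chromatin_states`: `chrom`, `start`, `end`,
#'   `name`, `call_active`, `call_repressive`, `state` (character in
#'   `c("N","A","R","B", NA)`).
#' @export
classify_states <- function(active_calls, repressive_calls) {
  check_same_regions(active_calls, repressive_calls,
                     labels = c("active", "repressive"))
  out <- as_tibble(active_calls)[, c("chrom", "start", "end", "name")]
  out$call_active <- active_calls$call
  out$call_repressive <- repressive_calls$call
  out$state <- classify_state(out$call_active, out$call_repressive)
  class(out) <- c("chromatin_states", class(out))
  out
}

#' Truth-table state mapping
#'
#' Vectorized mapping (active, repressive) -> state:
#' (0,0)->N, (1,0)->A, (0,1)->R, (1,1)->B, any NA -> NA.
#'
#' @param active,repressive Integer calls in `{0, 1, NA}`.
#' @return Character vector of states.
#' @export
classify_state <- function(active, repressive) {
  dplyr::case_when(
    is.na(active) | is.na(repressive) ~ NA_character_,
    active == 1L & repressive == 1L ~ "B",
    active == 1L & repressive == 0L ~ "A",
    active == 0L & repressive == 1L ~ "R",
    active == 0L & repressive == 0L ~ "N"
  )
}

#' Annotate a call table with expression values
#'
#' Joins gene-level expression onto regions by the region name (the
#' TSS-derived identifier carried by the promoter BED); no coordinate
#' matching is attempted. Regions without a matching key get `NA`; unmatched
#' expression keys are counted and reported. Idempotent: re-annotating
#' replaces the column.
#'
#' @param calls A `region_calls` tibble.
#' @param expression A two-column data frame (`name`, `expression`) or a
#'   named numeric vector.
#' @return `calls` with an `expression` column appended.
#' @export
annotate_expression <- function(calls, expression) {
  if (is.numeric(expression) && !is.null(names(expression))) {
    expression <- tibble(name = names(expression), expression = unname(expression))
  }
  if (!is.data.frame(expression) || ncol(expression) < 2L) {
    abort("expression must be a named numeric vector or a two-column table")
  }
  names(expression)[1:2] <- c("name", "expression")
  if (nrow(expression) == 0L) {
    warn("empty expression table: all regions annotated NA")
  }
  unmatched <- sum(!expression$name %in% calls$name)
  if (unmatched > 0L) {
    inform(paste0(unmatched, " expression key(s) match no region and were ignored"))
  }
  calls$expression <- expression$expression[match(calls$name, expression$name)]
  calls
}

#' Read a two-column expression TSV
#'
#' Header optional and auto-detected (a non-numeric second field on line one
#' is taken as a header).
#'
#' @param path Path to a TSV with columns name, value.
#' @return Tibble with columns `name`, `expression`.
#' @export
read_expression_tsv <- function(path) {
  first <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  has_header <- length(first) >= 2L &&
    is.na(suppressWarnings(as.numeric(first[2])))
  out <- readr::read_tsv(path, col_names = has_header,
                         show_col_types = FALSE, progress = FALSE)
  names(out)[1:2] <- c("name", "expression")
  out[, 1:2]
}

#' Compare two samples over the same region set
#'
#' Per-region delta metrics between sample A and baseline sample B:
#' `delta_score = score_A - score_B`, `delta_z = z_A - z_B`, and
#' `delta_expression` when both tables carry expression. When chromatin
#' states are supplied, a transition label `"<state_B>-><state_A>"` is added
#' (baseline first, reading chronologically for longitudinal pairs such as
#' primary -> recurrent). Deltas are `NA` whenever either side is `NA`.
#'
#' @param calls_a,calls_b `region_calls` tibbles over the identical region
#'   set (enforced, not coerced; B is the baseline).
#' @param states_a,states_b Optional `chromatin_states` tibbles for the same
#'   samples.
#' @return A tibble of class `region_comparison`: `chrom`, `start`, `end`,
#'   `name`, `score_a`, `score_b`, `delta_score`, `z_a`, `z_b`, `delta_z`,
#'   `call_a`, `call_b`, and optionally `state_a`, `state_b`, `transition`,
#'   `expr_a`, `expr_b`, `delta_expression`.
#' @export
compare_samples <- function(calls_a, calls_b, states_a = NULL, states_b = NULL) {
  check_same_regions(calls_a, calls_b, labels = c("A", "B"))
  out <- as_tibble(calls_a)[, c("chrom", "start", "end", "name")]
  out$score_a <- calls_a$score
  out$score_b <- calls_b$score
  out$delta_score <- calls_a$score - calls_b$score
  out$z_a <- calls_a$z
  out$z_b <- calls_b$z
  out$delta_z <- calls_a$z - calls_b$z
  out$call_a <- calls_a$call
  out$call_b <- calls_b$call
  if (!is.null(states_a) && !is.null(states_b)) {
    check_same_regions(states_a, states_b, labels = c("states A", "states B"))
    check_same_regions(calls_a, states_a, labels = c("A", "states A"))
    out$state_a <- states_a$state
    out$state_b <- states_b$state
    out$transition <- ifelse(is.na(out$state_a) | is.na(out$state_b),
                             NA_character_,
                             paste0(out$state_b, "->", out$state_a))
  }
  if ("expression" %in% names(calls_a) || "expression" %in% names(calls_b)) {
    out$expr_a <- calls_a[["expression"]] %||% rep(NA_real_, nrow(out))
    out$expr_b <- calls_b[["expression"]] %||% rep(NA_real_, nrow(out))
    out$delta_expression <- out$expr_a - out$expr_b
  }
  class(out) <- c("region_comparison", class(out))
  out
}

check_same_regions <- function(a, b, labels = c("A", "B")) {
  if (nrow(a) != nrow(b)) {
    abort(sprintf("%s has %d regions but %s has %d: region sets must be identical",
                  labels[1], nrow(a), labels[2], nrow(b)))
  }
  bad <- which(a$name != b$name | a$chrom != b$chrom |
                 a$start != b$start | a$end != b$end)
  if (length(bad) > 0L) {
    k <- bad[1]
    abort(sprintf(
      "region %d differs between %s (%s %s:%d-%d) and %s (%s %s:%d-%d)",
      k, labels[1], a$name[k], a$chrom[k], a$start[k], a$end[k],
      labels[2], b$name[k], b$chrom[k], b$start[k], b$end[k]))
  }
  invisible(TRUE)
}

#' Write a comparison table to TSV
#'
#' @param comparison A `region_comparison` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparison_tsv <- function(comparison, path) {
  out <- as_tibble(comparison)
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(v) signif(v, 6))
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}
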