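# small call tables over a shared region set, built directly
fake_calls <- function(score, z, call, expression = NULL) {
  n <- length(call)
  out <- tibble::tibble(
    chrom = "chr1", start = 4000L * (seq_len(n) - 1L),
    end = 4000L * (seq_len(n) - 1L) + 2000L,
    name = sprintf("GENE%04d", seq_len(n)),
    blacklisted = is.na(call),
    y = 10L, y_ctrl = NA_integer_, m = 1, lambda_t = 10,
    p = 0.5, padj = 0.5, score = score, z = z, call = as.integer(call))
  if (!is.null(expression)) out$expression <- expression
  class(out) <- c("region_calls", class(out))
  out
}

test_that("state classification enumerates the full truth table", {
  grid <- expand.grid(active = c(0L, 1L, NA), repressive = c(0L, 1L, NA))
  got <- classify_state(grid$active, grid$repressive)
  want <- ifelse(is.na(grid$active) | is.na(grid$repressive), NA,
                 ifelse(grid$active == 1 & grid$repressive == 1, "B",
                        ifelse(grid$active == 1, "A",
                               ifelse(grid$repressive == 1, "R", "N"))))
  expect_identical(got, as.character(want))
  expect_identical(classify_state(1L, 1L), "B")
  expect_identical(classify_state(0L, 0L), "N")
  expect_identical(classify_state(1L, 0L), "A")
  expect_identical(classify_state(0L, 1L), "R")
  expect_identical(classify_state(NA_integer_, 1L), NA_character_)
})

test_that("classify_states joins two marks over the identical region set", {
  act <- fake_calls(score = c(2, 0, 2, 0, 2), z = 1, call = c(1, 0, 1, 0, NA))
  rep_ <- fake_calls(score = c(2, 2, 0, 0, 2), z = 1, call = c(1, 1, 0, 0, 1))
  st <- classify_states(act, rep_)
  expect_equal(st$state, c("B", "R", "A", "N", NA))

  mismatched <- fake_calls(score = 1, z = 1, call = c(0, 0, 0, 0, 0))
  mismatched$name[2] <- "OTHER"
  expect_error(classify_states(act, mismatched), "differs")
  expect_error(classify_states(act, mismatched[1:3, ]), "identical")
})

test_that("expression annotation joins by name, NA-fills, and is idempotent", {
  calls <- fake_calls(score = 1, z = 1, call = c(0, 0, 0))
  expr <- tibble::tibble(name = c("GENE0001", "GENE0003", "NOT_A_REGION"),
                         expression = c(7.2, 1.1, 9.9))
  expect_message(out <- annotate_expression(calls, expr), "1 expression key")
  expect_equal(out$expression, c(7.2, NA, 1.1))

  again <- suppressMessages(annotate_expression(out, expr))
  expect_equal(again$expression, out$expression)

  expect_warning(none <- annotate_expression(calls, expr[0, ]), "empty")
  expect_true(all(is.na(none$expression)))

  vec <- annotate_expression(calls, c(GENE0002 = 3.3))
  expect_equal(vec$expression, c(NA, 3.3, NA))
})

test_that("expression TSVs are read with or without a header", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("GENE0001\t7.2", "GENE0002\t1.5"), f)
  e1 <- read_expression_tsv(f)
  expect_equal(e1$expression, c(7.2, 1.5))
  writeLines(c("gene\ttpm", "GENE0001\t7.2"), f)
  e2 <- read_expression_tsv(f)
  expect_equal(e2$name, "GENE0001")
  expect_equal(e2$expression, 7.2)
})

test_that("self-comparison is identically zero with X->X transitions", {
  a <- fake_calls(score = c(2, 0.5, 1), z = c(3, -1, 0), call = c(1, 0, 0),
                  expression = c(1.5, 2.5, NA))
  st <- classify_states(a, a)
  cmp <- compare_samples(a, a, st, st)
  expect_true(all(cmp$delta_score == 0))
  expect_true(all(cmp$delta_z == 0))
  expect_equal(cmp$transition, paste0(st$state, "->", st$state))
  expect_equal(cmp$delta_expression, c(0, 0, NA))
})

test_that("comparison deltas are A minus baseline B and antisymmetric", {
  a <- fake_calls(score = c(2, 1, NA), z = c(2, 0, 1), call = c(1, 0, 0))
  b <- fake_calls(score = c(0.5, 2, 1), z = c(1, 1, NA), call = c(0, 1, 0))
  ab <- compare_samples(a, b)
  expect_equal(ab$delta_score[1], 1.5)
  expect_true(is.na(ab$delta_score[3]))
  expect_true(is.na(ab$delta_z[3]))
  ba <- compare_samples(b, a)
  expect_equal(ab$delta_score, -ba$delta_score)
  expect_equal(ab$delta_z, -ba$delta_z)
})

test_that("comparisons refuse mismatched region sets, naming the discrepancy", {
  a <- fake_calls(score = 1, z = 1, call = c(0, 0))
  b <- fake_calls(score = 1, z = 1, call = c(0, 0))
  b$start[2] <- 99L
  expect_error(compare_samples(a, b), "region 2")
})

test_that("expression missing on one side propagates NA deltas", {
  a <- fake_calls(score = c(1, 1), z = c(0, 0), call = c(0, 0),
                  expression = c(2, 3))
  b <- fake_calls(score = c(1, 1), z = c(0, 0), call = c(0, 0))
  cmp <- compare_samples(a, b)
  expect_true(all(is.na(cmp$delta_expression)))
  expect_equal(cmp$expr_a, c(2, 3))
})

test_that("comparison tables export to TSV with NA rendered literally", {
  a <- fake_calls(score = c(2, NA), z = c(1, NA), call = c(1, NA))
  cmp <- compare_samples(a, a)
  f <- tempfile(fileext = ".tsv")
  write_comparison_tsv(cmp, f)
  lines <- readLines(f)
  expect_match(lines[1], "^chrom\tstart\tend\tname\tscore_a")
  expect_match(lines[3], "NA")
})
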