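test_that("error model validates its parameters", {
  expect_error(error_model(-0.1), "rate")
  expect_error(error_model(0.1, 0.5, 0.5, 0.5), "equal 1")
  m <- error_model(0.02, seed = 9L)
  expect_s3_class(m, "error_model")
})

test_that("a zero-error simulation is the exact tiled array", {
  expect_identical(simulate_telomere("TTAGGG", 600L, error_model(0)),
                   strrep("TTAGGG", 100L))
  # truncation of the final copy
  expect_identical(simulate_telomere("TTAGGG", 8L, error_model(0)),
                   "TTAGGGTT")
  expect_error(simulate_telomere("TTAGGG", 3L, error_model(0)),
               "at least the unit length")
})

test_that("simulation is deterministic under a fixed seed", {
  m <- error_model(0.05, seed = 123L)
  expect_identical(simulate_telomere("TTAGGG", 2000L, m),
                   simulate_telomere("TTAGGG", 2000L, m))
})

test_that("the realized edit distance tracks the binomial error count", {
  # with rate p over n bases, the number of edits is Binomial(n, p); the
  # edit distance to the clean array can only undershoot it (adjacent edits
  # may cancel), so check the mean over replicates within 3 sigma
  set.seed(55)
  n <- 600L
  p <- 0.10
  clean <- strrep("TTAGGG", 100L)
  model <- error_model(p)
  d <- replicate(100, utils::adist(simulate_telomere("TTAGGG", n, model),
                                   clean)[1L, 1L])
  sigma <- sqrt(n * p * (1 - p))
  expect_lt(abs(mean(d) - n * p), 3 * sigma)
})

test_that("error-free conditions recover the canonical repeat at every length", {
  cfg <- explore_config(4L, 8L, 50L)
  for (len in c(600L, 12000L, 30000L)) {
    res <- run_condition("TTAGGG", len, error_model(0, seed = 1L), 10L, cfg)
    expect_identical(res$top_repeat, "AACCCT")
    expect_true(res$true_repeat_found)
  }
})

test_that("fully randomizing substitutions destroy every qualifying run", {
  model <- error_model(1, sub_frac = 1, ins_frac = 0, del_frac = 0, seed = 2L)
  res <- run_condition("TTAGGG", 600L, model, 10L, explore_config(4L, 8L, 50L))
  expect_false(res$true_repeat_found)
  expect_identical(res$top_repeat, NA_character_)
  expect_error(run_condition("TTAGGG", 600L, model, 0L), ">= 1")
})

test_that("recovered repeat counts decay with the error rate", {
  g <- run_grid(lengths = 6000L, rates = c(0, 0.01, 0.05), n_replicates = 30L,
                cfg = explore_config(5L, 7L, 50L), seed = 7L)
  expect_identical(nrow(g$results), 3L)
  counts <- vapply(g$conditions, function(cond) {
    tab <- cond$table
    sum(tab$count[tab$canonical_repeat_unit == "AACCCT"])
  }, numeric(1))
  expect_identical(order(counts, decreasing = TRUE), 1:3)
  # grid reproducibility under the same seed
  g2 <- run_grid(lengths = 6000L, rates = c(0, 0.01, 0.05),
                 n_replicates = 30L, cfg = explore_config(5L, 7L, 50L),
                 seed = 7L)
  expect_identical(g$results, g2$results)
})

test_that("the grid report TSV round-trips its headline columns", {
  g <- run_grid(lengths = 600L, rates = c(0, 0.05), n_replicates = 10L,
                cfg = explore_config(5L, 7L, 20L), seed = 3L)
  path <- tempfile(fileext = ".tsv")
  write_grid_tsv(g, path)
  back <- read_tsv(path)
  expect_identical(back$top_repeat, g$results$top_repeat)
  expect_identical(back$length, g$results$length)
})

test_that("the synthetic assembly places telomeric arrays at the right ends", {
  asm <- simulate_assembly(n_both = 3L, n_single = 2L, chr_length = 12000L,
                           telo_length = 1200L, seed = 4L)
  expect_identical(nrow(asm), 5L)
  rows <- search_motif(asm, "TTAGGG", 1200L)
  for (i in 1:3) {
    sub <- rows[rows$id == sprintf("chr%d", i), ]
    total <- sub$forward_count + sub$reverse_count
    expect_gt(total[1L], 100L)
    expect_gt(total[length(total)], 100L)
    expect_true(all(total[2:(length(total) - 1L)] < 10L))
  }
  for (i in 4:5) {
    sub <- rows[rows$id == sprintf("chr%d", i), ]
    total <- sub$forward_count + sub$reverse_count
    expect_gt(total[1L], 100L)
    expect_true(all(total[-1L] < 10L))
  }
})
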