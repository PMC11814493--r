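test_that("detect_runs collapses identical consecutive chunks", {
  runs <- detect_runs(strrep("TTAGGG", 3L), 6L)
  expect_identical(runs$unit, "TTAGGG")
  expect_identical(runs$start, 0L)
  expect_identical(runs$count, 3L)

  runs <- detect_runs("ACGTACGTTTTTTTTT", 4L)
  expect_identical(runs$unit, c("ACGT", "TTTT"))
  expect_identical(runs$start, c(0L, 8L))
  expect_identical(runs$count, c(2L, 2L))

  expect_identical(nrow(detect_runs("ACGT", 5L)), 0L)
  expect_identical(nrow(detect_runs("TTAGGGNTAGGGTTAGGG", 6L)), 0L)
  expect_error(detect_runs("ACGT", 1L), ">= 2")
})

test_that("run slices reproduce the unit tiling and stay on the chunk grid", {
  set.seed(31)
  for (i in 1:60) {
    seq <- random_repeatish_seq(sample(50:400, 1L))
    k <- sample(2:6, 1L)
    runs <- detect_runs(seq, k)
    if (nrow(runs)) {
      expect_true(all(runs$start %% k == 0L))
      expect_true(all(runs$count >= 2L))
      for (j in seq_len(nrow(runs))) {
        slice <- substr(seq, runs$start[j] + 1L,
                        runs$start[j] + runs$count[j] * k)
        expect_identical(slice, strrep(runs$unit[j], runs$count[j]))
      }
    }
  }
})

test_that("explore_record thresholds runs and tallies canonical units", {
  expect_equal(explore_record(strrep("TTAGGG", 100L), 6L, 50L),
               c(AACCCT = 100))
  expect_length(explore_record(strrep("TTAGGG", 100L), 6L, 200L), 0L)
  # a frame-shifting base merges two phase-shifted runs under one canonical
  shifted <- paste0(strrep("CCCTAA", 60L), "G", strrep("TTAGGG", 60L))
  expect_equal(explore_record(shifted, 6L, 50L), c(AACCCT = 120))
})

test_that("explore agrees with the naive run oracle on random sequences", {
  set.seed(32)
  for (i in 1:150) {
    seq <- random_repeatish_seq(sample(30:500, 1L))
    k <- sample(2:6, 1L)
    runs <- detect_runs(seq, k)
    oruns <- oracle_runs(seq, k)
    expect_equal(runs, oruns, ignore_attr = TRUE)
    threshold <- sample(2:6, 1L)
    expect_equal(explore_record(seq, k, threshold),
                 oracle_explore_record(seq, k, threshold))
  }
})

test_that("explore output is sorted, additive over records and k-correct", {
  one <- data.frame(id = "r1", seq = strrep("TTAGGG", 100L))
  tab <- explore(one, explore_config(6L, 6L, 50L))
  expect_identical(tab$canonical_repeat_unit, "AACCCT")
  expect_identical(tab$kmer_length, 6L)
  expect_equal(tab$count, 100)

  # at k = 12 the same array is seen as a dimer of the unit
  tab12 <- explore(one, explore_config(12L, 12L, 40L))
  expect_identical(tab12$canonical_repeat_unit, "AACCCTAACCCT")
  expect_equal(tab12$count, 50)

  two <- rbind(one, data.frame(id = "r2", seq = strrep("TTAGGG", 100L)))
  expect_equal(explore(two, explore_config(6L, 6L, 50L))$count, 200)

  # sort order: k ascending, count descending, unit ascending on ties
  recs <- data.frame(
    id = c("a", "b", "c"),
    seq = c(strrep("TTAGG", 80L), strrep("TTAGG", 30L), strrep("AACCCT", 60L)))
  tab <- explore(recs, explore_config(5L, 6L, 10L))
  expect_identical(tab$kmer_length, sort(tab$kmer_length))
  for (k in unique(tab$kmer_length)) {
    sub <- tab[tab$kmer_length == k, ]
    expect_identical(sub$count, sort(sub$count, decreasing = TRUE))
  }
})

test_that("explore is invariant to record order and conserves counts", {
  set.seed(33)
  recs <- data.frame(
    id = sprintf("r%d", 1:6),
    seq = vapply(1:6, function(i) random_repeatish_seq(400L), character(1)),
    stringsAsFactors = FALSE)
  cfg <- explore_config(2L, 6L, 4L)
  tab <- explore(recs, cfg)
  shuffled <- explore(recs[sample(nrow(recs)), , drop = FALSE], cfg)
  expect_identical(tab, shuffled)

  # per-k totals equal the sum of qualifying run counts over all records
  for (k in unique(tab$kmer_length)) {
    total_runs <- sum(unlist(lapply(recs$seq, function(s) {
      r <- detect_runs(s, k)
      sum(r$count[r$count >= cfg$threshold])
    })))
    expect_equal(sum(tab$count[tab$kmer_length == k]), total_runs)
  }

  expect_identical(nrow(explore(recs[0L, , drop = FALSE], cfg)), 0L)
})
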