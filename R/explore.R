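#' Detect tandem runs of identical k-chunks
#'
#' Cuts `seq` into non-overlapping chunks of `k` nucleotides starting at
#' offset 0 (a trailing remainder shorter than `k` is ignored) and collapses
#' maximal groups of two or more identical consecutive chunks into runs.
#' Chunks containing any character outside A/C/G/T terminate runs and never
#' join one. Each chunk is compared only with its successor, so the scan is a
#' single pass over the sequence.
#'
#' @param seq A single uppercase nucleotide string.
#' @param k Chunk size in nucleotides, at least 2.
#' @return A data.frame with columns `unit` (the repeated chunk), `start`
#'   (0-based nucleotide offset, always a multiple of `k`) and `count`
#'   (number of consecutive identical chunks, at least 2), in ascending
#'   `start` order. Zero rows when no run exists.
#' @examples
#' detect_runs(strrep("TTAGGG", 3), 6)
#' @export
detect_runs <- function(seq, k) {
  stopifnot(is.character(seq), length(seq) == 1L)
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stop("`k` must be an integer >= 2", call. = FALSE)
  n <- nchar(seq)
  m <- n %/% k
  empty <- data.frame(unit = character(0), start = integer(0),
                      count = integer(0), stringsAsFactors = FALSE)
  if (m < 2L) return(empty)
  r <- charToRaw(seq)
  used <- m * k
  # adjacency of consecutive chunks: chunk j == chunk j+1 iff all k byte
  # comparisons at lag k agree within the chunk
  lag_eq <- r[seq_len(used - k)] == r[(k + 1L):used]
  eq_counts <- .colSums(lag_eq, k, m - 1L)
  adj <- eq_counts == k
  # chunks containing non-ACGT bytes are excluded from runs
  bad_base <- !(r[seq_len(used)] %in% as.raw(c(65L, 67L, 71L, 84L)))
  if (any(bad_base)) {
    bad_chunk <- .colSums(bad_base, k, m) > 0L
    adj <- adj & !bad_chunk[seq_len(m - 1L)] & !bad_chunk[2:m]
  }
  if (!any(adj)) return(empty)
  runs <- rle(adj)
  ends <- cumsum(runs$lengths)
  keep <- runs$values
  run_adj_len <- runs$lengths[keep]          # number of TRUE adjacencies
  run_first_chunk <- (ends - runs$lengths + 1L)[keep]  # 1-based chunk index
  start <- (run_first_chunk - 1L) * k
  count <- run_adj_len + 1L
  unit <- substring(seq, start + 1L, start + k)
  data.frame(unit = unit, start = start, count = count,
             stringsAsFactors = FALSE)
}

#' Tally canonical repeat candidates in one sequence
#'
#' Runs [detect_runs()], keeps runs whose chunk count reaches `threshold`,
#' adds each qualifying run's chunk count (the number of repeat units it
#' spans, not the number of runs) to the tally of its unit, and merges the
#' tallies under canonical forms with [merge_counts()].
#'
#' @inheritParams detect_runs
#' @param threshold Minimum run chunk count for a run to be tallied
#'   (at least 2).
#' @return A named numeric vector: canonical unit -> total unit count. Empty
#'   when no run reaches the threshold.
#' @export
explore_record <- function(seq, k, threshold = 100L) {
  threshold <- as.integer(threshold)
  if (is.na(threshold) || threshold < 2L) {
    stop("`threshold` must be an integer >= 2", call. = FALSE)
  }
  runs <- detect_runs(seq, k)
  runs <- runs[runs$count >= threshold, , drop = FALSE]
  if (nrow(runs) == 0L) {
    out <- numeric(0)
    names(out) <- character(0)
    return(out)
  }
  tally <- tapply(as.numeric(runs$count), runs$unit, sum)
  counts <- as.numeric(tally)
  names(counts) <- names(tally)
  merge_counts(counts)
}

#' Configuration for the discovery scan
#'
#' @param k_min,k_max Inclusive k-mer length range to scan; both at least 2.
#'   Known telomeric units are almost all under 15 bp, so 4-15 is the
#'   recommended discovery range (not enforced).
#' @param threshold Minimum tandem-run chunk count for a run to be tallied.
#'   The default of 100 is conservative; values of 50 or more keep the
#'   candidate set small, and the threshold can be lowered if nothing is
#'   reported.
#' @return An object of class `explore_config`.
#' @export
explore_config <- function(k_min = 5L, k_max = 12L, threshold = 100L) {
  k_min <- as.integer(k_min); k_max <- as.integer(k_max)
  threshold <- as.integer(threshold)
  if (is.na(k_min) || k_min < 2L) stop("`k_min` must be >= 2", call. = FALSE)
  if (is.na(k_max) || k_max < k_min) {
    stop("`k_max` must be >= `k_min`", call. = FALSE)
  }
  if (is.na(threshold) || threshold < 2L) {
    stop("`threshold` must be >= 2", call. = FALSE)
  }
  structure(list(k_min = k_min, k_max = k_max, threshold = threshold),
            class = "explore_config")
}

#' Discover candidate telomeric repeats in a set of sequences
#'
#' For each k in `[k_min, k_max]`, scans every record with
#' [explore_record()] and sums the per-record canonical tallies. The result
#' does not depend on record order (pure aggregation).
#'
#' @param records A data.frame of sequence records as returned by
#'   [read_fasta()] (columns `id` and `seq`), or a character vector of
#'   sequences.
#' @param cfg An [explore_config()].
#' @return A data.frame with columns `canonical_repeat_unit`, `kmer_length`
#'   and `count`, sorted by `kmer_length` ascending, then `count` descending,
#'   then unit ascending. Zero rows when nothing passes the threshold.
#' @examples
#' recs <- data.frame(id = "r1", seq = strrep("TTAGGG", 100))
#' explore(recs, explore_config(6, 6, threshold = 50))
#' @export
explore <- function(records, cfg = explore_config()) {
  if (!inherits(cfg, "explore_config")) {
    stop("`cfg` must be an explore_config()", call. = FALSE)
  }
  seqs <- if (is.data.frame(records)) records$seq else as.character(records)
  out <- vector("list", cfg$k_max - cfg$k_min + 1L)
  for (k in seq.int(cfg$k_min, cfg$k_max)) {
    total <- new.env(parent = emptyenv())
    for (s in seqs) {
      tal <- explore_record(s, k, cfg$threshold)
      for (u in names(tal)) {
        prev <- if (is.null(total[[u]])) 0 else total[[u]]
        total[[u]] <- prev + tal[[u]]
      }
    }
    units <- ls(total)
    if (length(units)) {
      counts <- vapply(units, function(u) total[[u]], numeric(1))
      df <- data.frame(canonical_repeat_unit = units, kmer_length = k,
                       count = unname(counts), stringsAsFactors = FALSE)
      df <- df[order(-df$count, df$canonical_repeat_unit), , drop = FALSE]
      out[[k - cfg$k_min + 1L]] <- df
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(canonical_repeat_unit = character(0),
                      kmer_length = integer(0), count = numeric(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
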