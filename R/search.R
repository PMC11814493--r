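#' All exact occurrences of a motif in a sequence
#'
#' Reports every exact match start position, including overlapping matches
#' (`"AA"` in `"AAAA"` matches at 0, 1 and 2). Matching is literal:
#' characters outside A/C/G/T in the sequence never match any motif
#' position. Pattern matching is delegated to [Biostrings::matchPattern()],
#' which runs in linear time for the short motifs used here.
#'
#' @param seq A single nucleotide string.
#' @param motif A non-empty motif over A/C/G/T (case-insensitive).
#' @return Ascending integer vector of 0-based match start offsets.
#' @examples
#' find_occurrences("AAAA", "AA")  # 0 1 2
#' @export
find_occurrences <- function(seq, motif) {
  stopifnot(is.character(seq), length(seq) == 1L)
  motif <- toupper(motif)
  .check_unit(motif, "motif")
  if (nchar(motif) > nchar(seq)) return(integer(0))
  hits <- Biostrings::matchPattern(motif, Biostrings::DNAString(seq),
                                   fixed = TRUE)
  as.integer(Biostrings::start(hits)) - 1L
}

#' Count motif occurrences in fixed-width windows
#'
#' Tiles the sequence with non-overlapping windows of `window` nucleotides
#' starting at offset 0 (the final window may be shorter) and counts exact
#' occurrences of the motif (`forward_count`) and of its reverse complement
#' (`reverse_count`) per window. A match is assigned to the window containing
#' its start offset; matches spanning a window boundary are not split, so
#' window counts partition the genome-wide occurrence list exactly.
#'
#' @param record A one-row data.frame with columns `id` and `seq`, or a list
#'   with those elements.
#' @param motif Motif over A/C/G/T.
#' @param window Window width in nucleotides; must be at least the motif
#'   length.
#' @return A data.frame with columns `id`, `window_start` (0-based),
#'   `window_end` (exclusive), `forward_count`, `reverse_count`; zero rows
#'   for an empty sequence.
#' @examples
#' rec <- data.frame(id = "chr1", seq = strrep("TTAGGG", 10))
#' count_in_windows(rec, "TTAGGG", 30)
#' @export
count_in_windows <- function(record, motif, window) {
  motif <- toupper(motif)
  .check_unit(motif, "motif")
  window <- as.integer(window)
  if (is.na(window) || window < nchar(motif)) {
    stop("`window` must be at least the motif length", call. = FALSE)
  }
  id <- record$id[1L]
  seq <- record$seq[1L]
  n <- nchar(seq)
  if (n == 0L) {
    return(data.frame(id = character(0), window_start = integer(0),
                      window_end = integer(0), forward_count = integer(0),
                      reverse_count = integer(0), stringsAsFactors = FALSE))
  }
  starts <- seq.int(0L, n - 1L, by = window)
  ends <- pmin(starts + window, n)
  fwd <- find_occurrences(seq, motif)
  rev <- find_occurrences(seq, reverse_complement(motif))
  bin <- function(pos) {
    if (!length(pos)) return(integer(length(starts)))
    tabulate(pos %/% window + 1L, nbins = length(starts))
  }
  data.frame(id = id, window_start = starts, window_end = ends,
             forward_count = bin(fwd), reverse_count = bin(rev),
             stringsAsFactors = FALSE)
}

#' Windowed motif search over a set of sequences
#'
#' Applies [count_in_windows()] to every record, concatenating rows in input
#' order.
#'
#' @param records A data.frame of records as returned by [read_fasta()].
#' @param motif Motif over A/C/G/T (case-insensitive).
#' @param window Window width in nucleotides (default 10000).
#' @return A data.frame of per-window counts; see [count_in_windows()].
#' @export
search_motif <- function(records, motif, window = 10000L) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    count_in_windows(records[i, , drop = FALSE], motif, window)
  })
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(res)) {
    res <- count_in_windows(list(id = character(0), seq = ""), motif, window)
    res <- res[0L, , drop = FALSE]
  }
  res
}
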