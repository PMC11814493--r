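# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

all_rotations <- function(u) {
  n <- nchar(u)
  vapply(seq_len(n) - 1L, function(i) {
    paste0(substr(u, i + 1L, n), substr(u, 1L, i))
  }, character(1))
}

oracle_revcomp <- function(u) {
  # route independent of chartr: via Biostrings
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(u)))
}

oracle_least_rotation <- function(u) min(all_rotations(u))

oracle_canonical <- function(u) {
  min(c(all_rotations(u), all_rotations(oracle_revcomp(u))))
}

# naive run detector: walk chunk by chunk, growing runs explicitly
oracle_runs <- function(seq, k) {
  n <- nchar(seq)
  m <- n %/% k
  chunks <- if (m > 0) {
    substring(seq, (seq_len(m) - 1L) * k + 1L, seq_len(m) * k)
  } else {
    character(0)
  }
  ok <- !grepl("[^ACGT]", chunks)
  out <- list()
  i <- 1L
  while (i <= m) {
    j <- i
    while (j < m && ok[j] && ok[j + 1L] && chunks[j + 1L] == chunks[i]) {
      j <- j + 1L
    }
    if (j > i) {
      out[[length(out) + 1L]] <- data.frame(
        unit = chunks[i], start = (i - 1L) * k, count = j - i + 1L,
        stringsAsFactors = FALSE)
    }
    i <- j + 1L
  }
  if (!length(out)) {
    return(data.frame(unit = character(0), start = integer(0),
                      count = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

oracle_explore_record <- function(seq, k, threshold) {
  runs <- oracle_runs(seq, k)
  runs <- runs[runs$count >= threshold, , drop = FALSE]
  if (!nrow(runs)) return(stats::setNames(numeric(0), character(0)))
  canon <- vapply(runs$unit, oracle_canonical, character(1))
  tal <- tapply(as.numeric(runs$count), canon, sum)
  out <- as.numeric(tal)
  names(out) <- names(tal)
  out[order(names(out))]
}

# quadratic all-occurrences scanner
oracle_find <- function(seq, motif) {
  n <- nchar(seq)
  m <- nchar(motif)
  if (m > n) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(n - m + 1L)) {
    if (substr(seq, i, i + m - 1L) == motif) hits <- c(hits, i - 1L)
  }
  hits
}

random_unit <- function(k) {
  paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# repeat-rich random sequence: biased towards tandem structure so that run
# detection actually has runs to find
random_repeatish_seq <- function(n) {
  parts <- character(0)
  total <- 0L
  while (total < n) {
    if (stats::runif(1) < 0.6) {
      u <- random_unit(sample(2:6, 1L))
      piece <- strrep(u, sample(1:12, 1L))
    } else {
      piece <- random_seq(sample(1:30, 1L), c("A", "C", "G", "T", "N"))
    }
    parts <- c(parts, piece)
    total <- total + nchar(piece)
  }
  substr(paste(parts, collapse = ""), 1L, n)
}
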