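.BASES <- c("A", "C", "G", "T")

.check_unit <- function(unit, arg = "unit") {
  if (!is.character(unit) || length(unit) != 1L || is.na(unit)) {
    stop(sprintf("`%s` must be a single character string", arg), call. = FALSE)
  }
  if (nchar(unit) == 0L) {
    stop(sprintf("`%s` must be non-empty", arg), call. = FALSE)
  }
  if (grepl("[^ACGT]", unit)) {
    stop(sprintf("`%s` contains characters outside A/C/G/T: \"%s\"", arg, unit),
         call. = FALSE)
  }
  invisible(unit)
}

#' Reverse complement of a repeat unit
#'
#' Complements each base (A<->T, C<->G) and reverses the result. Only defined
#' for sequences over the A/C/G/T alphabet; ambiguity codes are rejected
#' because their complement would be undefined for downstream
#' canonicalization.
#'
#' @param unit A single string over A/C/G/T.
#' @return A string of the same length; applying the function twice returns
#'   the input.
#' @examples
#' reverse_complement("TTAGGG")  # "CCCTAA"
#' @export
reverse_complement <- function(unit) {
  .check_unit(unit)
  paste(rev(strsplit(chartr("ACGT", "TGCA", unit), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

#' Lexicographically least rotation of a string
#'
#' Returns the rotation of `unit` that is smallest in plain byte order
#' (A < C < G < T on uppercase DNA). Uses Booth's linear-time least-rotation
#' algorithm.
#'
#' @param unit A single non-empty string over A/C/G/T.
#' @return The minimal rotation of `unit`.
#' @examples
#' least_rotation("TTAGGG")  # "AGGGTT"
#' @export
least_rotation <- function(unit) {
  .check_unit(unit)
  n <- nchar(unit)
  if (n == 1L) return(unit)
  s <- strsplit(paste0(unit, unit), "", fixed = TRUE)[[1L]]
  # Booth's algorithm: failure-function scan over the doubled string
  f <- rep.int(-1L, 2L * n)
  k <- 0L
  for (j in seq.int(2L, 2L * n)) {
    sj <- s[j]
    i <- f[j - k - 1L]
    while (i != -1L && sj != s[k + i + 2L]) {
      if (sj < s[k + i + 2L]) k <- j - i - 2L
      i <- f[i + 1L]
    }
    if (sj != s[k + i + 2L]) {
      if (sj < s[k + 1L]) k <- j - 1L
      f[j - k] <- -1L
    } else {
      f[j - k] <- i + 1L
    }
  }
  substr(paste(s, collapse = ""), k + 1L, k + n)
}

#' Canonical form of a repeat unit
#'
#' The canonical form is the lexicographically smallest string among all
#' rotations of the unit and all rotations of its reverse complement. It
#' identifies a tandem repeat irrespective of the phase in which it was read
#' and of the strand it was read from: `canonical("TTAGGG")`,
#' `canonical("GTTAGG")` and `canonical("CCCTAA")` all return `"AACCCT"`.
#'
#' A unit that is a whole multiple of a shorter unit (e.g. `"AACCCTAACCCT"`)
#' is *not* reduced to its primitive root; dimers and higher multiples are
#' distinct canonical forms.
#'
#' @param unit A single non-empty string over A/C/G/T.
#' @return The canonical form; idempotent under re-application.
#' @examples
#' canonical("TTAGGG")   # "AACCCT"
#' canonical("TTTAGGG")  # "AAACCCT"
#' @export
canonical <- function(unit) {
  fwd <- least_rotation(unit)
  rev <- least_rotation(reverse_complement(unit))
  if (fwd <= rev) fwd else rev
}

#' Merge a repeat-count map under canonical equivalence
#'
#' Re-keys a named count vector so that units identical up to rotation and
#' reverse complement share one canonical key, summing their counts. All keys
#' must be repeat units of equal length. The total count is conserved
#' exactly.
#'
#' @param counts A named numeric/integer vector: unit -> count. May be empty.
#' @return A named numeric vector keyed by canonical forms, sorted by key.
#' @examples
#' merge_counts(c(TTAGGG = 5, CCCTAA = 2, AACCCT = 3))  # AACCCT = 10
#' @export
merge_counts <- function(counts) {
  if (length(counts) == 0L) {
    out <- numeric(0)
    names(out) <- character(0)
    return(out)
  }
  keys <- names(counts)
  if (is.null(keys) || any(!nzchar(keys))) {
    stop("`counts` must be a named vector of repeat units", call. = FALSE)
  }
  if (length(unique(nchar(keys))) != 1L) {
    stop("all repeat units in `counts` must have equal length", call. = FALSE)
  }
  canon <- vapply(keys, canonical, character(1), USE.NAMES = FALSE)
  out <- tapply(as.numeric(counts), canon, sum)
  res <- as.numeric(out)
  names(res) <- names(out)
  res[order(names(res))]
}
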