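#' Read a FASTA file into a record table
#'
#' Reads a multi-record FASTA file (plain or gzip-compressed; compression is
#' detected from the file content, not the extension) and returns one row per
#' record in file order. Sequences are folded to uppercase. The record `id`
#' is the first whitespace-delimited token of the header line; the full
#' header is kept in `desc`. Characters outside A/C/G/T (N, IUPAC ambiguity
#' codes) are retained; downstream operations define their own handling.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id`, `desc`, `seq`, `length`
#'   (nucleotides), one row per record, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1 assembled", "ttaggg"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!is.character(path) || length(path) != 1L) {
    stop("`path` must be a single file path", call. = FALSE)
  }
  if (!file.exists(path)) {
    stop(sprintf("FASTA file not found: \"%s\"", path), call. = FALSE)
  }
  .check_fasta_leader(path)
  set <- Biostrings::readDNAStringSet(path, format = "fasta")
  headers <- names(set)
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", headers)
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop(sprintf("FASTA record \"%s\" has an empty sequence body",
                 ids[which(empty)[1L]]), call. = FALSE)
  }
  data.frame(id = unname(ids), desc = unname(headers), seq = unname(seqs),
             length = unname(nchar(seqs)), stringsAsFactors = FALSE)
}

# First non-blank character must open a header line; checked through a
# gz-transparent connection so plain and compressed input behave alike.
.check_fasta_leader <- function(path) {
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) {
      stop(sprintf("\"%s\" is empty: not a FASTA file", path), call. = FALSE)
    }
    trimmed <- sub("^\\s+", "", line)
    if (nzchar(trimmed)) {
      if (substr(trimmed, 1L, 1L) != ">") {
        stop(sprintf("\"%s\" is not FASTA: first non-blank character is not '>'",
                     path), call. = FALSE)
      }
      return(invisible(TRUE))
    }
  }
}

#' Write a FASTA file
#'
#' Companion writer for [read_fasta()], used mainly to build fixtures and to
#' persist simulated sequences. Sequences are wrapped at `width` characters.
#'
#' @param records A data.frame with columns `id` and `seq` (a `desc` column,
#'   if present, is written as the header instead of `id`).
#' @param path Output file path; a `.gz` suffix triggers gzip compression.
#' @param width Line-wrap width in characters.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 80L) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  headers <- if ("desc" %in% names(records)) records$desc else records$id
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    seq <- records$seq[i]
    n <- nchar(seq)
    starts <- seq.int(1L, max(n, 1L), by = width)
    body <- substring(seq, starts, pmin(starts + width - 1L, n))
    writeLines(c(paste0(">", headers[i]), body), con, sep = "\n")
  }
  invisible(path)
}

#' Write a tab-separated table
#'
#' Writes the toolkit's TSV dialect: UTF-8, one header line, tab-delimited
#' fields, LF line endings, no trailing tab and no quoting.
#'
#' @param rows A list of rows (each a vector with one element per column), or
#'   a data.frame.
#' @param header Character vector of column names.
#' @param path Output path, or `""` for standard output.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(rows, header, path) {
  if (is.data.frame(rows)) {
    rows <- lapply(seq_len(nrow(rows)), function(i) unlist(lapply(rows[i, ], as.character)))
  }
  arity <- length(header)
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) != arity) {
      stop(sprintf("TSV row %d has %d fields; header has %d", i,
                   length(rows[[i]]), arity), call. = FALSE)
    }
  }
  lines <- c(paste(header, collapse = "\t"),
             vapply(rows, function(r) paste(as.character(r), collapse = "\t"),
                    character(1)))
  if (identical(path, "")) {
    writeLines(lines, sep = "\n")
  } else {
    con <- file(path, open = "wb", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

#' Read a tab-separated table written by [write_tsv()]
#'
#' @param path Input TSV path.
#' @return A data.frame with character columns converted by type.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("TSV file not found: \"%s\"", path), call. = FALSE)
  }
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = NA)
}
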