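#' Load a clade-to-repeat database
#'
#' Reads a TSV with columns `clade`, `repeat`, `n_species`, `note` and
#' validates every row: the repeat must already be in canonical form (see
#' [canonical()]) and no (clade, repeat) pair may occur twice. A clade may
#' legitimately carry several repeats (compound telomeric landscapes such as
#' the bumblebee genus *Bombus*), so multiple rows per clade are allowed.
#'
#' @param path Path to the database TSV. Defaults to the table bundled with
#'   the package, which holds clade-level repeats reported from chromosomally
#'   complete reference assemblies (e.g. Chordata AACCCT, Arthropoda AACCT,
#'   flowering plants AAACCCT, Vespidae AACCCAGACCC).
#' @return A data.frame with columns `clade`, `repeat_unit`, `n_species`,
#'   `note`, in file order.
#' @export
load_database <- function(path = default_database_path()) {
  db <- read_tsv(path)
  expect <- c("clade", "repeat", "n_species", "note")
  if (!identical(names(db)[seq_along(expect)], expect)) {
    stop(sprintf("database \"%s\" must have columns: %s", path,
                 paste(expect, collapse = ", ")), call. = FALSE)
  }
  names(db)[names(db) == "repeat"] <- "repeat_unit"
  db$clade <- as.character(db$clade)
  db$repeat_unit <- toupper(as.character(db$repeat_unit))
  if (nrow(db)) {
    for (i in seq_len(nrow(db))) {
      canon <- canonical(db$repeat_unit[i])
      if (!identical(canon, db$repeat_unit[i])) {
        stop(sprintf(
          "database row %d: repeat \"%s\" is not canonical (canonical form is \"%s\")",
          i, db$repeat_unit[i], canon), call. = FALSE)
      }
    }
    key <- paste(tolower(db$clade), db$repeat_unit)
    if (anyDuplicated(key)) {
      stop(sprintf("database row %d: duplicate clade/repeat entry \"%s\"",
                   which(duplicated(key))[1L],
                   db$clade[which(duplicated(key))[1L]]), call. = FALSE)
    }
  }
  db
}

#' Path of the bundled clade database
#'
#' @return Path to the TSV installed with the package.
#' @export
default_database_path <- function() {
  system.file("extdata", "clade_repeats.tsv", package = "teloscan",
              mustWork = TRUE)
}

#' Look up the telomeric repeat(s) recorded for a clade
#'
#' Case-insensitive exact match on the clade name. When the name is unknown,
#' the error message suggests database entries within edit distance 2.
#'
#' @param clade Clade name, e.g. `"Chordata"`.
#' @param db A database as returned by [load_database()].
#' @return The matching rows of `db` (one or more).
#' @examples
#' lookup_clade("chordata")
#' @export
lookup_clade <- function(clade, db = load_database()) {
  stopifnot(is.character(clade), length(clade) == 1L)
  hit <- tolower(db$clade) == tolower(clade)
  if (!any(hit)) {
    dist <- utils::adist(tolower(clade), tolower(unique(db$clade)))[1L, ]
    near <- unique(db$clade)[dist <= 2L]
    msg <- sprintf("clade \"%s\" not found in the database", clade)
    if (length(near)) {
      msg <- paste0(msg, "; did you mean: ", paste(near, collapse = ", "), "?")
    }
    stop(msg, call. = FALSE)
  }
  db[hit, , drop = FALSE]
}

#' Install the clade database into a user data directory
#'
#' Copies the bundled database (or a user-supplied table, validated first)
#' into a per-user data directory so that other tools can find it at a
#' stable path.
#'
#' @param from_file Optional path to a user-supplied database TSV; validated
#'   with [load_database()] before installation.
#' @param data_dir Destination directory; defaults to the package's per-user
#'   data directory.
#' @return The installed file path, invisibly.
#' @export
build_database <- function(from_file = NULL,
                           data_dir = tools::R_user_dir("teloscan", "data")) {
  src <- if (is.null(from_file)) default_database_path() else from_file
  load_database(src)  # validate before installing
  dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)
  dest <- file.path(data_dir, "clade_repeats.tsv")
  file.copy(src, dest, overwrite = TRUE)
  invisible(dest)
}

#' Search a genome for the repeats recorded for a clade
#'
#' Looks the clade up with [lookup_clade()] and runs [search_motif()] once
#' per recorded repeat.
#'
#' @param records A data.frame of records as returned by [read_fasta()].
#' @param clade Clade name.
#' @param window Window width in nucleotides.
#' @param db A database as returned by [load_database()].
#' @return A named list of window-count tables, one per repeat, named by the
#'   repeat unit.
#' @export
find_clade <- function(records, clade, window = 10000L, db = load_database()) {
  hits <- lookup_clade(clade, db)
  out <- lapply(hits$repeat_unit, function(m) search_motif(records, m, window))
  names(out) <- hits$repeat_unit
  out
}
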