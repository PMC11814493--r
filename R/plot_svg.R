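#' Read a window-count TSV for plotting
#'
#' Parses the TSV dialect written by [search_motif()] /
#' [write_windows_tsv()], validating every data line and reporting the line
#' number of the first malformed one.
#'
#' @param path Input TSV path.
#' @return A window-count data.frame (columns `id`, `window_start`,
#'   `window_end`, `forward_count`, `reverse_count`).
#' @export
read_windows_tsv <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("TSV file not found: \"%s\"", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  cols <- c("id", "window_start", "window_end", "forward_repeat_number",
            "reverse_repeat_number")
  if (!length(lines) || !identical(strsplit(lines[1L], "\t")[[1L]], cols)) {
    stop(sprintf("line 1 of \"%s\": expected header %s", path,
                 paste(cols, collapse = "\\t")), call. = FALSE)
  }
  n <- length(lines) - 1L
  out <- data.frame(id = character(n), window_start = integer(n),
                    window_end = integer(n), forward_count = integer(n),
                    reverse_count = integer(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    fields <- strsplit(lines[i + 1L], "\t")[[1L]]
    nums <- suppressWarnings(as.integer(fields[-1L]))
    if (length(fields) != 5L || anyNA(nums)) {
      stop(sprintf("line %d of \"%s\": malformed window-count row", i + 1L,
                   path), call. = FALSE)
    }
    out$id[i] <- fields[1L]
    out[i, 2:5] <- as.list(nums)
  }
  out
}

#' Write a window-count table in the search TSV dialect
#'
#' @param rows A window-count data.frame from [search_motif()].
#' @param path Output path, or `""` for standard output.
#' @return `path`, invisibly.
#' @export
write_windows_tsv <- function(rows, path) {
  header <- c("id", "window_start", "window_end", "forward_repeat_number",
              "reverse_repeat_number")
  write_tsv(rows, header, path)
}

.svg_num <- function(x) sprintf("%.2f", x)

#' Render window counts as an SVG of per-sequence line plots
#'
#' Draws one track (sub-plot) per sequence: the x axis is the position along
#' the sequence and the y axis the number of motif hits per window, plotted
#' as `forward_count + reverse_count` (an assembled telomere may sit on
#' either strand). Tracks are ordered by descending sequence length and
#' capped at `max_tracks`. The output is plain SVG 1.1 with inline styling
#' and no timestamps or generated identifiers, so identical input produces
#' byte-identical files.
#'
#' @param rows A window-count data.frame ([search_motif()] output or
#'   [read_windows_tsv()]).
#' @param out Output SVG path.
#' @param width Total image width in pixels.
#' @param height_per_track Height of each per-sequence track in pixels.
#' @param max_tracks Maximum number of sequences drawn.
#' @return `out`, invisibly.
#' @export
plot_svg <- function(rows, out, width = 1000, height_per_track = 120,
                     max_tracks = 25L) {
  if (!is.data.frame(rows) || nrow(rows) == 0L) {
    stop("nothing to plot: the window-count table is empty", call. = FALSE)
  }
  stopifnot(width > 0, height_per_track > 0, max_tracks >= 1L)
  ids <- unique(rows$id)
  len <- vapply(ids, function(i) max(rows$window_end[rows$id == i]),
                numeric(1))
  ids <- ids[order(-len, ids)]
  if (length(ids) > max_tracks) ids <- ids[seq_len(max_tracks)]
  margin <- c(left = 60, right = 20, top = 28, bottom = 26)
  plot_w <- width - margin[["left"]] - margin[["right"]]
  svg <- c(sprintf(
    paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" version=\"1.1\" ",
           "width=\"%s\" height=\"%s\" viewBox=\"0 0 %s %s\">"),
    .svg_num(width), .svg_num(length(ids) * height_per_track),
    .svg_num(width), .svg_num(length(ids) * height_per_track)))
  for (t in seq_along(ids)) {
    id <- ids[t]
    sub <- rows[rows$id == id, , drop = FALSE]
    sub <- sub[order(sub$window_start), , drop = FALSE]
    y_top <- (t - 1) * height_per_track
    seq_len_nt <- max(sub$window_end)
    y_max <- max(sub$forward_count + sub$reverse_count, 1)
    ph <- height_per_track - margin[["top"]] - margin[["bottom"]]
    mid <- (sub$window_start + sub$window_end) / 2
    px <- margin[["left"]] + plot_w * mid / seq_len_nt
    py <- y_top + margin[["top"]] +
      ph * (1 - (sub$forward_count + sub$reverse_count) / y_max)
    pts <- paste(paste0(.svg_num(px), ",", .svg_num(py)), collapse = " ")
    svg <- c(svg,
      sprintf("<g id=\"track-%d\">", t),
      sprintf("<text x=\"%s\" y=\"%s\" font-family=\"sans-serif\" font-size=\"12\">%s</text>",
              .svg_num(margin[["left"]]), .svg_num(y_top + 16),
              .xml_escape(id)),
      sprintf("<line x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" stroke=\"#333333\" stroke-width=\"1\"/>",
              .svg_num(margin[["left"]]),
              .svg_num(y_top + margin[["top"]] + ph),
              .svg_num(margin[["left"]] + plot_w),
              .svg_num(y_top + margin[["top"]] + ph)),
      sprintf("<line x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" stroke=\"#333333\" stroke-width=\"1\"/>",
              .svg_num(margin[["left"]]), .svg_num(y_top + margin[["top"]]),
              .svg_num(margin[["left"]]),
              .svg_num(y_top + margin[["top"]] + ph)),
      sprintf("<text x=\"%s\" y=\"%s\" font-family=\"sans-serif\" font-size=\"10\" text-anchor=\"end\">%s</text>",
              .svg_num(margin[["left"]] - 4),
              .svg_num(y_top + margin[["top"]] + 4), .svg_num(y_max)),
      sprintf("<text x=\"%s\" y=\"%s\" font-family=\"sans-serif\" font-size=\"10\" text-anchor=\"end\">position (nt); max %s</text>",
              .svg_num(margin[["left"]] + plot_w),
              .svg_num(y_top + margin[["top"]] + ph + 18),
              .svg_num(seq_len_nt)),
      sprintf("<polyline fill=\"none\" stroke=\"#1f77b4\" stroke-width=\"1.5\" points=\"%s\"/>",
              pts),
      "</g>")
  }
  svg <- c(svg, "</svg>")
  con <- file(out, open = "wb")
  on.exit(close(con))
  writeLines(svg, con, sep = "\n")
  invisible(out)
}

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}
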