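#' Read an RR-interval series from disk
#'
#' Two plain-text layouts are supported. `txt`: one interval per line in
#' milliseconds, with `#`-prefixed comment lines allowed. `csv`: two columns
#' `t_s, rr_ms` (header optional); the time column is trusted only for row
#' ordering — the cumulative time axis is always re-derived from the
#' intervals, so the intervals are the single source of truth.
#'
#' @param path path to the file.
#' @param format `"txt"`, `"csv"`, or `"auto"` (by file extension, default
#'   `txt`).
#' @param label optional subject/group tag stored on the result.
#' @return An [rr_series] with `meta$source` set to `path`.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(c("800", "810", "790"), f)
#' read_rr_series(f)
#' @export
read_rr_series <- function(path, format = c("auto", "txt", "csv"),
                           label = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "txt"
  series <- switch(format,
                   txt = read_rr_txt(path),
                   csv = read_rr_csv(path))
  series$label <- label
  series$meta$source <- path
  series$meta$format <- format
  series
}

read_rr_txt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop(sprintf("empty series: %s", path))
  vals <- suppressWarnings(as.numeric(lines))
  bad <- which(is.na(vals) | !nzchar(trimws(lines)))
  if (length(bad) > 0L)
    stop(sprintf("non-numeric or blank line%s at line %s in %s",
                 if (length(bad) > 1L) "s" else "",
                 paste(head(lineno[bad], 10L), collapse = ", "), path))
  neg <- which(vals <= 0)
  if (length(neg) > 0L)
    stop(sprintf("non-positive RR interval at line %s in %s",
                 paste(head(lineno[neg], 10L), collapse = ", "), path))
  rr_series(vals)
}

read_rr_csv <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) stop(sprintf("empty series: %s", path))
  has_header <- is.na(suppressWarnings(as.numeric(strsplit(first, ",")[[1]][1])))
  df <- read.csv(path, header = has_header,
                 col.names = c("t_s", "rr_ms"),
                 colClasses = c("numeric", "numeric"))
  if (nrow(df) == 0L) stop(sprintf("empty series: %s", path))
  # the time column orders the rows; intervals define the time axis
  df <- df[order(df$t_s), , drop = FALSE]
  neg <- which(df$rr_ms <= 0)
  if (length(neg) > 0L)
    stop(sprintf("non-positive RR interval at data row %s in %s",
                 paste(head(neg, 10L), collapse = ", "), path))
  rr_series(df$rr_ms)
}

#' Write an RR-interval series to disk
#'
#' Inverse of [read_rr_series()]; a read-write-read round trip reproduces
#' the interval values exactly.
#'
#' @param series an [rr_series].
#' @param path output path.
#' @param format `"txt"` (one ms value per line) or `"csv"` (`t_s,rr_ms`
#'   with header).
#' @return `path`, invisibly.
#' @export
write_rr_series <- function(series, path, format = c("txt", "csv")) {
  stopifnot(inherits(series, "rr_series"))
  format <- match.arg(format)
  if (format == "txt") {
    writeLines(sprintf("%.17g", series$intervals), path)
  } else {
    df <- data.frame(t_s = sprintf("%.17g", series$t),
                     rr_ms = sprintf("%.17g", series$intervals))
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
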