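#' Construct an RR-interval series (tachogram)
#'
#' An `rr_series` holds an ordered sequence of RR intervals in milliseconds
#' together with the derived cumulative occurrence time of each beat. The
#' time axis is always re-derived from the intervals: beat `i` occurs at
#' `t[i] = sum(intervals[1:(i-1)]) / 1000` seconds, with `t[1] = 0`.
#'
#' @param intervals numeric vector of RR intervals, milliseconds; all must be
#'   finite and strictly positive.
#' @param label optional free-text subject/group tag.
#' @param meta named list of provenance information (source file,
#'   preprocessing applied, generator parameters, ...).
#' @return An object of class `rr_series` with elements `intervals` (ms),
#'   `t` (s, cumulative), `label` and `meta`.
#' @examples
#' rr <- rr_series(c(800, 810, 790))
#' rr$t  # 0.00 0.80 1.61
#' @export
rr_series <- function(intervals, label = NULL, meta = list()) {
  intervals <- as.numeric(intervals)
  if (length(intervals) < 1L)
    stop("empty series: at least one RR interval is required")
  if (anyNA(intervals) || any(!is.finite(intervals)))
    stop("RR intervals must be finite and non-missing")
  if (any(intervals <= 0)) {
    bad <- which(intervals <= 0)
    stop(sprintf("RR intervals must be strictly positive (offending index%s: %s)",
                 if (length(bad) > 1L) "es" else "",
                 paste(head(bad, 5L), collapse = ", ")))
  }
  structure(
    list(intervals = intervals,
         t = cumsum(c(0, intervals[-length(intervals)])) / 1000,
         label = label,
         meta = meta),
    class = "rr_series")
}

#' @export
length.rr_series <- function(x) length(x$intervals)

#' Total recording span of a tachogram
#'
#' Duration in seconds from the first beat to the end of the last interval.
#'
#' @param series an [rr_series].
#' @return span in seconds.
#' @export
rr_span <- function(series) {
  stopifnot(inherits(series, "rr_series"))
  n <- length(series$intervals)
  series$t[n] + series$intervals[n] / 1000
}

#' @export
print.rr_series <- function(x, ...) {
  n <- length(x$intervals)
  cat(sprintf("<rr_series> %d beats, span %.1f s, mean RR %.1f ms",
              n, rr_span(x), mean(x$intervals)))
  if (!is.null(x$label)) cat(sprintf(" [%s]", x$label))
  cat("\n")
  invisible(x)
}

#' @export
plot.rr_series <- function(x, type = "l", xlab = "time (s)",
                           ylab = "RR (ms)", ...) {
  graphics::plot(x$t, x$intervals, type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

# Coerce numeric vectors for internal use; analyses accept either an
# rr_series or a bare numeric vector of intervals in ms.
as_rr_intervals <- function(x) {
  if (inherits(x, "rr_series")) x$intervals else as.numeric(x)
}
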