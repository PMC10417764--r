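#' Physiologic-bounds preprocessing policy
#'
#' RR intervals outside `[rr_min, rr_max]` are treated as artifacts. The
#' defaults, 333 and 2000 ms, are the conventional physiologic plausibility
#' bounds for adult normal-to-normal intervals (180 and 30 beats/min). No
#' ectopic-beat (NN-vs-RR) classification is attempted: bounds filtering is
#' the only cleaning performed.
#'
#' @param rr_min,rr_max inclusive bounds, ms; `0 < rr_min < rr_max`.
#' @param action what to do with an offending interval: `"drop"` removes it
#'   and rebuilds the time axis, `"interpolate"` replaces it by linear
#'   interpolation of its valid neighbours, `"error"` aborts.
#' @return An object of class `preprocess_policy`.
#' @export
preprocess_policy <- function(rr_min = 333, rr_max = 2000,
                              action = c("drop", "interpolate", "error")) {
  action <- match.arg(action)
  if (!(rr_min > 0 && rr_min < rr_max))
    stop("invalid policy: need 0 < rr_min < rr_max")
  structure(list(rr_min = rr_min, rr_max = rr_max, action = action),
            class = "preprocess_policy")
}

#' Filter artifacts from an RR series by physiologic bounds
#'
#' Applies a [preprocess_policy()] to a tachogram. The operation is
#' idempotent: applying it twice gives the same result as applying it once.
#' If more than 20% of the beats violate the bounds, a warning is emitted
#' regardless of the action, since the surviving series may not be
#' representative.
#'
#' @param series an [rr_series].
#' @param policy a [preprocess_policy()].
#' @return A cleaned [rr_series]; `meta$preprocess` records the policy and
#'   the number of intervals removed or interpolated.
#' @examples
#' rr <- rr_series(c(800, 50, 810))
#' preprocess_rr(rr)$intervals                        # 800 810
#' preprocess_rr(rr, preprocess_policy(action = "interpolate"))$intervals
#' @export
preprocess_rr <- function(series, policy = preprocess_policy()) {
  stopifnot(inherits(series, "rr_series"), inherits(policy, "preprocess_policy"))
  x <- series$intervals
  bad <- which(x < policy$rr_min | x > policy$rr_max)
  n_bad <- length(bad)
  if (n_bad > 0.2 * length(x))
    warning(sprintf("%d of %d intervals (%.0f%%) violate [%g, %g] ms",
                    n_bad, length(x), 100 * n_bad / length(x),
                    policy$rr_min, policy$rr_max))
  if (n_bad > 0L && policy$action == "error")
    stop(sprintf("%d interval(s) outside [%g, %g] ms (first at index %d)",
                 n_bad, policy$rr_min, policy$rr_max, bad[1]))
  if (n_bad == 0L) {
    out <- x
  } else if (policy$action == "drop") {
    out <- x[-bad]
    if (length(out) == 0L)
      stop("preprocessing removed every interval")
  } else { # interpolate
    good <- setdiff(seq_along(x), bad)
    if (length(good) < 2L)
      stop("too few valid intervals to interpolate")
    out <- x
    out[bad] <- approx(good, x[good], xout = bad, rule = 2)$y
  }
  meta <- series$meta
  meta$preprocess <- list(rr_min = policy$rr_min, rr_max = policy$rr_max,
                          action = policy$action,
                          n_removed = if (policy$action == "drop") n_bad else 0L,
                          n_interpolated = if (policy$action == "interpolate") n_bad else 0L)
  rr_series(out, label = series$label, meta = meta)
}

#' Segment a tachogram into consecutive time windows
#'
#' Splits the series into non-overlapping windows of `window_s` seconds of
#' cumulative time. Each beat belongs to exactly one window (by its
#' occurrence time); a trailing window not fully covered by the recording is
#' kept and flagged partial. Concatenating the segments reproduces the input
#' intervals exactly, in order.
#'
#' @param series an [rr_series].
#' @param window_s window length, seconds (default 300 = 5 min, the
#'   conventional SDANN/SDNN-index block).
#' @return A list of [rr_series] segments; each has `meta$window_index`,
#'   `meta$window_start` (s) and logical `meta$partial`.
#' @export
segment_series <- function(series, window_s = 300) {
  stopifnot(inherits(series, "rr_series"))
  if (window_s <= 0) stop("window_s must be positive")
  if (window_s < series$intervals[1] / 1000)
    stop("window shorter than the first RR interval")
  idx <- floor(series$t / window_s)
  span <- rr_span(series)
  n_win <- max(idx) + 1L
  lapply(seq_len(n_win) - 1L, function(w) {
    sel <- idx == w
    seg <- rr_series(series$intervals[sel], label = series$label)
    seg$meta <- list(window_index = w + 1L,
                     window_start = w * window_s,
                     partial = span < (w + 1L) * window_s)
    seg
  })
}
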