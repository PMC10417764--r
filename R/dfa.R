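#' Default DFA box sizes
#'
#' Log2-spaced (quarter-octave) integer box sizes between `n_min` and
#' `n_max` beats. The 4–64 beat range with the short/long split at 16 is
#' the de facto standard for HRV DFA.
#'
#' @param n_min,n_max smallest and largest box, beats.
#' @return Sorted unique integer vector.
#' @export
dfa_default_boxes <- function(n_min = 4, n_max = 64) {
  unique(round(2^seq(log2(n_min), log2(n_max), by = 0.25)))
}

#' Detrended fluctuation analysis
#'
#' Estimates the DFA scaling exponent of an RR series. The integrated
#' profile `y = cumsum(x - mean(x))` is split, for each box size `n`, into
#' `floor(N/n)` non-overlapping boxes counted both from the start and from
#' the end of the record (so that no tail is systematically discarded);
#' each box is detrended by a least-squares polynomial of the given order
#' and `F(n)` is the root-mean-square residual over the boxes of both
#' passes. The exponents are least-squares slopes of `log2 F` versus
#' `log2 n`:
#'
#' * `alpha`  — over all box sizes;
#' * `alpha1` — short-range boxes, `short_range[1] <= n <= short_range[2]`
#'   (default 4–16 beats);
#' * `alpha2` — long-range boxes, `short_range[2] < n <= long_range[2]`
#'   (default 16–64 beats).
#'
#' `alpha = 0.5` corresponds to an uncorrelated (white-noise) series,
#' `alpha < 0.5` to anti-correlation, and `0.5 < alpha < 1` to long-range
#' persistence; for fractional Gaussian noise with Hurst exponent H,
#' `alpha` estimates H.
#'
#' @param series an [rr_series] or numeric vector (ms).
#' @param box_sizes integer box sizes, beats; boxes larger than the series
#'   are dropped with a warning.
#' @param order polynomial detrending order (default 1, linear).
#' @param short_range,long_range inclusive `[lo, hi]` box ranges for
#'   `alpha1` and `alpha2`.
#' @return An object of class `dfa_result`: `box_sizes`, `fluctuations`,
#'   `alpha`, `alpha1`, `alpha2`, `fit_ranges`, and `log2_n` / `log2_f`
#'   points for log-log plotting.
#' @examples
#' d <- dfa(gen_gaussian_rr(4000, seed = 1))
#' d$alpha   # near 0.5 for an uncorrelated series
#' @export
dfa <- function(series, box_sizes = dfa_default_boxes(), order = 1,
                short_range = c(4, 16), long_range = c(16, 64)) {
  x <- as_rr_intervals(series)
  N <- length(x)
  box_sizes <- sort(unique(as.integer(box_sizes)))
  if (any(box_sizes < order + 2))
    stop(sprintf("box sizes must be at least order + 2 = %d", order + 2))
  usable <- box_sizes[box_sizes <= N %/% 2]
  if (length(usable) < length(box_sizes))
    warning(sprintf("dropping %d box size(s) too large for a series of %d beats",
                    length(box_sizes) - length(usable), N))
  if (length(usable) < 3L) stop("fewer than 3 usable box sizes")

  y <- cumsum(x - mean(x))
  Fn <- vapply(usable, function(n) {
    nb <- N %/% n
    X <- stats::poly(seq_len(n), degree = order, raw = TRUE)
    Q <- qr.Q(qr(cbind(1, X)))
    ms <- function(idx) {
      Y <- matrix(y[idx], nrow = n)
      R <- Y - Q %*% crossprod(Q, Y)
      mean(R^2)
    }
    fwd <- ms(seq_len(nb * n))
    bwd <- ms((N - nb * n + 1L):N)
    sqrt((fwd + bwd) / 2)
  }, 0)

  slope <- function(sel) {
    if (sum(sel) < 2L) return(NA_real_)
    unname(coef(lm.fit(cbind(1, log2(usable[sel])),
                       log2(Fn[sel])))[2])
  }
  structure(
    list(box_sizes = usable,
         fluctuations = Fn,
         alpha = slope(rep(TRUE, length(usable))),
         alpha1 = slope(usable >= short_range[1] & usable <= short_range[2]),
         alpha2 = slope(usable > short_range[2] & usable <= long_range[2]),
         fit_ranges = list(short = short_range, long = long_range),
         log2_n = log2(usable),
         log2_f = log2(Fn)),
    class = "dfa_result")
}

#' @export
print.dfa_result <- function(x, ...) {
  cat(sprintf("<dfa_result> alpha %.3f  alpha1 %.3f  alpha2 %.3f  (%d box sizes %d-%d)\n",
              x$alpha, x$alpha1, x$alpha2, length(x$box_sizes),
              min(x$box_sizes), max(x$box_sizes)))
  invisible(x)
}

#' @export
plot.dfa_result <- function(x, xlab = "log2 n (beats)",
                            ylab = "log2 F(n)", ...) {
  graphics::plot(x$log2_n, x$log2_f, xlab = xlab, ylab = ylab, ...)
  graphics::abline(lm(x$log2_f ~ x$log2_n), lty = 2)
  invisible(x)
}
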