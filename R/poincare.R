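#' Poincare plot descriptors
#'
#' From the scatter of each interval against its successor, SD1 measures
#' dispersion across the identity line (beat-to-beat, parasympathetically
#' mediated variability) and SD2 dispersion along it (longer-term
#' variability). They are computed from the moment identities
#' `sd1^2 = var(diff(RR)) / 2` and `sd2^2 = 2 * var(RR) - sd1^2`, using
#' population (n-denominator) variances — these are identities on the
#' point cloud, not estimators — so `sd1^2 + sd2^2 = 2 * var(RR)` holds
#' exactly on every input for which the construction is well defined. For
#' extreme anti-correlation at very short lengths (roughly n < 10; never
#' physiologic tachograms) the implied `sd2^2` can be negative; `sd2` is
#' then reported as 0 and the result flagged `degenerate`.
#'
#' @param series an [rr_series] or numeric vector (ms), length >= 3.
#' @return An object of class `poincare_result`: `sd1`, `sd2` (ms), `ratio`
#'   (`sd1/sd2`, `NA` when `sd2 = 0`), and the scatter payload `x`
#'   (RR\[i\]) / `y` (RR\[i+1\]) for plotting.
#' @examples
#' poincare_descriptors(gen_gaussian_rr(1000, seed = 1))
#' @export
poincare_descriptors <- function(series) {
  x <- as_rr_intervals(series)
  n <- length(x)
  if (n < 3L) stop("Poincare descriptors need at least 3 intervals")
  pvar <- function(v) mean((v - mean(v))^2)
  sd1sq <- pvar(diff(x)) / 2
  sd2sq <- 2 * pvar(x) - sd1sq
  degenerate <- sd2sq < 0
  sd1 <- sqrt(sd1sq)
  sd2 <- sqrt(max(sd2sq, 0))
  structure(
    list(sd1 = sd1, sd2 = sd2,
         ratio = if (sd2 > 0) sd1 / sd2 else NA_real_,
         degenerate = degenerate,
         x = x[-n], y = x[-1]),
    class = "poincare_result")
}

#' @export
print.poincare_result <- function(x, ...) {
  cat(sprintf("<poincare_result> SD1 %.2f ms  SD2 %.2f ms  SD1/SD2 %s\n",
              x$sd1, x$sd2, fmt_or_na(x$ratio, "%.3f")))
  invisible(x)
}

#' @export
plot.poincare_result <- function(x, xlab = "RR[i] (ms)",
                                 ylab = "RR[i+1] (ms)", pch = ".", ...) {
  graphics::plot(x$x, x$y, xlab = xlab, ylab = ylab, pch = pch,
                 asp = 1, ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}
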