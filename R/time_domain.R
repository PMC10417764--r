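#' Time-domain HRV statistics
#'
#' Computes the standard statistical time-domain HRV battery from a
#' tachogram:
#'
#' * `mean_rr`, `mean_hr` (= 60000 / `mean_rr`), `rr_min`, `rr_max`;
#' * `sdnn` — sample standard deviation of all intervals;
#' * `rmssd` — root mean square of successive differences;
#' * `nn50`, `pnn50` — count / percentage of successive differences whose
#'   absolute value exceeds 50 ms (strict `>`), denominator `n - 1`;
#' * `sdann` — sample sd of per-window mean RR over consecutive `window_s`
#'   blocks (needs at least 2 usable windows);
#' * `sdnn_index` — mean of the per-window sample sd.
#'
#' Windows with fewer than `min_beats` beats are excluded from SDANN and the
#' SDNN index: the per-window sd is unstable on very short blocks, and the
#' trailing partial block of a long recording would otherwise contaminate
#' the summary. Sample (n−1) standard deviations are used throughout, the
#' convention of reference HRV software; set `population_sd = TRUE` for the
#' n-denominator variant.
#'
#' @param series an [rr_series] of length at least 2.
#' @param window_s SDANN / SDNN-index block length, seconds (default 300).
#' @param min_beats minimum beats for a window to enter SDANN / SDNN index
#'   (default 30).
#' @param population_sd use n instead of n−1 denominators.
#' @return An object of class `time_domain_result`: a list with fields
#'   `mean_rr`, `mean_hr`, `rr_min`, `rr_max`, `sdnn`, `sdann`, `rmssd`,
#'   `nn50`, `pnn50`, `sdnn_index`, `n_beats`. `sdann` / `sdnn_index` are
#'   `NA` (with `attr(, "reason")`) when too few usable windows exist.
#' @examples
#' rr <- rr_series(c(800, 810, 790, 850))
#' time_domain_summary(rr)$rmssd   # sqrt((10^2 + 20^2 + 60^2)/3)
#' @export
time_domain_summary <- function(series, window_s = 300, min_beats = 30,
                                population_sd = FALSE) {
  stopifnot(inherits(series, "rr_series"))
  x <- series$intervals
  n <- length(x)
  if (n < 2L) stop("time-domain analysis needs at least 2 intervals")
  sdfun <- if (population_sd) function(v) sqrt(mean((v - mean(v))^2)) else sd
  d <- diff(x)
  nn50 <- sum(abs(d) > 50)

  segs <- segment_series(series, window_s)
  usable <- Filter(function(s) length(s$intervals) >= min_beats, segs)
  if (length(usable) >= 2L) {
    sdann <- sdfun(vapply(usable, function(s) mean(s$intervals), 0))
  } else {
    sdann <- NA_real_
    attr(sdann, "reason") <- sprintf("only %d usable %gs window(s)",
                                     length(usable), window_s)
  }
  if (length(usable) >= 1L) {
    sdnn_index <- mean(vapply(usable, function(s) sdfun(s$intervals), 0))
  } else {
    sdnn_index <- NA_real_
    attr(sdnn_index, "reason") <- "no usable window"
  }

  structure(
    list(mean_rr = mean(x),
         mean_hr = 60000 / mean(x),
         rr_min = min(x),
         rr_max = max(x),
         sdnn = sdfun(x),
         sdann = sdann,
         rmssd = sqrt(mean(d^2)),
         nn50 = nn50,
         pnn50 = 100 * nn50 / (n - 1L),
         sdnn_index = sdnn_index,
         n_beats = n,
         window_s = window_s),
    class = "time_domain_result")
}

#' @export
print.time_domain_result <- function(x, ...) {
  cat("<time_domain_result>\n")
  cat(sprintf("  MeanRR %.2f ms  MeanHR %.2f bpm  N %d\n",
              x$mean_rr, x$mean_hr, x$n_beats))
  cat(sprintf("  SDNN %.2f  SDANN %s  RMSSD %.2f  SDNN index %s (ms)\n",
              x$sdnn, fmt_or_na(x$sdann), x$rmssd, fmt_or_na(x$sdnn_index)))
  cat(sprintf("  NN50 %d  pNN50 %.2f%%  RR range [%g, %g] ms\n",
              x$nn50, x$pnn50, x$rr_min, x$rr_max))
  invisible(x)
}

fmt_or_na <- function(v, fmt = "%.2f") {
  if (is.na(v)) "NA" else sprintf(fmt, v)
}

#' Serialize a time-domain result to the conventional parameter names
#'
#' @param x a `time_domain_result`.
#' @return A named list keyed `MeanRR`, `MeanHR`, `RRmin`, `RRmax`, `SDNN`,
#'   `SDANN`, `RMSSD`, `NN50`, `pNN50`, `SDNNIndex`, `N`, suitable for
#'   `jsonlite::toJSON`.
#' @export
as_table1_list <- function(x) {
  stopifnot(inherits(x, "time_domain_result"))
  list(MeanRR = x$mean_rr, MeanHR = x$mean_hr,
       RRmin = x$rr_min, RRmax = x$rr_max,
       SDNN = x$sdnn, SDANN = as.numeric(x$sdann),
       RMSSD = x$rmssd, NN50 = x$nn50, pNN50 = x$pnn50,
       SDNNIndex = as.numeric(x$sdnn_index), N = x$n_beats)
}
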