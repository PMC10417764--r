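#' Approximate entropy of an RR series
#'
#' ApEn(m, r) = phi_m(r) − phi_(m+1)(r), where phi_m is the mean logarithm
#' of the proportion of length-`m` templates lying within Chebyshev
#' distance `r` of each template, self-matches included. Low values
#' indicate regularity; higher values indicate complexity.
#'
#' Defaults follow the literature convention for HRV: embedding length
#' `m = 2` and a tolerance of 0.2 times the sample standard deviation of
#' the series (in ms, since the intervals are in ms).
#'
#' @param series an [rr_series] or numeric vector (ms).
#' @param m embedding (template) length.
#' @param r tolerance, ms. Default `0.2 * sd(series)`; a constant series
#'   has sd 0, in which case an explicit positive `r` must be supplied.
#' @return Dimensionless entropy value.
#' @examples
#' approximate_entropy(rep(800, 50), r = 1)  # 0: perfect regularity
#' @export
approximate_entropy <- function(series, m = 2, r = NULL) {
  x <- as_rr_intervals(series)
  if (length(x) <= m + 1) stop("series too short for embedding length m")
  r <- default_entropy_r(x, r)
  apen_phi(x, as.integer(m), r) - apen_phi(x, as.integer(m) + 1L, r)
}

#' Sample entropy of an RR series
#'
#' SampEn(m, r) = −ln(A/B), where B counts pairs of length-`m` templates
#' within Chebyshev distance `r` and A the subset that still match when
#' extended to length `m + 1`; self-matches are excluded. Unlike
#' approximate entropy it is unbiased by self-counting and is exactly 0 on
#' strictly periodic series.
#'
#' @inheritParams approximate_entropy
#' @return Dimensionless entropy value, or `NA` with
#'   `attr(, "flag") = "undefined (no matches)"` when either count is zero.
#' @examples
#' sample_entropy(rep(c(800, 600), 25), r = 50)  # 0: A = B
#' @export
sample_entropy <- function(series, m = 2, r = NULL) {
  x <- as_rr_intervals(series)
  if (length(x) <= m + 1) stop("series too short for embedding length m")
  r <- default_entropy_r(x, r)
  ab <- sampen_counts(x, as.integer(m), r)
  if (ab[1] == 0 || ab[2] == 0) {
    out <- NA_real_
    attr(out, "flag") <- "undefined (no matches)"
    return(out)
  }
  -log(ab[1] / ab[2])
}

default_entropy_r <- function(x, r) {
  if (is.null(r)) r <- 0.2 * sd(x)
  if (!is.finite(r) || r <= 0)
    stop("tolerance r must be positive; supply an explicit r for a constant series")
  r
}
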