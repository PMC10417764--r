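#' Full HRV analysis battery for one subject
#'
#' Runs the time-domain, geometric and nonlinear analyses (and, when the
#' recording is long enough, the spectral band powers) on one tachogram
#' and returns a flat named numeric vector — the per-subject row used by
#' [summarize_cohort()] and [flag_against_norms()]. Parameters that are
#' undefined for the input (e.g. SampEn with no matches, SDANN with a
#' single window) are `NA`.
#'
#' For very long recordings the entropy statistics are computed on the
#' first `entropy_max_beats` intervals: the template-counting algorithms
#' are quadratic in the series length and ApEn/SampEn estimates stabilize
#' well below that size.
#'
#' @param series an [rr_series].
#' @param config configuration list from [hrv_config()].
#' @return Named numeric vector with elements `MeanRR`, `MeanHR`, `RRmin`,
#'   `RRmax`, `SDNN`, `SDANN`, `RMSSD`, `NN50`, `pNN50`, `SDNNIndex`,
#'   `HRVTi`, `TINN`, `alpha`, `alpha1`, `alpha2`, `SD1`, `SD2`,
#'   `SD1SD2`, `ApEn`, `SampEn`, `h`, `VLF`, `LF`, `HF`, `LFHF`, `N`.
#' @export
hrv_battery <- function(series, config = hrv_config()) {
  suppressWarnings(hrv_battery_impl(series, config))
}

# warnings about degenerate sub-analyses are expected when screening whole
# cohorts; undefined cells surface as NA instead
hrv_battery_impl <- function(series, config) {
  stopifnot(inherits(series, "rr_series"))
  x <- series$intervals
  td <- time_domain_summary(series,
                            window_s = config$time_domain$window_s,
                            min_beats = config$time_domain$min_beats)
  geo <- tryCatch(geometric_summary(series, config$geometric$bin_width),
                  error = function(e) NULL)
  nl_alpha <- tryCatch(
    dfa(series,
        box_sizes = dfa_default_boxes(config$dfa$n_min, config$dfa$n_max),
        order = config$dfa$order,
        short_range = config$dfa$short_range,
        long_range = config$dfa$long_range),
    error = function(e) NULL)
  pc <- tryCatch(poincare_descriptors(series), error = function(e) NULL)
  n_ent <- min(length(x), config$entropy$max_beats)
  xe <- x[seq_len(n_ent)]
  r_ent <- config$entropy$r_factor * sd(xe)
  apen <- tryCatch(approximate_entropy(xe, m = config$entropy$m, r = r_ent),
                   error = function(e) NA_real_)
  sampen <- tryCatch(sample_entropy(xe, m = config$entropy$m, r = r_ent),
                     error = function(e) NA_real_)
  hrs <- tryCatch(hurst_rs(series, correction = config$hurst$correction),
                  error = function(e) NULL)
  bp <- tryCatch({
    tach <- resample_tachogram(series, fs = config$spectral$fs)
    band_powers(welch_psd(tach,
                          window_s = config$spectral$welch_window_s,
                          overlap = config$spectral$welch_overlap),
                bands = config$spectral$bands)
  }, error = function(e) NULL)

  na_or <- function(obj, field) {
    if (is.null(obj)) NA_real_ else as.numeric(obj[[field]])
  }
  c(MeanRR = td$mean_rr, MeanHR = td$mean_hr,
    RRmin = td$rr_min, RRmax = td$rr_max,
    SDNN = td$sdnn, SDANN = as.numeric(td$sdann),
    RMSSD = td$rmssd, NN50 = as.numeric(td$nn50), pNN50 = td$pnn50,
    SDNNIndex = as.numeric(td$sdnn_index),
    HRVTi = na_or(geo, "hrv_ti"), TINN = na_or(geo, "tinn"),
    alpha = na_or(nl_alpha, "alpha"), alpha1 = na_or(nl_alpha, "alpha1"),
    alpha2 = na_or(nl_alpha, "alpha2"),
    SD1 = na_or(pc, "sd1"), SD2 = na_or(pc, "sd2"),
    SD1SD2 = na_or(pc, "ratio"),
    ApEn = as.numeric(apen), SampEn = as.numeric(sampen),
    h = na_or(hrs, "h"),
    VLF = na_or(bp, "vlf"), LF = na_or(bp, "lf"), HF = na_or(bp, "hf"),
    LFHF = na_or(bp, "lf_hf_ratio"),
    N = length(x))
}
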