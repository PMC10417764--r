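#' Default analysis configuration
#'
#' Every tunable constant of the analysis battery in one nested list:
#'
#' * `preprocess`: physiologic bounds (`rr_min` 333 ms, `rr_max` 2000 ms)
#'   and `action` (`"drop"`).
#' * `time_domain`: `window_s` (300 s SDANN/SDNN-index blocks),
#'   `min_beats` (30) per usable window.
#' * `geometric`: histogram `bin_width` (7.8125 ms = 1/128 s).
#' * `dfa`: box range `n_min`/`n_max` (4/64 beats), detrending `order`
#'   (1), `short_range` (4-16) and `long_range` (16-64) fit windows.
#' * `entropy`: embedding `m` (2), tolerance `r_factor` (0.2 x sd),
#'   `max_beats` cap for the quadratic template counts (10000).
#' * `hurst`: bias `correction` (`"anis-lloyd"`).
#' * `spectral`: resampling `fs` (4 Hz), Welch window/overlap (300 s,
#'   0.5), STFT window/overlap (64 s, 0.5), Morlet `omega0` (6), VLF/LF/HF
#'   `bands`.
#' * `ttest`: `var_equal` (FALSE = Welch).
#'
#' @param ... named overrides merged (recursively) into the defaults,
#'   e.g. `hrv_config(dfa = list(order = 2))`.
#' @return Nested configuration list of class `hrv_config`.
#' @export
hrv_config <- function(...) {
  cfg <- list(
    preprocess = list(rr_min = 333, rr_max = 2000, action = "drop"),
    time_domain = list(window_s = 300, min_beats = 30),
    geometric = list(bin_width = 7.8125),
    dfa = list(n_min = 4, n_max = 64, order = 1,
               short_range = c(4, 16), long_range = c(16, 64)),
    entropy = list(m = 2, r_factor = 0.2, max_beats = 10000),
    hurst = list(correction = "anis-lloyd"),
    spectral = list(fs = 4, welch_window_s = 300, welch_overlap = 0.5,
                    stft_window_s = 64, stft_overlap = 0.5, omega0 = 6,
                    bands = hrv_bands()),
    ttest = list(var_equal = FALSE))
  over <- list(...)
  if (length(over)) cfg <- modify_list_deep(cfg, over)
  structure(cfg, class = "hrv_config")
}

#' Read an analysis configuration from a YAML file
#'
#' The file may specify any subset of the [hrv_config()] keys; missing
#' entries keep their defaults.
#'
#' @param path YAML file path.
#' @return An `hrv_config` list.
#' @export
read_hrv_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  over <- yaml::read_yaml(path)
  if (is.null(over)) return(hrv_config())
  do.call(hrv_config, over)
}

modify_list_deep <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]]))
      base[[nm]] <- modify_list_deep(base[[nm]], over[[nm]])
    else
      base[[nm]] <- over[[nm]]
  }
  base
}
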