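#' Canonical battery parameter names
#'
#' The full vocabulary of parameter names produced by [hrv_battery()],
#' used to validate user-supplied normal-range tables.
#'
#' @return Character vector of parameter names.
#' @export
hrv_parameter_names <- function() {
  c("MeanRR", "MeanHR", "RRmin", "RRmax", "SDNN", "SDANN", "RMSSD",
    "NN50", "pNN50", "SDNNIndex", "HRVTi", "TINN",
    "alpha", "alpha1", "alpha2", "SD1", "SD2", "SD1SD2",
    "ApEn", "SampEn", "h", "VLF", "LF", "HF", "LFHF", "N")
}
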