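#' Published normal ranges for HRV parameters
#'
#' Closed reference intervals for 24 h recordings of healthy adults:
#' SDNN 102-180 ms, SDANN 92-162 ms, RMSSD 15-39 ms, HRV triangular index
#' 22-52, mean heart rate 60-100 beats/min, plus the physiologic interval
#' bounds (shortest interval above 333 ms, longest below 2000 ms).
#' Parameters without an accepted reference range (pNN50, TINN, SDNN
#' index, the nonlinear and spectral sets) are intentionally absent and
#' will be flagged `no_reference`.
#'
#' @return A data.frame with columns `parameter`, `low`, `high`, `unit`.
#' @export
hrv_normal_ranges <- function() {
  data.frame(
    parameter = c("SDNN", "SDANN", "RMSSD", "HRVTi", "MeanHR",
                  "RRmin", "RRmax"),
    low = c(102, 92, 15, 22, 60, 333, 0),
    high = c(180, 162, 39, 52, 100, Inf, 2000),
    unit = c("ms", "ms", "ms", "", "bpm", "ms", "ms"),
    stringsAsFactors = FALSE)
}

#' Flag analysis results against normal ranges
#'
#' Compares each computed parameter with its reference interval. Ranges
#' are closed: a value exactly on a boundary is `in_range`. Parameters
#' without a reference are flagged `no_reference`; parameters with a
#' reference and a value outside `[low, high]` are `out_of_range` — the
#' values a clinical report would print in red. Range rows naming
#' parameters outside the battery vocabulary are ignored with a warning;
#' ranges for known parameters simply absent from `results` are ignored
#' silently (flagging a subset of the battery is routine).
#'
#' @param results named numeric vector (e.g. from [hrv_battery()]) or
#'   named list of parameter values.
#' @param ranges data.frame as returned by [hrv_normal_ranges()].
#' @return A data.frame of class `flagged_report` with columns
#'   `parameter`, `value`, `unit`, `low`, `high`, `flag`.
#' @examples
#' flag_against_norms(c(SDNN = 88.36, RMSSD = 16.42))
#' @export
flag_against_norms <- function(results, ranges = hrv_normal_ranges()) {
  vals <- unlist(results)
  if (length(vals) == 0L) stop("empty results")
  unknown <- setdiff(ranges$parameter,
                     union(names(vals), hrv_parameter_names()))
  if (length(unknown) > 0L)
    warning(sprintf("range(s) for unknown parameter(s) ignored: %s",
                    paste(unknown, collapse = ", ")))
  rows <- lapply(names(vals), function(p) {
    v <- vals[[p]]
    r <- ranges[ranges$parameter == p, , drop = FALSE]
    if (nrow(r) == 0L) {
      data.frame(parameter = p, value = v, unit = "",
                 low = NA_real_, high = NA_real_,
                 flag = "no_reference", stringsAsFactors = FALSE)
    } else {
      flag <- if (is.na(v)) "no_reference"
              else if (v >= r$low && v <= r$high) "in_range"
              else "out_of_range"
      data.frame(parameter = p, value = v, unit = r$unit,
                 low = r$low, high = r$high, flag = flag,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("flagged_report", "data.frame")
  out
}

#' Run the full analysis pipeline on a tachogram file
#'
#' Reads a tachogram, applies the physiologic-bounds preprocessing, runs
#' the complete battery (time-domain, geometric, nonlinear, spectral) and
#' flags the results against the normal ranges. The returned report is a
#' plain nested list, schema-stable for a given input and configuration,
#' and can be written to JSON with [write_hrv_report()].
#'
#' @param input path to a tachogram file, or an [rr_series] directly.
#' @param format passed to [read_rr_series()] when `input` is a path.
#' @param config an [hrv_config()] list.
#' @param ranges normal ranges for flagging.
#' @return An object of class `hrv_report`: a list with `meta` (source,
#'   beat counts before/after preprocessing), `parameters` (the battery
#'   vector as a named list), `flags` (the [flag_against_norms()] table),
#'   and plot payloads `histogram` (edges/counts), `dfa` (log2 n /
#'   log2 F), `poincare` (sd1/sd2) when computable.
#' @export
hrv_analyze <- function(input, format = "auto", config = hrv_config(),
                        ranges = hrv_normal_ranges()) {
  series <- if (inherits(input, "rr_series")) input
            else read_rr_series(input, format = format)
  n_raw <- length(series$intervals)
  policy <- preprocess_policy(config$preprocess$rr_min,
                              config$preprocess$rr_max,
                              config$preprocess$action)
  clean <- preprocess_rr(series, policy)
  battery <- hrv_battery(clean, config)
  flags <- flag_against_norms(battery, ranges)
  hist <- tryCatch(rr_histogram(clean, config$geometric$bin_width),
                   error = function(e) NULL)
  dfa_res <- tryCatch(
    dfa(clean, dfa_default_boxes(config$dfa$n_min, config$dfa$n_max),
        order = config$dfa$order),
    error = function(e) NULL)
  structure(
    list(meta = list(source = series$meta$source %||% "<rr_series>",
                     label = series$label,
                     n_beats_raw = n_raw,
                     n_beats = length(clean$intervals),
                     preprocess = clean$meta$preprocess),
         parameters = as.list(battery),
         flags = flags,
         histogram = if (!is.null(hist))
           list(edges = hist$bin_edges, counts = hist$counts) else NULL,
         dfa = if (!is.null(dfa_res))
           list(log2_n = dfa_res$log2_n, log2_f = dfa_res$log2_f) else NULL),
    class = "hrv_report")
}

#' Write an analysis report to JSON
#'
#' @param report an `hrv_report` from [hrv_analyze()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hrv_report <- function(report, path) {
  stopifnot(inherits(report, "hrv_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null",
                       dataframe = "rows")
  invisible(path)
}

#' @export
print.hrv_report <- function(x, ...) {
  cat(sprintf("<hrv_report> %s: %d beats (%d raw)\n",
              x$meta$source, x$meta$n_beats, x$meta$n_beats_raw))
  out <- x$flags[x$flags$flag == "out_of_range", ]
  if (nrow(out) > 0L) {
    cat("  out of range:\n")
    for (i in seq_len(nrow(out)))
      cat(sprintf("    %-10s %.2f %s (normal %g-%g)\n", out$parameter[i],
                  out$value[i], out$unit[i], out$low[i], out$high[i]))
  } else cat("  all referenced parameters in range\n")
  invisible(x)
}
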