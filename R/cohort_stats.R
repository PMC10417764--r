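#' Two-group comparison of an HRV parameter
#'
#' Two-sided t-test between per-subject parameter values of two groups,
#' summarized as mean ± sample sd per group, with the p-value banded in
#' table style (`<0.001`, `<0.005`, `<0.01`, `<0.05`, `NS`). Significance
#' uses the inclusive rule p <= 0.05, so a p of exactly 0.05 is
#' significant and falls in the `<0.05` band. The unequal-variance
#' (Welch) test is the default; set `var_equal = TRUE` for the pooled
#' variant. Degenerate inputs (zero variance in both groups) are handled
#' without error: equal means give p = 1, unequal means p = 0 with a
#' `degenerate` flag.
#'
#' @param values_a,values_b numeric vectors of per-subject values
#'   (each length >= 2).
#' @param parameter parameter name carried into the result.
#' @param var_equal use the pooled-variance t-test.
#' @param paired run a paired test (equal lengths, matched order).
#' @return A one-row data.frame of class `group_comparison`: `parameter`,
#'   `mean_a`, `sd_a`, `n_a`, `mean_b`, `sd_b`, `n_b`, `p_value`,
#'   `significant`, `label`, `degenerate`.
#' @examples
#' compare_groups(rnorm(20, 100, 10), rnorm(20, 130, 10), "SDNN")
#' @export
compare_groups <- function(values_a, values_b, parameter = "",
                           var_equal = FALSE, paired = FALSE) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("each group needs at least 2 non-missing values")
  if (paired && length(values_a) != length(values_b))
    stop("paired comparison needs matched, equal-length groups")
  degenerate <- FALSE
  pooled_var <- var(values_a) + var(values_b)
  if (paired) pooled_var <- var(values_a - values_b)
  if (pooled_var == 0) {
    degenerate <- TRUE
    p <- if (isTRUE(all.equal(mean(values_a), mean(values_b)))) 1 else 0
  } else {
    p <- t.test(values_a, values_b, var.equal = var_equal,
                paired = paired)$p.value
  }
  res <- data.frame(parameter = parameter,
                    mean_a = mean(values_a), sd_a = sd(values_a),
                    n_a = length(values_a),
                    mean_b = mean(values_b), sd_b = sd(values_b),
                    n_b = length(values_b),
                    p_value = p,
                    significant = p <= 0.05,
                    label = p_band_label(p),
                    degenerate = degenerate,
                    stringsAsFactors = FALSE)
  class(res) <- c("group_comparison", class(res))
  res
}

#' Paired before/after comparison
#'
#' Paired two-sided t-test on matched per-subject values, e.g. the same
#' patients before and after a course of treatment. Same summary and
#' banding as [compare_groups()].
#'
#' @param before,after numeric vectors, matched order, equal length >= 2.
#' @inheritParams compare_groups
#' @return A `group_comparison` row (before = group a, after = group b).
#' @export
paired_before_after <- function(before, after, parameter = "") {
  compare_groups(before, after, parameter = parameter, paired = TRUE)
}

# Banding in the style of clinical HRV tables. The top band is inclusive
# at 0.05 so that the band structure agrees with the p <= 0.05
# significance rule.
p_band_label <- function(p) {
  if (p > 0.05) return("NS")
  if (p < 0.001) return("<0.001")
  if (p < 0.005) return("<0.005")
  if (p < 0.01) return("<0.01")
  "<0.05"
}

#' Group-level summary of an HRV parameter battery
#'
#' Runs the full analysis battery ([hrv_battery()]) on every subject of a
#' labeled cohort, then compares each non-reference group against the
#' reference group parameter by parameter. Subjects for which a battery
#' item is undefined (e.g. SampEn with no template matches) contribute
#' `NA` for that cell and are dropped from that comparison only.
#'
#' @param cohort list of labeled [rr_series] (see [gen_cohort()]).
#' @param battery character vector of parameter names to compare;
#'   default: every numeric parameter [hrv_battery()] produces.
#' @param reference name of the reference (control) group; default the
#'   last group label in the cohort.
#' @param var_equal passed to [compare_groups()].
#' @param ... passed to [hrv_battery()].
#' @return A data.frame with one `group_comparison` row per (parameter,
#'   comparison-pair); column `comparison` names the pair
#'   `"<group> vs <reference>"`.
#' @export
summarize_cohort <- function(cohort, battery = NULL, reference = NULL,
                             var_equal = FALSE, ...) {
  labels <- vapply(cohort, function(s) s$label %||% "", "")
  groups <- unique(labels)
  if (length(groups) < 2L) stop("cohort must contain at least 2 groups")
  if (is.null(reference)) reference <- groups[length(groups)]
  if (!reference %in% groups) stop("reference group not present in cohort")

  mat <- t(vapply(cohort, function(s) hrv_battery(s, ...),
                  hrv_battery(cohort[[1]], ...)))
  if (is.null(battery)) battery <- colnames(mat)

  rows <- list()
  for (g in setdiff(groups, reference)) {
    for (p in battery) {
      va <- mat[labels == g, p]
      vb <- mat[labels == reference, p]
      if (sum(!is.na(va)) < 2L || sum(!is.na(vb)) < 2L) next
      row <- compare_groups(va, vb, parameter = p, var_equal = var_equal)
      row$comparison <- sprintf("%s vs %s", g, reference)
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_summary", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
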