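# Published operating characteristics of the source validation study.
# These printed values are inputs to the internal-consistency analysis:
# derived metrics (PLR, NLR, PPV, NPV, F1) are recomputed from each row's
# sensitivity/specificity and the cohort prevalence and compared to the
# printed values at print precision.

#' Cohort composition of the source validation study
#'
#' @return named integer vector: confirmed TED and non-TED counts in the
#'   final analytic cohort (92,150 patients in total).
#' @export
published_cohort_counts <- function() {
  c(ted = 66396L, non_ted = 25754L)
}

#' Published performance of the rule-based algorithms and ML models
#'
#' Point estimates as printed (percentages at one decimal for
#' proportions, two decimals for likelihood ratios and F1). `panel`
#' distinguishes the six rule-based algorithms from the full and
#' simplified gradient-boosted models; `label` is the algorithm id or
#' probability threshold.
#'
#' @return tibble with columns panel, label, sens_pct, spec_pct,
#'   ppv_pct, npv_pct, plr, nlr, f1.
#' @export
published_performance <- function() {
  m <- rbind(
    c("rules", "1",    48.7, 59.9, 75.8, 31.2, 1.21, 0.86, 0.59),
    c("rules", "2",    23.6, 90.4, 86.4, 31.5, 2.47, 0.84, 0.37),
    c("rules", "3",    25.7, 88.5, 85.2, 31.6, 2.24, 0.84, 0.39),
    c("rules", "4",    27.0, 87.2, 84.5, 31.7, 2.11, 0.84, 0.41),
    c("rules", "5",    17.8, 93.5, 87.6, 30.6, 2.74, 0.88, 0.30),
    c("rules", "6",    33.4, 86.8, 86.7, 33.6, 2.54, 0.77, 0.48),
    c("ml_full", "0.60", 86.8, 29.4, 76.0, 46.3, 1.23, 0.45, 0.81),
    c("ml_full", "0.65", 70.8, 55.4, 80.4, 42.4, 1.59, 0.53, 0.75),
    c("ml_full", "0.70", 57.9, 70.3, 83.4, 39.3, 1.95, 0.60, 0.68),
    c("ml_full", "0.75", 49.0, 78.4, 85.4, 37.3, 2.27, 0.65, 0.62),
    c("ml_full", "0.80", 40.1, 85.4, 87.6, 35.6, 2.75, 0.70, 0.55),
    c("ml_full", "0.85", 27.7, 92.5, 90.5, 33.2, 3.69, 0.78, 0.43),
    c("ml_simplified", "0.60", 70.1, 51.2, 78.8, 39.9, 1.44, 0.58, 0.74),
    c("ml_simplified", "0.65", 61.9, 63.0, 81.2, 39.0, 1.67, 0.61, 0.70),
    c("ml_simplified", "0.70", 56.7, 69.4, 82.7, 38.3, 1.85, 0.62, 0.67),
    c("ml_simplified", "0.75", 49.3, 77.2, 84.8, 37.1, 2.16, 0.66, 0.62),
    c("ml_simplified", "0.80", 39.3, 84.8, 86.9, 35.1, 2.58, 0.72, 0.54),
    c("ml_simplified", "0.85", 28.5, 91.7, 89.8, 33.2, 3.43, 0.78, 0.43)
  )
  out <- tibble::tibble(
    panel = m[, 1], label = m[, 2],
    sens_pct = as.numeric(m[, 3]), spec_pct = as.numeric(m[, 4]),
    ppv_pct = as.numeric(m[, 5]), npv_pct = as.numeric(m[, 6]),
    plr = as.numeric(m[, 7]), nlr = as.numeric(m[, 8]), f1 = as.numeric(m[, 9])
  )
  out
}

#' Recompute derived metrics for every published row
#'
#' From each row's printed sensitivity and specificity plus the cohort
#' prevalence (66,396 / 92,150), recomputes PLR, NLR, PPV, NPV and F1
#' and reports them side by side with the printed values, rounded to
#' print precision.
#'
#' @return tibble: published columns plus plr_rc, nlr_rc, ppv_pct_rc,
#'   npv_pct_rc, f1_rc.
#' @export
published_consistency <- function() {
  tab <- published_performance()
  counts <- published_cohort_counts()
  prev <- counts[["ted"]] / sum(counts)
  rc <- derived_metrics_from_rates(tab$sens_pct / 100, tab$spec_pct / 100, prev)
  tab$plr_rc <- round(rc$plr, 2)
  tab$nlr_rc <- round(rc$nlr, 2)
  tab$ppv_pct_rc <- round(100 * rc$ppv, 1)
  tab$npv_pct_rc <- round(100 * rc$npv, 1)
  tab$f1_rc <- round(rc$f1, 2)
  tab
}
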