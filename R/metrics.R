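#' Cross-tabulate predictions against the reference standard
#'
#' @param predicted,reference logical vectors of equal length.
#' @return object of class `confusion_counts`: list with tp, fp, fn, tn.
#' @export
confusion <- function(predicted, reference) {
  if (length(predicted) != length(reference)) {
    stop_input("predicted (%d) and reference (%d) differ in length",
               length(predicted), length(reference))
  }
  if (!length(predicted)) stop_input("empty vectors")
  predicted <- as.logical(predicted); reference <- as.logical(reference)
  structure(list(
    tp = sum(predicted & reference), fp = sum(predicted & !reference),
    fn = sum(!predicted & reference), tn = sum(!predicted & !reference)
  ), class = "confusion_counts")
}

#' @method print confusion_counts
#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion> tp=%d fp=%d fn=%d tn=%d\n", x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

safe_div <- function(num, den) if (den > 0) num / den else NA_real_

#' Diagnostic metrics from 2x2 counts
#'
#' Computes sensitivity, specificity, PPV, NPV, PLR, NLR, F1 and
#' prevalence with 95% confidence intervals (Wilson score for
#' proportions, log method for likelihood ratios). Metrics whose
#' denominator is an empty cell are reported as NA with the offending
#' cell named in `notes`, never as silent zeros; a PLR with zero
#' false-positive rate (and tp > 0) is `Inf`.
#'
#' @param cm a [confusion()] result.
#' @param level confidence level (default 0.95).
#' @return object of class `ted_metrics`: list with `estimates` (named
#'   numeric), `ci` (named list of (low, high)), `counts`, `notes`.
#' @export
metrics_from_counts <- function(cm, level = 0.95) {
  n1 <- cm$tp + cm$fn; n0 <- cm$fp + cm$tn
  n <- n1 + n0
  if (n == 0L) stop_input("empty confusion table")
  notes <- character(0)
  sens <- safe_div(cm$tp, n1)
  if (is.na(sens)) notes <- c(notes, "sensitivity undefined: no reference positives (tp+fn=0)")
  spec <- safe_div(cm$tn, n0)
  if (is.na(spec)) notes <- c(notes, "specificity undefined: no reference negatives (fp+tn=0)")
  ppv <- safe_div(cm$tp, cm$tp + cm$fp)
  if (is.na(ppv)) notes <- c(notes, "ppv undefined: no predicted positives (tp+fp=0)")
  npv <- safe_div(cm$tn, cm$tn + cm$fn)
  if (is.na(npv)) notes <- c(notes, "npv undefined: no predicted negatives (tn+fn=0)")
  plr <- if (is.na(sens) || is.na(spec)) NA_real_
         else if (spec < 1) sens / (1 - spec)
         else if (sens > 0) Inf else NA_real_
  nlr <- if (is.na(sens) || is.na(spec) || spec == 0) NA_real_ else (1 - sens) / spec
  f1 <- safe_div(2 * cm$tp, 2 * cm$tp + cm$fp + cm$fn)
  est <- c(sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
           plr = plr, nlr = nlr, f1 = f1, prevalence = n1 / n)
  ci <- list(
    sensitivity = proportion_ci(cm$tp, n1, level),
    specificity = proportion_ci(cm$tn, n0, level),
    ppv = proportion_ci(cm$tp, cm$tp + cm$fp, level),
    npv = proportion_ci(cm$tn, cm$tn + cm$fn, level)
  )
  ci <- c(ci, lr_ci(cm, level))
  structure(list(estimates = est, ci = ci, counts = cm, level = level, notes = notes),
            class = "ted_metrics")
}

#' @method print ted_metrics
#' @export
print.ted_metrics <- function(x, ...) {
  e <- x$estimates
  cat(sprintf("sens %.1f%%  spec %.1f%%  PPV %.1f%%  NPV %.1f%%  PLR %.2f  NLR %.2f  F1 %.2f\n",
              100 * e["sensitivity"], 100 * e["specificity"], 100 * e["ppv"],
              100 * e["npv"], e["plr"], e["nlr"], e["f1"]))
  if (length(x$notes)) cat(paste0("  note: ", x$notes, collapse = "\n"), "\n")
  invisible(x)
}

#' Transport predictive values to a target prevalence
#'
#' Bayes' rule: \eqn{PPV = s\pi / (s\pi + (1-c)(1-\pi))} and
#' \eqn{NPV = c(1-\pi) / ((1-s)\pi + c(1-\pi))} for sensitivity s,
#' specificity c and prevalence \eqn{\pi}. Predictive values are
#' prevalence-dependent, so transported values at the cohort prevalence
#' reproduce the raw 2x2 PPV/NPV, and lower-prevalence settings yield
#' lower PPV and higher NPV.
#'
#' @param sensitivity,specificity fractions in [0,1] (vectorized).
#' @param prevalence fraction in (0,1).
#' @return list with `ppv` and `npv` (NA where the denominator is zero).
#' @export
predictive_values_at_prevalence <- function(sensitivity, specificity, prevalence) {
  if (any(prevalence <= 0 | prevalence >= 1)) stop_config("prevalence must be in (0,1)")
  dp <- sensitivity * prevalence + (1 - specificity) * (1 - prevalence)
  dn <- (1 - sensitivity) * prevalence + specificity * (1 - prevalence)
  list(ppv = ifelse(dp > 0, sensitivity * prevalence / dp, NA_real_),
       npv = ifelse(dn > 0, specificity * (1 - prevalence) / dn, NA_real_))
}

#' Wilson score interval for a binomial proportion
#'
#' @param successes,n counts with 0 <= successes <= n, n >= 1.
#' @param level confidence level.
#' @return numeric (low, high), contained in [0,1]; c(NA, NA) if n = 0.
#' @export
proportion_ci <- function(successes, n, level = 0.95) {
  if (n < 1 || is.na(n)) return(c(NA_real_, NA_real_))
  if (successes < 0 || successes > n) stop_input("successes must lie in [0, n]")
  z <- qnorm(1 - (1 - level) / 2)
  phat <- successes / n
  denom <- 1 + z^2 / n
  center <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  c(max(0, center - half), min(1, center + half))
}

#' Log-method confidence intervals for likelihood ratios
#'
#' \eqn{\exp(\ln LR \pm z \cdot SE)} with
#' \eqn{SE(\ln PLR) = \sqrt{(1-s)/(s n_1) + c/((1-c) n_0)}} and
#' \eqn{SE(\ln NLR) = \sqrt{s/((1-s) n_1) + (1-c)/(c n_0)}}.
#'
#' @param cm a [confusion()] result.
#' @param level confidence level.
#' @return list with `plr` and `nlr` intervals (NA when degenerate).
#' @export
lr_ci <- function(cm, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  n1 <- cm$tp + cm$fn; n0 <- cm$fp + cm$tn
  out <- list(plr = c(NA_real_, NA_real_), nlr = c(NA_real_, NA_real_))
  if (n1 > 0 && n0 > 0) {
    s <- cm$tp / n1; c0 <- cm$tn / n0
    if (s > 0 && c0 < 1) {
      se <- sqrt((1 - s) / (s * n1) + c0 / ((1 - c0) * n0))
      out$plr <- exp(log(s / (1 - c0)) + c(-1, 1) * z * se)
    }
    if (s < 1 && c0 > 0) {
      se <- sqrt(s / ((1 - s) * n1) + (1 - c0) / (c0 * n0))
      out$nlr <- exp(log((1 - s) / c0) + c(-1, 1) * z * se)
    }
  }
  out
}

#' Area under the ROC curve (rank statistic)
#'
#' Mann-Whitney U normalized by n1*n0; tied scores count one half.
#' Invariant under strictly increasing transforms of the scores.
#'
#' @param scores numeric vector.
#' @param reference logical vector.
#' @return AUC in [0,1], or NA (with a warning) if one class is absent.
#' @export
auc_score <- function(scores, reference) {
  reference <- as.logical(reference)
  n1 <- sum(reference); n0 <- sum(!reference)
  if (n1 == 0L || n0 == 0L) {
    warning("AUC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[reference]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Threshold grid for probability classifiers
#' @param thresholds strictly increasing fractions in (0,1).
#' @export
threshold_grid <- function(thresholds = seq(0.60, 0.85, by = 0.05)) {
  if (any(thresholds <= 0 | thresholds >= 1) || is.unsorted(thresholds, strictly = TRUE)) {
    stop_config("thresholds must be strictly increasing fractions in (0,1)")
  }
  thresholds
}

#' Metric table across probability thresholds
#'
#' Classifies positive iff probability >= threshold (ties positive) and
#' computes the full metric row per threshold. Sensitivity is
#' nonincreasing and specificity nondecreasing in the threshold. If
#' `prevalence` is supplied, PPV and NPV are transported to it;
#' otherwise the empirical 2x2 values are reported.
#'
#' @param probabilities numeric in [0,1].
#' @param reference logical vector.
#' @param grid thresholds (default [threshold_grid()]).
#' @param prevalence optional target prevalence for PPV/NPV transport.
#' @param level confidence level for CIs.
#' @return tibble with one row per threshold.
#' @export
threshold_sweep <- function(probabilities, reference, grid = threshold_grid(),
                            prevalence = NULL, level = 0.95) {
  if (any(probabilities < 0 | probabilities > 1, na.rm = TRUE)) {
    stop_input("probabilities must lie in [0,1]")
  }
  rows <- lapply(grid, function(th) {
    m <- metrics_from_counts(confusion(probabilities >= th, reference), level)
    e <- m$estimates
    if (!is.null(prevalence)) {
      pv <- predictive_values_at_prevalence(e[["sensitivity"]], e[["specificity"]], prevalence)
      e[["ppv"]] <- pv$ppv; e[["npv"]] <- pv$npv
      e[["f1"]] <- 2 * pv$ppv * e[["sensitivity"]] / (pv$ppv + e[["sensitivity"]])
    }
    tibble::tibble(threshold = th, sensitivity = e[["sensitivity"]],
                   specificity = e[["specificity"]], ppv = e[["ppv"]], npv = e[["npv"]],
                   plr = e[["plr"]], nlr = e[["nlr"]], f1 = e[["f1"]])
  })
  do.call(rbind, rows)
}

#' Derived metrics from sensitivity, specificity and prevalence alone
#'
#' The internal-consistency backbone: PLR = s/(1-c), NLR = (1-s)/c, PPV
#' and NPV by prevalence transport, and F1 as the harmonic mean of the
#' transported PPV and sensitivity. Vectorized.
#'
#' @param sensitivity,specificity fractions.
#' @param prevalence fraction in (0,1).
#' @return tibble with plr, nlr, ppv, npv, f1.
#' @export
derived_metrics_from_rates <- function(sensitivity, specificity, prevalence) {
  pv <- predictive_values_at_prevalence(sensitivity, specificity, prevalence)
  tibble::tibble(
    plr = ifelse(specificity < 1, sensitivity / (1 - specificity), Inf),
    nlr = ifelse(specificity > 0, (1 - sensitivity) / specificity, NA_real_),
    ppv = pv$ppv, npv = pv$npv,
    f1 = 2 * pv$ppv * sensitivity / (pv$ppv + sensitivity)
  )
}
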