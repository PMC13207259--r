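#' Study inclusion criteria
#'
#' Adults (>= `min_age_years` at index) with continuous pre-index
#' enrollment over `lookback_days` (gaps up to `max_gap_days` tolerated;
#' the lookback window excludes the index date itself) and, optionally,
#' an evaluated reference label. "12 months" is interpreted as 365 days.
#'
#' @param min_age_years minimum age at index (default 18).
#' @param lookback_days continuous-enrollment lookback (default 365).
#' @param max_gap_days maximum tolerated uncovered run (default 0).
#' @param require_reference_evaluated drop patients without a reference
#'   label (default TRUE).
#' @return object of class `inclusion_criteria`.
#' @export
inclusion_criteria <- function(min_age_years = 18, lookback_days = 365,
                               max_gap_days = 0, require_reference_evaluated = TRUE) {
  if (lookback_days < 1 || max_gap_days < 0) {
    stop_config("lookback_days must be >= 1 and max_gap_days >= 0")
  }
  structure(list(min_age_years = min_age_years, lookback_days = lookback_days,
                 max_gap_days = max_gap_days,
                 require_reference_evaluated = require_reference_evaluated),
            class = "inclusion_criteria")
}

#' Continuous-enrollment check for one patient
#'
#' TRUE iff every day of `[index - lookback_days, index - 1]` is covered
#' by an enrollment span, allowing maximal uncovered runs of at most
#' `max_gap_days` days.
#'
#' @param span_start,span_end integer day vectors of closed enrollment
#'   intervals, sorted and pairwise non-overlapping.
#' @param index_date integer day.
#' @param lookback_days,max_gap_days window length and gap tolerance.
#' @return logical scalar.
#' @export
continuous_enrollment_ok <- function(span_start, span_end, index_date,
                                     lookback_days = 365, max_gap_days = 0) {
  if (length(span_start) != length(span_end)) stop_input("span vectors differ in length")
  if (is.na(index_date)) return(FALSE)
  if (length(span_start)) {
    if (any(span_end < span_start)) stop_input("span with end before start")
    if (is.unsorted(span_start, strictly = FALSE)) stop_input("spans must be sorted by start")
    if (length(span_start) > 1L &&
        any(span_start[-1] <= span_end[-length(span_end)])) {
      stop_input("spans must be pairwise non-overlapping")
    }
  }
  lo <- index_date - lookback_days
  hi <- index_date - 1L
  cur <- lo  # first uncovered day candidate
  for (i in seq_along(span_start)) {
    s <- max(span_start[i], lo); e <- min(span_end[i], hi)
    if (e < lo || s > hi) next
    if (s - cur > max_gap_days) return(FALSE)
    cur <- max(cur, e + 1L)
    if (cur > hi) break
  }
  (hi - cur + 1L) <= max_gap_days
}

#' Apply the inclusion criteria to a cohort
#'
#' Each excluded patient carries exactly one first-failing reason,
#' evaluated in the fixed order age, then enrollment, then reference
#' evaluated, so the exclusion log is deterministic. Patients whose
#' index date could not be assigned (no claims) fail the enrollment
#' step, since the lookback cannot be anchored.
#'
#' @param cohort a `ted_cohort`.
#' @param criteria an [inclusion_criteria()].
#' @return list with `patients` (included rows), `exclusions`
#'   (patient_id, reason) and `summary` (reason counts).
#' @export
apply_inclusion <- function(cohort, criteria = inclusion_criteria()) {
  p <- cohort$patients
  enr <- data.table::as.data.table(cohort$enrollment)
  data.table::setkeyv(enr, c("patient_id", "span_start"))
  spans <- split(enr, by = "patient_id", keep.by = FALSE)

  ok_age <- p$age_at_index >= criteria$min_age_years
  ok_enr <- vapply(seq_len(nrow(p)), function(i) {
    sp <- spans[[p$patient_id[i]]]
    if (is.null(sp)) return(FALSE)
    continuous_enrollment_ok(sp$span_start, sp$span_end, p$index_date[i],
                             criteria$lookback_days, criteria$max_gap_days)
  }, logical(1))
  missing_idx <- if ("proxy_index_missing" %in% names(p)) p$proxy_index_missing else FALSE
  ok_enr <- ok_enr & !missing_idx & !is.na(p$index_date)
  ok_ref <- if (criteria$require_reference_evaluated) !is.na(p$reference_label) else TRUE

  reason <- rep(NA_character_, nrow(p))
  reason[!ok_ref] <- "reference_not_evaluated"
  reason[!ok_enr] <- "enrollment"
  reason[!ok_age] <- "age"
  keep <- is.na(reason)
  excl <- tibble::tibble(patient_id = p$patient_id[!keep], reason = reason[!keep])
  tb <- table(excl$reason)
  summary <- tibble::tibble(reason = as.character(names(tb)), n = as.integer(tb))
  list(patients = p[keep, , drop = FALSE], exclusions = excl, summary = summary)
}

#' Minimum number of reference-positive patients for a sensitivity estimate
#'
#' Smallest integer n with \eqn{z \sqrt{p(1-p)/n} \le E}, i.e.
#' \eqn{\lceil z^2 p(1-p) / E^2 \rceil}, the standard normal-approximation
#' sample size for estimating a proportion to margin of error E. With the
#' study's planning values (expected sensitivity 0.70, 95% confidence,
#' E = 0.025) this is 1291.
#'
#' @param p expected sensitivity, in (0,1).
#' @param confidence_level two-sided confidence level (default 0.95).
#' @param margin_of_error maximum half-width E, in (0,1).
#' @return integer sample size.
#' @export
min_positive_sample_size <- function(p, confidence_level = 0.95, margin_of_error = 0.025) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p >= 1) {
    stop_config("expected sensitivity p must lie strictly inside (0, 1)")
  }
  if (confidence_level <= 0 || confidence_level >= 1) stop_config("confidence_level must be in (0,1)")
  if (margin_of_error <= 0 || margin_of_error >= 1) stop_config("margin_of_error must be in (0,1)")
  z <- qnorm(1 - (1 - confidence_level) / 2)
  n <- max(1L, as.integer(ceiling(z^2 * p * (1 - p) / margin_of_error^2 - 1e-9)))
  while (z * sqrt(p * (1 - p) / n) > margin_of_error + 1e-12) n <- n + 1L
  while (n > 1L && z * sqrt(p * (1 - p) / (n - 1L)) <= margin_of_error + 1e-12) n <- n - 1L
  n
}

#' Random train/test split of a patient table
#'
#' @param patients patient tibble.
#' @param train_fraction fraction assigned to training (default 0.5).
#' @param seed integer seed (reproducible).
#' @param stratify_by_reference balance the reference label across splits.
#' @return list with `train_ids` and `test_ids` (disjoint, exhaustive).
#' @export
split_cohort <- function(patients, train_fraction = 0.5, seed = 1L,
                         stratify_by_reference = FALSE) {
  if (train_fraction <= 0 || train_fraction >= 1) stop_config("train_fraction must be in (0,1)")
  if (nrow(patients) < 2L) stop_input("need at least 2 patients to split")
  set.seed(seed)
  ids <- patients$patient_id
  if (stratify_by_reference) {
    train <- unlist(lapply(split(ids, patients$reference_label), function(g) {
      sample(g, round(length(g) * train_fraction))
    }), use.names = FALSE)
  } else {
    train <- sample(ids, round(length(ids) * train_fraction))
  }
  list(train_ids = sort(train), test_ids = sort(setdiff(ids, train)))
}

#' Per-code patient frequencies in symmetric windows around the index date
#'
#' For each code and each window half-width w, counts patients with at
#' least one claim of that code with |service date - index date| <= w
#' (the index day itself counts). Rows are sorted by descending
#' frequency within window.
#'
#' @param claims claims tibble.
#' @param patients patient tibble (denominator; must carry `index_date`).
#' @param window_days_list window half-widths (default 90/180/365).
#' @return tibble with columns window, code, system, n, pct.
#' @export
characterize_coding_patterns <- function(claims, patients,
                                         window_days_list = c(90, 180, 365)) {
  dt <- data.table::as.data.table(claims)
  dt <- dt[dt$patient_id %in% patients$patient_id, ]
  dt$index_date <- patients$index_date[match(dt$patient_id, patients$patient_id)]
  dt$absdiff <- abs(dt$service_date - dt$index_date)
  denom <- nrow(patients)
  out <- lapply(sort(window_days_list), function(w) {
    sub <- dt[dt$absdiff <= w, ]
    agg <- sub[, list(n = data.table::uniqueN(patient_id)), by = c("code", "system")]
    data.table::setorderv(agg, c("n", "code"), order = c(-1L, 1L))
    agg$window <- w
    agg$pct <- agg$n / denom
    agg
  })
  res <- data.table::rbindlist(out)
  tibble::as_tibble(res[, c("window", "code", "system", "n", "pct"), with = FALSE])
}
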