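#' Configuration for the synthetic linked-cohort generator
#'
#' Defaults emulate the validation cohort the analysis assumes: ~72% TED
#' prevalence in the enriched linked sample, a note-derived reference
#' standard with precision 0.90 and recall 0.91, index dates spanning
#' 2016-01-01 to 2024-09-30, age at index ~ Normal(60.4, 14.5) truncated
#' to adults, and 76% female. `enrollment_gap_prob` is the fraction of
#' patients whose pre-index coverage is shorter than a year (they fail
#' the continuous-enrollment criterion downstream); its default 0.108
#' mirrors the attrition the enrollment criterion produced in the source
#' cohort (103,309 to 92,150).
#'
#' @param n_patients number of patients to simulate.
#' @param ted_prevalence fraction of true TED patients, in (0,1).
#' @param reference_precision,reference_recall operating characteristics
#'   of the simulated note-derived reference label.
#' @param index_date_range length-2 date interval for index dates.
#' @param enrollment_mean_span_days mean total enrollment span.
#' @param enrollment_gap_prob fraction with truncated pre-index coverage.
#' @param age_mean,age_sd age-at-index distribution (truncated to [18,100)).
#' @param female_fraction fraction female.
#' @param proxy_intervals optional numeric vector of (index - first
#'   record) day gaps used for proxy index assignment; default NULL means
#'   empirical resampling from the simulated TED patients' own gaps.
#' @param profile a `ted_code_profile` driving claim generation.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients,
                          ted_prevalence = 0.72,
                          reference_precision = 0.90,
                          reference_recall = 0.91,
                          index_date_range = c("2016-01-01", "2024-09-30"),
                          enrollment_mean_span_days = 1460,
                          enrollment_gap_prob = 0.108,
                          age_mean = 60.4, age_sd = 14.5,
                          female_fraction = 0.76,
                          proxy_intervals = NULL,
                          profile = default_code_profile(),
                          seed = 1L) {
  if (!is.numeric(n_patients) || n_patients < 1) stop_config("n_patients must be >= 1")
  if (!is_fraction(ted_prevalence) || ted_prevalence <= 0 || ted_prevalence >= 1) {
    stop_config("ted_prevalence must lie in the open interval (0, 1)")
  }
  for (f in c(reference_precision, reference_recall, enrollment_gap_prob, female_fraction)) {
    if (!is_fraction(f)) stop_config("all fractions must lie in [0, 1]")
  }
  rng <- as_day(index_date_range)
  if (length(rng) != 2L || is.na(rng[1]) || is.na(rng[2]) || rng[2] < rng[1]) {
    stop_config("index_date_range must be a valid, non-empty date interval")
  }
  if (enrollment_mean_span_days <= 730) stop_config("enrollment_mean_span_days must exceed 730")
  if (!inherits(profile, "ted_code_profile")) stop_config("profile must be a ted_code_profile")
  structure(list(
    n_patients = as.integer(n_patients), ted_prevalence = ted_prevalence,
    reference_precision = reference_precision, reference_recall = reference_recall,
    index_date_range = rng, enrollment_mean_span_days = enrollment_mean_span_days,
    enrollment_gap_prob = enrollment_gap_prob, age_mean = age_mean, age_sd = age_sd,
    female_fraction = female_fraction, proxy_intervals = proxy_intervals,
    profile = profile, seed = as.integer(seed)
  ), class = "cohort_config")
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x >= hi)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] >= hi]
  }
  x
}

# Claims for one class: occurrence is drawn independently per nested
# window band with conditional probabilities chosen so the marginal
# probability of >= 1 claim within each window equals the profile value
# exactly; claim dates are uniform within the band; repeats 1+Poisson.
generate_claims_for_class <- function(ids, anchors, span_lo, span_hi, prof, cls) {
  codes <- prof$codes
  pick <- function(w) codes[[paste0("p", w, "_", cls)]]
  p90 <- pick(90); p180 <- pick(180); p365 <- pick(365)
  q2 <- ifelse(p90 < 1, (p180 - p90) / (1 - p90), 0)
  q3 <- ifelse(p180 < 1, (p365 - p180) / (1 - p180), 0)
  n <- length(ids)
  out <- vector("list", nrow(codes) * 3L)
  band_offsets <- list(`1` = -90:90, `2` = c(-180:-91, 91:180), `3` = c(-365:-181, 181:365))
  k <- 0L
  for (j in seq_len(nrow(codes))) {
    pband <- c(p90[j], q2[j], q3[j])
    for (b in 1:3) {
      if (pband[b] <= 0) next
      hit <- which(runif(n) < pband[b])
      if (!length(hit)) next
      reps <- 1L + rpois(length(hit), prof$repeat_lambda)
      pid <- rep(hit, reps)
      off <- sample(band_offsets[[b]], length(pid), replace = TRUE)
      k <- k + 1L
      out[[k]] <- data.table::data.table(
        row = pid, service_date = anchors[pid] + off,
        code = codes$code[j], system = codes$system[j]
      )
    }
  }
  if (k == 0L) {
    return(data.table::data.table(patient_id = character(0),
                                  service_date = integer(0),
                                  code = character(0), system = character(0)))
  }
  cl <- data.table::rbindlist(out[seq_len(k)])
  cl <- cl[cl$service_date >= span_lo[cl$row] & cl$service_date <= span_hi[cl$row], ]
  cl$patient_id <- ids[cl$row]
  cl$row <- NULL
  data.table::setcolorder(cl, c("patient_id", "service_date", "code", "system"))
  cl
}

#' Generate a synthetic linked cohort
#'
#' Produces a patient table, a longitudinal claims table, and an
#' enrollment table with the statistical structure the validation
#' analysis assumes: claims concentrated around a per-patient index date
#' according to the configured code profile, claims only inside
#' enrollment spans, proxy index dates for non-TED patients resampled
#' from the TED patients' (index - first record) gap distribution, and a
#' reference label derived from the true label at the configured
#' precision/recall.
#'
#' @param config a [cohort_config()].
#' @return object of class `ted_cohort`: list with `patients`, `claims`,
#'   `enrollment` tibbles plus the config.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) stop_config("config must be a cohort_config")
  set.seed(config$seed)
  n <- config$n_patients
  true_ted <- runif(n) < config$ted_prevalence
  age <- rtrunc_norm(n, config$age_mean, config$age_sd, 18, 100)
  sex <- ifelse(runif(n) < config$female_fraction, "F", "M")
  pid <- sprintf("P%07d", seq_len(n))
  rng <- config$index_date_range
  anchor <- as.integer(rng[1] + floor(runif(n) * (rng[2] - rng[1] + 1)))

  extra_mean <- (config$enrollment_mean_span_days - 730) / 2
  short_lb <- runif(n) < config$enrollment_gap_prob
  pre <- ifelse(short_lb, sample(30:364, n, replace = TRUE),
                365 + rexp(n, 1 / extra_mean))
  post <- 365 + rexp(n, 1 / extra_mean)
  span_lo <- as.integer(anchor - round(pre))
  span_hi <- as.integer(anchor + round(post))

  cl_ted <- generate_claims_for_class(pid[true_ted], anchor[true_ted],
                                      span_lo[true_ted], span_hi[true_ted],
                                      config$profile, "ted")
  cl_non <- generate_claims_for_class(pid[!true_ted], anchor[!true_ted],
                                      span_lo[!true_ted], span_hi[!true_ted],
                                      config$profile, "non")
  claims <- data.table::rbindlist(list(cl_ted, cl_non))
  data.table::setorderv(claims, c("patient_id", "service_date", "code"))

  patients <- tibble::tibble(
    patient_id = pid, age_at_index = age, sex = sex, true_ted = true_ted,
    reference_label = NA, index_date = as.integer(anchor)
  )

  # proxy index dates for non-TED patients, from TED patients' gaps
  first_rec <- claims[, list(first = min(service_date), last = max(service_date)),
                      by = "patient_id"]
  intervals <- config$proxy_intervals
  if (is.null(intervals)) {
    ted_first <- first_rec[first_rec$patient_id %in% pid[true_ted], ]
    gaps <- patients$index_date[match(ted_first$patient_id, patients$patient_id)] -
      ted_first$first
    intervals <- gaps
  }
  patients <- assign_proxy_index_dates(patients, claims, intervals,
                                       seed = derive_seed(config$seed, "proxy"))
  patients <- assign_reference_labels(patients, config$reference_precision,
                                      config$reference_recall,
                                      seed = derive_seed(config$seed, "reference"))

  enrollment <- tibble::tibble(patient_id = pid, span_start = span_lo, span_end = span_hi)
  structure(list(patients = patients,
                 claims = tibble::as_tibble(claims),
                 enrollment = enrollment,
                 config = config),
            class = "ted_cohort")
}

#' @method print ted_cohort
#' @export
print.ted_cohort <- function(x, ...) {
  cat(sprintf("<ted_cohort> %d patients (%.1f%% TED), %d claims\n",
              nrow(x$patients), 100 * mean(x$patients$true_ted), nrow(x$claims)))
  invisible(x)
}

#' Derive the reference label from the true label
#'
#' Simulates an imperfect note-derived reference standard: reference
#' positives are drawn from true positives at the configured recall, and
#' the false-positive probability among true negatives is solved
#' analytically so the expected precision at the cohort's empirical
#' prevalence equals the configured precision:
#' \deqn{fpr = recall \cdot \pi (1 - precision) / (precision (1 - \pi))}
#' An infeasible request (implied fpr outside [0,1]) raises an error
#' reporting the implied rate.
#'
#' @param patients patient tibble with `true_ted`.
#' @param precision,recall target operating characteristics in (0,1].
#' @param seed integer seed.
#' @return patients with `reference_label` filled in.
#' @export
assign_reference_labels <- function(patients, precision, recall, seed) {
  if (!is_fraction(precision) || precision <= 0 || !is_fraction(recall) || recall <= 0) {
    stop_config("precision and recall must lie in (0, 1]")
  }
  pi_hat <- mean(patients$true_ted)
  fpr <- if (pi_hat >= 1) 0 else recall * pi_hat * (1 - precision) / (precision * (1 - pi_hat))
  if (fpr > 1 + 1e-12) {
    stop_infeasible(paste0("requested precision %.3f is infeasible at prevalence %.3f ",
                           "and recall %.3f: implied false-positive probability %.3f > 1"),
                    precision, pi_hat, recall, fpr)
  }
  set.seed(seed)
  u <- runif(nrow(patients))
  patients$reference_label <- ifelse(patients$true_ted, u < recall, u < fpr)
  patients
}

#' Assign proxy index dates to non-TED patients
#'
#' The index date is anchored to the first disease record for TED
#' patients; non-TED patients have no such record, so each receives a
#' proxy index equal to their first observed claim date plus a gap
#' sampled from the supplied interval distribution (by default the TED
#' patients' own empirical index-minus-first-record gaps). Proxy dates
#' are clamped to the patient's observed record range. Patients with no
#' claims are flagged (`proxy_index_missing`) for downstream exclusion.
#'
#' @param patients patient tibble (`true_ted`, `index_date`).
#' @param claims claims tibble.
#' @param intervals non-empty numeric vector of day gaps.
#' @param seed integer seed.
#' @return patients with non-TED `index_date` replaced.
#' @export
assign_proxy_index_dates <- function(patients, claims, intervals, seed) {
  if (!length(intervals)) stop_config("interval distribution must be non-empty")
  dt <- data.table::as.data.table(claims)
  rec <- dt[, list(first = min(service_date), last = max(service_date)), by = "patient_id"]
  idx <- !patients$true_ted
  set.seed(seed)
  gap <- sample(as.integer(round(intervals)), sum(idx), replace = TRUE)
  m <- match(patients$patient_id[idx], rec$patient_id)
  proxy <- rec$first[m] + gap
  proxy <- pmin(pmax(proxy, rec$first[m]), rec$last[m])
  patients$proxy_index_missing <- FALSE
  patients$proxy_index_missing[idx] <- is.na(m)
  patients$index_date[idx] <- as.integer(proxy)
  patients
}
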