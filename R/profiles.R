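# Per-code occurrence profiles driving the claims generator.
#
# The published frequency table for confirmed TED patients reports, for
# each of the 20 most frequent codes per window, the fraction of patients
# with >= 1 occurrence within +/-90, +/-180 and +/-365 days of the index
# date. The three top-20 lists do not fully overlap, so a code missing a
# printed value in one window has it filled by the median adjacent-window
# growth ratio of the fully observed codes (monotone by construction).

table3_observed <- function() {
  # code, system, p90, p180, p365 (percent; NA = not in that window's top 20)
  m <- rbind(
    c("99214",   "CPT",       "Office/outpatient visit, established, moderate", 42.1, 52.5, 63.1),
    c("99213",   "CPT",       "Office/outpatient visit, established, low",      37.4, 49.3, 61.5),
    c("E05.00",  "ICD-10-CM", "Thyrotoxicosis with diffuse goiter",             32.3, 37.1, 42.4),
    c("36415",   "CPT",       "Venipuncture",                                   24.9, 32.7, 41.6),
    c("I10",     "ICD-10-CM", "Essential hypertension",                         23.7, 31.2, 39.4),
    c("84443",   "CPT",       "TSH test",                                       19.0, 25.2, 32.6),
    c("99204",   "CPT",       "Office/outpatient visit, new, moderate",         18.4, 25.4, 35.6),
    c("80053",   "CPT",       "Comprehensive metabolic panel",                  16.5, 23.9, 32.7),
    c("85025",   "CPT",       "CBC with differential",                          16.3, 23.7, 32.7),
    c("E03.9",   "ICD-10-CM", "Hypothyroidism, unspecified",                    15.3, 21.4, 28.4),
    c("84439",   "CPT",       "Free T4 test",                                   14.7, 19.4, 25.3),
    c("E78.5",   "ICD-10-CM", "Hyperlipidemia, unspecified",                    12.3, 18.1, 24.9),
    c("99203",   "CPT",       "Office/outpatient visit, new, low",              11.9, 18.3, 28.2),
    c("H04.123", "ICD-10-CM", "Dry eye syndrome, bilateral lacrimal glands",    11.8, 14.2, NA),
    c("92014",   "CPT",       "Comprehensive eye exam, established",            11.8, 15.4, 21.0),
    c("80061",   "CPT",       "Lipid panel",                                    11.3, 17.7, 25.0),
    c("E05.90",  "ICD-10-CM", "Thyrotoxicosis, unspecified",                    11.1, 14.3, NA),
    c("92083",   "CPT",       "Visual field examination",                       10.7, NA,   NA),
    c("92012",   "CPT",       "Intermediate eye exam, established",             10.6, NA,   NA),
    c("H05.20",  "ICD-10-CM", "Unspecified exophthalmos",                       10.1, NA,   NA),
    c("Z00.00",  "ICD-10-CM", "General adult medical examination",              NA,   14.9, 22.5),
    c("83036",   "CPT",       "HbA1c test",                                     NA,   14.4, 20.1),
    c("Z12.31",  "ICD-10-CM", "Screening mammogram encounter",                  NA,   14.4, 21.4),
    c("Z23",     "ICD-10-CM", "Encounter for immunization",                     NA,   NA,   21.7),
    c("Z79.899", "ICD-10-CM", "Long term use of other medications",             NA,   NA,   19.5)
  )
  data.frame(code = m[, 1], system = m[, 2], description = m[, 3],
             p90 = as.numeric(m[, 4]) / 100, p180 = as.numeric(m[, 5]) / 100,
             p365 = as.numeric(m[, 6]) / 100, stringsAsFactors = FALSE)
}

fill_profile_windows <- function(df) {
  full <- !is.na(df$p90) & !is.na(df$p180) & !is.na(df$p365)
  r180 <- stats::median(df$p180[full] / df$p90[full])
  r365 <- stats::median(df$p365[full] / df$p180[full])
  df$p180 <- ifelse(is.na(df$p180),
                    ifelse(!is.na(df$p90), df$p90 * r180, df$p365 / r365), df$p180)
  df$p90 <- ifelse(is.na(df$p90), df$p180 / r180, df$p90)
  df$p365 <- ifelse(is.na(df$p365), df$p180 * r365, df$p365)
  # enforce nesting p90 <= p180 <= p365 and [0, 1]
  df$p180 <- pmax(df$p180, df$p90)
  df$p365 <- pmin(pmax(df$p365, df$p180), 1)
  df
}

#' Construct a per-code occurrence profile
#'
#' A profile row gives, per code, the probability that a patient of each
#' class (TED / non-TED) has at least one claim of that code within
#' +/-90, +/-180 and +/-365 days of the index date. Probabilities must be
#' nondecreasing across the nested windows. `repeat_lambda` controls the
#' number of claims given occurrence (1 + Poisson(lambda)).
#'
#' @param codes data.frame with columns `code`, `system`, `description`,
#'   `p90_ted`, `p180_ted`, `p365_ted`, `p90_non`, `p180_non`, `p365_non`.
#' @param repeat_lambda nonnegative Poisson mean for repeat claims.
#' @return object of class `ted_code_profile`.
#' @export
code_profile <- function(codes, repeat_lambda = 0.7) {
  need <- c("code", "system", "description",
            "p90_ted", "p180_ted", "p365_ted", "p90_non", "p180_non", "p365_non")
  if (!all(need %in% names(codes))) {
    stop_config("profile must have columns: %s", paste(need, collapse = ", "))
  }
  pcols <- need[4:9]
  for (col in pcols) {
    if (any(codes[[col]] < 0 | codes[[col]] > 1)) {
      stop_config("profile probabilities must be in [0,1] (column %s)", col)
    }
  }
  for (cls in c("ted", "non")) {
    p90 <- codes[[paste0("p90_", cls)]]
    p180 <- codes[[paste0("p180_", cls)]]
    p365 <- codes[[paste0("p365_", cls)]]
    if (any(p180 < p90 - 1e-12 | p365 < p180 - 1e-12)) {
      stop_config("window probabilities must be nondecreasing (+/-90 <= +/-180 <= +/-365)")
    }
  }
  if (anyDuplicated(code_key(codes$system, normalize_code(codes$code, codes$system)))) {
    stop_config("duplicate (system, code) rows in profile")
  }
  structure(list(codes = codes, repeat_lambda = repeat_lambda),
            class = "ted_code_profile")
}

#' Default synthetic-claims code profile
#'
#' TED-class probabilities come from the published per-window frequency
#' table of confirmed TED patients (top-20 codes per window, union of the
#' three lists). Non-TED probabilities are not published; they default to
#' 0.6x the TED values, except TED-specific codes (the exophthalmos code
#' H05.20) which are set near zero. A handful of additional TED
#' symptom/sign codes (diplopia, lid retraction, orbital inflammation,
#' strabismus) with modest synthetic frequencies are included so the
#' rule-based algorithms have all their criteria represented, plus
#' `n_noise` uninformative filler codes with identical frequencies in
#' both classes.
#'
#' @param n_noise number of uninformative filler codes.
#' @param nonted_scale scale factor mapping TED to non-TED probabilities.
#' @return a `ted_code_profile`.
#' @export
default_code_profile <- function(n_noise = 30, nonted_scale = 0.6) {
  t3 <- fill_profile_windows(table3_observed())
  specific <- t3$code %in% "H05.20"
  prof <- data.frame(
    code = t3$code, system = t3$system, description = t3$description,
    p90_ted = t3$p90, p180_ted = t3$p180, p365_ted = t3$p365,
    p90_non = t3$p90 * ifelse(specific, 0.02, nonted_scale),
    p180_non = t3$p180 * ifelse(specific, 0.02, nonted_scale),
    p365_non = t3$p365 * ifelse(specific, 0.02, nonted_scale),
    stringsAsFactors = FALSE
  )
  # synthetic defaults for symptom concepts absent from the printed table
  extra <- data.frame(
    code = c("H53.2", "H02.531", "H05.10", "H50.9", "E05.01", "H57.1"),
    system = "ICD-10-CM",
    description = c("Diplopia", "Lid retraction, right upper eyelid",
                    "Unspecified acute inflammation of orbit",
                    "Unspecified strabismus",
                    "Thyrotoxicosis with diffuse goiter with crisis",
                    "Ocular pain"),
    p90_ted = c(0.050, 0.030, 0.015, 0.020, 0.010, 0.040),
    p180_ted = c(0.062, 0.037, 0.019, 0.025, 0.012, 0.050),
    p365_ted = c(0.078, 0.046, 0.024, 0.031, 0.015, 0.062),
    stringsAsFactors = FALSE
  )
  extra_specific <- extra$code %in% c("H02.531", "H05.10")
  extra_scale <- ifelse(extra_specific, 0.02, 0.3)
  extra$p90_non <- extra$p90_ted * extra_scale
  extra$p180_non <- extra$p180_ted * extra_scale
  extra$p365_non <- extra$p365_ted * extra_scale
  prof <- rbind(prof, extra)
  if (n_noise > 0) {
    p90 <- seq(0.02, 0.10, length.out = n_noise)
    noise <- data.frame(
      code = sprintf("0%04d", seq_len(n_noise)), system = "CPT",
      description = sprintf("Filler procedure %d", seq_len(n_noise)),
      p90_ted = p90, p180_ted = p90 * 1.3, p365_ted = p90 * 1.6,
      p90_non = p90, p180_non = p90 * 1.3, p365_non = p90 * 1.6,
      stringsAsFactors = FALSE
    )
    prof <- rbind(prof, noise)
  }
  code_profile(prof)
}
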