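# The six declarative claims-based TED identification algorithms.
#
# Algorithm 1 flags any claim from the broad 13-concept symptom/sign
# list with no hyperthyroidism requirement. Algorithms 2-5 require >= 1
# hyperthyroidism claim and >= 1 claim from their symptom list within 12
# months (|gap| <= 365 days, either order, same day counts). Algorithm 6
# uses Algorithm 2's symptom list without the timing restriction.

ALG1_SETS <- c("exophthalmos", "diplopia", "lid_retraction", "strabismus",
               "orbital_inflammation", "ocular_pain", "keratoconjunctivitis",
               "eye_edema", "visual_disturbance", "scotoma", "vision_deficiency",
               "corneal_ulcer", "optic_neuropathy")
ALG2_SETS <- ALG1_SETS[1:5]
ALG3_SETS <- c(ALG2_SETS, "ocular_pain", "keratoconjunctivitis")
ALG5_SETS <- c("exophthalmos", "lid_retraction", "periorbital_edema", "eyelid_erythema")

#' Specifications of the six rule-based TED algorithms
#'
#' @return tibble with columns `id`, `require_hyperthyroidism`,
#'   `window_days` (NA = no timing restriction) and `symptom_sets`
#'   (list column of code-set names).
#' @export
algorithm_specs <- function() {
  tibble::tibble(
    id = 1:6,
    require_hyperthyroidism = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
    window_days = c(NA, 365, 365, 365, 365, NA),
    symptom_sets = list(ALG1_SETS, ALG2_SETS, ALG3_SETS, ALG1_SETS,
                        ALG5_SETS, ALG2_SETS)
  )
}

union_codeset <- function(codesets, names) {
  unknown <- setdiff(names, names(codesets))
  if (length(unknown)) stop_config("unknown code set name: %s", unknown[1])
  do.call(rbind, unname(codesets[names]))
}

#' Dates of a patient's claims matching a code set
#'
#' @param claims claims tibble for a single patient.
#' @param codeset one element of a `ted_codelists` (data.frame with
#'   system/code/wildcard).
#' @return sorted integer vector of service dates (duplicates kept).
#' @export
matching_claim_dates <- function(claims, codeset) {
  if (!nrow(claims)) return(integer(0))
  code <- normalize_code(claims$code, claims$system)
  sort(claims$service_date[codes_match(claims$system, code, codeset)])
}

#' Temporal co-occurrence test between two date sets
#'
#' TRUE iff some pair (a, b) with a from `datesA`, b from `datesB`
#' satisfies |a - b| <= `window_days` (either temporal order; boundary
#' inclusive; same-day pairs count). Runs as a sorted sweep, linear after
#' sorting.
#'
#' @param datesA,datesB integer day vectors.
#' @param window_days nonnegative window half-width.
#' @return logical scalar (FALSE if either set is empty).
#' @export
co_occurrence_within <- function(datesA, datesB, window_days) {
  if (window_days < 0) stop_input("window_days must be >= 0")
  if (!length(datesA) || !length(datesB)) return(FALSE)
  min_date_gap(sort(datesA), sort(datesB)) <= window_days
}

# smallest |a - b| over pairs of two sorted vectors
min_date_gap <- function(a, b) {
  i <- findInterval(b, a)
  lo <- ifelse(i >= 1L, b - a[pmax(i, 1L)], Inf)
  hi <- ifelse(i < length(a), a[pmin(i + 1L, length(a))] - b, Inf)
  as.numeric(min(pmin(lo, hi)))
}

#' Classify one patient under one algorithm specification
#'
#' @param spec one row of [algorithm_specs()] (as a list or 1-row tibble).
#' @param claims that patient's claims.
#' @param codesets a `ted_codelists`.
#' @return logical verdict.
#' @export
classify_patient <- function(spec, claims, codesets = default_code_lists()) {
  sets <- spec$symptom_sets
  if (is.list(sets) && !is.character(sets)) sets <- sets[[1]]
  sympt <- matching_claim_dates(claims, union_codeset(codesets, sets))
  if (!isTRUE(spec$require_hyperthyroidism)) return(length(sympt) > 0L)
  hyper <- matching_claim_dates(claims, union_codeset(codesets, "hyperthyroidism"))
  if (!length(hyper) || !length(sympt)) return(FALSE)
  w <- spec$window_days
  if (is.na(w)) TRUE else co_occurrence_within(hyper, sympt, w)
}

#' Run all algorithms over a cohort
#'
#' Evaluates every (patient, algorithm) pair over each patient's entire
#' available claims history and returns a complete prediction matrix.
#' Verdicts are invariant to claim order and duplicate claims.
#'
#' @param cohort a `ted_cohort` (or list with `patients` and `claims`).
#' @param specs algorithm table, default [algorithm_specs()].
#' @param codesets a `ted_codelists`.
#' @return tibble: `patient_id` plus one logical column `alg_<id>` per
#'   algorithm.
#' @export
run_algorithms <- function(cohort, specs = algorithm_specs(),
                           codesets = default_code_lists()) {
  p <- cohort$patients
  dt <- data.table::as.data.table(cohort$claims)
  out <- tibble::tibble(patient_id = p$patient_id)
  if (nrow(dt)) {
    dt$norm <- normalize_code(dt$code, dt$system)
    hyper_set <- union_codeset(codesets, "hyperthyroidism")
    dt$is_hyper <- codes_match(dt$system, dt$norm, hyper_set)
  }
  # per-algorithm matched flags, then grouped verdicts
  for (k in seq_len(nrow(specs))) {
    id <- specs$id[k]
    col <- paste0("alg_", id)
    if (!nrow(dt)) { out[[col]] <- rep(FALSE, nrow(p)); next }
    sympt_set <- union_codeset(codesets, specs$symptom_sets[[k]])
    is_sympt <- codes_match(dt$system, dt$norm, sympt_set)
    if (!specs$require_hyperthyroidism[k]) {
      pos <- unique(dt$patient_id[is_sympt])
    } else if (is.na(specs$window_days[k])) {
      pos <- intersect(unique(dt$patient_id[is_sympt]),
                       unique(dt$patient_id[dt$is_hyper]))
    } else {
      w <- specs$window_days[k]
      sub <- dt[is_sympt | dt$is_hyper, c("patient_id", "service_date", "is_hyper"), with = FALSE]
      sub$is_sympt <- is_sympt[is_sympt | dt$is_hyper]
      # keep only patients having both claim types
      both <- sub[, list(ok = any(is_hyper) && any(is_sympt)), by = "patient_id"]
      sub <- sub[sub$patient_id %in% both$patient_id[both$ok], ]
      if (nrow(sub)) {
        data.table::setorderv(sub, c("patient_id", "service_date"))
        gaps <- sub[, list(gap = min_date_gap(sort(service_date[is_hyper]),
                                              sort(service_date[is_sympt]))),
                    by = "patient_id"]
        pos <- gaps$patient_id[gaps$gap <= w]
      } else pos <- character(0)
    }
    out[[col]] <- p$patient_id %in% pos
  }
  out
}
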