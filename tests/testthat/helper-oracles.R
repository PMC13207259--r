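# Independent brute-force oracles the fast implementations are checked
# against. Kept deliberately naive.

# all-pairs temporal co-occurrence
bf_co_occurrence <- function(a, b, w) {
  if (!length(a) || !length(b)) return(FALSE)
  any(abs(outer(a, b, "-")) <= w)
}

# day-by-day enrollment coverage with gap tolerance
bf_enrollment_ok <- function(span_start, span_end, index, lookback, max_gap) {
  days <- seq(index - lookback, index - 1L)
  covered <- rep(FALSE, length(days))
  for (i in seq_along(span_start)) {
    covered <- covered | (days >= span_start[i] & days <= span_end[i])
  }
  if (all(covered)) return(TRUE)
  runs <- rle(covered)
  max(runs$lengths[!runs$values]) <= max_gap
}

# exhaustive pair-counting AUC (ties half)
bf_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# random enrollment-span fixture: sorted, disjoint closed intervals
random_spans <- function() {
  k <- sample(0:4, 1)
  if (k == 0) return(list(start = integer(0), end = integer(0)))
  bounds <- sort(sample(-500:50, 2 * k))
  list(start = bounds[seq(1, 2 * k, by = 2)], end = bounds[seq(2, 2 * k, by = 2)])
}

derive_seed_for_test <- tedclaims:::derive_seed

# naive per-row code-set membership, independent of the vectorized path
codes_match_oracle <- function(system, code, set) {
  vapply(seq_along(code), function(i) {
    nc <- toupper(code[i])
    if (system[i] %in% c("ICD-9", "ICD-10-CM")) nc <- gsub(".", "", nc, fixed = TRUE)
    any(vapply(seq_len(nrow(set)), function(j) {
      if (set$system[j] != system[i]) return(FALSE)
      if (set$wildcard[j]) startsWith(nc, sub("\\*$", "", set$code[j]))
      else nc == set$code[j]
    }, logical(1)))
  }, logical(1))
}

# minimal hand-built cohort for inclusion / phenotyping fixtures
tiny_cohort <- function() {
  idx <- as_day("2020-06-01")
  patients <- tibble::tibble(
    patient_id = c("A", "B", "C", "D", "E"),
    age_at_index = c(45, 17.9, 60, 70, 30),
    sex = c("F", "F", "M", "F", "F"),
    true_ted = c(TRUE, TRUE, FALSE, TRUE, FALSE),
    reference_label = c(TRUE, TRUE, FALSE, NA, FALSE),
    index_date = rep(idx, 5)
  )
  enrollment <- tibble::tibble(
    patient_id = c("A", "B", "C", "D", "E"),
    span_start = c(idx - 900, idx - 900, idx - 200, idx - 900, idx - 900),
    span_end = rep(idx + 400, 5)
  )
  claims <- tibble::tibble(
    patient_id = c("A", "A", "C", "E"),
    service_date = c(idx - 10, idx + 5, idx - 50, idx),
    code = c("E05.00", "H05.20", "99213", "H53.2"),
    system = c("ICD-10-CM", "ICD-10-CM", "CPT", "ICD-10-CM")
  )
  structure(list(patients = patients, claims = claims, enrollment = enrollment),
            class = "ted_cohort")
}
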