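test_that("continuous-enrollment logic handles coverage, holes and gap tolerance", {
  idx <- as_day("2021-01-01")
  # single span covering the whole lookback
  expect_true(continuous_enrollment_ok(idx - 365, idx, idx))
  # 30-day hole with zero tolerance
  expect_false(continuous_enrollment_ok(c(idx - 365, idx - 100),
                                        c(idx - 131, idx), idx))
  # same hole tolerated at max_gap_days = 30
  expect_true(continuous_enrollment_ok(c(idx - 365, idx - 100),
                                       c(idx - 131, idx), idx, max_gap_days = 30))
  # the index day itself does not count towards the lookback
  expect_false(continuous_enrollment_ok(idx - 364, idx, idx))
  expect_error(continuous_enrollment_ok(c(10, 5), c(20, 8), 30),
               class = "tedclaims_input_error")
  expect_error(continuous_enrollment_ok(c(5, 15), c(20, 30), 40),
               class = "tedclaims_input_error")
})

test_that("inclusion applies first-failing reasons in a fixed order and is idempotent", {
  co <- tiny_cohort()
  res <- apply_inclusion(co)
  excl <- setNames(res$exclusions$reason, res$exclusions$patient_id)
  expect_equal(excl[["B"]], "age")               # 17.9 years at index
  expect_equal(excl[["C"]], "enrollment")        # 200 days of lookback
  expect_equal(excl[["D"]], "reference_not_evaluated")
  expect_setequal(res$patients$patient_id, c("A", "E"))

  again <- apply_inclusion(list(patients = res$patients, claims = co$claims,
                                enrollment = co$enrollment))
  expect_equal(nrow(again$exclusions), 0)
  expect_identical(again$patients, res$patients)
})

test_that("an all-passing cohort yields an empty exclusion log", {
  co <- tiny_cohort()
  co$patients <- co$patients[co$patients$patient_id %in% c("A", "E"), ]
  res <- apply_inclusion(co)
  expect_equal(nrow(res$exclusions), 0)
  expect_equal(nrow(res$patients), 2)
})

test_that("minimum positive sample size matches the closed form and brute force", {
  expect_identical(min_positive_sample_size(0.70, 0.95, 0.025), 1291L)
  # brute-force smallest n satisfying the margin inequality
  bf <- function(p, conf, E) {
    z <- qnorm(1 - (1 - conf) / 2)
    n <- 1L
    while (z * sqrt(p * (1 - p) / n) > E) n <- n + 1L
    n
  }
  expect_identical(min_positive_sample_size(0.50, 0.95, 0.05), bf(0.50, 0.95, 0.05))
  expect_identical(min_positive_sample_size(0.50, 0.95, 0.05), 385L)
  for (p in c(0.1, 0.3, 0.7, 0.9)) {
    for (E in c(0.01, 0.025, 0.05)) {
      expect_identical(min_positive_sample_size(p, 0.95, E), bf(p, 0.95, E))
    }
  }
  # monotone: larger margin needs fewer patients; higher confidence more
  expect_lte(min_positive_sample_size(0.7, 0.95, 0.05),
             min_positive_sample_size(0.7, 0.95, 0.025))
  expect_gte(min_positive_sample_size(0.7, 0.99, 0.025),
             min_positive_sample_size(0.7, 0.95, 0.025))
  expect_error(min_positive_sample_size(1.0), class = "tedclaims_config_error")
})

test_that("cohort splits are disjoint, exhaustive, reproducible and stratifiable", {
  pats <- tibble::tibble(patient_id = sprintf("P%02d", 1:10),
                         reference_label = rep(c(TRUE, FALSE), 5))
  s <- split_cohort(pats, 0.5, seed = 3)
  expect_length(s$train_ids, 5)
  expect_length(intersect(s$train_ids, s$test_ids), 0)
  expect_setequal(c(s$train_ids, s$test_ids), pats$patient_id)
  expect_identical(split_cohort(pats, 0.5, seed = 3), s)

  n <- 1000
  pats2 <- tibble::tibble(patient_id = sprintf("Q%04d", 1:n),
                          reference_label = seq_len(n) <= round(0.72 * n))
  st <- split_cohort(pats2, 0.5, seed = 1, stratify_by_reference = TRUE)
  prev_tr <- mean(pats2$reference_label[pats2$patient_id %in% st$train_ids])
  prev_te <- mean(pats2$reference_label[pats2$patient_id %in% st$test_ids])
  expect_lte(abs(prev_tr - prev_te) * n / 2, 1)  # within one patient
})

test_that("coding-pattern windows include the index day and respect boundaries", {
  idx <- as_day("2020-01-01")
  pats <- tibble::tibble(patient_id = c("A", "B"), index_date = idx)
  claims <- tibble::tibble(
    patient_id = c("A", "B", "B"),
    service_date = c(idx, idx + 91, idx - 90),
    code = c("E05.00", "E05.00", "99213"),
    system = c("ICD-10-CM", "ICD-10-CM", "CPT")
  )
  tab <- characterize_coding_patterns(claims, pats)
  get_n <- function(code, w) {
    r <- tab[tab$code == code & tab$window == w, ]
    if (nrow(r)) r$n else 0L
  }
  expect_equal(get_n("E05.00", 90), 1)   # on-index claim counts everywhere
  expect_equal(get_n("E05.00", 180), 2)  # +91 enters at the 180-day window
  expect_equal(get_n("E05.00", 365), 2)
  expect_equal(get_n("99213", 90), 1)    # -90 is inside the closed boundary
  # nondecreasing in window size for every code
  for (cd in unique(tab$code)) {
    ns <- sapply(c(90, 180, 365), function(w) get_n(cd, w))
    expect_true(all(diff(ns) >= 0))
  }
})
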