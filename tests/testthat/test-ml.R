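test_that("baseline feature matrix binarizes occurrences inside the window", {
  idx <- as_day("2021-06-01")
  pats <- tibble::tibble(patient_id = c("A", "B"), index_date = idx)
  claims <- tibble::tibble(
    patient_id = c("A", "A", "A", "A", "B", "B"),
    service_date = c(idx - 800, idx - 10, idx - 10, idx - 5, idx, idx + 1),
    code = c("E05.00", "99213", "99213", "99213", "12345678901", "H53.2"),
    system = c("ICD-10-CM", "CPT", "CPT", "CPT", "NDC", "ICD-10-CM")
  )
  fm <- build_feature_matrix(claims, pats)
  x <- as.matrix(fm$matrix)
  expect_false("ICD-10-CM:E0500" %in% colnames(x))     # outside 730-day window
  expect_equal(x["A", "CPT:99213"], 1)                 # binary, not a count of 3
  expect_false(any(fm$meta$system == "NDC"))           # pharmacy codes excluded
  expect_false("ICD-10-CM:H532" %in% colnames(x))      # post-index claim unseen

  # brute-force per-patient scan on a generated cohort
  co <- generate_cohort(cohort_config(50, seed = 31))
  fm2 <- build_feature_matrix(co$claims, co$patients)
  for (i in sample(50, 10)) {
    id <- co$patients$patient_id[i]
    sub <- co$claims[co$claims$patient_id == id &
                       co$claims$service_date >= co$patients$index_date[i] - 730 &
                       co$claims$service_date <= co$patients$index_date[i], ]
    expected <- sort(unique(paste(sub$system, normalize_code(sub$code, sub$system), sep = ":")))
    expect_equal(sort(colnames(fm2$matrix)[as.matrix(fm2$matrix)[id, ] > 0]), expected)
  }
})

test_that("the prevalence screen requires the threshold in both classes", {
  n <- 4000
  y <- rep(c(TRUE, FALSE), each = n / 2)
  x <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(n, 3), dimnames = list(NULL, c("a", "b", "c")))
  x[1:4, 1] <- 1                      # 0.2% of TED, absent in non-TED
  x[c(1:1000, 2001:3000), 2] <- 1     # 50% in both
  x[c(1:4, 2001), 3] <- 1             # 0.2% TED, 0.05% non-TED
  kept <- prevalence_screen(x, y, 0.001)
  expect_equal(kept, "b")
  expect_setequal(prevalence_screen(x, y, 0), c("a", "b", "c"))
  expect_error(prevalence_screen(x, rep(TRUE, n)), class = "tedclaims_input_error")
})

test_that("expert-list merge reports data-driven / expert / overlap arithmetic", {
  dd <- sprintf("ICD-10-CM:D%04d", 1:4233)
  expert <- c(sprintf("ICD-10-CM:D%04d", 1:43), sprintf("ICD-10-CM:E%03d", 1:125))
  merged <- merge_expert_list(dd, expert)
  counts <- attr(merged, "counts")
  expect_equal(unname(counts["final"]), 4358)
  expect_equal(unname(counts["overlap"]), 43)
  expect_length(merged, 4358)

  expect_equal(as.character(merge_expert_list(dd, character(0))), sort(dd))
  expect_equal(as.character(merge_expert_list(dd, dd[1:10])), sort(dd))
})

test_that("utilization-chapter exclusion drops only ICD-10 X/Y/Z columns", {
  cols <- c("ICD-10-CM:Z79899", "ICD-10-CM:E0500", "CPT:99214",
            "ICD-10-CM:Y930", "ICD-9:E8500", "HCPCS:J1234")
  kept <- exclude_utilization_codes(cols)
  expect_setequal(kept, c("ICD-10-CM:E0500", "CPT:99214", "ICD-9:E8500", "HCPCS:J1234"))
})

test_that("RFE keeps a dominant feature, shrinks strictly, and is deterministic", {
  sim <- simulate_planted_features(600, n_informative = 1, n_noise = 15,
                                   rate_pos = 0.7, rate_neg = 0.05, seed = 5)
  cfg <- ml_config(seed = 5, n_folds = 4)
  lr <- boosted_tree_learner(nrounds = 25, max_depth = 3)
  tr <- rfe_select(sim$matrix, sim$labels, lr, cfg)
  expect_true(all(diff(tr$trace$n_features) < 0))
  expect_true("SIM:INF1" %in% tr$features[[nrow(tr$trace)]])  # survives to the last iterate
  expect_true("SIM:INF1" %in% tr$selected)
  expect_equal(tr$trace$cv_auc[tr$best_iteration], max(tr$trace$cv_auc))

  tr2 <- rfe_select(sim$matrix, sim$labels, lr, cfg)
  expect_identical(tr$trace, tr2$trace)
  expect_identical(tr$selected, tr2$selected)
  expect_error(rfe_select(sim$matrix[, 1, drop = FALSE], sim$labels, lr, cfg),
               class = "tedclaims_input_error")
})

test_that("a 1x1 grid reduces to a single direct RFE run", {
  sim <- simulate_planted_features(400, n_informative = 1, n_noise = 10, seed = 2)
  cfg <- ml_config(seed = 11, n_folds = 3,
                   grid = data.frame(eta = 0.3, max_depth = 3, nrounds = 20, lambda = 1))
  traces <- run_grid(sim$matrix, sim$labels, cfg)
  expect_length(traces, 1)
  direct <- rfe_select(sim$matrix, sim$labels,
                       boosted_tree_learner(eta = 0.3, max_depth = 3, nrounds = 20, lambda = 1),
                       cfg, seed = derive_seed_for_test(11, "grid_1"))
  expect_identical(traces[[1]]$trace, direct$trace)
  expect_equal(nrow(default_hyperparameter_grid()), 81)
})

test_that("consensus ranking orders by frequency, then importance, then code", {
  mk_trace <- function(selected, imp) {
    structure(list(selected = selected,
                   importance = imp,
                   trace = tibble::tibble()), class = "rfe_trace")
  }
  traces <- list(
    mk_trace(c("a", "b", "c"), c(a = 0.5, b = 0.3, c = 0.2)),
    mk_trace(c("a", "c"), c(a = 0.6, c = 0.4)),
    mk_trace(c("a", "d"), c(a = 0.4, d = 0.6))
  )
  cons <- consensus_features(traces, 3)
  expect_equal(cons$column[1], "a")              # in all three traces
  expect_equal(cons$column[2], "c")              # 2/3 beats 1/3
  # tie between b and d (1/3 each) broken by mean importance: d (0.6) > b (0.3)
  expect_equal(cons$column[3], "d")
  expect_warning(all4 <- consensus_features(traces, 10), "exceeds")
  expect_equal(nrow(all4), 4)
  # ties all the way to the name fall back to lexicographic order
  t2 <- list(mk_trace(c("x", "y"), c(x = 0.5, y = 0.5)))
  expect_equal(consensus_features(t2, 2)$column, c("x", "y"))
})

test_that("the simplified model uses only consensus columns", {
  sim <- simulate_planted_features(500, n_informative = 2, n_noise = 10, seed = 8)
  model <- train_simplified(sim$matrix, sim$labels, c("SIM:INF1", "SIM:INF2"), trees = 10)
  p <- predict(model, sim$matrix)
  expect_true(all(p >= 0 & p <= 1))
  # altering non-consensus columns cannot change predictions
  x2 <- sim$matrix
  x2[, "SIM:NOISE01"] <- 1 - x2[, "SIM:NOISE01"]
  expect_identical(predict(model, x2), p)

  one_tree <- train_simplified(sim$matrix, sim$labels, "SIM:INF1", trees = 1)
  p1 <- predict(one_tree, sim$matrix)
  expect_true(all(p1 >= 0 & p1 <= 1))
})

test_that("evaluation refuses overlapping train and test sets", {
  sim <- simulate_planted_features(200, seed = 6)
  model <- train_simplified(sim$matrix, sim$labels, "SIM:INF1", trees = 5)
  expect_error(
    evaluate_model(model, sim$matrix, sim$labels, train_ids = rownames(sim$matrix)[1:10]),
    class = "tedclaims_leakage_error"
  )
  ok <- evaluate_model(model, sim$matrix[101:200, ], sim$labels[101:200],
                       train_ids = rownames(sim$matrix)[1:100])
  expect_true(ok$auc > 0.5)
  expect_equal(nrow(ok$sweep), 6)
})

test_that("stratified folds keep both classes everywhere or fail loudly", {
  y <- rep(c(TRUE, FALSE), c(40, 10))
  f <- tedclaims:::stratified_folds(y, 5, seed = 1)
  for (k in 1:5) expect_setequal(unique(y[f == k]), c(TRUE, FALSE))
  expect_error(tedclaims:::stratified_folds(rep(c(TRUE, FALSE), c(48, 2)), 5, seed = 1),
               class = "tedclaims_stratification_error")
})
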