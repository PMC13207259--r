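test_that("confusion counts match hand tabulation", {
  ref <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(unclass(confusion(ref, ref))[c("fp", "fn")], list(fp = 0L, fn = 0L))
  expect_equal(unclass(confusion(!ref, ref))[c("tp", "tn")], list(tp = 0L, tn = 0L))
  set.seed(10)
  for (i in 1:20) {
    pred <- runif(20) > 0.5; refr <- runif(20) > 0.5
    cm <- confusion(pred, refr)
    tab <- table(factor(pred, c(FALSE, TRUE)), factor(refr, c(FALSE, TRUE)))
    expect_equal(cm$tp, tab["TRUE", "TRUE"], ignore_attr = TRUE)
    expect_equal(cm$fp, tab["TRUE", "FALSE"], ignore_attr = TRUE)
    expect_equal(cm$fn, tab["FALSE", "TRUE"], ignore_attr = TRUE)
    expect_equal(cm$tn, tab["FALSE", "FALSE"], ignore_attr = TRUE)
  }
  expect_error(confusion(TRUE, c(TRUE, FALSE)), class = "tedclaims_input_error")
})

test_that("2x2 metric formulas and degenerate cells behave as documented", {
  m <- metrics_from_counts(structure(list(tp = 25, fp = 25, fn = 25, tn = 25),
                                     class = "confusion_counts"))
  e <- m$estimates
  expect_equal(unname(e[c("sensitivity", "specificity", "ppv", "npv", "f1")]),
               rep(0.5, 5))
  expect_equal(unname(e[c("plr", "nlr")]), c(1, 1))

  # the observed sensitivity/specificity of the broadest rule-based
  # algorithm (48.7% / 59.9%) as counts
  m2 <- metrics_from_counts(structure(list(tp = 487, fn = 513, fp = 401, tn = 599),
                                      class = "confusion_counts"))
  expect_equal(round(m2$estimates[["plr"]], 2), 1.21)
  expect_equal(round(m2$estimates[["nlr"]], 2), 0.86)

  inf <- metrics_from_counts(structure(list(tp = 5, fp = 0, fn = 1, tn = 10),
                                       class = "confusion_counts"))
  expect_identical(inf$estimates[["plr"]], Inf)

  allneg <- metrics_from_counts(structure(list(tp = 0, fp = 3, fn = 0, tn = 7),
                                          class = "confusion_counts"))
  expect_true(is.na(allneg$estimates[["sensitivity"]]))
  expect_match(paste(allneg$notes, collapse = " "), "no reference positives")
})

test_that("predictive values transport across prevalence by Bayes' rule", {
  counts <- published_cohort_counts()
  prev <- counts[["ted"]] / sum(counts)
  pv <- predictive_values_at_prevalence(0.487, 0.599, prev)
  expect_equal(round(100 * pv$ppv, 1), 75.8)
  expect_equal(round(100 * pv$npv, 1), 31.2)

  pv1 <- predictive_values_at_prevalence(1, 1, 0.3)
  expect_equal(c(pv1$ppv, pv1$npv), c(1, 1))

  grid <- seq(0.05, 0.95, by = 0.05)
  ppvs <- predictive_values_at_prevalence(0.8, 0.7, grid)$ppv
  expect_true(all(diff(ppvs) > 0))  # PPV rises with prevalence
  npvs <- predictive_values_at_prevalence(0.8, 0.7, grid)$npv
  expect_true(all(diff(npvs) < 0))

  # at the empirical cohort prevalence, transport reproduces the raw 2x2
  cm <- confusion(c(TRUE, TRUE, FALSE, TRUE, FALSE), c(TRUE, FALSE, FALSE, TRUE, TRUE))
  m <- metrics_from_counts(cm)
  pv2 <- predictive_values_at_prevalence(m$estimates[["sensitivity"]],
                                         m$estimates[["specificity"]],
                                         m$estimates[["prevalence"]])
  expect_equal(pv2$ppv, m$estimates[["ppv"]])
  expect_equal(pv2$npv, m$estimates[["npv"]])
})

test_that("Wilson score intervals match the closed form and achieve nominal-ish coverage", {
  expect_equal(proportion_ci(0, 10, 0.95)[1], 0)
  expect_equal(round(proportion_ci(5, 10, 0.95), 4), c(0.2366, 0.7634))
  ci <- proportion_ci(90, 100, 0.95)
  expect_true(ci[1] > 0 && ci[2] < 1 && ci[1] < 0.9 && ci[2] > 0.9)

  set.seed(99)
  x <- rbinom(10000, 100, 0.5)
  z <- qnorm(0.975); n <- 100
  phat <- x / n
  denom <- 1 + z^2 / n
  center <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  covered <- (center - half <= 0.5) & (0.5 <= center + half)
  expect_gte(mean(covered), 0.93)
})

test_that("likelihood-ratio intervals tighten to the point estimate and match a bootstrap", {
  mk <- function(k) structure(list(tp = 487 * k, fn = 513 * k, fp = 401 * k, tn = 599 * k),
                              class = "confusion_counts")
  big <- lr_ci(mk(10000))
  expect_lt(diff(big$plr), 0.005)
  expect_true(big$plr[1] < 487 / 401 && 487 / 401 < big$plr[2])
  wide <- lr_ci(mk(1))
  expect_gt(diff(wide$plr), diff(big$plr))

  set.seed(7)
  n <- 500
  ref <- runif(n) < 0.6
  pred <- ifelse(ref, runif(n) < 0.7, runif(n) < 0.3)
  asym <- lr_ci(confusion(pred, ref))
  boots <- t(replicate(800, {
    i <- sample(n, replace = TRUE)
    cm <- confusion(pred[i], ref[i])
    s <- cm$tp / (cm$tp + cm$fn); c0 <- cm$tn / (cm$tn + cm$fp)
    c(s / (1 - c0), (1 - s) / c0)
  }))
  bp <- quantile(boots[, 1], c(0.025, 0.975))
  bn <- quantile(boots[, 2], c(0.025, 0.975))
  expect_equal(round(asym$plr, 1), round(unname(bp), 1), tolerance = 0.11)
  expect_equal(round(asym$nlr, 1), round(unname(bn), 1), tolerance = 0.11)
})

test_that("rank AUC matches exhaustive pair counting and an external implementation", {
  expect_equal(auc_score(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  s6 <- c(0.1, 0.4, 0.35, 0.8, 0.35, 0.7)
  l6 <- c(FALSE, TRUE, FALSE, TRUE, TRUE, FALSE)
  expect_equal(auc_score(s6, l6), bf_auc(s6, l6))

  set.seed(3)
  sc <- runif(200); lb <- runif(200) < 0.4
  expect_equal(auc_score(sc, lb), bf_auc(sc, lb))
  expect_equal(auc_score(sc, lb),
               as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE, direction = "<"))))
  # invariance under strictly increasing transforms
  expect_equal(auc_score(qlogis(sc), lb), auc_score(sc, lb))

  set.seed(4)
  null_auc <- auc_score(runif(2000), runif(2000) < 0.5)
  expect_lt(abs(null_auc - 0.5), 0.05)
  expect_warning(a1 <- auc_score(1:3, c(TRUE, TRUE, TRUE)), "one class")
  expect_true(is.na(a1))
})

test_that("threshold sweeps are monotone and reproduce the derived ratios", {
  ref <- c(rep(TRUE, 6), rep(FALSE, 4))
  sweep0 <- threshold_sweep(as.numeric(ref), ref)
  expect_true(all(sweep0$sensitivity == 1 & sweep0$specificity == 1))

  set.seed(12)
  p <- runif(500); r <- runif(500) < p  # informative probabilities
  sw <- threshold_sweep(p, r)
  expect_true(all(diff(sw$sensitivity) <= 1e-12))
  expect_true(all(diff(sw$specificity) >= -1e-12))

  # ratios recomputed from rates alone: the simplified-model operating
  # point (sens 49.3%, spec 77.2%) gives PLR 2.16
  d <- derived_metrics_from_rates(0.493, 0.772, 0.5)
  expect_equal(round(d$plr, 2), 2.16)
  expect_error(threshold_sweep(c(0.5, 1.2), c(TRUE, FALSE)),
               class = "tedclaims_input_error")
  expect_error(threshold_grid(c(0.3, 0.3)), class = "tedclaims_config_error")
})
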