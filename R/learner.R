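# Pluggable learner contract: the feature-selection pipeline only needs
# fit / predict_probability / feature_importance, deterministic under a
# fixed seed, so any gradient-boosted implementation (or a linear model)
# can stand behind it.

#' Gradient-boosted tree learner
#'
#' Wraps xgboost binary-logistic boosting behind the learner contract
#' used by the feature-selection pipeline. Subsampling is disabled and a
#' single thread is used, so fits are deterministic given the data.
#'
#' @param eta learning rate.
#' @param max_depth tree depth.
#' @param nrounds number of boosting rounds (trees).
#' @param lambda L2 regularization strength.
#' @return object of class `ted_learner`: list of `fit(x, y)`,
#'   `predict_probability(model, x)`, `feature_importance(model)`
#'   (named, zero for unused features), and `params`.
#' @export
boosted_tree_learner <- function(eta = 0.1, max_depth = 4, nrounds = 60, lambda = 1) {
  params <- list(objective = "binary:logistic", eta = eta, max_depth = max_depth,
                 lambda = lambda, nthread = 1, subsample = 1, colsample_bytree = 1)
  structure(list(
    params = c(params, nrounds = nrounds),
    fit = function(x, y) {
      dm <- xgboost::xgb.DMatrix(x, label = as.numeric(y))
      fit <- xgboost::xgb.train(params = params, data = dm,
                                nrounds = nrounds, verbose = 0)
      list(booster = fit, features = colnames(x))
    },
    predict_probability = function(model, x) {
      stats::predict(model$booster, xgboost::xgb.DMatrix(x[, model$features, drop = FALSE]))
    },
    feature_importance = function(model) {
      imp <- setNames(rep(0, length(model$features)), model$features)
      tab <- tryCatch(xgboost::xgb.importance(model = model$booster),
                      error = function(e) NULL)
      if (!is.null(tab) && nrow(tab)) imp[tab$Feature] <- tab$Gain
      imp
    }
  ), class = "ted_learner")
}

# Stratified fold assignment: each class is shuffled and dealt round
# robin, so every fold holds both classes whenever counts permit.
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  if (any(vapply(split(y, fold), function(g) length(unique(g)) < 2L, logical(1)))) {
    ted_stop("tedclaims_stratification_error",
             "degenerate fold: a class is absent from at least one fold")
  }
  fold
}

# k-fold cross-validated AUC plus fold-averaged feature importance for
# one feature subset.
cv_fit_stats <- function(x, y, learner, folds) {
  k <- max(folds)
  aucs <- numeric(k)
  imp <- setNames(rep(0, ncol(x)), colnames(x))
  for (f in seq_len(k)) {
    tr <- folds != f
    model <- learner$fit(x[tr, , drop = FALSE], y[tr])
    p <- learner$predict_probability(model, x[!tr, , drop = FALSE])
    aucs[f] <- auc_score(p, y[!tr])
    imp <- imp + learner$feature_importance(model)
  }
  list(auc = mean(aucs), importance = imp / k)
}
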