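#' Configuration of the machine-learning feature pipeline
#'
#' Defaults follow the study procedure: binary code indicators over a
#' 2-year (730-day) baseline window, a 0.1% prevalence screen applied
#' within both classes, exclusion of ICD-10 X/Y/Z utilization chapters,
#' recursive feature elimination evaluated by 5-fold stratified
#' cross-validated AUC, a 3x3x3x3 = 81-configuration hyperparameter grid
#' (learning rate, tree depth, boosting rounds, L2 strength), a
#' 201-feature cap on each selected subset, a 29-code consensus set, and
#' a 10-tree simplified model. The RFE drop schedule (bottom 20% of
#' features per iteration, minimum 1) and the stopping rule (two
#' consecutive iterations without AUC gain > 1e-4) are stated,
#' configurable conventions.
#'
#' @param baseline_days baseline window length in days.
#' @param screen_threshold minimum within-class prevalence.
#' @param excluded_icd_chapters leading letters of excluded ICD-10 chapters.
#' @param n_folds stratified CV folds.
#' @param grid data.frame of hyperparameter configurations with columns
#'   eta, max_depth, nrounds, lambda.
#' @param rfe_feature_cap hard maximum size of a selected subset.
#' @param consensus_k consensus set size.
#' @param simplified_trees boosting rounds of the simplified model.
#' @param thresholds probability thresholds for evaluation.
#' @param drop_fraction fraction of features dropped per RFE iteration.
#' @param min_auc_gain,patience stopping rule.
#' @param seed base seed; per-configuration seeds are derived from it.
#' @return object of class `ml_config`.
#' @export
ml_config <- function(baseline_days = 730,
                      screen_threshold = 0.001,
                      excluded_icd_chapters = c("X", "Y", "Z"),
                      n_folds = 5,
                      grid = default_hyperparameter_grid(),
                      rfe_feature_cap = 201,
                      consensus_k = 29,
                      simplified_trees = 10,
                      thresholds = threshold_grid(),
                      drop_fraction = 0.2,
                      min_auc_gain = 1e-4,
                      patience = 2,
                      seed = 1L) {
  if (consensus_k > rfe_feature_cap) stop_config("consensus_k must be <= rfe_feature_cap")
  if (drop_fraction <= 0 || drop_fraction >= 1) stop_config("drop_fraction must be in (0,1)")
  structure(list(baseline_days = baseline_days, screen_threshold = screen_threshold,
                 excluded_icd_chapters = excluded_icd_chapters, n_folds = n_folds,
                 grid = grid, rfe_feature_cap = rfe_feature_cap,
                 consensus_k = consensus_k, simplified_trees = simplified_trees,
                 thresholds = thresholds, drop_fraction = drop_fraction,
                 min_auc_gain = min_auc_gain, patience = patience,
                 seed = as.integer(seed)),
            class = "ml_config")
}

#' Default 81-model hyperparameter grid (3 values on each of 4 axes)
#' @export
default_hyperparameter_grid <- function() {
  expand.grid(eta = c(0.05, 0.1, 0.3), max_depth = c(3, 4, 6),
              nrounds = c(40, 80, 150), lambda = c(0.5, 1, 2),
              KEEP.OUT.ATTRS = FALSE)
}

feature_colname <- function(system, code) paste(system, code, sep = ":")

#' Binary baseline feature matrix from claims
#'
#' One column per (system, code) among diagnosis and procedure systems
#' (ICD-9, ICD-10-CM, CPT, HCPCS; NDC pharmacy codes are excluded), one
#' row per patient; an entry is 1 iff the patient has >= 1 claim of that
#' code with service date in `[index - baseline_days, index]` (the index
#' day is observable and included). Column names are `system:code` after
#' normalization.
#'
#' @param claims claims tibble.
#' @param patients patient tibble with `index_date`.
#' @param baseline_days window length (default 730).
#' @return list with sparse 0/1 `matrix` (dgCMatrix) and `meta` tibble
#'   (column, system, code).
#' @export
build_feature_matrix <- function(claims, patients, baseline_days = 730) {
  dt <- data.table::as.data.table(claims)
  dt <- dt[dt$system %in% c("ICD-9", "ICD-10-CM", "CPT", "HCPCS"), ]
  dt$index_date <- patients$index_date[match(dt$patient_id, patients$patient_id)]
  dt <- dt[!is.na(dt$index_date) &
             dt$service_date >= dt$index_date - baseline_days &
             dt$service_date <= dt$index_date, ]
  dt$colname <- feature_colname(dt$system, normalize_code(dt$code, dt$system))
  cols <- sort(unique(dt$colname))
  i <- match(dt$patient_id, patients$patient_id)
  j <- match(dt$colname, cols)
  keep <- !is.na(i)
  x <- Matrix::sparseMatrix(i = i[keep], j = j[keep], x = 1,
                            dims = c(nrow(patients), length(cols)),
                            dimnames = list(patients$patient_id, cols))
  x@x[] <- 1  # binarize repeats
  x <- methods::as(x, "CsparseMatrix")
  meta <- tibble::tibble(
    column = cols,
    system = sub(":.*$", "", cols),
    code = sub("^[^:]*:", "", cols)
  )
  list(matrix = x, meta = meta)
}

#' Within-class prevalence screen
#'
#' Retains a column iff its mean is at least `threshold` within the TED
#' class AND within the non-TED class.
#'
#' @param x binary feature matrix.
#' @param labels logical class labels.
#' @param threshold minimum within-class prevalence (default 0.001).
#' @return character vector of retained column names.
#' @export
prevalence_screen <- function(x, labels, threshold = 0.001) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) stop_input("both classes must be present")
  p1 <- Matrix::colMeans(x[labels, , drop = FALSE])
  p0 <- Matrix::colMeans(x[!labels, , drop = FALSE])
  colnames(x)[p1 >= threshold & p0 >= threshold]
}

#' Merge a data-driven column set with an expert-curated code list
#'
#' Set union after normalization; the counts of data-driven, expert-only
#' and overlap codes are attached as the `counts` attribute.
#'
#' @param columns character vector of `system:code` column names.
#' @param expert_columns character vector in the same format.
#' @return merged, sorted column set.
#' @export
merge_expert_list <- function(columns, expert_columns) {
  overlap <- intersect(columns, expert_columns)
  merged <- sort(union(columns, expert_columns))
  structure(merged, counts = c(data_driven = length(columns),
                               expert = length(expert_columns),
                               overlap = length(overlap),
                               final = length(merged)))
}

#' Drop ICD-10 utilization-chapter columns
#'
#' Removes ICD-10-CM columns whose code begins with one of the excluded
#' chapter letters (default X, Y, Z: external causes and factors
#' influencing health status). Procedure and ICD-9 columns are untouched.
#'
#' @param columns `system:code` column names.
#' @param chapters excluded leading letters.
#' @return filtered column vector.
#' @export
exclude_utilization_codes <- function(columns, chapters = c("X", "Y", "Z")) {
  system <- sub(":.*$", "", columns)
  code <- sub("^[^:]*:", "", columns)
  drop <- system == "ICD-10-CM" & substr(code, 1, 1) %in% chapters
  columns[!drop]
}

#' Recursive feature elimination with cross-validated AUC
#'
#' Starting from all columns of `x`, each iteration evaluates the
#' current subset by stratified k-fold cross-validated AUC, recomputes
#' feature importance (fold-averaged), and drops the lowest-importance
#' `drop_fraction` of current features (at least one). Elimination stops
#' after `patience` consecutive iterations without an AUC improvement
#' greater than `min_auc_gain`, or when fewer than two features remain.
#' The selected subset is the argmax-AUC iterate among those within the
#' feature cap (ties to the smaller subset).
#'
#' @param x feature matrix (columns named).
#' @param y logical labels.
#' @param learner a `ted_learner`.
#' @param config an [ml_config()].
#' @param seed seed for fold assignment (default derived from config).
#' @return object of class `rfe_trace`: `trace` tibble (iteration,
#'   n_features, cv_auc), `features` list per iteration, `importance`
#'   of the selected iterate, `selected` character vector.
#' @export
rfe_select <- function(x, y, learner, config = ml_config(),
                       seed = derive_seed(config$seed, "rfe")) {
  if (ncol(x) < 2L) stop_input("need at least 2 features")
  y <- as.logical(y)
  folds <- stratified_folds(y, config$n_folds, seed)
  current <- colnames(x)
  iter <- 0L
  best_auc <- -Inf
  stall <- 0L
  trace <- list(); feats <- list(); imps <- list()
  while (TRUE) {
    iter <- iter + 1L
    st <- cv_fit_stats(x[, current, drop = FALSE], y, learner, folds)
    trace[[iter]] <- tibble::tibble(iteration = iter,
                                    n_features = length(current),
                                    cv_auc = st$auc)
    feats[[iter]] <- current
    imps[[iter]] <- st$importance
    if (st$auc > best_auc + config$min_auc_gain) {
      best_auc <- st$auc; stall <- 0L
    } else stall <- stall + 1L
    if (stall >= config$patience || length(current) <= 2L) break
    ndrop <- max(1L, floor(config$drop_fraction * length(current)))
    ord <- order(st$importance, sample(length(current)))  # random tiebreak among zeros
    current <- sort(current[-ord[seq_len(ndrop)]])
  }
  tr <- do.call(rbind, trace)
  cand <- which(tr$n_features <= config$rfe_feature_cap)
  if (length(cand)) {
    best <- cand[order(-tr$cv_auc[cand], tr$n_features[cand])][1]
    selected <- feats[[best]]
  } else {
    best <- nrow(tr)
    selected <- names(sort(imps[[best]], decreasing = TRUE))[seq_len(config$rfe_feature_cap)]
  }
  structure(list(trace = tr, features = feats, importance = imps[[best]],
                 selected = sort(selected), best_iteration = best),
            class = "rfe_trace")
}

#' Run RFE across the hyperparameter grid
#'
#' One [rfe_select()] trace per grid configuration; configuration i uses
#' a learner built from grid row i and a seed derived deterministically
#' from (base seed, i).
#'
#' @param x,y feature matrix and labels.
#' @param config an [ml_config()].
#' @param learner_factory function(eta, max_depth, nrounds, lambda) ->
#'   learner; default [boosted_tree_learner()].
#' @return list of `rfe_trace` objects, one per grid row.
#' @export
run_grid <- function(x, y, config = ml_config(),
                     learner_factory = boosted_tree_learner) {
  g <- config$grid
  lapply(seq_len(nrow(g)), function(i) {
    learner <- learner_factory(eta = g$eta[i], max_depth = g$max_depth[i],
                               nrounds = g$nrounds[i], lambda = g$lambda[i])
    rfe_select(x, y, learner, config,
               seed = derive_seed(config$seed, paste0("grid_", i)))
  })
}

#' Consensus feature ranking across RFE traces
#'
#' Codes are ranked by selection frequency across traces, then by mean
#' importance among traces that selected them, then lexicographically —
#' a deterministic, reproducible tiebreak. The top k are returned.
#'
#' @param traces list of `rfe_trace` objects.
#' @param k consensus size.
#' @return tibble (column, frequency, mean_importance) of min(k, pool)
#'   rows; warns if k exceeds the pool.
#' @export
consensus_features <- function(traces, k) {
  if (!length(traces)) stop_input("need at least one trace")
  sel <- lapply(traces, function(t) t$selected)
  pool <- sort(unique(unlist(sel)))
  freq <- vapply(pool, function(f) mean(vapply(sel, function(s) f %in% s, logical(1))),
                 numeric(1))
  mimp <- vapply(pool, function(f) {
    v <- vapply(traces, function(t) {
      if (f %in% t$selected) t$importance[[f]] else NA_real_
    }, numeric(1))
    mean(v, na.rm = TRUE)
  }, numeric(1))
  ord <- order(-freq, -mimp, pool)
  if (k > length(pool)) {
    warning(sprintf("requested k=%d exceeds the %d-feature pool; returning all", k, length(pool)))
    k <- length(pool)
  }
  tibble::tibble(column = pool[ord], frequency = freq[ord],
                 mean_importance = mimp[ord])[seq_len(k), ]
}

#' Fit the simplified small-tree model on the consensus features
#'
#' @param x feature matrix (will be restricted to `features`).
#' @param y logical labels.
#' @param features consensus column names (non-empty).
#' @param trees boosting rounds (default 10).
#' @param eta,max_depth,lambda learner settings.
#' @return object of class `ted_model`: learner, fitted model, features.
#' @export
train_simplified <- function(x, y, features, trees = 10,
                             eta = 0.3, max_depth = 4, lambda = 1) {
  if (!length(features)) stop_input("consensus feature set is empty")
  learner <- boosted_tree_learner(eta = eta, max_depth = max_depth,
                                  nrounds = trees, lambda = lambda)
  model <- learner$fit(x[, features, drop = FALSE], as.logical(y))
  structure(list(learner = learner, model = model, features = features),
            class = "ted_model")
}

#' Predict TED probabilities from a fitted model
#' @param object a `ted_model`.
#' @param x feature matrix containing the model's columns.
#' @param ... unused.
#' @export
predict.ted_model <- function(object, x, ...) {
  object$learner$predict_probability(object$model, x[, object$features, drop = FALSE])
}

#' Evaluate a fitted model on a held-out test set
#'
#' Guards against train/test leakage (overlapping patient ids raise an
#' error), then reports the AUC and the threshold-sweep metric table.
#'
#' @param model a `ted_model`.
#' @param x_test,y_test test features and labels.
#' @param thresholds probability thresholds.
#' @param prevalence optional prevalence for PPV/NPV transport.
#' @param train_ids ids used in training (checked against test rownames).
#' @return list with `auc` and `sweep` tibble.
#' @export
evaluate_model <- function(model, x_test, y_test, thresholds = threshold_grid(),
                           prevalence = NULL, train_ids = NULL) {
  if (!is.null(train_ids) && length(intersect(train_ids, rownames(x_test)))) {
    stop_leakage("train and test sets overlap (%d shared patients)",
                 length(intersect(train_ids, rownames(x_test))))
  }
  p <- predict(model, x_test)
  list(auc = auc_score(p, y_test),
       sweep = threshold_sweep(p, y_test, thresholds, prevalence))
}

#' Planted-signal feature simulation
#'
#' Binary labels at the given prevalence; `n_informative` features occur
#' at `rate_pos` in positives and `rate_neg` in negatives; `n_noise`
#' features occur at `noise_rate` independently of the label. Used to
#' test whether the RFE-consensus pipeline recovers known signal and
#' stays at chance when there is none.
#'
#' @param n patients.
#' @param n_informative,n_noise feature counts.
#' @param rate_pos,rate_neg class-conditional occurrence rates of
#'   informative features.
#' @param noise_rate occurrence rate of noise features.
#' @param prevalence label prevalence.
#' @param seed integer seed.
#' @return list with sparse `matrix` (columns INF1..., NOISE01...) and
#'   logical `labels`.
#' @export
simulate_planted_features <- function(n, n_informative = 2, n_noise = 48,
                                      rate_pos = 0.6, rate_neg = 0.1,
                                      noise_rate = 0.3, prevalence = 0.5,
                                      seed = 1L) {
  set.seed(seed)
  y <- runif(n) < prevalence
  cols <- c(sprintf("SIM:INF%d", seq_len(n_informative)),
            sprintf("SIM:NOISE%02d", seq_len(n_noise)))
  x <- matrix(0, n, n_informative + n_noise, dimnames = list(sprintf("P%05d", seq_len(n)), cols))
  for (j in seq_len(n_informative)) {
    x[, j] <- as.numeric(runif(n) < ifelse(y, rate_pos, rate_neg))
  }
  for (j in seq_len(n_noise)) {
    x[, n_informative + j] <- as.numeric(runif(n) < noise_rate)
  }
  list(matrix = methods::as(Matrix::Matrix(x, sparse = TRUE), "CsparseMatrix"),
       labels = y)
}
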