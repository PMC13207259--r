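#' Default end-to-end pipeline configuration
#'
#' A compact configuration for demonstration runs: a reduced
#' hyperparameter grid and light boosting so a full simulate / include /
#' phenotype / ML / evaluate cycle completes quickly. The cohort
#' generator itself keeps its study-condition defaults.
#'
#' @param n_patients cohort size.
#' @param seed top-level seed; stage seeds are derived from it.
#' @param grid hyperparameter grid for the ML stage.
#' @param consensus_k consensus feature-set size.
#' @return nested list understood by [run_pipeline()].
#' @export
demo_pipeline_config <- function(n_patients = 5000, seed = 7L,
                                 grid = expand.grid(eta = c(0.1, 0.3), max_depth = 3,
                                                    nrounds = 40, lambda = 1,
                                                    KEEP.OUT.ATTRS = FALSE),
                                 consensus_k = 15) {
  list(n_patients = n_patients, seed = as.integer(seed),
       codelists = NULL,  # NULL = packaged defaults
       ml = list(grid = grid, consensus_k = consensus_k, simplified_trees = 10))
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) stop_stage(stage, e))
}

#' Run the full validation pipeline on synthetic data
#'
#' Sequences simulate, build-cohort, coding-patterns, phenotype,
#' ml-train and evaluate, writing report tables (coding-pattern
#' frequencies, rule-based algorithm performance, ML threshold sweep,
#' consensus features) and a manifest (config snapshot, seed, stage
#' seeds, file digests, timestamp) under `out_dir`. Any stage failure
#' halts with the stage name and cause. Reruns with the same config are
#' byte-identical except for the manifest timestamp.
#'
#' @param config nested list as from [demo_pipeline_config()], or a path
#'   to a JSON file holding one.
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)

  codesets <- pipeline_stage("rule_phenotyping", {
    if (is.null(config$codelists)) default_code_lists() else read_code_lists(config$codelists)
  })

  cohort <- pipeline_stage("synthetic_linked_data", {
    generate_cohort(cohort_config(n_patients = config$n_patients,
                                  seed = derive_seed(seed, "simulate")))
  })

  built <- pipeline_stage("cohort_builder", apply_inclusion(cohort))
  included <- list(patients = built$patients,
                   claims = cohort$claims[cohort$claims$patient_id %in%
                                            built$patients$patient_id, ],
                   enrollment = cohort$enrollment)
  prev <- mean(included$patients$reference_label)

  patterns <- pipeline_stage("cohort_builder", {
    characterize_coding_patterns(included$claims,
                                 included$patients[included$patients$reference_label, ])
  })

  preds <- pipeline_stage("rule_phenotyping", run_algorithms(included, codesets = codesets))
  rule_rows <- lapply(1:6, function(a) {
    m <- metrics_from_counts(confusion(preds[[paste0("alg_", a)]],
                                       included$patients$reference_label))
    e <- m$estimates
    tibble::tibble(algorithm = a, sensitivity = e[["sensitivity"]],
                   specificity = e[["specificity"]], ppv = e[["ppv"]], npv = e[["npv"]],
                   plr = e[["plr"]], nlr = e[["nlr"]], f1 = e[["f1"]])
  })
  rule_tab <- do.call(rbind, rule_rows)

  ml <- pipeline_stage("ml_feature_pipeline", {
    cfg <- ml_config(grid = config$ml$grid,
                     consensus_k = config$ml$consensus_k,
                     simplified_trees = config$ml$simplified_trees,
                     seed = derive_seed(seed, "ml"))
    fm <- build_feature_matrix(included$claims, included$patients, cfg$baseline_days)
    split <- split_cohort(included$patients, 0.5, seed = derive_seed(seed, "split"))
    tr <- rownames(fm$matrix) %in% split$train_ids
    y <- included$patients$reference_label
    keep <- prevalence_screen(fm$matrix[tr, , drop = FALSE], y[tr], cfg$screen_threshold)
    keep <- exclude_utilization_codes(keep, cfg$excluded_icd_chapters)
    xtr <- fm$matrix[tr, keep, drop = FALSE]
    traces <- run_grid(xtr, y[tr], cfg)
    cons <- consensus_features(traces, cfg$consensus_k)
    model <- train_simplified(xtr, y[tr], cons$column, trees = cfg$simplified_trees)
    eval <- evaluate_model(model, fm$matrix[!tr, keep, drop = FALSE], y[!tr],
                           cfg$thresholds, prevalence = prev,
                           train_ids = split$train_ids)
    list(consensus = cons, sweep = eval$sweep, auc = eval$auc)
  })

  data.table::fwrite(patterns, file.path(out_dir, "coding_patterns.csv"))
  data.table::fwrite(rule_tab, file.path(out_dir, "rule_performance.csv"))
  data.table::fwrite(ml$sweep, file.path(out_dir, "ml_thresholds.csv"))
  data.table::fwrite(ml$consensus, file.path(out_dir, "consensus_features.csv"))

  files <- c("coding_patterns.csv", "rule_performance.csv",
             "ml_thresholds.csv", "consensus_features.csv")
  manifest <- list(
    config = config[setdiff(names(config), "ml")],
    ml = list(grid = config$ml$grid, consensus_k = config$ml$consensus_k),
    seed = seed,
    stage_seeds = list(simulate = derive_seed(seed, "simulate"),
                       split = derive_seed(seed, "split"),
                       ml = derive_seed(seed, "ml")),
    test_auc = ml$auc,
    digests = as.list(setNames(unname(tools::md5sum(file.path(out_dir, files))), files)),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Render a human-readable summary of a completed run
#'
#' @param run_dir directory written by [run_pipeline()].
#' @return character vector of summary lines (also printed).
#' @export
render_reports <- function(run_dir) {
  need <- file.path(run_dir, c("rule_performance.csv", "ml_thresholds.csv", "manifest.json"))
  missing <- need[!file.exists(need)]
  if (length(missing)) {
    stop_input("incomplete run: missing artifacts %s", paste(basename(missing), collapse = ", "))
  }
  rules <- data.table::fread(need[1])
  sweep <- data.table::fread(need[2])
  pct <- function(x) sprintf("%.1f%%", 100 * x)
  lines <- c(
    "Rule-based algorithms (reference standard = simulated note-derived label):",
    sprintf("  Algorithm %d: sens %s, spec %s, PPV %s, NPV %s, PLR %.2f, NLR %.2f, F1 %.2f",
            rules$algorithm, pct(rules$sensitivity), pct(rules$specificity),
            pct(rules$ppv), pct(rules$npv), rules$plr, rules$nlr, rules$f1),
    "Simplified boosted model across probability thresholds:",
    sprintf("  threshold %.2f: sens %s, spec %s, PPV %s, NPV %s, PLR %.2f, NLR %.2f, F1 %.2f",
            sweep$threshold, pct(sweep$sensitivity), pct(sweep$specificity),
            pct(sweep$ppv), pct(sweep$npv), sweep$plr, sweep$nlr, sweep$f1)
  )
  cat(lines, sep = "\n")
  invisible(lines)
}
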