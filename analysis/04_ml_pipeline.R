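#!/usr/bin/env Rscript
# Stage 4 — machine-learning feature pipeline and simplified model.
#
# Training rows only are used for the prevalence screen, RFE and
# consensus selection; the held-out half is touched once, for the final
# threshold sweep. The hyperparameter grid here is a 4-configuration
# subset of the full 81-model grid (the synthetic cohort carries ~60
# candidate codes, far fewer than the thousands in a real claims
# extract, so a larger grid only replicates identical selections).

library(tedclaims)

cohort <- read_dataset("scratch/dataset")
res <- apply_inclusion(cohort)
patients <- res$patients
claims <- cohort$claims[cohort$claims$patient_id %in% patients$patient_id, ]
y <- patients$reference_label

cfg <- ml_config(
  grid = expand.grid(eta = c(0.1, 0.3), max_depth = c(3, 4),
                     nrounds = 40, lambda = 1, KEEP.OUT.ATTRS = FALSE),
  consensus_k = 15, simplified_trees = 10, seed = 4242
)

fm <- build_feature_matrix(claims, patients, cfg$baseline_days)
split <- split_cohort(patients, 0.5, seed = 4242)
tr <- rownames(fm$matrix) %in% split$train_ids

keep <- prevalence_screen(fm$matrix[tr, , drop = FALSE], y[tr], cfg$screen_threshold)
keep <- exclude_utilization_codes(keep, cfg$excluded_icd_chapters)
cat(sprintf("Features: %d extracted, %d after 0.1%%-in-both-classes screen and X/Y/Z exclusion\n",
            ncol(fm$matrix), length(keep)))

xtr <- fm$matrix[tr, keep, drop = FALSE]
traces <- run_grid(xtr, y[tr], cfg)
cat(sprintf("RFE traces: %d (one per hyperparameter configuration)\n", length(traces)))
for (i in seq_along(traces)) {
  t <- traces[[i]]$trace
  cat(sprintf("  config %d: %d iterations, best CV AUC %.3f with %d features\n",
              i, nrow(t), max(t$cv_auc),
              t$n_features[which.max(t$cv_auc)]))
}

cons <- consensus_features(traces, cfg$consensus_k)
write.csv(cons, "results/consensus_features.csv", row.names = FALSE)
cat(sprintf("\nConsensus set (%d codes; top 5 by selection frequency):\n", nrow(cons)))
print(as.data.frame(cons[1:5, ]), row.names = FALSE)

model <- train_simplified(xtr, y[tr], cons$column, trees = cfg$simplified_trees)
ev <- evaluate_model(model, fm$matrix[!tr, keep, drop = FALSE], y[!tr],
                     cfg$thresholds, prevalence = mean(y),
                     train_ids = split$train_ids)
sweep <- ev$sweep
for (cc in c("sensitivity", "specificity", "ppv", "npv")) sweep[[cc]] <- round(100 * sweep[[cc]], 1)
for (cc in c("plr", "nlr", "f1")) sweep[[cc]] <- round(sweep[[cc]], 2)
write.csv(sweep, "results/ml_thresholds.csv", row.names = FALSE)

cat(sprintf("\nSimplified %d-tree model, held-out AUC %.3f; threshold sweep:\n",
            cfg$simplified_trees, ev$auc))
print(as.data.frame(sweep), row.names = FALSE)
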