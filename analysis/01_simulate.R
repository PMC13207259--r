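#!/usr/bin/env Rscript
# Stage 1 — simulate the linked claims/registry cohort.
#
# Generates a synthetic analytic cohort with the statistical structure
# the validation study assumes: ~72% TED prevalence, a note-derived
# reference label with precision 0.90 / recall 0.91, claims concentrated
# around each patient's index date per the published code-frequency
# profile, proxy index dates for non-TED patients, and about 11% of
# patients with insufficient pre-index enrollment. Writes the dataset as
# CSV for the later stages.

library(tedclaims)

n <- 20000
seed <- 42

cfg <- cohort_config(n_patients = n, seed = seed)
cohort <- generate_cohort(cfg)
write_dataset(cohort, "scratch/dataset")

p <- cohort$patients
cat(sprintf("Simulated %d patients (seed %d):\n", n, seed))
cat(sprintf("  true TED prevalence        %.1f%% (target 72%%)\n", 100 * mean(p$true_ted)))
cat(sprintf("  reference-label precision  %.3f (target 0.90)\n",
            sum(p$reference_label & p$true_ted) / sum(p$reference_label)))
cat(sprintf("  reference-label recall     %.3f (target 0.91)\n",
            sum(p$reference_label & p$true_ted) / sum(p$true_ted)))
cat(sprintf("  claims generated           %d\n", nrow(cohort$claims)))
cat("Dataset written to scratch/dataset/\n")
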