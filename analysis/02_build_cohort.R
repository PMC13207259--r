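#!/usr/bin/env Rscript
# Stage 2 — apply inclusion criteria and characterize coding patterns.
#
# Adults with >= 365 days of continuous pre-index enrollment and an
# evaluated reference label are retained. The per-window code-frequency
# table among reference-positive patients mirrors the published
# frequency table's layout (code, system, window, n, pct), and the
# planning sample size for the sensitivity estimate is reported.

library(tedclaims)

cohort <- read_dataset("scratch/dataset")
res <- apply_inclusion(cohort, inclusion_criteria())

flow <- rbind(
  data.frame(step = "generated", n = nrow(cohort$patients)),
  data.frame(step = paste0("excluded_", res$summary$reason), n = -res$summary$n),
  data.frame(step = "included", n = nrow(res$patients))
)
write.csv(flow, "results/inclusion_flow.csv", row.names = FALSE)

cat("Inclusion flow:\n")
print(flow, row.names = FALSE)

included <- res$patients
claims <- cohort$claims[cohort$claims$patient_id %in% included$patient_id, ]
ref_pos <- included[included$reference_label, ]
patterns <- characterize_coding_patterns(claims, ref_pos)
write.csv(patterns, "results/coding_patterns.csv", row.names = FALSE)

top <- patterns[patterns$window == 90, ][1:5, ]
cat("\nTop codes within +/-90 days of index among reference-positive patients:\n")
print(as.data.frame(top), row.names = FALSE)

n_min <- min_positive_sample_size(p = 0.70, confidence_level = 0.95,
                                  margin_of_error = 0.025)
cat(sprintf("\nMinimum reference-positive patients for a sensitivity estimate at 70%% +/- 2.5%%: %d\n", n_min))
cat(sprintf("Reference-positive patients available: %d (test half: ~%d)\n",
            nrow(ref_pos), nrow(ref_pos) %/% 2))
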