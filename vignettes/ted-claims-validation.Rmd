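---
title: "Validating claims-based thyroid eye disease phenotyping: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating claims-based thyroid eye disease phenotyping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Thyroid eye disease (TED, Graves' orbitopathy) has no dedicated ICD
code. Observational studies in administrative claims therefore identify
cases with composite *phenotyping algorithms* — rules over
hyperthyroidism and eye symptom/sign codes — whose operating
characteristics have historically been unknown. `tedclaims` implements
a complete validation workflow for such algorithms: a synthetic
generator for linked claims/registry cohorts, the cohort inclusion
logic, six declarative rule-based algorithms, a full
diagnostic-accuracy toolkit, and a recursive-feature-elimination (RFE)
consensus pipeline over gradient-boosted tree models. Everything runs
on synthetic data because the real linked dataset that motivated the
design (an ophthalmology registry linked to all-payer claims) is
proprietary; the generator reproduces its statistical structure so that
every stage of the workflow is exercised and testable.

# The reference standard and why it is imperfect

Validation requires a label treated as truth. Here that label is a
simulated note-derived classification with precision 0.90 and recall
0.91 — the operating characteristics reported for the NLP model that
produced the real reference standard. The generator separates the
*true* disease state from the *reference label*: reference positives
are drawn from true positives at the configured recall, and the
false-positive probability among true negatives is solved analytically
so that expected precision matches at the cohort's empirical
prevalence,

$$ \mathrm{fpr} \;=\; \frac{r\,\pi\,(1-p)}{p\,(1-\pi)}, $$

for precision $p$, recall $r$ and prevalence $\pi$. An analytic solve
(rather than rejection sampling) makes the expectation exact and the
parameter-recovery test sharp; requests that imply $\mathrm{fpr} > 1$
fail with the implied rate reported. Because downstream evaluation
compares algorithms against the *reference* label, the simulation also
reproduces the key interpretive caveat of imperfect reference
standards: measured sensitivity understates true sensitivity when
reference false positives look like algorithm false negatives.

# What the generator emulates — and what it does not

`cohort_config()` defaults are the study conditions:

* ~72% TED prevalence (the enriched linked cohort, not a
  population prevalence);
* age at index ~ Normal(60.4, 14.5) truncated to adults, 76% female;
* index dates uniform over 2016-01-01 to 2024-09-30;
* per-code occurrence probabilities within ±90/±180/±365 days of the
  index date taken from the published frequency table of confirmed TED
  patients (top-20 codes per window, union of the three lists);
* claims generated only inside enrollment spans — what a claims
  database can observe;
* proxy index dates for non-TED patients: first observed record plus a
  gap resampled from the TED patients' empirical (index − first
  record) distribution, clamped to the observed record range;
* 10.8% of patients with under a year of pre-index coverage, matching
  the attrition the enrollment criterion produced in the source cohort
  (103,309 → 92,150).

Occurrence is drawn independently per nested window *band* with
conditional probabilities chosen so the marginal probability of ≥ 1
claim within each window equals the configured value exactly; claim
counts given occurrence are 1 + Poisson(0.7) and dates are uniform
within the band. Dates are integer day offsets from 1970-01-01
internally (exact window arithmetic); calendars appear only at I/O.

Three published-table gaps are filled by stated convention. (1) The
three windows' top-20 lists differ, so a code missing a printed value
in one window gets it from the median adjacent-window growth ratio of
fully observed codes — monotone across nested windows by construction.
(2) Non-TED frequencies are unpublished and default to 0.6× the TED
values, except TED-specific codes (unspecified exophthalmos), set near
zero, and a handful of synthetic symptom/sign codes (diplopia, lid
retraction, orbital inflammation, strabismus, ocular pain) added with
modest frequencies so every rule criterion is representable; these are
overridable data, not code. (3) The proxy-gap distribution's shape is
unpublished beyond "matched to the TED gap distribution", so the
default is empirical resampling.

The generator does **not** emulate payer adjudication, costs,
pharmacy-fill structure beyond code occurrence, record linkage,
regional or clinician coding variation, or code–code correlation beyond
the class-conditional structure. Passing tests therefore demonstrate
that the *machinery* is correct under the stated statistical structure,
not that any algorithm achieves particular accuracy on real claims.

# Cohort inclusion

`apply_inclusion()` keeps adults (≥ 18 at index) with 365 days of
continuous pre-index enrollment and an evaluated reference label.
Decisions fixed here: "12 months" is 365 days (leap years ignored); the
lookback excludes the index date itself ("prior to"), while coding-
pattern windows include it ("before, on, or after"); gap tolerance
defaults to 0 days but is configurable, since "continuous" is undefined
in the source; exclusion reasons are evaluated in the fixed order age →
enrollment → reference-evaluated so the log is deterministic, with
missing index dates (patients with no claims) failing the enrollment
step because the lookback cannot be anchored. The planning sample size
`min_positive_sample_size()` is the closed form
$\lceil z^2 p(1-p)/E^2 \rceil$; with $p = 0.70$, 95% confidence and
$E = 0.025$ it gives 1291 positives, which motivated the 50/50
train/test split in the source design.

# The six rule-based algorithms

Each algorithm is data, not code: named code sets (hyperthyroidism =
E05.x/242.x, exophthalmos = H05.2x, diplopia = H53.2, lid retraction =
H02.53x, …) live in an editable JSON file with trailing-`*` prefix
wildcards; matching is exact after normalization (uppercase,
dot-insensitive for ICD) unless a wildcard is explicit. The shipped
lists are the package's own reconstruction of the appendix lists, which
are not public — another reason the engine is parameterized by the
list file.

Algorithm 1 fires on any claim from the broad 13-concept symptom list.
Algorithms 2–5 require ≥ 1 hyperthyroidism claim and ≥ 1 symptom claim
within 12 months, varying the symptom list; algorithm 6 is algorithm 2
without the window. "Within 12 months" is |Δ| ≤ 365 days, inclusive,
either temporal order, same-day counts — the source states no
direction. Rules are applied over each patient's entire claims history
(the unwindowed algorithm requires unbounded lookback; the source does
not state a bound), with an index-anchored mode available through the
feature-matrix path. These choices make the positive sets provably
nested — Alg2 ⊆ Alg3 ⊆ Alg4 ⊆ Alg1 and Alg2 ⊆ Alg6 — mirroring the
printed sensitivity ordering, and the property is tested on every
synthetic cohort. The window test itself is a sorted sweep verified
against an all-pairs brute-force oracle on 10,000 random instances.

# Diagnostic metrics

`metrics_from_counts()` computes sensitivity, specificity, PPV, NPV,
PLR = s/(1−c), NLR = (1−s)/c and F1 = 2·PPV·sens/(PPV+sens) with
explicit NA markers (never silent zeros) for empty denominators and an
`Inf` sentinel for a zero false-positive rate. The source does not
state CI methods, so the package uses Wilson score intervals for
proportions, the log method for likelihood ratios
($\exp(\ln LR \pm z\,SE)$ with the standard cell-count SEs), and a
normal approximation for AUC-free reporting — standard, closed-form,
testable choices declared in the output; printed CIs are deliberately
not reproduction targets. AUC is the tie-adjusted Mann–Whitney rank
statistic, checked against exhaustive pair counting and an external
implementation. Threshold classification uses ≥ (ties positive), fixed
for determinism since the source does not specify it.

Predictive values transport across prevalence by Bayes' rule. At the
source cohort's prevalence (66,396/92,150 ≈ 72.05%) the transported
PPV/NPV coincide with the raw 2×2 values — which is also the
acceptance backbone: every printed row of the two performance tables is
internally consistent (PLR, NLR, PPV, NPV, F1 recomputable from printed
sensitivity/specificity and that prevalence to within one unit in the
last printed digit), and the suite verifies all 90 derived cells.

# The ML feature pipeline

Features are binary indicators of ≥ 1 occurrence of each diagnosis or
procedure code (NDC pharmacy codes excluded) in the 2-year baseline
window [index − 730, index] — the index day is observable and
included, consistent with the coding-pattern convention. The screen
keeps codes with ≥ 0.1% prevalence *in both classes*, computed on
training rows only; the expert-list merge is a set union with
data-driven/expert/overlap counts reported; ICD-10 X/Y/Z chapters
(external causes, health-status factors) are excluded for
interpretability.

RFE evaluates each candidate subset by 5-fold stratified
cross-validated AUC, recomputes fold-averaged feature importance each
iteration, and drops the bottom 20% (≥ 1) of features. Unstated details
are fixed as configurable defaults: stopping is two consecutive
iterations without AUC gain > 1e-4; the 201-feature cap is a hard
maximum on the selected subset (argmax-AUC iterate among those within
the cap, ties to the smaller subset); the default grid is 3 values on
each of learning rate, depth, boosting rounds and L2 strength (3⁴ = 81
configurations, preserving the published model count) with each
configuration's seed derived deterministically from the base seed.
Consensus ranks codes by selection frequency across traces, then mean
importance, then code string — a stated tiebreak where the source says
only "consistently retained". The simplified model restricts to the
consensus codes with 10 boosting rounds.

The learner is a pluggable contract (fit / predict-probability /
feature-importance, deterministic under a fixed seed), implemented with
xgboost gradient-boosted trees (single-threaded, no subsampling, hence
bit-reproducible). Train/test leakage is guarded structurally:
screening and selection see training rows only, and `evaluate_model()`
refuses overlapping id sets.

# Problem sizes and numerical choices

The test and acceptance runs use scaled-down problem sizes chosen to
exercise every code path with sharp statistical checks: generator
recovery at n = 50,000 patients (3-standard-error bands on prevalence,
reference precision/recall, and every printed-profile code frequency,
measured on the included cohort where the ±365-day window is fully
observable); rule-engine and enrollment oracles at 10,000 and 1,000
random instances; planted-signal recovery (2 informative features at
class-conditional rates 0.6 vs 0.1 among 48 noise features, n = 2,000)
over 20 seeded consensus runs of a 4-configuration grid, with an
all-noise run required to stay within AUC 0.5 ± 0.05 on held-out data.
The analysis scripts use n = 20,000 and a 4-configuration grid for the
same reason: the synthetic cohort carries ~60 candidate codes, so the
full 81-model grid only replicates identical selections.

# Known limitations

* Code lists are reconstructions; real-data use requires reviewing them
  against a curated appendix or local coding practice.
* The generator's independence assumptions (codes conditionally
  independent given class; bands independent) understate the
  correlation structure of real claims; consensus selection is
  correspondingly easier here than in practice.
* Reference-standard misclassification is simulated but not corrected
  for; the package reports accuracy against the reference label, as the
  source design does.
* Printed confidence intervals are not reproduction targets because the
  source's CI methods are unstated.
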