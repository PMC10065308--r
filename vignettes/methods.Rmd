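---
title: "Outlier screening of clinical cohorts: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Outlier screening of clinical cohorts: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(outlierscreen)
```

## The screening problem

Clinical discoveries often begin with a single unusual case that a busy
clinician happens to notice. `outlierscreen` mechanizes the noticing step for
tabular cohort data (one row per participant, mixed continuous and
categorical variables, a binary outcome such as preeclampsia): it flags
candidate cases with two complementary detectors and assembles the material a
human expert needs to judge each one. The adjudication itself — whether a
flagged case is a potential novelty or a natural deviation — is deliberately
left to the reviewer; the package only ever sets `assessment: unreviewed`.

The two detectors formalize two different ideas of "unusual":

* **Point outliers** are unusual in their marginal values. They are scored
  with an isolation forest: an ensemble of random binary partition trees,
  each grown on a subsample of size $\psi$, in which easily isolated
  observations have short average path lengths. The anomaly score of
  observation $x$ is
  $s(x) = 2^{-\mathbb{E}[h(x)]/c(\psi)}$,
  where $h(x)$ is the path length and $c(\psi)$ the expected path length of
  an unsuccessful binary-search-tree lookup; larger scores are more
  anomalous. Scores are standardized against their own sample mean and SD,
  and an observation is flagged iff its z-score satisfies $|z| \ge 3$
  (two-sided, inclusive). The contamination parameter (0.05, the assumption
  that at most 5% of a sample could be outliers) is recorded in the model
  configuration but plays no role in flagging — the z-rule alone produces
  flags.

* **Contextual outliers** are individually typical but contradict the
  pattern linking features to the outcome. A random-forest classifier is
  trained on the outcome, and an observation is flagged iff it is
  *misclassified with extreme confidence*: predicted class ≠ recorded class
  and the vote fraction of the predicted class strictly exceeds 0.90.
  Confidence is the fraction of base trees whose individual hard prediction
  is that class — never an average of leaf probabilities, which would be a
  different (smoother) statistic. A tie at 0.5 resolves to the
  lexicographically smaller label; ties cannot exceed the threshold, so
  flagging is unaffected.

## Preprocessing

**Variable filtering.** Five exclusion rules are applied in a fixed order,
first match wins, so the exclusion log is unambiguous: (1) variables declared
as variations or sub-categorizations of the outcome; (2) more than 50%
missing — strictly greater, so a variable at exactly 50% is retained; (3)
re-categorizations of a retained variable; (4) a single unique non-missing
value; (5) one value covering ≥ 99% of all observations, with missing cells
counted in the denominator (the conservative reading of "all observations").
The outcome and identifier are never dropped. Rules are evaluated as ordered
passes; a re-categorization is dropped only when its source survived the
earlier passes. Role-based rules (1 and 3) rely on metadata declarations —
the package does not attempt to detect outcome-derived variables
automatically.

Filtering runs *before* gate fills. A consequence worth knowing: a gated
variable asked of a minority of participants (cigarettes/day in a cohort
with 40% smokers) exceeds the 50% missingness bar and is dropped before its
gate fill could rescue it. This mirrors filtering on raw data; users who
want the other order can call `apply_gate_fills()` first.

**Structured missingness.** Missing cells caused by an upstream exclusionary
question ("not applicable") cannot be treated as missing at random. Each
gated variable carries a rule (gate variable, gate value, fill): a numeric
sentinel for continuous targets (zero cigarettes), a new category token for
categorical ones. Only cells that are missing *and* gated-off are filled;
a smoker with a missing count proceeds to imputation.

**Iterative imputation.** Remaining gaps are imputed round-robin: each
incomplete variable in turn is regressed on all others (linear regression
for continuous targets, multinomial logistic for categorical ones, fitted
with `nnet::multinom`), its missing cells replaced by predictions, for 10
rounds; the tenth round's values are returned. Choices the procedure leaves
open, fixed here: missing cells are pre-filled with the column mean/mode so
round 1 has complete predictors; variables are visited in order of
increasing missingness; categorical predictors enter the regressions as
factors over their observed level sets. Observed cells are never altered,
and imputation is deterministic given the data (the config seed is threaded
through for manifests). Imputation is fit on the full dataset before
splitting — simple and consistent with a single-dataset screening workflow,
but it does leak distributional information across splits; since the forest
here is a screening device rather than a validated clinical predictor, we
accept this and note it.

## Isolation-forest stage

Features are encoded as a numeric matrix: categorical levels integer-coded
in lexicographic order with a persisted level map (reused across stages),
outcome and identifier excluded. Excluding the outcome keeps the
unsupervised stage blind to it, so the two detectors answer genuinely
different questions; `encode_features()` is shared machinery, so a user who
wants the outcome among the isolation-forest features can append it.

Hyperparameters are tuned by a stabilization heuristic: scan an increasing
grid (trees: 100–1000 by 100, starting at 100; subsample: 256, 512, 700,
1024 capped at *n*, starting at 256), fit `tuning_replicates` forests per
candidate under distinct derived seeds, and choose the first candidate at
which both the mean and the SD of the anomaly scores change by less than
`tuning_tolerance` (default 0.01, relative) versus the next candidate. "Least
variation beyond this value" needs a numeric criterion to be computable;
successive relative change below a tolerance is the simplest monotone one.
If nothing stabilizes, the largest candidate is returned with a warning. The
per-candidate statistics are returned as a ledger so the decision can be
re-derived by scanning it.

Internally the feature columns are sorted by name before any random feature
draws, making flags invariant to the column order of the input — otherwise
the RNG stream would couple to an arbitrary property of the file. Scores are
oriented so larger = more anomalous; the z-rule is applied two-sidedly, so
both easily isolated observations and unusually *hard to isolate* ones
(deep in the densest region) can be flagged. With a degenerate table
(score SD = 0) no outliers are flagged, with a warning.

## Random-forest stage

The cohort is split into train/test/validation sets of exact requested
sizes (e.g. 1200/800/301 at *n* = 2301), disjoint, exhaustive, and
seed-reproducible. Hyperparameters can be searched in two phases — a random
phase sampling configurations over ensemble size, depth, features per
split, node-size minima and bootstrap, scored on the test set; then a small
exhaustive grid bracketing the random winner in the key dimensions
(ensemble size, depth, features per split), other dimensions held at the
winner. The scoring metric defaults to F1 on the positive class: with a
7–14% outcome, accuracy would reward the degenerate always-negative
classifier. Both phases' scores are returned as a ledger; the winner is the
ledger argmax. No class rebalancing is applied by default — the imbalance
and its consequence (depressed recall on the rare class) are reported
rather than corrected, since flagging confident *mistakes* does not require
a calibrated classifier.

Flagging is applied over the entire dataset (train + test + validation) by
default, matching a screening workflow in which every participant deserves
a look. In-sample votes are optimistic — a tree that memorized a case will
not confidently mislabel it — so full-dataset flagging is conservative for
training rows; restricting to held-out rows is a one-line subset of the
per-row output for users who prefer it.

## Synthetic cohorts and what the benchmarks show

The generator emulates a high-risk obstetric cohort: six continuous
measurements (age, weight, BMI, blood pressures, gestational age at
delivery) drawn jointly normal with exchangeable correlation 0.3; four
obstetric-history counts (Poisson); ten binary risk factors and supplement
indicators at the prevalences of the emulated trial population; a binary
outcome from a logistic mechanism over declared coefficients, with the
intercept calibrated by bisection so the expected prevalence hits the
target (14.1% trial-like by default, 7.4% for the cohort-study variant);
gated variables (cigarettes/day behind smoking, frequency behind alcohol
use); and missing-at-random gaps whose probability is a logistic function
of two fully observed covariates (age, weight) — keeping the MAR assumption
literally true inside the generator. Everything is reproducible from
(spec, seed), and planted ground truth is recorded separately from the
table.

Two kinds of outliers can be planted, always disjoint:

* **Point outliers**: rows shifted by a set number of SDs (default 8) on a
  set number of continuous features (default 3), direction away from the
  mean.
* **Contextual outliers** (`label_flip_extreme`): rows drawn from the top
  decile of |linear predictor| (intercept included, i.e. distance from the
  decision boundary — rows whose outcome is near-deterministic), filtered
  to marginally typical rows (≥ 90% of continuous features within 2 SD),
  with their recorded outcome flipped. A `hidden_modifier` variant instead
  draws an unrecorded binary modifier that reverses the odds for carriers
  and resamples their outcomes; the modifier never enters the table.

The recovery benchmarks fix the conditions under which the detectors are
validated, and those conditions are part of the claim:

* The **point benchmark** uses a continuous-only cohort (the six
  measurements; 5 rows shifted at 8 SD on 3 of 6 features, *n* = 1000).
  On the full mixed roster the same shift is diluted across ~20 dimensions
  of which 10 are integer-coded binaries, and isolation-forest geometry
  rewards rare binary combinations over a 3-dimensional continuous shift —
  we verified the identical behaviour with an independent isolation-forest
  implementation on the same matrix. The benchmark therefore demonstrates
  the scoring and z-rule machinery on a recoverable signal; it does not
  claim the detector finds any planted anomaly in any feature mixture.
* The **contextual benchmark** (*n* = 3000, 30 flips, 1%) uses
  `strong_outcome_coefficients()` — the default coefficient vector scaled
  3× — so the outcome mechanism is strongly separable. The flagging rule
  demands that >90% of trees confidently contradict the recorded label;
  that is only possible when the mechanism itself is near-deterministic for
  the selected rows. With realistic (weaker) effect sizes, label noise
  produces natural contradictions that swamp any planted signal — a real
  limitation of extreme-misclassification screening on noisy outcomes, not
  an artifact of this implementation. Both benchmark cohorts are generated
  complete-case (no gates, no MAR) so the detectors are measured in
  isolation; imputation has its own oracle tests.

On these conditions (10 seeds each): all planted point outliers rank in the
top 1% by |z|; the contextual flag recovers the planted flips with median
recall ≈ 0.7–0.8 and precision ≈ 0.6–0.7; and the two detectors' flag sets
are disjoint or nearly so, reproducing the near-zero overlap expected from
their different definitions of "unusual". Run
`benchmark_point_recovery()` / `benchmark_contextual_recovery()` to
recompute all of these; the package states no benchmark number the code
does not itself produce.

What passing these tests does **not** show about real data: real cohorts
have measurement error, informative missingness beyond MAR, longitudinal
structure this generator omits, and outcome mechanisms far noisier than the
strong-coefficient benchmark; the lost-to-follow-up phenomenon (isolation
forests latching onto administratively truncated records) is visible in
real screening and not simulated here.

## Reporting and privacy

Characterization tables compare the flagged subset against the full cohort
(mean (SD) for continuous variables, median (IQR) for count-like ones —
integer-valued with at most 12 unique values, or by metadata override —
and n (%) for categorical levels). Any rendered count cell covering one to
six participants is replaced by `Suppressed`, together with its percentage
(from which the count would be recoverable); zero and ≥ 7 are rendered.
Suppression is applied to *every* count cell, subset or cohort — a
full-cohort cell of 3 participants is just as identifying.
`audit_suppression()` re-scans rendered output for leaks and is run in the
test suite.

Case narratives assemble, per flagged participant: detector provenance
(score/z or predicted-vs-recorded with confidence), the values of all
declared risk-factor variables, and the k (default 5) most deviant
variables by robust z (cohort median / MAD). The "interesting variables"
list is auto-seeded from the deviation ranking but is a reviewer-editable
field: judgments like "SSRIs in concomitant medication" are human calls the
package does not attempt.

## Numerical and degenerate-input choices

* Missing cells on disk: empty fields; `"NA"` and `""` both parse to
  missing. Numerics are serialized at up to 17 significant digits so
  read∘write is the identity, bit for bit.
* All randomized stages derive their seeds from one master seed and a stage
  key (`derive_seed`), so a single integer reproduces a whole run while
  stages remain decoupled; derived seeds stay within 32-bit range.
* Bisection for the outcome intercept runs on [−30, 30] with tolerance
  1e−8 and errors if the target prevalence is unattainable there.
* Degenerate cases: anomaly-score SD of 0 flags nothing (warning); a
  single-class training outcome is a hard error; a tuning grid of size 1 is
  returned as-is (warning); an empty post-filter feature set is legal and
  logged.

## Problem sizes

The shipped tests and the acceptance script use: filter/imputation fixtures
of 20–200 rows; vote-oracle and threshold checks at 250–300 rows with 10–50
trees; point recovery at *n* = 1000 × 10 seeds; contextual recovery at
*n* = 3000 × 10 seeds; and two full pipeline runs at the trial-sized
*n* = 2301 with 1200/800/301 splits. These sizes were chosen to exercise
every stage at realistic scale while keeping a complete run in the order of
a few minutes on one CPU.
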