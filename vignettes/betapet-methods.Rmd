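---
title: "Quantifying task-associated brain metabolism with paired PET scans: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying task-associated brain metabolism with paired PET scans: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`betapet` implements a differential analysis of paired small-animal FDG-PET
scans taken around a behavioral task. A first scan follows familiarization
with a conditioning chamber (baseline, "F1"); associative threat
conditioning happens in between; a second scan follows the contextual-recall
session ("F3"). Because FDG uptake integrates metabolic activity during the
behavioral session preceding the scan, the difference between the two scans
isolates the task-associated component of regional glucose metabolism. This
vignette describes the model behind each stage, the parameters that matter,
the design decisions that were genuinely open, and what the synthetic-data
tests do and do not establish.

## The differential uptake model (delta-SUV)

Each registered, skull-stripped volume is first normalized to its
whole-brain mean, the standard per-animal normalization for this design:
after `normalize_scan()` the mean over brain-mask voxels is exactly 1, so
all downstream quantities are dimensionless and invariant to the arbitrary
global scale of a reconstruction (injected dose, body weight, scanner
gain). `region_suv_table()` then averages normalized uptake over each
region's mask separately per coronal slice and per hemisphere — prefrontal
regions (PLC, ILC) sit on the midline and are measured as one object per
slice — and `delta_suv()` subtracts baseline from recall record-wise:

$$\Delta \mathrm{SUV}_{s,r,z,h} \;=\; \mathrm{SUV}^{F3}_{s,r,z,h} - \mathrm{SUV}^{F1}_{s,r,z,h}$$

for subject $s$, region $r$, slice $z$, hemisphere $h$. Eight regions are
analyzed: the threat-memory core (basolateral amygdala BA, prelimbic PLC,
infralimbic ILC) and the contextual/spatial system (dorsal and ventral
hippocampus DH/VH, subiculum SB, lateral and medial entorhinal cortex
LEC/MEC).

Conventions that the data formats do not pin down and that we therefore fix
and document: voxel and slice indices are 1-based (R's native convention); a
coronal slice is a fixed third-axis index; the hemisphere split is a
configurable `midline_x` with $x < $ midline assigned left and voxels
exactly on the midline assigned right; slices whose mask intersection is
empty are dropped with a warning rather than zero-filled, because
zero-filling would bias region means. The per-mouse summary used for
correlations and classification (`subject_region_mean()`) is the unweighted
mean over a region's slice/hemisphere records; a voxel-weighted mean is a
defensible alternative, but with roughly equal mask footprints per slice the
two differ negligibly, and the unweighted mean matches the record-level
nesting the group model uses.

## Group inference

Each subject contributes many slice/hemisphere records per region, so
per-region group tests use a nested linear mixed model
(`lmm_group_test()`):

$$\Delta \mathrm{SUV}_{ij} = \beta_0 + \beta_1\,\mathrm{group}_i + b_i + \varepsilon_{ij},
\qquad b_i \sim \mathcal N(0, \sigma_s^2),\ \varepsilon_{ij} \sim \mathcal N(0, \sigma_e^2),$$

fit by REML (`lme4`). The group effect is tested as $F = (\hat\beta_1 /
\mathrm{se})^2$ with 1 numerator and $n_\mathrm{subjects} - 2$ denominator
degrees of freedom — the conservative between-subject choice, appropriate
when the effect of interest is a between-animal contrast. Random effects are
a subject intercept only: slices and hemispheres of one mouse share the
subject deviation but are otherwise exchangeable; richer structures
(hemisphere within subject) are possible but not identified at these sample
sizes. When every subject has exactly one record, the mixed model is
unidentifiable and collapses exactly to ordinary least squares; the function
takes that path, which reproduces the pooled two-sample t test ($F = t^2$) —
a property the tests verify to $10^{-8}$. No multiple-testing correction is
applied across the eight regions (per-region values are reported raw); a
Holm adjustment is a one-liner on the output table if wanted.

Behavioral comparisons use the pooled-variance Student t
(`t_test_groups()`; degenerate zero-variance inputs return the documented
limits $T = 0, p = 1$ for equal means and $T = \pm\infty, p = 0$ otherwise),
and delta-SUV/freezing relationships use least squares plus the Pearson
product-moment coefficient (`region_behavior_correlation()`), with a
constant input explicitly reported as undefined rather than silently zero.

## Freezing from activity traces

Video tracking reduces each session to a frame-wise activity score (pixel
change counts). `binarize_activity()` marks a frame inactive iff its score
is *strictly* below a threshold — the strict inequality makes a zero
threshold yield zero freezing, the safer degenerate case. The threshold is
inherently experiment-specific (it depends on camera, lighting, and
tracking settings); the package default of 20 is arbitrary and every entry
point takes it as a parameter. Percent freezing is computed on 10-s bins
(fraction of inactive frames × 100); the session summary is the unweighted
mean of complete bins inside the analysis window — the conditioning session
uses only the tone + trace intervals, the recall session the last 4
minutes, both configurable. A trailing partial bin is reported but excluded
from the session mean. Bouts are maximal runs of consecutive inactive
frames lasting at least 2 s (a run of exactly 2 s counts); no smoothing or
blip-merging is applied. Bout-duration distributions are compared with the
two-sample Kolmogorov–Smirnov statistic computed exactly as the sup-gap of
the two ECDFs at the pooled sample points, with the asymptotic Smirnov
p-value — appropriate for the hundreds of bouts a cohort produces, not for
tiny samples.

## Leave-one-out classification

`loocv()` predicts each subject's group (CON negative, LS positive) from
the eight regional mean delta-SUVs, training on the other subjects only.
Inside each iteration, features are standardized with the training fold's
mean and SD, and hyperparameters are tuned by stratified inner
cross-validation on the training fold alone — the held-out subject can
never influence its own model, which the tests assert directly by
perturbing the held-out row and checking the fold model is unchanged.
Model kinds: ridge-penalized logistic regression (`glmnet`, $\lambda$ over
a log grid), linear SVM (`e1071`, cost over a log grid), and GentleBoost —
implemented in-package as weighted-least-squares regression stumps with the
multiplicative weight update $w_i \leftarrow w_i e^{-y_i f_t(x_i)}$; since
stump outputs are weighted class means they stay in $[-1, 1]$ and the
training exponential loss is nonincreasing, a property the tests re-verify
numerically every round. A decision score of exactly zero predicts the
positive class. With fewer than four training subjects in a class the inner
CV cannot keep both classes in every split and tuning falls back to
mid-grid defaults.

One subtlety matters for the ROC. Only one held-out score exists per
subject, so the ROC must pool scores across folds — but raw scores from
different folds are not on a common scale: each fold's score offset tracks
its training class mix, which differs systematically by the held-out
subject's own class. For an uninformative model this offset *alone*
deterministically ranks every true negative above every true positive
(AUC 0 rather than 0.5) — a known pathology of pooled leave-one-out
scores. `loocv()` therefore calibrates each held-out score by subtracting
the mean decision score of its own training fold before pooling: an
uninformative model then scores everyone 0 (AUC exactly 0.5), scrambled
controls hover around chance, and informative classifiers are unchanged
(within-fold orderings are preserved). Raw scores are returned alongside.
Hard predictions and confusion rates always use the raw score against the
model's own threshold. `scrambled_control()` permutes the labels (seeded,
count-preserving) and reruns the identical pipeline.

## Ordinal-trends analysis

The regional pipeline presupposes its regions. As a complementary,
mask-free validation, `ort_analysis()` looks for a whole-brain voxel-weight
pattern whose per-subject expression moves consistently from baseline to
recall. The package fixes a concrete, testable variant and records every
choice in the result metadata:

- **Decomposition.** The scan matrix (rows = scans, subject-major;
  columns = brain-mask voxels) is grand-mean centered column-wise and
  decomposed by SVD; components are unit-norm voxel patterns, expressions
  their per-scan projections.
- **Pattern selection.** Candidate component sets are every singleton
  $\{PC_k\}$ and every prefix $\{PC_1..PC_k\}$, $k \le K_{max}$. For each,
  the condition design ($-1$ baseline, $+1$ recall) is regressed on the
  candidate expressions by OLS and scored with
  $AIC = n\ln(RSS/n) + 2(k+1)$; the lowest AIC wins, ties going to the
  smaller set. The combined pattern is the coefficient-weighted component
  sum, renormalized, with its sign fixed so the majority of subjects
  increase from baseline to recall. A zero RSS is floored at machine
  epsilon with a warning.
- **Why $K_{max} = 3$ by default.** The permutation test below reruns this
  selection on every permuted dataset, so the null distribution inherits
  the selection's flexibility. The trend statistic is bounded by the number
  of subjects, and with $n = 9$ subjects (18 scans) a pool of 8 components
  plus prefixes lets the AIC fit saturate the bound on a large share of
  *null* permutations — measured mass at the ceiling of roughly 0.16 at
  $K_{max} = 8$, 0.03 at 3, 0.007 at 1. Once the null puts more than
  $\alpha$ at the ceiling, no dataset can ever reach significance: the pool
  size must stay small relative to the number of subjects. Three components
  keep that mass near 0.03 at this design size while still reaching
  third-ranked components, and $K_{max}$ scales as a config parameter for
  larger cohorts.
- **Permutation test.** Each of `n_perm` permutations independently swaps
  each subject's scan pair with probability 1/2 and reruns the *full*
  pipeline (decomposition, selection, sign fix), so selection bias is
  present in the null; $p = (1 + \#\{\mathrm{perm} \ge \mathrm{obs}\}) /
  (1 + n_\mathrm{perm})$. The statistic is the count of subjects whose
  expression increases, plus a continuous tie-break in $(0,1)$ — the
  logistic of the standardized mean expression change. The count alone
  takes at most $\lceil n/2 \rceil + 1$ values after the sign convention,
  and that discreteness parks the test far below its nominal level at
  small $n$; the tie-break orders equal counts by trend strength and makes
  the attained level track $\alpha$ (measured rejection ≈ 0.06 at nominal
  0.05 under the null) without affecting validity, since permutation tests
  are exact for any statistic. A fixed-pattern mode (`refit = FALSE`) that
  only re-scores the observed pattern is provided for comparison; it is
  anti-conservative precisely because the observed pattern was selected on
  the unpermuted data, and the refit mode is the default for that reason.
- **Bootstrap reliability.** Subjects are resampled with replacement
  (keeping scan pairs intact), the pipeline is rerun, each resampled
  pattern is sign-aligned to the original, and $z_v = w_v /
  \mathrm{SD}_\mathrm{boot}(w_v)$ flags voxels whose weights are stable
  (one-tailed normal quantile, $|z| > 1.645$ at $\alpha = 0.05$; a
  percentile variant would need far more than 500 replicates to resolve a
  5% tail, which is why the normal approximation is the default). Zero
  bootstrap SDs are floored at $10^{-12}$ with a warning.
- **Direction matters.** Under whole-brain-mean normalization the brain
  mean is 1 by construction, so a focal increase occupying fraction $f$ of
  the mask at size $p$ forces a genuine distributed decrease of
  $pf/(1-f)$ everywhere else. Reliable negative weights outside an
  activated region are therefore expected, not artifacts; the result
  separates `sig_pos` (increase-direction) from `sig_neg`
  (decrease-direction) voxels, and spatial-specificity claims about an
  activation should be made on `sig_pos`.
- **Expression change.** A scan's "nodal expression" is its projection on
  the pattern, z-scored across all scans in the evaluation set (the
  reference-set choice is recorded in the output; a control-only reference
  is the obvious alternative and changes only the affine scale). The
  per-subject change $\Delta E = E(F3) - E(F1)$, the fraction of subjects
  increasing per group, and a pooled t test between groups summarize how
  strongly each group expresses the control-derived pattern.

## The synthetic cohort: what it emulates and what it does not

All tests run against `generate_cohort()`, which emulates the two-scan
design with known ground truth:

- **Planted effects.** Group-mean regional increments applied to the recall
  scan only; the defaults are the real study's printed group means (e.g.
  BA 0.15 control vs 0.049 long-sepsis, in normalized units). Increments
  are written on the normalized scale with the background compensated so
  the brain mean is exactly 1 before an arbitrary global scale factor —
  this makes zero-noise planted effects survive normalization *exactly*
  (the pipeline's exact-recovery invariant) and mirrors the physical fact,
  noted above, that globally normalized uptake redistributes rather than
  adds.
- **Nested noise.** Additive Gaussian terms per (subject, scan) shared
  across regions, per hemisphere, per slice, and per voxel. The
  subject-scan term is applied to regional uptake relative to the brain
  mean, not as a global offset — a global additive offset would be removed
  by normalization and could not generate the between-subject variance the
  mixed model exists to absorb. Defaults (0.03 / 0.015 / 0.04 / 0.10) were
  calibrated once so the record-level delta-SUV SD is ≈ 0.09, consistent
  with record-level standard errors of a few parts per thousand at the
  study's record counts, and so effects of the printed size are
  recoverable at n = 9 vs 15.
- **Behavior.** Activity traces are alternating renewal processes:
  gamma-distributed immobility runs (mean and CV per group and session,
  recall bouts longer in controls) and exponential mobility runs whose mean
  sets the target freezing fraction; the initial state and residual run are
  drawn from the equilibrium distribution, so the expected freezing
  fraction over any window equals the target without edge bias (verified
  by Monte Carlo against the analytic SE). Session freezing targets are the
  printed group means. Scores for immobile frames fall strictly below the
  default threshold, mobile frames strictly above.
- **Reproducibility.** One master seed; every per-subject, per-session
  stream is derived by a stable string hash, so outputs are bit-identical
  across runs and independent of generation order.

Not emulated: scanner physics, attenuation, reconstruction, motion,
partial-volume effects, registration error, anatomical region shapes
(footprints are boxes), spatial noise correlation, or any tone/shock
dynamics within sessions. Passing tests therefore establish that the
*statistics* behave as claimed under the declared noise model — exact
recovery, calibration, power, spatial specificity — not that the pipeline
is robust to preprocessing failures upstream of registered volumes, which
are out of scope by design.

## Problem sizes and tolerances used by the test suite

Deterministic identities are asserted at 1e-10 to 1e-12; the F = t²
equivalence at 1e-8 (REML vs OLS round-off). Monte-Carlo checks use 3-SE
bands around analytic targets. Calibration and power studies run 200
simulated cohorts at the study's group sizes (9 vs 15) with the BA record
structure (12 slices × 2 hemispheres) on a reduced grid — record-level
variance structure, not voxel count, is what drives these statistics — and
the ORT null calibration runs 200 cohorts at 200 permutations on the
detection scenario's geometry. The end-to-end directional check and the
acceptance script use the full default 32 × 48 × 32 grid with 500
permutations and 500 bootstrap replicates.

## Known limitations

- The mixed model's between-subject denominator df is conservative;
  Satterthwaite-style approximations would be less so but are not needed at
  these effect sizes.
- The AIC pattern-selection pool must be chosen relative to the number of
  subjects (see above); the default suits 9-24 subjects, and users with
  much larger cohorts should raise `Kmax` deliberately.
- Pooled LOOCV ROC curves, even calibrated, rest on n points (one per
  subject) and are correspondingly coarse.
- The KS p-value is asymptotic; with fewer than ~20 bouts per group use a
  permutation version instead.
- Printed confusion matrices and p-values from the real study depend on its
  actual scans and videos; the synthetic cohort reproduces the *direction
  and detectability* of those contrasts, not their exact values.
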