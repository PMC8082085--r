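---
title: "Spike-train analysis of odor-guided go/no-go behavior: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike-train analysis of odor-guided go/no-go behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gonogo)
```

This vignette is the package's own account of its methods: the task and
data model, the statistics, the tunable parameters and why their defaults
are what they are, what the synthetic-session generator does and does not
emulate, and the numerical choices made where the design was genuinely
open.

## Task and data model

A session couples per-unit spike timestamps (seconds, session clock) with
a per-trial event table. Each trial carries the end of the inter-trial
interval (`iti_end`), odor valve opening (`odor_on`, which coincides with
odor-port entry), valve closing (`odor_off`, 0.5 s presentation by
default), odor-port exit (`port_exit`), and — when go behavior is
executed — water-port entry and water onset. Events are instants; all
analysis epochs are half-open intervals `[start, end)`:

* `baseline_long`, 1000–0 ms before ITI end — the classification
  baseline;
* `baseline_short`, 200–0 ms before ITI end — the sliding-trace
  baseline;
* `odor_sampling`, odor valve opening to port exit;
* `drinking` and `no_go_waiting`, 1 s epochs anchored at water onset and
  at port exit on correct no-go trials.

Both baselines are kept deliberately: the epoch-level classification uses
the longer, lower-variance window, while the sliding traces use the short
window so the per-trial baseline estimate is local to each trial.

## auROC and its permutation test

Discriminability between two sets of per-trial rates is the area under
the ROC curve, computed from mid-ranks so ties count one half. It equals
the Mann–Whitney U statistic divided by `n_a * n_b` and satisfies
`auroc(a, b) + auroc(b, a) = 1` exactly. Significance is a two-sided
permutation test on `|auROC - 0.5|`. The Monte-Carlo p value uses
add-one smoothing, `(1 + k) / (1 + n_perm)`, so it is never zero; an
exact enumeration over all label assignments is available for small
samples and is used as the oracle in the test suite. The default
`n_perm = 1000` resolves the working threshold p < 0.01 comfortably; the
permutation count is not stated by convention in this literature, so it
is exposed as a parameter. Per-bin tests are deliberately uncorrected
for multiple comparisons — the sliding traces are descriptive, and the
onset rule below handles isolated false positives.

A caveat worth recording: the test assumes exchangeability of the two
samples. Epoch rates are computed over windows of different lengths
(variable sampling epochs versus a fixed 1 s baseline), so under the
no-modulation null the two rate distributions have equal means but
slightly different shapes. Empirically this inflates the false-responsive
rate of truly constant units from the nominal ~2% to ~3% at p < 0.01;
this is inherent to comparing rates across unequal windows and is shared
by the classification procedure this package implements.

## Five-type classification

Applied to correct trials, odor-sampling epoch versus `baseline_long`,
with three permutation tests per unit (go response, no-go response,
go-versus-no-go preference), all at p < 0.01:

1. no significant response to either cue → type V;
2. significant preference → type I (go) or II (no-go);
3. responsive without preference, all significant responses excitatory →
   III; all suppressed → IV;
4. mixed directions without preference (a case the rules above do not
   cover): the direction of the larger `|auROC - 0.5|` across the two
   cues decides III versus IV, an exact tie falling back to V. This rule
   is deterministic and documented here because the case is genuinely
   ambiguous; it occurs rarely (<1% of units in default simulations).

Units with fewer than 10 correct trials per condition are flagged
unclassifiable and excluded from proportions.

## Sliding-window traces and temporal measures

Traces use 100 ms bins stepped by 20 ms, aligned to odor onset by
default. A trial contributes to a bin only when the whole bin lies
before that trial's port exit, so bins never mix odor-sampling with
post-exit activity; bins with fewer than 5 trials on either side are
left undefined. Onset time is the left edge of the first run of at least
3 consecutive significant bins — a run criterion that suppresses
isolated false positives at the cost of ~40 ms onset resolution. The
same run-of-3 convention defines the divergence onset of population
geometry traces. Duration is the length of the union of significant bin
spans (overlapping 100 ms bins are not double-counted). The center of
mass weights bin centers by `|auROC - 0.5|` over significant bins.

"60 ms Gaussian smoothing" of PSTHs is interpreted as a kernel standard
deviation of 60 ms (width conventions differ between labs; SD is the
most common reading and is exposed as `kernel_sd`). At window edges the
truncated kernel is renormalized, which preserves constant rates exactly
and conserves spike mass to within 1% for windows wider than six kernel
SDs.

## Encoding model

Per-bin (20 ms) spike counts of correct go trials, restricted to the
analysis span from 370 ms after odor onset (the median go-cue excitation
onset measured by the auROC traces) to port exit, are regressed on two
kernel groups: one anchored at odor onset (window 0.37–1.3 s) and one
anchored at port exit (window −0.8–0 s). Each group is spanned by 8
raised-cosine bumps (boxcar bases are available and used in tests, where
their exact partition-of-unity makes oracles sharp). The family is
Poisson with log link — the natural choice for counts; a mild ridge
penalty (chosen per outer fold on inner folds from the fixed grid
10^-4…10^0) handles the near-collinearity of the two groups, which
jointly tile the analysis span.

"Explained variance" is implemented as cross-validated fraction of
Poisson deviance explained relative to an intercept-only model, with
folds cut by whole trials. The relative contribution of a variable is
`max(0, R²_full − R²_without_it)`, normalized across variables; when no
variable contributes the fractions are uniform with a warning. PSTH
reconstruction quality is the Pearson correlation between held-out
predicted and observed rates averaged on a lag grid relative to either
anchor.

## Population geometry

The population matrix holds trial-averaged, smoothed rates per unit and
condition on a common grid (−0.5 to 1.0 s around odor onset), then
z-scores each unit over its concatenated condition time courses. The
paper-level preprocessing is not stated in this literature consistently;
z-scoring is the default because raw rates would let a handful of
high-rate units dominate the subspace, and the raw option is retained
for sensitivity checks. PCA is fitted jointly on both conditions — a
shared subspace is required for condition trajectories to be comparable.
Distance between condition trajectories is computed in the full
normalized space by default (any k-dimensional projection can only
shrink it; the subspace option is provided), velocity as
`||x(t + w) − x(t)|| / w` with `w` = 100 ms. Significance bands are mean
+ 2 SD over baseline bins (−0.45 to −0.05 s pre-onset on the
trial-averaged grid; pre-onset bins are the natural baseline for an
odor-onset-aligned grid). By construction ~2.3% of null bins exceed a
2 SD band, hence the run-of-3 convention for divergence onsets.

## Decoding

Pseudopopulation vectors are built by pooling units across sessions and
resampling each unit's correct trials class-conditionally and
independently — the standard construction when units were not recorded
simultaneously; it balances classes and deliberately destroys
within-session noise correlations. Critically, cross-validation is
separated at the level of *original* trials: each unit's trials are
partitioned into folds first and pseudotrials of a fold are resampled
only from that fold. Resampling before splitting leaks the per-class
empirical distributions into every fold; in our null simulations that
alone inflated "chance" accuracy to ~0.62. With trial-level separation,
non-selective populations decode at 0.49 ± 0.03.

The classifier is a linear-kernel SVM with cost fixed at 1 (not stated
by convention; accuracy is insensitive to it over 0.1–10 on synthetic
data), 5-fold stratified CV, 20 unit-resamples per population size by
default. The behavioral-accuracy reference is computed from the analyzed
sessions' trial outcomes.

## The synthetic-session generator

The generator is a first-class module: it encodes the study conditions
the analyses assume and provides ground truth for recovery testing.

* **Baseline rates** are log-normal with parameters solved from the
  target median 0.90 Hz and IQR 0.23–3.07 Hz
  (`meanlog = ln 0.90`, `sdlog = ln(3.07/0.23) / (2 z_0.75)` ≈ 1.92). A
  two-parameter log-normal cannot match an asymmetric IQR exactly; the
  implied quartiles (0.25, 3.29) are within 8% of the targets.
* **Sampling durations** are log-normal per trial type (medians 788 and
  642 ms, IQRs matched the same way), clipped below at the 0.5 s odor
  presentation the animal must sit through. Clipping — rather than
  truncating-and-renormalizing — leaves the medians and IQRs exactly
  invariant (all target quantiles exceed 0.5 s) and mirrors the actual
  behavioral mechanism: an animal that would have exited early exits at
  valve close.
* **Archetypes.** Types I/II carry a phasic Gaussian cue response
  (peak 500 ms after odor onset, SD 80 ms, trial-to-trial latency jitter
  SD 20 ms — jitter is not reported in this literature, so it is a
  parameter) whose integral over the bump window exceeds the baseline
  integral by `excitation_gain` (default 5), plus a persistent
  suppression (`suppression_gain`, default 0.2) from 300 ms after odor
  onset to 800 ms past port exit on the opposite cue, plus
  drinking/waiting modulation after the behavior. Types III/IV respond
  to *both* cues with a sustained epoch-wide gain: a fixed-shape phasic
  response would produce a spurious rate preference purely because go
  and no-go sampling epochs have different durations, contradicting the
  "no preference" phenotype these types represent.
* **Near-silent units** (baseline below 0.2 Hz, ~14% of the baseline
  distribution) are always assigned the non-responsive archetype. A
  response phenotype is an observable property: a unit contributing a
  handful of spikes per session cannot express a detectable rate
  modulation at any effect size, and in recorded data such units could
  only ever be classified as non-responsive. Without this constraint
  ground-truth recovery is bounded at ~88% by pure information limits;
  with it, recovery reflects the classifier.
* **Error and odorless trials** fire at baseline for every archetype:
  distinct cue responses belong to correctly executed go behavior, and
  this default makes the condition-contrast analysis testable.
* Spikes are drawn by thinning a homogeneous Poisson process at each
  unit's per-trial intensity bound; no refractory period is modeled
  because every analysis operates on rates, not inter-spike intervals.

What passing tests on this generator do **not** show: robustness to
bursting and refractory structure, non-Poisson count dispersion,
correlated noise across simultaneously recorded units (the decoder
explicitly destroys such correlations), respiration-locked dynamics, or
drift. Results on recorded data depend on those properties; the
generator validates the statistical machinery, not the biology.

## Problem sizes and determinism

Default analyses run on one synthetic session of 100 units and 200
trials (~90 correct trials per condition), 1000 permutations per test,
and modest decoding grids — sizes chosen so the full pipeline runs on a
laptop in minutes while keeping every statistic well inside its
asymptotic regime. All randomness flows from explicit integer seeds
through a counter-based fan-out (`child_seed`), so every table the
pipeline writes is byte-reproducible from its configuration.

## Known limitations

* The permutation test's mild anticonservatism for unequal-window rate
  comparisons (above).
* Onset times are quantized by the 20 ms step and biased late by the
  run-of-3 criterion when responses emerge gradually.
* The encoding model names only the two kernel groups; spike-history and
  coupling terms are out of scope.
* The adapter for externally deposited session layouts is limited to the
  documented plain-text format written by `write_session()`.
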