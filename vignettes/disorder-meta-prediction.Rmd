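---
title: "Meta-prediction of protein intrinsic disorder: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-prediction of protein intrinsic disorder: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dismeta)
```

## The problem

Intrinsically disordered regions (IDRs) are protein segments that lack a
stable three-dimensional structure under physiological conditions.  The
operational reference used throughout this package is the crystallographic
one: residues present in a chain's SEQRES record but missing from the model
(listed under REMARK 465) are labelled disordered, everything else ordered,
and residues that cannot be observed at all are carried as an explicit
*unknown* state that every metric skips.

Many primary disorder predictors exist, with complementary strengths.  This
package implements three ways of going beyond any single one of them:

1. **Accuracy-weighted consensus** (`fit_consensus()`): a per-residue
   weighted mean of the score columns of the available primary methods, in a
   binary variant (every method reduced to its two-state call) and a
   continuous variant (continuous scores used as-is).
2. **Template-coverage prediction** (`fit_template3d()`): fold-recognition
   methods align the target to proteins of known structure; residues that no
   alignment covers have no detectable structured counterpart and are
   candidate disorder.  Hits are classed *good/medium/poor* by score cutoffs
   and each (method mode, tier) class carries a trainable weight.
3. **The combined model** (`fit_combined()`): a convex mixture of the two
   channels, trained jointly.

## The weighted score and its relatives

All training criteria build on the class-weighted score
$$
S_w \;=\; \frac{w_{dis}\,TP - w_{ord}\,FP + w_{ord}\,TN - w_{dis}\,FN}
               {w_{dis}\,(TP+FN) + w_{ord}\,(TN+FP)},
$$
where, deliberately cross-assigned, $w_{dis}$ is the fraction of *ordered*
and $w_{ord}$ the fraction of *disordered* residues in the reference.
Because ordered residues dominate known structures, this rewards a correct
disorder call more than a correct order call and removes the incentive to
over-predict order.  The numerator of a perfect prediction equals the
denominator, so $S_w \in [-1, 1]$ with 1 for a perfect predictor, and the
expectation for any label-independent predictor is exactly 0.  A widely
circulated variant of the formula normalises by
$w_{dis}(TN+FN) + w_{ord}(TN+FP)$; that version cannot reach 1 for a
perfect predictor, which contradicts the score's stated range, so this
package uses the $S_{max}$ normaliser above and keeps the other variant
available behind `sw(..., denominator = "printed")` for comparison only.

`sww()` averages $S_w$ over the inclusive threshold grid
$\{0, 0.01, \dots, 1\}$ (101 points), blending ranking quality into the
weighted score; it is the training criterion of the "MD2" combined variant.
`mcc()` and `roc_auc()` are the usual Matthews correlation and trapezoidal
ROC area (tie-aware, equal to pairwise concordance).  Statistical error
bars come from `bootstrap_mae()` — 1000 subsamples of 80% of the targets
drawn *without* replacement, reporting the mean absolute deviation from the
full-data score — and method comparisons from `wilcoxon_paired()`, exact
(by enumeration of the signed-rank null, midranks under ties) up to n = 25
and tie-corrected normal beyond.

A residue is called disordered when its score is `>= threshold`.  The
inclusive convention makes threshold 0 the all-disordered call, anchoring
the degenerate ROC endpoint; a `strict` flag flips to `>` where needed.
Grid threshold selection breaks ties toward the lowest threshold, which
makes `select_threshold()` deterministic.

## The consensus model

Binary calls are encoded as 1 (disorder) and 0.01 (order): a strictly
positive order code keeps every weighted sum positive, so later
normalisations can never divide by zero.  Each method's weight is its own
calibration $S_w$ (computed at that method's best grid threshold); methods
with negative calibration $S_w$ would *invert* a predictor if used with a
negative weight, so they are floored at 0 and thereby excluded.  Missing
method outputs are dropped from numerator and denominator at that residue
(re-normalisation) rather than imputed; a residue with no prediction at all
propagates a missing consensus score that downstream metrics skip.

Chain termini are, on average, considerably more disordered than chain
interiors.  `estimate_terminal_correction()` measures, on the calibration
labels, the ratio of the disorder frequency at each terminal offset
(1–15 from either end) to the interior frequency, and the predictor
multiplies scores by those factors (then clips to [0, 1]).  The exact
functional form of such a correction is an open design point; the frequency
ratio is the most direct estimator of positional enrichment and is what is
implemented.  Factors are *not* floored at 1: nothing forces termini to be
more disordered in a given calibration set, and a ratio below 1 is
legitimate information.  On chains short enough for the two 15-residue
windows to overlap, the nearer terminus wins and ties go to the N-terminus.

Final two-state calls pass through the **repair filter**: every maximal run
of predicted disorder of length ≤ 3 flanked by predicted order on both
sides is deleted; runs touching a terminus survive.  Stated as a 5-residue
window smoother, the rule is implemented run-based because only the
run-based reading reproduces the canonical worked example
`DDD---D--` → `DDD------` (the terminal `DDD` kept, the isolated interior
`D` removed); a sliding-majority variant does not obviously do so.  The
filter is one-sided (never creates disorder) and idempotent.

The decision threshold is chosen by 10-fold residue-level cross-validation:
the $S_w$-optimal grid threshold of each training split is averaged and
snapped back to the grid.  Residue-level binning follows the original
protocol; `kfold_protein_bins()` offers a leakage-safe protein-level
alternative for experiments where within-chain correlation matters.

## The template-coverage model

Each of 8 fold-recognition method modes (six methods, two of which run in
two modes) contributes up to 10 ranked hits.  A hit's raw score classifies
it as good, medium or poor via fixed per-method cutoffs
(`default_tier_thresholds()`); e-value-like scores improve downwards,
score-like upwards, and boundary values fall to the worse tier (strict
comparisons as printed in the reference table).  The per-residue disorder
score is
$$
s(r) = 1 - \frac{\sum_h w_{[mode(h),\,tier(h)]}\; \mathbf 1[r \in h]}
                {\sum_h w_{[mode(h),\,tier(h)]}},
$$
i.e. one minus coverage evidence normalised by the maximum evidence any
residue could accumulate.  This residue-level formula is the package's own
reconstruction — the coverage idea fixes only the numerator's spirit — and
is deliberately isolated in `predict_gs3d()` so alternatives can be
swapped.  It is scale-invariant in the 24 weights and monotone: adding a
covering hit can only lower a residue's disorder score.  Evidence from a
method's multiple alignments is *summed* (max and rank-decay are noted
alternatives; sum preserves monotonicity and needs no extra parameter).
A target with no retained hits scores 1.0 everywhere — no structural
counterpart detected — which is aggressive but consistent with the
coverage premise; `no_hit_score` makes the floor configurable.

The 24 weights (8 modes × 3 tiers, each in [0, 1]) are trained by a real
valued genetic algorithm (`ga_optimize()`): tournament selection (size 2),
uniform crossover (probability 0.9), per-gene Gaussian mutation
(probability 0.02, σ = 0.1), population 80, 100 generations, elitism 1.
These hyperparameters are conventional mid-size GA settings; elitism
guarantees a non-decreasing best-fitness trace, and the whole run is a pure
function of the seed.  Fitness is the pooled $S_w$ at the best grid
threshold (or pooled $S_{ww}$ of the raw scores).

## The combined model

The two channels are fused linearly:
$s(r) = (a\,c(r) + b\,t(r))/(a+b)$ with $a, b \ge 0$.  A linear convex
form is the simplest reading of "optimising the relationship between the
two components"; the channel weights are appended to the tier genome,
giving one 26-gene genome trained jointly (the alternative reading — a
full 24 × 2 interaction matrix — would square the parameter count without
a stated justification).  Thresholding and repair are applied after
combination, reusing the consensus machinery.  Training with the $S_{ww}$
criterion instead of $S_w$ gives the "MD2" variant.

## What the synthetic generators emulate

Because the upstream predictors and fold-recognition services are external
services, all testing runs on synthetic fixtures (`sim_dataset()`):

* **Labels** (`gen_labels()`): alternating geometric runs of order and
  disorder — segmental, not i.i.d., because the repair filter and terminal
  correction are only exercised by runs.  Defaults: 23.45% disordered
  overall (the composition of the combined calibration dataset,
  `calibration_dataset_counts()`), mean disordered run 12 residues, chain
  lengths uniform on 60–300, and a two-fold disorder enrichment in the 15
  terminal residues (flips applied to ordered terminal residues; the
  baseline fraction is solved analytically so the realised overall fraction
  stays on target).
* **Profiles** (`sim_profile()`): disordered residues score
  $\mathrm{Beta}(2+d, 2)$, ordered ones the mirror $\mathrm{Beta}(2, 2+d)$.
  The separation $d$ sets the method's theoretical AUC in closed form
  (`score_model_auc()`); the default 13-method panel spans AUC ≈ 0.63–0.83,
  the range primary disorder predictors realistically occupy, with three
  binary methods thresholding their latent score at 0.5.
* **Hits** (`sim_hits()`): each hit draws a tier, a raw score from a band
  strictly inside that tier's cutoff region (so `classify_tier()` recovers
  the generating tier exactly), covers each ordered segment with
  probability equal to its generative (mode, tier) weight, and each
  disordered segment with a small leak probability (default 0.05).

The fixtures reproduce the *statistical* structure the methods rely on, not
biological realism: no amino-acid composition bias of IDRs, no correlation
between primary methods beyond the shared labels, and a cleaner
order/coverage relationship than real fold-recognition output.  Passing
tests therefore demonstrate the correctness of the machinery and the
qualitative behaviour of the meta-predictors (the consensus beating each
constituent, GA recovery of informative tiers, down-weighting of a noise
channel), not benchmark-grade accuracy on real proteins.

## Numerical choices and degenerate inputs

* Unknown labels (NA) are excluded from every count in every metric.
* `mcc()` returns 0 with a warning when a confusion margin is empty.
* Single-class references are errors wherever class weights are needed.
* Bootstrap subsamples on which the metric fails (single-class draws) are
  redrawn with a capped retry budget.
* Sequences beyond 1000 residues warn but process: the historical limit
  came from upstream tools, not from this package.
* All randomised procedures (generators, GA, cross-validation splits,
  bootstrap) are reproducible given their seed argument.

Test and fixture sizes were chosen to characterise each property at desk
scale: 100,000-residue references for the stochastic endpoint checks
(sampling error well below the 0.02 assertion bands), 200 randomised
instances for oracle equivalence, 50 seeded replicates of 20 targets for
the consensus-improvement property, and 50 targets with the full GA budget
for parameter recovery.

## Known limitations

* The package consumes primary predictor scores and fold-recognition hit
  tables; it does not run those services.
* NMR-ensemble-derived disorder labels are consumed as pre-made two-state
  annotations only; no ensemble variability criterion is implemented.
* REMARK 465 entries are matched to SEQRES positions via an explicit
  `numbering` vector (default: sequential); author numbering schemes must
  be supplied by the caller, since coordinate records are not parsed.
* Bootstrap MAE is the only error estimate provided for ROC statistics; no
  analytic standard error of the AUC is computed.
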