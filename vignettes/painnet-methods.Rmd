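---
title: "Methods: network and multivariate analysis of biopsychosocial pain measures around joint replacement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network and multivariate analysis of biopsychosocial pain measures around joint replacement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A substantial minority of knee (KOA) and hip (HOA) osteoarthritis patients
keep experiencing pain after total joint replacement.  `painnet` implements
a reusable pipeline for studying this: it quantifies how much of a
patient's pre-surgical pain remains after surgery, reduces a battery of
questionnaire subscales and physical-performance scores to a small number
of latent dimensions, asks whether those pre-surgical dimensions predict
post-surgical pain, and — treating the inter-measure correlation matrix as
a network — asks how the whole biopsychosocial profile reorganizes after
surgery.

The measure battery comprises 21 non-outcome measures (HADS anxiety and
depression; the three PCS catastrophizing subscales; MPQ sensory and
affective scores; DN4; four KOOS function subscales; seven SF-36 subscales;
timed-up-and-go; six-minute walk) and four pain intensity outcomes (NRS,
BPI severity, KOOS/HOOS pain, SF-36 bodily pain).  `default_registry()`
records each measure's native range, orientation and community label.

## Residual pain

For each outcome scale, percent residual pain is

\[
\%\text{residual} = 100 \cdot \frac{\text{post}}{\text{pre}},
\]

so 100% means no change, 0% complete relief, and values above 100%
worsening.  The statistic is undefined when baseline pain is zero; such
subject-scale pairs are returned as `NA`, excluded from aggregates and
logged, rather than mapped to 0 or infinity.  An aggregate pain score is
the arithmetic mean of the four scales per subject-visit.

## Missing data and harmonization

An instrument score with 30% or more of its items missing is excluded;
below that threshold, missing items are replaced by the mean of the
observed items of the same score (`handle_missing()`).  The boundary is
treated as inclusive ("30% or more" excludes; strictly less imputes).
Cohort tables in this package are stored at subscale level, where item
columns are unavailable; there the documented fallback imputes a missing
subscale cell with the group-visit mean of that subscale, and a
subject-visit missing 30% or more of an instrument's subscales produces an
exclusion record.  Imputed cells are flagged in the provenance matrix so
downstream stages can report them.

All measures are harmonized to a common 0–10 scale with 10 = worst, by an
invertible affine map from the registry's native range (higher-is-better
instruments are reversed).  Performance times and distances are rescaled
like the questionnaires by default; the raw-units alternative is supported
by passing a registry with adjusted entries.

## Factor reduction

The 21 harmonized measures (pain outcomes excluded — they are what the
factors are later asked to predict) enter a correlation-matrix PCA.
Sampling adequacy is checked with Kaiser–Meyer–Olkin statistics comparing
correlations against anti-image partial correlations; components are
retained when their eigenvalue strictly exceeds 1.0 (the scree elbow is
reported for inspection but never applied automatically); retained
components are rotated with Promax (varimax pre-rotation followed by the
power-target oblique transform, power κ = 4, the conventional default —
configurable).  Measures belong to the component on which their rotated
pattern loading reaches |0.5|; a measure exceeding the threshold on
several components is assigned to the largest absolute loading, ties
broken by component order, and flagged as multi-loading.

Scoring weights are the regression-method weights of the unrotated
solution rotated into the Promax basis
(`W = V Λ^{-1/2} (R^{\mathsf T})^{-1}` with `R` the full rotation).
Standardization always uses the fitting sample's means and SDs, so the
smaller hip arm can be projected through the knee-arm weights and compared
in the same component space.  PCA on the correlation (not covariance)
matrix was chosen because the measures live on heterogeneous scales and
because the KMO diagnostics presuppose it.

## Outcome models

Pain at baseline, pain at 6 months and residual pain at 6 months are each
modeled per scale by stepwise forward/backward regression over eleven
candidates: the five factor scores plus age, gender (0 = male, 1 =
female), education (ordinal 0/1/2), BMI, pain duration and radiographic
KL grade.  Entry requires a partial-F p-value below 0.05 and retention
requires staying below 0.10; entry and removal alternate until stable,
with ties broken by candidate order.  After selection, cases with
studentized deleted residuals beyond ±3 SD are pruned — largest first,
refitting after each removal, at most 3 cases — and the selection is
re-run once on the pruned data.  Whether pruning precedes or follows
selection is not uniquely determined by the protocol; selection-first is
the default and the alternative is available
(`outlier_handling = "before_selection"`).  Factor scores enter
unstandardized, with standardized coefficients (β = b·sd(x)/sd(y))
reported alongside; the knee-arm predictor sets are re-tested in the hip
arm as plain multiple regressions (`apply_model()`).

## Networks

Pearson correlation matrices of the 21 measures (per group, per visit) are
binarized by ranking the 210 measure pairs by absolute correlation and
keeping the top `round(0.25 · 210) = 53` (rounding half-up).  Ranking by
absolute value is the default because the six-minute walk loads negatively
yet participates in the networks; positive-only ranking is available.
Nodes carry the PCA-derived communities.  Two metrics summarize topology:
the mean local clustering coefficient (triangle density around each node;
nodes of degree < 2 contribute 0, the convention of the standard brain
connectivity toolbox) and Newman–Girvan modularity maximized by Louvain,
averaged over 100 repetitions with independently randomized node order.
Because greedy Louvain can stall in local optima on small, weakly modular
graphs, every repetition is followed by a refinement stage — single-node
moves and community merges accepted while Q improves — and the reported
metric additionally refines one random coarse partition per repetition and
keeps the best result.  On graphs small enough for exhaustive search the
refined mean Q stays within 0.02 of the global optimum (and can never
exceed it); the permutation machinery uses the lighter no-restart variant,
applied identically to the observed networks and every resampled draw so
the test remains internally consistent.
Reorganization between visits is the mean over all pairs of the absolute
change in correlation (mean Δr); the signed mean is reported alongside,
since a signed average would hide simultaneous strengthening and
weakening.

## Permutation inference

The protocol's resampling is its least-specified component; the package
implements the two exchangeability-respecting schemes:

* **within-subject visit swap** for change statistics — each subject's two
  visit vectors are swapped with probability ½ per draw and the full
  pipeline (correlation → binarization → metric → delta) is recomputed,
  which is exact when surgery has no effect on the correlation structure;
* **group-label shuffle** for between-group contrasts — subjects, carrying
  their visit pairs, are reallocated between arms preserving arm sizes.

Probabilities are one-sided on the magnitude statistic with the add-one
correction `(1 + #{null ≥ obs}) / (1 + reps)`, never exactly zero.  Draws
on which a statistic is undefined (zero variance) are redrawn and counted.

## The synthetic cohort generator

No patient-level data ship with the package; a generator
(`synthetic_spec()`, `generate_cohort()`) emulates the study conditions so
every stage is testable end-to-end:

* two arms, 84 knee and 22 hip subjects;
* 21 measures driven by 5 orthogonal standard-normal factors through a
  simple-structure loading matrix (|0.75| on the own factor, negative for
  higher-is-better measures in native orientation);
* uniqueness 0.15 per measure, implying within-factor correlations near
  0.79 — chosen to match the observed within-construct correlations of
  these instruments (0.79–0.96 between pain scales of the same construct),
  rather than the much noisier structure a unit-variance convention would
  give;
* four pain scales tied to the Pain Quality factor with standardized
  loading 0.5; baseline means/SDs anchored to the observed cohort (e.g.
  knee NRS 6.53 ± 1.67) and post-surgical means equal to baseline times a
  per-scale retention fraction fitted to the observed 3-month/baseline
  ratios (knee NRS 0.289, hip NRS 0.090);
* a surgery effect on the correlation structure parameterized by
  `rewire_strength` ∈ [0, 1]: factor scores are convexly remixed with
  fresh draws, and the loading matrix blends toward a single shared
  "global recovery" dimension whose row norm moves toward 0.95.  The
  collapse-toward-a-global-dimension target was chosen over a random
  re-assignment of factor memberships because only the former reproduces
  the observed direction of the topology change (clustering and
  modularity decrease while overall correlations strengthen after
  surgery); a pure membership shuffle preserves modular topology and is
  undetectable by the topology statistics at these sample sizes;
* defaults `rewire_strength = 0.2` (knee) and `0.9` (hip), calibrated only
  to the qualitative ordering of the reported findings: a larger mean Δr
  in the hip arm, significant topology change only in the hip arm;
* 6-month factor scores persist from 3 months with correlation 0.9 and
  the 3-month structure is held fixed, reflecting the reported stability
  of outcomes from 3 months onward;
* missingness is completely at random (rate 0.02; the observed cohort had
  item-level missingness in 8% of subjects at under 12% per
  questionnaire), and values are clipped to native ranges (clipping, not
  resampling, preserves the mean structure; the clipped fraction, about
  2% at defaults, is reported in the ground truth).

What the generator does **not** emulate: floor effects and skewness of
real questionnaire distributions beyond clipping, shared method variance
within instruments beyond the factor structure, informative dropout,
medication effects, and any radiographic detail beyond a categorical KL
grade.  Passing recovery tests on this generator therefore demonstrates
the correctness and calibration of the pipeline's machinery, not the
clinical validity of conclusions on real data.

## Numerical choices and degenerate inputs

* Edge counts round half away from zero, so 25% of 210 pairs is 53 edges.
* Binarization tie-breaks: higher |r| first, then lexicographic pair
  order; the edge set is invariant to monotone transforms of |r|.
* Residual pain at zero baseline is `NA` (undefined), not 0 or ∞.
* Component retention uses a strict inequality, so an eigenvalue of
  exactly 1.0 is not retained.
* Promax columns are sign-fixed (largest |loading| positive) and ordered
  by explained variance; the factor correlation matrix is symmetrized and
  its diagonal pinned to 1 against rounding drift.
* A singular correlation matrix makes `kmo()` fail with advice rather
  than returning values from a pseudo-inverse.
* Stepwise selection errors out if entry/removal cycles (possible only if
  `alpha_enter >= alpha_remove`); zero-variance candidates are dropped
  with a warning.
* Outlier pruning refuses to reduce the sample below predictors + 3.
* All stochastic stages take explicit seeds and restore the caller's RNG
  state; `run_full_analysis()` derives per-stage sub-seeds from one root
  seed so any stage can be re-run in isolation.

## Problem sizes used by the test suite

The shipped tests exercise the pipeline at the study's own scale (84/22
subjects, 21 measures).  Simulation-based checks use 500 cohorts with 500
resampling draws for the type-I calibration of the mean-Δr test, 150
cohorts for its power under rewiring 0.6, 100 seeds for factor recovery,
500 seeds for stepwise power and calibration, and 15 cohorts with 300
draws per test for the qualitative end-to-end reproduction, with
majority-vote aggregation across cohorts for the qualitative clauses.
Exhaustive graph oracles go up to 7 nodes (clustering, 200 graphs) and 10
nodes (modularity over all set partitions).

## Known limitations

* Fisher z comparisons of correlations across visits use the
  independent-samples form even though within-subject correlations are
  dependent; this matches the protocol as printed and slightly overstates
  p-values for dependent comparisons.
* The hip arm (n = 22) gives the topology statistics limited power; at
  the default rewiring the clustering test detects the planted change in
  roughly three quarters of cohorts, which is why the qualitative suite
  aggregates by majority instead of requiring every cohort to reject.
* On clean data at n = 84 the ±3 SD studentized-residual rule still flags
  at least one case in roughly a quarter of samples (the expected number
  of exceedances of a |t| > 3 cut at this n is about 0.3); the cap of 3
  keeps this benign.
* Item-level imputation is only available when item columns are supplied;
  subscale-level tables use the documented group-mean fallback.
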