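---
title: "Methods: quantifying treatment efficacy from time-course metabolomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying treatment efficacy from time-course metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(metabodereg)
```

This vignette is the package's own account of its models, conventions and
numerical choices.  The pipeline quantifies how far a toxin pushes a serum
metabolome away from the healthy state over time, and how much of that
excursion each treatment prevents, using two scores: a principal-curve
deregulation score (MDS) for the global profile, and a fold-change area
statistic (RAUC) for individual metabolites.

## The study layout being modelled

The expected design is a rodent toxicity study: a control group, a
toxin-only group, and one or more treated groups (toxin plus candidate
intervention), each animal sampled at a baseline day and several
post-dose days.  The default design carries six groups of 10–12 animals
(63 in total) sampled at days −1, 1, 4, 7 and 10, pooled-QC injections
and blank injections, matching a delayed-toxicity episode that peaks
around day 4 and resolves by day 10.  Phenotypes recorded per animal and
day are a 0–3 diarrhea score (DS) and body weight relative to baseline
(RBW, %).

## The synthetic-data generator

No public raw data accompanies studies of this kind, so the generator is
a first-class module with full ground truth rather than a test fixture.
Its generative model, per feature $j$ and sample $i$ (animal $a$, group
$g$, day $d$):

$$\log_2 x_{ij} = m_j + u_{aj} + s_j\,\delta_j\, \alpha_g\, \pi_d + \varepsilon_{ij}$$

* $m_j \sim N(14, 0.8)$ — base log2 abundance.  A *post-detection* peak
  table has a compressed dynamic range (faint peaks never survive peak
  detection), and this moderate spread keeps feature influence in
  Pareto-scaled models driven by the planted effects rather than by raw
  abundance; with a very wide abundance distribution, VIP becomes an
  abundance ranking, which is not the structure the screening step
  assumes.
* $u_{aj} \sim N(0, 0.15)$ — animal-by-feature random intercept, giving
  per-animal trajectories their persistence across days.
* $\delta_j$ — peak log2 effect of perturbed features, magnitude
  $1.5 \times \mathrm{Uniform}(0.5, 1.5)$ with random sign (about a
  2–5-fold change at peak).  The magnitude was calibrated from the
  marker–phenotype correlation algebra: with within-group noise
  $\sigma \approx 0.43$ and deregulation spread $\mathrm{sd}(d) \approx
  0.25$ across the study, a typical marker correlates with the phenotype
  at $|\rho| = \delta\,\mathrm{sd}(d)/\sqrt{\delta^2\mathrm{var}(d) +
  \sigma^2} \gtrsim 0.5$ only when $\delta \approx 1.5$; this is the
  regime in which a Spearman screen at 0.5 retains most true markers,
  as reported for this kind of severe-toxicity study.
* $\alpha_g \in [0,1]$ — group attenuation: 0 for control, 1 for
  toxin-only, defaults 0.25/0.35/0.5/0.75 for the four treated groups
  (full formula strongest, formula-minus-key-herb weakest).
* $\pi_d$ — day profile: 0 at baseline, 0.6 at day 1, 1 at day 4
  (peak), 0.25 at day 7, 0.05 at day 10.
* $\varepsilon_{ij} \sim N(0, 0.4)$ — residual log2 noise (~32% CV,
  typical of untargeted serum LC/MS).

Additional structure: exogenous (decoction-derived) features are present
only in their own treated group's samples, drawn at high abundance
($N(15, 0.5)$ — dosed constituents circulate well above the detection
limit, which is exactly why they must be recognized and removed);
background features also appear in blanks; pooled QCs are the grand mean
of all study samples with 5% log-scale replicate noise; missingness is
left-censoring below a single global detection threshold (the 5%
quantile of all study intensities), so low-abundance features carry most
of the non-detects, as real peak detection produces.  DS is
$\mathrm{clip}(3\,\alpha_g \pi_d + N(0, 0.25),\,0,\,3)$ and RBW is
$100 + 1.2\,(d+1) - 35\,\alpha_g \pi_d + N(0,2)$, so both phenotypes are
monotone in the latent deregulation.

What the generator does **not** emulate: retention-time drift, batch
effects, correlated metabolite modules (pathway structure), adduct
ladders, or heteroscedastic technical noise.  Tests passing on this
generator therefore demonstrate the pipeline's statistical behaviour
under its stated assumptions, not robustness to instrument artefacts.

## Preprocessing chain

Per platform (LC/MS+, LC/MS−, GC/MS), in order:

1. **Background filter** — keep a feature iff mean study intensity ≥ 3×
   mean blank intensity (non-detected blank values count as 0).  The
   ratio rule and its default of 3 are common practice; both are
   config-exposed (`background_min_ratio`).
2. **80% rule** — keep a feature iff observed in ≥ 80% of the samples of
   at least one study group; QCs and blanks never count.
3. **QC RSD filter** — keep a feature iff sd/mean over the pooled-QC
   injections ≤ 0.15 (sample standard deviation, n−1).
4. **Total-ion-intensity normalization** — divide each sample by its
   observed total; per platform, because total ion current is
   platform-specific.  Blanks are dropped at this point (their retained
   intensity is empty by construction).
5. **Ion fusion** (optional, off by default) — single-linkage merging of
   features within a declared grouping window whose Pearson correlation
   ≥ 0.9, summing intensities.  The generator plants no adduct
   structure, so the pipeline default leaves it off; the operation is
   fully config-driven for real tables that carry window annotations.

The platform matrices are then concatenated feature-wise; a sample's row
exists in the merged matrix iff it exists on all platforms.  Missing
values are *never* imputed by any of these steps: a recorded 0 is an
observed zero, absence is absence.  Multivariate models need a complete
matrix, so the modelling boundary fills non-detects explicitly
(`fill_missing()`, half the feature's minimum observed value — the usual
detection-limit surrogate), and Pareto scaling (center, divide by the
square root of the standard deviation) is fitted on study samples only.

## Multivariate engines

PCA is `stats::prcomp` behind a thin surface carrying R²X and
cross-validated Q².  OPLS-DA is a NIPALS implementation for one binary
response: each orthogonal round deflates the Y-orthogonal part of the
loading, so orthogonal scores are *exactly* uncorrelated with the
response; with zero orthogonal components the predictive component is
the one-component PLS1 solution.  Conventions:

* Classes are encoded ±1; reported scores are sign-fixed so the named
  positive class (the toxin/treated group in pipeline use) has positive
  mean predictive score.
* VIP is computed over the predictive plus orthogonal components with
  SSY weights; orthogonal components explain no response variance, so
  $\sum_j \mathrm{VIP}_j^2 = p$ holds exactly.  This is one of several
  published OPLS-VIP variants; it is the declared one here.
* The S-plot reports per-feature covariance and correlation with the
  predictive score.
* Cross-validation uses 7 folds (the usual software convention),
  stratified by class for supervised models; Q² = 1 − PRESS/SS on
  held-out predictions.  For PCA, held-out rows are reconstructed from
  loadings fitted on the training rows.  The number of orthogonal
  components is chosen by increasing while Q² improves by more than
  0.01.  Fold assignment is the pipeline's only randomness besides the
  generator, and it derives deterministically from the master seed.

## Screening cascade

1. **Exogenous removal.**  Control and toxin-only samples are pooled
   into a reference that lacks decoction exposure ("CT").  A feature is
   exogenous iff observed in < 10% of CT study samples and in ≥ 90% of
   the treated group's samples (`absence_fraction = 0.1` quantifies the
   visual "absent in the reference" trend-plot inspection); an OPLS-DA
   of treated vs CT supplies the |p(corr)| ranking an analyst would read
   the S-plot by.  Removal precedes all marker selection, so exogenous
   compounds can never enter a biomarker set.
2. **Per-day selection.**  For each sampling day and each comparison of
   the toxin group against another group: OPLS-DA for VIP, per-feature
   two-sided Mann–Whitney tests, BH adjustment within the comparison; a
   marker needs VIP > 1.0 and adjusted p < 0.05.  Two deliberate
   departures from the shared stats layer's small-sample convention
   apply *inside the screen*: the exact Mann–Whitney null distribution
   is used whenever a feature is tie-free (the FDR step depends on
   deep-tail p-values that the normal approximation truncates — at
   n = 10 + 10 the approximation's attainable minimum is ~2·10⁻⁴ while
   the exact distribution reaches ~10⁻⁵), and the tests run on
   detection-limit-filled values so that censored observations rank
   lowest instead of disappearing (a non-detect of a down-regulated
   metabolite is its most informative measurement).  Applying the
   threshold to raw p-values instead is a config switch
   (`adjust_p = FALSE`).
3. **Union and Spearman filter.**  Selected ids are unioned across all
   comparisons and days with every record's evidence retained.  Each
   marker's intensity is then paired with its own animal's same-day DS
   and RBW; markers with |Spearman rho| < 0.5 against both phenotypes
   are removed.  Under the default noise this is the strictest stage of
   the cascade: it passes roughly the stronger half of the planted
   markers, which are also the ones that carry the MDS stage well.

## MDS: principal-curve deregulation score

The retained markers' Pareto-scaled matrix is reduced to the smallest
number of PCs explaining ≥ 85% of its variance (config-exposed).  A
principal curve is fitted by the classical projection–smoothing
iteration: initialize at the first PC; project every sample onto the
current polyline to get an arc-length parameter; smooth each coordinate
against the parameter with a running-mean window spanning 30% of the
points; reparametrize by arc length; stop when the total squared
projection distance changes by less than 0.1% (`curve_tol = 1e-3` — the
iteration oscillates below this level without further improving the
ordering) or after 50 iterations, in which case a warning carries the
diagnostics.  The curve is fitted through the *full* cloud and oriented
so the control samples' mean parameter sits at the low end (a
fit-on-healthy-only question was considered and rejected: with few
healthy samples the curve would not span the deregulated region it must
score).

A sample's MDS is the arc-length position of its projection divided by
the total curve length — "how far along the disease axis", in [0, 1] —
with the orthogonal residual kept as a diagnostic column.  The
along-curve position (not the orthogonal distance) is the deregulation
reading, matching the pathway-deregulation-score methodology this
transplants.  Samples beyond the smoothed curve's ends clamp to the
endpoints and can tie at exactly 0 or 1; on exactly collinear data the
MDS is therefore a monotone (tied only at the ends) function of the PC1
score.  Per animal, MDS-vs-day curves are integrated by the trapezoid
rule, and groups are compared pairwise by Mann–Whitney tests on the
per-animal areas — per-animal, rather than on group means, because that
is what gives the group comparisons their significance tests.

## RAUC: fold-change areas

For each metabolite, animal and window day (default window days 4–10,
the delayed-toxicity episode), the relative level is
$\log_2(x / \bar{x}_{\text{control, same day}})$, so control sits at
zero by construction; a linear fold-change mode (`fc_minus_1`) is a
config switch.  Non-detects are detection-limit-filled first — a
censored day is a large deviation, not a missing one.  The RAUC is the
trapezoidal area of the *absolute* relative level over the window:
deviation in either direction is dissimilarity to control.  Per
metabolite, every group is tested against the toxin-only group by
Mann–Whitney on per-animal RAUCs with *unadjusted* p-values (the
re-regulation calls are declared exploratory, mirroring how such panels
are reported); a metabolite is re-regulated in a group iff p < 0.05 and
the group median is below the toxin median.  Intersections of
re-regulated lists across configurable group sets give the "common
re-regulated metabolites".

## Shared statistics layer

Mann–Whitney U (exact by enumeration-equivalent distribution when the
combined sample is ≤ 12 and tie-free, otherwise normal approximation
with tie and continuity correction — documented and overridable),
Benjamini–Hochberg step-up adjustment, Spearman correlation with average
ranks, and the trapezoid rule.  These wrap the corresponding base-R
routines behind contract-enforcing fronts; the tests verify them against
independent enumeration, step-up and rank-formula oracles.

## Problem sizes used by the test-suite

The suite exercises the full six-group design where the design itself is
the point (layout, trajectories, orderings) and scaled-down studies
elsewhere: 4–6 animals per group and 25–40 features for module tests;
the screening-recovery studies use the six-group design at 10 animals
per group with 80 features (20 perturbed at 1.5 noise SDs); the RAUC
monotonicity property is measured on a two-group design with 20 animals
per group, because at 11 animals the sampling noise of a per-metabolite
median alone caps the measurable rank correlation near 0.78 regardless
of the statistic's quality.  Null calibration of the BH step uses
100 p-values × 1000 replicates.

## Known limitations

* Screening power at 10 animals per group is modest: with BH-adjusted
  selection, a 1.5-noise-SD effect is recovered in roughly half to
  two-thirds of cases per comparison even with exact tests — a property
  of rank-test FDR at this sample size, not of the implementation.  The
  default study's stronger effects (~3 SDs) are recovered at ~0.85–0.95.
* The Spearman filter is the strictest stage under default noise; real
  studies with tighter phenotype coupling would retain more markers.
* MDS saturates at 1 for samples beyond the deregulated end of the
  curve, so extreme-group means can hit the ceiling exactly.
* Total-ion normalization couples features within a sample; strongly
  perturbed samples slightly shift apparent levels of unperturbed
  features (visible as a handful of "indirect" marker selections on
  synthetic data, which the Spearman filter mostly removes).
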