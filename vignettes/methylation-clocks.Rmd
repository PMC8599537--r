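---
title: "Epigenetic clocks, relative age, and methylation EWAS with cpgclock"
author: "cpgclock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Epigenetic clocks, relative age, and methylation EWAS with cpgclock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(cpgclock)
```

## The model

An epigenetic clock is a sparse linear estimator of age from CpG
methylation fractions ("beta values", each in [0, 1]). Writing
$x_{j}$ for the beta value of CpG $j$ and $F$ for an age transform, the
clock is

$$\hat{F}(\text{age}) \;=\; b_0 + \sum_{j \in S} w_j x_j,
\qquad \widehat{\text{DNAmAge}} = F^{-1}\!\big(b_0 + \textstyle\sum_j w_j x_j\big),$$

with the active set $S$ and weights $w$ chosen by elastic-net regression
(`glmnet`) at mixing fraction $\alpha = 0.5$ — fixed by convention, the
midpoint between ridge and lasso, never tuned for performance. The
penalty strength is the one minimizing ten-fold internal
cross-validated mean-squared error along glmnet's descending penalty
path; ties resolve toward the larger penalty, i.e. the sparser model.
Predictors are standardized internally by the fitting routine and the
stored weights are reported back on the original beta scale, so a model
file can be applied directly to a new beta matrix.

### Age transforms

Three transforms `F` are supported, selected with `age_transform()`:

* **identity** — age in years. Appropriate for a single species over a
  moderate age range (the blood clock).
* **log-linear** — $F(a) = \log\frac{a + o}{A + o}$ for $a \le A$ and
  $F(a) = \frac{a - A}{A + o}$ above, with adult-age knot $A$ and offset
  $o$ (default 1 y). The two branches meet at $a = A$ with equal value
  (0) and equal slope $1/(A+o)$, so the map is strictly increasing and
  continuously differentiable, compressing the fast methylation drift
  of development relative to adulthood.
* **relative age** — $a / L$ with $L$ the species' maximum recorded
  lifespan. Defaults are 22.8 y (marmoset) and 122.5 y (human). Relative
  age puts a marmoset and a human at the same regression value exactly
  when their lifespan fractions agree, and is deliberately *not* clipped
  at 1 in either direction: clipping would bias error estimates for
  animals that outlive their species' recorded maximum.

### Dual-species clocks and the "single formula" skew

A dual-species *chronological* clock regresses one common transform of
age in years for both species. We parameterize that literally: the
log-linear transform takes a single scalar knot (default the human
adult age, 15 y) applied to both species. This is a considered design
choice. If instead each species were given its own knot proportional to
its lifespan, the log-linear target would collapse to nearly the same
function of relative age for every species — the "chronological" clock
would be a relative-age clock in disguise, and comparisons between the
two would measure nothing. Keeping the chronological clock a single
common formula preserves the real phenomenon: ages from a species
living 22.8 years and one living 122.5 years occupy incommensurate
parts of one scale, the fit must compromise between species-specific
target shapes, and its weights are correspondingly noisier. The
relative-age clock removes this skew by construction, which is why it
transfers better to a species never seen in training. The acceptance
suite checks exactly this pattern on simulated data.

Per-species knots remain available (`adult_age` as a named vector) for
users who want a lifespan-calibrated chronological scale; model files
record whichever parameterization was used.

## Unbiased evaluation

Accuracy is always reported from cross-validation, never from training
fit: `loocv_clock()` (leave-one-out) and `kfold_clock()` (stratified
k-fold). Two details matter for unbiasedness:

* the internal penalty-selection CV is re-run inside every outer fold
  (fold $i$ uses seed `seed + i`); no penalty chosen on the full data is
  ever reused, so the held-out sample can not influence the model that
  predicts it;
* k-fold folds are assigned by seeded round-robin within species
  strata, so both species of a dual-species clock appear in every
  training fold. With $k = n$ the assignment is the identity
  permutation and the scheme coincides exactly with leave-one-out.
  Strata smaller than $k$ fall back to unstratified assignment with a
  warning. The internal fold count is capped at half the fold's
  training size so small cohorts remain fittable.

Metrics are the two conventional ones: $R$, the Pearson correlation of
DNAm age with chronological age, and the median absolute error in
years, overall and per species.

## EWAS

`screen_numeric_trait()` computes per-CpG Pearson correlations with a
numeric trait and the exact t test
($t = r\sqrt{n-2}/\sqrt{1-r^2}$, two-sided p at $n-2$ df).
`ewas_covariate()` fits per-CpG ordinary least squares of beta on
an intercept, a binary group, and covariates, reporting the group
coefficient; with no covariates it is identical to the correlation
screen (the tests assert agreement to 1e-10). Both convert p to a
standard-normal score $z = \mathrm{sign} \cdot \Phi^{-1}(1 - p/2)$ so
strata can be combined by Stouffer's method,
$Z = \sum_i w_i z_i / \sqrt{\sum_i w_i^2}$, with $w_i = \sqrt{n_i}$
when stratum sizes are given and equal weights otherwise; strata
missing a z for some CpG are dropped there with weight
renormalization.

Constant CpGs have no defined correlation; they are reported with
$p = 1$, $z = 0$ and a `degenerate` flag rather than propagating NaN.
No genome-wide correction is applied by default — the selection rule
below operates on raw p — but a Bonferroni column is emitted for
reference.

Top-CpG selection (`select_top_cpgs()`) keeps CpGs with p *strictly*
below the threshold (default 0.005) and caps each direction of
association at 500 CpGs ranked by $|z|$, ties broken by CpG id, so the
output is invariant to input row order. `region_distribution()`
summarizes a selected set over genic region classes against the
background of all annotated probes; the reported p per class is the
upper-tail (enrichment) hypergeometric probability
$P(X \ge x)$. Coordinates in annotation tables are 1-based inclusive;
the promoter window convention (TSS −2000 to +200 bp, negative =
upstream) is the annotation producer's concern, not recomputed here.
`set_overlap()` returns upset-style exclusive intersection counts whose
sum equals the union size.

## Downstream analyses

`treatment_effect()` fits the intervention regression
$\text{DNAmAge} \sim \text{Age} + \text{Female} + \text{Rapamycin}$
by OLS, with Female and Rapamycin coded 1/0, reporting per-term
estimate, SE, t, two-sided p, and $R^2$. The DNAm ages must come from a
clock trained on animals disjoint from the test cohort; passing
`training_ids` makes that check mandatory and any overlap an error.
With `covariates = character(0)` the model reduces to the pooled
two-group t test (asserted in the tests to 1e-10).
`age_acceleration()` returns the residual of DNAm age on chronological
age — mean zero, uncorrelated with age by construction.

`sex_predictor_oob()` wraps a `randomForest` classifier (500 trees,
$\sqrt{p}$ candidate features per split, unlimited depth — standard
defaults, since no better-informed values exist) and scores each sample
by out-of-bag majority vote, an honest accuracy estimate without a
held-out set. A generalized-linear-model alternative is deliberately
not provided; in the motivating setting it added nothing over the
forest.

## The simulator and what it does (not) establish

`simulate_methylation()` generates a conserved-CpG array study with
known truth. Its noise model draws each beta from
$\mathrm{Beta}(\mu\kappa, (1-\mu)\kappa)$ — mean $\mu$, concentration
$\kappa$ — respecting the [0, 1] support; variance is
$\mu(1-\mu)/(\kappa+1)$. Age-associated CpGs drift linearly in
*relative* age, $\mu = \beta_0 + d\,A\,(a/L)$ with direction
$d = \pm 1$ and amplitude $A$, so the aging signal is shared across
species on the relative-age scale by construction; sex and treatment
CpGs carry constant group offsets; all means are clipped to
[0.01, 0.99], and baselines are drawn so that effects are not flattened
by the clipping. Ages are uniform over each species' range; sexes are
balanced; treatment arms exist only in the older (above-median-age)
half of the first species, mirroring an intervention cohort of
middle-aged animals, with 46% of that stratum treated.

Defaults describe a marmoset blood cohort at desk scale: 2,000 CpGs,
60 samples aged 0.5–15.5 y, 20 age CpGs of amplitude 0.4 at
concentration 100, **no** sex CpGs — marmosets are hematopoietic
chimeras, litter mates exchanging stem cells in utero, which blurs
methylation sex signals in blood; the default therefore makes sex
unlearnable, and the out-of-bag sex predictor is expected to sit at
chance — and a treatment effect of exactly zero, the null the
intervention analysis should reproduce. Effect amplitudes are free
parameters of the generator (no empirical effect-size distribution is
available to copy); 0.4 at concentration 100 gives association
strengths comparable, at this reduced scale, to a strongly
age-reflective methylome.

What the simulator does **not** model: the bimodal beta-value landscape
of real arrays, probe-level QC and detection failures, batch and plate
effects, outlier samples, species-specific baseline differences, and
partial sharing of age CpGs across species. Passing tests therefore
demonstrate that the statistical machinery is correct and calibrated
under the stated generative model — not that any particular biological
cohort will reach the same accuracies. In particular, real
cross-species transfer degrades for reasons (probe divergence,
baseline shifts) that this generator deliberately excludes.

## Numerical choices and degenerate inputs

* Clipping bounds 0.01/0.99 keep Beta parameters finite.
* An all-constant predictor matrix yields an intercept-only clock
  predicting the mean transformed age; a constant age vector is a
  degenerate-response error.
* At prediction time, model CpGs absent from the input are imputed at
  their stored training means; more than 20% missing is a hard error
  rather than silent extrapolation.
* Clock files are plain CSV with a commented header carrying the
  transform specification (e.g. `max_lifespan.marmoset=22.8`) and
  training provenance; round-trips are lossless to 1e-10 in
  predictions, and numbers are serialized at full precision (`%.17g`).
* One user-visible seed governs every stochastic step (fold
  assignment, simulation, forest bootstraps); identical inputs and
  seed reproduce every number exactly.

## Problem sizes

The validation suite and the acceptance script run at 2,000 CpGs and
60–160 samples, with multi-seed properties evaluated over 10 fixed
seeds; these sizes were chosen as the smallest at which the elastic
net, the EWAS calibration, and the forest behave as they do at array
scale, while keeping a full run in minutes on one core. The held-out
transfer cohort uses 60 samples of a third, vervet-like species
(maximum lifespan 30.8 y, ages 0.5–25 y) never seen in training.

## Known limitations

* The log-linear knot and offset for chronological dual-species clocks
  are configuration with stated defaults, not estimated; model files
  record them.
* LOOCV correlation on null data is a high-variance statistic (fold
  models share spuriously selected CpGs), so null behavior is asserted
  as absence of systematic skill across seeds rather than a tight
  per-seed band.
* `region_distribution()` tests enrichment only (upper tail);
  depletion is visible in the proportions but not tested.
* The pipeline consumes normalized beta values; normalization of raw
  array intensities is upstream of this package and out of scope.
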