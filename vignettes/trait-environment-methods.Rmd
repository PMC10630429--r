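---
title: "Models and methods behind traitclines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind traitclines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitclines)
```

# The setting

Ten tree species spanning an eightfold climatic moisture gradient are
grown together in four common gardens positioned along the same gradient.
Moisture supply is indexed by P/E~p~, the ratio of mean annual
precipitation to pan evaporation (dimensionless). Each species carries a
"species P/E~p~" (the mean over its native occurrences, 0.19–0.98 for the
default design) and each garden a "site P/E~p~" (0.16, 0.39, 1.03, 1.25).
For every trait analysed, the response to *site* P/E~p~ within species
measures plasticity, and the response to *species* P/E~p~ within gardens
measures fixed, evolved differentiation. The package asks whether both
responses run in the directions optimality theory predicts, and whether
realized growth (survival × height) shows adaptive cross-over along the
gradient.

# The phylogenetic mixed model

For one trait, let $y_{ij}$ be the (possibly transformed) trait mean of
species $i$ at site $j$. The model is

$$y_{ij} = \beta_0 + \beta_1 \ln(\text{site P/E}_p)_j
  + \beta_2 \ln(\text{species P/E}_p)_i
  \;[+\, \beta_3 \,\text{interaction}] + u_j + v_i + w_i + z_{ij} + e_{ij}$$

with four candidate random effects: iid site intercepts $u_j$, iid
species intercepts $v_i$, a phylogenetic species effect $w_i$ with
covariance $\sigma^2_{phylo}\,C$ where $C$ is the Brownian-motion
covariance of the time-calibrated tree (shared root-to-tip path lengths,
scaled to unit height so components are comparable), and a
"phylogenetic attraction" term $z_{ij}$ — an independent Brownian draw
per site, so close relatives covary within but not across gardens.
Residuals $e_{ij}$ are iid Gaussian. Both predictors enter on the log
scale because trait variation along this gradient is close to log-linear
in P/E~p~.

Estimation profiles the fixed effects and the residual variance out of
the Gaussian likelihood and optimizes the variance *ratios* on a log
scale with multi-start bounded quasi-Newton (three starts; bounds
$e^{-18}$ to $e^{12}$). A floor of $10^{-13}\times\widehat{\rm var}(y)$
on the profiled residual variance keeps the objective finite when the
fixed effects fit exactly. A near-singular covariance receives a ridge of
$10^{-8}$ times its mean diagonal.

## Model choice

Fixed-effect form (additive vs interaction) and trait transform (none,
log, square root) are chosen by lowest AIC on preliminary ordinary
regressions, with ties inside ΔAIC < 2 broken toward fewer parameters.
Because AIC values on differently transformed responses are not
comparable as likelihoods of the same data, the transform's log-Jacobian
is added, putting every candidate on the raw trait scale. Random effects
are then backward-eliminated from the full four-component model by
likelihood-ratio tests at a deliberately generous p ≥ 0.5 — variance
components are retained unless clearly useless — with the rule that the
iid species term is not removable while a phylogenetic term remains, so
non-phylogenetic species differences cannot masquerade as phylogenetic
signal. The df = 1 chi-square reference is used without a boundary
mixture correction: halving the p-values at a 0.5 cutoff would only make
elimination more aggressive, and retention is the conservative direction
here.

## Inference with four gardens: why ML alone is not enough

The default estimator is maximum likelihood, which keeps AIC comparisons
across fixed-effect forms valid and lets the star-phylogeny fit be
checked to $10^{-6}$ against an independent iid-group mixed-model
implementation. But the site slope is identified by only four site-level
values, and ML variance components are biased low with so few levels: in
simulation at study dimensions, normal-quantile Wald intervals for the
site slope cover roughly 77–84% instead of 95%, and normal-reference
p-values are strongly anticonservative (the statistic is approximately
t-distributed with 2 df, whose tails dwarf the normal's). The package
therefore

* offers `method = "REML"` in `fit_candidate()` for interval estimation,
* computes every Wald p-value against a Student-t reference with
  *between-cluster* degrees of freedom — `n_sites − 2` for the site
  slope, `n_species − 2` for the species slope, the smaller of the two
  for intercept and interaction — and
* builds `confint()` intervals from the same t quantiles.

With REML and between-cluster df, simulated coverage is 94–98% for both
slopes and the global-null false-discovery simulation behaves correctly.
This is the standard small-sample treatment for cluster-level predictors
in multilevel models; it is the package's own choice, documented here
because the inferential behaviour with four gardens depends on it.

## R² and multiplicity

Total R² is likelihood-ratio based,
$R^2 = 1 - \exp\{-(2/N)(\ell_{model} - \ell_{null})\}$ with the
intercept-only ordinary model as null; partial R² for each predictor is
the drop in total R² when that predictor's terms are removed from the
final model (refitted with the same random effects), clamped to [0, 1].
The two slopes of all traits form one FDR family of $2\times n_{traits}$
tests (conservatively sized at 106 for a 53-trait study), adjusted by the
Benjamini–Yekutieli step-up with harmonic correction
$c(m)=\sum_{i=1}^m 1/i$, which is valid under arbitrary dependence.
`ybh_adjust()` accepts a family size larger than the number of p-values
supplied, treating the remainder as tests at p = 1.

## Agreement tallies

Each trait × predictor relationship scores 1 when the fitted slope sign
matches the predicted direction and 0 when it contradicts it.
Relationships that agree except for the one or two species of driest
origin are discounted to 0.9 or 0.8; those that agree except at the one
or two driest gardens, to 0.75 or 0.5. The exception assignments encode
inspection of per-species and per-garden refits and are supplied by the
caller as configuration rather than inferred automatically — the mapping
"one exception → 0.9/0.75, two → 0.8/0.5" is fixed. Aggregates report
the weighted percentage agreeing and the percentage agreeing with an
adjusted p below 0.05.

# Ordination

The PCA standardizes every trait column (correlation-scale), drops rows
flagged as excluded, and mean-imputes sporadic missing cells with the
count recorded — full-information alternatives exist, but with trait
means over a 10 × 4 grid the imputation touches few cells and keeps the
ordination deterministic. Axis signs are fixed so the projected site
gradient points into the positive quadrant. Gradients are projected as
supplementary variables: the unit-scaled coefficients of the regression
of the log gradient on the PC1–PC2 scores. Trait vectors are classified
into eight sectors by nearest direction among the two projected gradient
directions, their opposites, and the four bisectors; each loading is
first multiplied by the trait's predicted direction so that alignment
always means accord with theory. The sector geometry is descriptive, and
the 22.5°-band construction is equivalent to nearest-centre assignment
when the two gradients are near-orthogonal.

Reaction-norm summaries regress PC1 on species P/E~p~ within each garden
(fixed differentiation) and on site P/E~p~ within each species grown at
two or more sites (plasticity), on the raw P/E~p~ scale, reporting each
slope set's mean ± s.d., an ANCOVA interaction F-test of slope
homogeneity, and the ratio of mean plastic to mean fixed slope (also as a
percentage, since "plasticity is X% as strong as fixed differences" is
the natural summary).

# Performance statistics

Realized height growth $H^* = \hat p \, m$ multiplies the survival
fraction $\hat p = n_{survived}/n'$ (all $n'$ planted plants) by the mean
height $m$ of the $n$ measured survivors, treating dead plants as zero
height. Because the two factors come from different samples, the
delta-method variance combines both:
$\mathrm{se}^2 = (\hat p^2 + \hat p(1-\hat p)/n')\,s^2/n
 + m^2\,\hat p(1-\hat p)/n'.$
This is exact for the product of an independent binomial fraction and a
Gaussian mean, and the tests verify it against a $10^6$-replicate
Monte-Carlo oracle across a grid of survival rates, planting numbers and
coefficients of variation. When nothing survives, $H^*$ and its se are
both zero; with fewer than two measured plants the se is flagged
undefined and the species is excluded from pairwise comparisons.

Within a site, species pairs are compared by
$z = (H^*_1 - H^*_2)/\sqrt{se_1^2+se_2^2}$ with two-sided normal
p-values, Benjamini–Hochberg adjusted within the site, and summarised by
an insert-and-absorb compact letter display. Survival pairs use the 2 × 2
chi-square with Yates continuity correction; per-plant height or mass
means use Tukey HSD with singleton groups excluded. The survival–gradient
relationship can be fit by the sigmoid
$s = s_{max}/(1+\exp[\beta(a - \text{P/E}_p)])$ (either sign of β;
starting values from a logistic linearization, refined by
Levenberg–Marquardt, with the linear alternative always reported and
preferred when its AIC is lower). `counterfactual_survival()` replaces
one species' survival with the value predicted from the other species'
survival–species-P/E~p~ regression (linear by default, sigmoidal as an
option) and recomputes $H^*$.

Adaptive cross-over is operationalized as a sign change in the Spearman
correlation between $H^*$ and species P/E~p~ from the driest to the
wettest site; the per-site report also flags whether the top-ranked
species' P/E~p~ lies closer to the site's P/E~p~ than the median
competitor's does.

# The synthetic-data generator

The generator reproduces the study design: 10 species × 4 gardens, site
P/E~p~ {0.16, 0.39, 1.03, 1.25}, species P/E~p~ log-even on 0.19–0.98,
81–254 plants per cell, a pure-birth ultrametric tree of height 52 My.
Traits follow the fitted model's generative counterpart — a log-linear
plane in both gradients plus Brownian phylogenetic effects (variance
0.08), site effects (0.03) and residual noise (0.04) on the transformed
scale, slope magnitudes near one. These variances are the package's
choice of a realistic regime (moderate phylogenetic signal, site noise
smaller than the site effect, R² in the 0.85–0.95 range typical of
strong trait–climate relationships); they are fixed once in
`default_trait_params()`. Survival follows per-site sigmoids that
decline steeply with species P/E~p~ at the driest site and rise steeply
at the wettest; heights are lognormal with a log-mean increasing in
species P/E~p~ more steeply at moister sites. Together these plant a
performance rank reversal for the cross-over detector. A second
configuration, `independent_trait_params()`, makes disjoint trait sets
respond to the two gradients; under it the projected gradient vectors
are near-orthogonal, which is the regime in which sector classification
is most interpretable. Under the default configuration — every trait
responding to both gradients in the same direction — the two projected
gradients are intrinsically nearly collinear in trait space; that is a
property of the configuration, not an artifact.

What the generator does *not* emulate: within-cell measurement replicate
structure (it produces cell means directly, with per-trait sample sizes
exposed as a parameter rather than fixed), non-Gaussian noise,
trait–trait residual correlation beyond what the shared gradients induce,
weather time series, soil variation, fire or herbivory. Tests passing on
synthetic data therefore certify the statistical machinery — estimator
calibration, FDR control, detector behaviour — not the field validity of
any particular biological conclusion.

Raw measurement streams (drying curves, flow–pressure series, vessel
samples, root segment tables, growth series) are generated with their
true derived values recorded alongside, so each derived-trait function is
tested for exact recovery at zero noise.

# Numerical and interface choices

* Saturation vapor pressure uses the Tetens equation over liquid water
  (adequate for 15–30 °C chambers); molar mass of water 18.015 g mol⁻¹,
  density 998.2 kg m⁻³ and viscosity 1.002 mPa s at 20 °C; the
  temperature standardization of K~stem~ uses the dynamic-viscosity
  ratio from the standard empirical correlation.
* The g~min~ "quasi-linear phase" is the longest suffix of valid
  intervals whose conductance stays within 20% of its median; the
  reported value is the mean of the lowest-conductance sequential pair,
  earliest pair on ties. Both the Fv/Fm threshold (0.7) and the band
  width are arguments.
* The k~leaf~ exclusion threshold (0.3 MPa) is configurable.
* K~stem~ area rescaling (`rescale_kstem()`) fits
  ln(K/XA) ~ ln(XA) + site per species and moves measurements to the
  per-species median xylem area by default (`"global-median"` optional).
* Root breakage is detected by matching distal ends to unattached
  proximal diameters within a 10% relative tolerance, largest first;
  unmatched ends at least as thick as the smallest proximal diameter are
  treated as breaks and their child's mass imputed from the allometry,
  smallest break first. Ends thinner than that are fine-root tips.
* D~h~ is the power-4 mean $((1/n)\sum D_i^4)^{1/4}$, the standard
  hydraulically weighted diameter.
* All tabular I/O is comma-separated UTF-8 with "." decimals and
  "NA"/empty as missing; rows are keyed by (species, site) and row order
  never carries meaning. Excluded combinations (e.g. total mortality)
  are flagged, never silently dropped.
* One master seed governs every stochastic stage through a deterministic
  counter-based derivation (`stage_seeds()`), so stages can be re-run
  independently and identical (config, seed) pairs produce byte-identical
  outputs, verified by content hashes in the run manifest.
* The pipeline is driven from R: `run_pipeline()` orchestrates
  simulate → regress → ordinate → perform with per-stage outputs and a
  manifest, and `end_to_end_check()` asserts the core properties on the
  default study. The exported functions are the intended interface; no
  shell entry point is installed.

# Problem sizes used in the test suite

The suite exercises the study dimensions directly (10 species × 4 sites):
200 replicate studies for slope recovery and interval calibration, a
500-trait single-dataset simulation for the global-null FDR check, $10^6$
Monte-Carlo replicates per grid cell for the $H^*$ standard error, and
4 000 replicate draws for the Brownian-covariance convergence check on a
5-species tree. These sizes give Monte-Carlo standard errors comfortably
below the tolerances asserted.

# Known limitations

* The packaged default tree is synthetic (pure-birth, height 52 My); no
  claim is made that its topology matches any real eucalypt phylogeny.
* Only Gaussian responses on a chosen transform are supported; no
  binomial survival GLMMs (survival enters the performance module as
  census fractions, per the delta-method formulation).
* The PCA is phylogenetically unstructured; no phylogenetic ordination
  over species × sites is attempted.
* Backward selection prunes random effects only; the fixed form is fixed
  by the earlier AIC step, so an interaction retained there is never
  re-tested afterwards.
* Sector labels presume the projected gradients are roughly orthogonal;
  with strongly collinear gradients the bisector sectors lose meaning.
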