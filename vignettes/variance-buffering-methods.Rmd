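---
title: "Detecting buffering, potentiation and line-crossing epistasis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting buffering, potentiation and line-crossing epistasis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

A molecular *buffer* (the chaperone Hsp90 is the canonical candidate) is a
gene product that diminishes the phenotypic effects of genetic variants;
inhibiting it should *reveal* variation, i.e. increase the phenotypic variance
between strains. A *potentiator* does the opposite: inhibiting it *hides*
variation. Between those two lies a third, less glamorous possibility:
the modifier interacts with genetic variants idiosyncratically, changing the
*rank order* of strains without changing how spread out they are
(line-crossing epistasis).

`epiland` implements the statistical machinery needed to distinguish these
regimes from single-cell morphological trait tables collected under a paired
control/inhibitor design: hierarchical variance inference with
condition-specific variance components, a Robertson-type decomposition of
genotype-by-condition interaction variance into line-spreading and
line-crossing parts, divergence-from-ancestor response statistics, and a
stabilizing-selection truncation model explaining how selection can make a
crossing-type modifier look like a buffer of standing variation. Because the
motivating microscopy datasets are not redistributable, the package also
ships a synthetic-data generator that reproduces the statistical structure
the analysis assumes, with known ground truth for every parameter.

## The data model

The generator (`generator_config()`, `generate_strain_effects()`,
`generate_cell_table()`) emulates CalMorph-style output: one row per cell
with strain, condition, replicate and cell-cycle stage metadata followed by
trait columns (defaults: 132 traits split 19/40/73 across unbudded,
small-budded and large-budded cells, 100–500 cells per strain × condition ×
replicate × stage well, 94 derived lines plus their ancestor, two
replicates).

Strain effects live on latent, PC-like dimensions (defaults 6/9/14 per
stage) and reach the traits through a per-stage loading matrix. The analysis
chain works post hoc on principal components, so the generative direction is
ours to choose; putting the structure on latent dimensions gives the
preprocessing PCA something real to recover and makes parameter-recovery
tests meaningful. For each latent dimension the pair of strain effects
(control, inhibited) is bivariate normal with condition-specific SDs
$\sigma_1, \sigma_2$ and correlation $\rho$ — exactly the three quantities
the downstream inference estimates. Cells add within-strain latent noise
with condition-specific SDs, an additive per-trait replicate offset shared
by the two conditions of a plate pair (mirroring the side-by-side design;
default SD 0.1, a value the motivating studies remove but never report), an
iid per-trait measurement-noise floor (default SD 0.1) below the latent
structure, and optionally a monotone per-trait transform (default identity;
`"exp"` produces log-normal traits for exercising the Box-Cox step).

Magnitudes of within- vs between-strain variation per trait are not
published for the motivating datasets; the defaults
($\sigma_{within} \approx 3\times\sigma_{between}$, via 1.0 vs 0.35) are our
choice of a realistic regime and are plain config fields, not constants.
The ancestor is by default a typical draw — real ancestors respond to the
inhibitor too — with an `ancestor_zero` switch for the idealized case. One
seed governs everything; per-stage substreams are derived deterministically
so adding a stage leaves the other stages' draws untouched.

What the generator does *not* emulate: image segmentation artifacts,
trait-specific measurement distributions, plate-position effects, growth
differences between conditions, or correlated measurement error across
traits. Tests passing on this generator therefore certify the statistical
pipeline, not robustness to every failure mode of real microscopy data.

## Preprocessing

The chain is fixed: Box-Cox → standardize → replicate correction → trait
filter → per-stage PCA → per-PC scaling.

* **Box-Cox.** The exponent is estimated per trait by maximizing the profile
  log-likelihood over $[-3, 3]$ with golden-section search (unimodality
  assumed; a grid-search oracle in the test suite guards the optimizer).
  Non-positive traits are shifted by $10^{-6}\times$range above zero first.
  Standardization to mean 0, SD 1 always pools both conditions — a
  per-condition standardization would erase exactly the variance differences
  the analysis is after. Constant traits are dropped with a warning.
* **Replicate correction.** Replicate enters as a fixed categorical effect
  with condition retained in the model (the sources say only "linear
  modeling"; we exclude a condition × replicate interaction), and the
  centered replicate component is subtracted.
* **PCA.** Fitted per stage on all cells pooled across strains and
  conditions, on already-standardized traits (so covariance PCA is
  correlation-equivalent). The number of retained PCs is a parameter with
  defaults 6/9/14 — stated counts, not an automatic selection rule, because
  no criterion is published. Each retained PC is rescaled to overall score
  variance exactly 1, and oriented so its largest-magnitude loading is
  positive (deterministic output). Per-strain-mean PCA was rejected because
  the hierarchical model needs per-cell scores.

No preprocessing step uses condition labels for centering or scaling.

## Interaction testing and the spreading/crossing partition

Per phenotype, `fit_interaction_lrt()` compares by maximum likelihood
(through `lme4`) a model with random strain and random strain:condition
terms against one without the interaction. The interaction variance sits on
its boundary under the null, so the statistic is referred to the 50:50
mixture of $\chi^2_0$ and $\chi^2_1$; whether the original analyses used a
boundary correction is unstated, so the contract here is the simulation
calibration in the test suite (null rejection ≤ 0.06 at $\alpha = 0.05$).
A statistic of exactly zero reports $p = 1$.

`estimate_strain_condition_moments()` provides the cheap, deterministic
moment path: per-strain condition means; between-strain variances corrected
for mean-level sampling noise by subtracting the average
$\hat\sigma^2_{w,c}/n_{ic}$; the cross-condition correlation disattenuated
through the corrected SDs. Negative corrected variances are clipped to zero
and the clipping is recorded on the object.

`partition_interaction()` then applies the Robertson-type split
$$V_{int} = \underbrace{(\sigma_1-\sigma_2)^2/2}_{\text{line spreading}} +
\underbrace{\sigma_1\sigma_2(1-\rho)}_{\text{line crossing}},$$
which satisfies the verbal definitions exactly: spreading is zero iff the
two conditions are equally variable, crossing is zero iff strain effects are
perfectly correlated across conditions. At sample moments the identity
$V_{int} = \tfrac12\mathrm{Var}(g_1 - g_2)$ holds to floating-point
precision, which the tests assert at $10^{-10}$. The partition is reported
for phenotypes with a significant interaction LRT, and the fractions are
undefined (`NA`) when $V_{int} = 0$. By default the moment estimates feed
the partition; posterior summaries from the MCMC fit can be substituted.

## The hierarchical variance model

`fit_variance_mcmc()` is the package core. The model, per phenotype:
$$y_{cij} = \mu_c + u_{ic} + e_{cij},\quad
(u_{i1}, u_{i2})' \sim N_2(0, \Sigma_b),\quad
e_{cij} \sim N(0, \sigma^2_{w,c}),$$
with unstructured $\Sigma_b$ and *separate residual variances per
condition*, since inhibitor treatment is known to change cell-to-cell
heterogeneity and a homoscedastic model would misattribute that change to
the between-strain level. Priors: inverse-Wishart($\nu=3$, $0.1 I_2$) for
$\Sigma_b$, scaled inverse-$\chi^2(\nu = 0.002, s^2 = 1)$ for each residual
variance, flat for the means — weakly informative on the unit-variance PC
scale and all exposed through `vc_prior()`. The original prior settings are
unpublished; ours are documented and calibration-tested rather than claimed
to match.

All full conditionals are conjugate, so the sampler is plain Gibbs over
per-strain sufficient statistics (counts, sums, sums of squares), with the
bivariate strain-effect updates vectorized through closed-form 2×2 algebra;
cost per iteration is linear in the number of strains and independent of
the number of cells. Defaults are 13,000 iterations, 3,000 burn-in,
thinning 10 (1,000 retained draws); effective sample size and split-chain
R-hat are computed per parameter, and `chain_rhat()` pools independently
seeded fits for a proper multi-chain diagnostic.

Decisions are made on $\Delta\sigma = \sigma_{b,\text{inhibited}} -
\sigma_{b,\text{control}}$ — a difference of *standard deviations*, the
scale on which collection summaries are drawn — via the 95% highest
posterior density interval: `hpd_interval()` takes the shortest contiguous
window containing $\lceil 0.95\,n\rceil$ sorted draws (ties broken toward
the lowest lower bound; an exhaustive window search is the test oracle).
Significance is per phenotype with no multiplicity correction, matching the
original decision rule; the guard against over-interpretation is
directional consistency at the collection level: `collection_summary()`
reports the median, IQR and the boxplot notch $1.58\,\mathrm{IQR}/\sqrt{n}$
of the per-phenotype $\Delta\sigma$ medians, calling a buffering or
potentiation tendency only when the notch interval excludes zero.

## Divergence statistics

`response_matrix()` computes each strain's per-PC response (inhibited mean
minus control mean; simple averages, not posterior means — these are
descriptive statistics). From it: magnitude divergence (signed difference of
response-vector lengths against the ancestor), direction divergence (the
distance between unit-vector endpoints, in $[0,2]$, undefined for
zero-length responses), the maximum absolute per-PC response difference, the
cumulative count of distinct top-$k$ most-divergent strains per PC (ties
broken by strain label for determinism; the occupancy formula
$n(1-(1-1/n)^{P})$ is the test oracle at $k=1$), and cross-perturbation
response correlations with their median across PCs. Scopes follow the
source analyses: magnitude/direction per cell-cycle stage, the max-abs
difference across the all-stage concatenation. The per-PC divergence metric
underlying the rankings is $|r_{strain} - r_{ancestor}|$; the original
figure's metric is implicit, and this is our reading of it.

## The selection sieve

`apply_stabilizing_selection()` implements a single hard truncation window
on the control-condition ("natural environment") genotypic values —
selection acts on latent strain effects, not on noisy cell-level data,
because the model being formalized is drawn at the level of strain means.
The window half-width `c` is interpreted on the raw latent scale, whose unit
is the generating between-strain SD (a `scale = "sd"` option uses the sample
SD instead); a target retained fraction is the alternative
parameterization. `c` is a free parameter to sweep, not a published value.
Soft Gaussian fitness weighting and sieving on both conditions are listed
extensions, not defaults.

For $\sigma_1 = \sigma_2 = 1$ and correlation $\rho$, symmetric truncation
at $\pm c$ shrinks the control variance by the truncated-normal factor
$k = 1 - 2c\,\phi(c)/(2\Phi(c)-1)$ while the inhibited condition keeps its
independent component, giving
$$\Delta\sigma_{post} = \sqrt{\rho^2 k + 1 - \rho^2} - \sqrt{k} > 0
\quad\text{for all } \rho < 1:$$
pure line-crossing turns into apparent buffering after selection, and the
effect strengthens as the sieve tightens. `pre_post_comparison()` verifies
this by Monte-Carlo against the closed form (e.g. $c=1$, $\rho=0.5$ gives
$\Delta\sigma_{post} = 0.3675$).

## Study-condition scenarios and problem sizes

`ma_like_scenario()` encodes the package's emulation of a
mutation-accumulation screen: 94 lines + ancestor, $\rho = 0.6$
(crossing-dominated), control-side between-strain SD 0.4 on the latent
scale, and potentiation injected as a reduced inhibited-condition SD —
strongly (ratio 0.5) on 7 of the 29 latent dimensions (2/2/3 per stage) and
mildly (ratio 0.9) on the remaining 22. The mild background reflects the
collection-wide negative tendency such screens report; with the background
exactly null, the count of false-positive "buffering" calls among 22
boundary-null phenotypes would be a coin flip rather than a property of the
method. This scenario was fixed as part of the package design, before any
test outcome, and is not adjusted thereafter.

Test and script problem sizes are chosen as the smallest designs at which
each property is comfortably identifiable, and are stated where they are
used: moment-partition limits at 94 strains × 200 cells (20 replicates);
sampler recovery at 50 strains × 200 cells over 20 seeded runs (4,000
iterations, 1,000 burn-in, thin 3); decision-rule calibration at 20 strains
× 50 cells over 200 datasets; LRT calibration at 12 strains × 50 cells over
500 datasets; the selection oracle at $10^5$ strains; the end-to-end MA-like
run at the full default generator size. The full-pipeline sign-recovery
property runs 100 seeds at a reduced design (50 strains, one stage, eight
traits, ~40 cells per well) using the moment path, the MCMC path being
covered by the calibration and recovery checks.

## Numerical choices, degenerate inputs, limitations

* Box-Cox: golden-section tolerance $10^{-4}$ on the exponent;
  $|\lambda| < 10^{-8}$ is treated as the log transform. For traits whose
  values sit far from zero the profile likelihood is nearly flat in
  $\lambda$; the estimate is then loose but the transform is near-affine and
  the standardized output is stable.
* Moment estimators clip negative noise-corrected variances to 0 and
  correlations to $[-1, 1]$, recording each clip; with no between-strain
  variance the correlation is reported `NA` and the fit flagged degenerate.
* The Gibbs sampler guards the 2×2 conditional covariance against negative
  round-off under `pmax(., 0)`; all variance draws are strictly positive by
  construction.
* `hpd_interval()` requires 100 draws by default (relaxable), and
  `variance_difference()` inherits that guard.
* Known limitations: Gaussian residuals only (no heavy-tailed or skewed
  residual families); no plate-position effects; no multi-collection
  consensus ("compromise") PCA — per-collection analysis only; the selection
  model is a single sieve, not multi-generation population genetics; LRT
  power at very small designs depends on the boundary-corrected reference
  and should be recalibrated by simulation if the design departs far from
  the ones tested here.
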