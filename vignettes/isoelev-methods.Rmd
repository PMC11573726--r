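---
title: "Methods: stable-isotope diet and elevational-origin inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stable-isotope diet and elevational-origin inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

isoelev implements the statistical chain used to infer what small mammals eat,
and where along an elevational gradient they foraged, from liver stable-isotope
ratios (δ¹³C, δ¹⁵N, δ³⁴S) referenced against plant baselines. This vignette
is the package's own account of the models, the numerical choices, and what
the shipped tests do and do not demonstrate.

## Lipid correction of δ¹³C

Lipids are synthesized ¹³C-depleted relative to protein, and liver lipid
content varies among individuals, so bulk liver δ¹³C confounds diet with
body condition. The package applies the standard log-linear normalization

$$\delta^{13}C_{corr} = \delta^{13}C_{bulk} + \beta_0 + \beta_1 \ln(C{:}N),$$

where C:N is the elemental carbon-to-nitrogen *mass* ratio (the tissue data
the correction literature is built on report elemental percentages, and
`read_samples()` computes C:N as %C/%N). δ¹⁵N and δ³⁴S are never corrected.

The shipped `"liver"` coefficient set (β₀ = −4.1015, β₁ = 3.8743) is
calibrated by `calibrate_lipid_coeffs()`: an ordinary least-squares fit of the
site-level correction shift against ln(C:N) across the reference mouse cohort
bundled as `phyllotis_sites()`. The calibration reproduces the single-animal
summit row exactly at the 0.1 ‰ reporting precision and the multi-animal site
means to ≤ 0.15 ‰; site means cannot be reproduced exactly because the
correction is nonlinear in C:N, so a site's mean corrected value is not the
correction evaluated at the site-mean C:N. Users with their own tissue
calibration pass `coeffs = c(beta0, beta1)` anywhere a set name is accepted.

## Elevational bins and baselines

Capture elevations are grouped into half-open 1000 m bins
[2000, 3000), [3000, 4000), [4000, 5000) and [5000, ∞); a boundary elevation
belongs to the bin whose lower bound it equals. Plant baselines are built per
bin and keep the raw δ¹⁵N/δ¹³C observations, because the Bayesian models
treat baseline values as data rather than as fixed moments.

Where a bin's plant δ¹³C is bimodal — photosynthetic pathways differ, C3
plants near −27 ‰ and C4/CAM near −13 ‰ — `split_two_sources()` partitions
the plants into two sources by the optimal two-group one-dimensional split
(exhaustive scan over the sorted values, which attains the 2-means optimum in
1-D). The ¹³C-depleted group is always `source1` (C3). If the best split
explains less than 75% of the δ¹³C variance the data do not look bimodal and
a warning suggests the one-baseline model instead; the 75% cut sits between
the ~64% a single Gaussian can achieve and the >95% of a well-separated
pathway mixture. A `source` column in the plant table overrides the
automatic split.

The default site-to-baseline mapping uses a combined 2000–3000 m baseline for
the lowest site, the two-source 3000–4000 m split for the mid-elevation site,
and plants above 4000 m (the union of the two top bins) for the high sites
and the summit individual. Published accounts of the summit baseline differ
between "plants above 4000 m" and "plants above 5000 m"; both are
expressible (`bins = "> 4000"` or `"> 5000"` in the mapping), and the
pooled wider baseline is the default because it is the better-replicated
choice for a sparse top bin.

## Trophic-position models

The deterministic estimate is
$$TP = \lambda + (\delta^{15}N_{consumer} - \delta^{15}N_{baseline}) / \Delta^{15}N,$$
with λ = 1 for a plant baseline and Δ¹⁵N the nitrogen trophic discrimination
factor. The default TDFs are the mouse-liver values Δ¹³C = 0.7 ± 0.3 ‰,
Δ¹⁵N = 4.3 ± 0.2 ‰, Δ³⁴S = −2.1 ± 0.1 ‰ (`tdf_liver()`).

`fit_tp()` wraps three Bayesian models sampled with JAGS (rjags):

* **oneBaseline** (population): baseline obs ~ N(μ_b, σ_b); consumer obs ~
  N(μ_b + Δ¹⁵N·(TP − λ), σ_c); Δ¹⁵N ~ N(4.3, 0.2); TP uniform.
* **twoBaselinesFull**: both elements modelled; consumer means mix the two
  source means by a diet proportion α ~ U(0, 1) (α = share of the C3
  source) and shift by the elemental TDF times (TP − λ). Lipid-corrected
  δ¹³C is the carbon input.
* **individualOneBaseline**: for a single animal. μ_b ~ N(plant mean, plant
  SD); σ_b ~ Cauchy(location = plant SD, scale 3) truncated to [0, ∞); the
  one observation is N(μ_b + Δ¹⁵N·(TP − λ), σ_b).

Priors the source material leaves open were set once: TP ~ U(λ − 0.5, 10),
permissive enough to express sub-baseline consumers yet bounded for sampler
stability; residual SDs get half-Cauchy(0, 3) priors, matching the scale-3
Cauchy used for the individual model's baseline SD. All are exposed through
`tp_config()`.

Default MCMC settings are 3 chains, 1000 adaptive iterations, 20 000
sampling iterations, 1000 burn-in, thinning 10 for the population models,
and 16 chains × 625 kept draws (10 000 pooled) after 1000 warm-up for the
individual model. A phrase sometimes used for such runs, "thinning of 1000
samples as warm-up", is interpreted here as 1000 warm-up iterations with no
thinning — thinning by 1000 while keeping 10 000 draws would require 10⁷
iterations for no inferential gain.

### Numerical choices

* **Initial values.** Chains start from data-informed values (TP at the
  deterministic estimate clamped into the prior, means at sample means, SDs
  at sample SDs floored at 10⁻³). This matters in near-degenerate
  configurations (tight priors, tiny variances) where a prior-drawn start
  can have numerically zero likelihood.
* **Truncated-Cauchy sampling.** With a single observation, the individual
  model's σ_b is essentially prior-dominated, and slice sampling a heavy
  Cauchy tail directly mixes poorly. σ_b is therefore sampled through its
  inverse CDF — u uniform on the truncated quantile range,
  σ_b = loc + scale·tan(π(u − ½)) — an exact reparametrization on a bounded
  domain. Split-R̂ for σ_b drops from occasionally > 1.5 to < 1.05.
* **Summaries.** The point estimate is the posterior mode: argmax of a
  Gaussian KDE (Silverman bandwidth) on a 512-point grid over the pooled
  draws (≥ 1000 required); intervals are central 2.5%/97.5% quantiles.
* **Convergence.** Split-R̂ on every monitored parameter; ≥ 1.1 is an error
  unless `allow_nonconverged`, ≥ 1.05 flags the fit as not converged.
* **Determinism.** Per-chain RNG streams are seeded from the single
  configuration seed, so identical configuration ⇒ identical draws.

## PERMANOVA and CAP

Among-site differences are tested with one-way PERMANOVA on Euclidean
distances over (lipid-corrected δ¹³C, δ¹⁵N, δ³⁴S). Variables enter
unstandardized — all three share the ‰ scale — and the pseudo-F is computed
from interpoint sums of squared distances, with significance from raw-label
permutations: p = (#{F* ≥ F} + 1)/(n_perm + 1), never below 1/(n_perm + 1).
On univariate Euclidean input the pseudo-F reduces algebraically to the
classical ANOVA F, which the tests verify to 10⁻¹⁰ against `aov()` (and the
multivariate statistic against `vegan::adonis2`). Pairwise post hoc
comparisons report t = √F of each two-group test with unadjusted permutation
p-values. Single-animal sites are excluded (no within-group variance).

CAP (canonical analysis of principal coordinates) embeds the distance matrix
by Gower-centered eigen-decomposition, retains m orthonormal PCo axes, and
relates them to group membership by canonical correlation; the trace (sum of
squared canonical correlations, ≤ min(m, g−1)) is tested by label
permutation with m held fixed. Choices:

* **m selection.** If unset, m maximizes leave-one-out classification
  success over 1..min(N−2, 20) axes, smallest m on ties.
* **Scaling.** Canonical scores are scaled to unit pooled within-group
  variance, which makes nearest-centroid assignment on full-rank Euclidean
  input identical to classical LDA under equal priors (verified against
  `MASS::lda`).
* **Held-out projection.** New or held-out samples enter by the Gower
  add-a-point formula, u = −½Λ⁻¹U′(d²_new − diag(G)), which reproduces a
  training point's own coordinates to 10⁻⁸. Classification ties break to
  the lexicographically first label and are flagged.
* **Negative eigenvalues** (impossible for Euclidean input) are dropped
  with a warning; corrections are out of scope.

## Synthetic data

The generators exist so that every stage runs and is testable without the
original field data. `simulate_sites()` draws per-individual values from the
per-site summary moments of the reference cohort (41 animals over seven
sites from 2370 m to 6739 m), with C:N from a truncated Normal(3.8, 0.5) on
[3.0, 6.0] and a −0.3 correlation between C:N and bulk δ¹³C, reflecting the
reported within-site lipid effect; other variables are independent because
no within-site covariance structure is published. `simulate_plants()` draws
per-bin Gaussian mixtures whose defaults mirror the regional flora:
δ¹⁵N ≈ 5–6 ‰ below 4000 m falling to ≈ 1.8 ‰ above (so that a consumer at
δ¹⁵N ≈ 7 ‰ sits one trophic step up, TP ≈ 2.2, at the default TDF), and a
bimodal C3/C4 δ¹³C mixture in the 3000–4000 m bin.
`simulate_consumers_known_tp()` inverts the TP equation to produce cohorts
with known TP and α for recovery studies.

What passing tests on these data show — and do not show. They demonstrate
that the estimators recover the parameters of their own generating model,
that the permutation engines are calibrated, and that the pipeline is
deterministic. They do not validate the TDF values, the lipid calibration's
transfer to other tissues, or the assumption that plant baselines sampled in
one survey transfer to consumers caught in another — those are scientific
assumptions carried by the design, not testable from synthetic data.

## Problem sizes used by the shipped tests

Chosen to exercise each claim at meaningful resolution while keeping the
suite quick: PERMANOVA/ANOVA equivalence over 50 random univariate fixtures;
type-I error over 1000 simulated null datasets × 199 permutations (15
samples, 3 groups); population-model recovery over 100 simulated cohorts
(n = 8 consumers, baseline n = 20) at TP ∈ {1.5, 2.2, 3.0} with reduced MCMC
(2000 iterations, no thinning — the posterior is low-dimensional and mixes
in hundreds of iterations); individual-model coverage over 50 replicates;
and the end-to-end pipeline on the 41-animal fixture bundle with 999
permutations and 4000-iteration chains.

## Known limitations

* The population and two-source likelihoods are reconstructions of the
  standard model family for this analysis; the exact priors of any given
  published run are not recoverable and modest prior differences move modal
  TP by less than the reporting precision in the regimes tested.
* The two-source model assumes both sources share the consumer TDF and that
  α is constant across individuals of a site.
* Confusion-table percentages are plain-rounded; a printed table that mixes
  rounding conventions (e.g. 7/8 shown as 86%) will differ by one point.
* PERMANOVA here is one-way only; no nested or multi-factor designs, and no
  distance measures other than Euclidean.
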