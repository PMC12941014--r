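---
title: "Spatio-temporal models for areal count panels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatio-temporal models for areal count panels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stareal)
```

## The model family

`stareal` fits hierarchical count models on an areal lattice of n tracts
observed over T calendar periods. The likelihood is

$$Y_{it} \sim \mathrm{Poisson}(P_i \lambda_{it}),$$

optionally replaced by a negative binomial with the same mean and
dispersion $\theta$ (variance $\mu + \mu^2/\theta$) when counts are
overdispersed. $P_i$ is a known, time-constant population at risk entering
as a log offset, so the model describes per-capita rates. The log rate is
additive:

$$\log \lambda_{it} = \beta_0 + x_{it}'\beta + (\text{temporal terms}) +
  s_i + v_i,$$

where $x_{it}$ holds tract-level covariates that step at calendar-year
boundaries. Every model carries the BYM convolution pair: an intrinsic CAR
field $s$ with conditionals
$s_i \mid s_{-i} \sim N(\bar s_i, 1/(\tau_s m_i))$ ($\bar s_i$ the mean
over the $m_i$ neighbours), whose joint precision $\tau_s (D - W)$ has
rank $n - 1$ and requires the sum-to-zero constraint, plus i.i.d.
heterogeneity $v_i \sim N(0, 1/\tau_v)$. CAR-type neighbourhood structure
is preferred here over distance-decay covariances because urban deprivation
patterns are patchy: advantaged and disadvantaged tracts can be close
together, which an inverse-distance correlation cannot represent well.

The five temporal structures (`modelSpec(1)` … `modelSpec(5)`) are: year
indicators with the first year as reference; a single indicator for the
last two of four years (the pandemic period); a first-order random walk
$\gamma_t \sim N(\gamma_{t-1}, 1/\tau_\gamma)$ plus i.i.d. period effects
$\phi_t \sim N(0, 1/\tau_\phi)$ at yearly resolution; the same at monthly
resolution; and the monthly model augmented by an i.i.d. space–time
interaction $\delta_{it} \sim N(0, 1/\tau_\delta)$ (the "Type I"
interaction — the simplest of the four classical interaction types, and
the only one implemented). Without the interaction, space and time are
additive, so two tracts' fitted log-rate curves are parallel except where
covariates step at the December→January boundary; the interaction is what
allows tracts to move in different directions within a year.

### Identifiability conventions

* $s$ is kept on the sum-to-zero subspace; its level lives in the
  intercept.
* The random-walk start is pinned at $\gamma_0 = 0$, so the walk's level
  is also absorbed by the intercept. $\gamma_1 \sim N(0, 1/\tau_\gamma)$
  remains a proper prior.
* $s$ and $v$ (and likewise $\gamma$ and $\phi$) are only weakly
  identified individually — their sum is what the data constrain. This is
  intrinsic to BYM-type models; posterior summaries of the individual
  precisions should be read with that in mind.

### Priors

Defaults follow common disease-mapping practice: a flat (precision 0)
normal prior on the intercept, vague $N(0, \text{prec}=0.001)$ priors on
slopes, and $\mathrm{gamma}(1, 0.00005)$ on every precision — an
exponential with mean $1/0.00005 = 20{,}000$. The negative-binomial
log-dispersion gets a vague normal prior (the dispersion scale is a
declared configuration choice; different parameterisations of the NB in
other software make cross-package comparison of this one hyperparameter
approximate). `priorSensitivity()` refits under all $2^3$ combinations of
{default, alternative} for the intercept, slope and precision priors; the
shipped alternatives are $N(0, 0.001)$, $N(0, 0.1)$ and
$\mathrm{gamma}(0.5, 0.0005)$, all overridable.

## Posterior computation

Inference is by Markov chain Monte Carlo, implemented in C++:

* **Fixed effects** are updated jointly by adaptive Metropolis: the
  proposal covariance is the running empirical covariance of the chain
  (scaled, target acceptance 0.25), built during warm-up and then frozen.
  Design columns other than the intercept are centred internally, which
  removes most intercept–slope correlation; the intercept draw is mapped
  back to the raw scale afterwards, and fixed-effect priors apply to the
  centred coordinates.
* **Latent fields** ($s$, $v$, $\gamma$, $\phi$, $\delta$) use single-site
  random-walk Metropolis with per-element proposal scales tuned to 44%
  acceptance during warm-up. Elements with no observed likelihood (masked
  cells) are drawn exactly from their conditional priors.
* **The ICAR constraint** is enforced by re-centring $s$ every sweep and
  moving the subtracted mean into the intercept, which leaves the
  likelihood and the (shift-invariant) ICAR prior unchanged and is exact
  under the flat intercept prior.
* **Precisions** have conjugate gamma full conditionals, e.g.
  $\tau_s \mid s \sim \mathrm{gamma}(a + (n - c)/2,\; b + \tfrac12
  \sum_{i \sim j}(s_i - s_j)^2)$ with $c$ the number of graph components.
* **NB dispersion** is updated by random-walk Metropolis on
  $\log\theta$.

Chains are independent (initial values jittered); split-chain Rhat and an
autocorrelation-based effective sample size are computed for every
reported parameter. A fit whose worst Rhat exceeds 1.05 or whose smallest
ESS is below 100 (both configurable) is *flagged* — the object carries
`converged = FALSE` and a warning is raised — never silently accepted.
The single-site/joint Metropolis scheme was chosen over a Laplace-type
approximation because it is simple to validate exactly: the sampler is
checked against the closed-form conjugate Poisson–gamma posterior, and
slope recovery is checked by repeated-simulation coverage at the package's
test scale.

Numerical details worth knowing: cell order is tract-fastest; masked cells
(`mask` argument) contribute no likelihood, which turns the sampler into a
prior sampler when everything is masked (used by the prior-reproduction
test); isolated tracts keep $s_i = 0$ since the ICAR conditional is
undefined there; ICAR simulation uses the exact eigendecomposition of the
graph Laplacian, restricted to eigenvectors with positive eigenvalue — an
$O(n^3)$ choice that is exact and entirely adequate at desk scale
($n \lesssim 500$), which is why it is also used as the test oracle's
sampling route.

## DIC

`dic()` reports $\mathrm{DIC} = \bar D + p_D$ with
$\bar D$ the mean over retained draws of $-2 \log L$ (unsaturated) and
$p_D = \bar D - D(\hat\lambda)$, the point estimate taken at the posterior
mean of the cell rates $\lambda_{it}$ (and, for the NB, the posterior mean
dispersion). This plug-in convention is applied identically across
compared models, which is all a DIC ranking requires. `compareDIC()`
encodes the usual reading that differences of 2 or less indicate a similar
degree of fit.

## Moran's I

$$I = \frac{N}{S_0}\;\frac{\sum_{ij} w_{ij}(x_i - \bar x)(x_j - \bar x)}
  {\sum_i (x_i - \bar x)^2},$$

with binary (default) or row-standardised weights and null expectation
$-1/(N-1)$. Inference is a one-sided (greater) permutation test,
$p = (1 + \#\{I^{perm} \ge I\})/(1 + n_{perm})$, ties counted in the
numerator (conservative), 999 permutations by default. The statistic is
computed on per-tract rates (counts over population) by default — the
epidemiological convention, matching how areal rates are mapped — though
any per-tract value can be supplied. Both the weight scheme and the
p-value method are configurable because published tables rarely state
them.

## The synthetic-data generator

The generator is the package's stand-in for confidential discharge data.
Its defaults describe a study of roughly 50–100 contiguous urban tracts
observed 2018–2021:

* populations at risk log-uniform on [200, 3000] (tract counts of women
  aged 15–49);
* five ACS-style covariates (% private insurance, % public insurance,
  median age, median income in $1000s, % high-school diploma) with
  spatially smooth baselines (an ICAR draw per covariate) and small
  independent yearly steps (10% of the cross-tract spread per year, the
  "changes slightly each January" regime); percentages clipped to
  [0, 100]. The step size is a free parameter — no empirical value for
  "small year-to-year change" is available — and 0.1 was fixed once as a
  visually realistic magnitude;
* intercept $\beta_0 = -4$ (about 1.8 visits per 100 women-years, giving
  tract-year counts in the tens, the scale of a mid-size city's
  mental-health ED panel);
* slopes of order 0.01 per covariate unit and year effects
  (0.07, −0.18, −0.28) echoing the magnitude and sign pattern of published
  urban ED analyses: a small pre-pandemic rise then a sustained drop;
* precisions $\tau_s = 10$, $\tau_v = 25$, $\tau_\gamma = \tau_\phi =
  \tau_\delta = 100$ — moderate spatial structure (sd of $s$ about 0.3 on
  the log scale), smaller unstructured noise, monthly drifts of a few
  percent.

Every generator accepts a seed and is bit-reproducible given it. What the
generator does **not** emulate: time-varying populations (held at one
census estimate, as typical), visit-level covariates, diagnostic
misclassification, tract boundary changes, and spatially structured
*interaction* terms (the interaction is i.i.d. by construction — Type I).
Passing recovery tests on these panels therefore demonstrates internal
statistical correctness of the machinery, not robustness to the
misclassification and confounding a real discharge dataset carries.

## Visit categorisation

`defaultCategoryMap()` implements the eight-category ICD-10 grouping used
in ED mental-health surveillance (Depression, Bipolar Disorder, Anxiety,
PTSD, OCD, Psychosis, Substance Abuse, Other). Codes match exactly, except
the undotted substance-use stems F10–F19, which match by prefix — listed
bare, they would otherwise match nothing in real ICD-10-CM data, where
substance codes always carry subcodes. A visit with diagnoses in several
categories counts once in each; visits with no mappable code are excluded
from panels but reported, since the study population is defined by having
a qualifying diagnosis. The map includes a handful of unusual entries
(e.g. `F32A` without a dot, symptom codes `R45.7`/`R46.81` inside
diagnosis categories) kept verbatim from the surveillance grouping; users
with a different code dialect can supply their own `CategoryMap`.

## Design choices where the design was open

* **Quartile convention**: linear interpolation (R type 7), the common
  statistical default; the quartile-contrast effect only depends on it
  through the two quartile values, which are also printable inputs.
* **Contiguity from polygons**: queen (a shared point suffices) by
  default, rook available; derived by shared-vertex matching since the
  environment's geometry stack does not include a contiguity routine.
  This is exact for topologically consistent polygon layers (census
  products) and approximate otherwise.
* **Tract ordering**: lexicographic, fixed at lattice construction; every
  array in the package follows it.
* **Period bins**: half-open calendar bins on the visit date.
* **Pandemic indicator**: the last two years of a four-year yearly panel;
  the model errors on any other shape rather than guessing.
* **VIF**: computed over pooled tract-year rows with calendar year as an
  optional numeric predictor — matching how a single "Year" row appears in
  screening tables, deliberately unlike the indicator coding used in the
  fitted models.
* **Income units**: thousands of dollars in the generator; treated as a
  declared configuration rather than a convention, since published
  coefficient tables are not always consistent about the scaling.

## Problem sizes used by the tests

The shipped tests run at desk scale, chosen so the full suite completes in
a couple of minutes while keeping every check statistically meaningful:
5×5–7×7 lattices, yearly panels (T = 4) for recovery and DIC-selection
checks (50 and 25 replicates respectively), monthly panels (T = 48) for
the parallel-curves property, 20,000 ICAR draws for the covariance oracle,
and 2,000–4,000 retained MCMC draws per fit. The same machinery scales to
~100–200 tracts and T = 48 in seconds per fit.

## Known limitations

* The interaction model stores and updates $nT$ cell effects; fine at
  desk scale, but the single-site updates make it the slowest component.
* BYM precision hyperparameters mix slowly when their field is shrunk to
  near zero (the classic funnel); the convergence flag reports this
  honestly rather than hiding it. Interpret $\tau_s$, $\tau_v$ jointly.
* DIC is reported because it is the conventional comparison for these
  models; its known optimism with many weakly identified random effects
  is shared by all models compared, so rankings are meaningful but
  absolute values are not.
* No Types II–IV space–time interactions, no distance-based covariance
  alternatives, no geocoding: inputs are already tract-linked.
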