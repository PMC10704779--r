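---
title: "Models and methods behind cavegrowth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cavegrowth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cavegrowth)
```

cavegrowth implements the quantitative core of a fish life-history study:
how fast a population grows, how reliably its ages can be read, how weight
scales with length, how its growth performance compares with related
species once phylogeny is accounted for, and how much energy its tissue
stores. The motivating system is a slow-growing subterranean loach — a
small, blind, cave-restricted fish whose life history (late maturity around
4.8 yr, maximum ages above 15 yr, high lipid reserves) is typical of
food-limited cave habitats — but every function takes plain tabular input
and applies to any species with length, weight, age and composition data.

## Growth model

Length-at-age follows the von Bertalanffy growth function (VBGF)

$$L(t) = L_\infty\,\bigl(1 - e^{-K (t - t_0)}\bigr),$$

with asymptotic length $L_\infty$ (cm), Brody growth coefficient $K$
(yr$^{-1}$) and theoretical age at zero length $t_0$ (yr). `fit_vbgf()`
minimises the residual sum of squares by Levenberg–Marquardt nonlinear
least squares. Design choices a user should know about:

* **Starting values** are data-driven: $L_\infty^0 = 1.1\max L$, $K^0$
  from the slope of $\log(1 - L/L_\infty^0)$ on age (a Ford–Walford-style
  linearisation), $t_0^0 = 0$. On noiseless data the optimum is reached
  from wide ranges of perturbed starts (tested at 100 random starts,
  $10^{-4}$ relative tolerance).
* **No box constraints by default.** Poorly informative data — e.g. an
  adults-only sample with no small fish to anchor the rising limb — can
  push $\hat L_\infty$ far beyond any observed length with huge standard
  errors. That is a finding about the data, and the package reports it
  (flags, SEs, non-significant t-tests) rather than clipping it away.
  Bounds can be imposed by passing explicit `start` values and examining
  convergence, but are deliberately not the default.
* **Inference**: per-parameter SEs come from the Jacobian-based
  covariance $s^2 (J^\top J)^{-1}$ at the optimum, $t = \hat\theta/SE$,
  and two-sided P-values on $n - 3$ degrees of freedom. This convention
  was validated against an independently published partitioned growth
  table: recomputing every printed $t$ from its printed estimate and SE,
  and every printed $P$ from the printed $t$ at $df = n - 3$, reproduces
  the published values within print rounding (see the acceptance tests).
* **Partitions**: `fit_vbgf_partitions()` fits five series — all fish,
  females, males, females + juveniles, males + juveniles — with the
  unsexed juveniles duplicated into both mixed series. Partitions under
  4 fish are flagged infeasible rather than fitted.

Growth performance is summarised by
$\Phi' = \log_{10} K + 2\log_{10} L_\infty$ (`growth_performance()`),
which is constant along slope $-2$ lines in
$(\log_{10} L_\infty, \log_{10} K)$ space; `auximetric_table()` and
`phi_iso_lines()` emit plot-ready coordinates and those iso-contours.

## Length–weight allometry

`fit_lwr()` fits $W = a L^b$ by OLS of $\log_{10} W$ on $\log_{10} L$;
$b = 3$ is isometric growth, tested by `test_isometry()` with
$t = (b - 3)/SE(b)$ on $n - 2$ df. `test_sex_effect()` is the
ANCOVA-style comparison: the slope test is the t on the
sex-by-log-length interaction in the full model, the intercept test the t
on the sex indicator in the common-slope model; juveniles are excluded
because they are a life stage, not a sex.

Composition trends (`fit_trend()`) are untransformed OLS of analyte
content (mg g$^{-1}$) on total length (cm). `compare_trend_slopes()`
compares two slopes with $t = (b_2 - b_1)/\sqrt{SE_1^2 + SE_2^2}$ on
$n_1 + n_2 - 4$ df; because published analyses of this kind compare
analytes measured on the same fish without stating a pairing, the
independent-SE form is the default and a paired difference-series form
(`compare_trend_slopes_paired()`) is provided for same-individual
comparisons, which is statistically the sharper choice when it applies.

## Age-reading precision

With $R$ reads $X_{ij}$ per fish $j$ (three is the conventional number)
and per-fish mean $\bar X_j$:

* APE$_j = 100 \cdot \frac{1}{R}\sum_i |X_{ij} - \bar X_j|/\bar X_j$
  (Beamish–Fournier average percent error),
* CV$_j = 100\, s_j / \bar X_j$ with the sample SD (divisor $R-1$; a
  population-SD option exists).

`age_ape()`/`age_acv()` return the unweighted mean over fish, so fish
with more reads are not upweighted. Both indices are zero exactly when
all reads agree, are invariant to rescaling all reads, and for $R = 2$
satisfy ACV $= \sqrt 2\,$APE identically. `consensus_age()` defaults to
the per-fish median — deterministic, since software has no re-reading
step — and the modal rule flags ties and three-way disagreement as the
in-silico analogue of "re-evaluate the structure".
`compare_structures()` regresses vertebra on otolith consensus ages;
because a published agreement line of the form "vertebrae = otoliths −
0.035" leaves open whether its slope was fixed at 1 or merely rounded to
it, both a free-slope (default) and a slope-fixed-at-1 mode exist, and
neither is claimed to be the published convention.

## Phylogenetic regression

`fit_pgls()` regresses $\log_{10} K$ on $\log_{10} L_\infty$ across
species under error covariance $\sigma^2 C(\lambda)$, where $C$ is the
shared branch-length (Brownian-motion) matrix and Pagel's $\lambda$
multiplies its off-diagonal entries. $\lambda$ is profiled by ML over
$[0, 1]$ with bounded scalar optimization plus explicit endpoint checks.
Choices made where the method leaves room:

* **Pagel's $\lambda$** is the branch-length transformation, as it is the
  default transformation optimized by the R toolchain this kind of
  analysis conventionally uses; fixed-$\lambda$ mode supports sensitivity
  grids.
* **ML, not REML**, matching the "maximum likelihood" convention.
* **$R^2$** is $1 - RSS/TSS$ in the GLS-whitened space against the
  whitened intercept-only model — definitions of PGLS $R^2$ vary, so the
  definition is carried in the fit object.
* At $\lambda = 0$, or on a star phylogeny, the estimator reduces to OLS
  exactly (tested to $10^{-10}$), and fixed-$\lambda$ fits match the
  `nlme::gls` + `ape::corPagel` reference implementation to $10^{-8}$,
  including the log-likelihood.
* Species–tip name matching is case-insensitive with spaces and
  underscores equivalent; unmatched names are an error listing the
  offenders, never a silent drop.

With only six species, $\hat\lambda$ and the PGLS P-value are weakly
determined and depend on the exact pruned tree; the package therefore
asserts OLS/PGLS *slope agreement* properties rather than any particular
six-species PGLS P-value.

## Energy density

`energy_content()` computes
$E = (P c_P + L c_L + G c_G)/1000$ kJ g$^{-1}$ from protein, lipid and
glycogen contents in mg g$^{-1}$, with combustion coefficients defaulting
to 23.6, 39.5 and 17.2 kJ g$^{-1}$ (configurable via
`energy_coefficients()`); ash is measured but carries no energy. Whether
contents are per wet or per dry mass is left opaque — the formula is
basis-agnostic and the package never converts. `pool_small_individuals()`
implements the assay practice of pooling small fish of comparable size:
greedy from the smallest, a fish joins the current pool while its length
is within 2 mm (0.2 cm) of the pool's first member. The grouping
algorithm is stated because the practice is usually reported without one;
greedy-from-smallest makes results reproducible, and under an exactly
linear composition–length relationship pooling provably leaves trend
slopes unchanged (tested).

## The synthetic-data generator

`simulate_cohort()` and friends invert the analysis models, so every
estimator can be exercised against known truth:

* ages uniform on 3.3–15.8 yr (observed span; uniform is the transparent
  default where the true age distribution is unknown);
* true lengths on the VBGF at $L_\infty = 23.4$, $K = 0.060$,
  $t_0 = 0.12$, plus additive Gaussian length error (default SD 0.5 cm,
  a caliper-plus-curve residual scale consistent with the reference
  fits); non-positive draws are redrawn and counted;
* weights $W = 0.0046 L^{3.03} e^{\varepsilon}$ with
  $\varepsilon \sim N(0, 0.1)$ — multiplicative lognormal error is the
  standard residual model for power-law length–weight data;
* juveniles below 4.8 yr, otherwise female/male at an even ratio;
* repeated age reads add structure-specific Gaussian error (otolith SD
  0.5 yr, vertebra 0.8 yr, reflecting the published finding that otoliths
  read more precisely), optionally rounded to whole years;
* composition analytes are linear in length plus Gaussian noise, with
  zero-truncation counted and reportable or disableable; the default
  lipid trend rises at 11.3 mg g$^{-1}$ cm$^{-1}$ while protein, glycogen
  and ash drift weakly, emulating the published pattern on a wet-mass
  scale that keeps energy densities in the published 4.5–11.4 kJ g$^{-1}$
  region;
* `simulate_species_set()` draws $\log_{10} L_\infty$ uniform on
  (0.9, 1.4) and $\log_{10} K$ from the slope $-1.64$ / intercept $1.09$
  allometry with marginal residual SD 0.07 (matching $R^2 \approx 0.9$
  over that span), i.i.d. or Brownian on a supplied tree;
* `simulate_tree()` is a constant-rate pure-birth (Yule) process.

Every generator is a pure function of (config, seed). What the generator
does **not** emulate: seasonal sampling structure, capture bias toward
accessible pool habitat, integer-banding-to-fractional-age conversion
(true ages are continuous, sidestepping the unstated birth-date
convention behind published fractional ages), age-dependent reading
error, and covariance between composition analytes beyond their shared
length trend. Tests passing on synthetic cohorts therefore validate the
estimators and their inference conventions, not the field realism of any
particular dataset.

## Numerical conventions and degenerate inputs

* Logs are base 10 wherever a log is taken.
* Optimizer tolerances: VBGF $10^{-10}$ on objective/parameter relative
  change; $\lambda$ profile $10^{-8}$.
* A constant response yields slope 0 and $R^2$ defined as 0 (not NaN).
* Straight-line fits require $n \ge 3$ and non-degenerate predictors;
  VBGF fits require $n \ge 4$ and non-constant ages; violations are
  errors naming the problem, and non-convergence is flagged on the
  returned object, never silent.
* Replicate sizes used by the test-suite simulations (60–200 replicates,
  cohorts of 30–1000 fish) were chosen to keep Monte-Carlo error well
  below the tolerances asserted while the whole suite stays fast.

## Known limitations

* Only the classical VBGF is offered — no seasonal oscillation, Gompertz
  or logistic alternatives, and no information-criterion model
  competition.
* PGLS assumes the supplied tree is accurate and the trait covariance is
  Brownian-with-$\lambda$; no Ornstein–Uhlenbeck or measurement-error
  extensions.
* The composition slope comparison treats trend SEs as independent in its
  default form (see above).
* Observation error in age (the x-axis of the growth fit) is not modelled
  as errors-in-variables; with reading SDs near half a year it mildly
  attenuates $K$, which is visible in (and bounded by) the recovery
  simulations.
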