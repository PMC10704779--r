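# cavegrowth

Life-history analysis for slow-growing fishes: von Bertalanffy growth,
length–weight allometry, age-reading precision, phylogenetically corrected
growth-performance comparison, and body-composition energy density — with a
seeded synthetic-cohort generator so the whole pipeline is testable without
specimen data.

The package grew out of the analysis of a subterranean loach
(*Triplophysa rosa*), a blind cave fish that matures around 4.8 years,
lives past 15, grows toward an asymptotic length of ~23 cm at a rate of
only ~0.06 yr⁻¹, and stores unusually high lipid reserves — the classic
slow/small/high-storage life history of food-limited caves. Everything it
does, however, takes ordinary tabular input (one row per fish, or one row
per species) and applies to any population.

## What it computes

* **Growth.** `fit_vbgf()` fits L(t) = L∞(1 − e^(−K(t−t₀))) by
  Levenberg–Marquardt nonlinear least squares, with SEs from the Jacobian
  covariance, t = estimate/SE and two-sided P on n − 3 df.
  `fit_vbgf_partitions()` runs the five standard series (total, female,
  male, female+juvenile, male+juvenile). `growth_performance()` gives
  Φ′ = log₁₀K + 2log₁₀L∞.
* **Allometry.** `fit_lwr()` fits W = aL^b on log–log axes;
  `test_isometry()` tests b against 3; `test_sex_effect()` is the
  sex-covariate (ANCOVA-style) slope/intercept comparison; `fit_trend()`
  and `compare_trend_slopes()` handle composition-versus-length lines.
* **Ageing precision.** `age_ape()`, `age_acv()` (Beamish–Fournier APE and
  average CV over replicated reads), `consensus_age()`, and
  `compare_structures()` for otolith-versus-vertebra agreement.
* **Interspecific comparison.** `fit_loglog_allometry()` (OLS of log₁₀K on
  log₁₀L∞), `fit_pgls()` (GLS with ML-optimized Pagel's λ on a supplied
  tree), `compare_groups()`, `auximetric_table()` + `phi_iso_lines()` for
  auximetric plots (`plot_auximetric()`).
* **Energy.** `energy_content()` = (23.6·protein + 39.5·lipid +
  17.2·glycogen)/1000 kJ g⁻¹ (coefficients configurable);
  `pool_small_individuals()` implements 2-mm pooling of small fish.
* **Simulation.** `simulate_cohort()`, `simulate_readings()`,
  `simulate_composition()`, `simulate_species_set()`, `simulate_tree()` —
  pure functions of (config, seed) whose defaults match the reference
  cave-loach conditions.
* **Orchestration.** `run_pipeline()` executes every stage from one config
  and `make_report()` renders a markdown summary; `write_results()` saves
  CSVs plus a JSON manifest. Fit objects have `tidy()`/`glance()` and
  `autoplot()` methods.

## Worked example

```r
library(cavegrowth)

# six-species growth-parameter table bundled for the worked example
sp <- triplophysa_growth()
fit_loglog_allometry(sp)
#> Linear fit: log10_K = 1.092 + -1.645 * log10_L_inf  (R^2 = 0.910, n = 6, P[slope] = 0.00315)

round(growth_performance(sp$L_inf, sp$K), 2)
#> [1] 1.52 1.40 1.68 1.56 1.48 1.52
```

The allometry says: across these six loaches, every tenfold increase in
asymptotic length trades off against a ~44-fold (10^1.645) decrease in
growth coefficient, with 91% of the log-K variance explained — the classic
negative K–L∞ allometry. The Φ′ values collapse each (L∞, K) pair onto one
growth-performance scale; the cave species (first row, Φ′ = 1.52) sits
inside the range of its surface relatives, so its slow growth is a
genus-wide trait rather than a cave-specific one.

A full synthetic run, end to end:

```r
bundle <- run_pipeline(pipeline_config(seed = 2024))
writeLines(make_report(bundle)[1:16])
#> # Life-history analysis report
#>
#> ## Cohort
#> Total n = 102
#> - female: n = 51, length 6.5-14.6 cm, weight 1.32-15.82 g, age 5.6-15.5 yr
#> - male: n = 36, length 4.8-14.4 cm, weight 0.59-15.97 g, age 4.9-15.5 yr
#> - juvenile: n = 15, length 3.7-6.5 cm, weight 0.27-1.34 g, age 3.3-4.8 yr
#>
#> ## Age-reading precision
#> - otolith: APE = 3.90%, ACV = 5.32% (n = 102 fish)
#> - vertebra: APE = 6.98%, ACV = 9.51% (n = 102 fish)
#> - agreement: vertebra = -0.065 + 1.010 x otolith (R^2 = 0.972, n = 102)
#>
#> ## Length-weight relationship
#> W = 0.00459 * L^3.04 (R^2 = 0.993, n = 102)
#> Isometry test vs b = 3: t = 1.506, df = 100, P = 0.135
```

The simulated cohort is read more precisely from otoliths than vertebrae
(lower APE/ACV), its length–weight exponent is statistically isometric
(b ≈ 3), and the growth table in the remainder of the report reproduces the
characteristic pattern that only the partitions containing young fish
identify the growth curve well.

## Package layout

* `R/` — implementation (io, simulate, ageing, allometry, growth,
  interspecific, energy, pipeline, plots).
* `tests/testthat/` — unit, property and acceptance tests; fixtures are
  generated in code.
* `vignettes/cavegrowth-methods.Rmd` — the models, their assumptions, all
  tunable parameters, and the design decisions.
* `scripts/acceptance.R` — the reproduction script above.
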