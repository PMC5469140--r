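# inbrex

Analysis of **lineage extinction under enforced inbreeding** in relation
to **sexually antagonistic (SA)** and **sexually concordant (SC)**
genetic variation for fitness.

When isofemale lines — each founded from a single wild-caught mating
pair — are pushed through repeated single-pair full-sib matings,
homozygosity rises rapidly and lineages go extinct. If a population
harbours SA variation (a negative intersexual genetic correlation for
fitness), the question arises whether *male-benefit/female-detriment*
genotypes tolerate that inbreeding worse than female-benefit genotypes,
over and above the burden of generally low fitness (mutation load).
`inbrex` provides the statistical machinery for that question, aimed at
evolutionary biologists and quantitative geneticists working with
isofemale-line or inbred-panel designs.

## What it implements

* **Derived fitness axes.** Per-line mean fitness is log-transformed,
  variance-standardized within sex, and rotated 45° clockwise:
  *antagonism* = (m − f)/√2, *concordance* = (m + f)/√2
  (`fitness_axes()`).
* **Mixed-effects Cox model.** Lineage extinction hazard
  h(t) = h₀(t) · exp(x'β + b_line), with a Gaussian frailty
  b_line ~ N(0, σ²) shared by all lineages of a line. Fitted by
  penalized partial likelihood (Efron ties) with a Laplace-approximate
  integrated likelihood for σ² (`coxfr()`, with `summary`, `ranef`,
  `anova`, `lrt`, `delta_aic` methods).
* **Influence diagnostics.** Exact leave-one-out dfbeta screening of
  the fixed-effects model, grouped by line (`dfbeta_screen()`).
* **Extinction forecasts without inbreeding.** A fecundity-only
  demographic simulator (single mating pair per generation; survival
  requires ≥ 1 offspring of each sex) and geometric/linear projections
  of first-generation extinction rates
  (`forecast_fecundity_extinction()`, `project_first_generation()`).
* **Follow-up assay analyses.** Zero-rate chi-square tests, linear
  mixed models for non-zero offspring counts, and PC1-based selection
  of extreme lines (`test_zero_rates()`, `fit_offspring_lmm()`,
  `select_extreme_lines()`).
* **Synthetic-data generator.** Every input above with known ground
  truth (`sim_config()`, `simulate_study()`), defaulting to the study
  conditions: 41 lines × 20 lineages, 10 generations, r_MF = −0.51,
  planted log hazard ratios 0.20 / −0.14, frailty variance 0.14, and a
  baseline hazard calibrated to 77.8% overall extinction.
* **End-to-end pipeline.** `run_pipeline()` chains all stages and
  returns a reproducible report.

See `vignettes/lineage-extinction-methods.Rmd` for the models,
estimation details, and design choices.

## Worked example

```r
library(inbrex)
cfg <- sim_config(seed = 2, time_mode = "discrete")
rep <- run_pipeline(cfg, forecast_replicates = 100)
print(rep)
```

```
Lineage-extinction pipeline report (package version 0.1.0, seed 2)

Antagonism/concordance model:
         term   Coef   s.e.    z        P
1  antagonism 0.2162 0.0592 3.65 0.000261
2 concordance 0.0203 0.0883 0.23 0.818241
  frailty variance: 0.127
  interaction LRT: chi-square = 0.199, P = 0.655

Female/male fitness model:
        term   Coef   s.e.     z      P
1 female_std -0.139 0.0751 -1.84 0.0652
2   male_std  0.167 0.0753  2.22 0.0263
  frailty variance: 0.127

Delta AIC (null - fitted): 7.78
Influence screen: 20 flagged records; flagged line(s): L17, L40, L20, L04

Extinction: observed 78.3% | fecundity-only forecast 0.39% | first-generation projection 69.9%
Follow-up category tests (chi-square, P): fecundity 0.986, 0.321; fertility 0.0624, 0.803
```

Reading the report: the positive antagonism coefficient (0.22, P <
0.001) says lineages from male-benefit/female-detriment lines went
extinct faster — the planted effect (0.20), recovered. The frailty
variance 0.127 estimates the planted line-level heterogeneity (0.14).
The female/male block is the same fit on unrotated covariates
(coefficients related by the exact inverse rotation), the interaction
LRT shows no support for an antagonism × concordance term (none was
planted), and the fecundity-only forecast versus observed extinction
(0.4% vs 78%) shows that, in this simulated world as in the motivating
experiment, demography alone explains almost none of the observed
extinction. Follow-up category tests are null, as generated.

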