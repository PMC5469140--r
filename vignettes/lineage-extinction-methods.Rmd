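---
title: "Models and methods: sexually antagonistic fitness variation and extinction under inbreeding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: sexually antagonistic fitness variation and extinction under inbreeding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inbrex)
```

## The scientific problem

Populations carry two qualitatively different kinds of genetic variation
for fitness. Sexually concordant (SC) variation — chiefly deleterious
mutation load — depresses fitness in both sexes. Sexually antagonistic
(SA) variation helps one sex and harms the other, producing a negative
intersexual genetic correlation for fitness across genotypes. When
isofemale lines (each founded by a single wild-caught mating pair and
therefore carrying a frozen sample of segregating variation) are forced
through repeated brother–sister matings, homozygosity rises quickly and
lineages start failing: no eggs, infertile eggs, or a brood of only one
sex, any of which ends a single-pair lineage. The question this package
addresses is whether *male-benefit/female-detriment* SA genotypes are
systematically more vulnerable to that extinction process than their
female-benefit counterparts, over and above the vulnerability caused by
generally low fitness (mutation load).

`inbrex` implements the statistical machinery for that question as a
reusable, tested pipeline and pairs it with a synthetic-data generator
with known ground truth, so every estimator can be validated by
parameter recovery rather than by eyeballing.

## Derived fitness axes

Line-mean lifetime offspring counts for each sex are log-transformed
and variance-standardized (mean 0, variance 1, $n-1$ denominator)
within sex. The standardized plane $(m, f)$ is then rotated 45°
clockwise:

$$
\mathrm{antagonism} = \frac{m - f}{\sqrt 2}, \qquad
\mathrm{concordance} = \frac{m + f}{\sqrt 2}.
$$

Positive antagonism marks male-benefit/female-detriment lines; positive
concordance marks generally high-fitness lines. Design choices worth
making explicit:

* **Natural logarithm.** Any log base cancels after standardization, so
  the choice is immaterial; the natural log is used.
* **Orthonormal scaling.** The $1/\sqrt2$ factor makes the rotation an
  isometry: per line, $a^2 + c^2 = m^2 + f^2$, and the inverse map is
  exact. It also gives the clean identities
  $\beta_m = (\beta_a + \beta_c)/\sqrt2$ and
  $\beta_f = (\beta_c - \beta_a)/\sqrt2$ between the coefficients of
  the two model parameterizations.
* **No re-standardization of the derived axes** (default). After
  rotation the axes have variances $1 - r$ and $1 + r$, where $r$ is
  the intersexual correlation. Re-standardizing them would break the
  exact coefficient mapping above; since the two parameterizations of
  the survival model are meant to be two views of the same fit, the
  un-re-standardized convention is the default, with
  `fitness_axes(..., restandardize = TRUE)` available for users who
  want unit-variance derived scores.

## The mixed-effects Cox model

The survival unit is the inbred lineage: extinction generation in
$1..G$ ($G = 10$ by default) or censoring at $G$. Lineages from the
same isofemale line share genotype, so their hazards are correlated;
this is modelled by a shared Gaussian random intercept (log-normal
frailty) per line:

$$
h_{ij}(t) = h_0(t)\, \exp\!\big(x_j'\beta + b_j\big),
\qquad b_j \sim N(0, \sigma^2),
$$

for lineage $i$ of line $j$. `coxfr()` estimates $(\beta, \sigma^2)$ by
penalized partial likelihood:

1. **Inner loop.** For fixed $\sigma^2$, Newton–Raphson jointly
   maximizes the Cox partial log-likelihood penalized by
   $b'b / 2\sigma^2$ over $(\beta, b)$, with monotone step-halving.
   Convergence is declared when the penalized log-likelihood changes by
   less than $10^{-9}$ between iterations.
2. **Outer loop.** $\sigma^2$ maximizes the Laplace-approximate
   integrated partial likelihood
   $\ell(\hat\beta,\hat b) - \hat b'\hat b/2\sigma^2 -
   \tfrac12 \log\det(I + \sigma^2 K_{bb})$, where $K_{bb}$ is the
   observed-information block of the group effects. The search is
   Brent's method on $\sigma^2 \in [10^{-6}, 10]$ with tolerance
   $5\times10^{-5}$, warm-starting each inner solve from the previous
   one.
3. **Boundary.** If the maximized integrated likelihood does not exceed
   the fixed-effects likelihood (the $\sigma^2 \to 0$ limit), the
   variance is reported as exactly 0 with a boundary warning.

Tied event times use the **Efron** approximation by default — the right
choice for generation-scale data, where ties are heavy — with Breslow
available via `ties = "breslow"`. Standard errors of the fixed effects
come from the inverse of the joint penalized information; $z$ ratios
are referred to the standard normal, two-sided. With `sigma2 = 0` (or
`random = NULL`) the fit reduces exactly to a standard Cox model; the
test suite verifies agreement with an independent implementation
(`survival::coxph`) to well below $10^{-6}$, plus agreement with a
brute-force partial-likelihood oracle on small worked examples.

**Information criteria.** `logLik()` returns the integrated
log-likelihood with `df` equal to the number of fixed coefficients plus
one when the frailty variance was estimated, so
$\mathrm{AIC} = -2\ell + 2\,\mathrm{df}$; `delta_aic(fit, null)` is
positive when the fitted model beats the null. This convention (the
variance counts as one parameter) is stated here because AIC
conventions for mixed models vary; all comparisons inside the package
are internally consistent. Interaction terms are judged by
likelihood-ratio tests (`lrt()`), using the integrated likelihoods and
a $\chi^2$ reference with df equal to the parameter difference.

## Influence screening

Mixed-effects Cox fits offer no usable residuals, so outliers are
screened on the fixed-effects model: `dfbeta_screen()` refits the model
exactly (not by a one-step approximation — at a few hundred records the
exact refit is cheap) with each record deleted in turn, and records are
flagged when any coefficient delta exceeds the mean $+ k\,\mathrm{SD}$
($k = 3$) of the delta distribution.

One property of this screen deserves emphasis: covariates are
line-level, so all lineages of a line share leverage, and their
influence deltas are strongly correlated. Even under exchangeable
hazards the flagged records therefore land in the most extreme-covariate
lines, and isolated same-line pairs of flags arise routinely — they are
leverage, not pathology. The working definition of a *flagged cluster*
(`flagged_lines()`) consequently requires at least three flagged
records from one line, and the property the test suite verifies under
the null is the calibrated one: no line ever has a *majority* of its
records flagged. A genuinely aberrant line — several SD out on
antagonism with uniformly early extinctions — tops both the
flagged-count and mean-influence rankings, which is the diagnostic
signature the screen is designed to surface. In the pipeline the
screen's top line is refitted out (with the derived axes recalculated
in its absence) and both coefficient blocks are reported, leaving the
exclusion decision in the analyst's hands with the delta-AIC evidence
alongside.

## Extinction forecasts without inbreeding

Two forecasts quantify how much extinction would be expected from
demography alone, with no inbreeding effect — the baseline against
which the observed extinction is interpreted.

**Fecundity-only simulation.** Each simulated lineage draws, per
generation, one female's lifetime offspring count (resampled with
replacement from the line's fecundity samples, or negative-binomial
when a parametric summary is given), sexes each offspring independently
at ratio 1/2, and survives only if at least one offspring of each sex
emerged. Draws are iid across generations — deliberately: the forecast
excludes inbreeding by construction. For degenerate brood size $n$ the
closed form $1 - (1 - 2^{1-n})^G$ is available and the Monte-Carlo
engine is verified against it at $n \in \{1, 2, 5, 10\}$.

**First-generation projection.** Each line's extinction rate
$\hat p_1$ in generation 1 (before inbreeding has any real effect) is
projected forward either geometrically, $1 - (1-\hat p_1)^G$ (default),
or linearly, $\min(1, G\hat p_1)$. Both conventions are implemented
because the verbal description "linear projection" is ambiguous about
compounding; the geometric form is the default since it is the
probabilistically coherent one, it never exceeds the linear form, and
the choice is recorded in the result's `method` field.

## Follow-up assay analyses

Offspring counts from crossing focal individuals of extreme lines to an
outbred base population are zero-inflated: zeros are compared between
categories by a Pearson $\chi^2$ (1 df, no continuity correction —
matching the style of single-df chi-square reporting), and the non-zero
counts by a Gaussian linear mixed model, `offspring ~ category +
base_cohort + (1|line) + (1|lineage:line) + (1|date)`, with the
category effect tested by a maximum-likelihood likelihood-ratio test.
Singular variance components are dropped (smallest first) with a
warning. Note that the category contrast is carried by *lines*: with
three lines per category its effective sample size is six, whatever the
record count, so the $\chi^2_1$ reference is only trustworthy — and
power only accumulates — as lines per category grow. The calibration
and power simulations in the test suite therefore use designs with ten
lines per category at realistic total record counts.

Extreme lines are selected by the first principal component of the
standardized (antagonism, extinction-risk) pair — the eigenvector of
their $2\times2$ correlation matrix (correlation, not covariance,
because the two scores have incommensurate natural scales) — oriented
so that positive scores align with antagonism; the three most positive
and three most negative lines form the male-benefit/high-extinction and
female-benefit/low-extinction categories.

## The synthetic-data generator

`sim_config()` fixes the study conditions; every generator is a pure
function of the configuration, with per-generator sub-streams derived
deterministically from the master seed. The defaults emulate the
motivating experiment:

| knob | default | meaning |
|---|---|---|
| `n_lines` × `lineages_per_line` | 41 × 20 | study design (~800 lineages) |
| `max_generations` | 10 | follow-up horizon |
| `r_mf` | −0.51 | intersexual correlation of log fitness |
| `beta_antagonism`, `beta_concordance` | 0.20, −0.14 | planted log hazard ratios |
| `frailty_variance` | 0.14 | planted line-level variance |
| `baseline_hazard` | 0.1591 | calibrated (see below) |

The baseline hazard was calibrated **once**, by root-finding on the
expected overall extinction $E_\eta[1 - e^{-G h_0 e^\eta}] = 0.778$
with $\eta \sim N(0,\, \beta_a^2(1-r) + \beta_c^2(1+r) + \sigma^2)$,
and stored in the default configuration;
`calibrate_baseline_hazard()` reproduces it. Discrete mode draws
generation-scale times from the grouped proportional-hazards model
(per-generation extinction probability $1 - e^{-h_0 e^\eta}$), which
shares its survival function with the continuous exponential model at
integer times, so one calibration serves both.

Continuous-time mode is the default and is used for all parameter
recovery experiments: it is tie-free, so the partial likelihood is
exact and recovery is unbiased by tie approximation. Discrete mode is
the realistic choice for demonstrations, since real extinction times
are generations. Raw fitness scales (log-means log 40 and log 60, log-SDs
0.30 and 0.20 for males and females) are realistic lifetime offspring
scales for a seed beetle; males get the larger SD because male
reproductive success is the noisier assay. Fecundity samples are
negative-binomial with line mean proportional to female fitness
(dispersion 5), and follow-up counts are zero-inflated (zero
probability 0.10) around a mean of 60 with line/lineage/date SDs of
5/3/3 and residual SD 12.

**What the generator does *not* emulate** — and hence what passing
recovery tests do and do not show: it has no inbreeding dynamics (the
hazard model is the data-generating truth, not an emergent property of
genetics), no time-varying hazards, no correlation between fecundity
and frailty beyond the shared female-fitness dependence, and its
fecundity distributions are parametric rather than resampled from real
assays. Recovery results validate the *estimators*; they cannot
validate the biological model itself against real data.

## Validation problem sizes

The package's validation experiments use: 600 replicates of the full
41 × 20 design for fixed-effect and frailty-variance recovery (replicate
means within 10% and 0.05 of the planted values, respectively);
$10^5$ Monte-Carlo lineages per degenerate-brood closed-form check;
500 null replicates each for the likelihood-ratio and mixed-model
calibration checks (nominal 5% size, ±2 points). These sizes keep
Monte-Carlo error comfortably below the tolerances being asserted.

## Known limitations

* The Gaussian-frailty Laplace estimator shows the usual mild downward
  bias in $\hat\sigma^2$ at moderate numbers of clusters (mean ≈ 0.13
  for a planted 0.14 at 41 lines); gamma frailty is not implemented.
* Only a random intercept per line is supported — no nested or crossed
  frailties, time-varying covariates, stratified baselines, or
  competing risks across extinction modes (the extinction-mode label is
  carried through the data model but not analyzed).
* The influence screen is a ranking diagnostic, not a calibrated test;
  see above.
* Interval censoring is handled only at generation granularity, via the
  grouped proportional-hazards generator and tie-aware partial
  likelihood, not by an explicit interval-censored likelihood.
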