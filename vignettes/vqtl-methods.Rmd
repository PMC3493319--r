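---
title: "Detecting variance-controlling loci: models, tests and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting variance-controlling loci: models, tests and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vqtlmap)
```

## The problem

A classical QTL shifts the *expected value* of a trait with each allelic
substitution. A variance-controlling QTL (vQTL) instead predicts how much the
trait *varies* about its genotype-specific mean. A vQTL signal is interesting
precisely because it is a one-dimensional footprint of unmodelled
interactions: if the locus interacts with an unmeasured gene or environment,
the interaction shows up marginally as genotype-dependent spread. vqtlmap
implements three families of tests for this signal, a scale diagnostic, and a
simulation benchmark that measures their calibration and power.

## Models and tests

### Classical group-based tests

`levene_test()` computes absolute deviations of the trait from its
genotype-class centre and applies a one-way ANOVA F test to them;
`fligner_killeen_test()` replaces deviations by normal scores of their
midranks and uses a chi-squared reference. Both are robust to distributional
misspecification but cannot adjust for continuous covariates and need hard
genotype classes (`dosage_to_groups()` hard-calls fractional dosages,
warning when the dosage is far from an integer).

**Centring choice.** The Levene family comes in a mean-centred and a
median-centred ("Brown–Forsythe") variant. The median-centred form is the
default here, for two reasons: it is the robust default of the major
implementations (e.g. `car::leveneTest`), and on strongly skewed traits
(low-mean Poisson counts, for example) the mean-centred form is considerably
more anticonservative. The benchmark study under the Poisson null makes the
difference concrete: the median-centred test rejects at roughly 0.5 at
$\alpha = 0.05$, the mean-centred one at roughly 0.8. `center = "mean"` is
available as an option.

### The double generalized linear model

`dglm()` fits, for a Gaussian trait,
$$y_i \sim N(x_i^\top\beta,\ \sigma_i^2), \qquad
  \log \sigma_i^2 = z_i^\top\lambda ,$$
by cycling between weighted least squares for $\beta$ (weights
$1/\sigma_i^2$) and a gamma GLM with log link for $\lambda$, whose response
is the leverage-corrected squared residual $\hat e_i^2 / (1-h_{ii})$ with
prior weights $(1-h_{ii})/2$. The leverage correction matters: fitted
residuals are systematically smaller than true errors by the factor
$1-h_{ii}$, and ignoring this biases the dispersion submodel. The prior
weight $(1-h_{ii})/2$ reflects the $\sigma_i^2\chi^2_1$-like distribution of
a squared residual (a gamma variable with dispersion 2).

For a Poisson trait the mean submodel is a log-link Poisson GLM with prior
weights $1/\phi_i$ and the dispersion response is the leverage-corrected unit
deviance $d_i = 2[y_i\log(y_i/\hat\mu_i) - (y_i-\hat\mu_i)]$ (with
$0\log 0 = 0$). Here $\phi_i$ is a multiplicative over/under-dispersion
factor; a genotype effect on $\log\phi$ is a variance effect *beyond* the
mean–variance relation already implied by the Poisson law. The reported
objective is the extended quasi-likelihood; its $\log V(y_i)$ term is
undefined at $y_i = 0$ and we use $V(y) = \max(y, 1/6)$, which is constant
across nested fits and therefore cancels from every likelihood-ratio test.

`dglm_vqtl_test()` builds the single-marker test: full model with dosage in
both submodels (mean design $[1, \text{covariates}, g]$, dispersion design
$[1, g]$) against a null with the same mean design and constant dispersion,
so the test isolates the variance effect while always adjusting the mean for
the marker. The default statistic is the likelihood ratio on 1 df. A Wald
option exists and agrees closely for Gaussian traits; for low-mean Poisson
traits the gamma-GLM standard error of $\lambda_g$ is a poor match to the
sampling variance of deviance responses and the Wald test is markedly
conservative, which is why it is not the default.

**Numerical choices.** Outer convergence is declared when the maximum
relative change of $(\beta, \lambda)$ falls below `tol` (default $10^{-8}$)
with `maxit = 100`; the inner gamma IRLS runs to $10^{-12}$ so that the
closed-form identity (constant dispersion $\Rightarrow$ OLS with
$\hat\sigma^2 = RSS/(n-p)$) holds to $10^{-8}$. Unit deviances of exactly
zero are floored at $10^{-10}$ (the gamma response must be positive), the
dispersion linear predictor is bounded at $|\eta| \le 700$ to prevent
overflow, and a decreasing Gaussian log-likelihood across outer iterations
raises a convergence warning. Non-convergence returns the current fit flagged
`converged = FALSE` rather than an error, so genome scans are not aborted by
one marker.

### Two-stage approximations

`svlm_test()` first fits an ordinary least-squares GWAS model (intercept,
covariates, and by default the marker), then regresses a residual summary on
the dosage: squared residuals with a t test (SVLM), squared residuals through
a gamma GLM with log link, or absolute residuals. These are fast
approximations to the joint fit that condition on estimated residuals; they
ignore both the estimation error of the residuals and any heteroscedasticity
when estimating the mean. The stage-2 reference is a t distribution on
$n - p_2$ df. Defaults keep the marker in stage 1 (an "ordinary GWAS" model
contains the SNP) and leave covariates out of stage 2 (they were already
removed); both are switchable.

Deliberately, *no* leverage correction is applied inside the two-stage tests:
their published behaviour is exactly the uncorrected shortcut, and its
adequacy is instead assessed by `hat_screen()`, which computes the stage-1
leverages and passes the design when all $h_{ii} < 0.05$. At benchmark sizes
($n = 10{,}000$, a dosage predictor) the screen always passes, which is the
regime where SVLM and DGLM agree almost perfectly (p-value correlation
$> 0.999$ in the power study below).

### Scale diagnostics

A locus that raises both mean and variance may be a mean-effect QTL observed
on an unsuitable scale (volume versus length of a cylindrical organism, say).
`boxcox_profile()` profiles the Box–Cox exponent over a grid (default
$[-2, 2]$ in steps of 0.05) by direct enumeration — robust, reproducible, and
precise enough for a guidance tool — returning the argmax and a
$\chi^2_1$-cutoff profile interval. The transformation is user-invoked
preprocessing, never applied automatically inside a test. With tightly
concentrated data (log-scale SD of 0.1) the profile is nearly flat, so the
argmax concentrates only slowly: recovering the generating scale to within
one grid step needs on the order of $2\times 10^4$ observations, which the
tests use.

## The simulation scenarios

`simulate_scenario()` generates the three single-marker designs the
benchmark rests on, with genotypes $g \sim Bin(2, 0.4)$ throughout:

* **interaction_vqtl** — $y \sim N(\beta_F F + \beta_{gF}\, g F,\ 1)$ with
  an unobserved factor $F \sim N(0,1)$, $\beta_F = 0.85$,
  $\beta_{gF} = 0.06$. Marginally $\mathrm{Var}(y\,|\,g) =
  1 + (\beta_F + \beta_{gF} g)^2$: a genuine vQTL with no direct mean
  effect. $F$ is stored for truth-checking but hidden from every test.
* **gaussian_null** — $y \sim N(0,1)$ independent of $g$.
* **poisson_null** — $y \sim \mathrm{Poisson}(e^{\mu + \beta_g g})$ with
  $\mu = -1$, $\beta_g = 0.05$: a pure mean effect whose variance tracks the
  mean only through the Poisson law. The genotype law is the same
  $Bin(2,0.4)$ as the other scenarios (an assumption; the scenario
  definition fixes only the trait law).

These defaults are the study conditions; the benchmark does not vary them.
The generator emulates a single biallelic marker in an unstructured,
unrelated population. It does not emulate linkage between markers, polygenic
background, population structure or relatedness, genotyping error, or
covariate confounding — so passing benchmarks demonstrate calibration and
power in the idealised single-locus setting, not robustness to those
real-data complications (population-structure-aware extensions are out of
scope here).

## The benchmark

`run_study()` draws `trials` datasets and applies every requested method to
the *same* data within a trial (a paired design; per-trial seeds are
`seed + trial - 1`, so studies are reproducible and extendable). It reports
rejection rates at $\alpha$ with Monte-Carlo standard errors
$\sqrt{r(1-r)/\text{trials}}$ and stores the p-value matrix, from which
`rejection_rates()` evaluates other levels exactly — hence monotonicity in
$\alpha$ holds by construction. Non-converged DGLM fits contribute their
returned p-value; a warning counter flags studies where more than 2% of
trials warned. `run_power_study()` adds the SVLM–DGLM p-value correlation
under the interaction alternative.

At the study conditions (1000 trials of $n = 10{,}000$, $\alpha = 0.05$) the
Gaussian-null false-positive rates of Levene/SVLM/DGLM-Gaussian sit near
0.05; under the Poisson null the Gaussian-family tests inflate severely
(roughly 0.4–0.6) while the Poisson-family DGLM stays near 0.05; and under
the interaction alternative SVLM and DGLM both reach power near 0.82 with
Levene around 0.69. The test suite verifies these in a 250-trial scaled-down
mode for the null studies (tolerances widened to six Monte-Carlo standard
errors accordingly) and at the full 1000 trials for the power study;
`scripts/acceptance.R` reruns everything at 1000 trials.

## Known limitations

* The Poisson EQL is a likelihood surrogate; its LRT is approximately, not
  exactly, $\chi^2_1$-calibrated (slightly conservative at low means).
* Group-based tests silently lose information on imputed (fractional)
  dosages through hard-calling; regression-based tests take the dosage
  directly and should be preferred with genotype uncertainty.
* No random effects in either submodel: relatedness and population structure
  must be handled upstream.
* Two-stage tests inherit every caveat of conditioning on estimated
  residuals; consult the hat screen before trusting them on small or
  unbalanced designs.
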