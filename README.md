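# recurbias

**What happens to a treatment-effect estimate in a recurrent-event analysis
when a prognostic covariate is left out of the model?**

Recurrent events — COPD exacerbations, epileptic seizures, skeletal
complications in cancer, pulmonary exacerbations in cystic fibrosis — are
routinely analysed with two semiparametric rate-based models:

- the **marginal (Andersen–Gill-type) model**
  `ρ(t | X) = ρ0*(t) exp(βX)`, fitted from the profile partial score with a
  Breslow baseline and a robust (sandwich) variance; and
- the **partially conditional (PWP-type / stratified Andersen–Gill) model**
  `ρ_j(t | X) = ρ_{j0}*(t) exp(βX)`, which stratifies on the cumulative
  event count `N(t⁻) = j − 1` with event-specific baselines.

Suppose events are truly generated by a modulated Poisson process
`ρ(t | X, Z) = ρ0(t) exp(ηX + ζZ)` but the analysis omits `Z`. Each
estimator then converges to a limit — `β†` (marginal) or `β‡` (partially
conditional) — that generally differs from the causal effect `η`:

- **Marginal model, fixed `Z`:**
  `exp(β†) = E[X e^{ηX+ζZ}] / E[(1−X) e^{ηX+ζZ}]` (for `P(X=1) = 1/2`), a
  closed form free of the baseline and the censoring distribution. If
  `X ⟂ Z` (a randomized trial), `β† = η`: the marginal analysis keeps its
  causal interpretation.
- **Partially conditional model:** the limit solves a population score that
  conditions on being at risk for the *j*-th event. Because the event count
  responds to both `X` and `Z`, conditioning on it *induces* association
  between them (`X ⊄ Z | N(t⁻)`), so `β‡ ≠ η` **even when `X ⟂ Z`** —
  randomization does not protect the stratified analysis.

The package provides, as a library plus a small CLI:

- `fit_marginal()` / `fit_partially_conditional()` — estimating-equation
  fitters on counting-process `(start, stop]` data (Rcpp core), with
  Breslow baselines, naive (inverse-information) and robust sandwich
  variances, and `wald_ci()`;
- `simulate_poisson_cohort()` / `simulate_markov_cohort()` — exact
  generators for the Weibull–Poisson process and a state-escalating Markov
  process (`q_k = q0 e^{α·min(k, K+1)}`), plus calibration utilities
  (`calibrate_weibull()`, `calibrate_markov_q0()` via the
  Chapman–Kolmogorov matrix exponential);
- `limit_marginal()` / `limit_pc()` — the limiting values above (closed
  form, and adaptive quadrature + root-finding), and `asymptotic_se()` for
  asymptotic naive/robust standard errors by controlled Monte Carlo;
- `scenario()`, `run_scenario()`, `run_table()`, `compare_to_limit()` — a
  simulation-study runner reporting BIAS, ESE, average naive/robust SE and
  empirical coverage, all ×100 as in the published tables.

## Worked example

Four subjects followed on `(0, 1]`; subjects 1–2 treated; subject 1 has an
event at 0.5, subject 3 at 0.25 and 0.75:

```r
library(recurbias)
cd <- to_counting_data(toy_histories())
fit_marginal(cd, "x")
#> Marginal rate model: 3 events, 4 subjects
#>         coef exp(coef) naive se robust se
#> x -0.6931472       0.5 1.224745         1
fit_partially_conditional(cd, "x")
#> Partially conditional rate model: 3 events, 4 subjects
#>         coef exp(coef) naive se robust se
#> x -0.9406136 0.3903882 1.240258 0.7783111
```

These are the exact hand-solvable roots `log 0.5` and
`log((−1 + √17)/8)`: one treated event against three at-risk subjects per
risk set for the marginal score, and stratum-restricted risk sets for the
stratified score.

Limiting bias in the observational setting (`P(Z=1) = 0.25`, odds ratio
`φ = 4` between treatment and covariate, `η = log 0.75`, `ζ = log 3`):

```r
j <- solve_binary_joint(0.5, 0.25, 4)
limit_marginal(j, log(0.75), log(3))
#> Limiting value of the marginal treatment estimator
#>   beta* = 0.0387405  bias = beta* - eta = 0.3264226
```

A true effect of `exp(η) = 0.75` (25% rate reduction) is estimated in the
limit as `exp(β†) = 1.04` — the benefit disappears entirely. Even with
`φ = 1` (independent covariates) the *stratified* model is biased:

```r
m <- weibull_poisson_model(calibrate_weibull(1.25, 2, 1), 1.25, log(0.75), log(3))
limit_pc(solve_binary_joint(0.5, 0.25, 1), m, censoring_scheme(1, 0.2))
#> Limiting value of the partially conditional treatment estimator
#>   beta* = -0.2123969  bias = beta* - eta = 0.07528518
```

A finite-sample check (200 replicates of n = 1000; the published study
uses 1000 replicates):

```r
s <- scenario(m, j, censoring_scheme(1, 0.2), n = 1000, nsim = 200, seed = 1,
              models = c("marginal", "pc"))
sm <- run_scenario(s)
sm$marginal
#> marginal model (x100): BIAS 33.67  ESE 5.57  ASE1 4.20  ASE2 5.52  ECP1 0.0  ECP2 0.0  [200/200 converged]
sm$pc
#> pc model (x100): BIAS 32.10  ESE 4.32  ASE1 4.24  ASE2 4.24  ECP1 0.0  ECP2 0.0  [200/200 converged]
compare_to_limit(sm$marginal, limit_marginal(j, log(0.75), log(3)))$z
#> [1] 2.614697
```

The simulated bias (0.337) agrees with the closed form (0.326) within
Monte-Carlo error (|z| < 3); the robust SE (5.52) tracks the empirical SE
(5.57) while the naive SE (4.20) understates it; coverage of the true
effect collapses to 0 under this strong confounding.

## CLI

```sh
inst/cli/recurbias fit --model pc --data counting.csv --covariates x --out fit.json
inst/cli/recurbias limit --model marginal --scenario scenario.json --out limit.json
inst/cli/recurbias study --table 1 --nsim 1000 --seed 1 --out results/
inst/cli/recurbias fixtures --out fixtures/
```

Scenario configs are JSON (see `?scenario_from_config`).

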