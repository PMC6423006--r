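## Independent brute-force implementations used as oracles: plain-R,
## loop-based evaluation of the profile (pseudo-)score on counting data.
## Deliberately naive -- no shared code with the package's fitting path.

brute_score <- function(cd, beta, stratified = FALSE) {
  U <- 0
  evRows <- which(cd$status == 1L)
  for (e in evRows) {
    t <- cd$stop[e]
    atRisk <- cd$start < t & t <= cd$stop
    if (stratified) atRisk <- atRisk & cd$stratum == cd$stratum[e]
    w <- exp(beta * cd$x[atRisk])
    U <- U + cd$x[e] - sum(cd$x[atRisk] * w) / sum(w)
  }
  U
}

brute_root <- function(cd, stratified = FALSE, interval = c(-5, 5)) {
  uniroot(function(b) brute_score(cd, b, stratified), interval,
          tol = 1e-12)$root
}

## Brute-force per-subject score residuals at beta (shares no code with the
## C++ residual pass): own-event terms minus the compensator under the
## profile Breslow baseline, within stratum.
brute_residuals <- function(cd, beta, stratified = FALSE) {
  ids <- unique(cd$id)
  W <- setNames(numeric(length(ids)), ids)
  evRows <- which(cd$status == 1L)
  for (e in evRows) {
    t <- cd$stop[e]
    atRisk <- cd$start < t & t <= cd$stop
    if (stratified) atRisk <- atRisk & cd$stratum == cd$stratum[e]
    w <- exp(beta * cd$x[atRisk])
    xbar <- sum(cd$x[atRisk] * w) / sum(w)
    dmu <- 1 / sum(w)
    W[as.character(cd$id[e])] <- W[as.character(cd$id[e])] + cd$x[e] - xbar
    rr <- which(atRisk)
    W[as.character(cd$id[rr])] <- W[as.character(cd$id[rr])] -
      exp(beta * cd$x[rr]) * (cd$x[rr] - xbar) * dmu
  }
  W
}

## small simulated dataset shared across fit tests
sim_small_poisson <- function(n = 100, seed = 99, zeta = log(2), phi = 2) {
  j <- solve_binary_joint(0.5, 0.3, phi)
  cs <- censoring_scheme(1, 0.2)
  m <- weibull_poisson_model(calibrate_weibull(1.25, 2, 1), 1.25,
                             log(0.75), zeta)
  set.seed(seed)
  cov <- sample_covariates(j, n)
  cc <- sample_censoring(cs, n)
  coh <- simulate_poisson_cohort(m, cov$x, cov$z, cc)
  to_counting_data(coh)
}
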