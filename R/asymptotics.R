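## Golub-Welsch quadrature rules (eigenvalues of the Jacobi matrix); enough
## nodes are used that no external quadrature dependency is needed.

## Gauss-Legendre on [a, b]
gauss_legendre <- function(n, a = -1, b = 1) {
  i <- seq_len(n - 1)
  off <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- off
  J[cbind(i + 1, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  o <- order(x)
  list(nodes = (b - a) / 2 * x[o] + (a + b) / 2, weights = (b - a) / 2 * w[o])
}

## Gauss-Hermite (physicists', weight exp(-x^2), total mass sqrt(pi))
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  off <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- off
  J[cbind(i + 1, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- sqrt(pi) * e$vectors[1, ]^2
  o <- order(x)
  list(nodes = x[o], weights = w[o])
}

## Discretize the covariate law into atoms (x, z, weight). A binary joint
## law gives its four cells; a normal confounder gives pX x Gauss-Hermite
## atoms (exact for the polynomial-exponential expectations used here).
covariate_atoms <- function(law, pX = 0.5, ghNodes = 40) {
  if (inherits(law, "binary_joint")) {
    data.frame(x = c(1, 1, 0, 0), z = c(1, 0, 1, 0),
               w = c(law$p11, law$p10, law$p01, law$p00))
  } else if (inherits(law, "normal_confounder")) {
    if (law$sigma < 1e-12) {  # degenerate: point mass at the mean
      data.frame(x = c(1, 0),
                 z = law$theta0 + law$theta1 * c(1, 0),
                 w = c(pX, 1 - pX))
    } else {
      gh <- gauss_hermite(ghNodes)
      data.frame(
        x = rep(c(1, 0), each = ghNodes),
        z = c(law$theta0 + law$theta1 + sqrt(2) * law$sigma * gh$nodes,
              law$theta0 + sqrt(2) * law$sigma * gh$nodes),
        w = c(pX * gh$weights / sqrt(pi), (1 - pX) * gh$weights / sqrt(pi)))
    }
  } else stop("law must be a binary_joint or normal_confounder")
}

#' Limiting value of the marginal treatment-effect estimator
#'
#' Under a true rate \eqn{\rho_0(t) e^{\eta X + \zeta Z}} with a fixed
#' covariate `Z`, the marginal model fitted with `X` alone converges to
#' \deqn{\exp(\beta^\dagger) = \frac{1 - p_X}{p_X} \cdot
#'   \frac{E[X e^{\eta X + \zeta Z}]}{E[(1 - X) e^{\eta X + \zeta Z}]},}
#' which is free of the baseline rate and of the censoring distribution
#' (both cancel from the population score when `Z` is time-invariant). For
#' `pX = 0.5` this is the classical closed form; for a binary `Z` the
#' expectations are the four cell sums, giving
#' \eqn{\beta^\dagger - \eta = \log[(e^\zeta p_{11} + p_{10}) /
#' (e^\zeta p_{01} + p_{00})]} at `pX = 0.5`; for a normal confounder
#' `Z | X ~ N(theta0 + theta1 X, sigma^2)` the bias is exactly
#' \eqn{\zeta \theta_1}. With `X` independent of `Z` (odds ratio 1, or
#' `theta1 = 0`) the bias is 0: the marginal model retains the causal
#' interpretation of the treatment effect in a randomized trial.
#'
#' @param joint covariate law: a [solve_binary_joint()] result or a
#'   [normal_confounder()].
#' @param eta true treatment log rate ratio.
#' @param zeta true covariate log rate ratio.
#' @param pX treatment probability (only used with a normal confounder;
#'   a binary joint law carries its own).
#' @return An object of class `limit_result` with `betaStar`, `bias`,
#'   `model = "marginal"` and the inputs.
#' @examples
#' j <- solve_binary_joint(0.5, 0.25, 4)
#' limit_marginal(j, log(0.75), log(3))$bias   # 0.3264
#' @export
limit_marginal <- function(joint, eta, zeta, pX = 0.5) {
  if (inherits(joint, "binary_joint")) {
    pX <- joint$pX
    num <- exp(zeta) * joint$p11 + joint$p10   # E[X e^(zeta Z)] / e^eta... x=1 part
    den <- exp(zeta) * joint$p01 + joint$p00
    betaStar <- eta + log(((1 - pX) / pX) * num / den)
  } else if (inherits(joint, "normal_confounder")) {
    betaStar <- eta + zeta * joint$theta1
  } else stop("joint must be a binary_joint or normal_confounder")
  structure(list(betaStar = betaStar, bias = betaStar - eta,
                 model = "marginal", eta = eta, zeta = zeta,
                 diagnostics = list()),
            class = "limit_result")
}

#' @exportS3Method base::print
print.limit_result <- function(x, ...) {
  cat("Limiting value of the", if (x$model == "pc") "partially conditional"
      else "marginal", "treatment estimator\n")
  cat("  beta* =", format(x$betaStar), " bias = beta* - eta =",
      format(x$bias), "\n")
  invisible(x)
}

#' Limiting value of the partially conditional treatment-effect estimator
#'
#' Solves the population pseudo-score of the event-count-stratified model
#' fitted with `X` alone, when events truly follow a modulated Poisson
#' process \eqn{\rho_0(t) e^{\eta X + \zeta Z}} with a fixed covariate `Z`:
#' \deqn{\sum_{j \ge 1} \int_0^A \left\{ s_j^{(1)}(t) - s_j^{(0)}(t)
#'   \frac{s_j^{(1)}(\beta, t)}{s_j^{(0)}(\beta, t)} \right\} dt = 0,}
#' where, writing \eqn{\mu(t) = \mu_0(t) e^{\eta X + \zeta Z}},
#' \eqn{s_j^{(r)}(t) = \mathcal{G}(t)\rho_0(t) E[\mathrm{pois}(j-1;
#' \mu(t)) e^{\eta X + \zeta Z} X^r]} and \eqn{s_j^{(r)}(\beta, t) =
#' \mathcal{G}(t) E[\mathrm{pois}(j-1; \mu(t)) e^{\beta X} X^r]}
#' (probability of being at risk in stratum `j` times the model terms).
#' The expectation over the covariate law is a four-cell sum (binary `Z`)
#' or Gauss-Hermite quadrature (normal `Z`); the event-count sum is
#' truncated where the Poisson tail mass is below `tailTol`; the time
#' integral uses Gauss-Legendre nodes on `(0, A]`; the root is bracketed in
#' `eta +- 5`. Because the at-risk-in-stratum probability depends on both
#' covariates, \eqn{\beta^\ddagger \ne \eta} in general even when `X` and
#' `Z` are independent (induced confounding through conditioning on the
#' event count); with `zeta = 0` the model is correctly specified and
#' \eqn{\beta^\ddagger = \eta}.
#'
#' @param joint covariate law (binary joint or normal confounder).
#' @param model a [weibull_poisson_model()] carrying `eta` and `zeta`.
#' @param censoring a [censoring_scheme()].
#' @param pX treatment probability for a normal-confounder law.
#' @param nTime number of Gauss-Legendre time nodes on `(0, A]`.
#' @param ghNodes Gauss-Hermite nodes for a normal confounder.
#' @param tailTol Poisson tail mass kept below this at the largest
#'   subject-level mean when choosing the stratum truncation `J_max`.
#' @param tol root tolerance on beta.
#' @return An object of class `limit_result` (`model = "pc"`), with
#'   diagnostics `Jmax` and `quadError` (score-scale difference between the
#'   full and a half-resolution time grid).
#' @export
limit_pc <- function(joint, model, censoring, pX = 0.5,
                     nTime = 128, ghNodes = 40, tailTol = 1e-12, tol = 1e-10) {
  stopifnot(inherits(model, "weibull_poisson_model"),
            inherits(censoring, "censoring_scheme"))
  atoms <- covariate_atoms(joint, pX, ghNodes)
  eta <- model$eta; zeta <- model$zeta
  g <- exp(eta * atoms$x + zeta * atoms$z)

  scoreFun <- function(nT) {
    gl <- gauss_legendre(nT, 0, censoring$A)
    tt <- gl$nodes
    mu0 <- mu0_weibull(model, tt)
    rho0 <- model$lam * model$kappa * (model$lam * tt)^(model$kappa - 1)
    Gt <- censoring_survivor(censoring, tt)
    mu <- outer(g, mu0)                        # atoms x times
    Jmax <- max(20, ceiling(stats::qpois(1 - tailTol, max(mu)) + 10))
    x1 <- atoms$x == 1
    wa0 <- atoms$w * g                         # weights for true terms
    wa1 <- wa0 * atoms$x
    P <- exp(-mu)                              # pois(j-1 = 0; mu)
    ## per-j K-vectors, accumulated as J x K matrices
    T1 <- matrix(0, Jmax, nT); T0 <- T1; C1 <- T1; C0 <- T1
    for (j in seq_len(Jmax)) {
      T1[j, ] <- crossprod(wa1, P)
      T0[j, ] <- crossprod(wa0, P)
      C1[j, ] <- crossprod(atoms$w * atoms$x, P)
      C0[j, ] <- crossprod(atoms$w * (1 - atoms$x), P)
      P <- P * mu / j
    }
    outer_w <- gl$weights * Gt * rho0
    list(Jmax = Jmax, f = function(beta) {
      eb <- exp(beta)
      ratio <- eb * C1 / (eb * C1 + C0)
      integrand <- colSums(T1 - T0 * ratio)
      sum(outer_w * integrand)
    })
  }

  sf <- scoreFun(nTime)
  lo <- eta - 5; hi <- eta + 5
  flo <- sf$f(lo); fhi <- sf$f(hi)
  if (flo * fhi > 0)
    stop("limit_pc: root not bracketed in [eta - 5, eta + 5]; score(",
         format(lo), ") = ", format(flo), ", score(", format(hi), ") = ",
         format(fhi))
  betaStar <- stats::uniroot(sf$f, c(lo, hi), tol = tol)$root
  sf2 <- scoreFun(max(16, nTime %/% 2))
  quadErr <- abs(sf2$f(betaStar) - sf$f(betaStar))
  structure(list(betaStar = betaStar, bias = betaStar - eta,
                 model = "pc", eta = eta, zeta = zeta,
                 diagnostics = list(Jmax = sf$Jmax, quadError = quadErr)),
            class = "limit_result")
}

#' Asymptotic naive and robust standard errors at the limiting value
#'
#' Evaluates the variance components \eqn{\mathcal{A} =
#' E[-\partial U_i / \partial \beta]} and \eqn{\mathcal{B} = E[U_i U_i']}
#' of the sandwich \eqn{\mathcal{A}^{-1}\mathcal{B}\mathcal{A}^{-1}} at a
#' given `betaStar` by controlled Monte Carlo: large cohorts are simulated
#' from the true event-generating process, the score machinery is evaluated
#' at the fixed `betaStar` (no refitting), and the per-subject information
#' and score-residual outer products estimate the expectations. Standard
#' errors at a reference sample size `n` are
#' `aseNaive = sqrt(A^-1 / n)` and `aseRobust = sqrt(A^-1 B A^-1 / n)`.
#'
#' @param model event-generating model: [weibull_poisson_model()] or
#'   [markov_model()] (carrying the true `eta`, `zeta`).
#' @param joint covariate law (binary joint or normal confounder).
#' @param censoring a [censoring_scheme()].
#' @param betaStar the limiting coefficient at which to evaluate (from
#'   [limit_marginal()] or [limit_pc()]).
#' @param whichModel `"marginal"` or `"pc"`.
#' @param n reference number of subjects for the reported SEs.
#' @param pX treatment probability for a normal-confounder law.
#' @param nSubjectsMC Monte-Carlo subjects per repetition.
#' @param reps repetitions (used to estimate the Monte-Carlo precision).
#' @param seed integer seed.
#' @param poolStratumAt optional stratum pooling cap for the PC model.
#' @param precisionTarget warn if the relative Monte-Carlo SE of
#'   `aseRobust` exceeds this.
#' @return list with `aseNaive`, `aseRobust`, their Monte-Carlo relative
#'   SEs (`relSE`), and the per-subject `A` and `B`.
#' @export
asymptotic_se <- function(model, joint, censoring, betaStar,
                          whichModel = c("marginal", "pc"), n,
                          pX = 0.5, nSubjectsMC = 50000L, reps = 3L,
                          seed = 1L, poolStratumAt = NULL,
                          precisionTarget = 0.01) {
  whichModel <- match.arg(whichModel)
  seeds <- spawn_seeds(seed, 3L * reps)
  naive <- robust <- numeric(reps)
  Abar <- Bbar <- 0
  for (r in seq_len(reps)) {
    cov <- sample_covariates(joint, nSubjectsMC, seed = seeds[3 * r - 2], pX = pX)
    cc <- sample_censoring(censoring, nSubjectsMC, seed = seeds[3 * r - 1])
    coh <- if (inherits(model, "weibull_poisson_model"))
      simulate_poisson_cohort(model, cov$x, cov$z, cc, seed = seeds[3 * r])
    else simulate_markov_cohort(model, cov$x, cov$z, cc, seed = seeds[3 * r])
    cd <- to_counting_data(coh, poolStratumAt = poolStratumAt)
    X <- matrix(cd$x, ncol = 1)
    subject <- match(cd$id, coh$subjects$id) - 1L
    stratum <- if (whichModel == "pc") as.integer(cd$stratum)
               else rep(1L, nrow(cd))
    ev <- .ag_score(cd$start, cd$stop, as.integer(cd$status), stratum,
                    X, subject, nSubjectsMC, betaStar, TRUE)
    A <- ev$info[1, 1] / nSubjectsMC
    B <- sum(ev$residuals^2) / nSubjectsMC
    Abar <- Abar + A / reps; Bbar <- Bbar + B / reps
    naive[r] <- sqrt(1 / (A * n))
    robust[r] <- sqrt(B / (A^2 * n))
  }
  relSE <- if (reps > 1)
    c(naive = stats::sd(naive) / sqrt(reps) / mean(naive),
      robust = stats::sd(robust) / sqrt(reps) / mean(robust))
  else c(naive = NA_real_, robust = NA_real_)
  if (reps > 1 && any(relSE > precisionTarget, na.rm = TRUE))
    warning("Monte-Carlo precision ", format(max(relSE), digits = 2),
            " exceeds the target ", precisionTarget,
            "; increase nSubjectsMC or reps")
  list(aseNaive = sqrt(1 / (Abar * n)),
       aseRobust = sqrt(Bbar / (Abar^2 * n)),
       relSE = relSE, A = Abar, B = Bbar, n = n)
}
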