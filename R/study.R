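#' Define a simulation scenario
#'
#' Bundles an event-generating process, covariate law, censoring scheme and
#' study dimensions into a reproducible scenario for [run_scenario()].
#'
#' @param process event-generating model: a [weibull_poisson_model()] or
#'   [markov_model()] carrying the true `eta` and `zeta`.
#' @param covariate covariate law: [solve_binary_joint()] result or
#'   [normal_confounder()].
#' @param censoring a [censoring_scheme()].
#' @param n subjects per replicate (>= 2).
#' @param nsim number of replicates (>= 1).
#' @param seed master integer seed; replicate sub-seeds are spawned from it
#'   so replicates can be recomputed independently.
#' @param models which models to fit: subset of `c("marginal", "pc")`.
#' @param covariateColumns columns entered in the fitted models: `"x"`
#'   (covariate omitted, the misspecified analyses) or `c("x", "z")`
#'   (correctly specified).
#' @param pX treatment probability for a normal-confounder law.
#' @param poolStratumAt optional stratum pooling cap for the PC fit.
#' @return An object of class `scenario`.
#' @export
scenario <- function(process, covariate, censoring, n = 1000L, nsim = 1000L,
                     seed = 1L, models = c("marginal", "pc"),
                     covariateColumns = "x", pX = 0.5, poolStratumAt = NULL) {
  stopifnot(n >= 2, nsim >= 1,
            inherits(process, c("weibull_poisson_model", "markov_model")),
            inherits(covariate, c("binary_joint", "normal_confounder")),
            inherits(censoring, "censoring_scheme"),
            all(models %in% c("marginal", "pc")))
  structure(list(process = process, covariate = covariate,
                 censoring = censoring, n = as.integer(n),
                 nsim = as.integer(nsim), seed = as.integer(seed),
                 models = models, covariateColumns = covariateColumns,
                 pX = pX, poolStratumAt = poolStratumAt,
                 trueEta = process$eta),
            class = "scenario")
}

#' Run a simulation scenario
#'
#' For each replicate: draw covariates, censoring times and event
#' histories; build counting-process data; fit the requested models; then
#' summarize the treatment coefficient across replicates in the tables'
#' x100 convention: `bias100 = 100 (mean(beta) - eta)`, `ese100` the
#' empirical SD, `aseNaive100` / `aseRobust100` the average naive / robust
#' SEs, and `ecpNaive100` / `ecpRobust100` the empirical coverage of the
#' nominal 95% Wald interval (normal quantile 1.959964) for the true `eta`.
#' Non-converged replicates are dropped and counted.
#'
#' @param s a [scenario()].
#' @param keepDraws if `TRUE`, attach the per-replicate estimates.
#' @return list of `sim_summary` objects, one per fitted model, each with
#'   fields `bias100`, `ese100`, `aseNaive100`, `aseRobust100`,
#'   `ecpNaive100`, `ecpRobust100`, `mcse100` (`= ese100 / sqrt(nsim)`),
#'   `nConverged`, `nsim`, `trueEta`.
#' @export
run_scenario <- function(s, keepDraws = FALSE) {
  stopifnot(inherits(s, "scenario"))
  seeds <- matrix(spawn_seeds(s$seed, 3L * s$nsim), ncol = 3L, byrow = TRUE)
  poisson <- inherits(s$process, "weibull_poisson_model")
  res <- lapply(s$models, function(m)
    list(beta = rep(NA_real_, s$nsim), se1 = rep(NA_real_, s$nsim),
         se2 = rep(NA_real_, s$nsim)))
  names(res) <- s$models

  for (r in seq_len(s$nsim)) {
    cov <- sample_covariates(s$covariate, s$n, seed = seeds[r, 1], pX = s$pX)
    cc <- sample_censoring(s$censoring, s$n, seed = seeds[r, 2])
    coh <- if (poisson)
      simulate_poisson_cohort(s$process, cov$x, cov$z, cc, seed = seeds[r, 3])
    else
      simulate_markov_cohort(s$process, cov$x, cov$z, cc, seed = seeds[r, 3])
    cd <- to_counting_data(coh, poolStratumAt = s$poolStratumAt)
    for (m in s$models) {
      fit <- tryCatch(suppressWarnings(
        if (m == "marginal") fit_marginal(cd, s$covariateColumns)
        else fit_partially_conditional(cd, s$covariateColumns)),
        error = function(e) NULL)
      if (!is.null(fit) && fit$converged) {
        res[[m]]$beta[r] <- fit$beta["x"]
        res[[m]]$se1[r] <- fit$naiveSE["x"]
        res[[m]]$se2[r] <- fit$robustSE["x"]
      }
    }
  }

  zq <- 1.959964
  out <- lapply(s$models, function(m) {
    b <- res[[m]]$beta; s1 <- res[[m]]$se1; s2 <- res[[m]]$se2
    ok <- !is.na(b)
    if (mean(!ok) > 0.01)
      warning(sprintf("%s model: %.1f%% of replicates did not converge",
                      m, 100 * mean(!ok)))
    b <- b[ok]; s1 <- s1[ok]; s2 <- s2[ok]
    sm <- list(model = m,
               bias100 = 100 * (mean(b) - s$trueEta),
               ese100 = 100 * stats::sd(b),
               aseNaive100 = 100 * mean(s1),
               aseRobust100 = 100 * mean(s2),
               ecpNaive100 = 100 * mean(abs(b - s$trueEta) <= zq * s1),
               ecpRobust100 = 100 * mean(abs(b - s$trueEta) <= zq * s2),
               nConverged = sum(ok), nsim = s$nsim, trueEta = s$trueEta)
    sm$mcse100 <- sm$ese100 / sqrt(sum(ok))
    if (keepDraws) sm$draws <- data.frame(beta = b, naiveSE = s1, robustSE = s2)
    structure(sm, class = "sim_summary")
  })
  names(out) <- s$models
  out
}

#' @exportS3Method base::print
print.sim_summary <- function(x, ...) {
  cat(sprintf(
    "%s model (x100): BIAS %.2f  ESE %.2f  ASE1 %.2f  ASE2 %.2f  ECP1 %.1f  ECP2 %.1f  [%d/%d converged]\n",
    x$model, x$bias100, x$ese100, x$aseNaive100, x$aseRobust100,
    x$ecpNaive100, x$ecpRobust100, x$nConverged, x$nsim))
  invisible(x)
}

## grid definitions for the three simulation studies
table_grid <- function(table) {
  if (table == 1 || table == 2) {
    expand.grid(pz = c(0.25, 0.5), phi = c(0.5, 1, 2, 4),
                zeta = c(0, log(1.5), log(3)), KEEP.OUT.ATTRS = FALSE)
  } else if (table == 4) {
    expand.grid(sigma_z = c(20, 26, 30),
                zeta = c(-0.50, -0.10, -0.01, 0, 0.20),
                KEEP.OUT.ATTRS = FALSE)
  } else stop("table must be 1, 2 or 4")
}

## scenario for one grid cell of a given study table
table_cell_scenario <- function(table, cell, nsim, seed, n = NULL,
                                overrides = list()) {
  ov <- function(name, default)
    if (!is.null(overrides[[name]])) overrides[[name]] else default
  if (table == 1) {
    proc <- weibull_poisson_model(
      lam = calibrate_weibull(ov("kappa", 1.25), ov("targetMean", 2),
                              ov("horizon", 1)),
      kappa = ov("kappa", 1.25), eta = ov("eta", log(0.75)),
      zeta = cell$zeta)
    covl <- solve_binary_joint(ov("pX", 0.5), cell$pz, cell$phi)
    cens <- censoring_scheme(ov("A", 1), ov("dropoutProb", 0.2))
    n <- if (is.null(n)) 1000L else n
  } else if (table == 2) {
    q0 <- ov("q0", calibrate_markov_q0(log(1.05), 5L, 20L, 2, 1))
    proc <- markov_model(q0, alpha = ov("alpha", log(1.05)),
                         K = ov("K", 5L), Km = ov("Km", 20L),
                         eta = ov("eta", log(0.75)), zeta = cell$zeta)
    covl <- solve_binary_joint(ov("pX", 0.5), cell$pz, cell$phi)
    cens <- censoring_scheme(ov("A", 1), ov("dropoutProb", 0.2))
    n <- if (is.null(n)) 1000L else n
  } else {
    proc <- markov_model(ov("q0", 0.0032), alpha = ov("alpha", 0.343),
                         K = ov("K", 2L), Km = ov("Km", 20L),
                         eta = ov("eta", -0.228), zeta = cell$zeta)
    covl <- normal_confounder(0, 0, cell$sigma_z)
    cens <- censoring_scheme(ov("A", 169), ov("dropoutProb", 0))
    n <- if (is.null(n)) 645L else n
  }
  scenario(proc, covl, cens, n = n, nsim = nsim, seed = seed,
           models = ov("models", c("marginal", "pc")),
           covariateColumns = ov("covariateColumns", "x"),
           pX = ov("pX", 0.5), poolStratumAt = ov("poolStratumAt", NULL))
}

#' Run a full simulation-study table
#'
#' Enumerates the grid of one of the three simulation studies and runs each
#' cell, returning a long-format data.frame mirroring the table layout.
#' Study 1: Poisson process (Weibull baseline, `kappa = 1.25`, scale
#' calibrated to 2 expected events at t = 1, `eta = log 0.75`, A = 1, 20%
#' dropout), binary covariate with `phi` in \{0.5, 1, 2, 4\}, `pz` in
#' \{0.25, 0.5\}, `zeta` in \{0, log 1.5, log 3\}, n = 1000. Study 2: the
#' same grid with a Markov process (`alpha = log 1.05`, K = 5, Km = 20,
#' `q0` calibrated to 2 expected events at t = 1). Study 4: trial-mimicking
#' Markov process (K = 2, Km = 20, `q0 = 0.0032`, `alpha = 0.343`,
#' `eta = -0.228`, A = 169, no dropout), normal covariate with mean 0 and
#' `sigma_z` in \{20, 26, 30\}, `zeta` in \{-0.5, -0.1, -0.01, 0, 0.2\},
#' n = 645.
#'
#' @param table which study: 1, 2 or 4.
#' @param nsim replicates per cell.
#' @param seed master seed; per-cell seeds are spawned deterministically so
#'   cells can be recomputed independently.
#' @param n subjects per replicate (default: the study's own n).
#' @param overrides named list of parameter overrides (e.g. `eta`, `A`,
#'   `dropoutProb`, `models`, `poolStratumAt`).
#' @param cells optional integer vector of grid-row indices to run (default
#'   all); the per-cell seed depends only on the cell's grid position.
#' @param out optional path: write the result as CSV.
#' @param verbose print per-cell progress.
#' @return data.frame with one row per (cell, model): `model`,
#'   `pz_or_sigma`, `phi` (NA for study 4), `zeta`, `bias100`, `ese100`,
#'   `ase1_100`, `ase2_100`, `ecp1_100`, `ecp2_100`, `mcse100`,
#'   `n_converged`.
#' @export
run_table <- function(table, nsim = 1000L, seed = 1L, n = NULL,
                      overrides = list(), cells = NULL, out = NULL,
                      verbose = interactive()) {
  grid <- table_grid(table)
  cellSeeds <- spawn_seeds(seed, nrow(grid))
  if (is.null(cells)) cells <- seq_len(nrow(grid))
  rows <- list()
  for (i in cells) {
    cell <- grid[i, , drop = FALSE]
    s <- table_cell_scenario(table, cell, nsim, cellSeeds[i], n, overrides)
    t0 <- Sys.time()
    sm <- run_scenario(s)
    if (verbose)
      message(sprintf("table %s cell %d/%d (%s) done in %.1f s", table, i,
                      nrow(grid), paste(names(cell), unlist(cell),
                                        sep = "=", collapse = ", "),
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    for (m in names(sm)) {
      x <- sm[[m]]
      rows[[length(rows) + 1L]] <- data.frame(
        model = m,
        pz_or_sigma = if (table == 4) cell$sigma_z else cell$pz,
        phi = if (table == 4) NA_real_ else cell$phi,
        zeta = cell$zeta,
        bias100 = x$bias100, ese100 = x$ese100,
        ase1_100 = x$aseNaive100, ase2_100 = x$aseRobust100,
        ecp1_100 = x$ecpNaive100, ecp2_100 = x$ecpRobust100,
        mcse100 = x$mcse100, n_converged = x$nConverged)
    }
  }
  res <- do.call(rbind, rows)
  if (!is.null(out)) utils::write.csv(res, out, row.names = FALSE)
  res
}

#' Compare a simulation summary with an asymptotic limit
#'
#' @param summary a `sim_summary` from [run_scenario()].
#' @param limit a `limit_result` from [limit_marginal()] or [limit_pc()].
#' @return list with the z-score
#'   `z = (bias_sim - bias_asymptotic) / (ese / sqrt(nsim))` and the flag
#'   `agrees = (|z| < 3)`.
#' @export
compare_to_limit <- function(summary, limit) {
  stopifnot(inherits(summary, "sim_summary"), inherits(limit, "limit_result"))
  mcse <- summary$ese100 / 100 / sqrt(summary$nConverged)
  z <- (summary$bias100 / 100 - limit$bias) / mcse
  list(z = z, agrees = abs(z) < 3, simBias = summary$bias100 / 100,
       asympBias = limit$bias, mcse = mcse)
}
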