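test_that("toy fits match closed forms and the brute-force score root", {
  cd <- to_counting_data(toy_histories())

  fm <- fit_marginal(cd, "x")
  expect_true(fm$converged)
  expect_lt(fm$scoreNorm, 1e-8)
  expect_equal(unname(fm$beta), log(0.5), tolerance = 1e-8)
  expect_equal(unname(fm$beta), brute_root(cd, stratified = FALSE),
               tolerance = 1e-8)

  fp <- fit_partially_conditional(cd, "x")
  expect_equal(unname(fp$beta), log((-1 + sqrt(17)) / 8), tolerance = 1e-8)
  expect_equal(unname(fp$beta), brute_root(cd, stratified = TRUE),
               tolerance = 1e-8)

  ## grid search on the score confirms the root location
  grid <- seq(-2, 0, by = 1e-4)
  um <- vapply(grid, function(b) abs(brute_score(cd, b, FALSE)), numeric(1))
  expect_lt(abs(grid[which.min(um)] - fm$beta), 1e-3)
  up <- vapply(grid, function(b) abs(brute_score(cd, b, TRUE)), numeric(1))
  expect_lt(abs(grid[which.min(up)] - fp$beta), 1e-3)
})

test_that("symmetric two-subject data give a zero treatment effect", {
  h <- list(event_history(1, 1, 0, 1, 0.5), event_history(2, 0, 0, 1, 0.5))
  cd <- to_counting_data(h)
  expect_equal(unname(fit_marginal(cd, "x")$beta), 0, tolerance = 1e-10)
})

test_that("fits agree with coxph (coefficients, naive and robust SE)", {
  skip_if_not_installed("survival")
  cd <- sim_small_poisson(n = 120, seed = 17)
  fm <- fit_marginal(cd, "x")
  cm <- survival::coxph(survival::Surv(start, stop, status) ~ x,
                        data = cd, cluster = id, ties = "breslow")
  expect_equal(unname(fm$beta), unname(coef(cm)), tolerance = 1e-7)
  expect_equal(unname(fm$naiveSE), sqrt(cm$naive.var[1, 1]), tolerance = 1e-7)
  expect_equal(unname(fm$robustSE), sqrt(cm$var[1, 1]), tolerance = 1e-7)

  fp <- fit_partially_conditional(cd, "x")
  cp <- survival::coxph(survival::Surv(start, stop, status) ~ x +
                          survival::strata(stratum),
                        data = cd, cluster = id, ties = "breslow")
  expect_equal(unname(fp$beta), unname(coef(cp)), tolerance = 1e-7)
  expect_equal(unname(fp$naiveSE), sqrt(cp$naive.var[1, 1]), tolerance = 1e-7)
  expect_equal(unname(fp$robustSE), sqrt(cp$var[1, 1]), tolerance = 1e-7)

  ## two-covariate fit
  fm2 <- fit_marginal(cd, c("x", "z"))
  cm2 <- survival::coxph(survival::Surv(start, stop, status) ~ x + z,
                         data = cd, cluster = id, ties = "breslow")
  expect_equal(unname(fm2$beta), unname(coef(cm2)), tolerance = 1e-6)
  expect_equal(unname(fm2$robustSE), sqrt(diag(cm2$var)), tolerance = 1e-6)
})

test_that("sandwich B uses per-subject aggregation (brute-force check)", {
  set.seed(33)
  h <- lapply(1:10, function(i) {
    nev <- rpois(1, 2)
    event_history(i, x = as.numeric(i <= 5), z = 0, c = 1,
                  eventTimes = sort(runif(nev)))
  })
  cd <- to_counting_data(h)
  for (stratified in c(FALSE, TRUE)) {
    fit <- if (stratified) fit_partially_conditional(cd, "x")
           else fit_marginal(cd, "x")
    Wb <- brute_residuals(cd, unname(fit$beta), stratified)
    expect_equal(unname(drop(fit$residuals)),
                 unname(Wb[as.character(unique(cd$id))]), tolerance = 1e-10)
    expect_equal(fit$B[1, 1], sum(Wb^2), tolerance = 1e-10)
  }
})

test_that("forcing beta = 0 recovers the Nelson-Aalen-type baseline", {
  cd <- sim_small_poisson(n = 60, seed = 5)
  fit0 <- suppressWarnings(fit_marginal(cd, "x", maxIter = 0L))
  evt <- sort(cd$stop[cd$status == 1L])
  na_inc <- vapply(evt, function(t) 1 / sum(cd$start < t & t <= cd$stop),
                   numeric(1))
  expect_equal(fit0$baseline$time, evt)
  expect_equal(fit0$baseline$increment, na_inc, tolerance = 1e-12)
})

test_that("fit is invariant to row splitting and subject permutation", {
  cd <- sim_small_poisson(n = 80, seed = 29)
  fm <- fit_marginal(cd, "x")

  ## split every censored row at its midpoint: same risk exposure
  split1 <- cd[cd$status == 0L & cd$stop - cd$start > 1e-6, ]
  mid <- (split1$start + split1$stop) / 2
  a <- split1; a$stop <- mid
  b <- split1; b$start <- mid
  keep <- cd[!(cd$status == 0L & cd$stop - cd$start > 1e-6), ]
  cd2 <- rbind(keep, a, b)
  fm2 <- fit_marginal(cd2, "x")
  expect_equal(unname(fm2$beta), unname(fm$beta), tolerance = 1e-10)
  expect_equal(unname(fm2$robustSE), unname(fm$robustSE), tolerance = 1e-10)

  ## permuting rows/subjects changes nothing beyond float noise
  set.seed(1)
  cd3 <- cd[sample(nrow(cd)), ]
  fm3 <- fit_marginal(cd3, "x")
  expect_equal(unname(fm3$beta), unname(fm$beta), tolerance = 1e-10)
  expect_equal(unname(fm3$naiveSE), unname(fm$naiveSE), tolerance = 1e-10)
  expect_equal(unname(fm3$robustSE), unname(fm$robustSE), tolerance = 1e-10)
})

test_that("with a single stratum the stratified score reduces to the marginal one", {
  ## survival-style data: follow-up ends at the (single) event, so only
  ## stratum 1 exists and the two fits coincide
  set.seed(44)
  h <- lapply(1:50, function(i) {
    ev <- if (runif(1) < 0.5) runif(1) else numeric(0)
    event_history(i, rbinom(1, 1, 0.5), 0,
                  c = if (length(ev)) ev else 1, eventTimes = ev)
  })
  cd <- to_counting_data(h)
  expect_true(all(cd$stratum == 1L))
  fm <- fit_marginal(cd, "x")
  fp <- fit_partially_conditional(cd, "x")
  expect_equal(unname(fp$beta), unname(fm$beta), tolerance = 1e-10)
  expect_equal(unname(fp$robustSE), unname(fm$robustSE), tolerance = 1e-10)

  ## likewise on recurrent-event data whose stratum is collapsed to 1
  cd2 <- sim_small_poisson(n = 60, seed = 91)
  cd2$stratum <- 1L
  expect_equal(unname(fit_partially_conditional(cd2, "x")$beta),
               unname(fit_marginal(cd2, "x")$beta), tolerance = 1e-10)
})

test_that("correctly specified fits recover (eta, zeta) across replicates", {
  j <- solve_binary_joint(0.5, 0.3, 2)
  cs <- censoring_scheme(1, 0.2)
  m <- weibull_poisson_model(calibrate_weibull(1.25, 2, 1), 1.25,
                             log(0.75), log(2))
  nrep <- 30
  est <- matrix(NA_real_, nrep, 2)
  seeds <- recurbias:::spawn_seeds(2024, nrep)
  for (r in seq_len(nrep)) {
    set.seed(seeds[r])
    cov <- sample_covariates(j, 1000)
    cc <- sample_censoring(cs, 1000)
    coh <- simulate_poisson_cohort(m, cov$x, cov$z, cc)
    est[r, ] <- fit_marginal(to_counting_data(coh), c("x", "z"))$beta
  }
  mc <- apply(est, 2, sd) / sqrt(nrep)
  expect_lt(abs(mean(est[, 1]) - log(0.75)), 3 * mc[1])
  expect_lt(abs(mean(est[, 2]) - log(2)), 3 * mc[2])
})

test_that("degenerate inputs raise clear errors", {
  cd <- to_counting_data(toy_histories())
  noev <- cd; noev$status <- 0L
  expect_error(fit_marginal(noev, "x"), "no events")
  expect_error(fit_marginal(cd, c("x", "nope")), "lacks columns")
  bad <- cd; bad$start[1] <- bad$stop[1]
  expect_error(fit_marginal(bad, "x"), "start < stop")
})

test_that("wald_ci computes normal-quantile intervals for both SEs", {
  cd <- to_counting_data(toy_histories())
  fit <- fit_marginal(cd, "x")
  ci <- wald_ci(fit, 0.95)
  expect_equal(nrow(ci), 2L)
  r <- ci[ci$type == "robust", ]
  expect_equal(r$lower, r$estimate - qnorm(0.975) * r$se, tolerance = 1e-12)
  ## beta 0, SE 1 reference case
  fake <- fit; fake$beta <- c(x = 0); fake$naiveSE <- fake$robustSE <- c(x = 1)
  ci0 <- wald_ci(fake, 0.95)
  expect_equal(ci0$lower, rep(-1.959964, 2), tolerance = 1e-6)
  expect_equal(ci0$upper, rep(1.959964, 2), tolerance = 1e-6)
})
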