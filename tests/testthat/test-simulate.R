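test_that("calibrate_weibull hits the target mean", {
  expect_equal(calibrate_weibull(1, 2, 1), 2)
  lam <- calibrate_weibull(1.25, 2, 1)
  expect_equal(lam, 2^0.8, tolerance = 1e-12)
  m <- weibull_poisson_model(lam, 1.25)
  expect_equal(mu0_weibull(m, 1), 2, tolerance = 1e-12)
})

test_that("Poisson generator: homogeneous special case is Poisson(2)", {
  m <- weibull_poisson_model(lam = 2, kappa = 1)
  n <- 1e5
  coh <- simulate_poisson_cohort(m, rep(0, n), rep(0, n), rep(1, n), seed = 21)
  counts <- tabulate(coh$events$id, nbins = n)
  expect_lt(abs(mean(counts) - 2), 3 * sqrt(2 / n))
  ## chi-square GOF against Poisson(2), pooling the tail
  kmax <- 8
  obs <- c(vapply(0:(kmax - 1), function(k) sum(counts == k), numeric(1)),
           sum(counts >= kmax))
  p <- c(dpois(0:(kmax - 1), 2), ppois(kmax - 1, 2, lower.tail = FALSE))
  chi2 <- sum((obs - n * p)^2 / (n * p))
  expect_gt(pchisq(chi2, df = kmax, lower.tail = FALSE), 0.01)
})

test_that("Poisson generator: calibrated Weibull case has mean 2 at t=1", {
  m <- weibull_poisson_model(calibrate_weibull(1.25, 2, 1), 1.25)
  n <- 1e5
  coh <- simulate_poisson_cohort(m, rep(0, n), rep(0, n), rep(1, n), seed = 22)
  counts <- tabulate(coh$events$id, nbins = n)
  expect_lt(abs(mean(counts) - 2), 3 * sd(counts) / sqrt(n))
})

test_that("Poisson histories are valid and reproducible", {
  m <- weibull_poisson_model(calibrate_weibull(1.25, 2, 1), 1.25,
                             log(0.75), log(3))
  h <- simulate_poisson_history(m, 1, 1, 0.8, seed = 31)
  expect_s3_class(h, "event_history")
  if (length(h$eventTimes)) {
    expect_true(all(h$eventTimes > 0 & h$eventTimes <= 0.8))
    expect_false(is.unsorted(h$eventTimes, strictly = TRUE))
  }
  expect_identical(simulate_poisson_history(m, 1, 1, 0.8, seed = 31), h)
  coh <- simulate_poisson_cohort(m, rep(1, 50), rep(1, 50), rep(1, 50), seed = 8)
  expect_identical(simulate_poisson_cohort(m, rep(1, 50), rep(1, 50),
                                           rep(1, 50), seed = 8), coh)
  expect_true(all(coh$events$time > 0 & coh$events$time <= 1))
})

test_that("time-transformed Poisson event times form a unit-rate process", {
  ## For fixed (x, z), mu0(t) e^(eta x + zeta z) maps event times to a
  ## unit-rate Poisson process on (0, T*]; conditional on the counts, the
  ## pooled transformed times are therefore exactly iid Uniform(0, T*).
  m <- weibull_poisson_model(calibrate_weibull(1.25, 3, 1), 1.25,
                             log(0.75), log(2))
  n <- 4000
  coh <- simulate_poisson_cohort(m, rep(1, n), rep(1, n), rep(1, n), seed = 41)
  mult <- exp(m$eta + m$zeta)
  tstar <- mu0_weibull(m, 1) * mult
  u <- mu0_weibull(m, coh$events$time) * mult / tstar
  ks <- suppressWarnings(ks.test(u, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("intensity matrix has the stated escalating structure", {
  mm <- markov_model(1, alpha = 0, K = 3, Km = 6)
  Q <- build_intensity_matrix(mm)
  expect_true(all(abs(rowSums(Q)) == 0))
  expect_true(all(Q[cbind(1:6, 2:7)] == 1))

  mm2 <- markov_model(0.5, alpha = log(1.05), K = 5, Km = 20)
  Q2 <- build_intensity_matrix(mm2)
  ## oracle: enumerate q_k directly from the recursion
  q <- numeric(20); q[1] <- 0.5
  for (k in 2:20) q[k] <- if (k - 1 <= 5 + 1) q[k - 1] * 1.05 else q[k - 1]
  expect_equal(Q2[cbind(1:20, 2:21)], q, tolerance = 1e-12)
  expect_equal(Q2[1, 2], 0.5)
  expect_equal(Q2[7, 8], 0.5 * 1.05^6, tolerance = 1e-12)
  expect_equal(Q2[8, 9], Q2[7, 8])
  expect_true(all(Q2[21, ] == 0))
  expect_true(all(rowSums(Q2) == 0))
})

test_that("markov_expected_count matches the Poisson special case", {
  mm <- markov_model(2, alpha = 0, K = 0, Km = 20)
  expect_lt(abs(markov_expected_count(mm, 1) - 2), 1e-10)
  expect_identical(markov_expected_count(mm, 0), 0)
  grid <- markov_expected_count(mm, seq(0.1, 2, by = 0.1))
  expect_true(all(diff(grid) > 0))
})

test_that("calibrate_markov_q0 hits the target and matches simulation", {
  expect_equal(calibrate_markov_q0(0, 0, 20, 2, 1), 2, tolerance = 1e-8)
  q0 <- calibrate_markov_q0(log(1.05), 5, 20, 2, 1)
  expect_lt(q0, 2)  # escalation inflates the mean, so q0 must sit below 2
  mm <- markov_model(q0, log(1.05), 5, 20)
  expect_lt(abs(markov_expected_count(mm, 1) - 2), 1e-8)
  ## simulation oracle
  n <- 3e4
  coh <- simulate_markov_cohort(mm, rep(0, n), rep(0, n), rep(1, n), seed = 51)
  counts <- tabulate(coh$events$id, nbins = n)
  expect_lt(abs(mean(counts) - 2), 3 * sd(counts) / sqrt(n))
})

test_that("Markov generator: alpha=0 is Poisson; absorbing cap respected", {
  mm <- markov_model(2, alpha = 0, K = 0, Km = 30)
  n <- 1e5
  coh <- simulate_markov_cohort(mm, rep(0, n), rep(0, n), rep(1, n), seed = 61)
  counts <- tabulate(coh$events$id, nbins = n)
  kmax <- 8
  obs <- c(vapply(0:(kmax - 1), function(k) sum(counts == k), numeric(1)),
           sum(counts >= kmax))
  p <- c(dpois(0:(kmax - 1), 2), ppois(kmax - 1, 2, lower.tail = FALSE))
  chi2 <- sum((obs - n * p)^2 / (n * p))
  expect_gt(pchisq(chi2, df = kmax, lower.tail = FALSE), 0.01)

  ## the absorbing state stops the process
  mm3 <- markov_model(50, alpha = 0, K = 0, Km = 3)
  coh3 <- simulate_markov_cohort(mm3, rep(0, 500), rep(0, 500), rep(1, 500),
                                 seed = 62)
  expect_lte(max(tabulate(coh3$events$id, nbins = 500)), 3)

  ## the study setting essentially never reaches the absorbing state
  q0 <- calibrate_markov_q0(log(1.05), 5, 20, 2, 1)
  mm4 <- markov_model(q0, log(1.05), 5, 20, eta = log(0.75), zeta = log(3))
  coh4 <- simulate_markov_cohort(mm4, rep(1, n), rep(1, n), rep(1, n), seed = 63)
  expect_identical(sum(tabulate(coh4$events$id, nbins = n) >= 20), 0L)

  expect_identical(simulate_markov_cohort(mm, rep(0, 20), rep(0, 20),
                                          rep(1, 20), seed = 64),
                   simulate_markov_cohort(mm, rep(0, 20), rep(0, 20),
                                          rep(1, 20), seed = 64))
})

test_that("markov_expected_count agrees with the simulated mean", {
  mm <- markov_model(1.2, alpha = log(1.3), K = 4, Km = 25)
  n <- 3e4
  coh <- simulate_markov_cohort(mm, rep(0, n), rep(0, n), rep(1.5, n), seed = 71)
  counts <- tabulate(coh$events$id, nbins = n)
  expect_lt(abs(mean(counts) - markov_expected_count(mm, 1.5)),
            3 * sd(counts) / sqrt(n))
})

test_that("cohort CSV round trip preserves the data", {
  m <- weibull_poisson_model(2, 1.25, -0.3, 0.5)
  coh <- simulate_poisson_cohort(m, rep(c(0, 1), 10), rnorm(20), rep(1, 20),
                                 seed = 81)
  fs <- tempfile(fileext = ".csv"); fe <- tempfile(fileext = ".csv")
  write_cohort_csv(coh, fs, fe)
  back <- read_cohort_csv(fs, fe)
  expect_equal(back$subjects, coh$subjects, tolerance = 1e-15)
  expect_equal(back$events, coh$events, tolerance = 1e-15)
})
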