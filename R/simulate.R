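#' Modulated Weibull-Poisson recurrent event model
#'
#' Event times follow an inhomogeneous Poisson process with rate
#' \deqn{\rho(t | x, z) = \rho_0(t) \exp(\eta x + \zeta z), \qquad
#'       \rho_0(t) = \lambda \kappa (\lambda t)^{\kappa - 1},}
#' so the cumulative baseline mean is \eqn{\mu_0(t) = (\lambda t)^\kappa}.
#'
#' @param lam Weibull scale \eqn{\lambda > 0} (inverse time units).
#' @param kappa Weibull shape \eqn{\kappa > 0}.
#' @param eta treatment log rate ratio.
#' @param zeta covariate log rate ratio.
#' @return An object of class `weibull_poisson_model`.
#' @export
weibull_poisson_model <- function(lam, kappa = 1, eta = 0, zeta = 0) {
  stopifnot(lam > 0, kappa > 0)
  structure(list(lam = lam, kappa = kappa, eta = eta, zeta = zeta),
            class = "weibull_poisson_model")
}

#' Cumulative baseline mean of a Weibull-Poisson model
#' @param model a [weibull_poisson_model()].
#' @param t vector of times, >= 0.
#' @return \eqn{\mu_0(t) = (\lambda t)^\kappa}.
#' @export
mu0_weibull <- function(model, t) (model$lam * t)^model$kappa

## inverse of mu0: t = u^(1/kappa) / lambda
mu0_inv_weibull <- function(model, u) u^(1 / model$kappa) / model$lam

#' Calibrate the Weibull scale to a target mean event count
#'
#' Returns the \eqn{\lambda} for which an uncensored baseline subject
#' (\eqn{x = z = 0}) expects `targetMean` events by `horizon`:
#' \eqn{(\lambda \cdot \mathrm{horizon})^\kappa = } `targetMean`.
#'
#' @param kappa Weibull shape.
#' @param targetMean target expected count, > 0.
#' @param horizon reference time, > 0.
#' @return the scale `lam`.
#' @examples
#' calibrate_weibull(1.25, 2, 1)  # 2^0.8
#' @export
calibrate_weibull <- function(kappa, targetMean, horizon) {
  stopifnot(kappa > 0, targetMean > 0, horizon > 0)
  targetMean^(1 / kappa) / horizon
}

#' One subject's recurrent event history
#'
#' @param subjectId identifier.
#' @param x treatment (0/1).
#' @param z covariate value.
#' @param c censoring (end of follow-up) time, > 0.
#' @param eventTimes strictly increasing event times in `(0, c]`.
#' @return An object of class `event_history`.
#' @export
event_history <- function(subjectId, x, z, c, eventTimes = numeric(0)) {
  stopifnot(c > 0)
  eventTimes <- as.numeric(eventTimes)
  if (length(eventTimes)) {
    if (is.unsorted(eventTimes, strictly = TRUE))
      stop("eventTimes must be strictly increasing")
    if (any(eventTimes <= 0) || any(eventTimes > c))
      stop("eventTimes must lie in (0, c]")
  }
  structure(list(subjectId = subjectId, x = x, z = z, c = c,
                 eventTimes = eventTimes),
            class = "event_history")
}

#' @exportS3Method base::print
print.event_history <- function(x, ...) {
  cat("Subject", x$subjectId, ": x =", x$x, ", z =", format(x$z),
      ", followed to", format(x$c), "-", length(x$eventTimes), "event(s)\n")
  if (length(x$eventTimes)) cat("  at:", paste(format(x$eventTimes), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate one Poisson-process event history
#'
#' Gap-inversion of the cumulative intensity: from current time `t` the next
#' event occurs at \eqn{\mu_0^{-1}(\mu_0(t) + E / e^{\eta x + \zeta z})}
#' with `E ~ Exp(1)`; generation stops past the censoring time `c`.
#'
#' @param model a [weibull_poisson_model()].
#' @param x,z subject covariates.
#' @param c censoring time, > 0.
#' @param seed optional integer seed.
#' @param subjectId identifier for the returned history.
#' @return an [event_history()].
#' @export
simulate_poisson_history <- function(model, x, z, c, seed = NULL, subjectId = 1L) {
  stopifnot(inherits(model, "weibull_poisson_model"), c > 0)
  if (!is.null(seed)) set.seed(seed)
  mult <- exp(model$eta * x + model$zeta * z)
  cap <- mu0_weibull(model, c)
  times <- numeric(0)
  cum <- 0
  repeat {
    cum <- cum + stats::rexp(1) / mult
    if (cum > cap) break
    times <- c(times, mu0_inv_weibull(model, cum))
  }
  event_history(subjectId, x, z, c, times)
}

#' Simulate a cohort of Poisson-process histories
#'
#' Vectorized batch version of [simulate_poisson_history()]: all active
#' subjects draw their next standardized gap in rounds, which is the same
#' gap-inversion construction applied breadth-first.
#'
#' @param model a [weibull_poisson_model()].
#' @param x,z covariate vectors (length n).
#' @param c censoring-time vector (length n).
#' @param seed optional integer seed.
#' @return a `cohort`: list with `subjects` (data.frame `id, x, z, c`) and
#'   `events` (data.frame `id, time`, ordered by id then time).
#' @export
simulate_poisson_cohort <- function(model, x, z, c, seed = NULL) {
  stopifnot(inherits(model, "weibull_poisson_model"))
  n <- length(c)
  stopifnot(length(x) == n, length(z) == n, all(c > 0))
  if (!is.null(seed)) set.seed(seed)
  mult <- exp(model$eta * x + model$zeta * z)
  cap <- mu0_weibull(model, c)
  cum <- numeric(n)
  active <- seq_len(n)
  ids <- integer(0); times <- numeric(0)
  while (length(active)) {
    cum[active] <- cum[active] + stats::rexp(length(active)) / mult[active]
    alive <- cum[active] <= cap[active]
    hit <- active[alive]
    if (length(hit)) {
      ids <- c(ids, hit)
      times <- c(times, mu0_inv_weibull(model, cum[hit]))
    }
    active <- hit
  }
  o <- order(ids, times)
  list(subjects = data.frame(id = seq_len(n), x = x, z = z, c = c),
       events = data.frame(id = ids[o], time = times[o]))
}

#' State-escalating Markov recurrent event model
#'
#' Transitions `k -> k+1` (k = current cumulative event count) occur with
#' intensity \eqn{q_k \exp(\eta x + \zeta z)} where
#' \eqn{q_k = q_0 e^{\alpha \min(k, K+1)}}: each of the first `K + 1` events
#' scales the baseline rate of the next event by \eqn{e^\alpha}, after which
#' the rate is constant. At most `Km` transitions are modelled (state `Km`
#' is absorbing); `Km` should be large enough that reaching it within the
#' observation window is essentially impossible.
#'
#' @param q0 baseline transition rate out of state 0, > 0.
#' @param alpha per-event log escalation.
#' @param K last escalating event index (escalation applies to events
#'   `1..K+1`).
#' @param Km maximum number of transitions modelled.
#' @param eta,zeta log rate ratios for treatment and covariate.
#' @return An object of class `markov_model` with the rate vector `q`
#'   (`q[k+1]` = rate out of state `k`, `k = 0..Km-1`).
#' @export
markov_model <- function(q0, alpha = 0, K = 0, Km = 20, eta = 0, zeta = 0) {
  stopifnot(q0 > 0, Km >= 1, K >= 0, K < Km)
  k <- 0:(Km - 1)
  q <- q0 * exp(alpha * pmin(k, K + 1))
  structure(list(q0 = q0, alpha = alpha, K = K, Km = Km,
                 eta = eta, zeta = zeta, q = q),
            class = "markov_model")
}

#' Transition intensity matrix of the Markov model
#'
#' Builds the `(Km+1) x (Km+1)` upper-bidiagonal intensity matrix `Q` for
#' the baseline covariate pattern: `Q[j, j] = -q[j-1]`, `Q[j, j+1] = q[j-1]`
#' and the last row (absorbing state) is zero. Row sums are exactly 0.
#'
#' @param model a [markov_model()].
#' @return a base matrix of rates.
#' @export
build_intensity_matrix <- function(model) {
  stopifnot(inherits(model, "markov_model"))
  m <- model$Km + 1L
  Q <- matrix(0, m, m)
  idx <- seq_len(model$Km)
  Q[cbind(idx, idx)] <- -model$q
  Q[cbind(idx, idx + 1L)] <- model$q
  Q
}

#' Expected event count under the Markov model
#'
#' Chapman-Kolmogorov: the state-occupancy probabilities at `t` for a
#' baseline subject are the first row of `expm(Q t)`, and the expected count
#' is \eqn{\mu(t | X=0, Z=0) = \sum_k k \, P_{1,k+1}(0, t)}.
#'
#' @param model a [markov_model()].
#' @param t time, >= 0 (vectorized).
#' @return expected number of events by `t` for `x = z = 0`.
#' @export
markov_expected_count <- function(model, t) {
  stopifnot(inherits(model, "markov_model"), all(t >= 0))
  Q <- build_intensity_matrix(model)
  vapply(t, function(ti) {
    if (ti == 0) return(0)
    P <- as.matrix(Matrix::expm(Q * ti))
    sum((0:model$Km) * P[1L, ])
  }, numeric(1))
}

#' Calibrate the Markov base rate q0 to a target mean count
#'
#' Root-finds `q0` such that [markov_expected_count()] at `horizon` equals
#' `targetMean`, for fixed escalation parameters.
#'
#' @param alpha per-event log escalation.
#' @param K last escalating event index.
#' @param Km maximum transitions modelled.
#' @param targetMean target expected count at `horizon`, > 0.
#' @param horizon reference time, > 0.
#' @param tol root tolerance on the expected count.
#' @return the calibrated `q0`.
#' @export
calibrate_markov_q0 <- function(alpha, K, Km, targetMean, horizon, tol = 1e-10) {
  stopifnot(targetMean > 0, horizon > 0)
  f <- function(q0)
    markov_expected_count(markov_model(q0, alpha, K, Km), horizon) - targetMean
  ## the expected count is increasing in q0; bracket around the alpha=0 value
  q_lo <- targetMean / horizon * 1e-3
  q_hi <- targetMean / horizon * 1e3
  if (f(q_lo) > 0 || f(q_hi) < 0)
    stop("calibrate_markov_q0: root not bracketed in [", q_lo, ", ", q_hi, "]")
  stats::uniroot(f, c(q_lo, q_hi), tol = tol * horizon / targetMean)$root
}

#' Simulate one Markov-process event history
#'
#' Sequential exponential gaps: while in state `k < Km` the time to the next
#' event is `Exp(q[k] * exp(eta x + zeta z))`; generation stops at the
#' censoring time or on entering the absorbing state `Km`.
#'
#' @inheritParams simulate_poisson_history
#' @param model a [markov_model()].
#' @return an [event_history()].
#' @export
simulate_markov_history <- function(model, x, z, c, seed = NULL, subjectId = 1L) {
  stopifnot(inherits(model, "markov_model"), c > 0)
  if (!is.null(seed)) set.seed(seed)
  mult <- exp(model$eta * x + model$zeta * z)
  times <- numeric(0)
  t <- 0
  for (k in 0:(model$Km - 1L)) {
    t <- t + stats::rexp(1, model$q[k + 1L] * mult)
    if (t > c) break
    times <- c(times, t)
  }
  event_history(subjectId, x, z, c, times)
}

#' Simulate a cohort of Markov-process histories
#'
#' Vectorized over subjects: in round `k` every subject still under
#' observation and in state `k` draws its `Exp(q[k] e^{\eta x + \zeta z})`
#' gap, so at most `Km` vectorized rounds are needed.
#'
#' @inheritParams simulate_poisson_cohort
#' @param model a [markov_model()].
#' @return a `cohort` list (`subjects`, `events`) as in
#'   [simulate_poisson_cohort()].
#' @export
simulate_markov_cohort <- function(model, x, z, c, seed = NULL) {
  stopifnot(inherits(model, "markov_model"))
  n <- length(c)
  stopifnot(length(x) == n, length(z) == n, all(c > 0))
  if (!is.null(seed)) set.seed(seed)
  mult <- exp(model$eta * x + model$zeta * z)
  tcur <- numeric(n)
  active <- seq_len(n)
  ids <- integer(0); times <- numeric(0)
  for (k in 0:(model$Km - 1L)) {
    if (!length(active)) break
    tcur[active] <- tcur[active] +
      stats::rexp(length(active), model$q[k + 1L] * mult[active])
    hit <- active[tcur[active] <= c[active]]
    if (length(hit)) {
      ids <- c(ids, hit)
      times <- c(times, tcur[hit])
    }
    active <- hit
  }
  o <- order(ids, times)
  list(subjects = data.frame(id = seq_len(n), x = x, z = z, c = c),
       events = data.frame(id = ids[o], time = times[o]))
}

#' Write / read a cohort as a two-file CSV pair
#'
#' @param cohort a cohort list (`subjects`, `events`).
#' @param subjectsFile,eventsFile file paths.
#' @return `read_cohort_csv` returns a cohort list; `write_cohort_csv`
#'   returns its input invisibly.
#' @export
write_cohort_csv <- function(cohort, subjectsFile, eventsFile) {
  utils::write.csv(format(cohort$subjects, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   subjectsFile, row.names = FALSE, quote = FALSE)
  utils::write.csv(format(cohort$events, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   eventsFile, row.names = FALSE, quote = FALSE)
  invisible(cohort)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(subjectsFile, eventsFile) {
  list(subjects = utils::read.csv(subjectsFile),
       events = utils::read.csv(eventsFile))
}
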