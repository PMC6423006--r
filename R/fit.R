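## Newton solver shared by the marginal and partially conditional fitters.
## The two models differ only in the stratum variable: the marginal model
## treats all rows as one stratum; the partially conditional model keeps the
## time-dependent event-count stratum, restricting risk sets within stratum
## and giving each stratum its own Breslow baseline.
fit_rate_model <- function(data, covariateColumns, stratified,
                           maxIter = 50L, tol = 1e-10,
                           smallSample = FALSE, betaInit = NULL) {
  stopifnot(is.data.frame(data))
  need <- c("id", "start", "stop", "status", covariateColumns)
  if (stratified) need <- c(need, "stratum")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("data lacks columns: ", paste(miss, collapse = ", "))
  if (any(data$start >= data$stop)) stop("rows must satisfy start < stop")
  if (!any(data$status == 1L)) stop("no events in the data")

  X <- as.matrix(data[, covariateColumns, drop = FALSE])
  storage.mode(X) <- "double"
  p <- ncol(X)
  ids <- unique(data$id)
  subject <- match(data$id, ids) - 1L
  stratum <- if (stratified) as.integer(data$stratum) else rep(1L, nrow(data))

  beta <- if (is.null(betaInit)) numeric(p) else as.numeric(betaInit)
  cur <- .ag_score(data$start, data$stop, as.integer(data$status), stratum,
                   X, subject, length(ids), beta, FALSE)
  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    step <- tryCatch(solve(cur$info, cur$score),
                     error = function(e) stop("singular information matrix; ",
                                              "are the covariates collinear ",
                                              "on the risk sets?"))
    ## step-halving on non-increase of the log partial likelihood (slack
    ## relative to its magnitude: the loglik is a sum over all events and
    ## carries rounding noise of that order); a step that shrinks the score
    ## norm is also accepted, which matters near the noise floor
    slack <- 1e-11 * (1 + abs(cur$loglik))
    curNorm <- sqrt(sum(cur$score^2))
    fac <- 1
    repeat {
      cand <- beta + fac * step
      new <- .ag_score(data$start, data$stop, as.integer(data$status), stratum,
                       X, subject, length(ids), cand, FALSE)
      if (new$loglik >= cur$loglik - slack ||
          sqrt(sum(new$score^2)) < curNorm || fac < 1 / 1024) break
      fac <- fac / 2
    }
    delta <- max(abs(cand - beta))
    beta <- cand
    cur <- new
    ## noise floor for "score is numerically zero": the score is a sum of
    ## O(1) per-event terms, so its rounding noise scales with the event
    ## count; 1e-8 suffices up to ~10^4 events
    nfloor <- max(1e-8, 1e-12 * cur$nevent)
    if (sqrt(sum(cur$score^2)) < tol) { converged <- TRUE; break }
    ## the step no longer moves beta and the score sits at the noise floor
    if (delta < 1e-12 && sqrt(sum(cur$score^2)) < nfloor) { converged <- TRUE; break }
  }
  if (!converged && sqrt(sum(cur$score^2)) < max(1e-8, 1e-12 * cur$nevent))
    converged <- TRUE
  if (!converged)
    warning("Newton iteration did not converge (score norm ",
            format(sqrt(sum(cur$score^2))),
            "); possible separation on the risk sets")

  full <- .ag_score(data$start, data$stop, as.integer(data$status), stratum,
                    X, subject, length(ids), beta, TRUE)
  A <- full$info
  W <- full$residuals
  B <- crossprod(W)
  if (smallSample) B <- B * length(ids) / (length(ids) - p)
  Ainv <- solve(A)
  robust <- Ainv %*% B %*% t(Ainv)

  baseline <- data.frame(stratum = full$baselineStratum,
                         time = full$baselineTime,
                         increment = full$baselineInc)
  baseline <- baseline[order(baseline$stratum, baseline$time), ]
  rownames(baseline) <- NULL

  structure(list(
    beta = stats::setNames(as.numeric(beta), covariateColumns),
    naiveSE = stats::setNames(sqrt(diag(Ainv)), covariateColumns),
    robustSE = stats::setNames(sqrt(diag(robust)), covariateColumns),
    naiveVar = Ainv, robustVar = robust,
    A = A, B = B, residuals = W,
    scoreNorm = sqrt(sum(full$score^2)),
    loglik = full$loglik,
    baseline = baseline,
    nEvents = full$nevent, nSubjects = length(ids),
    iterations = iter, converged = converged,
    model = if (stratified) "pc" else "marginal"),
    class = "recur_fit")
}

#' Fit the marginal (Andersen-Gill-type) rate model
#'
#' Solves the profile partial score equation
#' \deqn{U(\beta) = \sum_i \int_0^\infty Y_i(t)\left\{X_i -
#'   \frac{S^{(1)}(\beta,t)}{S^{(0)}(\beta,t)}\right\} dN_i(t) = 0}
#' by Newton iteration, where all at-risk rows form a single risk set at
#' each event time. The baseline is the profile Breslow-type estimator
#' \eqn{d\tilde\mu_0(t;\hat\beta) = d\bar N(t) / \sum_i Y_i(t)
#' e^{X_i'\hat\beta}}. The naive variance is the inverse observed
#' information; the robust sandwich variance is
#' \eqn{\mathcal{A}^{-1}\mathcal{B}\mathcal{A}^{-1}} with \eqn{\mathcal{B}}
#' the outer-product sum of per-subject score residuals (own-event terms
#' minus the subject's compensator under the profiled baseline), which is
#' valid when the rate model is misspecified.
#'
#' @param data a `counting_data` data.frame (see [to_counting_data()]).
#' @param covariateColumns character vector of covariate column names.
#' @param maxIter,tol Newton controls: at most `maxIter` iterations,
#'   convergence when the score norm falls below `tol`.
#' @param smallSample if `TRUE`, multiply the sandwich middle term by
#'   `n/(n-p)`; the asymptotics carry no such factor, so the default is off.
#' @param betaInit optional starting value (default 0).
#' @return An object of class `recur_fit` with elements `beta`, `naiveSE`,
#'   `robustSE`, `scoreNorm`, `baseline` (per-stratum Breslow steps),
#'   `nEvents`, `nSubjects`, `converged`, and the variance components
#'   `A`, `B`, `residuals`.
#' @examples
#' h <- list(event_history(1, 1, 0, 1, 0.5),
#'           event_history(2, 1, 0, 1),
#'           event_history(3, 0, 0, 1, c(0.25, 0.75)),
#'           event_history(4, 0, 0, 1))
#' fit_marginal(to_counting_data(h), "x")$beta   # log 0.5
#' @export
fit_marginal <- function(data, covariateColumns = "x", maxIter = 50L,
                         tol = 1e-10, smallSample = FALSE, betaInit = NULL) {
  fit_rate_model(data, covariateColumns, stratified = FALSE,
                 maxIter = maxIter, tol = tol, smallSample = smallSample,
                 betaInit = betaInit)
}

#' Fit the partially conditional (event-count-stratified) rate model
#'
#' Solves the stratified pseudo-score equation in which subject `i`
#' contributes to the risk set for a `j`th event only while their cumulative
#' event count is `j - 1`: \eqn{S_j^{(r)}(\beta,t)} sums over rows in
#' stratum `j` at risk at `t`, and each stratum gets its own Breslow
#' baseline. Naive and robust variances are formed as in [fit_marginal()],
#' with residuals accumulated across strata within subject. When the data
#' contain a single stratum the stratified score reduces to the marginal
#' one and the two fits coincide.
#'
#' @inheritParams fit_marginal
#' @return An object of class `recur_fit`.
#' @export
fit_partially_conditional <- function(data, covariateColumns = "x",
                                      maxIter = 50L, tol = 1e-10,
                                      smallSample = FALSE, betaInit = NULL) {
  fit_rate_model(data, covariateColumns, stratified = TRUE,
                 maxIter = maxIter, tol = tol, smallSample = smallSample,
                 betaInit = betaInit)
}

#' @exportS3Method base::print
print.recur_fit <- function(x, ...) {
  cat(if (x$model == "pc") "Partially conditional" else "Marginal",
      "rate model:", x$nEvents, "events,", x$nSubjects, "subjects\n")
  tab <- data.frame(coef = x$beta, `exp(coef)` = exp(x$beta),
                    `naive se` = x$naiveSE, `robust se` = x$robustSE,
                    check.names = FALSE)
  print(tab, ...)
  if (!x$converged) cat("WARNING: did not converge\n")
  invisible(x)
}

#' Wald confidence intervals from a fitted rate model
#'
#' @param fit a `recur_fit`.
#' @param level confidence level in (0, 1).
#' @return data.frame with one row per coefficient and per SE type
#'   (`naive`, `robust`): `estimate`, `se`, `lower`, `upper`.
#' @export
wald_ci <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "recur_fit"), level > 0, level < 1)
  zq <- stats::qnorm((1 + level) / 2)
  out <- do.call(rbind, lapply(c("naive", "robust"), function(type) {
    se <- if (type == "naive") fit$naiveSE else fit$robustSE
    data.frame(coefficient = names(fit$beta), type = type,
               estimate = as.numeric(fit$beta), se = as.numeric(se),
               lower = as.numeric(fit$beta - zq * se),
               upper = as.numeric(fit$beta + zq * se))
  }))
  rownames(out) <- NULL
  out
}
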