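#' Binary covariate joint law with given margins and odds ratio
#'
#' Constructs the unique 2x2 joint distribution of a binary treatment
#' indicator \eqn{X} and a binary prognostic covariate \eqn{Z} with margins
#' \eqn{P(X=1)=p_X}, \eqn{P(Z=1)=p_Z} and odds ratio
#' \deqn{\phi = \frac{P(Z=1|X=1)/P(Z=0|X=1)}{P(Z=1|X=0)/P(Z=0|X=0)}.}
#' This is the classical Plackett construction: the cell \eqn{p_{11} =
#' P(X=1,Z=1)} solves a quadratic and the admissible root is the one inside
#' the Frechet bounds \eqn{[\max(0, p_X+p_Z-1), \min(p_X, p_Z)]}.
#'
#' @param pX probability of treatment, in (0,1).
#' @param pZ probability of the covariate, in (0,1).
#' @param phi odds ratio, > 0; `phi = 1` gives independence.
#'
#' @return An object of class `binary_joint` with fields `pX`, `pZ`, `phi`
#'   and cell probabilities `p11`, `p10`, `p01`, `p00` (`pab = P(X=a,Z=b)`).
#' @examples
#' j <- solve_binary_joint(0.5, 0.25, 4)
#' j$p11 / (j$p11 + j$p10)   # P(Z=1|X=1)
#' @export
solve_binary_joint <- function(pX, pZ, phi) {
  stopifnot(is.numeric(pX), is.numeric(pZ), is.numeric(phi),
            length(pX) == 1L, length(pZ) == 1L, length(phi) == 1L)
  if (!(pX > 0 && pX < 1)) stop("pX must lie strictly in (0, 1)")
  if (!(pZ > 0 && pZ < 1)) stop("pZ must lie strictly in (0, 1)")
  if (!(phi > 0)) stop("phi must be positive")

  lo <- max(0, pX + pZ - 1)
  hi <- min(pX, pZ)
  if (phi == 1) {
    p11 <- pX * pZ
  } else {
    ## (1-phi) p11^2 + [(1 - pX - pZ) + phi (pX + pZ)] p11 - phi pX pZ = 0
    a <- 1 - phi
    b <- (1 - pX - pZ) + phi * (pX + pZ)
    cc <- -phi * pX * pZ
    disc <- b^2 - 4 * a * cc
    if (disc < 0) stop("no admissible cell probabilities")
    roots <- c((-b + sqrt(disc)) / (2 * a), (-b - sqrt(disc)) / (2 * a))
    ok <- roots >= lo - 1e-12 & roots <= hi + 1e-12
    if (!any(ok)) stop("no admissible cell probabilities")
    p11 <- min(max(roots[ok][1L], lo), hi)
  }
  out <- list(pX = pX, pZ = pZ, phi = phi,
              p11 = p11, p10 = pX - p11, p01 = pZ - p11,
              p00 = 1 - pX - pZ + p11)
  class(out) <- "binary_joint"
  out
}

#' @exportS3Method base::print
print.binary_joint <- function(x, ...) {
  cat("Binary (X, Z) joint law: P(X=1) =", x$pX, ", P(Z=1) =", x$pZ,
      ", odds ratio =", x$phi, "\n")
  m <- matrix(c(x$p00, x$p01, x$p10, x$p11), 2, 2, byrow = TRUE,
              dimnames = list(c("X=0", "X=1"), c("Z=0", "Z=1")))
  print(m, ...)
  invisible(x)
}

#' Normal prognostic covariate, conditionally on treatment
#'
#' Describes `Z | X = x ~ N(theta0 + theta1 * x, sigma^2)`. `theta1 = 0`
#' encodes independence of X and Z, the randomized-trial case.
#'
#' @param theta0 mean intercept.
#' @param theta1 mean shift per unit of treatment.
#' @param sigma standard deviation, > 0.
#' @return An object of class `normal_confounder`.
#' @export
normal_confounder <- function(theta0 = 0, theta1 = 0, sigma = 1) {
  stopifnot(length(theta0) == 1L, length(theta1) == 1L, length(sigma) == 1L)
  if (!(sigma > 0)) stop("sigma must be positive")
  structure(list(theta0 = theta0, theta1 = theta1, sigma = sigma),
            class = "normal_confounder")
}

#' Censoring scheme: administrative end-of-study plus exponential dropout
#'
#' Follow-up ends at `C = min(R, A)` where `A` is the administrative
#' censoring time and `R` is an exponential early-dropout time with rate
#' `r` chosen so that `P(R < A) = dropoutProb`, i.e.
#' `r = -log(1 - dropoutProb) / A`. The censoring survivor function is
#' `G(t) = P(C >= t) = exp(-r t)` for `0 <= t <= A` and 0 beyond `A`.
#'
#' @param A administrative censoring time, > 0.
#' @param dropoutProb probability of dropout before `A`, in `[0, 1)`.
#' @return An object of class `censoring_scheme` with derived rate `r`.
#' @examples
#' cs <- censoring_scheme(A = 1, dropoutProb = 0.2)
#' cs$r                       # -log(0.8)
#' censoring_survivor(cs, 0.5)
#' @export
censoring_scheme <- function(A, dropoutProb = 0) {
  stopifnot(length(A) == 1L, length(dropoutProb) == 1L)
  if (!(A > 0)) stop("A must be positive")
  if (dropoutProb < 0 || dropoutProb >= 1)
    stop("dropoutProb must lie in [0, 1)")
  r <- if (dropoutProb == 0) 0 else -log(1 - dropoutProb) / A
  structure(list(A = A, dropoutProb = dropoutProb, r = r),
            class = "censoring_scheme")
}

#' Censoring survivor function G(t)
#'
#' @param scheme a [censoring_scheme()].
#' @param t vector of non-negative times.
#' @return `P(C >= t)`, vectorized over `t`.
#' @export
censoring_survivor <- function(scheme, t) {
  stopifnot(inherits(scheme, "censoring_scheme"))
  if (any(t < 0)) stop("t must be non-negative")
  ifelse(t > scheme$A, 0, exp(-scheme$r * t))
}

#' Draw effective censoring times C = min(R, A)
#'
#' @param scheme a [censoring_scheme()].
#' @param n number of subjects.
#' @param seed optional integer seed for reproducibility.
#' @return numeric vector of `n` censoring times in `(0, A]`.
#' @export
sample_censoring <- function(scheme, n, seed = NULL) {
  stopifnot(inherits(scheme, "censoring_scheme"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (scheme$r == 0) rep(scheme$A, n) else pmin(stats::rexp(n, scheme$r), scheme$A)
}

#' Draw (treatment, covariate) pairs
#'
#' Treatment is Bernoulli(`pX`); the covariate is drawn from its conditional
#' law given treatment. With a [solve_binary_joint()] law, `Z | X = x` is
#' Bernoulli with the conditional cell probability; with a
#' [normal_confounder()], `Z | X = x` is normal.
#'
#' @param joint a `binary_joint` object, or a `normal_confounder` (in which
#'   case `pX` must be supplied).
#' @param n number of subjects.
#' @param seed optional integer seed.
#' @param pX treatment probability; only used with a `normal_confounder`.
#' @return data.frame with columns `x` and `z`.
#' @export
sample_covariates <- function(joint, n, seed = NULL, pX = 0.5) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (inherits(joint, "binary_joint")) {
    x <- stats::rbinom(n, 1L, joint$pX)
    pz1 <- joint$p11 / joint$pX        # P(Z=1 | X=1)
    pz0 <- joint$p01 / (1 - joint$pX)  # P(Z=1 | X=0)
    z <- stats::rbinom(n, 1L, ifelse(x == 1L, pz1, pz0))
  } else if (inherits(joint, "normal_confounder")) {
    x <- stats::rbinom(n, 1L, pX)
    z <- stats::rnorm(n, joint$theta0 + joint$theta1 * x, joint$sigma)
  } else stop("joint must be a binary_joint or normal_confounder")
  data.frame(x = x, z = z)
}

## One master seed -> deterministic sub-stream seeds, so covariates,
## censoring and events (or replicates) can be regenerated independently.
spawn_seeds <- function(master, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(master %% 2147483647L))
  sample.int(2147483646L, n)
}
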