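#' Baseline time-to-event family for an AFT submodel
#'
#' The gap-time submodels are accelerated failure time (AFT) models
#' \eqn{\log T = \eta + \epsilon}, where the law of the residual
#' \eqn{\epsilon} determines the baseline hazard.  Supported families and
#' their residual laws (with `shape` the residual scale \eqn{\sigma} of
#' log-time):
#'
#' * `lognormal`: \eqn{\epsilon \sim N(0, \sigma^2)};
#' * `loglogistic`: \eqn{\epsilon \sim} Logistic(0, \eqn{\sigma});
#' * `weibull`: \eqn{\epsilon = \sigma \xi} with \eqn{\xi} standard
#'   minimum extreme value, i.e. \eqn{\exp(\epsilon)} is Weibull with
#'   shape \eqn{1/\sigma} and unit scale;
#' * `exponential`: the Weibull family with \eqn{\sigma} fixed at 1
#'   (no free shape parameter).
#'
#' @param family One of `"exponential"`, `"weibull"`, `"lognormal"`,
#'   `"loglogistic"`.
#' @param shape Positive residual scale \eqn{\sigma}; ignored (fixed at 1)
#'   for the exponential family.
#' @return An object of class `baseline_family`: a list with elements
#'   `family` and `shape`.
#' @examples
#' baseline_family("lognormal", shape = 1.2)
#' baseline_family("exponential")
#' @export
baseline_family <- function(family = c("exponential", "weibull",
                                       "lognormal", "loglogistic"),
                            shape = 1) {
  family <- match.arg(family)
  if (family == "exponential") {
    shape <- 1
  } else {
    if (!is.numeric(shape) || length(shape) != 1L || !is.finite(shape) ||
        shape <= 0) {
      stop("'shape' must be a single positive number for the ",
           family, " family", call. = FALSE)
    }
  }
  structure(list(family = family, shape = as.numeric(shape)),
            class = "baseline_family")
}

#' @export
print.baseline_family <- function(x, ...) {
  if (x$family == "exponential") {
    cat("AFT baseline family: exponential (shape fixed at 1)\n")
  } else {
    cat(sprintf("AFT baseline family: %s (shape = %.4g)\n",
                x$family, x$shape))
  }
  invisible(x)
}

as_baseline_family <- function(x) {
  if (inherits(x, "baseline_family")) return(x)
  if (is.character(x) && length(x) == 1L) return(baseline_family(x))
  stop("cannot interpret 'family'; supply a baseline_family object ",
       "or a family name", call. = FALSE)
}

#' Linear predictor of a submodel
#'
#' Computes \eqn{\eta = x^T\beta + z}, the episode-level linear predictor of
#' any of the submodels, where `z` is the value of the subject's random
#' effect for that submodel.
#'
#' @param x Numeric covariate vector (including the leading intercept 1).
#' @param beta Numeric coefficient vector of the same length.
#' @param z Scalar random-effect value (0 for submodels without one).
#' @param submodel Label used in error messages ("rate", "duration", ...).
#' @return The scalar linear predictor.
#' @export
linear_predictor <- function(x, beta, z = 0, submodel = "submodel") {
  if (length(x) != length(beta)) {
    stop(sprintf(
      "%s: covariate vector has length %d but coefficient vector has length %d",
      submodel, length(x), length(beta)), call. = FALSE)
  }
  sum(as.numeric(x) * as.numeric(beta)) + z
}

## standardized log-time residual u = (log t - eta) / sigma
aft_resid <- function(t, eta, sigma) (log(t) - eta) / sigma

#' AFT log density, log survival and hazard
#'
#' Density, survival and hazard of a gap time `t` under the AFT law
#' \eqn{\log T = \eta + \epsilon} with the residual family of `family`.
#' All three are vectorized over `t` and `eta`.
#'
#' @param t Gap time (days); strictly positive for the density and hazard,
#'   non-negative for the survival function.
#' @param eta Linear predictor (finite).
#' @param family A [baseline_family()] object (or family name, shape 1).
#' @return `aft_log_density` returns \eqn{\log f(t)}; `aft_log_survival`
#'   returns \eqn{\log S(t)} (0 at `t = 0`); `aft_hazard` returns the hazard
#'   \eqn{f(t)/S(t)}.
#' @examples
#' fam <- baseline_family("lognormal", shape = 1)
#' aft_log_density(exp(0.5), eta = 0.5, family = fam) # mode of log-time
#' aft_hazard(3, eta = 0, family = baseline_family("exponential"))
#' @export
aft_log_density <- function(t, eta, family) {
  family <- as_baseline_family(family)
  check_time_eta(t, eta, positive = TRUE)
  s <- family$shape
  u <- aft_resid(t, eta, s)
  switch(family$family,
    lognormal   = stats::dnorm(u, log = TRUE) - log(s * t),
    loglogistic = stats::dlogis(u, log = TRUE) - log(s * t),
    weibull     = ,
    exponential = u - exp(u) - log(s * t)
  )
}

#' @rdname aft_log_density
#' @export
aft_log_survival <- function(t, eta, family) {
  family <- as_baseline_family(family)
  check_time_eta(t, eta, positive = FALSE)
  s <- family$shape
  out <- numeric(length(t + eta))
  tt <- rep_len(t, length(out))
  ee <- rep_len(eta, length(out))
  pos <- tt > 0
  if (any(pos)) {
    u <- aft_resid(tt[pos], ee[pos], s)
    out[pos] <- switch(family$family,
      lognormal   = stats::pnorm(u, lower.tail = FALSE, log.p = TRUE),
      loglogistic = stats::plogis(u, lower.tail = FALSE, log.p = TRUE),
      weibull     = ,
      exponential = -exp(u)
    )
  }
  out
}

#' @rdname aft_log_density
#' @export
aft_hazard <- function(t, eta, family) {
  exp(aft_log_density(t, eta, family) - aft_log_survival(t, eta, family))
}

check_time_eta <- function(t, eta, positive) {
  if (!all(is.finite(eta))) {
    stop("non-finite linear predictor 'eta'", call. = FALSE)
  }
  if (positive) {
    if (any(!is.finite(t) | t <= 0)) {
      stop("gap times must be strictly positive and finite", call. = FALSE)
    }
  } else {
    if (any(!is.finite(t) | t < 0)) {
      stop("gap times must be non-negative and finite", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Conditional severity probability
#'
#' Probability that an exacerbation is severe given covariates and the
#' subject's severity random effect: a logistic regression on the linear
#' predictor \eqn{x^T\beta_S + z_S}.
#'
#' @param x Covariate vector (including intercept).
#' @param beta_S Severity coefficient vector.
#' @param z_S Severity random-effect value.
#' @return Probability in (0, 1).
#' @export
severity_prob <- function(x, beta_S, z_S = 0) {
  stats::plogis(linear_predictor(x, beta_S, z_S, submodel = "severity"))
}

#' Non-susceptibility (zero-inflation) probability
#'
#' Probability that a subject belongs to the latent non-susceptible class
#' (never experiences an event), modelled by logistic regression on the
#' baseline covariates only; this mixture component carries no random
#' effect.
#'
#' @param x0 Baseline covariate vector (including intercept).
#' @param beta_ZI Zero-inflation coefficient vector.
#' @return Probability in (0, 1).
#' @export
nonsusceptible_prob <- function(x0, beta_ZI) {
  stats::plogis(linear_predictor(x0, beta_ZI, 0, submodel = "zero-inflation"))
}

## --- unconstrained parametrization of the random-effects covariance -----
##
## Sigma_Z = D R D with D = diag(exp(re_log_sd)) and R a correlation matrix
## parameterized through its Cholesky factor by tanh-scaled canonical
## partial correlations (row-wise), a smooth bijection between R^{d(d-1)/2}
## and the set of full-rank correlation matrices.

corr_chol_from_unconstrained <- function(gamma, d) {
  stopifnot(length(gamma) == d * (d - 1L) / 2L)
  L <- diag(d)
  k <- 0L
  for (i in seq_len(d)[-1L]) {
    rem <- 1
    for (j in seq_len(i - 1L)) {
      k <- k + 1L
      L[i, j] <- tanh(gamma[k]) * sqrt(rem)
      rem <- max(rem - L[i, j]^2, 0) # guard fp underflow at |corr| -> 1
    }
    L[i, i] <- sqrt(rem)
  }
  L
}

unconstrained_from_corr_chol <- function(L) {
  d <- nrow(L)
  gamma <- numeric(d * (d - 1L) / 2L)
  k <- 0L
  for (i in seq_len(d)[-1L]) {
    rem <- 1
    for (j in seq_len(i - 1L)) {
      k <- k + 1L
      gamma[k] <- atanh(L[i, j] / sqrt(rem))
      rem <- rem - L[i, j]^2
    }
  }
  gamma
}

#' Random-effects covariance from its unconstrained parametrization
#'
#' The trivariate random effect \eqn{Z = (Z_B, Z_W, Z_S)} is mean-zero
#' multivariate normal with covariance \eqn{\Sigma_Z} governed by 3 standard
#' deviations and 3 correlations.  Internally \eqn{\Sigma_Z} is parameterized
#' by the log standard deviations and by 3 unconstrained reals that map to
#' the Cholesky factor of the correlation matrix (tanh-transformed canonical
#' partial correlations), so every real input yields a symmetric
#' positive-definite matrix.
#'
#' @param re_log_sd Numeric vector of log standard deviations (length 3 for
#'   the full model).
#' @param re_corr_chol Numeric vector of `d(d-1)/2` unconstrained correlation
#'   parameters.
#' @return A list with `sigma` (the covariance matrix), `sd` (standard
#'   deviations), `corr` (the correlation matrix) and `corr_chol` (its lower
#'   Cholesky factor).
#' @seealso [re_covariance_to_unconstrained()] for the inverse transform.
#' @examples
#' build_re_covariance(c(0, 0, 0), c(0, 0, 0))$sigma # identity
#' @export
build_re_covariance <- function(re_log_sd, re_corr_chol) {
  d <- length(re_log_sd)
  L <- corr_chol_from_unconstrained(re_corr_chol, d)
  R <- L %*% t(L)
  R <- (R + t(R)) / 2
  diag(R) <- 1
  sd <- exp(re_log_sd)
  sigma <- R * tcrossprod(sd)
  nm <- c("B", "W", "S")[seq_len(d)]
  dimnames(sigma) <- dimnames(R) <- list(nm, nm)
  list(sigma = sigma, sd = stats::setNames(sd, nm), corr = R, corr_chol = L)
}

#' Unconstrained parametrization of a random-effects covariance
#'
#' Inverse of [build_re_covariance()]: maps a symmetric positive-definite
#' covariance matrix to `(re_log_sd, re_corr_chol)`.
#'
#' @param sigma Symmetric positive-definite covariance matrix.
#' @return A list with `re_log_sd` and `re_corr_chol`.
#' @export
re_covariance_to_unconstrained <- function(sigma) {
  sigma <- as.matrix(sigma)
  if (!isTRUE(all.equal(sigma, t(sigma), tolerance = 1e-8))) {
    stop("'sigma' must be symmetric", call. = FALSE)
  }
  sd <- sqrt(diag(sigma))
  if (any(sd <= 0)) stop("'sigma' must have positive diagonal", call. = FALSE)
  R <- sigma / tcrossprod(sd)
  diag(R) <- 1
  L <- t(chol(R))
  list(re_log_sd = log(sd), re_corr_chol = unconstrained_from_corr_chol(L))
}
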