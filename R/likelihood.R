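## Likelihood of the joint rate-duration-severity model.
##
## Two engines compute the marginal (random effects integrated out) log
## likelihood: a plain-R reference implementation, used by default for
## single subjects and in cross-checks, and a compiled implementation used
## by the fitter (`engine = "cpp"`).  Both share the same adaptive
## Gauss-Hermite construction.

family_code <- function(family) {
  switch(family$family,
         exponential = 0L, weibull = 0L, lognormal = 1L, loglogistic = 2L)
}

gh_rule <- function(n) {
  if (n == 1L) return(list(x = 0, w = sqrt(pi)))
  r <- pracma::gaussHermite(n)
  list(x = r$x, w = r$w)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Reconstruct a config from a parameter object (covariate lists from the
## coefficient names, submodel inclusion from which betas are present).
config_from_params <- function(params,
                               quad_points = 5L,
                               quad_mode = "adaptive",
                               derive_episode_covariates = FALSE) {
  covs <- function(beta) if (is.null(beta)) character() else names(beta)[-1L]
  rds_config(
    covariates_B = covs(params$beta_B),
    covariates_W = covs(params$beta_W),
    covariates_S = covs(params$beta_S),
    covariates_ZI = covs(params$beta_ZI),
    family_B = params$family_B$family,
    family_W = if (!is.null(params$family_W)) params$family_W$family
               else params$family_B$family,
    include_duration = !is.null(params$beta_W),
    include_severity = !is.null(params$beta_S),
    include_zi = !is.null(params$beta_ZI),
    random_effects = params$re,
    derive_episode_covariates = derive_episode_covariates,
    quad_points = quad_points,
    quad_mode = quad_mode
  )
}

as_re_vector <- function(z) {
  if (is.list(z)) z <- unlist(z)
  if (is.null(names(z))) {
    if (length(z) == 3L) names(z) <- c("B", "W", "S")
    else stop("unnamed random-effect value must have length 3", call. = FALSE)
  }
  out <- c(B = 0, W = 0, S = 0)
  out[names(z)] <- z
  out
}

#' Conditional log-likelihood of one subject
#'
#' Log-likelihood of a subject's history given a fixed value of the random
#' effects: the sum over episodes of the between-gap log density, the
#' within-gap log density (or log survival if the within-gap is censored)
#' and the Bernoulli severity term, plus the log survival of the final
#' censored between-gap.
#'
#' @param subject A [subject_history()] object.
#' @param params An [rds_params()] object.
#' @param z Random-effect value: named vector with any of `B`, `W`, `S`
#'   (missing components are 0), or an unnamed length-3 vector `(B, W, S)`.
#' @param config Optional [rds_config()]; reconstructed from `params` if
#'   missing.
#' @return Scalar log-likelihood.
#' @export
conditional_loglik <- function(subject, params, z = c(B = 0, W = 0, S = 0),
                               config = config_from_params(params)) {
  unname(drop(conditional_loglik_multi(
    subject, params,
    matrix(as_re_vector(z), nrow = 1L,
           dimnames = list(NULL, c("B", "W", "S"))),
    config)))
}

## Vectorized conditional log-likelihood over a K x 3 matrix of z values
## (columns B, W, S); returns a length-K vector.  Plain-R path used by the
## R engine, the Monte-Carlo cross-checks and empirical-Bayes prediction.
conditional_loglik_multi <- function(subject, params, Z, config) {
  validate_subject_history(subject)
  des <- build_design(subject, config)
  m <- n_episodes(subject)
  Z <- as.matrix(Z)
  if (is.null(colnames(Z))) colnames(Z) <- c("B", "W", "S")[seq_len(ncol(Z))]
  zB <- if ("B" %in% colnames(Z)) Z[, "B"] else rep(0, nrow(Z))
  zW <- if ("W" %in% colnames(Z)) Z[, "W"] else rep(0, nrow(Z))
  zS <- if ("S" %in% colnames(Z)) Z[, "S"] else rep(0, nrow(Z))
  K <- nrow(Z)
  ll <- numeric(K)

  eta_B0 <- drop(des$X_B %*% params$beta_B)
  famB <- params$family_B
  if (m > 0L) {
    ep <- subject$episodes
    ## residual matrices: rows = episodes, cols = nodes
    rB <- outer(log(ep$between_gap) - eta_B0[seq_len(m)], zB, "-") / famB$shape
    ll <- ll + colSums(aft_logdens_u(rB, famB)) -
      K_const(m, sum(log(famB$shape * ep$between_gap)))
    if (!is.null(params$beta_W)) {
      famW <- params$family_W
      eta_W0 <- drop(des$X_W %*% params$beta_W)
      rW <- outer(log(ep$duration) - eta_W0, zW, "-") / famW$shape
      dens <- aft_logdens_u(rW, famW) - log(famW$shape * ep$duration)
      surv <- aft_logsurv_u(rW, famW)
      cens <- ep$within_censored == 1
      mixed <- dens
      if (any(cens)) mixed[cens, ] <- surv[cens, , drop = FALSE]
      ll <- ll + colSums(mixed)
    }
    if (!is.null(params$beta_S)) {
      lp0 <- drop(des$X_S %*% params$beta_S)
      lp <- outer(lp0, zS, "+")
      s <- ep$severity
      ll <- ll + colSums(s * stats::plogis(lp, log.p = TRUE) +
                         (1 - s) * stats::plogis(-lp, log.p = TRUE))
    }
  }
  if (subject$final_gap_censored == 1L && subject$final_gap > 0) {
    rC <- (log(subject$final_gap) - eta_B0[m + 1L] - zB) / famB$shape
    ll <- ll + aft_logsurv_u(matrix(rC, nrow = 1L), famB)[1L, ]
  }
  ll
}

K_const <- function(m, v) if (m > 0L) v else 0

## log density / log survival of the standardized residual u (matrix ok),
## excluding the 1/(sigma t) Jacobian (added by the caller where needed)
aft_logdens_u <- function(u, family) {
  switch(family$family,
         lognormal = stats::dnorm(u, log = TRUE),
         loglogistic = stats::dlogis(u, log = TRUE),
         u - exp(u))
}

aft_logsurv_u <- function(u, family) {
  switch(family$family,
         lognormal = stats::pnorm(u, lower.tail = FALSE, log.p = TRUE),
         loglogistic = stats::plogis(u, lower.tail = FALSE, log.p = TRUE),
         -exp(u))
}

## ---- quadrature ----------------------------------------------------------

#' Gauss--Hermite quadrature rule for the random-effect integral
#'
#' Builds the tensor Gauss--Hermite rule used to integrate the conditional
#' likelihood over the multivariate normal random effects.  Without a
#' subject the object only carries the 1-D nodes/weights and the mode; with
#' `subject` and `params` the realized multivariate rule is returned:
#' nodes `z_k` and log-coefficients `logc_k` such that
#' \deqn{E_Z[e^{g(Z)}] \approx \sum_k \exp(logc_k + g(z_k) + \log\phi_\Sigma(z_k)).}
#' In `adaptive` mode the grid is recentred at the subject's posterior mode
#' of the random effects and rescaled by the inverse square root of the
#' negative log-posterior Hessian there; if that Hessian is not positive
#' definite the rule falls back to the fixed (prior-based) grid with a
#' warning.  Subjects without episodes involve only the rate random effect,
#' so their rule is one-dimensional.
#'
#' @param points_per_dim Number of Gauss--Hermite points per dimension.
#' @param mode `"adaptive"` or `"fixed"`.
#' @param subject,params Optional; when both are given the realized rule for
#'   that subject is computed.
#' @param config Optional [rds_config()].
#' @return An object of class `quadrature_rule`.
#' @export
make_quadrature <- function(points_per_dim = 5L,
                            mode = c("adaptive", "fixed"),
                            subject = NULL, params = NULL, config = NULL) {
  mode <- match.arg(mode)
  if (points_per_dim < 1L) stop("'points_per_dim' must be >= 1", call. = FALSE)
  gh <- gh_rule(points_per_dim)
  rule <- structure(list(points_per_dim = as.integer(points_per_dim),
                         mode = mode, x = gh$x, w = gh$w),
                    class = "quadrature_rule")
  if (!is.null(subject) && !is.null(params)) {
    if (is.null(config)) config <- config_from_params(params)
    rule <- c(unclass(rule),
              realize_quadrature(rule, subject, params, config))
    class(rule) <- "quadrature_rule"
  }
  rule
}

#' @export
print.quadrature_rule <- function(x, ...) {
  cat(sprintf("Gauss-Hermite rule: %d point(s)/dimension, %s mode%s\n",
              x$points_per_dim, x$mode,
              if (!is.null(x$nodes)) sprintf(" (realized, %d node(s) in %d dim)",
                                             nrow(x$nodes), ncol(x$nodes))
              else ""))
  invisible(x)
}

## posterior mode of the active random effects (R engine); returns the mode
## and the negative Hessian of the log posterior there
posterior_mode_r <- function(subject, params, config, active) {
  d <- length(active)
  cov <- build_re_covariance(params$re_log_sd, params$re_corr_chol)
  sig <- cov$sigma[active, active, drop = FALSE]
  siginv <- solve(sig)
  g <- function(za) {
    Z <- matrix(0, 1L, 3L, dimnames = list(NULL, c("B", "W", "S")))
    Z[, active] <- za
    conditional_loglik_multi(subject, params, Z, config) -
      0.5 * drop(za %*% siginv %*% za)
  }
  opt <- stats::optim(rep(0, d), function(za) -g(za), method = "BFGS",
                      control = list(reltol = 1e-12, maxit = 200))
  H <- -pracma::hessian(g, opt$par)
  list(mode = opt$par, negH = H, converged = opt$convergence == 0)
}

## realized multivariate rule for one subject (R engine)
realize_quadrature <- function(rule, subject, params, config) {
  m <- n_episodes(subject)
  active <- params$re
  if (m == 0L) active <- intersect(active, "B")
  d <- length(active)
  if (d == 0L) {
    return(list(nodes = matrix(numeric(0), 0L, 0L), logc = numeric(0),
                active = character(0)))
  }
  cov <- build_re_covariance(params$re_log_sd, params$re_corr_chol)
  sig <- cov$sigma[active, active, drop = FALSE]
  center <- rep(0, d)
  A <- t(chol(sig)) # fixed rule: covariance factor of the prior
  if (rule$mode == "adaptive") {
    pm <- posterior_mode_r(subject, params, config, active)
    ok <- all(is.finite(pm$negH))
    if (ok) {
      ch <- tryCatch(chol(pm$negH), error = function(e) NULL)
      ok <- !is.null(ch)
    }
    if (ok) {
      center <- pm$mode
      A <- backsolve(ch, diag(d)) # A A^T = (negH)^{-1}
    } else {
      warning("posterior-mode Hessian not positive definite for subject ",
              subject$subject_id, "; falling back to the fixed rule",
              call. = FALSE)
    }
  }
  grid <- as.matrix(expand.grid(rep(list(seq_len(rule$points_per_dim)), d)))
  X <- matrix(rule$x[grid], ncol = d)
  logw <- matrix(log(rule$w)[grid], ncol = d)
  nodes <- sweep(X %*% t(sqrt(2) * A), 2L, center, "+")
  colnames(nodes) <- active
  logdetA <- sum(log(abs(diag(as.matrix(A)))))
  logc <- d / 2 * log(2) + logdetA + rowSums(logw) + rowSums(X^2)
  list(nodes = nodes, logc = logc, active = active,
       siginv = solve(sig), logdetsig = determinant(sig)$modulus[1L])
}

## ---- marginal likelihood -------------------------------------------------

#' Marginal log-likelihood of one subject
#'
#' Integrates the conditional likelihood over the multivariate normal random
#' effects by (adaptive) Gauss--Hermite quadrature, and applies the
#' zero-inflation mixture outside the integral: for subjects without
#' episodes the likelihood is \eqn{\pi_i + (1-\pi_i) E_Z[e^{\ell_i(Z)}]},
#' for subjects with episodes \eqn{(1-\pi_i) E_Z[e^{\ell_i(Z)}]} (without
#' the zero-inflation component, just the expectation).  For subjects
#' without episodes the integrand involves only the rate random effect, so
#' the integral collapses to one dimension.
#'
#' @inheritParams conditional_loglik
#' @param quad A [make_quadrature()] rule (unrealized is fine) or `NULL`
#'   (then `config`'s quadrature settings are used).
#' @return Scalar log-likelihood.
#' @export
marginal_subject_loglik <- function(subject, params, quad = NULL,
                                    config = config_from_params(params)) {
  if (is.null(quad)) {
    quad <- make_quadrature(config$quad_points, config$quad_mode)
  }
  rule <- make_quadrature(quad$points_per_dim, quad$mode,
                          subject = subject, params = params, config = config)
  m <- n_episodes(subject)
  if (length(rule$active) == 0L) {
    logE <- conditional_loglik(subject, params, config = config)
  } else {
    Z <- matrix(0, nrow(rule$nodes), 3L,
                dimnames = list(NULL, c("B", "W", "S")))
    Z[, rule$active] <- rule$nodes
    cll <- conditional_loglik_multi(subject, params, Z, config)
    q <- rowSums((rule$nodes %*% rule$siginv) * rule$nodes)
    logphi <- -ncol(rule$nodes) / 2 * log(2 * pi) - 0.5 * rule$logdetsig -
      0.5 * q
    logE <- logsumexp(rule$logc + cll + logphi)
  }
  ll <- apply_zi(subject, params, config, m, logE)
  if (!is.finite(ll)) {
    stop("marginal likelihood is non-finite for subject ",
         subject$subject_id, call. = FALSE)
  }
  ll
}

apply_zi <- function(subject, params, config, m, logE) {
  if (!config$include_zi || is.null(params$beta_ZI)) return(logE)
  des <- build_design(subject, config)
  lp <- linear_predictor(des$x_zi, params$beta_ZI, 0, "zero-inflation")
  log_pi <- stats::plogis(lp, log.p = TRUE)
  log_1mpi <- stats::plogis(-lp, log.p = TRUE)
  if (m == 0L) logsumexp(c(log_pi, log_1mpi + logE)) else log_1mpi + logE
}

#' Total marginal log-likelihood of a dataset
#'
#' Subjects are independent, so the dataset log-likelihood is the sum of the
#' per-subject marginal log-likelihoods.
#'
#' @param dataset An [rds_data()] list of subjects.
#' @param params An [rds_params()] object.
#' @param config Optional [rds_config()].
#' @param quad Optional [make_quadrature()] rule overriding the config's
#'   quadrature settings.
#' @param engine `"cpp"` (compiled, default) or `"R"` (reference
#'   implementation); both compute the same quantity.
#' @return Scalar log-likelihood.
#' @export
total_loglik <- function(dataset, params, config = config_from_params(params),
                         quad = NULL, engine = c("cpp", "R")) {
  engine <- match.arg(engine)
  if (!length(dataset)) stop("empty dataset", call. = FALSE)
  if (!is.null(quad)) {
    config$quad_points <- quad$points_per_dim
    config$quad_mode <- quad$mode
  }
  if (engine == "R") {
    q0 <- make_quadrature(config$quad_points, config$quad_mode)
    return(sum(vapply(dataset, marginal_subject_loglik, 0,
                      params = params, quad = q0, config = config)))
  }
  prep <- prepare_loglik_data(dataset, config)
  loglik_cpp(prep, params, config)$total
}

## ---- compiled engine plumbing -------------------------------------------

## Flatten a dataset once; re-used across likelihood evaluations.
prepare_loglik_data <- function(dataset, config) {
  des <- lapply(dataset, build_design, config = config)
  m <- vapply(dataset, n_episodes, 0L)
  ep <- function(f) unlist(lapply(dataset, f), use.names = FALSE)
  list(
    n = length(dataset),
    m = m,
    logB = log(as.numeric(ep(function(s) s$episodes$between_gap))),
    logW = log(as.numeric(ep(function(s) s$episodes$duration))),
    S = as.integer(ep(function(s) s$episodes$severity)),
    WC = as.integer(ep(function(s) s$episodes$within_censored)),
    logfgap = log(vapply(dataset, function(s) s$final_gap, 0)),
    fgap_cens = vapply(dataset, function(s) s$final_gap_censored, 0L),
    XB = do.call(rbind, lapply(des, `[[`, "X_B")),
    XW = if (config$include_duration) do.call(rbind, lapply(des, `[[`, "X_W")),
    XS = if (config$include_severity) do.call(rbind, lapply(des, `[[`, "X_S")),
    XZI = if (config$include_zi) do.call(rbind, lapply(des, `[[`, "x_zi")))
}

## Evaluate the compiled marginal log-likelihood; `mode_start` optionally
## recycles posterior modes from a previous nearby evaluation.
loglik_cpp <- function(prep, params, config, mode_start = NULL,
                       want_modes = FALSE) {
  dat <- list(
    n = prep$n, m = prep$m, logB = prep$logB, logW = prep$logW,
    S = prep$S, WC = prep$WC,
    logfgap = prep$logfgap, fgap_cens = prep$fgap_cens,
    etaB0 = drop(prep$XB %*% params$beta_B),
    etaW0 = if (!is.null(params$beta_W) && !is.null(prep$XW))
      drop(prep$XW %*% params$beta_W) else numeric(0),
    lpS0 = if (!is.null(params$beta_S) && !is.null(prep$XS))
      drop(prep$XS %*% params$beta_S) else numeric(0),
    log_pi = numeric(prep$n), log_1mpi = numeric(prep$n),
    has_zi = config$include_zi && !is.null(params$beta_ZI))
  if (dat$has_zi) {
    lp <- drop(prep$XZI %*% params$beta_ZI)
    dat$log_pi <- stats::plogis(lp, log.p = TRUE)
    dat$log_1mpi <- stats::plogis(-lp, log.p = TRUE)
  }
  active <- params$re
  d <- length(active)
  par <- list(
    sigB = params$family_B$shape, famB = family_code(params$family_B),
    hasW = !is.null(params$beta_W),
    sigW = if (!is.null(params$family_W)) params$family_W$shape else 1,
    famW = if (!is.null(params$family_W)) family_code(params$family_W) else 0L,
    hasS = !is.null(params$beta_S),
    d = d,
    reIdx = as.integer(match(c("B", "W", "S"), active, nomatch = 0L) - 1L))
  if (d > 0L) {
    cov <- build_re_covariance(params$re_log_sd, params$re_corr_chol)
    par$cholSig <- cov$corr_chol * cov$sd # row-scaled: chol of Sigma
    par$sdBmarg <- if ("B" %in% active) cov$sd[["B"]] else 0
  }
  gh <- gh_rule(config$quad_points)
  rds_marginal_loglik_cpp(dat, par, gh$x, gh$w,
                          config$quad_mode == "adaptive",
                          mode_start, want_modes)
}
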