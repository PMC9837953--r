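## Empirical-Bayes random-effect prediction and marginal predictions.

#' Empirical-Bayes random-effect estimate for one subject
#'
#' The posterior mode of the random effects given the subject's data at the
#' fitted parameters:
#' \deqn{\hat z = \arg\max_z \{\ell_i(z) + \log\phi_{\Sigma_Z}(z)\},}
#' found by Newton iteration from \eqn{z = 0} (the posterior is log-concave
#' for every supported family).  For subjects without episodes only the rate
#' component is identified, so only `z_B` is returned (the duration and
#' severity components are `NA`).
#'
#' @param subject A [subject_history()] object.
#' @param params An [rds_params()] object (typically the MLE).
#' @param config Optional [rds_config()].
#' @return Named numeric vector `c(B =, W =, S =)`; components without an
#'   active random effect (or unidentified for this subject) are `NA`.
#' @export
empirical_bayes <- function(subject, params,
                            config = config_from_params(params)) {
  active <- params$re
  out <- c(B = NA_real_, W = NA_real_, S = NA_real_)
  if (n_episodes(subject) == 0L) {
    active <- intersect(active, "B")
    if (!length(active)) return(out)
    out["B"] <- eb_zero_event(subject, params, config)
    return(out)
  }
  if (!length(active)) return(out)
  pm <- posterior_mode_r(subject, params, config, active)
  if (!pm$converged) {
    stop("empirical-Bayes mode search did not converge for subject ",
         subject$subject_id, call. = FALSE)
  }
  out[active] <- pm$mode
  out
}

## EB mode for a subject without episodes: the posterior of z_B given "no
## events over the follow-up" includes the zero-inflation mixture,
## p(z | M = 0) proportional to [pi + (1-pi) S(T | z)] phi(z); without the
## mixture term the mode would be biased upward for every zero-event subject
eb_zero_event <- function(subject, params, config) {
  cov <- build_re_covariance(params$re_log_sd, params$re_corr_chol)
  sd_B <- cov$sd[[match("B", params$re)]]
  lp <- -Inf
  if (config$include_zi && !is.null(params$beta_ZI)) {
    des <- build_design(subject, config)
    lp <- linear_predictor(des$x_zi, params$beta_ZI, 0, "zero-inflation")
  }
  log_pi <- stats::plogis(lp, log.p = TRUE)
  log_1mpi <- stats::plogis(-lp, log.p = TRUE)
  g <- function(z) {
    cond <- conditional_loglik(subject, params, c(B = z, W = 0, S = 0), config)
    lik <- if (is.finite(log_pi)) logsumexp(c(log_pi, log_1mpi + cond)) else cond
    lik + stats::dnorm(z, 0, sd_B, log = TRUE)
  }
  stats::optimize(function(z) -g(z), interval = c(-8, 8) * sd_B,
                  tol = 1e-9)$minimum
}

## all-subject EB modes: compiled mode search for subjects with episodes,
## the mixture-aware 1-D search for zero-event subjects
empirical_bayes_all <- function(dataset, params,
                                config = config_from_params(params)) {
  prep <- prepare_loglik_data(dataset, config)
  res <- loglik_cpp(prep, params, config, want_modes = TRUE)
  modes <- res$modes
  colnames(modes) <- c("B", "W", "S")
  if ("B" %in% params$re) {
    for (i in seq_along(dataset)) {
      if (n_episodes(dataset[[i]]) == 0L) {
        modes[i, "B"] <- eb_zero_event(dataset[[i]], params, config)
      }
    }
  }
  modes
}

## E[exp(epsilon)] for each residual family (closed forms)
mean_exp_resid <- function(family) {
  s <- family$shape
  switch(family$family,
         lognormal = exp(s^2 / 2),
         weibull = gamma(1 + s),
         exponential = 1,
         loglogistic = if (s < 1) pi * s / sin(pi * s) else Inf)
}

#' Marginal predicted mean gap time
#'
#' The mean gap time for a covariate row, marginalized over the residual and
#' (optionally) the random effect:
#' \deqn{E[T] = e^{x^T\beta}\, E[e^\epsilon]\, E[e^{Z}],}
#' using the closed forms \eqn{E[e^\epsilon] = e^{\sigma^2/2}} (log-normal),
#' \eqn{\Gamma(1+\sigma)} (Weibull), \eqn{\pi\sigma/\sin(\pi\sigma)} for
#' \eqn{\sigma < 1} (log-logistic, divergent otherwise), and
#' \eqn{E[e^Z] = e^{\sigma_z^2/2}}.  With `z` supplied the prediction is
#' conditional on that random-effect value instead of marginal.
#'
#' @param x_row Named covariate vector (without intercept) or a row of a
#'   covariate table.
#' @param params An [rds_params()] object.
#' @param which `"between"` or `"within"`.
#' @param z Optional random-effect value for an empirical-Bayes conditional
#'   mean; `NULL` (default) marginalizes over the random effect.
#' @return Mean gap time in days; `Inf` if the family moment diverges.
#' @export
marginal_mean_gap <- function(x_row, params, which = c("between", "within"),
                              z = NULL) {
  which <- match.arg(which)
  comp <- if (which == "between") "B" else "W"
  beta <- params[[paste0("beta_", comp)]]
  family <- params[[paste0("family_", comp)]]
  if (is.null(beta)) stop("submodel not present in 'params'", call. = FALSE)
  if (is.list(x_row)) x_row <- unlist(x_row)
  x <- c(1, as.numeric(x_row[names(beta)[-1L]]))
  eta <- linear_predictor(x, beta, 0, which)
  me <- mean_exp_resid(family)
  mz <- 1
  if (!is.null(z)) {
    mz <- exp(z)
  } else if (comp %in% params$re) {
    mz <- exp(exp(2 * params$re_log_sd[[match(comp, params$re)]]) / 2)
  }
  exp(eta) * me * mz
}

#' Marginal predicted severity probability
#'
#' \eqn{E[\mathrm{logit}^{-1}(x^T\beta_S + Z_S)]}, the probability that an
#' episode is severe for a covariate row, integrating the severity random
#' effect by Gauss--Hermite quadrature (or conditioning on a supplied `z`).
#'
#' @inheritParams marginal_mean_gap
#' @param gh_points Quadrature points for the 1-D integral.
#' @return Probability in (0, 1).
#' @export
marginal_severity_prob <- function(x_row, params, z = NULL, gh_points = 21L) {
  if (is.null(params$beta_S)) stop("no severity submodel", call. = FALSE)
  x <- c(1, as.numeric(x_row[names(params$beta_S)[-1L]]))
  lp <- linear_predictor(x, params$beta_S, 0, "severity")
  if (!is.null(z)) return(stats::plogis(lp + z))
  if (!"S" %in% params$re) return(stats::plogis(lp))
  sd_s <- exp(params$re_log_sd[[match("S", params$re)]])
  gh <- gh_rule(gh_points)
  sum(gh$w / sqrt(pi) * stats::plogis(lp + sqrt(2) * sd_s * gh$x))
}

#' Per-subject predictions
#'
#' Empirical-Bayes random effects and marginal predicted means for every
#' subject, using each subject's baseline covariate row.
#'
#' @param dataset An [rds_data()] object.
#' @param fit An [rds_fit()] object (or an [rds_params()] object).
#' @param config Optional [rds_config()].
#' @return A data frame with one row per subject: `subject_id`, `n_episodes`,
#'   the EB modes `z_B`, `z_W`, `z_S`, and the marginal predicted
#'   `mean_between` (days), `mean_within` (days) and `severity_prob`.
#' @export
predict_subjects <- function(dataset, fit, config = NULL) {
  params <- if (inherits(fit, "rds_fit")) fit$params_hat else fit
  if (is.null(config)) {
    config <- if (inherits(fit, "rds_fit")) fit$config
              else config_from_params(params)
  }
  modes <- empirical_bayes_all(dataset, params, config)
  rows <- lapply(seq_along(dataset), function(i) {
    s <- dataset[[i]]
    x <- unlist(covariate_table(s, config$derive_episode_covariates)[1L, ,
                                                                     drop = FALSE])
    data.frame(
      subject_id = as.character(s$subject_id),
      n_episodes = n_episodes(s),
      z_B = modes[i, "B"], z_W = modes[i, "W"], z_S = modes[i, "S"],
      mean_between = marginal_mean_gap(x, params, "between"),
      mean_within = if (!is.null(params$beta_W))
        marginal_mean_gap(x, params, "within") else NA_real_,
      severity_prob = if (!is.null(params$beta_S))
        marginal_severity_prob(x, params) else NA_real_
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## covariate rows realized in the dataset for a gap kind: between-gaps use
## all M+1 rate rows (episodes + censored final gap), within-gaps the M
## episode rows
realized_eta <- function(dataset, params, config, which) {
  comp <- if (which == "between") "B" else "W"
  beta <- params[[paste0("beta_", comp)]]
  etas <- lapply(dataset, function(s) {
    des <- build_design(s, config)
    m <- n_episodes(s)
    if (which == "between") {
      list(eta = drop(des$X_B %*% beta),
           lp_zi = if (config$include_zi && !is.null(params$beta_ZI))
             linear_predictor(des$x_zi, params$beta_ZI, 0, "zero-inflation")
           else -Inf)
    } else {
      if (m == 0L) return(NULL)
      list(eta = drop(des$X_W %*% beta), lp_zi = -Inf)
    }
  })
  etas <- etas[!vapply(etas, is.null, TRUE)]
  list(eta = unlist(lapply(etas, `[[`, "eta")),
       pi = unlist(lapply(etas, function(e) {
         rep(stats::plogis(e$lp_zi), length(e$eta))
       })))
}

#' Fitted marginal CDF curve
#'
#' The model-implied marginal cumulative distribution function of a gap
#' time, averaged over the covariate rows realized in the dataset: at each
#' grid point the conditional CDF is integrated over the random effect by
#' 1-D Gauss--Hermite quadrature and averaged across rows.  For the
#' between-gap curve the zero-inflation component is, by default,
#' conditioned away (the curve describes susceptible subjects); with
#' `conditional_on_susceptible = FALSE` each row is weighted by its
#' susceptibility probability \eqn{1-\pi_i}, so the curve plateaus below 1.
#'
#' @param dataset An [rds_data()] object.
#' @param params An [rds_params()] object (typically the MLE).
#' @param which `"between"` or `"within"`.
#' @param grid Increasing vector of time points (days).
#' @param config Optional [rds_config()].
#' @param conditional_on_susceptible See above; defaults to the config's
#'   `zi_conditional_cdf`.
#' @param gh_points Quadrature points for the random-effect integral.
#' @return A data frame with columns `time` and `cdf`.
#' @export
marginal_cdf_curve <- function(dataset, params,
                               which = c("between", "within"),
                               grid,
                               config = config_from_params(params),
                               conditional_on_susceptible =
                                 config$zi_conditional_cdf,
                               gh_points = 21L) {
  which <- match.arg(which)
  if (!length(grid)) stop("empty time grid", call. = FALSE)
  comp <- if (which == "between") "B" else "W"
  family <- params[[paste0("family_", comp)]]
  re <- realized_eta(dataset, params, config, which)
  sd_z <- if (comp %in% params$re) exp(params$re_log_sd[[match(comp, params$re)]]) else 0
  gh <- gh_rule(if (sd_z > 0) gh_points else 1L)
  zs <- sqrt(2) * sd_z * gh$x
  wt <- gh$w / sqrt(pi)
  weight <- if (which == "between" && !conditional_on_susceptible) {
    1 - re$pi
  } else {
    rep(1, length(re$eta))
  }
  cdf <- vapply(grid, function(t) {
    if (t <= 0) return(0)
    ## rows x nodes matrix of conditional CDFs
    fz <- vapply(zs, function(z) {
      1 - exp(aft_log_survival(t, re$eta + z, family))
    }, numeric(length(re$eta)))
    mean(weight * drop(as.matrix(fz) %*% wt))
  }, 0)
  data.frame(time = grid, cdf = cdf)
}

#' Empirical (Kaplan--Meier) CDF curve of pooled gap times
#'
#' Pools the requested gap times across subjects and episodes (between-gaps
#' include the censored final gaps; within-gaps are censored only when the
#' history flags them) and returns one minus the Kaplan--Meier survival
#' estimate on the grid.
#'
#' @param dataset An [rds_data()] object.
#' @param which `"between"` or `"within"`.
#' @param grid Increasing vector of time points (days).
#' @return A data frame with columns `time` and `cdf`; the attribute
#'   `defined_to` gives the largest event time, beyond which the KM curve is
#'   undefined if all later observations are censored (values there carry
#'   the last defined value).
#' @export
empirical_cdf_curve <- function(dataset, which = c("between", "within"),
                                grid) {
  which <- match.arg(which)
  if (!length(grid)) stop("empty time grid", call. = FALSE)
  if (which == "between") {
    time <- unlist(lapply(dataset, function(s) {
      c(s$episodes$between_gap,
        if (s$final_gap_censored == 1L && s$final_gap > 0) s$final_gap)
    }))
    event <- unlist(lapply(dataset, function(s) {
      c(rep(1L, n_episodes(s)),
        if (s$final_gap_censored == 1L && s$final_gap > 0) 0L)
    }))
  } else {
    time <- unlist(lapply(dataset, function(s) s$episodes$duration))
    event <- unlist(lapply(dataset, function(s) 1L - s$episodes$within_censored))
  }
  if (!length(time)) stop("no pooled gap times of kind '", which, "'",
                          call. = FALSE)
  if (!any(event == 1L)) {
    out <- data.frame(time = grid, cdf = 0)
    attr(out, "defined_to") <- 0
    return(out)
  }
  km <- survival::survfit(survival::Surv(time, event) ~ 1)
  surv <- summary(km, times = grid, extend = TRUE)$surv
  out <- data.frame(time = grid, cdf = 1 - surv)
  attr(out, "defined_to") <- max(time[event == 1L])
  out
}

#' Observed and fitted CDF curves in tidy form
#'
#' Convenience wrapper combining [empirical_cdf_curve()] and
#' [marginal_cdf_curve()] on a common grid, for writing or plotting.
#'
#' @inheritParams marginal_cdf_curve
#' @return A data frame with columns `kind`, `time`, `observed`, `fitted`.
#' @export
cdf_curves <- function(dataset, params, which = c("between", "within"),
                       grid, config = config_from_params(params), ...) {
  which <- match.arg(which)
  obs <- empirical_cdf_curve(dataset, which, grid)
  fit <- marginal_cdf_curve(dataset, params, which, grid, config, ...)
  data.frame(kind = which, time = grid, observed = obs$cdf, fitted = fit$cdf)
}
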