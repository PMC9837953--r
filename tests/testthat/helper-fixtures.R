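# Shared fixtures: all built in code, deterministic under fixed seeds.

# hand-built subject: two episodes plus a censored final gap
toy_subject <- function() {
  subject_history(
    subject_id = "t1",
    episodes = data.frame(onset = c(30, 100),
                          termination = c(40, 112),
                          severity = c(0L, 1L)),
    final_gap = 50,
    final_gap_censored = 1L,
    baseline = c(trt = 1, age_dec = 5)
  )
}

# intercept-only parameters with small random effects, all submodels on
toy_params <- function(re_sd = c(0.5, 0.4, 0.8),
                       corr = c(0.3, 0.2, 0.1),
                       family_B = "lognormal", family_W = "lognormal") {
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- corr[1]
  R[1, 3] <- R[3, 1] <- corr[2]
  R[2, 3] <- R[3, 2] <- corr[3]
  un <- re_covariance_to_unconstrained(R * tcrossprod(re_sd))
  rds_params(
    beta_B = c("(Intercept)" = 4.0, trt = 0.3),
    beta_W = c("(Intercept)" = 2.4, trt = -0.1),
    beta_S = c("(Intercept)" = -1.2, trt = 0.2),
    beta_ZI = c("(Intercept)" = -1.0, trt = 0.2),
    family_B = baseline_family(family_B, 1.1),
    family_W = baseline_family(family_W, 0.6),
    re_log_sd = un$re_log_sd,
    re_corr_chol = un$re_corr_chol
  )
}

toy_config <- function(params = toy_params(), quad_points = 5,
                       quad_mode = "adaptive") {
  rdsjoint:::config_from_params(params, quad_points = quad_points,
                                quad_mode = quad_mode)
}

# small simulation setup around toy_params
toy_sim_config <- function(n = 60, params = toy_params()) {
  simulation_config(
    n_subjects = n,
    true_params = params,
    covariate_spec = list(trt = list(dist = "bernoulli", par = 0.5)),
    nominal_follow_up = c(364, 224),
    dropout_rate = 4e-4,
    model_config = rdsjoint:::config_from_params(params)
  )
}

# Monte-Carlo estimate of one subject's marginal log-likelihood
# (independent of the quadrature path): E over Z ~ MVN(0, Sigma) of
# exp(conditional loglik), with the zero-inflation mixture applied outside.
mc_marginal_loglik <- function(subject, params, config, n_draws = 2e4,
                               seed = 1) {
  set.seed(seed)
  cov <- build_re_covariance(params$re_log_sd, params$re_corr_chol)
  Z <- matrix(rnorm(3 * n_draws), ncol = 3) %*% chol(cov$sigma)
  colnames(Z) <- c("B", "W", "S")
  cll <- rdsjoint:::conditional_loglik_multi(subject, params, Z, config)
  mx <- max(cll)
  ex <- exp(cll - mx)
  E <- mean(ex)
  se <- stats::sd(ex) / sqrt(n_draws)
  logE <- mx + log(E)
  out <- logE
  if (config$include_zi && !is.null(params$beta_ZI)) {
    des <- rdsjoint:::build_design(subject, config)
    lp <- sum(des$x_zi * params$beta_ZI)
    if (n_episodes(subject) == 0L) {
      pi_i <- plogis(lp)
      out <- log(pi_i + (1 - pi_i) * exp(logE))
      se <- (1 - pi_i) * exp(logE) * (se / E) / exp(out)
    } else {
      out <- plogis(-lp, log.p = TRUE) + logE
      se <- se / E
    }
  } else {
    se <- se / E
  }
  list(loglik = out, se_log = se)
}
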