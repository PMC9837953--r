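test_that("conditional loglik of a zero-event subject is a survival term", {
  p <- toy_params()
  cfg <- toy_config(p)
  s0 <- subject_history("z", final_gap = 200, baseline = c(trt = 1))
  z <- c(B = 0.4, W = -1, S = 2)
  eta <- sum(c(1, 1) * p$beta_B) + z[["B"]]
  expect_equal(conditional_loglik(s0, p, z, cfg),
               aft_log_survival(200, eta, p$family_B))
})

test_that("conditional loglik: one unit-rate episode with p = 0.5", {
  # all coefficients zero, exponential families, B = W = 1, S = 1:
  # log f_B(1) + log f_W(1) + log 0.5 = -1 - 1 + log(0.5)
  p <- rds_params(beta_B = 0, beta_W = 0, beta_S = 0,
                  family_B = baseline_family("exponential"),
                  family_W = baseline_family("exponential"),
                  re = character(0))
  cfg <- rdsjoint:::config_from_params(p)
  s <- subject_history("u", episodes = data.frame(onset = 1, termination = 2,
                                                  severity = 1L),
                       final_gap = 0, baseline = c(x = 1)[0])
  expect_equal(conditional_loglik(s, p, c(0, 0, 0), cfg), -2 + log(0.5))
})

test_that("conditional loglik matches an independent term-by-term computation", {
  p <- toy_params()
  cfg <- toy_config(p)
  s <- toy_subject()
  z <- c(B = -0.3, W = 0.25, S = 0.6)
  # independent re-implementation with stats d/p functions
  x <- c(1, 1) # intercept, trt = 1
  etaB <- sum(x * p$beta_B) + z[["B"]]
  etaW <- sum(x * p$beta_W) + z[["W"]]
  lpS <- sum(x * p$beta_S) + z[["S"]]
  B <- c(30, 60)  # onsets 30, 100 with terminations 40 -> gaps 30, 60
  W <- c(10, 12)
  S <- c(0, 1)
  expected <-
    sum(dlnorm(B, etaB, p$family_B$shape, log = TRUE)) +
    sum(dlnorm(W, etaW, p$family_W$shape, log = TRUE)) +
    sum(dbinom(S, 1, plogis(lpS), log = TRUE)) +
    plnorm(50, etaB, p$family_B$shape, lower.tail = FALSE, log.p = TRUE)
  expect_equal(conditional_loglik(s, p, z, cfg), expected, tolerance = 1e-12)
})

test_that("degenerate non-susceptible subjects have likelihood one", {
  p <- toy_params()
  p$beta_ZI[1] <- 40 # pi -> 1
  cfg <- toy_config(p)
  s0 <- subject_history("z", final_gap = 150, baseline = c(trt = 0))
  expect_equal(marginal_subject_loglik(s0, p, config = cfg), 0,
               tolerance = 1e-12)
})

test_that("point-mass random effects collapse to the conditional at z = 0", {
  p <- toy_params(re_sd = c(1e-7, 1e-7, 1e-7), corr = c(0, 0, 0))
  p$beta_ZI <- NULL # no zero-inflation
  cfg <- toy_config(p)
  s <- toy_subject()
  expect_equal(marginal_subject_loglik(s, p, config = cfg),
               conditional_loglik(s, p, c(0, 0, 0), cfg), tolerance = 1e-8)
})

test_that("zero-inflation collapses as its intercept goes to -Inf", {
  p <- toy_params()
  cfg <- toy_config(p)
  p_no <- p
  p_no$beta_ZI <- NULL
  cfg_no <- toy_config(p_no)
  p$beta_ZI[] <- c(-40, 0)
  set.seed(5)
  dat <- simulate_dataset(toy_sim_config(20, p_no), seed = 5)
  expect_equal(total_loglik(dat, p, cfg), total_loglik(dat, p_no, cfg_no),
               tolerance = 1e-8)
})

test_that("quadrature marginal matches a Monte-Carlo oracle", {
  p <- toy_params()
  cfg <- toy_config(p)
  dat <- simulate_dataset(toy_sim_config(40, p), seed = 21)
  m <- vapply(dat, n_episodes, 0L)
  picks <- c(which(m == 0)[1], which(m == 1)[1], which(m >= 2)[1])
  picks <- picks[!is.na(picks)]
  expect_gte(length(picks), 2)
  for (i in picks) {
    q <- marginal_subject_loglik(dat[[i]], p, config = cfg)
    mc <- mc_marginal_loglik(dat[[i]], p, cfg, n_draws = 2e4, seed = 100 + i)
    expect_lt(abs(q - mc$loglik), 3 * mc$se_log + 1e-4)
  }
})

test_that("total loglik is additive, order-invariant, engine-consistent", {
  p <- toy_params()
  cfg <- toy_config(p)
  dat <- simulate_dataset(toy_sim_config(25, p), seed = 31)
  one <- total_loglik(dat[1], p, cfg)
  expect_equal(one, marginal_subject_loglik(dat[[1]], p, config = cfg),
               tolerance = 1e-3)
  s2 <- dat[[1]]
  s2$subject_id <- "copy"
  dup <- rds_data(list(dat[[1]], s2))
  expect_equal(total_loglik(dup, p, cfg), 2 * one, tolerance = 1e-6)
  perm <- dat[sample(seq_along(dat))]
  expect_equal(total_loglik(perm, p, cfg), total_loglik(dat, p, cfg),
               tolerance = 1e-10)
  # reference R engine agrees with the compiled engine
  expect_equal(total_loglik(dat, p, cfg, engine = "R"),
               total_loglik(dat, p, cfg, engine = "cpp"), tolerance = 1e-3)
})

test_that("quadrature rules normalize and realize correctly", {
  p <- toy_params()
  cfg <- toy_config(p)
  # one fixed point sits at zero with weight one
  r1 <- make_quadrature(1, "fixed")
  expect_equal(r1$x, 0)
  expect_equal(r1$w, sqrt(pi))
  # realized fixed rule integrates the constant 1 exactly: sum of
  # exp(logc + logphi(node)) = 1
  s <- toy_subject()
  for (np in c(1, 5, 7)) {
    r <- make_quadrature(np, "fixed", s, p, cfg)
    q <- rowSums((r$nodes %*% r$siginv) * r$nodes)
    logphi <- -ncol(r$nodes) / 2 * log(2 * pi) - 0.5 * r$logdetsig - 0.5 * q
    expect_equal(sum(exp(r$logc + logphi)), 1, tolerance = 1e-12)
  }
  # adaptive rule on a flat integrand reduces to the prior grid: a subject
  # whose conditional likelihood is constant in z (final gap 0)
  s_flat <- subject_history("f", episodes = data.frame(
    onset = 5, termination = 364, severity = 0L), final_gap = 0,
    baseline = c(trt = 0))
  p_b <- toy_params()
  p_b$beta_W <- NULL
  p_b$beta_S <- NULL
  p_b$beta_ZI <- NULL
  p_b$re <- "B"
  p_b$re_log_sd <- p_b$re_log_sd[1]
  p_b$re_corr_chol <- numeric(0)
  cfg_b <- toy_config(p_b)
  # not truly flat (one density term), but E[1] under the adaptive rule must
  # still be 1 up to Gauss-Hermite accuracy on a Gaussian-like weight
  r_ad <- make_quadrature(7, "adaptive", s_flat, p_b, cfg_b)
  q <- rowSums((r_ad$nodes %*% r_ad$siginv) * r_ad$nodes)
  logphi <- -0.5 * log(2 * pi) - 0.5 * r_ad$logdetsig - 0.5 * q
  expect_equal(sum(exp(r_ad$logc + logphi)), 1, tolerance = 1e-4)
})

test_that("quadrature reproduces the log-normal moment generating function", {
  # E[exp(a z_B)] = exp(a^2 sd_B^2 / 2) for z_B ~ N(0, sd_B^2)
  p <- toy_params()
  cfg <- toy_config(p)
  s <- toy_subject()
  a <- 0.5
  sd_B <- exp(p$re_log_sd[[1]])
  for (np in c(5, 9)) {
    r <- make_quadrature(np, "fixed", s, p, cfg)
    q <- rowSums((r$nodes %*% r$siginv) * r$nodes)
    logphi <- -ncol(r$nodes) / 2 * log(2 * pi) - 0.5 * r$logdetsig - 0.5 * q
    mgf <- sum(exp(r$logc + a * r$nodes[, "B"] + logphi))
    expect_equal(mgf, exp(a^2 * sd_B^2 / 2), tolerance = 1e-8)
  }
  expect_error(make_quadrature(0), ">= 1")
})

test_that("the adaptive quadrature is converged at the default settings", {
  p <- toy_params()
  dat <- simulate_dataset(toy_sim_config(150, p), seed = 77)
  ll <- vapply(c(5L, 9L, 15L), function(np) {
    total_loglik(dat, p, toy_config(p, quad_points = np))
  }, 0)
  # 5 -> 9 points: relative change in the dataset loglik is negligible
  expect_lt(abs(ll[1] - ll[2]) / abs(ll[2]), 1e-6)
  # 9 -> 15 points: absolutely converged
  expect_lt(abs(ll[2] - ll[3]), 1e-4)
})

test_that("with no random effects and no zero-inflation the joint loglik is
           the sum of three independent fixed-effects model logliks", {
  p <- toy_params()
  p$re <- character(0)
  p$re_log_sd <- numeric(0)
  p$re_corr_chol <- numeric(0)
  p$beta_ZI <- NULL
  cfg <- toy_config(p)
  dat <- simulate_dataset(toy_sim_config(80, p), seed = 13)
  joint <- total_loglik(dat, p, cfg)
  # independent reconstruction: censored AFT on between-gaps + AFT on
  # within-gaps + Bernoulli-logit on severities, all at the same parameters
  ll <- 0
  for (s in dat) {
    m <- n_episodes(s)
    xb <- c(1, s$baseline[["trt"]])
    etaB <- sum(xb * p$beta_B)
    if (m > 0) {
      ll <- ll + sum(dlnorm(s$episodes$between_gap, etaB, p$family_B$shape,
                            log = TRUE))
      ll <- ll + sum(dlnorm(s$episodes$duration, sum(xb * p$beta_W),
                            p$family_W$shape, log = TRUE))
      ll <- ll + sum(dbinom(s$episodes$severity, 1,
                            plogis(sum(xb * p$beta_S)), log = TRUE))
    }
    if (s$final_gap > 0) {
      ll <- ll + plnorm(s$final_gap, etaB, p$family_B$shape,
                        lower.tail = FALSE, log.p = TRUE)
    }
  }
  expect_equal(joint, ll, tolerance = 1e-8)
})

test_that("rate-only configuration equals a hand-rolled zero-inflated
           AFT-frailty likelihood on the gaps alone", {
  p <- toy_params()
  p$beta_W <- NULL
  p$beta_S <- NULL
  p$re <- "B"
  p$re_log_sd <- p$re_log_sd[1]
  p$re_corr_chol <- numeric(0)
  cfg <- toy_config(p, quad_points = 25, quad_mode = "fixed")
  dat <- simulate_dataset(toy_sim_config(40, toy_params()), seed = 99)
  joint <- total_loglik(dat, p, cfg)
  # independent 1-D Gauss-Hermite construction
  gh <- pracma::gaussHermite(25)
  sd_B <- exp(p$re_log_sd[[1]])
  ll <- 0
  for (s in dat) {
    xb <- c(1, s$baseline[["trt"]])
    etaB <- sum(xb * p$beta_B)
    z <- sqrt(2) * sd_B * gh$x
    cond <- vapply(z, function(zi) {
      v <- 0
      if (n_episodes(s) > 0) {
        v <- sum(dlnorm(s$episodes$between_gap, etaB + zi, p$family_B$shape,
                        log = TRUE))
      }
      if (s$final_gap > 0) {
        v <- v + plnorm(s$final_gap, etaB + zi, p$family_B$shape,
                        lower.tail = FALSE, log.p = TRUE)
      }
      v
    }, 0)
    E <- sum(gh$w / sqrt(pi) * exp(cond))
    pi_i <- plogis(sum(xb * p$beta_ZI))
    ll <- ll + if (n_episodes(s) == 0) log(pi_i + (1 - pi_i) * E) else
      log(1 - pi_i) + log(E)
  }
  expect_equal(joint, ll, tolerance = 1e-4)
})

test_that("likelihood errors carry context", {
  p <- toy_params()
  cfg <- toy_config(p)
  s <- toy_subject()
  s$episode_covariates <- data.frame(trt = c(1, 1)) # M + 1 = 3 rows required
  expect_error(validate_subject_history(s), "M \\+ 1")
  expect_error(total_loglik(structure(list(), class = "rds_data"), p, cfg),
               "empty")
})
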