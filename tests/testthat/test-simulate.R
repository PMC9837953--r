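test_that("simulated histories satisfy the structural invariants", {
  cfg <- default_case_study_config(150)
  dat <- simulate_dataset(cfg, seed = 1)
  expect_s3_class(dat, "rds_data")
  for (s in dat) {
    expect_silent(validate_subject_history(s))
    ep <- s$episodes
    if (nrow(ep)) {
      expect_true(all(ep$between_gap > 0))
      expect_true(all(ep$duration > 0))
      expect_true(!is.unsorted(ep$onset, strictly = TRUE))
      expect_true(all(ep$severity %in% 0:1))
    }
    expect_gte(s$final_gap, 0)
    expect_equal(s$final_gap_censored, 1L)
  }
  truth <- attr(dat, "truth")
  expect_equal(dim(truth$z), c(150L, 3L))
  expect_length(truth$susceptible, 150)
})

test_that("simulation is bit-reproducible under a fixed seed", {
  cfg <- default_case_study_config(40)
  d1 <- simulate_dataset(cfg, seed = 33)
  d2 <- simulate_dataset(cfg, seed = 33)
  expect_identical(lapply(d1, unclass), lapply(d2, unclass))
  expect_identical(attr(d1, "truth")$z, attr(d2, "truth")$z)
  d3 <- simulate_dataset(cfg, seed = 34)
  expect_false(identical(lapply(d1, unclass), lapply(d3, unclass)))
})

test_that("a non-susceptible population yields only zero-event subjects", {
  p <- toy_params()
  p$beta_ZI[] <- c(40, 0) # pi = 1
  scfg <- toy_sim_config(30, p)
  scfg$dropout_rate <- 0
  dat <- simulate_dataset(scfg, seed = 2)
  m <- vapply(dat, n_episodes, 0L)
  expect_true(all(m == 0))
  fg <- vapply(dat, function(s) s$final_gap, 0)
  expect_true(all(fg %in% c(364, 224))) # the nominal follow-up lengths
})

test_that("a very long mean gap empties the event process", {
  p <- toy_params()
  p$beta_B[[1]] <- 15 # mean gap >> follow-up
  dat <- simulate_dataset(toy_sim_config(60, p), seed = 3)
  expect_gt(mean(vapply(dat, n_episodes, 0L) == 0), 0.95)
})

test_that("event counts match an independent renewal simulation", {
  # exponential gaps, no covariates, REs, or zero-inflation
  lambda <- 1 / 60 # rate/day
  mean_w <- 8
  p <- rds_params(beta_B = log(1 / lambda), beta_W = log(mean_w),
                  beta_S = 0,
                  family_B = baseline_family("exponential"),
                  family_W = baseline_family("exponential"),
                  re = character(0))
  scfg <- simulation_config(4000, p, covariate_spec = list(),
                            nominal_follow_up = 300, dropout_rate = 0,
                            model_config = rdsjoint:::config_from_params(p))
  dat <- simulate_dataset(scfg, seed = 17)
  m <- vapply(dat, n_episodes, 0L)
  # brute-force oracle: direct alternating exponential renewal process
  set.seed(18)
  m_oracle <- replicate(4000, {
    t <- 0
    k <- 0
    repeat {
      t <- t + rexp(1, lambda)
      if (t >= 300) break
      k <- k + 1
      t <- t + rexp(1, 1 / mean_w)
      if (t >= 300) break
    }
    k
  })
  se <- sqrt(var(m) / 4000 + var(m_oracle) / 4000)
  expect_lt(abs(mean(m) - mean(m_oracle)), 3 * se)
})

test_that("the zero-event fraction matches a first-principles oracle", {
  cfg <- default_case_study_config(2000)
  dat <- simulate_dataset(cfg, seed = 19)
  zero_frac <- mean(vapply(dat, n_episodes, 0L) == 0)
  # oracle: P(zero) = pi + (1 - pi) P(B_1 > T) computed from the model-core
  # primitives only (no episode loop), MC over covariates/frailty/follow-up
  set.seed(20)
  nmc <- 4e4
  p <- cfg$true_params
  trt <- rbinom(nmc, 1, 0.5)
  age <- rnorm(nmc, 4.9, 1.3)
  fem <- rbinom(nmc, 1, 0.6)
  X <- cbind(1, trt, age, fem)
  nominal <- sample(c(364, 224), nmc, replace = TRUE)
  drop_t <- rexp(nmc, 4e-4)
  Tend <- pmin(nominal, drop_t)
  pi_i <- plogis(X %*% p$beta_ZI)
  sd_B <- 0.8
  eta <- X %*% p$beta_B + rnorm(nmc, 0, sd_B)
  p_nozero <- plnorm(Tend, eta, p$family_B$shape, lower.tail = FALSE)
  oracle <- mean(pi_i + (1 - pi_i) * p_nozero)
  se <- sqrt(zero_frac * (1 - zero_frac) / 2000 + var(pi_i + (1 - pi_i) * p_nozero) / nmc)
  expect_lt(abs(zero_frac - oracle), 3 * se)
  # and the calibrated target of one half
  expect_lt(abs(zero_frac - 0.5), 0.06)
})

test_that("observed severity frequency matches the generating probabilities", {
  cfg <- default_case_study_config(1500)
  dat <- simulate_dataset(cfg, seed = 23)
  truth <- attr(dat, "truth")
  p <- cfg$true_params
  sev <- c()
  psev <- c()
  for (i in seq_along(dat)) {
    s <- dat[[i]]
    if (n_episodes(s) == 0) next
    sev <- c(sev, s$episodes$severity)
    x <- c(1, s$baseline[c("trt", "age_dec", "female")])
    pij <- severity_prob(x, p$beta_S, truth$z[i, "S"])
    psev <- c(psev, rep(pij, n_episodes(s)))
  }
  se <- sqrt(sum(psev * (1 - psev))) / length(psev)
  expect_lt(abs(mean(sev) - mean(psev)), 3 * se)
})

test_that("simulated random effects reproduce the generating covariance", {
  cfg <- default_case_study_config(3000)
  dat <- simulate_dataset(cfg, seed = 29)
  z <- attr(dat, "truth")$z
  p <- cfg$true_params
  cov_true <- build_re_covariance(p$re_log_sd, p$re_corr_chol)
  expect_equal(unname(apply(z, 2, sd)), unname(cov_true$sd), tolerance = 0.08)
  emp_corr <- cor(z)
  expect_equal(emp_corr[lower.tri(emp_corr)],
               cov_true$corr[lower.tri(cov_true$corr)], tolerance = 0.08)
})

test_that("the default study configuration is internally coherent", {
  cfg <- default_case_study_config()
  expect_equal(cfg$n_subjects, 1100L)
  p <- cfg$true_params
  expect_equal(exp(p$beta_B[["trt"]]), 2) # treatment AFT factor on the rate
  cov <- build_re_covariance(p$re_log_sd, p$re_corr_chol)
  expect_equal(unname(cov$sd), c(0.8, 0.5, 1.5), tolerance = 1e-10)
  expect_equal(cov$corr[lower.tri(cov$corr)], c(0.40, 0.45, 0.45),
               tolerance = 1e-10)
  expect_gt(min(eigen(cov$sigma)$values), 0)
  expect_equal(p$family_B$shape, 1.22)
  expect_equal(p$family_W$shape, 0.62)
})

test_that("ongoing exacerbations can be censored instead of followed", {
  p <- toy_params()
  p$beta_W[[1]] <- 5 # very long episodes: many overlap the follow-up end
  scfg <- toy_sim_config(80, p)
  scfg$follow_ongoing_exacerbation <- FALSE
  dat <- simulate_dataset(scfg, seed = 41)
  wc <- unlist(lapply(dat, function(s) s$episodes$within_censored))
  expect_gt(sum(wc), 0)
  for (s in dat) {
    if (any(s$episodes$within_censored == 1)) {
      expect_equal(s$final_gap, 0) # censoring ends the follow-up
      expect_lte(max(s$episodes$termination), max(c(364, 224)))
    }
  }
  # default: followed to termination, no within-censoring
  scfg2 <- toy_sim_config(80, p)
  dat2 <- simulate_dataset(scfg2, seed = 41)
  expect_equal(sum(unlist(lapply(dat2, function(s) s$episodes$within_censored))),
               0)
})
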