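test_that("empirical-Bayes modes shrink to zero with a degenerate prior", {
  p <- toy_params(re_sd = c(1e-4, 1e-4, 1e-4))
  cfg <- toy_config(p)
  z <- empirical_bayes(toy_subject(), p, cfg)
  expect_true(all(abs(z) < 1e-3))
  # zero-event subject: only the rate component is identified
  s0 <- subject_history("z", final_gap = 100, baseline = c(trt = 0))
  z0 <- empirical_bayes(s0, toy_params(), toy_config(toy_params()))
  expect_false(is.na(z0[["B"]]))
  expect_true(is.na(z0[["W"]]) && is.na(z0[["S"]]))
})

test_that("empirical-Bayes predictions shrink and track the simulated truth", {
  p <- toy_params(re_sd = c(0.8, 0.5, 0.8))
  scfg <- toy_sim_config(500, p)
  dat <- simulate_dataset(scfg, seed = 2024)
  truth <- attr(dat, "truth")
  modes <- rdsjoint:::empirical_bayes_all(dat, p, scfg$model_config)
  has_ep <- vapply(dat, n_episodes, 0L) >= 1
  # compiled and reference mode searches agree
  i1 <- which(has_ep)[1]
  expect_equal(unname(modes[i1, ]),
               unname(empirical_bayes(dat[[i1]], p, scfg$model_config)),
               tolerance = 1e-4)
  sd_B <- exp(p$re_log_sd[[1]])
  zb <- modes[, "B"]
  # centered near zero: 3 SEs of the mean on the true z scale
  expect_lt(abs(mean(zb)), 3 * sd_B / sqrt(length(zb)))
  n1 <- sum(has_ep)
  expect_lt(abs(mean(modes[has_ep, "W"])),
            3 * exp(p$re_log_sd[[2]]) / sqrt(n1))
  expect_lt(abs(mean(modes[has_ep, "S"])),
            3 * exp(p$re_log_sd[[3]]) / sqrt(n1))
  # shrinkage: posterior modes are less dispersed than the prior
  expect_lt(var(zb), sd_B^2)
  expect_lt(var(modes[has_ep, "S"], na.rm = TRUE), exp(2 * p$re_log_sd[[3]]))
  # informative: EB modes correlate with the simulated random effects
  expect_gt(cor(zb[has_ep], truth$z[has_ep, "B"]), 0.5)
  expect_gt(cor(modes[has_ep, "W"], truth$z[has_ep, "W"], use = "complete"), 0.3)
})

test_that("marginal mean gap times use the closed-form moments", {
  # degenerate: no residual scale, no random effect
  p <- rds_params(beta_B = c("(Intercept)" = log(100)),
                  family_B = baseline_family("lognormal", 1e-12),
                  re = character(0))
  expect_equal(marginal_mean_gap(numeric(0), p, "between"), 100,
               tolerance = 1e-6)
  # log-normal multiplier exp(sigma^2/2) * exp(sd_z^2/2)
  p2 <- rds_params(beta_B = c("(Intercept)" = log(100)),
                   family_B = baseline_family("lognormal", sqrt(0.5)),
                   re = "B", re_log_sd = log(sqrt(0.5)),
                   re_corr_chol = numeric(0))
  expect_equal(marginal_mean_gap(numeric(0), p2, "between"),
               100 * exp(0.25) * exp(0.25))
  # log-logistic with shape >= 1 has no finite mean
  p3 <- rds_params(beta_B = c("(Intercept)" = 2),
                   family_B = baseline_family("loglogistic", 1.1),
                   re = character(0))
  expect_equal(marginal_mean_gap(numeric(0), p3, "between"), Inf)
  # weibull moment: E[exp(eps)] = Gamma(1 + sigma), against numerical
  # integration of the density (independent oracle)
  p4 <- rds_params(beta_B = c("(Intercept)" = 1.5),
                   family_B = baseline_family("weibull", 0.7),
                   re = character(0))
  num <- integrate(function(t) t * exp(aft_log_density(t, 1.5, p4$family_B)),
                   0, Inf, rel.tol = 1e-10)$value
  expect_equal(marginal_mean_gap(numeric(0), p4, "between"), num,
               tolerance = 1e-7)
  # conditioning on a supplied random effect replaces the marginal factor
  expect_equal(marginal_mean_gap(numeric(0), p2, "between", z = 0.3),
               100 * exp(0.25) * exp(0.3))
})

test_that("marginal severity probability integrates the severity RE", {
  p <- toy_params()
  x <- c(trt = 1)
  lp <- p$beta_S[[1]] + p$beta_S[[2]]
  sd_s <- exp(p$re_log_sd[[3]])
  oracle <- integrate(function(z) plogis(lp + z) * dnorm(z, 0, sd_s),
                      -Inf, Inf, rel.tol = 1e-10)$value
  expect_equal(marginal_severity_prob(x, p), oracle, tolerance = 1e-6)
  expect_equal(marginal_severity_prob(x, p, z = 0.5), plogis(lp + 0.5))
})

test_that("fitted marginal CDF matches the family CDF without REs or ZI", {
  p0 <- rds_params(beta_B = c("(Intercept)" = 3),
                   beta_W = c("(Intercept)" = 2.5),
                   family_B = baseline_family("lognormal", 1.2),
                   family_W = baseline_family("lognormal", 0.6),
                   re = character(0))
  cfg0 <- rdsjoint:::config_from_params(p0)
  cfg0$include_zi <- FALSE
  s <- subject_history(1, data.frame(onset = 10, termination = 20,
                                     severity = 0L),
                       final_gap = 30, baseline = c(x = 1)[0])
  d <- rds_data(list(s))
  g <- c(0, 2, 10, 30, 90, 400)
  cw <- marginal_cdf_curve(d, p0, "within", g, cfg0)
  expect_equal(cw$cdf, plnorm(g, 2.5, 0.6), tolerance = 1e-12)
  cb <- marginal_cdf_curve(d, p0, "between", g, cfg0)
  expect_equal(cb$cdf, plnorm(g, 3, 1.2), tolerance = 1e-12)
  expect_error(marginal_cdf_curve(d, p0, "within", numeric(0), cfg0), "grid")
})

test_that("fitted marginal CDF is a CDF and honours the ZI weighting", {
  p <- toy_params()
  cfg <- toy_config(p)
  dat <- simulate_dataset(toy_sim_config(50, p), seed = 9)
  g <- seq(0, 500, by = 10)
  cc <- marginal_cdf_curve(dat, p, "between", g, cfg)
  expect_equal(cc$cdf[1], 0)
  expect_true(all(diff(cc$cdf) >= -1e-12))
  expect_true(all(cc$cdf <= 1 + 1e-12))
  # unconditional curve is pointwise below the susceptible-only curve
  cu <- marginal_cdf_curve(dat, p, "between", g, cfg,
                           conditional_on_susceptible = FALSE)
  expect_true(all(cu$cdf <= cc$cdf + 1e-12))
})

test_that("empirical CDF curve is one minus the Kaplan-Meier estimate", {
  # no censoring: reduces to the empirical step CDF
  mk <- function(id, gaps) {
    onset <- cumsum(gaps + c(0, rep(5, length(gaps) - 1)))
    subject_history(id,
                    data.frame(onset = onset, termination = onset + 5,
                               severity = 0L),
                    final_gap = 0, baseline = c(x = 1)[0])
  }
  d1 <- rds_data(list(mk("a", c(2, 7)), mk("b", c(4))))
  g <- c(1, 2, 3, 4, 5, 7, 8)
  obs <- empirical_cdf_curve(d1, "between", g)
  expect_equal(obs$cdf, ecdf(c(2, 7, 4))(g))
  # all censored: CDF identically zero up to the censoring time
  s_c <- subject_history("c", final_gap = 50, baseline = c(x = 1)[0])
  obs0 <- empirical_cdf_curve(rds_data(list(s_c)), "between", c(10, 40))
  expect_equal(obs0$cdf, c(0, 0))
  # hand-computed KM on 5 gaps with 2 censored:
  # events at 1, 3, 5; censored at 2 and 4
  # S(1) = 4/5, S(3) = 4/5 * 2/3 = 8/15, S(5) = 0
  subs <- list(
    mk("e1", 1), mk("e3", 3), mk("e5", 5),
    subject_history("c2", final_gap = 2, baseline = c(x = 1)[0]),
    subject_history("c4", final_gap = 4, baseline = c(x = 1)[0])
  )
  dk <- rds_data(subs)
  km <- empirical_cdf_curve(dk, "between", c(1, 2, 3, 4, 5))
  expect_equal(km$cdf, 1 - c(4 / 5, 4 / 5, 8 / 15, 8 / 15, 0),
               tolerance = 1e-12)
})

test_that("per-subject prediction table has valid ranges", {
  p <- toy_params()
  scfg <- toy_sim_config(40, p)
  dat <- simulate_dataset(scfg, seed = 12)
  pred <- predict_subjects(dat, p, scfg$model_config)
  expect_equal(nrow(pred), 40)
  expect_true(all(pred$mean_between > 0))
  expect_true(all(pred$mean_within > 0))
  expect_true(all(pred$severity_prob > 0 & pred$severity_prob < 1))
  expect_true(all(is.na(pred$z_W[pred$n_episodes == 0])))
  expect_true(all(!is.na(pred$z_B)))
})
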