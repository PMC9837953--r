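families_all <- c("exponential", "weibull", "lognormal", "loglogistic")

test_that("linear predictor is x.beta + z and checks dimensions", {
  expect_equal(linear_predictor(c(1, 0, 0), c(0, 0, 0), 0), 0)
  expect_equal(linear_predictor(c(1, 2), c(0.5, -0.25), 0.1), 0.1)
  expect_equal(linear_predictor(1, 1, -1), 0)
  expect_error(linear_predictor(c(1, 2), c(1, 2, 3), 0, submodel = "rate"),
               "rate")
})

test_that("AFT log density matches closed forms at reference points", {
  # log-normal, shape 1, t = e^eta: standard normal at 0 with Jacobian 1/t
  eta <- 0.7
  t <- exp(eta)
  fam <- baseline_family("lognormal", 1)
  expect_equal(aft_log_density(t, eta, fam), log(1 / (t * sqrt(2 * pi))))
  # unit-rate exponential at t = 1
  expect_equal(aft_log_density(1, 0, baseline_family("exponential")), -1)
  expect_error(aft_log_density(-1, 0, fam))
  expect_error(aft_log_density(0, 0, fam))
  expect_error(aft_log_density(1, Inf, fam))
})

test_that("AFT log survival has S(0) = 1, known medians, monotonicity", {
  for (f in families_all) {
    fam <- baseline_family(f, 0.8)
    expect_identical(aft_log_survival(0, 1.3, fam), 0)
    ts <- exp(seq(-3, 4, length.out = 60))
    expect_true(all(diff(aft_log_survival(ts, 0.5, fam)) < 0))
  }
  # median of the log-normal law is e^eta
  expect_equal(aft_log_survival(exp(1.2), 1.2, baseline_family("lognormal", 2)),
               log(0.5))
  # unit-rate exponential
  expect_equal(aft_log_survival(2, 0, baseline_family("exponential")), -2)
  expect_error(aft_log_survival(-0.1, 0, baseline_family("weibull", 1)))
})

test_that("density integrates to one over (0, Inf) for every family", {
  for (f in families_all) {
    for (shape in c(0.6, 1.3)) {
      fam <- baseline_family(f, shape)
      for (eta in c(-0.5, 1.5)) {
        total <- integrate(function(t) exp(aft_log_density(t, eta, fam)),
                           0, Inf, rel.tol = 1e-9)$value
        expect_equal(total, 1, tolerance = 1e-6)
      }
    }
  }
})

test_that("hazard identity h = f/S holds pointwise and is non-negative", {
  ts <- c(0.2, 1, 5, 40, 200)
  for (f in families_all) {
    fam <- baseline_family(f, 0.7)
    h <- aft_hazard(ts, 1.1, fam)
    expect_true(all(h >= 0))
    expect_equal(h, exp(aft_log_density(ts, 1.1, fam) -
                        aft_log_survival(ts, 1.1, fam)),
                 tolerance = 1e-10)
  }
  # exponential: constant hazard exp(-eta)
  expect_equal(aft_hazard(c(1, 7, 30), 0, baseline_family("exponential")),
               rep(1, 3))
  expect_equal(aft_hazard(c(1, 7, 30), log(2), baseline_family("exponential")),
               rep(0.5, 3))
})

test_that("weibull density agrees with numerical differentiation of survival", {
  fam <- baseline_family("weibull", 0.5)
  for (t in c(0.5, 2, 10)) {
    h <- 1e-6 * t
    fd <- (exp(aft_log_survival(t - h, 0.4, fam)) -
           exp(aft_log_survival(t + h, 0.4, fam))) / (2 * h)
    expect_equal(exp(aft_log_density(t, 0.4, fam)), fd, tolerance = 1e-6)
  }
})

test_that("AFT factor property: S(t | eta + b) = S(t exp(-b) | eta) exactly", {
  ts <- c(0.5, 3, 25, 120)
  b <- 0.7
  for (f in families_all) {
    fam <- baseline_family(f, 1.4)
    expect_equal(aft_log_survival(ts, 0.9 + b, fam),
                 aft_log_survival(ts * exp(-b), 0.9, fam), tolerance = 1e-12)
  }
})

test_that("exponential equals weibull with unit shape", {
  ts <- c(0.1, 1, 10, 100)
  fe <- baseline_family("exponential")
  fw <- baseline_family("weibull", 1)
  expect_equal(aft_log_density(ts, 0.3, fe), aft_log_density(ts, 0.3, fw),
               tolerance = 1e-12)
  expect_equal(aft_log_survival(ts, 0.3, fe), aft_log_survival(ts, 0.3, fw),
               tolerance = 1e-12)
  expect_equal(aft_hazard(ts, 0.3, fe), aft_hazard(ts, 0.3, fw),
               tolerance = 1e-12)
})

test_that("severity and zero-inflation probabilities follow the logistic law", {
  expect_equal(severity_prob(c(1, 0), c(0, 1), 0), 0.5)
  expect_equal(severity_prob(1, log(3), 0), 0.75)
  # monotone decrease towards 0 as z_S -> -Inf
  ps <- vapply(c(0, -2, -5, -10, -20), function(z) severity_prob(1, 0.5, z), 0)
  expect_true(all(diff(ps) < 0))
  expect_lt(ps[5], 1e-6)
  expect_equal(nonsusceptible_prob(c(1, 2, 3), c(0, 0, 0)), 0.5)
  expect_equal(nonsusceptible_prob(1, log(1 / 3)), 0.25)
  expect_lt(nonsusceptible_prob(1, -30), 1e-10)
  expect_error(severity_prob(c(1, 2), 1, 0), "severity")
})

test_that("random-effects covariance parametrization is a PD bijection", {
  # zero parameters give the identity
  expect_equal(build_re_covariance(c(0, 0, 0), c(0, 0, 0))$sigma,
               diag(3), ignore_attr = TRUE)
  # round trip from (SDs, correlations) through the unconstrained scale
  sd <- c(0.8, 0.5, 1.5)
  R <- matrix(c(1, .4, .45, .4, 1, .45, .45, .45, 1), 3, 3)
  sigma <- R * tcrossprod(sd)
  un <- re_covariance_to_unconstrained(sigma)
  back <- build_re_covariance(un$re_log_sd, un$re_corr_chol)
  expect_equal(back$sigma, sigma, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(unname(back$sd), sd, tolerance = 1e-10)
  # positive definiteness for arbitrary real inputs (eigenvalue oracle)
  set.seed(42)
  for (i in 1:50) {
    cov <- build_re_covariance(rnorm(3, 0, 2), rnorm(3, 0, 2))
    expect_gt(min(eigen(cov$sigma, symmetric = TRUE)$values), 0)
    expect_equal(cov$sigma, t(cov$sigma), tolerance = 1e-12)
  }
  # two-dimensional case (duration RE switched off)
  cov2 <- build_re_covariance(c(0.1, -0.3), 0.7)
  expect_equal(dim(cov2$sigma), c(2L, 2L))
  expect_gt(min(eigen(cov2$sigma)$values), 0)
})

test_that("baseline family validates its shape", {
  expect_error(baseline_family("lognormal", -1), "positive")
  expect_error(baseline_family("weibull", 0), "positive")
  expect_equal(baseline_family("exponential")$shape, 1)
  expect_error(baseline_family("gamma"))
})
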