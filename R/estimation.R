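## Maximum-likelihood estimation of the joint model.
##
## The optimizer works on the unconstrained parameter vector of
## pack_params(): coefficients, log shape parameters, log random-effect SDs
## and the unconstrained correlation-Cholesky parameters.  BFGS with a
## central-difference gradient is followed by Newton polishing steps with
## the finite-difference observed information (which also supplies the
## variance-covariance matrix).

surv_dist <- function(family) {
  switch(family, exponential = "exponential", weibull = "weibull",
         lognormal = "lognormal", loglogistic = "loglogistic")
}

## stacked between-gap rows (episodes + positive final gaps) for stage-wise
## starting values
stack_gaps <- function(dataset, config, which = c("between", "within")) {
  which <- match.arg(which)
  rows <- lapply(dataset, function(s) {
    m <- n_episodes(s)
    tab <- covariate_table(s, config$derive_episode_covariates)
    if (which == "between") {
      time <- c(s$episodes$between_gap,
                if (s$final_gap_censored == 1L && s$final_gap > 0) s$final_gap)
      event <- c(rep(1L, m),
                 if (s$final_gap_censored == 1L && s$final_gap > 0) 0L)
      keep <- seq_len(length(time))
      cbind(time = time, event = event,
            tab[keep, config$covariates_B, drop = FALSE])
    } else {
      if (m == 0L) return(NULL)
      cbind(time = s$episodes$duration,
            event = 1L - s$episodes$within_censored,
            severity = s$episodes$severity,
            tab[seq_len(m), union(config$covariates_W, config$covariates_S),
                drop = FALSE])
    }
  })
  do.call(rbind, rows)
}

capped_logit <- function(p, cap = 10) {
  pmin(pmax(stats::qlogis(pmin(pmax(p, 1e-12), 1 - 1e-12)), -cap), cap)
}

#' Stage-wise starting values
#'
#' Obtains starting values for the joint fit from independent fixed-effects
#' fits: a censored AFT fit on the between-gaps (via [survival::survreg()]),
#' an AFT fit on the within-gaps, a logistic fit on episode severity, and a
#' logistic fit of the zero-event indicator for the zero-inflation
#' component.  Random-effect SDs start at 0.5 and correlations at 0.  Any
#' failing stage falls back to zero coefficients with the intercept at the
#' empirical log-mean (or capped logit), with a warning.
#'
#' @param dataset An [rds_data()] object.
#' @param config An [rds_config()] object.
#' @return An [rds_params()] object.
#' @export
initial_values <- function(dataset, config) {
  template <- params_template(dataset, config)
  p <- template

  bg <- stack_gaps(dataset, config, "between")
  p$beta_B <- aft_start(bg, config$covariates_B, config$family_B,
                        names(p$beta_B), "rate")
  fam <- attr(p$beta_B, "family")
  if (!is.null(fam)) p$family_B <- fam
  attr(p$beta_B, "family") <- NULL

  if (config$include_duration) {
    wg <- stack_gaps(dataset, config, "within")
    p$beta_W <- aft_start(wg, config$covariates_W, config$family_W,
                          names(p$beta_W), "duration")
    fam <- attr(p$beta_W, "family")
    if (!is.null(fam)) p$family_W <- fam
    attr(p$beta_W, "family") <- NULL
  }

  if (config$include_severity) {
    wg <- stack_gaps(dataset, config, "within")
    p$beta_S <- logit_start(wg, "severity", config$covariates_S,
                            names(p$beta_S), "severity")
  }

  if (config$include_zi) {
    zi <- do.call(rbind, lapply(dataset, function(s) {
      row <- data.frame(zero = as.integer(n_episodes(s) == 0L))
      for (v in config$covariates_ZI) row[[v]] <- s$baseline[[v]]
      row
    }))
    p$beta_ZI <- logit_start(zi, "zero", config$covariates_ZI,
                             names(p$beta_ZI), "zero-inflation")
  }

  if (length(p$re)) {
    p$re_log_sd[] <- log(0.5)
    p$re_corr_chol[] <- 0
    ## the stage-wise AFT scale absorbs the random-effect variance; hand the
    ## starting RE variance back to the residual scale (exact decomposition
    ## for the log-normal family, a serviceable approximation otherwise)
    for (comp in intersect(p$re, c("B", "W"))) {
      fam <- p[[paste0("family_", comp)]]
      if (!is.null(fam) && fam$family != "exponential") {
        fam$shape <- sqrt(max(fam$shape^2 - 0.25, 0.04))
        p[[paste0("family_", comp)]] <- fam
      }
    }
  }
  p
}

aft_start <- function(df, covariates, family, coef_names, label) {
  fam <- baseline_family(family, 1)
  out <- tryCatch({
    if (is.null(df) || !nrow(df) || !any(df$event == 1)) stop("no events")
    fit <- survival::survreg(
      stats::as.formula(paste("survival::Surv(time, event) ~",
                              paste(c("1", covariates), collapse = "+"))),
      data = df, dist = surv_dist(family))
    beta <- stats::coef(fit)
    if (family != "exponential") fam <- baseline_family(family, fit$scale)
    stats::setNames(as.numeric(beta), coef_names)
  }, error = function(e) {
    warning(sprintf("%s start: fixed-effects AFT fit failed (%s); using empirical intercept",
                    label, conditionMessage(e)), call. = FALSE)
    b <- stats::setNames(numeric(length(coef_names)), coef_names)
    if (!is.null(df) && nrow(df)) b[1L] <- mean(log(df$time))
    b
  })
  attr(out, "family") <- fam
  out
}

logit_start <- function(df, response, covariates, coef_names, label) {
  tryCatch({
    if (is.null(df) || !nrow(df)) stop("no rows")
    y <- df[[response]]
    if (length(unique(y)) < 2L) { # complete separation guard
      b <- stats::setNames(numeric(length(coef_names)), coef_names)
      b[1L] <- capped_logit(mean(y))
      return(b)
    }
    fit <- stats::glm(stats::reformulate(c("1", covariates), response = response),
                      family = stats::binomial(), data = df)
    stats::setNames(pmin(pmax(as.numeric(stats::coef(fit)), -10), 10),
                    coef_names)
  }, error = function(e) {
    warning(sprintf("%s start: logistic fit failed (%s); using empirical logit",
                    label, conditionMessage(e)), call. = FALSE)
    b <- stats::setNames(numeric(length(coef_names)), coef_names)
    if (!is.null(df) && nrow(df)) b[1L] <- capped_logit(mean(df[[response]]))
    b
  })
}

## central-difference gradient of f at theta (f returns a scalar)
fd_gradient <- function(f, theta, h = NULL) {
  if (is.null(h)) h <- 1e-5 * pmax(1, abs(theta))
  vapply(seq_along(theta), function(i) {
    tp <- tm <- theta
    tp[i] <- tp[i] + h[i]
    tm[i] <- tm[i] - h[i]
    (f(tp) - f(tm)) / (2 * h[i])
  }, 0)
}

## symmetric finite-difference Hessian (central differences of the gradient)
fd_hessian <- function(f, theta, h = NULL) {
  if (is.null(h)) h <- 1e-4 * pmax(1, abs(theta))
  p <- length(theta)
  H <- matrix(0, p, p)
  f0 <- f(theta)
  fp <- fm <- numeric(p)
  for (i in seq_len(p)) {
    tp <- tm <- theta
    tp[i] <- tp[i] + h[i]
    tm[i] <- tm[i] - h[i]
    fp[i] <- f(tp)
    fm[i] <- f(tm)
    H[i, i] <- (fp[i] - 2 * f0 + fm[i]) / h[i]^2
  }
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      tpp <- tpm <- tmp <- tmm <- theta
      tpp[c(i, j)] <- tpp[c(i, j)] + h[c(i, j)]
      tmm[c(i, j)] <- tmm[c(i, j)] - h[c(i, j)]
      tpm[i] <- tpm[i] + h[i]; tpm[j] <- tpm[j] - h[j]
      tmp[i] <- tmp[i] - h[i]; tmp[j] <- tmp[j] + h[j]
      H[i, j] <- H[j, i] <-
        (f(tpp) - f(tpm) - f(tmp) + f(tmm)) / (4 * h[i] * h[j])
    }
  }
  (H + t(H)) / 2
}

#' Fit the joint rate--duration--severity model
#'
#' Maximizes the marginal likelihood over the unconstrained parametrization
#' with BFGS (central-difference gradient, posterior modes recycled between
#' nearby evaluations), then polishes with Newton steps using the
#' finite-difference observed information, which also provides the
#' variance-covariance matrix.  Convergence is declared when the gradient
#' max-norm falls below `tol_grad` and the relative log-likelihood change in
#' the final polishing step is below `tol_loglik`.
#'
#' @param dataset An [rds_data()] object.
#' @param config An [rds_config()] object.
#' @param start Optional [rds_params()] starting values (default
#'   [initial_values()]).
#' @param max_iter Maximum BFGS iterations (default 500).
#' @param tol_grad Gradient max-norm tolerance (default 1e-5).
#' @param tol_loglik Relative log-likelihood change tolerance (default 1e-9).
#' @param hessian If `FALSE`, skip the observed information (no vcov, no
#'   CIs, no Newton polish); useful for quick exploratory fits.
#' @param trace Print optimizer progress.
#' @return An object of class `rds_fit`: the parameter estimates
#'   (`params_hat`), `loglik`, `aic`, `vcov`, the exponentiated report
#'   tables (`report`, `re_report`) and a `convergence` record.  A fit that
#'   fails the tolerances is returned with `convergence$converged = FALSE`,
#'   never silently as converged.
#' @export
rds_fit <- function(dataset, config, start = NULL,
                    max_iter = 500L, tol_grad = 1e-5, tol_loglik = 1e-9,
                    hessian = TRUE, trace = FALSE) {
  if (!inherits(dataset, "rds_data")) dataset <- rds_data(dataset)
  if (is.null(start)) start <- initial_values(dataset, config)
  template <- start
  prep <- prepare_loglik_data(dataset, config)
  cache <- new.env(parent = emptyenv())
  cache$modes <- NULL
  n_eval <- 0L

  nll <- function(theta) {
    p <- unpack_params(theta, template)
    res <- tryCatch(
      loglik_cpp(prep, p, config, mode_start = cache$modes,
                 want_modes = config$quad_mode == "adaptive"),
      error = function(e) NULL)
    n_eval <<- n_eval + 1L
    if (is.null(res) || !is.finite(res$total)) return(1e10)
    if (!is.null(res$vmodes)) cache$modes <- res$vmodes
    -res$total
  }

  ## forward-difference gradient reusing the objective value at the base
  ## point (BFGS progress only; the convergence check and the Newton polish
  ## below use central differences)
  last <- new.env(parent = emptyenv())
  nll_cached <- function(theta) {
    v <- nll(theta)
    last$theta <- theta
    last$value <- v
    v
  }
  gr_forward <- function(theta) {
    f0 <- if (!is.null(last$theta) && identical(theta, last$theta)) {
      last$value
    } else nll(theta)
    h <- 1e-6 * pmax(1, abs(theta))
    vapply(seq_along(theta), function(i) {
      tp <- theta
      tp[i] <- tp[i] + h[i]
      (nll(tp) - f0) / h[i]
    }, 0)
  }

  theta0 <- pack_params(start)
  opt <- stats::optim(theta0, nll_cached, gr = gr_forward, method = "BFGS",
                      control = list(maxit = max_iter, reltol = tol_loglik,
                                     trace = as.integer(trace), REPORT = 10))
  theta <- opt$par
  f_cur <- opt$value

  vcov <- NULL
  grad <- fd_gradient(nll, theta)
  polish_steps <- 0L
  rel_change <- NA_real_
  if (hessian) {
    H <- fd_hessian(nll, theta)
    Hc <- tryCatch(chol(H), error = function(e) NULL)
    if (!is.null(Hc)) {
      ## Newton polish with the observed information, driven by the gradient
      ## criterion (the loglik is already flat to ~1e-10 here; the point of
      ## polishing is to settle the score equations)
      for (k in seq_len(10L)) {
        if (max(abs(grad)) < tol_grad) break
        step <- backsolve(Hc, forwardsolve(t(Hc), grad))
        alpha <- 1
        repeat {
          f_new <- nll(theta - alpha * step)
          if (f_new <= f_cur + 1e-7 * (abs(f_cur) * 1e-3 + 1) || alpha < 1e-4) break
          alpha <- alpha / 2
        }
        grad_new <- fd_gradient(nll, theta - alpha * step)
        if (max(abs(grad_new)) >= max(abs(grad))) break # at the noise floor
        rel_change <- abs(f_cur - f_new) / (abs(f_cur) + 1e-10)
        theta <- theta - alpha * step
        f_cur <- f_new
        grad <- grad_new
        polish_steps <- polish_steps + 1L
      }
      if (polish_steps > 0L) {
        H <- fd_hessian(nll, theta)
        Hc <- tryCatch(chol(H), error = function(e) NULL)
      }
    }
    if (!is.null(Hc)) {
      vcov <- chol2inv(Hc)
      dimnames(vcov) <- list(names(theta0), names(theta0))
    } else {
      warning("observed information not positive definite; ",
              "variance-covariance matrix unavailable", call. = FALSE)
    }
  }

  params_hat <- unpack_params(theta, template)
  loglik <- -f_cur
  k <- length(theta)
  grad_norm <- max(abs(grad))
  ## without the observed information there is no Newton polish, so the
  ## gradient criterion is not enforceable; fall back to the optimizer status
  converged <- opt$convergence == 0 && (!hessian || grad_norm < tol_grad)
  if (!converged) {
    warning(sprintf(
      "fit not converged (optim code %d, gradient max-norm %.3g)",
      opt$convergence, grad_norm), call. = FALSE)
  }

  fit <- structure(list(
    params_hat = params_hat,
    theta_hat = stats::setNames(theta, names(theta0)),
    loglik = loglik,
    aic = -2 * loglik + 2 * k,
    n_free_params = k,
    vcov = vcov,
    config = config,
    start = start,
    n_subjects = length(dataset),
    n_episodes = sum(vapply(dataset, n_episodes, 0L)),
    convergence = list(converged = converged,
                       optim_code = opt$convergence,
                       iterations = opt$counts[["function"]],
                       n_eval = n_eval,
                       polish_steps = polish_steps,
                       gradient_norm = grad_norm,
                       rel_loglik_change = rel_change)
  ), class = "rds_fit")
  fit$report <- exponentiated_report(params_hat, vcov)
  fit$re_report <- re_report(params_hat, vcov)
  fit
}

#' @export
print.rds_fit <- function(x, digits = 3, ...) {
  cat("Joint rate-duration-severity model fit\n")
  cat(sprintf("  %d subjects, %d episodes; %s/%s baseline families\n",
              x$n_subjects, x$n_episodes, x$params_hat$family_B$family,
              if (!is.null(x$params_hat$family_W))
                x$params_hat$family_W$family else "-"))
  cat(sprintf("  logLik %.3f, AIC %.3f (%d free parameters)%s\n",
              x$loglik, x$aic, x$n_free_params,
              if (x$convergence$converged) "" else "  [NOT CONVERGED]"))
  if (!is.null(x$report)) {
    cat("\nExponentiated coefficients (AFT factors / odds ratios):\n")
    print(format_report(x$report, digits), row.names = FALSE)
  }
  if (!is.null(x$re_report)) {
    cat("\nShape and random-effects parameters:\n")
    print(format_report(x$re_report, digits), row.names = FALSE)
  }
  invisible(x)
}

format_report <- function(rep, digits) {
  out <- rep
  for (v in intersect(c("estimate", "lower", "upper"), names(out))) {
    out[[v]] <- signif(out[[v]], digits)
  }
  out
}

submodel_labels <- c(B = "rate", W = "duration", S = "severity",
                     ZI = "zero-inflation")

#' Exponentiated coefficient report
#'
#' Exponentiates the estimated coefficients and their Wald 95% confidence
#' limits: AFT factors for the two gap-time submodels, odds ratios for the
#' severity and zero-inflation submodels.  A positive coefficient (AFT
#' factor > 1) lengthens the expected gap time -- for the rate submodel this
#' means a lower event rate; an OR > 1 increases the probability of a severe
#' event (severity submodel) or of belonging to the non-susceptible class
#' (zero-inflation submodel).
#'
#' @param params_hat An [rds_params()] object (the MLE).
#' @param vcov Variance-covariance matrix over the packed parameter vector,
#'   or `NULL` (then the CI columns are `NA`).
#' @param level Confidence level (default 0.95).
#' @return A data frame with columns `submodel`, `term`, `measure`,
#'   `estimate`, `lower`, `upper` and `significant` (CI excludes 1).
#' @export
exponentiated_report <- function(params_hat, vcov = NULL, level = 0.95) {
  theta <- pack_params(params_hat)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  se <- rep(NA_real_, length(theta))
  if (!is.null(vcov)) se <- sqrt(pmax(diag(vcov), 0))
  names(se) <- names(theta)
  rows <- list()
  for (sub in c("B", "W", "S", "ZI")) {
    beta <- params_hat[[paste0("beta_", sub)]]
    if (is.null(beta)) next
    nm <- paste0(sub, ":", names(beta))
    est <- exp(beta)
    lo <- exp(beta - zq * se[nm])
    hi <- exp(beta + zq * se[nm])
    rows[[sub]] <- data.frame(
      submodel = submodel_labels[[sub]],
      term = names(beta),
      measure = if (sub %in% c("B", "W")) "AFT factor" else "OR",
      estimate = unname(est), lower = unname(lo), upper = unname(hi),
      significant = !is.na(lo) & (lo > 1 | hi < 1)
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## shape + random-effects SD/correlation estimates with delta-method CIs;
## SDs and shapes on the log scale, correlations on the atanh scale (so the
## back-transformed correlation limits always lie in (-1, 1))
re_report <- function(params_hat, vcov = NULL, level = 0.95) {
  theta <- pack_params(params_hat)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  nm <- names(theta)
  rows <- list()
  add_log_scale <- function(label, group, key) {
    if (!key %in% nm) return()
    est <- theta[[key]]
    se <- if (!is.null(vcov)) sqrt(max(vcov[key, key], 0)) else NA_real_
    rows[[length(rows) + 1L]] <<- data.frame(
      parameter = group, component = label, estimate = exp(est),
      lower = exp(est - zq * se), upper = exp(est + zq * se))
  }
  add_log_scale("rate", "shape", "B:log(shape)")
  add_log_scale("duration", "shape", "W:log(shape)")
  for (comp in params_hat$re) {
    add_log_scale(submodel_labels[[comp]], "SD",
                  paste0("RE:log(sd_", comp, ")"))
  }
  d <- length(params_hat$re)
  if (d >= 2L) {
    pairs <- utils::combn(params_hat$re, 2)
    gamma_idx <- which(startsWith(nm, "RE:corr("))
    corr_of_gamma <- function(g) {
      L <- corr_chol_from_unconstrained(g, d)
      R <- L %*% t(L)
      R[lower.tri(R)]
    }
    gam <- theta[gamma_idx]
    rho <- corr_of_gamma(gam)
    se_z <- rep(NA_real_, length(rho))
    if (!is.null(vcov)) {
      J <- pracma::jacobian(function(g) atanh(corr_of_gamma(g)), gam)
      V <- J %*% vcov[gamma_idx, gamma_idx, drop = FALSE] %*% t(J)
      se_z <- sqrt(pmax(diag(V), 0))
    }
    zr <- atanh(rho)
    for (k in seq_along(rho)) {
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = "correlation",
        component = paste(submodel_labels[[pairs[1, k]]],
                          submodel_labels[[pairs[2, k]]], sep = "-"),
        estimate = rho[k],
        lower = tanh(zr[k] - zq * se_z[k]),
        upper = tanh(zr[k] + zq * se_z[k]))
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Baseline-family selection by AIC
#'
#' Fits the joint model under each candidate baseline family (used for both
#' gap-time submodels) and ranks the candidates by AIC; ties are broken
#' toward the family with fewer parameters (the exponential).  Candidates
#' whose fit does not converge are excluded from the ranking with a warning.
#'
#' @param dataset An [rds_data()] object.
#' @param config An [rds_config()] object (its families are overridden).
#' @param families Candidate family names.
#' @param ... Passed to [rds_fit()].
#' @return A list with `table` (family, aic, loglik, n_params, converged,
#'   ranked by AIC) and `best` (the best [rds_fit]).
#' @export
select_family <- function(dataset, config,
                          families = c("exponential", "weibull",
                                       "lognormal", "loglogistic"),
                          ...) {
  if (!length(families)) stop("no candidate families", call. = FALSE)
  fits <- list()
  tab <- data.frame(family = families, aic = NA_real_, loglik = NA_real_,
                    n_params = NA_integer_, converged = NA)
  for (i in seq_along(families)) {
    cfg <- config
    cfg$family_B <- cfg$family_W <- families[i]
    fit <- tryCatch(rds_fit(dataset, cfg, ...), error = function(e) {
      warning(sprintf("family %s failed: %s", families[i],
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (is.null(fit)) next
    fits[[families[i]]] <- fit
    tab$aic[i] <- fit$aic
    tab$loglik[i] <- fit$loglik
    tab$n_params[i] <- fit$n_free_params
    tab$converged[i] <- fit$convergence$converged
  }
  ok <- which(!is.na(tab$aic) & tab$converged)
  if (!length(ok)) {
    warning("no candidate family converged; ranking all fitted candidates",
            call. = FALSE)
    ok <- which(!is.na(tab$aic))
    if (!length(ok)) stop("no candidate family could be fitted", call. = FALSE)
  }
  ord <- ok[order(tab$aic[ok], tab$n_params[ok])]
  tab <- tab[c(ord, setdiff(seq_len(nrow(tab)), ord)), ]
  rownames(tab) <- NULL
  list(table = tab, best = fits[[tab$family[1L]]])
}
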