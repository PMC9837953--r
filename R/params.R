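#' Joint model parameters
#'
#' Container for all parameters of the joint rate--duration--severity model:
#' the coefficient vectors of the four submodels (each with a leading
#' intercept), the baseline-family shape parameters, and the random-effects
#' covariance in its unconstrained parametrization.
#'
#' @param beta_B Named coefficients of the rate (between-gap) submodel; the
#'   first element is the intercept (the log-scale location of the baseline
#'   law, so the family `shape` is purely a scale parameter).
#' @param beta_W Coefficients of the duration (within-gap) submodel, or
#'   `NULL` if the duration submodel is excluded.
#' @param beta_S Coefficients of the severity submodel, or `NULL`.
#' @param beta_ZI Coefficients of the zero-inflation submodel (baseline
#'   covariates only), or `NULL`.
#' @param family_B,family_W [baseline_family()] objects for the two gap-time
#'   submodels (`family_W` `NULL` when the duration submodel is excluded).
#' @param re Character subset of `c("B", "W", "S")`: which submodels carry a
#'   random effect.
#' @param re_log_sd Log standard deviations of the active random effects
#'   (same length and order as `re`).
#' @param re_corr_chol Unconstrained correlation parameters, length
#'   `d(d-1)/2` where `d = length(re)`.
#' @return An object of class `rds_params`.
#' @export
rds_params <- function(beta_B,
                       beta_W = NULL,
                       beta_S = NULL,
                       beta_ZI = NULL,
                       family_B = baseline_family("lognormal"),
                       family_W = baseline_family("lognormal"),
                       re = c("B", "W", "S"),
                       re_log_sd = rep(0, length(re)),
                       re_corr_chol = rep(0, choose(length(re), 2))) {
  re <- match_re(re)
  d <- length(re)
  stopifnot(length(re_log_sd) == d,
            length(re_corr_chol) == choose(d, 2))
  if (is.null(beta_W)) family_W <- NULL
  obj <- structure(list(
    beta_B = as_coef(beta_B, "rate"),
    beta_W = if (!is.null(beta_W)) as_coef(beta_W, "duration"),
    beta_S = if (!is.null(beta_S)) as_coef(beta_S, "severity"),
    beta_ZI = if (!is.null(beta_ZI)) as_coef(beta_ZI, "zero-inflation"),
    family_B = as_baseline_family(family_B),
    family_W = if (!is.null(family_W)) as_baseline_family(family_W),
    re = re,
    re_log_sd = stats::setNames(as.numeric(re_log_sd), re),
    re_corr_chol = as.numeric(re_corr_chol)
  ), class = "rds_params")
  obj
}

match_re <- function(re) {
  if (length(re) == 0L) return(character(0))
  re <- match.arg(re, c("B", "W", "S"), several.ok = TRUE)
  ## keep canonical order B, W, S
  c("B", "W", "S")[c("B", "W", "S") %in% re]
}

as_coef <- function(beta, label) {
  if (is.null(names(beta))) {
    names(beta) <- c("(Intercept)",
                     if (length(beta) > 1L) paste0("x", seq_len(length(beta) - 1L)))
  }
  stats::setNames(as.numeric(beta), names(beta))
}

#' @export
print.rds_params <- function(x, ...) {
  cat("Joint rate-duration-severity model parameters\n")
  cat(sprintf("  rate:      %s family, shape %.3g, %d coefficient(s)\n",
              x$family_B$family, x$family_B$shape, length(x$beta_B)))
  if (!is.null(x$beta_W)) {
    cat(sprintf("  duration:  %s family, shape %.3g, %d coefficient(s)\n",
                x$family_W$family, x$family_W$shape, length(x$beta_W)))
  }
  if (!is.null(x$beta_S)) {
    cat(sprintf("  severity:  logistic, %d coefficient(s)\n", length(x$beta_S)))
  }
  if (!is.null(x$beta_ZI)) {
    cat(sprintf("  zero-inflation: logistic, %d coefficient(s)\n",
                length(x$beta_ZI)))
  }
  if (length(x$re)) {
    cov <- build_re_covariance(x$re_log_sd, x$re_corr_chol)
    cat("  random effects (", paste(x$re, collapse = ", "), "): SD ",
        paste(sprintf("%.3g", cov$sd), collapse = ", "), "\n", sep = "")
    if (length(x$re) > 1L) {
      cors <- cov$corr[lower.tri(cov$corr)]
      cat("    correlations: ", paste(sprintf("%.3g", cors), collapse = ", "),
          "\n", sep = "")
    }
  } else {
    cat("  no random effects\n")
  }
  invisible(x)
}

#' Random-effects covariance of a parameter object
#'
#' @param params An [rds_params()] object.
#' @return As [build_re_covariance()]; `NULL` when no random effects are
#'   active.
#' @export
re_covariance <- function(params) {
  if (!length(params$re)) return(NULL)
  build_re_covariance(params$re_log_sd, params$re_corr_chol)
}

#' Model configuration
#'
#' Describes which submodels are included, their covariates and baseline
#' families, which submodels carry a random effect, and the quadrature
#' settings used for the marginal likelihood.
#'
#' @param covariates_B,covariates_W,covariates_S Character vectors naming
#'   the covariate columns of the rate, duration and severity submodels (an
#'   intercept is always added; may be empty for intercept-only submodels).
#' @param covariates_ZI Covariates of the zero-inflation submodel; baseline
#'   covariates only.
#' @param family_B,family_W Baseline family names for the two gap
#'   submodels.
#' @param include_duration,include_severity,include_zi Logical switches for
#'   the optional submodels.
#' @param random_effects Character subset of `c("B","W","S")`; which
#'   submodels carry a subject-level random effect.
#' @param derive_episode_covariates If `TRUE`, the episode-specific
#'   covariates `N` (number of previous exacerbations during follow-up) and
#'   `N_S` (number of previous severe exacerbations) are derived
#'   automatically: for episode `j`, `N = j - 1` and `N_S` counts severe
#'   episodes among `1..j-1`; for the final censored gap, `N = M` and `N_S`
#'   is the total severe count.
#' @param quad_points Gauss--Hermite points per dimension (default 5).
#' @param quad_mode `"adaptive"` (recenter/rescale at the per-subject
#'   posterior mode of the random effects) or `"fixed"`.
#' @param zi_conditional_cdf If `TRUE` (default) the fitted marginal CDF of
#'   between-gaps conditions on the susceptible class.
#' @return An object of class `rds_config`.
#' @export
rds_config <- function(covariates_B = character(),
                       covariates_W = covariates_B,
                       covariates_S = covariates_B,
                       covariates_ZI = character(),
                       family_B = "lognormal",
                       family_W = family_B,
                       include_duration = TRUE,
                       include_severity = TRUE,
                       include_zi = TRUE,
                       random_effects = c("B", "W", "S"),
                       derive_episode_covariates = FALSE,
                       quad_points = 5L,
                       quad_mode = c("adaptive", "fixed"),
                       zi_conditional_cdf = TRUE) {
  quad_mode <- match.arg(quad_mode)
  if (quad_points < 1L) stop("'quad_points' must be >= 1", call. = FALSE)
  random_effects <- match_re(random_effects)
  if (!include_duration) random_effects <- setdiff(random_effects, "W")
  if (!include_severity) random_effects <- setdiff(random_effects, "S")
  structure(list(
    covariates_B = covariates_B,
    covariates_W = if (include_duration) covariates_W else character(),
    covariates_S = if (include_severity) covariates_S else character(),
    covariates_ZI = if (include_zi) covariates_ZI else character(),
    family_B = family_B,
    family_W = family_W,
    include_duration = include_duration,
    include_severity = include_severity,
    include_zi = include_zi,
    random_effects = random_effects,
    derive_episode_covariates = derive_episode_covariates,
    quad_points = as.integer(quad_points),
    quad_mode = quad_mode,
    zi_conditional_cdf = zi_conditional_cdf
  ), class = "rds_config")
}

#' @export
print.rds_config <- function(x, ...) {
  cat("rds_config:\n")
  cat("  rate:", x$family_B, "|",
      if (length(x$covariates_B)) paste(x$covariates_B, collapse = " + ")
      else "intercept only", "\n")
  if (x$include_duration) {
    cat("  duration:", x$family_W, "|",
        if (length(x$covariates_W)) paste(x$covariates_W, collapse = " + ")
        else "intercept only", "\n")
  }
  if (x$include_severity) {
    cat("  severity: logistic |",
        if (length(x$covariates_S)) paste(x$covariates_S, collapse = " + ")
        else "intercept only", "\n")
  }
  if (x$include_zi) {
    cat("  zero-inflation: logistic |",
        if (length(x$covariates_ZI)) paste(x$covariates_ZI, collapse = " + ")
        else "intercept only", "\n")
  }
  cat("  random effects:",
      if (length(x$random_effects)) paste(x$random_effects, collapse = ", ")
      else "none", "\n")
  cat(sprintf("  quadrature: %s, %d points/dimension\n",
              x$quad_mode, x$quad_points))
  invisible(x)
}

## ---- packing of the unconstrained parameter vector ----------------------

has_free_shape <- function(family) family$family != "exponential"

#' Pack model parameters into the unconstrained vector
#'
#' The optimizer works on a single unconstrained numeric vector: submodel
#' coefficients, log shape parameters, log random-effect SDs and the
#' unconstrained correlation parameters, in that order.
#'
#' @param params An [rds_params()] object.
#' @return Named numeric vector.
#' @export
pack_params <- function(params) {
  theta <- c()
  nm <- c()
  add <- function(v, names) {
    theta <<- c(theta, v)
    nm <<- c(nm, names)
  }
  add(params$beta_B, paste0("B:", names(params$beta_B)))
  if (has_free_shape(params$family_B)) {
    add(log(params$family_B$shape), "B:log(shape)")
  }
  if (!is.null(params$beta_W)) {
    add(params$beta_W, paste0("W:", names(params$beta_W)))
    if (has_free_shape(params$family_W)) {
      add(log(params$family_W$shape), "W:log(shape)")
    }
  }
  if (!is.null(params$beta_S)) add(params$beta_S, paste0("S:", names(params$beta_S)))
  if (!is.null(params$beta_ZI)) add(params$beta_ZI, paste0("ZI:", names(params$beta_ZI)))
  if (length(params$re)) {
    add(params$re_log_sd, paste0("RE:log(sd_", params$re, ")"))
    if (length(params$re_corr_chol)) {
      pairs <- utils::combn(params$re, 2)
      add(params$re_corr_chol,
          paste0("RE:corr(", pairs[1, ], ",", pairs[2, ], ")"))
    }
  }
  stats::setNames(theta, nm)
}

#' Unpack an unconstrained vector into model parameters
#'
#' @param theta Numeric vector as produced by [pack_params()].
#' @param template An [rds_params()] object defining the layout (covariate
#'   names, families, active random effects).
#' @return An [rds_params()] object with the values of `theta`.
#' @export
unpack_params <- function(theta, template) {
  i <- 0L
  take <- function(k) {
    out <- theta[i + seq_len(k)]
    i <<- i + k
    out
  }
  p <- template
  p$beta_B[] <- take(length(p$beta_B))
  if (has_free_shape(p$family_B)) p$family_B$shape <- exp(take(1L))
  if (!is.null(p$beta_W)) {
    p$beta_W[] <- take(length(p$beta_W))
    if (has_free_shape(p$family_W)) p$family_W$shape <- exp(take(1L))
  }
  if (!is.null(p$beta_S)) p$beta_S[] <- take(length(p$beta_S))
  if (!is.null(p$beta_ZI)) p$beta_ZI[] <- take(length(p$beta_ZI))
  if (length(p$re)) {
    p$re_log_sd[] <- take(length(p$re_log_sd))
    if (length(p$re_corr_chol)) {
      p$re_corr_chol[] <- take(length(p$re_corr_chol))
    }
  }
  if (i != length(theta)) {
    stop(sprintf("parameter vector has length %d, expected %d",
                 length(theta), i), call. = FALSE)
  }
  p
}

n_free_params <- function(params) length(pack_params(params))
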