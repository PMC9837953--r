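#' One subject's exacerbation history
#'
#' A subject's follow-up is an alternating two-state process: ordered
#' exacerbation episodes (each with onset, termination, duration `W`,
#' between-gap `B` measured from the previous termination, and binary
#' severity `S`), followed by a final between-gap that is censored at the end
#' of follow-up.  The first between-gap is measured from randomization
#' (the previous termination time is taken as 0).
#'
#' @param subject_id Identifier.
#' @param episodes A data frame with one row per episode and columns
#'   `onset`, `termination`, `severity` (0/1) and optionally
#'   `within_censored` (0/1, default 0); may have zero rows.
#' @param final_gap Observed time (days) from the last termination (or 0 if
#'   no episodes) to the end of between-exacerbation observation.
#' @param final_gap_censored 1 if the final between-gap is censored (the
#'   case-study convention: always, since follow-up was extended to the
#'   termination of an ongoing episode).
#' @param baseline Named numeric vector of baseline covariates.
#' @param episode_covariates Optional data frame of covariate values with
#'   `M + 1` rows: one per episode plus one for the final censored
#'   between-gap.  Columns absent here but present in `baseline` are filled
#'   in by replication.  If `NULL`, baseline covariates are replicated.
#' @param min_gap Smallest admissible positive gap (days); gaps at or below
#'   zero are invalid since the gap laws are continuous.
#' @return An object of class `subject_history`.
#' @export
subject_history <- function(subject_id,
                            episodes = data.frame(onset = numeric(0),
                                                  termination = numeric(0),
                                                  severity = integer(0)),
                            final_gap,
                            final_gap_censored = 1L,
                            baseline = c("(none)" = 0)[0],
                            episode_covariates = NULL,
                            min_gap = 1e-8) {
  episodes <- as.data.frame(episodes)
  m <- nrow(episodes)
  if (m > 0L) {
    req <- c("onset", "termination", "severity")
    miss <- setdiff(req, names(episodes))
    if (length(miss)) {
      stop("episodes lack column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    if (is.null(episodes$within_censored)) episodes$within_censored <- 0L
    o <- order(episodes$onset)
    episodes <- episodes[o, , drop = FALSE]
    episodes$duration <- episodes$termination - episodes$onset
    prev_term <- c(0, episodes$termination[-m])
    episodes$between_gap <- episodes$onset - prev_term
    rownames(episodes) <- NULL
  } else {
    episodes <- data.frame(onset = numeric(0), termination = numeric(0),
                           severity = integer(0), within_censored = integer(0),
                           duration = numeric(0), between_gap = numeric(0))
  }
  obj <- structure(list(
    subject_id = subject_id,
    episodes = episodes,
    final_gap = as.numeric(final_gap),
    final_gap_censored = as.integer(final_gap_censored),
    baseline = baseline,
    episode_covariates = episode_covariates,
    min_gap = min_gap
  ), class = "subject_history")
  obj$follow_up <- if (m > 0L) episodes$termination[m] + obj$final_gap else obj$final_gap
  validate_subject_history(obj)
  obj
}

#' Validate a subject history
#'
#' Checks the structural invariants: episodes ordered by onset, positive
#' durations and between-gaps, binary severities, non-negative final gap,
#' and (for subjects without episodes) a censored final gap spanning the
#' whole follow-up.
#'
#' @param subject A [subject_history()] object.
#' @return The object, invisibly; errors describe the first violation.
#' @export
validate_subject_history <- function(subject) {
  ep <- subject$episodes
  m <- nrow(ep)
  id <- subject$subject_id
  fail <- function(...) {
    stop(sprintf("subject %s: %s", as.character(id), sprintf(...)),
         call. = FALSE)
  }
  if (m > 0L) {
    if (is.unsorted(ep$onset, strictly = TRUE)) fail("episodes not ordered by onset")
    if (any(ep$duration <= 0)) fail("episode duration must be positive")
    if (any(ep$between_gap < subject$min_gap)) {
      fail("between-gap below the minimum admissible gap (%g days)",
           subject$min_gap)
    }
    if (any(ep$duration < subject$min_gap)) {
      fail("within-gap below the minimum admissible gap (%g days)",
           subject$min_gap)
    }
    if (!all(ep$severity %in% c(0, 1))) fail("severity must be 0 or 1")
    if (!all(ep$within_censored %in% c(0, 1))) {
      fail("within_censored must be 0 or 1")
    }
  }
  if (!is.finite(subject$final_gap) || subject$final_gap < 0) {
    fail("final gap must be non-negative")
  }
  if (!subject$final_gap_censored %in% c(0L, 1L)) {
    fail("final_gap_censored must be 0 or 1")
  }
  if (m == 0L) {
    if (subject$final_gap_censored != 1L) {
      fail("a subject without episodes must have a censored final gap")
    }
    if (abs(subject$final_gap - subject$follow_up) > 1e-9) {
      fail("for zero-episode subjects the final gap must span the follow-up")
    }
  }
  if (!is.null(subject$episode_covariates) &&
      nrow(subject$episode_covariates) != m + 1L) {
    fail("episode_covariates must have M + 1 = %d rows (episodes plus final gap)",
         m + 1L)
  }
  invisible(subject)
}

#' @export
print.subject_history <- function(x, ...) {
  cat(sprintf("subject %s: %d episode(s), follow-up %.1f days, final gap %.1f%s\n",
              as.character(x$subject_id), nrow(x$episodes), x$follow_up,
              x$final_gap,
              if (x$final_gap_censored) " (censored)" else ""))
  invisible(x)
}

#' Number of observed episodes
#' @param subject A [subject_history()] object.
#' @return Integer count `M`.
#' @export
n_episodes <- function(subject) nrow(subject$episodes)

#' A dataset of subject histories
#'
#' @param subjects List of [subject_history()] objects.
#' @return Object of class `rds_data` (a validated list).
#' @export
rds_data <- function(subjects) {
  if (!length(subjects)) stop("empty dataset", call. = FALSE)
  lapply(subjects, validate_subject_history)
  ids <- vapply(subjects, function(s) as.character(s$subject_id), "")
  if (anyDuplicated(ids)) {
    stop("duplicated subject ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  structure(subjects, class = "rds_data")
}

#' @export
print.rds_data <- function(x, ...) {
  m <- vapply(x, n_episodes, 0L)
  cat(sprintf("rds_data: %d subjects, %d episodes (%.1f%% with none)\n",
              length(x), sum(m), 100 * mean(m == 0)))
  invisible(x)
}

#' @export
`[.rds_data` <- function(x, i) {
  structure(unclass(x)[i], class = "rds_data")
}

#' Standardize covariates across a dataset
#'
#' Optional, opt-in centring/scaling of covariate columns: each named column
#' is replaced by `(x - center) / scale` in both the baseline vector and the
#' episode covariate table of every subject.  Nothing in the fitting
#' pipeline assumes standardized covariates; this utility exists for users
#' who want coefficients per standard deviation instead of per raw unit.
#'
#' @param dataset An [rds_data()] object.
#' @param columns Covariate columns to standardize; default: all baseline
#'   covariates.
#' @param center,scale Optional named numeric vectors; defaults are the
#'   across-subject mean and standard deviation of each baseline covariate.
#' @return The transformed [rds_data()] with attribute `standardization`
#'   (a list with `center` and `scale`) for back-transforming estimates.
#' @export
standardize_covariates <- function(dataset, columns = NULL,
                                   center = NULL, scale = NULL) {
  base <- do.call(rbind, lapply(dataset, function(s) s$baseline))
  if (is.null(columns)) columns <- colnames(base)
  if (!length(columns)) return(dataset)
  if (is.null(center)) center <- colMeans(base[, columns, drop = FALSE])
  if (is.null(scale)) {
    scale <- apply(base[, columns, drop = FALSE], 2, stats::sd)
  }
  scale[scale == 0 | !is.finite(scale)] <- 1
  out <- lapply(dataset, function(s) {
    for (v in columns) {
      s$baseline[[v]] <- (s$baseline[[v]] - center[[v]]) / scale[[v]]
      if (!is.null(s$episode_covariates) && v %in% names(s$episode_covariates)) {
        s$episode_covariates[[v]] <-
          (s$episode_covariates[[v]] - center[[v]]) / scale[[v]]
      }
    }
    s
  })
  out <- rds_data(out)
  attr(out, "standardization") <- list(center = center, scale = scale)
  out
}

## covariate table with M+1 rows (episodes + final gap), merging baseline
## values and any episode-specific columns; optionally auto-deriving the
## episode counters N (previous exacerbations) and N_S (previous severe).
covariate_table <- function(subject, derive_counters = FALSE) {
  m <- n_episodes(subject)
  tab <- subject$episode_covariates
  if (is.null(tab)) {
    tab <- as.data.frame(as.list(subject$baseline))[rep(1L, m + 1L), ,
                                                    drop = FALSE]
    if (!length(subject$baseline)) tab <- data.frame(row.names = seq_len(m + 1L))
  } else {
    tab <- as.data.frame(tab)
    for (nm in setdiff(names(subject$baseline), names(tab))) {
      tab[[nm]] <- subject$baseline[[nm]]
    }
  }
  if (derive_counters) {
    sev <- subject$episodes$severity
    tab$N <- 0:m
    tab$N_S <- c(0, cumsum(sev))
  }
  rownames(tab) <- NULL
  tab
}

design_matrix <- function(tab, covariates, rows, submodel) {
  miss <- setdiff(covariates, names(tab))
  if (length(miss)) {
    stop(sprintf("%s submodel: covariate column(s) not found: %s",
                 submodel, paste(miss, collapse = ", ")), call. = FALSE)
  }
  x <- cbind(`(Intercept)` = rep(1, length(rows)),
             as.matrix(tab[rows, covariates, drop = FALSE]))
  storage.mode(x) <- "double"
  x
}

## All design matrices of one subject under a config.
## X_B has M+1 rows (episodes then the final censored gap); X_W and X_S have
## M rows; x_zi is the baseline covariate row of the zero-inflation model.
build_design <- function(subject, config) {
  m <- n_episodes(subject)
  tab <- covariate_table(subject, config$derive_episode_covariates)
  out <- list(
    X_B = design_matrix(tab, config$covariates_B, seq_len(m + 1L), "rate")
  )
  if (config$include_duration) {
    out$X_W <- design_matrix(tab, config$covariates_W, seq_len(m), "duration")
  }
  if (config$include_severity) {
    out$X_S <- design_matrix(tab, config$covariates_S, seq_len(m), "severity")
  }
  if (config$include_zi) {
    b <- subject$baseline
    miss <- setdiff(config$covariates_ZI, names(b))
    if (length(miss)) {
      stop("zero-inflation submodel: baseline covariate(s) not found: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    out$x_zi <- c(`(Intercept)` = 1,
                  stats::setNames(as.numeric(b[config$covariates_ZI]),
                                  config$covariates_ZI))
  }
  out
}

## Template rds_params consistent with a dataset + config (zero coefficients,
## unit shapes, given RE start); used for packing layout and initial values.
params_template <- function(dataset, config) {
  d1 <- build_design(dataset[[1L]], config)
  zero <- function(X) stats::setNames(numeric(ncol(X)), colnames(X))
  rds_params(
    beta_B = zero(d1$X_B),
    beta_W = if (config$include_duration) zero(d1$X_W),
    beta_S = if (config$include_severity) zero(d1$X_S),
    beta_ZI = if (config$include_zi) stats::setNames(numeric(length(d1$x_zi)),
                                                     names(d1$x_zi)),
    family_B = baseline_family(config$family_B),
    family_W = if (config$include_duration) baseline_family(config$family_W),
    re = config$random_effects,
    re_log_sd = rep(0, length(config$random_effects)),
    re_corr_chol = rep(0, choose(length(config$random_effects), 2))
  )
}
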