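## Long-format CSV input/output.
##
## One row per episode plus exactly one `final_gap` row per subject, so the
## censoring of the last between-exacerbation gap is explicit and a
## within-censoring extension needs no schema change.  Reserved columns:
## subject_id, record_type, episode_index, between_gap, within_gap,
## severity, censored; every other column is a covariate.

reserved_columns <- c("subject_id", "record_type", "episode_index",
                      "between_gap", "within_gap", "severity", "censored")

time_scale <- function(unit) {
  switch(unit, days = 1, weeks = 7, years = 365.25,
         stop("unknown time unit: ", unit, call. = FALSE))
}

#' Write a dataset as long-format CSV
#'
#' @param dataset An [rds_data()] object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  rows <- lapply(dataset, function(s) {
    m <- n_episodes(s)
    tab <- covariate_table(s, derive_counters = FALSE)
    ep <- s$episodes
    base <- data.frame(
      subject_id = as.character(s$subject_id),
      record_type = c(rep("episode", m), "final_gap"),
      episode_index = c(seq_len(m), NA_integer_),
      between_gap = c(ep$between_gap, s$final_gap),
      within_gap = c(ep$duration, NA_real_),
      severity = c(ep$severity, NA_integer_),
      censored = c(ep$within_censored, s$final_gap_censored)
    )
    if (ncol(tab)) base <- cbind(base, tab)
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format CSV dataset
#'
#' Validates the file row by row (positive gaps, binary severities, exactly
#' one `final_gap` record per subject, contiguous episode indices) and
#' assembles [subject_history()] objects.  Subjects with missing values in
#' the covariate columns are dropped with a logged count (complete-case
#' handling); structural violations are hard errors naming the offending
#' data rows.
#'
#' @param path CSV path (header required).
#' @param config Optional [rds_config()]; when given, only the covariates the
#'   config uses are checked for missingness.
#' @param time_unit `"days"` (default), `"weeks"` or `"years"`; gap columns
#'   are rescaled to days on load.
#' @param min_gap Smallest admissible positive gap in days.
#' @return An [rds_data()] object.
#' @export
read_dataset <- function(path, config = NULL, time_unit = "days",
                         min_gap = 1e-8) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "record_type", "between_gap", "censored")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$.row <- seq_len(nrow(df)) + 1L # data row number in the file (after header)
  scale <- time_scale(time_unit)
  for (v in intersect(c("between_gap", "within_gap"), names(df))) {
    df[[v]] <- df[[v]] * scale
  }
  bad_type <- !df$record_type %in% c("episode", "final_gap")
  if (any(bad_type)) {
    stop("invalid record_type at row(s): ",
         paste(df$.row[bad_type], collapse = ", "), call. = FALSE)
  }
  ep <- df[df$record_type == "episode", , drop = FALSE]
  if (nrow(ep)) {
    for (v in c("episode_index", "within_gap", "severity")) {
      if (is.null(df[[v]])) {
        stop("missing required column for episode records: ", v, call. = FALSE)
      }
    }
    bad <- !is.finite(ep$between_gap) | ep$between_gap < min_gap
    if (any(bad)) {
      stop("non-positive between_gap at row(s): ",
           paste(ep$.row[bad], collapse = ", "), call. = FALSE)
    }
    bad <- !is.finite(ep$within_gap) | ep$within_gap < min_gap
    if (any(bad)) {
      stop("non-positive within_gap at row(s): ",
           paste(ep$.row[bad], collapse = ", "), call. = FALSE)
    }
    bad <- !ep$severity %in% c(0, 1)
    if (any(bad)) {
      stop("non-binary severity at row(s): ",
           paste(ep$.row[bad], collapse = ", "), call. = FALSE)
    }
  }
  fg <- df[df$record_type == "final_gap", , drop = FALSE]
  dup <- names(which(table(fg$subject_id) > 1L))
  if (length(dup)) {
    stop("duplicate final_gap record for subject(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  no_fg <- setdiff(unique(df$subject_id), fg$subject_id)
  if (length(no_fg)) {
    stop("no final_gap record for subject(s): ",
         paste(no_fg, collapse = ", "), call. = FALSE)
  }
  bad <- fg$censored != 1
  if (any(bad)) {
    stop("final_gap records must be censored (censored = 1); row(s): ",
         paste(fg$.row[bad], collapse = ", "), call. = FALSE)
  }

  cov_cols <- setdiff(names(df), c(reserved_columns, ".row"))
  check_cols <- cov_cols
  if (!is.null(config)) {
    check_cols <- intersect(cov_cols,
                            unique(c(config$covariates_B, config$covariates_W,
                                     config$covariates_S, config$covariates_ZI)))
  }

  subjects <- list()
  dropped <- 0L
  for (id in unique(df$subject_id)) {
    rows <- df[df$subject_id == id, , drop = FALSE]
    if (length(check_cols) &&
        anyNA(rows[, check_cols, drop = FALSE])) {
      dropped <- dropped + 1L
      next
    }
    e <- rows[rows$record_type == "episode", , drop = FALSE]
    f <- rows[rows$record_type == "final_gap", , drop = FALSE]
    m <- nrow(e)
    if (m) {
      e <- e[order(e$episode_index), , drop = FALSE]
      if (!identical(as.integer(e$episode_index), seq_len(m))) {
        stop("episode indices not contiguous from 1 for subject ", id,
             call. = FALSE)
      }
      onset <- cumsum(e$between_gap + c(0, e$within_gap[-m]))
      episodes <- data.frame(onset = onset,
                             termination = onset + e$within_gap,
                             severity = as.integer(e$severity),
                             within_censored = as.integer(e$censored))
    } else {
      episodes <- data.frame(onset = numeric(0), termination = numeric(0),
                             severity = integer(0))
    }
    covtab <- if (length(cov_cols)) {
      rbind(e[, cov_cols, drop = FALSE], f[, cov_cols, drop = FALSE])
    } else NULL
    baseline <- if (length(cov_cols)) {
      unlist(rows[1L, cov_cols, drop = FALSE])
    } else c(x = 0)[0]
    subjects[[length(subjects) + 1L]] <- subject_history(
      subject_id = id,
      episodes = episodes,
      final_gap = f$between_gap,
      final_gap_censored = 1L,
      baseline = baseline,
      episode_covariates = covtab,
      min_gap = min_gap
    )
  }
  if (dropped > 0L) {
    message(dropped, " subject(s) dropped because of missing covariate values")
  }
  if (!length(subjects)) stop("no subjects left after filtering", call. = FALSE)
  rds_data(subjects)
}

#' Write fit results
#'
#' Writes `estimates.csv` (exponentiated coefficient table),
#' `random_effects.csv` (shape/SD/correlation table), `fit.json` (log
#' likelihood, AIC, convergence, configuration echo) and `run.log` (plain
#' text summary including the RNG seed if supplied).
#'
#' @param fit An [rds_fit()] object.
#' @param dir Output directory (created if needed).
#' @param seed Optional RNG seed to echo into the log.
#' @return `dir`, invisibly.
#' @export
write_results <- function(fit, dir, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(fit$report, file.path(dir, "estimates.csv"),
                   row.names = FALSE)
  if (!is.null(fit$re_report)) {
    utils::write.csv(fit$re_report, file.path(dir, "random_effects.csv"),
                     row.names = FALSE)
  }
  cfg <- fit$config
  jsonlite::write_json(list(
    loglik = fit$loglik,
    aic = fit$aic,
    n_free_params = fit$n_free_params,
    n_subjects = fit$n_subjects,
    n_episodes = fit$n_episodes,
    convergence = fit$convergence,
    config = unclass(cfg),
    seed = seed
  ), file.path(dir, "fit.json"), auto_unbox = TRUE, digits = NA, null = "null")
  log_lines <- c(
    sprintf("rdsjoint %s fit run at %s",
            as.character(utils::packageVersion("rdsjoint")),
            format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("R %s.%s", R.version$major, R.version$minor),
    sprintf("seed: %s", if (is.null(seed)) "(not set)" else seed),
    sprintf("families: %s / %s", cfg$family_B,
            if (cfg$include_duration) cfg$family_W else "-"),
    sprintf("quadrature: %s, %d points/dim", cfg$quad_mode, cfg$quad_points),
    sprintf("logLik %.6f  AIC %.6f  converged %s",
            fit$loglik, fit$aic, fit$convergence$converged)
  )
  writeLines(log_lines, file.path(dir, "run.log"))
  invisible(dir)
}

#' Write per-subject predictions
#'
#' @param predictions Output of [predict_subjects()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  utils::write.csv(predictions, path, row.names = FALSE)
  invisible(path)
}

#' Read a fit summary written by [write_results()]
#'
#' @param dir Directory given to [write_results()].
#' @return A list with the parsed `fit.json` plus the two CSV tables.
#' @export
read_results <- function(dir) {
  out <- jsonlite::read_json(file.path(dir, "fit.json"), simplifyVector = TRUE)
  out$estimates <- utils::read.csv(file.path(dir, "estimates.csv"))
  re_path <- file.path(dir, "random_effects.csv")
  if (file.exists(re_path)) out$random_effects <- utils::read.csv(re_path)
  out
}
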