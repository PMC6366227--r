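#' Configuration for an end-to-end pipeline run
#'
#' @param mode `"synthetic"` (simulate a cohort) or `"real"` (ingest the two
#'   tables from `trial_path` / `participant_path`).
#' @param seed Master seed; recorded in every output's provenance header.
#' @param cohort A [cohort_config] (synthetic mode). Its seed is overridden
#'   by `seed`.
#' @param trial_path,participant_path Input tables (real mode).
#' @param fit_bounds,fit_starts Passed to [fit_cohort].
#' @param exclude_iqr Apply the two 1.5 x IQR screens (overall alignment
#'   score, then unpredictability z-score) before fitting/inference.
#' @param drop_clipped Drop trials whose feedback was clipped at the scale
#'   edge rather than classifying them by nominal condition.
#' @param meta_path Optional study-effects table (`study`, `beta`, `se`) to
#'   pool with [meta_fixed] at the end of the run.
#' @return List of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "real"),
                       seed = 1L,
                       cohort = cohort_config(seed = seed),
                       trial_path = NULL,
                       participant_path = NULL,
                       fit_bounds = default_fit_bounds(),
                       fit_starts = c(5L, 5L),
                       exclude_iqr = TRUE,
                       drop_clipped = FALSE,
                       meta_path = NULL) {
  mode <- match.arg(mode)
  if (mode == "real") {
    for (p in c(trial_path, participant_path)) {
      if (is.null(p) || !file.exists(p)) {
        stop("real mode: input table not found: ",
             if (is.null(p)) "(unset path)" else p, call. = FALSE)
      }
    }
  }
  cohort$seed <- as.integer(seed)
  structure(list(mode = mode, seed = as.integer(seed), cohort = cohort,
                 trial_path = trial_path, participant_path = participant_path,
                 fit_bounds = fit_bounds, fit_starts = fit_starts,
                 exclude_iqr = exclude_iqr, drop_clipped = drop_clipped,
                 meta_path = meta_path),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys map to [run_config] arguments; a `cohort:` mapping is
#' passed on to [cohort_config].
#'
#' @param path YAML file path.
#' @return A [run_config].
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  cohort_args <- raw$cohort
  raw$cohort <- NULL
  if (!is.null(cohort_args$initial_rating_pmf)) {
    cohort_args$initial_rating_pmf <- as.numeric(cohort_args$initial_rating_pmf)
  }
  cohort <- do.call(cohort_config, cohort_args %||% list())
  do.call(run_config, c(raw, list(cohort = cohort)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Simulate (or ingest) -> score questionnaires and alignment -> IQR
#' exclusion screens -> choice-model fits -> model-predicted alignment ->
#' participant-level regressions with slope-outlier diagnostics -> optional
#' meta-analytic pooling. Writes every intermediate table (with provenance
#' headers) plus a stage-by-stage log with participant counts to `out_dir`,
#' and returns the bundle invisibly.
#'
#' @param cfg A [run_config].
#' @param out_dir Output directory (created if needed); `NULL` skips writing.
#' @return List of class `socialign_run`: `trials`, `participants` (scored,
#'   with exclusion flags), `fits`, `predictions`, `inference` (list of
#'   [env_regression] / [slope_outlier_filter] results), `meta` (or `NULL`),
#'   `log` (character vector), `config`.
#' @export
#' @examples
#' \donttest{
#' cfg <- run_config("synthetic", seed = 1,
#'                   cohort = cohort_config(n_participants = 12))
#' run <- run_pipeline(cfg, out_dir = NULL)
#' run$log
#' }
run_pipeline <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  log <- character()
  say <- function(...) {
    line <- sprintf(...)
    log <<- c(log, line)
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  # -- ingest / simulate ------------------------------------------------
  if (cfg$mode == "synthetic") {
    coh <- stage("simulate", simulate_cohort(cfg$cohort))
    trials <- coh$trials
    participants <- coh$participants
    say("simulate: %d participants, %d trials (seed %d)",
        nrow(participants), nrow(trials), cfg$seed)
  } else {
    trials <- stage("ingest", read_trial_table(cfg$trial_path))
    participants <- stage("ingest", read_participant_table(cfg$participant_path))
    say("ingest: %d participants, %d trials", nrow(participants), nrow(trials))
  }
  if (cfg$drop_clipped && "clipped" %in% names(trials)) {
    n0 <- nrow(trials)
    trials <- trials[!trials$clipped, , drop = FALSE]
    say("clipped-trial drop: %d trials removed", n0 - nrow(trials))
  }

  # -- score ------------------------------------------------------------
  participants <- stage("score", score_cohort(participants))
  behav <- stage("score", summarise_alignment(trials))
  participants <- merge(participants, behav, by = "participant_id",
                        sort = TRUE)
  say("score: alignment and environment composites for %d participants",
      nrow(participants))
  alpha_u <- tryCatch(
    cronbach_alpha(participants[, c("u1", "u2", "u3")]), error = function(e) NA)
  alpha_h <- tryCatch(
    cronbach_alpha(8 - participants[, c("h1", "h2", "h3")]),
    error = function(e) NA)
  say("score: Cronbach alpha unpredictability = %.2f, harshness = %.2f",
      alpha_u, alpha_h)

  # -- exclude ----------------------------------------------------------
  participants$excluded_alignment <- FALSE
  participants$excluded_unpredictability <- FALSE
  if (cfg$exclude_iqr && nrow(participants) >= 4) {
    ex1 <- stage("exclude", iqr_exclude(participants$alignment_overall))
    ex2 <- stage("exclude", iqr_exclude(participants$unpredictability_z))
    participants$excluded_alignment <- as.logical(ex1)
    participants$excluded_unpredictability <- as.logical(ex2) & !ex1
    say("exclude: %d alignment outlier(s), %d unpredictability outlier(s) (1.5 x IQR)",
        sum(ex1), sum(participants$excluded_unpredictability))
  }
  participants$excluded <- participants$excluded_alignment |
    participants$excluded_unpredictability
  retained <- participants$participant_id[!participants$excluded]
  say("exclude: %d of %d participants retained (loss %.0f%%)",
      length(retained), nrow(participants),
      100 * (1 - length(retained) / nrow(participants)))
  kept_trials <- trials[trials$participant_id %in% retained, , drop = FALSE]

  # -- fit --------------------------------------------------------------
  fits <- stage("fit", fit_cohort(kept_trials, bounds = cfg$fit_bounds,
                                  n_starts = cfg$fit_starts))
  say("fit: choice model fitted to %d participants (%d converged)",
      nrow(fits), sum(fits$converged))

  # -- predict ----------------------------------------------------------
  predictions <- stage("predict", do.call(rbind, lapply(
    seq_len(nrow(fits)), function(i) {
      id <- fits$participant_id[i]
      pa <- predict_alignment(fits[i, ],
                              kept_trials[kept_trials$participant_id == id, ,
                                          drop = FALSE])
      data.frame(participant_id = id, t(pa$alignment),
                 predicted_overall = pa$overall)
    })))
  say("predict: model-predicted alignment for %d participants",
      nrow(predictions))

  # -- infer ------------------------------------------------------------
  analysed <- merge(participants[!participants$excluded, , drop = FALSE],
                    fits, by = "participant_id")
  inference <- stage("infer", {
    scores <- c("unpredictability_z", "harshness_z", "adversity")
    res <- list()
    for (sc in scores) {
      res[[paste0("alignment_on_", sc)]] <-
        env_regression(analysed, "alignment_overall", sc)
      res[[paste0("delta_on_", sc)]] <- env_regression(analysed, "delta", sc)
    }
    res$slope_outliers <- slope_outlier_filter(
      analysed, "alignment_overall",
      c("unpredictability_z", "harshness_z"))
    res
  })
  say("infer: %d slope outlier(s) by Cook's D > 4/N (union over regressions)",
      inference$slope_outliers$n_removed)

  # -- meta (optional) --------------------------------------------------
  meta <- NULL
  if (!is.null(cfg$meta_path)) {
    eff <- stage("meta", read_study_effects(cfg$meta_path))
    meta <- stage("meta", meta_fixed(eff$beta, eff$se, eff$study))
    say("meta: pooled beta = %.4f +/- %.4f over %d studies",
        meta$beta_pooled, meta$se_pooled, nrow(eff))
  }

  run <- structure(
    list(trials = trials, participants = participants, fits = fits,
         predictions = predictions, inference = inference, meta = meta,
         log = log, config = cfg),
    class = "socialign_run")

  if (!is.null(out_dir)) write_run(run, out_dir)
  invisible(run)
}

#' Write a pipeline run's artifact bundle
#'
#' Six delimited tables (trials, participants, truth sidecar, fits,
#' predictions, inference coefficients) plus the run log, each with a
#' provenance header.
#'
#' @param run A `socialign_run`.
#' @param out_dir Directory to write into (created recursively).
#' @return Character vector of paths written, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- run$config
  hash <- .config_hash(cfg)
  w <- function(d, name) {
    write_table_prov(d, file.path(out_dir, name), seed = cfg$seed,
                     config_hash = hash)
  }
  truth_cols <- intersect(c("participant_id", "delta_true", "sigma_true",
                            "adversity_true"), names(run$participants))
  public <- setdiff(names(run$participants),
                    c("delta_true", "sigma_true", "adversity_true"))
  coefs <- do.call(rbind, lapply(
    names(run$inference)[names(run$inference) != "slope_outliers"],
    function(nm) {
      r <- run$inference[[nm]]
      est <- r$coefficients[r$predictor, ]
      data.frame(analysis = nm, outcome = r$outcome, predictor = r$predictor,
                 beta = est["estimate"], se = est["se"], t = est["t"],
                 p = est["p"], n = r$n, row.names = NULL)
    }))
  paths <- c(
    w(run$trials, "trials.tsv"),
    w(run$participants[, public, drop = FALSE], "participants.tsv"),
    if (length(truth_cols) > 1)
      w(run$participants[, truth_cols, drop = FALSE], "truth_synthetic.tsv"),
    w(run$fits, "fits.tsv"),
    w(run$predictions, "predictions.tsv"),
    w(coefs, "inference.tsv")
  )
  log_path <- file.path(out_dir, "run_log.txt")
  writeLines(c(sprintf("# socialign run | seed=%s | config=%s",
                       cfg$seed, hash), run$log), log_path)
  invisible(c(paths, log_path))
}
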