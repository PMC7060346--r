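## End-to-end orchestration: simulate (or read) a cohort, compute HRV,
## behaviour summaries with the exclusion rule, interoception profiles,
## and the statistics tables. Every number in every output table is
## reproducible by calling the owning module's function directly on the
## same inputs; the pipeline adds no computation of its own.

fail_row <- function(file, row, msg) {
  stop_invalid(file, ", row ", row, ": ", msg)
}

#' Read and validate task-trial data
#'
#' @param path CSV with columns `subject_id`, `trial_index`, `trial_type`,
#'   `intended_phase`, `pressed`, `rt_ms` (blank when not pressed).
#' @return Validated data frame.
#' @export
read_task_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "trial_index", "trial_type", "intended_phase",
            "pressed", "rt_ms")
  if (!all(need %in% names(df)))
    stop_invalid(path, ": missing columns ",
                 paste(setdiff(need, names(df)), collapse = ", "))
  bad <- which(!df$trial_type %in% c("go", "nogo", "choose"))
  if (length(bad)) fail_row(path, bad[1], "unknown trial_type")
  bad <- which(!df$intended_phase %in% c("systole", "diastole"))
  if (length(bad)) fail_row(path, bad[1], "unknown intended_phase")
  bad <- which(!df$pressed %in% c(0L, 1L))
  if (length(bad)) fail_row(path, bad[1], "pressed must be 0 or 1")
  bad <- which(df$pressed == 1 & is.na(df$rt_ms))
  if (length(bad)) fail_row(path, bad[1], "pressed trial with blank rt_ms")
  bad <- which(df$pressed == 0 & !is.na(df$rt_ms))
  if (length(bad)) fail_row(path, bad[1], "rt_ms given on unpressed trial")
  df
}

#' Read and validate heartbeat-counting data
#'
#' @param path CSV with columns `subject_id`, `trial_index`, `duration_s`,
#'   `nbeats_real`, `nbeats_reported`, `confidence`.
#' @return Validated data frame.
#' @export
read_tracking_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "trial_index", "duration_s", "nbeats_real",
            "nbeats_reported", "confidence")
  if (!all(need %in% names(df)))
    stop_invalid(path, ": missing columns ",
                 paste(setdiff(need, names(df)), collapse = ", "))
  bad <- which(df$nbeats_real < 1)
  if (length(bad)) fail_row(path, bad[1], "nbeats_real must be >= 1")
  bad <- which(df$nbeats_reported < 0)
  if (length(bad)) fail_row(path, bad[1], "nbeats_reported must be >= 0")
  bad <- which(df$confidence < 0 | df$confidence > 10)
  if (length(bad)) fail_row(path, bad[1], "confidence must lie in [0, 10]")
  df
}

#' Read and validate questionnaire scores
#'
#' @param path CSV with a `subject_id` column and numeric scale columns
#'   (including `bpq_mean` on the 1-5 scale).
#' @return Validated data frame.
#' @export
read_questionnaires <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(df))
    stop_invalid(path, ": missing subject_id column")
  if ("bpq_mean" %in% names(df)) {
    bad <- which(!is.na(df$bpq_mean) & (df$bpq_mean < 1 | df$bpq_mean > 5))
    if (length(bad)) fail_row(path, bad[1], "bpq_mean must lie in [1, 5]")
  }
  df
}

#' Read an R-peak time file
#'
#' @param path Plain-text file, one R-peak time (ms) per line, ascending.
#' @return Numeric vector of peak times.
#' @export
read_rr_file <- function(path) {
  x <- as.numeric(readLines(path))
  if (any(is.na(x))) stop_invalid(path, ": non-numeric R-peak time")
  if (any(diff(x) <= 0)) stop_invalid(path, ": times must be ascending")
  x
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort (or reads one from `input_dir`), computes per-subject
#' HRV, behaviour summaries, and interoception profiles, applies the
#' NoGo-error exclusion rule before analysis, and produces the statistics
#' tables: systole-vs-diastole paired comparisons of the four behaviour
#' indices (Wilcoxon alongside the t-test for NoGo errors), the
#' interoception-behaviour and impulsivity-behaviour correlation matrices,
#' and the HRV regressions (RMSSD + bpm on each behaviour index). When
#' `out_dir` is given, every table is written as CSV together with a
#' `manifest.json` (config echo, seed, file checksums; no timestamps, so
#' repeated runs are byte-identical).
#'
#' @param config A [gen_config()] (used when simulating; its prior
#'   defaults also seed the Bayesian tests).
#' @param out_dir Optional output directory.
#' @param input_dir Optional directory of existing input files (the
#'   schemas written by [gen_dataset()]); when given, simulation is
#'   skipped and the files are read and validated instead.
#' @param priors A [prior_spec()].
#' @return List of tables: `behavior`, `exclusions`, `interoception`,
#'   `hrv`, `table2`, `ttests`, `corr_interoception`, `corr_impulsivity`,
#'   `regressions`, plus `cohort` (the input bundle).
#' @export
run_pipeline <- function(config = gen_config(), out_dir = NULL,
                         input_dir = NULL, priors = prior_spec()) {
  if (is.null(input_dir)) {
    cohort <- gen_cohort(config)
  } else {
    rr_files <- list.files(input_dir, pattern = "^rr_.*\\.txt$",
                           full.names = TRUE)
    rr <- lapply(rr_files, read_rr_file)
    names(rr) <- sub("^rr_(.*)\\.txt$", "\\1", basename(rr_files))
    cohort <- list(
      task_trials = read_task_trials(file.path(input_dir, "task_trials.csv")),
      tracking_trials = read_tracking_trials(file.path(input_dir,
                                                       "tracking_trials.csv")),
      questionnaires = read_questionnaires(file.path(input_dir,
                                                     "questionnaires.csv")),
      rr = rr, config = config)
  }

  behav <- behavior_summaries(cohort$task_trials)
  exclusions <- behav[behav$excluded, "subject_id", drop = FALSE]
  keep <- behav$subject_id[!behav$excluded]

  intero <- interoception_profiles(
    cohort$tracking_trials[cohort$tracking_trials$subject_id %in% keep, ],
    cohort$questionnaires)
  hrv <- hrv_table(cohort$rr[names(cohort$rr) %in% keep], window_s = 150)
  ba <- behav[!behav$excluded, ]

  ## systole vs diastole paired comparisons
  tt <- rbind(
    cbind(measure = "go_rt", paired_t(ba$go_rt_systole, ba$go_rt_diastole,
                                      priors$t_scale)),
    cbind(measure = "nogo_err", paired_t(ba$nogo_err_systole,
                                         ba$nogo_err_diastole,
                                         priors$t_scale)),
    cbind(measure = "choose_go", paired_t(ba$choose_go_systole,
                                          ba$choose_go_diastole,
                                          priors$t_scale)),
    cbind(measure = "choose_go_rt", paired_t(ba$choose_go_rt_systole,
                                             ba$choose_go_rt_diastole,
                                             priors$t_scale)))
  wil <- wilcoxon_signed_rank(ba$nogo_err_systole, ba$nogo_err_diastole)
  tt_w <- cbind(measure = "nogo_err_wilcoxon",
                wil[, setdiff(names(wil), "z")])
  ttests <- rbind(tt, tt_w)

  merged <- Reduce(function(a, b) merge(a, b, by = "subject_id"),
                   list(ba, intero, cohort$questionnaires))
  merged <- merge(merged, hrv, by = "subject_id")
  behaviour_vars <- c("go_rt_mean", "nogo_err_mean", "choose_go_mean",
                      "choose_go_rt_mean")
  intero_vars <- c("std_accuracy", "alt_accuracy", "insight", "awareness",
                   "confidence_mean", "sensibility", "tipe")
  imp_vars <- c("bis_attention", "bis_motor", "bis_planning", "bis_total",
                "caars_adhd", "upps_neg_urgency", "upps_premeditation",
                "upps_perseverance", "upps_sensation", "upps_pos_urgency")
  corr_intero <- correlation_matrix(merged, intero_vars, behaviour_vars,
                                    priors$corr_width)
  corr_imp <- correlation_matrix(merged, imp_vars, behaviour_vars,
                                 priors$corr_width)
  regressions <- do.call(rbind, lapply(behaviour_vars, function(v)
    cbind(outcome = v, ols_enter(merged[[v]], merged[, c("rmssd", "bpm")],
                                 priors$reg_scale))))

  tables <- list(behavior = behav, exclusions = exclusions,
                 interoception = intero, hrv = hrv,
                 table2 = cohort_table(merged[, c(behaviour_vars,
                                                  intero_vars, imp_vars,
                                                  "rmssd", "bpm")]),
                 ttests = ttests, corr_interoception = corr_intero,
                 corr_impulsivity = corr_imp, regressions = regressions)

  if (!is.null(out_dir)) write_results(tables, out_dir, config)
  c(tables, list(cohort = cohort))
}

#' Write pipeline result tables to disk
#'
#' @param tables Named list of data frames (as returned by
#'   [run_pipeline()]).
#' @param out_dir Output directory (created if absent).
#' @param config Config echoed into the manifest.
#' @return Invisibly, the manifest list.
#' @export
write_results <- function(tables, out_dir, config = NULL) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop_invalid("cannot create output directory: ", out_dir)
  tables <- Filter(is.data.frame, tables)
  paths <- vapply(names(tables), function(nm) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE, na = "",
                     fileEncoding = "UTF-8")
    p
  }, character(1))
  manifest <- list(
    seed = if (!is.null(config)) config$seed else NULL,
    config = if (!is.null(config))
      config[setdiff(names(config), "trial_mix")] else NULL,
    files = as.list(stats::setNames(unname(tools::md5sum(paths)),
                                    basename(paths))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
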