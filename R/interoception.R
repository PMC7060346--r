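## Heartbeat-tracking (counting) task scoring: the seven interoceptive
## indices. A "trials" argument is a data frame with one row per counting
## trial and columns nbeats_real, nbeats_reported, confidence (0-10);
## six trials of 25-50 s is the canonical design, but any >= 1 works.

check_trials <- function(trials) {
  need <- c("nbeats_real", "nbeats_reported", "confidence")
  if (!is.data.frame(trials) || !all(need %in% names(trials)))
    stop_invalid("trials must have columns ", paste(need, collapse = ", "))
  if (nrow(trials) < 1L) stop_invalid("need at least one trial")
  if (any(trials$nbeats_real < 1)) stop_invalid("nbeats_real must be >= 1")
  if (any(trials$nbeats_reported < 0)) stop_invalid("nbeats_reported must be >= 0")
  if (any(trials$confidence < 0 | trials$confidence > 10))
    stop_invalid("confidence must lie in [0, 10]")
  trials
}

trial_std_accuracy <- function(real, reported) {
  1 - abs(real - reported) / real
}

trial_alt_accuracy <- function(real, reported) {
  if (any(real + reported == 0)) stop_invalid("real + reported must be positive")
  1 - abs(real - reported) / ((real + reported) / 2)
}

#' 'Standard' heartbeat-tracking accuracy
#'
#' Per-trial `1 - |real - reported| / real`, averaged over trials. At most 1
#' (perfect counting); negative exactly when a trial's report exceeds twice
#' the real count, which is why the index is reserved for subjects who are
#' not substantial over-estimators (see [flag_overestimator()]).
#'
#' @param trials Data frame of counting trials (see section above).
#' @return Mean standard accuracy.
#' @export
std_accuracy <- function(trials) {
  trials <- check_trials(trials)
  mean(trial_std_accuracy(trials$nbeats_real, trials$nbeats_reported))
}

#' 'Alternative' heartbeat-tracking accuracy
#'
#' Per-trial `1 - |real - reported| / ((real + reported)/2)`, averaged.
#' Bounded in \[-1, 1\] for any report, so it remains valid for substantial
#' over-estimators.
#'
#' @inheritParams std_accuracy
#' @return Mean alternative accuracy.
#' @export
alt_accuracy <- function(trials) {
  trials <- check_trials(trials)
  mean(trial_alt_accuracy(trials$nbeats_real, trials$nbeats_reported))
}

#' Interoceptive insight (accuracy-confidence discrepancy)
#'
#' Confidence is rescaled from 0-10 to 0-1, a signed per-trial difference
#' (standard accuracy minus rescaled confidence) is formed, and the trial
#' values are averaged. 0 marks optimal metacognition; positive values mean
#' high performance with low confidence, negative values low performance
#' with high confidence. Uses standard accuracy, so it is undefined for
#' over-estimators.
#'
#' @inheritParams std_accuracy
#' @return Mean signed discrepancy; `NA` with a warning if the subject is a
#'   substantial over-estimator.
#' @export
insight <- function(trials) {
  trials <- check_trials(trials)
  if (flag_overestimator(trials)) {
    warning("substantial over-estimator: insight not applicable")
    return(NA_real_)
  }
  acc <- trial_std_accuracy(trials$nbeats_real, trials$nbeats_reported)
  mean(acc - trials$confidence / 10)
}

#' Interoceptive awareness (within-subject accuracy-confidence correlation)
#'
#' Pearson correlation across trials between per-trial alternative accuracy
#' and the confidence rating: the metacognitive index of whether a subject's
#' confidence tracks their actual counting performance.
#'
#' @inheritParams std_accuracy
#' @return r in \[-1, 1\], or `NA` with a warning if either sequence has
#'   zero variance or there are fewer than 3 trials.
#' @export
awareness <- function(trials) {
  trials <- check_trials(trials)
  if (nrow(trials) < 3L) {
    warning("fewer than 3 trials: awareness undefined")
    return(NA_real_)
  }
  acc <- trial_alt_accuracy(trials$nbeats_real, trials$nbeats_reported)
  if (stats::sd(acc) == 0 || stats::sd(trials$confidence) == 0) {
    warning("zero variance: awareness undefined")
    return(NA_real_)
  }
  stats::cor(acc, trials$confidence)
}

#' Mean heartbeat-tracking confidence
#'
#' @inheritParams std_accuracy
#' @return Mean rating on the 0-10 scale.
#' @export
confidence_mean <- function(trials) {
  trials <- check_trials(trials)
  mean(trials$confidence)
}

#' Interoceptive sensibility (Body Perception Questionnaire mean)
#'
#' @param x Either the 45 item responses (each in 1-5) or a single
#'   precomputed mean in \[1, 5\].
#' @return Mean item score.
#' @export
sensibility <- function(x) {
  if (any(!is.finite(x)) || any(x < 1 | x > 5))
    stop_invalid("BPQ items/mean must lie in [1, 5]")
  mean(x)
}

#' Flag substantial over-estimators
#'
#' A subject whose total reported beats exceed twice the total real beats
#' across the counting trials. For such subjects standard accuracy turns
#' negative and the standard-accuracy-based indices (standard accuracy,
#' insight) are withheld; alternative-accuracy indices remain valid.
#' Totals (not single trials) are used so one miscounted trial does not
#' exclude a subject.
#'
#' @inheritParams std_accuracy
#' @return Logical flag.
#' @export
flag_overestimator <- function(trials) {
  trials <- check_trials(trials)
  sum(trials$nbeats_reported) > 2 * sum(trials$nbeats_real)
}

#' Trait interoceptive prediction error (TIPE)
#'
#' Cohort-level index: alternative accuracy and sensibility are each
#' z-scored across subjects (sample SD, n-1 denominator) and TIPE is
#' z-sensibility minus z-accuracy. Positive values mark subjects who
#' over-estimate their interoceptive ability relative to performance.
#'
#' @param alt_accuracies Cohort vector of alternative-accuracy scores.
#' @param sensibilities Cohort vector of sensibility scores, same length.
#' @return Vector of per-subject TIPE values (cohort mean 0).
#' @export
tipe <- function(alt_accuracies, sensibilities) {
  if (length(alt_accuracies) != length(sensibilities))
    stop_invalid("cohort vectors must have equal length")
  if (length(alt_accuracies) < 3L) stop_invalid("cohort size must be >= 3")
  if (stats::sd(alt_accuracies, na.rm = TRUE) == 0 ||
      stats::sd(sensibilities, na.rm = TRUE) == 0)
    stop_invalid("zero variance: TIPE undefined")
  zs <- function(v) (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
  zs(sensibilities) - zs(alt_accuracies)
}

#' Per-subject interoception profile
#'
#' Applies all single-subject indices with the over-estimator rule:
#' flagged subjects get only the alternative-accuracy-based indices
#' (standard accuracy and insight come back `NA`). TIPE is cohort-level
#' and is added by [interoception_profiles()].
#'
#' @param trials Counting trials for one subject.
#' @param bpq_mean Precomputed Body Perception Questionnaire mean (1-5),
#'   or `NA` if not collected.
#' @return One-row data frame.
#' @export
interoception_profile <- function(trials, bpq_mean = NA_real_) {
  trials <- check_trials(trials)
  over <- flag_overestimator(trials)
  data.frame(
    std_accuracy = if (over) NA_real_ else std_accuracy(trials),
    alt_accuracy = alt_accuracy(trials),
    insight = if (over) NA_real_ else suppressWarnings(insight(trials)),
    awareness = suppressWarnings(awareness(trials)),
    confidence_mean = confidence_mean(trials),
    sensibility = if (is.na(bpq_mean)) NA_real_ else sensibility(bpq_mean),
    overestimator = over)
}

#' Cohort interoception profiles
#'
#' @param tracking Data frame of counting trials for all subjects, with a
#'   `subject_id` column plus the per-trial columns.
#' @param questionnaires Optional data frame with `subject_id` and
#'   `bpq_mean`.
#' @return Data frame, one row per subject, with the seven indices
#'   (`std_accuracy`, `alt_accuracy`, `insight`, `awareness`,
#'   `confidence_mean`, `sensibility`, `tipe`) and the `overestimator`
#'   flag; indices that are undefined for a subject are `NA`.
#' @export
interoception_profiles <- function(tracking, questionnaires = NULL) {
  stopifnot("subject_id" %in% names(tracking))
  ids <- unique(tracking$subject_id)
  bpq <- rep(NA_real_, length(ids))
  if (!is.null(questionnaires))
    bpq <- questionnaires$bpq_mean[match(ids, questionnaires$subject_id)]
  rows <- lapply(seq_along(ids), function(i)
    cbind(subject_id = ids[i],
          interoception_profile(tracking[tracking$subject_id == ids[i], ],
                                bpq[i])))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (sum(!is.na(out$sensibility)) >= 3 &&
      stats::sd(out$alt_accuracy, na.rm = TRUE) > 0 &&
      stats::sd(out$sensibility, na.rm = TRUE) > 0) {
    out$tipe <- tipe(out$alt_accuracy, out$sensibility)
  } else {
    out$tipe <- NA_real_
  }
  out[, c("subject_id", "std_accuracy", "alt_accuracy", "insight",
          "awareness", "confidence_mean", "sensibility", "tipe",
          "overestimator")]
}
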