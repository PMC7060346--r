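## Go/NoGo/Choose session scoring: the four behaviour indices (Go RT,
## % NoGo commission errors, % Choose-Go, Choose-Go RT) plus % Go
## omissions and NoGo-error RT, each split by cardiac phase and pooled.

pct <- function(num, den) if (den == 0L) NA_real_ else 100 * num / den
mean_or_na <- function(x) if (length(x) == 0L) NA_real_ else mean(x)

score_cells <- function(trials) {
  go <- trials[trials$trial_type == "go", ]
  nogo <- trials[trials$trial_type == "nogo", ]
  choose <- trials[trials$trial_type == "choose", ]
  c(go_rt = mean_or_na(go$rt_ms[go$pressed == 1]),
    go_omissions = pct(sum(go$pressed == 0), nrow(go)),
    nogo_err = pct(sum(nogo$pressed == 1), nrow(nogo)),
    nogo_rt = mean_or_na(nogo$rt_ms[nogo$pressed == 1]),
    choose_go = pct(sum(choose$pressed == 1), nrow(choose)),
    choose_go_rt = mean_or_na(choose$rt_ms[choose$pressed == 1]))
}

#' Score one Go/NoGo/Choose session
#'
#' Go RT is the mean RT over pressed Go trials (omissions excluded);
#' % Go omissions the share of unpressed Go trials; % NoGo errors the
#' share of pressed (commission-error) NoGo trials; NoGo RT the mean RT
#' over those error trials (absent if none); % Choose-Go the share of
#' Choose trials with a press; Choose-Go RT the mean RT over pressed
#' Choose trials. Each index is reported at systole, at diastole, and
#' pooled over all trials of that type ("mean" columns are pooled, not
#' the average of the two phase means).
#'
#' @param trials Data frame with columns `trial_type`
#'   (`"go"`/`"nogo"`/`"choose"`), `intended_phase`
#'   (`"systole"`/`"diastole"`), `pressed` (0/1) and `rt_ms`
#'   (NA when not pressed).
#' @return One-row data frame with columns
#'   `<index>_systole`, `<index>_diastole`, `<index>_mean` for each of
#'   `go_rt`, `go_omissions`, `nogo_err`, `nogo_rt`, `choose_go`,
#'   `choose_go_rt`; undefined cells are `NA`.
#' @export
score_session <- function(trials) {
  need <- c("trial_type", "intended_phase", "pressed", "rt_ms")
  if (!all(need %in% names(trials)))
    stop_invalid("trials must have columns ", paste(need, collapse = ", "))
  cells <- c(
    stats::setNames(score_cells(trials[trials$intended_phase == "systole", ]),
                    paste0(names(score_cells(trials)), "_systole")),
    stats::setNames(score_cells(trials[trials$intended_phase == "diastole", ]),
                    paste0(names(score_cells(trials)), "_diastole")),
    stats::setNames(score_cells(trials),
                    paste0(names(score_cells(trials)), "_mean")))
  as.data.frame(as.list(cells))
}

#' Flag subjects with outlying NoGo commission-error rates
#'
#' Single-pass rule: a subject is flagged when their NoGo error rate
#' exceeds the cohort mean by more than two sample standard deviations
#' (one-sided high; low error rates are never flagged, and there is no
#' iterative re-computation after removal).
#'
#' @param nogo_err Cohort vector of NoGo error percentages.
#' @return Logical vector of flags, same length.
#' @export
exclusion_flags <- function(nogo_err) {
  if (length(nogo_err) < 3L) stop_invalid("cohort size must be >= 3")
  s <- stats::sd(nogo_err, na.rm = TRUE)
  if (is.na(s) || s == 0) return(rep(FALSE, length(nogo_err)))
  nogo_err > mean(nogo_err, na.rm = TRUE) + 2 * s
}

#' Cohort descriptive table
#'
#' Mean, sample SD (n-1), minimum and maximum for every numeric column,
#' with missing values excluded column-wise (pairwise deletion); `n` is
#' the number of non-missing values per column.
#'
#' @param summaries Data frame (e.g. one row per subject from
#'   [score_session()]).
#' @return Data frame with one row per numeric column: `variable`, `mean`,
#'   `sd`, `min`, `max`, `n`. For a single observation `sd` is `NA`.
#' @export
cohort_table <- function(summaries) {
  if (nrow(summaries) < 1L) stop_invalid("need at least one subject")
  num <- names(summaries)[vapply(summaries, is.numeric, logical(1))]
  rows <- lapply(num, function(v) {
    x <- summaries[[v]]
    x <- x[!is.na(x)]
    if (length(x) == 0L)
      return(data.frame(variable = v, mean = NA_real_, sd = NA_real_,
                        min = NA_real_, max = NA_real_, n = 0L))
    data.frame(variable = v, mean = mean(x),
               sd = if (length(x) > 1L) stats::sd(x) else NA_real_,
               min = min(x), max = max(x), n = length(x))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Behaviour summaries for a cohort
#'
#' @param task_trials Data frame of trials for all subjects with a
#'   `subject_id` column plus the per-trial columns of [score_session()].
#' @return Data frame, one row per subject, with all phase-split and
#'   pooled behaviour columns plus `excluded` (the NoGo-error outlier
#'   flag from [exclusion_flags()], based on the pooled NoGo error rate).
#' @export
behavior_summaries <- function(task_trials) {
  stopifnot("subject_id" %in% names(task_trials))
  ids <- unique(task_trials$subject_id)
  rows <- lapply(ids, function(id)
    cbind(subject_id = id,
          score_session(task_trials[task_trials$subject_id == id, ])))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$excluded <- if (nrow(out) >= 3L) exclusion_flags(out$nogo_err_mean)
                  else rep(FALSE, nrow(out))
  out
}
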