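## Synthetic cohort generator. Every input the pipeline consumes (R-peak
## streams, gated task sessions, heartbeat-counting responses,
## questionnaires) is generated with known ground truth so the full
## analysis is testable without recorded data. Defaults reproduce the
## canonical study conditions: 41 subjects, 400-trial sessions
## (200 Go / 66 NoGo / 134 Choose, half of each type at systole),
## 75 bpm / RMSSD 54 ms cardiac streams, six counting trials of 25-50 s.

#' Generator configuration
#'
#' @param n_subjects Cohort size (default 41).
#' @param mean_bpm Cohort mean heart rate (default 75).
#' @param rmssd_target Cohort RMSSD in ms (default 54).
#' @param n_trials Trials per session (default 400).
#' @param trial_mix Go/NoGo/Choose proportions (default 0.50/0.165/0.335,
#'   i.e. exactly 200/66/134 at 400 trials).
#' @param phase_split Fraction of each trial type at systole (default 0.5).
#' @param effect_awareness_choosego Target cohort correlation between the
#'   measured awareness index and %Choose-Go (default 0).
#' @param effect_insight_rt Target cohort correlation between the measured
#'   insight index and Choose-Go RT (default 0).
#' @param omission_rate Go omission probability (default 0.01).
#' @param nogo_err_base Baseline NoGo commission-error probability
#'   (default 0.04).
#' @param count_noise_sd SD (beats) of the reporting noise in the counting
#'   task (default 2).
#' @param seed Master seed; per-subject substreams are derived from it.
#' @return List of class `gen_config`.
#' @export
gen_config <- function(n_subjects = 41, mean_bpm = 75, rmssd_target = 54,
                       n_trials = 400,
                       trial_mix = c(go = 0.50, nogo = 0.165, choose = 0.335),
                       phase_split = 0.5,
                       effect_awareness_choosego = 0,
                       effect_insight_rt = 0,
                       omission_rate = 0.01, nogo_err_base = 0.04,
                       count_noise_sd = 2, seed = 1) {
  if (abs(sum(trial_mix) - 1) > 1e-9)
    stop_invalid("trial_mix must sum to 1")
  if (rmssd_target <= 0) stop_invalid("rmssd_target must be positive")
  if (mean_bpm < 30 || mean_bpm > 180)
    stop_invalid("mean_bpm must lie in [30, 180]")
  if (phase_split <= 0 || phase_split >= 1)
    stop_invalid("phase_split must lie in (0, 1)")
  structure(list(n_subjects = n_subjects, mean_bpm = mean_bpm,
                 rmssd_target = rmssd_target, n_trials = n_trials,
                 trial_mix = trial_mix, phase_split = phase_split,
                 effect_awareness_choosego = effect_awareness_choosego,
                 effect_insight_rt = effect_insight_rt,
                 omission_rate = omission_rate,
                 nogo_err_base = nogo_err_base,
                 count_noise_sd = count_noise_sd,
                 seed = seed), class = "gen_config")
}

#' Generate an R-peak series with controlled mean rate and RMSSD
#'
#' Inter-beat intervals are independent Gaussians with mean `60000 /
#' mean_bpm` and standard deviation `rmssd_target / sqrt(2)`, so the
#' expected RMSSD equals `rmssd_target` exactly (for iid intervals the
#' successive difference has variance 2 sigma^2). Intervals are truncated
#' to the physiological band \[300, 2000\] ms.
#'
#' @param mean_bpm Mean heart rate (beats/min).
#' @param rmssd_target Target RMSSD (ms), > 0.
#' @param n_beats Number of R-peaks (>= 4).
#' @param seed Optional seed for a local RNG stream.
#' @return Strictly increasing R-peak times in ms, starting at 0.
#' @export
gen_rr_series <- function(mean_bpm, rmssd_target, n_beats, seed = NULL) {
  if (rmssd_target <= 0) stop_invalid("rmssd_target must be positive")
  if (n_beats < 4) stop_invalid("n_beats must be at least 4")
  with_seed(seed, {
    ibis <- stats::rnorm(n_beats - 1, 60000 / mean_bpm,
                         rmssd_target / sqrt(2))
    ibis <- pmin(pmax(ibis, 300), 2000)
    cumsum(c(0, ibis))
  })
}

#' Toy ECG-like waveform for exercising the peak detector
#'
#' Gaussian R-wave bumps (8 ms width) at the given peak times on a noisy
#' baseline. Not a physiological ECG model: only the R-peak timing matters
#' downstream.
#'
#' @param r_times R-peak times in ms.
#' @param fs Sampling rate in Hz (default 1000).
#' @param amplitude Peak height (default 1).
#' @param noise_sd Baseline noise SD (default 0.02).
#' @param seed Optional seed.
#' @return Numeric vector of samples covering `[0, max(r_times) + 500 ms]`.
#' @export
gen_ecg_wave <- function(r_times, fs = 1000, amplitude = 1,
                         noise_sd = 0.02, seed = NULL) {
  with_seed(seed, {
    t_ms <- seq(0, max(r_times) + 500, by = 1000 / fs)
    sig <- stats::rnorm(length(t_ms), 0, noise_sd)
    for (r in r_times)
      sig <- sig + amplitude * exp(-((t_ms - r)^2) / (2 * 8^2))
    sig
  })
}

#' Draw per-subject latent traits
#'
#' The unobserved individual-difference structure behind the generated
#' data: a metacognition latent (drives the accuracy-confidence coupling
#' and, when an effect is requested, the Choose-Go tendency), a tracking
#' ability (mean reported/real ratio), a confidence-bias latent (drives
#' the insight index and, when requested, Choose-Go RT), an impulsivity
#' latent (drives NoGo errors and questionnaire scores), and subject-level
#' cardiac and RT parameters.
#'
#' @param config A [gen_config()].
#' @return Data frame with one row per subject.
#' @export
subject_latents <- function(config) {
  n <- config$n_subjects
  with_seed(config$seed, {
    metacognition <- stats::rnorm(n)
    impulsivity <- stats::rnorm(n)
    tracking_ability <- pmin(pmax(stats::rnorm(n, 0.72, 0.17), 0.05), 1.5)
    confidence_coupling <- pmin(pmax(0.26 + 0.45 * metacognition,
                                     -0.95), 0.95)
    insight_bias <- stats::rnorm(n, 0.24, 0.18)
    bpm <- pmin(pmax(stats::rnorm(n, config$mean_bpm, 10), 45), 120)
    rmssd <- pmin(pmax(stats::rlnorm(n, log(config$rmssd_target) - 0.125,
                                     0.5), 10), 200)
    go_rt_mu <- pmin(pmax(stats::rnorm(n, 482, 57), 250), 900)
    ## Choose-Go RT mean: coupled to the confidence-bias (insight) latent
    ## with loading q, idiosyncratic residual otherwise
    q_rt <- max(min(config$effect_insight_rt / 0.93, 0.97), -0.97)
    choose_rt_mu <- pmin(pmax(523 + 82 * (q_rt * (insight_bias - 0.24) / 0.18 +
                                            sqrt(1 - q_rt^2) * stats::rnorm(n)),
                              250), 900)
    data.frame(subject_id = sprintf("s%02d", seq_len(n)),
               metacognition = metacognition,
               tracking_ability = tracking_ability,
               confidence_coupling = confidence_coupling,
               insight_bias = insight_bias,
               impulsivity = impulsivity,
               bpm = bpm, rmssd = rmssd,
               go_rt_mu = go_rt_mu, choose_rt_mu = choose_rt_mu,
               age = sample(18:28, n, replace = TRUE),
               sex = sample(c("F", "M"), n, replace = TRUE))
  })
}

## Logit slope on the metacognition latent needed for a target cohort
## correlation `e` between measured awareness and %Choose-Go.
## Linearized around p0: between-subject SD of %Choose-Go combines the
## latent path (d*s), an idiosyncratic logit component (d*s0) and binomial
## trial noise; the awareness index measured from 6 counting trials
## carries attenuation `atten` (empirically calibrated, see vignette).
choose_slope <- function(e, atten = 0.73, s0 = 0.45, n_choose = 134,
                         p0 = 0.60) {
  if (e == 0) return(0)
  q <- max(min(e / atten, 0.97), -0.97)
  d <- p0 * (1 - p0)
  v_within <- p0 * (1 - p0) / n_choose
  sign(q) * sqrt((d^2 * s0^2 + v_within) * q^2 / (d^2 * (1 - q^2)))
}

#' Generate a session schedule
#'
#' Exact trial-type counts (Go = round(n p_go), NoGo = round(n p_nogo),
#' Choose = remainder, guaranteeing 200/66/134 at the 400-trial default)
#' with the systole/diastole split balanced within each type (counts
#' differ by at most 1), in an order randomized by the seed.
#'
#' @param config A [gen_config()].
#' @param seed Optional seed (defaults to the config seed).
#' @return Data frame with columns `trial_type` and `intended_phase`.
#' @export
gen_session_schedule <- function(config, seed = config$seed) {
  n <- config$n_trials
  mix <- config$trial_mix
  counts <- c(go = round(n * mix[["go"]]), nogo = round(n * mix[["nogo"]]))
  counts <- c(counts, choose = n - sum(counts))
  rows <- do.call(rbind, lapply(names(counts), function(tt) {
    k <- counts[[tt]]
    n_sys <- round(k * config$phase_split)
    data.frame(trial_type = rep(tt, k),
               intended_phase = rep(c("systole", "diastole"),
                                    c(n_sys, k - n_sys)))
  }))
  out <- with_seed(seed, rows[sample.int(nrow(rows)), , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Generate per-trial behaviour for one subject
#'
#' Go trials are pressed with probability 1 - omission_rate, with
#' lognormal RTs around the subject's Go mean. NoGo commission errors
#' occur with a probability that increases in the impulsivity latent
#' (logistic link around the 4% baseline), with faster RTs. Choose
#' presses follow a logistic model whose metacognition slope is
#' calibrated from `effect_awareness_choosego`; Choose-Go RTs are
#' lognormal around the subject's Choose mean (which carries the insight
#' coupling). All RTs are clipped to (150, 1000\] ms, the cue's response
#' window.
#'
#' @param latents One row of [subject_latents()].
#' @param schedule Data frame from [gen_session_schedule()].
#' @param config A [gen_config()].
#' @param seed Optional seed.
#' @return `schedule` with added columns `trial_index`, `pressed`, `rt_ms`.
#' @export
gen_behavior <- function(latents, schedule, config, seed = NULL) {
  if (nrow(schedule) == 0L) stop_invalid("schedule must be nonempty")
  with_seed(seed, {
    n <- nrow(schedule)
    pressed <- integer(n)
    rt <- rep(NA_real_, n)
    draw_rt <- function(k, mu) {
      sdlog <- 0.15
      pmin(pmax(stats::rlnorm(k, log(mu) - sdlog^2 / 2, sdlog), 150), 1000)
    }
    is_go <- schedule$trial_type == "go"
    is_nogo <- schedule$trial_type == "nogo"
    is_choose <- schedule$trial_type == "choose"
    pressed[is_go] <- stats::rbinom(sum(is_go), 1, 1 - config$omission_rate)
    p_err <- stats::plogis(stats::qlogis(config$nogo_err_base) +
                             0.6 * latents$impulsivity)
    pressed[is_nogo] <- stats::rbinom(sum(is_nogo), 1, p_err)
    s <- choose_slope(config$effect_awareness_choosego)
    idio <- if (is.null(latents$choose_logit_noise)) 0
            else latents$choose_logit_noise
    p_go <- stats::plogis(stats::qlogis(0.60) + s * latents$metacognition +
                            0.45 * idio)
    pressed[is_choose] <- stats::rbinom(sum(is_choose), 1, p_go)
    rt[is_go & pressed == 1] <- draw_rt(sum(is_go & pressed == 1),
                                        latents$go_rt_mu)
    rt[is_nogo & pressed == 1] <- draw_rt(sum(is_nogo & pressed == 1),
                                          0.84 * latents$go_rt_mu)
    rt[is_choose & pressed == 1] <- draw_rt(sum(is_choose & pressed == 1),
                                            latents$choose_rt_mu)
    out <- schedule
    out$trial_index <- seq_len(n) - 1L
    out$pressed <- pressed
    out$rt_ms <- rt
    out[, c("trial_index", "trial_type", "intended_phase", "pressed",
            "rt_ms")]
  })
}

#' Generate heartbeat-counting trials for one subject
#'
#' Six trials of 25-50 s in randomized order. The real beat count is the
#' number of beats of a freshly generated R-peak stream falling inside
#' each window; the reported count is `round(ability * real + noise)`
#' floored at 0; confidence ratings are coupled to per-trial alternative
#' accuracy by rank assignment (values drawn around the subject's
#' confidence base, then ordered to match the ranks of a latent that
#' correlates with accuracy at the subject's coupling strength), which
#' keeps ratings inside \[0, 10\].
#'
#' @param latents One row of [subject_latents()].
#' @param mean_bpm Heart rate of the generated stream (beats/min).
#' @param seed Optional seed.
#' @param rmssd_target RMSSD of the generated stream (ms).
#' @param count_noise_sd Reporting noise SD in beats.
#' @return Data frame: `trial_index`, `duration_s`, `nbeats_real`,
#'   `nbeats_reported`, `confidence`.
#' @export
gen_tracking_trials <- function(latents, mean_bpm, seed = NULL,
                                rmssd_target = 54, count_noise_sd = 2) {
  with_seed(seed, {
    durations <- sample(c(25, 30, 35, 40, 45, 50))
    real <- vapply(durations, function(d) {
      r <- gen_rr_series(mean_bpm, rmssd_target,
                         n_beats = ceiling(d * mean_bpm / 60) + 15)
      sum(r > 0 & r <= d * 1000)
    }, numeric(1))
    reported <- pmax(0, round(latents$tracking_ability * real +
                                stats::rnorm(6, 0, count_noise_sd)))
    acc <- trial_alt_accuracy(pmax(real, 1), reported)
    cpl <- latents$confidence_coupling
    z <- if (stats::sd(acc) > 0) as.numeric(scale(acc)) else stats::rnorm(6)
    raw <- cpl * z + sqrt(1 - cpl^2) * stats::rnorm(6)
    exp_acc <- 1 - abs(1 - latents$tracking_ability)
    base <- min(max(10 * (exp_acc - latents$insight_bias), 0.3), 9.7)
    vals <- round(pmin(pmax(stats::rnorm(6, base, 1.3), 0), 10), 1)
    conf <- sort(vals)[rank(raw, ties.method = "first")]
    data.frame(trial_index = 0:5, duration_s = durations,
               nbeats_real = real, nbeats_reported = reported,
               confidence = conf)
  })
}

## Questionnaire scale definitions: cohort-typical mean/SD and the
## instrument-legal range the generator clips to.
quest_scales <- data.frame(
  scale = c("bis_attention", "bis_motor", "bis_planning", "caars_adhd",
            "upps_neg_urgency", "upps_premeditation", "upps_perseverance",
            "upps_sensation", "upps_pos_urgency"),
  mean = c(18, 24, 24, 13, 29, 23, 20, 38, 29),
  sd = c(4, 4, 5, 4, 7, 4, 3, 7, 9),
  lo = c(8, 11, 11, 0, 12, 11, 10, 12, 14),
  hi = c(32, 44, 44, 36, 48, 44, 40, 48, 56))

#' Generate questionnaire scores for one subject
#'
#' Integer scores around cohort-typical means, positively correlated
#' through the impulsivity latent (loading 0.6) and clipped to each
#' instrument's legal range. The BIS total is the sum of its three
#' subscales. The Body Perception Questionnaire mean (sensibility) is
#' drawn independently on the 1-5 scale.
#'
#' @param latents One row of [subject_latents()].
#' @param seed Optional seed.
#' @return One-row data frame with the scale columns and `bpq_mean`.
#' @export
gen_questionnaires <- function(latents, seed = NULL) {
  with_seed(seed, {
    sc <- quest_scales
    raw <- round(sc$mean + sc$sd * (0.6 * latents$impulsivity +
                                      0.8 * stats::rnorm(nrow(sc))))
    score <- pmin(pmax(raw, sc$lo), sc$hi)
    out <- as.data.frame(as.list(stats::setNames(score, sc$scale)))
    out$bis_total <- out$bis_attention + out$bis_motor + out$bis_planning
    out$bpq_mean <- round(min(max(stats::rnorm(1, 2.5, 0.64), 1), 5), 2)
    out[, c("bis_attention", "bis_motor", "bis_planning", "bis_total",
            "caars_adhd", "upps_neg_urgency", "upps_premeditation",
            "upps_perseverance", "upps_sensation", "upps_pos_urgency",
            "bpq_mean")]
  })
}

#' Generate a full synthetic cohort in memory
#'
#' Orchestrates the per-subject generators under deterministic
#' per-subject substreams of the master seed.
#'
#' @param config A [gen_config()].
#' @return List with elements `subjects`, `task_trials`,
#'   `tracking_trials`, `questionnaires` (data frames), `rr` (named list
#'   of R-peak vectors, ~190 s each for resting HRV), and `config`.
#' @export
gen_cohort <- function(config = gen_config()) {
  lat <- subject_latents(config)
  ## idiosyncratic choose-tendency component, part of the latent draw
  lat$choose_logit_noise <- with_seed(subject_seed(config$seed, 0),
                                      stats::rnorm(nrow(lat)))
  task <- tracking <- quest <- vector("list", nrow(lat))
  rr <- list()
  for (i in seq_len(nrow(lat))) {
    li <- lat[i, ]
    si <- subject_seed(config$seed, i)
    sched <- gen_session_schedule(config, seed = si)
    task[[i]] <- cbind(subject_id = li$subject_id,
                       gen_behavior(li, sched, config, seed = si + 1L))
    tracking[[i]] <- cbind(subject_id = li$subject_id,
                           gen_tracking_trials(li, li$bpm, seed = si + 2L,
                                               rmssd_target = li$rmssd,
                                               count_noise_sd = config$count_noise_sd))
    quest[[i]] <- cbind(subject_id = li$subject_id,
                        gen_questionnaires(li, seed = si + 3L))
    n_beats <- ceiling(190 * li$bpm / 60) + 5
    rr[[li$subject_id]] <- round(gen_rr_series(li$bpm, li$rmssd, n_beats,
                                               seed = si + 4L), 3)
  }
  list(subjects = lat[, c("subject_id", "age", "sex")],
       task_trials = do.call(rbind, task),
       tracking_trials = do.call(rbind, tracking),
       questionnaires = do.call(rbind, quest),
       rr = rr,
       latents = lat,
       config = config)
}

#' Write a synthetic cohort to disk
#'
#' Writes `subjects.csv`, `task_trials.csv`, `tracking_trials.csv`,
#' `questionnaires.csv`, one `rr_<subject>.txt` per subject (one ascending
#' R-peak time in ms per line) and a `manifest.json` echoing the config,
#' the seed, and an md5 checksum per file. All CSVs are UTF-8,
#' comma-separated, with a header row and '.' decimal separator.
#'
#' @param config A [gen_config()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the cohort list from [gen_cohort()].
#' @export
gen_dataset <- function(config = gen_config(), dir) {
  cohort <- gen_cohort(config)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop_invalid("cannot create output directory: ", dir)
  wcsv <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8", na = "")
    path
  }
  files <- c(wcsv(cohort$subjects, "subjects.csv"),
             wcsv(cohort$task_trials, "task_trials.csv"),
             wcsv(cohort$tracking_trials, "tracking_trials.csv"),
             wcsv(cohort$questionnaires, "questionnaires.csv"))
  for (id in names(cohort$rr)) {
    path <- file.path(dir, paste0("rr_", id, ".txt"))
    writeLines(format(cohort$rr[[id]], trim = TRUE, scientific = FALSE),
               path)
    files <- c(files, path)
  }
  manifest <- list(
    config = cohort$config[setdiff(names(cohort$config), "trial_mix")],
    trial_mix = as.list(cohort$config$trial_mix),
    seed = cohort$config$seed,
    files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                    basename(files))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(cohort)
}
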