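#' Configuration for cardiac-phase stimulus scheduling
#'
#' Defaults reproduce the standard design: systole cues 290 ms after a
#' detected R-wave (near the peak of arterial baroreceptor firing),
#' diastole cues 10 ms before the next R-wave, predicted as the last
#' detected R plus the median of the three preceding inter-beat intervals.
#' Timing precision is evaluated in 50 ms bins with a 200 ms tolerance.
#'
#' @param systole_offset ms after the anchor R-wave for systole cues.
#' @param diastole_offset ms before the predicted next R for diastole cues.
#' @param fixation_ms Inter-trial fixation duration in ms.
#' @param history Number of preceding IBIs in the median predictor.
#' @param bin_width Histogram bin width in ms for the timing report.
#' @param tolerance Absolute timing error (ms) counted as on-target.
#' @return List of class `gating_config`.
#' @export
gating_config <- function(systole_offset = 290, diastole_offset = 10,
                          fixation_ms = 1000, history = 3,
                          bin_width = 50, tolerance = 200) {
  vals <- c(systole_offset, diastole_offset, fixation_ms, history,
            bin_width, tolerance)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop_invalid("all gating parameters must be positive")
  if (history < 1) stop_invalid("history must be >= 1")
  structure(list(systole_offset = systole_offset,
                 diastole_offset = diastole_offset,
                 fixation_ms = fixation_ms, history = history,
                 bin_width = bin_width, tolerance = tolerance),
            class = "gating_config")
}

#' Detect R-peaks in a sampled ECG-like trace
#'
#' Threshold-crossing detector: at each upward crossing of `threshold` the
#' local maximum of the above-threshold excursion is taken as the peak;
#' crossings within `refractory_ms` of the previous accepted peak are
#' suppressed (default 250 ms, the physiological upper bound on heart
#' rate).
#'
#' @param signal Numeric vector of samples.
#' @param fs Sampling rate in Hz.
#' @param threshold Detection threshold (same units as `signal`).
#' @param refractory_ms Dead time after each accepted peak.
#' @return Numeric vector of peak times in ms (possibly empty).
#' @export
detect_r_peaks <- function(signal, fs, threshold, refractory_ms = 250) {
  if (!is.numeric(signal) || length(signal) < 2L)
    stop_invalid("signal must be a numeric vector")
  if (any(!is.finite(signal))) stop_invalid("signal contains non-finite samples")
  if (fs <= 0 || refractory_ms <= 0)
    stop_invalid("fs and refractory_ms must be positive")
  above <- signal > threshold
  rises <- which(!above[-length(above)] & above[-1]) + 1L
  peaks <- numeric(0)
  last_peak_ms <- -Inf
  for (i in rises) {
    ## extent of this above-threshold excursion
    j <- i
    while (j < length(signal) && above[j + 1L]) j <- j + 1L
    k <- i + which.max(signal[i:j]) - 1L
    t_ms <- (k - 1L) / fs * 1000
    if (t_ms - last_peak_ms >= refractory_ms) {
      peaks <- c(peaks, t_ms)
      last_peak_ms <- t_ms
    }
  }
  peaks
}

#' Predict the next R-wave time
#'
#' The real-time predictor: last detected R plus the median of the last
#' `history` inter-beat intervals (median of 3 by default, robust to one
#' deviant beat).
#'
#' @param r_times Detected R-peak times (ms), strictly increasing.
#' @param history Number of trailing IBIs in the median.
#' @return Predicted time (ms) of the next R-peak.
#' @export
predict_next_r <- function(r_times, history = 3) {
  if (length(r_times) < history + 1L)
    stop_invalid("insufficient history: need at least ", history + 1, " peaks")
  ibis <- ibis_from_rpeaks(r_times)
  utils::tail(r_times, 1) + stats::median(utils::tail(ibis, history))
}

#' Schedule one cue onset at a target cardiac phase
#'
#' Takes the first R-peak at or after `earliest_allowed` as the anchor R*.
#' Systole cues are anchored reactively: onset = R* + systole offset.
#' Diastole cues need a forward prediction, since a negative offset cannot
#' be realized reactively: onset = R* + median of the `history` IBIs ending
#' at R* minus the diastole offset (i.e. just before the predicted next R).
#' If R* does not yet have `history` preceding IBIs, the anchor advances to
#' the first peak that does.
#'
#' @param phase `"systole"` or `"diastole"`.
#' @param r_times R-peak times (ms) of the stream.
#' @param earliest_allowed Earliest permissible onset (ms), typically
#'   previous trial end + fixation.
#' @param config A [gating_config()].
#' @return List with `onset` (ms), `anchor_r` (ms) and `anchor_idx`, or
#'   `NULL` if the stream is exhausted before an anchor is available.
#' @export
schedule_trial_onset <- function(phase, r_times, earliest_allowed,
                                 config = gating_config()) {
  if (!phase %in% c("systole", "diastole"))
    stop_invalid("unknown phase label: ", phase)
  idx <- which(r_times >= earliest_allowed)
  if (length(idx) == 0L) return(NULL)
  i <- max(idx[1], config$history + 1L)
  if (i > length(r_times)) return(NULL)
  anchor <- r_times[i]
  onset <- if (phase == "systole") {
    anchor + config$systole_offset
  } else {
    ibis <- diff(r_times[(i - config$history):i])
    anchor + stats::median(ibis) - config$diastole_offset
  }
  list(onset = onset, anchor_r = anchor, anchor_idx = i)
}

#' Simulate a full cardiac-gated session
#'
#' Plays a trial schedule against an R-peak stream: each trial's cue onset
#' is placed by [schedule_trial_onset()], the cue then consumes its
#' duration (the response time if the subject pressed, otherwise the
#' 1000 ms maximum cue duration), followed by the fixation interval before
#' the next trial's ECG monitoring starts.
#'
#' @param schedule Data frame with columns `trial_type` and
#'   `intended_phase` (`"systole"`/`"diastole"`), one row per trial, in
#'   presentation order.
#' @param r_times R-peak times (ms) covering the session.
#' @param config A [gating_config()].
#' @param cue_ms Per-trial cue duration in ms (recycled); defaults to the
#'   1000 ms maximum, i.e. no presses.
#' @return Data frame: `trial_index`, `trial_type`, `intended_phase`,
#'   `onset_ms`, `anchor_r_ms`. If the stream runs out, the result is the
#'   completed prefix with attribute `truncated = TRUE` and a warning.
#' @export
simulate_gated_session <- function(schedule, r_times,
                                   config = gating_config(),
                                   cue_ms = 1000) {
  stopifnot(all(c("trial_type", "intended_phase") %in% names(schedule)))
  n <- nrow(schedule)
  cue_ms <- rep_len(cue_ms, n)
  onset <- anchor <- rep(NA_real_, n)
  clock <- r_times[1]
  truncated <- FALSE
  for (i in seq_len(n)) {
    s <- schedule_trial_onset(schedule$intended_phase[i], r_times,
                              earliest_allowed = clock, config = config)
    if (is.null(s)) {
      truncated <- TRUE
      break
    }
    onset[i] <- s$onset
    anchor[i] <- s$anchor_r
    clock <- s$onset + cue_ms[i] + config$fixation_ms
  }
  done <- !is.na(onset)
  out <- data.frame(trial_index = which(done) - 1L,
                    trial_type = schedule$trial_type[done],
                    intended_phase = schedule$intended_phase[done],
                    onset_ms = onset[done], anchor_r_ms = anchor[done])
  if (truncated) {
    warning("R-peak stream exhausted: session truncated after ",
            nrow(out), " of ", n, " trials")
    attr(out, "truncated") <- TRUE
  }
  out
}

#' Evaluate achieved cue timing against the cardiac cycle
#'
#' For each trial the signed offset of the cue onset from its reference
#' R-peak is computed: for systole trials the reference is the preceding R
#' (the cue is a forward offset from a detected beat); for diastole trials
#' it is the nearest R (the prediction may land the cue on either side of
#' the true beat). The timing error is the offset minus the intended
#' offset (+systole_offset, or -diastole_offset). Offsets are histogrammed
#' per phase in `bin_width` bins spanning \[-400, 600) ms (values outside
#' are clipped into the end bins), and the fraction of trials with
#' |error| <= tolerance is reported per phase.
#'
#' @param onsets Cue onset times (ms).
#' @param r_times R-peak times (ms) of the same recording.
#' @param phases Character vector, `"systole"`/`"diastole"` per trial.
#' @param config A [gating_config()].
#' @return List of class `timing_report`: `errors` (per-trial data frame
#'   with `phase`, `onset_ms`, `reference_r_ms`, `offset_ms`, `error_ms`),
#'   `histograms` (per-phase data frame of `bin_left`, `fraction`), and
#'   `fraction_within_tolerance` (named vector).
#' @export
evaluate_timing <- function(onsets, r_times, phases,
                            config = gating_config()) {
  if (length(onsets) != length(phases))
    stop_invalid("onsets and phases must have equal length")
  if (!all(phases %in% c("systole", "diastole")))
    stop_invalid("unknown phase label")
  ref <- vapply(seq_along(onsets), function(i) {
    if (phases[i] == "systole") {
      prev <- r_times[r_times <= onsets[i]]
      if (length(prev) == 0L) return(NA_real_)
      max(prev)
    } else {
      r_times[which.min(abs(r_times - onsets[i]))]
    }
  }, numeric(1))
  offset <- onsets - ref
  intended <- ifelse(phases == "systole",
                     config$systole_offset, -config$diastole_offset)
  err <- offset - intended
  edges <- seq(-400, 600, by = config$bin_width)
  clip <- pmin(pmax(offset, -400), 600 - 1e-9)
  bin_left <- edges[findInterval(clip, edges)]
  hist_phase <- function(ph) {
    sel <- phases == ph & !is.na(bin_left)
    tab <- table(factor(bin_left[sel], levels = utils::head(edges, -1)))
    data.frame(phase = ph, bin_left = as.numeric(names(tab)),
               fraction = as.numeric(tab) / max(sum(tab), 1L))
  }
  fr <- vapply(c("systole", "diastole"), function(ph) {
    e <- err[phases == ph]
    if (length(e) == 0L) return(NA_real_)
    mean(abs(e) <= config$tolerance, na.rm = TRUE)
  }, numeric(1))
  structure(list(
    errors = data.frame(trial_index = seq_along(onsets) - 1L,
                        phase = phases, onset_ms = onsets,
                        reference_r_ms = ref, offset_ms = offset,
                        error_ms = err),
    histograms = rbind(hist_phase("systole"), hist_phase("diastole")),
    fraction_within_tolerance = fr), class = "timing_report")
}

#' @export
print.timing_report <- function(x, ...) {
  cat("Cardiac-gating timing report\n")
  cat("  trials:", nrow(x$errors), "\n")
  fr <- x$fraction_within_tolerance
  for (ph in names(fr))
    cat(sprintf("  %-8s fraction within tolerance: %s\n", ph,
                ifelse(is.na(fr[ph]), "n/a", sprintf("%.3f", fr[ph]))))
  invisible(x)
}

#' Simulate and evaluate a gated session in one call
#'
#' Convenience wrapper: generates an R-peak stream, builds a balanced
#' schedule, runs the scheduler, and evaluates achieved timing.
#'
#' @param n_trials Number of trials (default 400).
#' @param bpm Mean heart rate of the simulated stream.
#' @param rmssd_target RMSSD of the simulated stream (ms).
#' @param seed Integer seed.
#' @param config A [gating_config()].
#' @return A `timing_report` with the session data frame attached as
#'   attribute `session`.
#' @export
gate_sim <- function(n_trials = 400, bpm = 75, rmssd_target = 54,
                     seed = 1, config = gating_config()) {
  cfg <- gen_config(n_trials = n_trials, mean_bpm = bpm,
                    rmssd_target = rmssd_target, seed = seed)
  ## generous stream: each trial consumes < cue + fixation + ~2 IBIs
  n_beats <- ceiling(n_trials * (1000 + config$fixation_ms + 2500) /
                       (60000 / bpm)) + 20
  rr <- gen_rr_series(bpm, rmssd_target, n_beats, seed = seed)
  sched <- gen_session_schedule(cfg, seed = seed)
  ses <- simulate_gated_session(sched, rr, config = config)
  rep <- evaluate_timing(ses$onset_ms, rr, ses$intended_phase, config)
  attr(rep, "session") <- ses
  rep
}
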