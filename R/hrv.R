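#' Inter-beat intervals from R-peak times
#'
#' @param r_times Numeric vector of R-peak times in ms, strictly increasing.
#' @return Numeric vector of successive differences (IBIs, ms).
#' @examples
#' ibis_from_rpeaks(c(0, 800, 1610))
#' @export
ibis_from_rpeaks <- function(r_times) {
  if (!is.numeric(r_times) || length(r_times) < 2L)
    stop_invalid("need at least two R-peak times")
  if (any(!is.finite(r_times)))
    stop_invalid("R-peak times must be finite")
  if (any(diff(r_times) <= 0))
    stop_invalid("R-peak times must be strictly increasing")
  diff(r_times)
}

#' Root mean square of successive differences (RMSSD)
#'
#' The time-domain heart-rate-variability index used throughout: the square
#' root of the mean squared difference between adjacent inter-beat intervals.
#' It is sensitive to beat-to-beat (vagally mediated) variability and, unlike
#' SDNN, insensitive to slow trends.
#'
#' @param ibis Numeric vector of inter-beat intervals in ms (at least 2).
#' @return RMSSD in ms.
#' @examples
#' rmssd(c(800, 810, 790)) # sqrt((100 + 400) / 2)
#' @export
rmssd <- function(ibis) {
  if (!is.numeric(ibis) || length(ibis) < 2L)
    stop_invalid("RMSSD needs at least two inter-beat intervals")
  d <- diff(ibis)
  sqrt(mean(d^2))
}

#' Mean heart rate in beats per minute
#'
#' Computed as 60000 divided by the mean inter-beat interval, which equals
#' beat count over elapsed time for a full window and is stable for partial
#' windows.
#'
#' @param r_times Strictly increasing R-peak times (ms), at least 2.
#' @return Heart rate in beats/min.
#' @export
mean_bpm <- function(r_times) {
  ibis <- ibis_from_rpeaks(r_times)
  60000 / mean(ibis)
}

#' Screen inter-beat intervals for artifacts
#'
#' Automated surrogate for visual inspection of a resting recording: flags
#' any interval outside a physiologically plausible band. Flagged recordings
#' are reported, never silently cleaned.
#'
#' @param ibis Inter-beat intervals (ms).
#' @param low_ms,high_ms Plausibility band in ms (defaults 300 and 2000,
#'   i.e. 30-200 bpm).
#' @return List with `flagged` (any interval out of band), `bad_idx`
#'   (indices of out-of-band intervals) and `clean_idx` (the rest).
#' @export
artifact_screen <- function(ibis, low_ms = 300, high_ms = 2000) {
  if (!(low_ms > 0 && high_ms > low_ms))
    stop_invalid("need 0 < low_ms < high_ms")
  bad <- which(ibis < low_ms | ibis > high_ms)
  list(flagged = length(bad) > 0L,
       bad_idx = bad,
       clean_idx = setdiff(seq_along(ibis), bad))
}

#' Summarise a resting R-peak recording
#'
#' @param r_times R-peak times in ms.
#' @param window_s Optional analysis window in s; if given, only peaks in
#'   `[first peak, first peak + window_s]` are used (default 150 s, the
#'   conventional short resting window).
#' @param low_ms,high_ms Artifact-screen band passed to [artifact_screen()].
#' @return One-row data frame: `rmssd`, `bpm`, `n_beats`, `flagged_artifact`.
#' @export
hrv_summary <- function(r_times, window_s = NULL, low_ms = 300, high_ms = 2000) {
  if (!is.null(window_s)) {
    keep <- r_times <= r_times[1] + window_s * 1000
    r_times <- r_times[keep]
  }
  ibis <- ibis_from_rpeaks(r_times)
  scr <- artifact_screen(ibis, low_ms, high_ms)
  data.frame(rmssd = rmssd(ibis),
             bpm = mean_bpm(r_times),
             n_beats = length(r_times),
             flagged_artifact = scr$flagged)
}

#' HRV table for a cohort of R-peak recordings
#'
#' @param rr_list Named list of R-peak time vectors (names are subject ids).
#' @param ... Passed to [hrv_summary()].
#' @return Data frame with one row per subject: `subject_id`, `rmssd`,
#'   `bpm`, `n_beats`, `flagged_artifact`.
#' @export
hrv_table <- function(rr_list, ...) {
  stopifnot(is.list(rr_list), !is.null(names(rr_list)))
  rows <- lapply(names(rr_list), function(id)
    cbind(subject_id = id, hrv_summary(rr_list[[id]], ...)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
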