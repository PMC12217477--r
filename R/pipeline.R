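# End-to-end session processing: the chain a recorded session goes through,
# also used to close the loop against synthetic ground truth.

#' Run the full analysis pipeline on a session
#'
#' Demodulates both channels, applies isosbestic subtraction + detrending +
#' Z-score, runs tracking QC / speed / bout detection, classifies
#' stimulus responses, and extracts stimulus-aligned epochs with window
#' summaries.
#'
#' @param session A `photometry_session` (typically from
#'   [synthesize_session()]).
#' @param output_rate Demodulated sampling rate in Hz.
#' @param spec A [filter_spec()].
#' @param method Isosbestic subtraction method.
#' @return A list with elements `signal` (`processed_signal`), `channels`
#'   (demodulated `ca`/`iso`), `scale`, `qc` (valid mask with counts),
#'   `speed`, `bouts` (detected locomotion), `responses`
#'   (per-trial flags + proportion), `epochs` (stimulus-aligned),
#'   `summary` (per-trial window means).
#' @export
run_session_pipeline <- function(session, output_rate = 100,
                                 spec = filter_spec(),
                                 method = c("fitted", "direct")) {
  stopifnot(inherits(session, "photometry_session"))
  method <- match.arg(method)
  channels <- demodulate_recording(session$photometry,
                                   output_rate = output_rate)
  sig <- process_photometry(channels$ca, channels$iso, spec, method)

  scale <- compute_calibration(tracked_corners(session$tracking),
                               arena_side_cm = session$config$arena_cm)
  qc <- qc_filter_positions(session$tracking, scale)
  speed <- compute_speed(session$tracking, qc, scale)
  bouts <- detect_bouts(speed)
  responses <- classify_stimulus_responses(session$events, speed)

  epochs <- extract_stimulus_epochs(sig, session$events, speed)
  summ <- summarize_epochs(epochs, "stimulus")

  list(signal = sig, channels = channels, scale = scale, qc = qc,
       speed = speed, bouts = bouts, responses = responses,
       epochs = epochs, summary = summ)
}

#' Match recovered signal peaks to ground-truth transient peaks
#'
#' For each true transient peak time, finds the local maximum of the
#' processed signal within `+/- half_window` and reports the timing error.
#'
#' @param signal A `processed_signal`.
#' @param peak_times True transient peak times in seconds.
#' @param half_window Search half-width in seconds (default 0.5).
#' @return Data frame with `true_peak`, `found_peak`, `error_s`.
#' @export
match_transient_peaks <- function(signal, peak_times, half_window = 0.5) {
  t_sig <- trace_time(signal)
  res <- lapply(peak_times, function(tp) {
    sel <- which(t_sig >= tp - half_window & t_sig <= tp + half_window)
    if (!length(sel)) return(NULL)
    i <- sel[which.max(signal$z[sel])]
    data.frame(true_peak = tp, found_peak = t_sig[i],
               error_s = t_sig[i] - tp)
  })
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out)) out <- data.frame(true_peak = numeric(),
                                      found_peak = numeric(),
                                      error_s = numeric())
  out
}

#' Interval-level precision and recall of detected bouts
#'
#' A detected bout matches a true bout when both onset and offset agree
#' within `tol` seconds (one frame period by default at 20 fps).
#'
#' @param detected,truth [bout_set()]s.
#' @param tol Matching tolerance in seconds.
#' @return List with `precision`, `recall`, `n_detected`, `n_true`.
#' @export
bout_detection_scores <- function(detected, truth, tol = 0.05) {
  nd <- nrow(detected); nt <- nrow(truth)
  if (nd == 0 || nt == 0)
    return(list(precision = as.numeric(nd == 0 && nt == 0),
                recall = as.numeric(nt == 0),
                n_detected = nd, n_true = nt))
  matched <- outer(seq_len(nd), seq_len(nt), Vectorize(function(i, j)
    abs(detected$onset[i] - truth$onset[j]) <= tol + 1e-9 &&
      abs(detected$offset[i] - truth$offset[j]) <= tol + 1e-9))
  list(precision = mean(apply(matched, 1, any)),
       recall = mean(apply(matched, 2, any)),
       n_detected = nd, n_true = nt)
}
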