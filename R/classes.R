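# Core S3 containers shared across the pipeline stages.

#' Raw frequency-multiplexed photometry recording
#'
#' A single photodetector voltage trace carrying two sinusoidally
#' amplitude-modulated excitation channels: the Ca2+-dependent 465 nm LED
#' modulated at 211 Hz and the isosbestic 405 nm LED at 531 Hz. Sampling is
#' uniform; time is implicit as `t0 + (i - 1) / fs`.
#'
#' @param voltage Numeric vector, photodetector output in volts.
#' @param fs Sampling rate in Hz; must exceed twice the highest carrier.
#' @param carrier_hz Named numeric vector `c(ca = 211, iso = 531)`.
#' @param t0 Time of the first sample in seconds.
#' @return An object of class `"raw_photometry"`.
#' @export
raw_photometry <- function(voltage, fs, carrier_hz = c(ca = 211, iso = 531),
                           t0 = 0) {
  stopifnot(is.numeric(voltage), length(voltage) > 1)
  if (is.null(names(carrier_hz)) || !all(c("ca", "iso") %in% names(carrier_hz)))
    stop("carrier_hz must be a named vector with elements 'ca' and 'iso'",
         call. = FALSE)
  if (fs <= 2 * max(carrier_hz))
    stop("sampling rate ", fs, " Hz violates the Nyquist criterion for a ",
         max(carrier_hz), " Hz carrier (aliasing)", call. = FALSE)
  structure(list(voltage = as.numeric(voltage), fs = fs,
                 carrier_hz = carrier_hz, t0 = t0),
            class = "raw_photometry")
}

#' @export
print.raw_photometry <- function(x, ...) {
  cat(sprintf("<raw_photometry> %d samples @ %.2f Hz (%.1f s), carriers ca=%g Hz iso=%g Hz\n",
              length(x$voltage), x$fs, length(x$voltage) / x$fs,
              x$carrier_hz[["ca"]], x$carrier_hz[["iso"]]))
  invisible(x)
}

#' Uniformly sampled fluorescence channel trace
#'
#' One demodulated (or intermediate) fluorescence channel. `settle_s`
#' flags the span at each end that is contaminated by filter edge
#' transients; Z-scoring statistics exclude it.
#'
#' @param value Numeric vector of fluorescence values.
#' @param rate Sampling rate in Hz.
#' @param channel Channel label, e.g. `"ca"`, `"iso"` or `"ca_corrected"`.
#' @param t0 Time of the first sample in seconds.
#' @param settle_s Settling span flagged at each end, in seconds.
#' @return An object of class `"channel_trace"`.
#' @export
channel_trace <- function(value, rate, channel = "ca", t0 = 0, settle_s = 0) {
  stopifnot(is.numeric(value), length(value) > 1, rate > 0)
  if (!all(is.finite(value)))
    stop("channel trace contains non-finite values", call. = FALSE)
  structure(list(value = as.numeric(value), rate = rate, channel = channel,
                 t0 = t0, settle_s = settle_s),
            class = "channel_trace")
}

#' Time axis of a trace
#'
#' @param x A `channel_trace`, `processed_signal` or `speed_trace`.
#' @param ... Unused.
#' @return Numeric vector of sample times in seconds.
#' @export
trace_time <- function(x, ...) UseMethod("trace_time")

#' @export
trace_time.channel_trace <- function(x, ...) {
  x$t0 + (seq_along(x$value) - 1) / x$rate
}

#' @export
trace_time.processed_signal <- function(x, ...) {
  x$t0 + (seq_along(x$z) - 1) / x$rate
}

#' @export
trace_time.speed_trace <- function(x, ...) x$time

#' @export
print.channel_trace <- function(x, ...) {
  cat(sprintf("<channel_trace:%s> %d samples @ %g Hz (%.1f s)\n",
              x$channel, length(x$value), x$rate, length(x$value) / x$rate))
  invisible(x)
}

#' Set of behavioral bouts
#'
#' Intervals of locomotion, grooming or rearing. Within a kind, intervals
#' must be non-overlapping with `onset < offset`.
#'
#' @param onset,offset Numeric vectors of interval bounds in seconds.
#' @param kind Character vector: `"locomotion"`, `"grooming"` or `"rearing"`.
#' @param source `"detected"` (from the speed trace) or `"manual"`.
#' @return A data frame of class `"bout_set"` with columns
#'   `onset`, `offset`, `kind`, `source`, sorted by onset.
#' @export
bout_set <- function(onset = numeric(), offset = numeric(),
                     kind = character(), source = "detected") {
  n <- length(onset)
  stopifnot(length(offset) == n)
  kind <- rep_len(as.character(kind), n)
  source <- rep_len(as.character(source), n)
  bad_kind <- setdiff(unique(kind), c("locomotion", "grooming", "rearing"))
  if (length(bad_kind))
    stop("unknown bout kind(s): ", paste(bad_kind, collapse = ", "),
         call. = FALSE)
  if (any(offset <= onset))
    stop("every bout must have onset < offset", call. = FALSE)
  df <- data.frame(onset = as.numeric(onset), offset = as.numeric(offset),
                   kind = kind, source = source)
  df <- df[order(df$onset), , drop = FALSE]
  rownames(df) <- NULL
  for (k in unique(df$kind)) {
    sub <- df[df$kind == k, , drop = FALSE]
    if (nrow(sub) > 1 &&
        any(sub$onset[-1] < sub$offset[-nrow(sub)] - 1e-9))
      stop("overlapping ", k, " bouts", call. = FALSE)
  }
  class(df) <- c("bout_set", "data.frame")
  df
}

#' Stimulus event table
#'
#' Trials of sensory stimulation. `alignment_offset` shifts the alignment
#' point relative to the recorded onset; visual looming trials use 0.803 s
#' so that t = 0 marks the start of exponential disk expansion.
#'
#' @param onset Strictly increasing onset times in seconds.
#' @param modality `"sound"`, `"looming"` or `"airpuff"` per trial.
#' @param series_id Series identifier per trial.
#' @param trial_index 1-based trial index within its series; contiguous.
#' @param alignment_offset Alignment offset in seconds; defaults to 0.803
#'   for looming trials and 0 otherwise.
#' @return A data frame of class `"event_table"`.
#' @export
event_table <- function(onset, modality = "sound", series_id = 1L,
                        trial_index = NULL, alignment_offset = NULL) {
  n <- length(onset)
  if (n > 1 && any(diff(onset) <= 0))
    stop("event onsets must be strictly increasing", call. = FALSE)
  modality <- rep_len(as.character(modality), n)
  bad <- setdiff(unique(modality), c("sound", "looming", "airpuff"))
  if (length(bad))
    stop("unknown modality: ", paste(bad, collapse = ", "), call. = FALSE)
  series_id <- rep_len(series_id, n)
  if (is.null(trial_index))
    trial_index <- stats::ave(seq_len(n), series_id, FUN = seq_along)
  for (s in unique(series_id)) {
    ti <- sort(trial_index[series_id == s])
    if (!identical(as.integer(ti), seq_along(ti)))
      stop("trial_index must be contiguous and 1-based within series ", s,
           call. = FALSE)
  }
  if (is.null(alignment_offset))
    alignment_offset <- ifelse(modality == "looming", 0.803, 0)
  df <- data.frame(onset = as.numeric(onset), modality = modality,
                   series_id = series_id,
                   trial_index = as.integer(trial_index),
                   alignment_offset = rep_len(alignment_offset, n))
  class(df) <- c("event_table", "data.frame")
  df
}
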