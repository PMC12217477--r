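# Software lock-in (quadrature) demodulation.
#
# The photodetector sees the sum of two amplitude-modulated fluorescence
# channels. Multiplying by a reference sine and cosine at one carrier shifts
# that channel's envelope to DC (and to twice the carrier); a low-pass keeps
# the DC term. Taking the quadrature magnitude makes the recovery
# independent of the unknown carrier phase. The other carrier lands at the
# difference frequency (|531 - 211| = 320 Hz) and is removed by the same
# low-pass, which is what gives the channel isolation.

#' Lock-in demodulation of one carrier channel
#'
#' Recovers the amplitude envelope of a single modulated channel from a raw
#' photometry recording by quadrature demodulation: the voltage is mixed
#' with reference sine and cosine waves at the carrier frequency, both
#' products are low-pass filtered (4th-order Butterworth, zero-phase), and
#' the envelope is `2 * sqrt(I^2 + Q^2)`, resampled to `output_rate`.
#'
#' @param raw A [raw_photometry()] recording.
#' @param carrier Which channel to recover: `"ca"`, `"iso"`, or a carrier
#'   frequency in Hz that must match one of `raw$carrier_hz`.
#' @param output_rate Output sampling rate in Hz (default 100).
#' @param demod_lp_cutoff Low-pass cutoff of the demodulation filter in Hz
#'   (default 10). Must stay below half the carrier separation, otherwise
#'   the other channel leaks through.
#' @param lp_order Order of the demodulation low-pass (default 4).
#' @param settle_s Span flagged as filter settling at each end (default 1 s).
#' @return A [channel_trace()] with the recovered envelope.
#' @examples
#' fs <- 6103.52
#' t <- seq(0, 5, by = 1 / fs)
#' raw <- raw_photometry(2 * sin(2 * pi * 211 * t), fs)
#' env <- lockin_demodulate(raw, "ca")
#' mean(env$value[env$rate:(4 * env$rate)])  # ~2
#' @export
lockin_demodulate <- function(raw, carrier = "ca", output_rate = 100,
                              demod_lp_cutoff = 10, lp_order = 4,
                              settle_s = 1) {
  stopifnot(inherits(raw, "raw_photometry"))
  if (is.character(carrier)) {
    if (!carrier %in% names(raw$carrier_hz))
      stop("unknown carrier channel '", carrier, "'", call. = FALSE)
    channel <- carrier
    f_c <- raw$carrier_hz[[carrier]]
  } else {
    hit <- which(abs(raw$carrier_hz - carrier) < 1e-6)
    if (!length(hit))
      stop("carrier ", carrier, " Hz is not one of the recording's carriers",
           call. = FALSE)
    channel <- names(raw$carrier_hz)[hit[1]]
    f_c <- raw$carrier_hz[[hit[1]]]
  }
  if (output_rate > raw$fs)
    stop("output_rate must not exceed the raw sampling rate", call. = FALSE)
  sep <- min(abs(diff(sort(unique(raw$carrier_hz)))))
  if (demod_lp_cutoff >= sep / 2)
    stop("demod_lp_cutoff ", demod_lp_cutoff, " Hz >= half the carrier ",
         "separation (", sep, " Hz): channels would cross-talk",
         call. = FALSE)

  n <- length(raw$voltage)
  t <- raw$t0 + (seq_len(n) - 1) / raw$fs
  lp <- design_butter(lp_order, demod_lp_cutoff, raw$fs, "low")
  # initialize the low-pass at the mixer product's local mean (its value
  # averaged over one carrier cycle), not at a raw oscillation sample --
  # otherwise the first samples of the envelope are badly off and seed
  # edge transients in the much slower detrending filters downstream
  cyc <- max(2L, round(raw$fs / f_c))
  demod_arm <- function(ref) {
    p <- raw$voltage * ref
    filtfilt_steady(lp$b, lp$a, p,
                    x0 = mean(p[seq_len(cyc)]),
                    x1 = mean(p[(n - cyc + 1):n]))
  }
  i_arm <- demod_arm(sin(2 * pi * f_c * t))
  q_arm <- demod_arm(cos(2 * pi * f_c * t))
  env <- 2 * sqrt(i_arm^2 + q_arm^2)

  # envelope bandwidth is demod_lp_cutoff, far below output Nyquist, so
  # linear interpolation onto the output grid is alias-free
  t_out <- seq(raw$t0, t[n], by = 1 / output_rate)
  v_out <- approx(t, env, xout = t_out, rule = 2)$y
  channel_trace(v_out, rate = output_rate, channel = channel,
                t0 = raw$t0, settle_s = settle_s)
}

#' Demodulate both channels of a recording
#'
#' @inheritParams lockin_demodulate
#' @return A list with elements `ca` and `iso`, both [channel_trace()]s on a
#'   shared time base.
#' @export
demodulate_recording <- function(raw, output_rate = 100,
                                 demod_lp_cutoff = 10, lp_order = 4,
                                 settle_s = 1) {
  list(ca = lockin_demodulate(raw, "ca", output_rate, demod_lp_cutoff,
                              lp_order, settle_s),
       iso = lockin_demodulate(raw, "iso", output_rate, demod_lp_cutoff,
                               lp_order, settle_s))
}
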