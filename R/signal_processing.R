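# Isosbestic subtraction, Butterworth detrending and per-recording Z-score.

#' Detrending/smoothing filter specification
#'
#' The detrending cascade is a 3rd-order high-pass at 0.0051 Hz (removes
#' photobleaching drift; time constant roughly half a minute) followed by a
#' 5th-order low-pass at 2.29 Hz (smoothing above the Ca2+ indicator's
#' kinetics). `zero_phase` applies each filter forward-backward so event
#' latencies are not shifted; `causal` is kept for sensitivity analysis.
#'
#' @param hp_order,hp_cutoff High-pass order and cutoff (Hz).
#' @param lp_order,lp_cutoff Low-pass order and cutoff (Hz).
#' @param phase_mode `"zero_phase"` (default) or `"causal"`.
#' @return An object of class `"filter_spec"`.
#' @export
filter_spec <- function(hp_order = 3, hp_cutoff = 0.0051,
                        lp_order = 5, lp_cutoff = 2.29,
                        phase_mode = c("zero_phase", "causal")) {
  phase_mode <- match.arg(phase_mode)
  if (hp_cutoff >= lp_cutoff)
    stop("high-pass cutoff must lie below the low-pass cutoff", call. = FALSE)
  structure(list(hp_order = hp_order, hp_cutoff = hp_cutoff,
                 lp_order = lp_order, lp_cutoff = lp_cutoff,
                 phase_mode = phase_mode),
            class = "filter_spec")
}

#' Remove the motion artifact using the isosbestic channel
#'
#' At the isosbestic excitation wavelength the indicator's fluorescence is
#' Ca2+-independent, so the 405 nm channel carries only artifact (movement,
#' fiber bending, hemodynamics). `method = "fitted"` (default) regresses the
#' isosbestic channel onto the Ca2+ channel over the whole recording and
#' subtracts the fitted affine prediction, which is correct even when the
#' two channels see the artifact with different gains; `method = "direct"`
#' subtracts the isosbestic trace as-is.
#'
#' @param ca,iso [channel_trace()]s on the same time base.
#' @param method `"fitted"` or `"direct"`.
#' @return A `channel_trace` (channel `"ca_corrected"`) with attribute
#'   `"fit"` giving the fitted slope and intercept (`NA` under `direct`).
#' @export
subtract_isosbestic <- function(ca, iso, method = c("fitted", "direct")) {
  method <- match.arg(method)
  stopifnot(inherits(ca, "channel_trace"), inherits(iso, "channel_trace"))
  if (length(ca$value) != length(iso$value))
    stop("ca and iso traces differ in length", call. = FALSE)
  if (abs(ca$rate - iso$rate) > 1e-9 || abs(ca$t0 - iso$t0) > 1e-9)
    stop("ca and iso traces are not on the same time base", call. = FALSE)
  fit <- c(slope = NA_real_, intercept = NA_real_)
  if (method == "fitted") {
    v <- var(iso$value)
    if (v <= .Machine$double.eps * mean(iso$value)^2 + .Machine$double.xmin) {
      warning("isosbestic channel has zero variance; falling back to ",
              "direct subtraction")
      out <- ca$value - iso$value
    } else {
      a <- cov(ca$value, iso$value) / v
      b <- mean(ca$value) - a * mean(iso$value)
      out <- ca$value - (a * iso$value + b)
      fit <- c(slope = a, intercept = b)
    }
  } else {
    out <- ca$value - iso$value
  }
  res <- channel_trace(out, rate = ca$rate, channel = "ca_corrected",
                       t0 = ca$t0, settle_s = max(ca$settle_s, iso$settle_s))
  attr(res, "fit") <- fit
  attr(res, "method") <- method
  res
}

#' High-pass detrend and low-pass smooth a trace
#'
#' Applies the [filter_spec()] cascade: Butterworth high-pass (bleaching
#' removal) followed by Butterworth low-pass (smoothing). In `zero_phase`
#' mode each filter runs forward-backward, squaring its magnitude response
#' (gain 0.5 at the nominal cutoff) and cancelling phase delay.
#'
#' @param trace A [channel_trace()].
#' @param spec A [filter_spec()].
#' @return A filtered `channel_trace`.
#' @export
bandpass_detrend <- function(trace, spec = filter_spec()) {
  stopifnot(inherits(trace, "channel_trace"), inherits(spec, "filter_spec"))
  if (trace$rate <= 2 * spec$lp_cutoff)
    stop("low-pass cutoff at or above Nyquist", call. = FALSE)
  dur <- length(trace$value) / trace$rate
  if (dur < 600)
    warning("recording of ", round(dur), " s is short relative to the ",
            1 / spec$hp_cutoff, " s high-pass period; detrending may be ",
            "unreliable")
  hp <- design_butter(spec$hp_order, spec$hp_cutoff, trace$rate, "high")
  lp <- design_butter(spec$lp_order, spec$lp_cutoff, trace$rate, "low")
  hp_pad <- round(0.5 / spec$hp_cutoff * trace$rate)
  y <- apply_filter(hp, trace$value, spec$phase_mode, pad = hp_pad)
  y <- apply_filter(lp, y, spec$phase_mode)
  out <- trace
  out$value <- y
  out
}

#' Normalize a trace to a per-recording Z-score
#'
#' `z = (x - mean) / SD`, with the mean and sample SD (n - 1 denominator)
#' computed over the scored span: the settling margins flagged by the
#' demodulator (`settle_s` at each end) are excluded from the statistics,
#' though the whole trace is normalized with them.
#'
#' @param trace A [channel_trace()].
#' @param provenance Optional named list recorded in the result.
#' @return An object of class `"processed_signal"` with fields `z`, `rate`,
#'   `t0`, `scored` (logical mask of the scored span) and `provenance`.
#' @export
zscore_trace <- function(trace, provenance = list()) {
  stopifnot(inherits(trace, "channel_trace"))
  n <- length(trace$value)
  i0 <- floor(trace$settle_s * trace$rate) + 1
  i1 <- n - floor(trace$settle_s * trace$rate)
  if (i1 - i0 + 1 < 2)
    stop("fewer than 2 samples in the scored span", call. = FALSE)
  scored <- rep(FALSE, n)
  scored[i0:i1] <- TRUE
  x <- trace$value[scored]
  m <- mean(x)
  s <- sd(x)
  if (!is.finite(s) || s == 0)
    stop("degenerate signal: zero variance over the scored span",
         call. = FALSE)
  structure(list(z = (trace$value - m) / s, rate = trace$rate, t0 = trace$t0,
                 scored = scored,
                 provenance = c(provenance,
                                list(zscore_mean = m, zscore_sd = s,
                                     settle_s = trace$settle_s))),
            class = "processed_signal")
}

#' Construct a processed signal directly
#'
#' Wraps an already-normalized (or otherwise prepared) trace in the
#' container the alignment stage consumes. Prefer [zscore_trace()] for the
#' standard path.
#'
#' @param z Numeric vector of signal values.
#' @param rate Sampling rate in Hz.
#' @param t0 Time of the first sample in seconds.
#' @param scored Logical mask of the scored span (default all `TRUE`).
#' @param provenance Named list of processing metadata.
#' @return A `processed_signal`.
#' @export
processed_signal <- function(z, rate, t0 = 0, scored = NULL,
                             provenance = list()) {
  if (is.null(scored)) scored <- rep(TRUE, length(z))
  stopifnot(length(scored) == length(z), rate > 0)
  structure(list(z = as.numeric(z), rate = rate, t0 = t0, scored = scored,
                 provenance = provenance),
            class = "processed_signal")
}

#' @export
print.processed_signal <- function(x, ...) {
  cat(sprintf("<processed_signal> %d samples @ %g Hz (%.1f s), scored %d\n",
              length(x$z), x$rate, length(x$z) / x$rate, sum(x$scored)))
  invisible(x)
}

#' Full photometry processing chain
#'
#' Isosbestic subtraction, detrending/smoothing, Z-score — the path from a
#' pair of demodulated channel traces to the `processed_signal` consumed by
#' the alignment stage.
#'
#' @param ca,iso Demodulated [channel_trace()]s.
#' @param spec A [filter_spec()].
#' @param method Subtraction method, see [subtract_isosbestic()].
#' @return A `processed_signal`; its `provenance` records the filter spec,
#'   subtraction method and fitted coefficients.
#' @export
process_photometry <- function(ca, iso, spec = filter_spec(),
                               method = c("fitted", "direct")) {
  method <- match.arg(method)
  corrected <- subtract_isosbestic(ca, iso, method)
  detrended <- bandpass_detrend(corrected, spec)
  zscore_trace(detrended,
               provenance = list(filter_spec = unclass(spec),
                                 subtraction_method = method,
                                 subtraction_fit = attr(corrected, "fit")))
}
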