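# Zero-phase Butterworth filtering with steady-state initial conditions.
#
# signal::filtfilt() starts both passes from zero internal state, which at
# very low normalized cutoffs (the detrending high-pass sits at ~1e-4 of
# Nyquist) leaves edge transients that decay over minutes of signal. The
# helpers here reflect the trace at both ends and seed the difference
# equation with its step-response steady state, so a constant input maps to
# an exactly settled filter (the approach used by MATLAB's and SciPy's
# filtfilt).

#' Design a digital Butterworth filter
#'
#' Thin wrapper around [signal::butter()] that takes the cutoff in Hz
#' together with the sampling rate and validates it against Nyquist.
#'
#' @param order Filter order.
#' @param cutoff_hz Cutoff frequency in Hz.
#' @param rate Sampling rate in Hz.
#' @param type `"low"` or `"high"`.
#' @return An object of class `"Arma"` (coefficients `b`, `a`).
#' @keywords internal
design_butter <- function(order, cutoff_hz, rate, type = c("low", "high")) {
  type <- match.arg(type)
  w <- cutoff_hz / (rate / 2)
  if (!is.finite(w) || w <= 0 || w >= 1) {
    stop("cutoff ", cutoff_hz, " Hz is not inside (0, Nyquist) at rate ",
         rate, " Hz", call. = FALSE)
  }
  signal::butter(order, w, type = type)
}

# One causal pass with step-response initial conditions: the filter starts
# as if level `x0` had been applied forever. For smooth inputs x0 = x[1] is
# right; for oscillatory inputs (demodulation mixer products) the local
# mean is the appropriate level.
filter_steady <- function(b, a, x, x0 = x[1]) {
  g <- sum(b) / sum(a)  # DC gain
  as.numeric(signal::filter(b, a, x,
                            init.x = rep(x0, length(b) - 1),
                            init.y = rep(x0 * g, length(a) - 1)))
}

# Forward-backward (zero-phase) pass with odd-reflection padding. `x0`/`x1`
# override the assumed steady levels at the start of the forward pass and
# of the backward pass (the latter on the forward-pass *output*; it
# defaults to that output's settled end value).
filtfilt_steady <- function(b, a, x, pad = NULL, x0 = NULL, x1 = NULL) {
  n <- length(x)
  if (is.null(pad)) pad <- 3L * max(length(a), length(b))
  pad <- min(pad, n - 1L)
  if (pad > 0) {
    # even (symmetric) reflection: keeps the local level and the sign of
    # transients in the padding. Odd (point) reflection turns the sparse
    # positive Ca2+ transients near a boundary into negative spikes, which
    # a slow high-pass smears back into the signal as a baseline swing.
    ext <- c(x[(pad + 1):2], x, x[(n - 1):(n - pad)])
  } else {
    ext <- x
  }
  # Default steady levels: robust local level of the *unreflected* signal
  # over a span matched to the filter's memory (slowest pole time
  # constant). A single boundary sample misestimates the level by the full
  # noise SD; the median over the memory span is insensitive to both noise
  # and sparse transients.
  if (is.null(x0) || is.null(x1)) {
    pole <- max(Mod(polyroot(rev(a))))
    tau <- if (pole < 1 - 1e-12) -1 / log(pole) else n
    span <- min(n, max(1L, ceiling(5 * tau)))
    if (is.null(x0)) x0 <- median(x[seq_len(span)])
  }
  y <- filter_steady(b, a, ext, x0 = x0)
  if (is.null(x1)) x1 <- median(y[(pad + n - span + 1L):(pad + n)])
  y <- rev(filter_steady(b, a, rev(y), x0 = x1))
  if (pad > 0) y[(pad + 1):(pad + n)] else y
}

# Apply an Arma filter in the requested phase mode. `pad` (zero-phase only)
# lengthens the reflection padding; slow high-passes benefit from a pad of
# order half their cutoff period.
apply_filter <- function(flt, x, phase_mode = c("zero_phase", "causal"),
                         pad = NULL) {
  phase_mode <- match.arg(phase_mode)
  if (phase_mode == "zero_phase") {
    filtfilt_steady(flt$b, flt$a, x, pad = pad)
  } else {
    filter_steady(flt$b, flt$a, x)
  }
}
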