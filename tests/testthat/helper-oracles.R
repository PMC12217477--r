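# Independent oracles used across tests.

# Brute-force bout enumeration: walk the trace, collect every maximal run
# of supra-threshold valid frames, keep those long enough. Written as a
# direct scan, independently of the rle-based detector.
oracle_bouts <- function(speed_vals, tvec, fps, threshold = 3,
                         min_duration = 0.5) {
  sup <- !is.na(speed_vals) & speed_vals > threshold
  n <- length(sup)
  out <- NULL
  i <- 1L
  while (i <= n) {
    if (sup[i]) {
      j <- i
      while (j < n && sup[j + 1L]) j <- j + 1L
      if ((tvec[j] - tvec[i]) + 1 / fps >= min_duration - 1e-9)
        out <- rbind(out, c(tvec[i], tvec[j] + 1 / fps))
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (is.null(out)) matrix(numeric(), ncol = 2) else out
}

# Random speed trace with missing frames, mixed around the 3 cm/s
# threshold so boundary runs of every length occur.
random_speed_trace <- function(n = 60, fps = 20) {
  v <- sample(c(NA, 0, 1, 2.5, 3, 3.0001, 4, 8, 20), n, replace = TRUE,
              prob = c(1, 2, 2, 1, 1, 1, 2, 2, 1))
  speed_trace(v, fps = fps)
}

# Table-lookup Student-Newman-Keuls oracle for 3 groups: explicit critical
# values from the studentized-range quantile function, explicit stepwise
# logic written out case by case.
snk3_oracle <- function(means, se, df_err, alpha = 0.05) {
  ord <- order(means)
  m <- means[ord]
  q31 <- (m[3] - m[1]) / se
  crit <- function(p) qtukey(1 - alpha, p, df_err)
  dec <- matrix(FALSE, 3, 3)  # in ordered positions
  if (q31 >= crit(3)) {
    dec[1, 3] <- TRUE
    dec[1, 2] <- (m[2] - m[1]) / se >= crit(2)
    dec[2, 3] <- (m[3] - m[2]) / se >= crit(2)
  }
  # map back to original group indices: dec[i, j] over ordered positions
  list(order = ord, significant = dec)
}

# Single-pass amplitude of a sinusoid in a trace, by least squares on
# quadrature regressors over a trimmed interior.
fitted_amplitude <- function(y, t, freq, trim = range(t)) {
  sel <- t >= trim[1] & t <= trim[2]
  fit <- lm(y[sel] ~ sin(2 * pi * freq * t[sel]) + cos(2 * pi * freq * t[sel]))
  sqrt(sum(coef(fit)[2:3]^2))
}

# Small fast session for module-level pipeline tests.
small_session_config <- function(...) {
  session_config(duration = 200, n_trials = 3, first_stim = 15,
                 stim_interval_mean = 60.1, stim_interval_sd = 0.3,
                 spont_bouts = 2, spont_rate = 0.01, ...)
}
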