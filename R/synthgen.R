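# Synthetic session generator.
#
# Builds complete sessions -- raw carrier-modulated photometry, open-field
# pose tracking, stimulus trains and behavior annotations -- from known
# ground truth, so that every downstream stage of the pipeline can be
# verified against what was injected.

#' Ca2+ transient kernel
#'
#' Difference-of-exponentials kernel emulating a fast genetically encoded
#' Ca2+ indicator (jGCaMP7f-like kinetics: sharp rise, sub-second decay),
#' normalized so its peak equals `amplitude`.
#'
#' @param rise_tau Rise time constant in seconds (> 0).
#' @param decay_tau Decay time constant in seconds (> rise_tau).
#' @param amplitude Peak amplitude in fluorescence units (> 0).
#' @return An object of class `"transient_kernel"`.
#' @export
transient_kernel <- function(rise_tau = 0.02, decay_tau = 0.2, amplitude = 5) {
  if (rise_tau <= 0 || decay_tau <= 0 || amplitude <= 0)
    stop("kernel time constants and amplitude must be positive", call. = FALSE)
  if (decay_tau <= rise_tau)
    stop("decay_tau must exceed rise_tau", call. = FALSE)
  structure(list(rise_tau = rise_tau, decay_tau = decay_tau,
                 amplitude = amplitude),
            class = "transient_kernel")
}

#' Time of the kernel peak after event onset
#'
#' Closed form for the peak of `exp(-t/decay) - exp(-t/rise)`.
#'
#' @param kernel A [transient_kernel()].
#' @return Peak latency in seconds.
#' @export
kernel_peak_time <- function(kernel) {
  with(kernel, rise_tau * decay_tau / (decay_tau - rise_tau) *
         log(decay_tau / rise_tau))
}

#' Evaluate a transient kernel
#'
#' @param kernel A [transient_kernel()].
#' @param t Times in seconds relative to event onset (0 at onset).
#' @return Kernel values; 0 for `t < 0`, peak equal to `kernel$amplitude`.
#' @export
eval_kernel <- function(kernel, t) {
  tp <- kernel_peak_time(kernel)
  peak <- exp(-tp / kernel$decay_tau) - exp(-tp / kernel$rise_tau)
  out <- ifelse(t < 0, 0,
                exp(-t / kernel$decay_tau) - exp(-t / kernel$rise_tau))
  out * kernel$amplitude / peak
}

#' Generate a Poisson train of Ca2+ transients
#'
#' Homogeneous Poisson event times over `[0, duration)` with kernel-shaped
#' transients superposed on a uniformly sampled clean trace.
#'
#' @param rate Event rate in events/s (>= 0).
#' @param kernel A [transient_kernel()].
#' @param duration Trace duration in seconds (> 0).
#' @param fs Sampling rate of the clean trace in Hz.
#' @param amplitude_cv Coefficient of variation of per-event amplitudes
#'   (lognormal, default 0 = identical amplitudes).
#' @param seed Optional RNG seed; omit to draw from the current RNG stream.
#' @return A list: `times` (event onsets, s), `amplitudes`, `peak_times`
#'   (onset + analytic kernel peak latency), `trace` (numeric vector),
#'   `fs`.
#' @export
generate_transient_train <- function(rate, kernel = transient_kernel(),
                                     duration, fs = 100, amplitude_cv = 0,
                                     seed = NULL) {
  if (rate < 0) stop("rate must be non-negative", call. = FALSE)
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n_ev <- rpois(1, rate * duration)
  times <- sort(runif(n_ev, 0, duration))
  amps <- if (amplitude_cv > 0 && n_ev > 0) {
    sdl <- sqrt(log(1 + amplitude_cv^2))
    kernel$amplitude * exp(rnorm(n_ev, -sdl^2 / 2, sdl))
  } else rep(kernel$amplitude, n_ev)
  trace <- superpose_transients(times, amps, kernel, duration, fs)
  list(times = times, amplitudes = amps,
       peak_times = times + kernel_peak_time(kernel),
       trace = trace, fs = fs)
}

# Add kernel-shaped transients at given times/amplitudes to a zero trace.
superpose_transients <- function(times, amplitudes, kernel, duration, fs) {
  n <- round(duration * fs)
  trace <- numeric(n)
  if (!length(times)) return(trace)
  support <- ceiling((kernel$decay_tau * 8 + kernel_peak_time(kernel)) * fs)
  for (k in seq_along(times)) {
    i0 <- floor(times[k] * fs) + 1
    frac <- times[k] - (i0 - 1) / fs
    idx <- i0:min(i0 + support, n)
    if (idx[1] > n) next
    # evaluate at the exact offset of the grid from the event time
    vals <- eval_kernel(kernel, (seq_along(idx) - 1) / fs - frac) /
      kernel$amplitude
    trace[idx] <- trace[idx] + amplitudes[k] * vals[seq_along(idx)]
  }
  trace
}

#' Synthesize a raw frequency-multiplexed photometry voltage
#'
#' Builds the photodetector voltage seen by the acquisition system: the
#' Ca2+-dependent envelope (baseline + clean transient trace + shared motion
#' artifact scaled by `mixing`) modulates the 211 Hz carrier, the isosbestic
#' envelope (baseline + artifact) modulates the 531 Hz carrier, both
#' envelopes decay with a shared double-exponential bleaching profile, and
#' white measurement noise is added.
#'
#' @param clean_trace Clean Ca2+ transient trace at `env_rate` Hz.
#' @param artifact_trace Shared motion-artifact trace at `env_rate` Hz (same
#'   length as `clean_trace`), or `NULL` for none.
#' @param fs Raw sampling rate in Hz (default 6103.52).
#' @param carrier_hz Named carriers, `c(ca = 211, iso = 531)`.
#' @param env_rate Sampling rate of the envelope inputs in Hz.
#' @param baselines Named LED baselines `c(ca = , iso = )` in volts.
#' @param mixing Artifact gain in the Ca2+ channel relative to the
#'   isosbestic channel (the recoverable mixing coefficient).
#' @param bleach List `(a1, tau1, a2, tau2)`: the envelopes are multiplied
#'   by `(1 - a1 - a2) + a1 exp(-t/tau1) + a2 exp(-t/tau2)`.
#' @param noise_sd White-noise SD in volts.
#' @param seed Optional RNG seed.
#' @return A list: `raw` (a [raw_photometry()]) and `truth` (list with the
#'   injected envelopes, mixing coefficient and bleach parameters).
#' @export
synthesize_raw_photometry <- function(clean_trace, artifact_trace = NULL,
                                      fs = 6103.52,
                                      carrier_hz = c(ca = 211, iso = 531),
                                      env_rate = 100,
                                      baselines = c(ca = 2, iso = 1),
                                      mixing = 1.5,
                                      bleach = list(a1 = 0.1, tau1 = 300,
                                                    a2 = 0.1, tau2 = 2000),
                                      noise_sd = 0.002, seed = NULL) {
  if (fs <= 2 * max(carrier_hz))
    stop("raw sampling rate violates Nyquist for the carriers (aliasing)",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n_env <- length(clean_trace)
  if (is.null(artifact_trace)) artifact_trace <- numeric(n_env)
  stopifnot(length(artifact_trace) == n_env)
  duration <- n_env / env_rate
  n <- round(duration * fs)
  t <- (0:(n - 1)) / fs
  t_env <- (0:(n_env - 1)) / env_rate
  up <- function(x) approx(t_env, x, xout = t, rule = 2)$y
  b_t <- (1 - bleach$a1 - bleach$a2) +
    bleach$a1 * exp(-t / bleach$tau1) + bleach$a2 * exp(-t / bleach$tau2)
  env_ca <- b_t * (baselines[["ca"]] + up(clean_trace) +
                     mixing * up(artifact_trace))
  env_iso <- b_t * (baselines[["iso"]] + up(artifact_trace))
  v <- env_ca * sin(2 * pi * carrier_hz[["ca"]] * t) +
    env_iso * sin(2 * pi * carrier_hz[["iso"]] * t)
  if (noise_sd > 0) v <- v + rnorm(n, 0, noise_sd)
  list(raw = raw_photometry(v, fs, carrier_hz),
       truth = list(mixing_coefficient = mixing, bleach = bleach,
                    baselines = baselines, env_rate = env_rate,
                    clean_trace = clean_trace,
                    artifact_trace = artifact_trace))
}

#' Synthesize an open-field tracking table from a bout plan
#'
#' Builds a body-center trajectory made of constant-speed frame steps with a
#' smoothly wandering heading, so the frame-to-frame speed is exactly the
#' planned speed. Planned bouts are snapped to the camera frame grid; the
#' returned `true_bouts` are the snapped intervals, which the bout detector
#' recovers exactly on the noiseless track.
#'
#' @param bout_plan Data frame with columns `onset` (s), `duration` (s) and
#'   `speed` (cm/s) for each planned locomotor bout, or `NULL`/empty for a
#'   stationary-paced session.
#' @param duration Session duration in seconds.
#' @param arena_cm Arena side length in cm (default 40).
#' @param fps Camera frame rate in Hz (default 20).
#' @param px_per_cm Nominal camera scale (default 10 px/cm).
#' @param base_speed Inter-bout ambling speed in cm/s (must stay below the
#'   3 cm/s bout threshold; default 1).
#' @param noise_px SD of Gaussian jitter added to the reported body-center
#'   pixels (default 0 = ideal tracking).
#' @param likelihood Reported tracking likelihood for every frame.
#' @param seed Optional RNG seed.
#' @return A list: `tracking` (a `tracking_table`) and `true_bouts`
#'   (a [bout_set()] of the frame-snapped planned bouts).
#' @export
synthesize_tracking <- function(bout_plan = NULL, duration, arena_cm = 40,
                                fps = 20, px_per_cm = 10, base_speed = 1,
                                noise_px = 0, likelihood = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(bout_plan) || !nrow(bout_plan))
    bout_plan <- data.frame(onset = numeric(), duration = numeric(),
                            speed = numeric())
  stopifnot(all(c("onset", "duration", "speed") %in% names(bout_plan)))
  if (nrow(bout_plan)) {
    if (any(bout_plan$speed <= 3))
      stop("planned bout speeds must exceed the 3 cm/s threshold",
           call. = FALSE)
    if (any(bout_plan$duration < 0.5 - 1e-9))
      stop("planned bout durations must be at least 0.5 s", call. = FALSE)
  }
  if (base_speed >= 3)
    stop("base_speed must stay below the 3 cm/s bout threshold",
         call. = FALSE)
  n_frames <- round(duration * fps) + 1
  tvec <- (0:(n_frames - 1)) / fps

  # snap the plan to the frame grid: bout b makes frames (k+1)..(k+m)
  # supra-threshold (the step INTO frame i sets speed[i]), so the detector
  # sees onset t[k+1] = k/fps and offset t[k+m] + 1/fps = (k+m)/fps
  step_speed <- rep(base_speed, n_frames)  # speed of the step INTO frame i
  step_speed[1] <- 0
  plan <- bout_plan[order(bout_plan$onset), , drop = FALSE]
  onsets <- offsets <- numeric(nrow(plan))
  last_supra <- 0L
  for (b in seq_len(nrow(plan))) {
    k <- round(plan$onset[b] * fps)
    m <- round(plan$duration[b] * fps)
    if (k < 1 || k + 1 <= last_supra + 1)  # >= 1 calm frame between bouts
      stop("planned bouts overlap or abut on the frame grid", call. = FALSE)
    if (k + m > n_frames)
      stop("planned bout extends past the session end", call. = FALSE)
    step_speed[(k + 1):(k + m)] <- plan$speed[b]
    onsets[b] <- k / fps
    offsets[b] <- (k + m) / fps
    last_supra <- k + m
  }

  # constant-speed steps with a wandering heading, reflected off a margin
  margin <- 2
  pos <- matrix(0, n_frames, 2)
  pos[1, ] <- arena_cm / 2
  heading <- runif(1, 0, 2 * pi)
  for (i in 2:n_frames) {
    heading <- heading + rnorm(1, 0, 0.25)
    step <- step_speed[i] / fps
    cand <- pos[i - 1, ] + step * c(cos(heading), sin(heading))
    if (any(cand < margin) || any(cand > arena_cm - margin)) {
      ctr <- c(arena_cm / 2, arena_cm / 2)
      heading <- atan2(ctr[2] - pos[i - 1, 2], ctr[1] - pos[i - 1, 1]) +
        rnorm(1, 0, 0.2)
      cand <- pos[i - 1, ] + step * c(cos(heading), sin(heading))
    }
    pos[i, ] <- cand
  }

  corners_px <- matrix(c(0, 0, arena_cm, 0, arena_cm, arena_cm, 0, arena_cm),
                       ncol = 2, byrow = TRUE) * px_per_cm
  body_px <- pos * px_per_cm
  if (noise_px > 0)
    body_px <- body_px + matrix(rnorm(2 * n_frames, 0, noise_px), ncol = 2)
  # tail base trails the body center; parsed downstream but unused
  tail_px <- body_px + matrix(rep(c(-8, 0), each = n_frames), ncol = 2)

  parts <- list(
    bodycenter = data.frame(x = body_px[, 1], y = body_px[, 2],
                            likelihood = rep(likelihood, n_frames)),
    tailbase = data.frame(x = tail_px[, 1], y = tail_px[, 2],
                          likelihood = rep(likelihood, n_frames)))
  for (k in 1:4) {
    parts[[paste0("corner", k)]] <-
      data.frame(x = rep(corners_px[k, 1], n_frames),
                 y = rep(corners_px[k, 2], n_frames),
                 likelihood = rep(1, n_frames))
  }
  tracking <- structure(list(time = tvec, parts = parts, fps = fps,
                             arena_cm = arena_cm),
                        class = "tracking_table")
  true_bouts <- if (length(onsets))
    bout_set(onsets, offsets, "locomotion", source = "detected")
  else bout_set()
  list(tracking = tracking, true_bouts = true_bouts)
}

#' @export
print.tracking_table <- function(x, ...) {
  cat(sprintf("<tracking_table> %d frames @ %g fps, parts: %s\n",
              length(x$time), x$fps, paste(names(x$parts), collapse = ", ")))
  invisible(x)
}

#' Default configuration for a synthetic session
#'
#' The defaults emulate the recorded regime: a 600 s open-field session,
#' stimuli every 60.1 +/- 0.3 s, jGCaMP7f-like transient kinetics, camera at
#' 20 fps over a 40 x 40 cm arena, carriers at 211/531 Hz sampled at
#' 6103.52 Hz. `habituation` is a per-trial amplitude multiplier (all 1 by
#' default, i.e. no habituation).
#'
#' @param duration Session length in seconds.
#' @param n_trials Number of stimulus trials.
#' @param stim_interval_mean,stim_interval_sd Stimulus spacing (s).
#' @param first_stim Earliest stimulus onset (s).
#' @param modality Stimulus modality for all trials.
#' @param responder_fraction Fraction of trials given a stimulus-locked
#'   transient plus an evoked locomotor bout.
#' @param habituation Per-trial amplitude multipliers (length `n_trials`).
#' @param kernel A [transient_kernel()].
#' @param evoked_latency Latency of the evoked transient after stimulus (s).
#' @param bout_latency Latency of the evoked bout onset after stimulus (s).
#' @param bout_duration,bout_speed Evoked bout parameters (s, cm/s).
#' @param spont_rate Spontaneous transient rate (events/s).
#' @param spont_bouts Number of spontaneous locomotor bouts.
#' @param n_grooming,n_rearing Annotated bout counts.
#' @param mixing,baselines,bleach,noise_sd,fs_raw,env_rate,artifact_sd
#'   Photometry synthesis parameters, see [synthesize_raw_photometry()];
#'   `artifact_sd` scales the shared low-frequency motion artifact.
#' @param fps,arena_cm,px_per_cm,tracking_noise_px Tracking parameters.
#' @return A named list of class `"session_config"`.
#' @export
session_config <- function(duration = 600, n_trials = 10,
                           stim_interval_mean = 60.1, stim_interval_sd = 0.3,
                           first_stim = 30, modality = "sound",
                           responder_fraction = 0.5,
                           habituation = rep(1, n_trials),
                           kernel = transient_kernel(),
                           evoked_latency = 0.3, bout_latency = 0.8,
                           bout_duration = 1.5, bout_speed = 12,
                           spont_rate = 0.02, spont_bouts = 6,
                           n_grooming = 3, n_rearing = 3,
                           mixing = 1.5, baselines = c(ca = 2, iso = 1),
                           bleach = list(a1 = 0.1, tau1 = 300,
                                         a2 = 0.1, tau2 = 2000),
                           noise_sd = 0.002, fs_raw = 6103.52,
                           env_rate = 100, artifact_sd = 0.05,
                           fps = 20, arena_cm = 40, px_per_cm = 10,
                           tracking_noise_px = 0) {
  cfg <- as.list(environment())
  if (length(cfg$habituation) != n_trials)
    stop("habituation must have one multiplier per trial", call. = FALSE)
  if (responder_fraction < 0 || responder_fraction > 1)
    stop("responder_fraction must lie in [0, 1]", call. = FALSE)
  class(cfg) <- "session_config"
  cfg
}

#' Synthesize a complete session with ground truth
#'
#' Generates the full bundle a real session would provide — raw multiplexed
#' photometry, pose tracking, a stimulus event table and manual-style
#' grooming/rearing annotations — from known ground truth. A configurable
#' fraction of trials are responders: they receive a stimulus-locked Ca2+
#' transient (amplitude scaled by the per-trial habituation multiplier) and
#' an evoked locomotor bout whose onset falls inside the 5 s response
#' window. Spontaneous transients and bouts are placed clear of all response
#' windows so the ground-truth response flags stay exact.
#'
#' @param config A [session_config()].
#' @param seed Integer seed; the same `(config, seed)` pair always yields an
#'   identical bundle.
#' @return An object of class `"photometry_session"`: a list with elements
#'   `photometry` ([raw_photometry()]), `tracking`, `events`
#'   ([event_table()]), `annotations` ([bout_set()]), `truth` and `config`.
#'   `truth` holds `transient_times`, `transient_amplitudes`,
#'   `transient_peak_times`, `true_bouts`, `true_response_flags`,
#'   `mixing_coefficient` and `habituation`.
#' @export
synthesize_session <- function(config = session_config(), seed = 1) {
  stopifnot(inherits(config, "session_config"))
  set.seed(seed)
  cfg <- config
  dur <- cfg$duration

  # --- stimulus train -------------------------------------------------
  # jittered spacing, truncated at +/- 2 SD so the spacing stays within
  # the emulated regime's bounds
  m <- cfg$stim_interval_mean; s <- cfg$stim_interval_sd
  u <- runif(max(cfg$n_trials - 1, 0),
             pnorm(m - 2 * s, m, s), pnorm(m + 2 * s, m, s))
  gaps <- qnorm(u, m, s)
  onsets <- cfg$first_stim + c(0, cumsum(gaps))
  if (cfg$n_trials > 0 && (tail(onsets, 1) + 15 > dur))
    stop("session too short for ", cfg$n_trials, " trials at ",
         cfg$stim_interval_mean, " s spacing", call. = FALSE)
  events <- event_table(onsets, modality = cfg$modality)

  # --- responder assignment ------------------------------------------
  n_resp <- round(cfg$responder_fraction * cfg$n_trials)
  flags <- rep(FALSE, cfg$n_trials)
  if (n_resp > 0) flags[sample(cfg$n_trials, n_resp)] <- TRUE

  # --- transients -----------------------------------------------------
  ev_times <- onsets[flags] + cfg$evoked_latency
  ev_amps <- cfg$kernel$amplitude * cfg$habituation[flags]
  # spontaneous transients anywhere outside a guard around each stimulus
  n_spont <- rpois(1, cfg$spont_rate * dur)
  sp_times <- numeric(0)
  if (n_spont > 0) {
    cand <- runif(3 * n_spont + 20, 2, dur - 3)
    near_stim <- vapply(cand, function(tt)
      any(tt > onsets - 2 & tt < onsets + 12), logical(1))
    cand <- sort(head(cand[!near_stim], n_spont))
    # 2 s refractory separation so every injected event has its own
    # identifiable peak in the trace (truth must stay a usable oracle)
    for (tt in cand) {
      if (!length(sp_times) || tt - tail(sp_times, 1) >= 2)
        sp_times <- c(sp_times, tt)
    }
  }
  sp_amps <- rep(cfg$kernel$amplitude, length(sp_times))
  all_times <- c(ev_times, sp_times)
  all_amps <- c(ev_amps, sp_amps)
  ord <- order(all_times)
  all_times <- all_times[ord]
  all_amps <- all_amps[ord]
  clean <- superpose_transients(all_times, all_amps, cfg$kernel, dur,
                                cfg$env_rate)

  # --- shared motion artifact (low-frequency wander) ------------------
  n_env <- round(dur * cfg$env_rate)
  artifact <- numeric(n_env)
  if (cfg$artifact_sd > 0) {
    lp1 <- design_butter(2, 0.5, cfg$env_rate, "low")
    artifact <- filtfilt_steady(lp1$b, lp1$a, rnorm(n_env))
    artifact <- artifact / sd(artifact) * cfg$artifact_sd
  }

  phot <- synthesize_raw_photometry(clean, artifact, fs = cfg$fs_raw,
                                    env_rate = cfg$env_rate,
                                    baselines = cfg$baselines,
                                    mixing = cfg$mixing,
                                    bleach = cfg$bleach,
                                    noise_sd = cfg$noise_sd)

  # --- locomotor bout plan -------------------------------------------
  evoked_plan <- data.frame(onset = onsets[flags] + cfg$bout_latency,
                            duration = rep(cfg$bout_duration, sum(flags)),
                            speed = rep(cfg$bout_speed, sum(flags)))
  # spontaneous bouts clear of every response window (and of each other)
  sp_on <- numeric(0)
  guard_lo <- onsets - 3
  guard_hi <- onsets + 5 + cfg$bout_duration + 1
  tries <- 0
  while (length(sp_on) < cfg$spont_bouts && tries < 500) {
    tries <- tries + 1
    cand <- runif(1, 5, dur - 5)
    in_guard <- any(cand < guard_hi & cand + cfg$bout_duration > guard_lo)
    near_other <- length(sp_on) &&
      any(abs(cand - sp_on) < cfg$bout_duration + 1)
    if (!in_guard && !near_other) sp_on <- c(sp_on, cand)
  }
  spont_plan <- data.frame(onset = sp_on,
                           duration = rep(cfg$bout_duration, length(sp_on)),
                           speed = rep(cfg$bout_speed, length(sp_on)))
  plan <- rbind(evoked_plan, spont_plan)
  trk <- synthesize_tracking(plan, duration = dur, arena_cm = cfg$arena_cm,
                             fps = cfg$fps, px_per_cm = cfg$px_per_cm,
                             noise_px = cfg$tracking_noise_px)

  # --- annotations (grooming / rearing in quiet stretches) ------------
  annot_df <- data.frame(onset = numeric(), offset = numeric(),
                         kind = character())
  want <- c(rep("grooming", cfg$n_grooming), rep("rearing", cfg$n_rearing))
  placed <- trk$true_bouts[, c("onset", "offset")]
  for (k in want) {
    d <- if (k == "grooming") runif(1, 4, 8) else runif(1, 2, 5)
    for (try in 1:200) {
      o <- runif(1, 5, dur - d - 5)
      busy <- nrow(placed) &&
        any(o < placed$offset + 1 & o + d > placed$onset - 1)
      if (!busy) {
        annot_df <- rbind(annot_df,
                          data.frame(onset = o, offset = o + d, kind = k))
        placed <- rbind(placed, data.frame(onset = o, offset = o + d))
        break
      }
    }
  }
  annotations <- bout_set(annot_df$onset, annot_df$offset, annot_df$kind,
                          source = "manual")

  truth <- list(transient_times = all_times,
                transient_amplitudes = all_amps,
                transient_peak_times = all_times + kernel_peak_time(cfg$kernel),
                true_bouts = trk$true_bouts,
                true_response_flags = flags,
                mixing_coefficient = cfg$mixing,
                habituation = cfg$habituation,
                clean_trace = clean, artifact_trace = artifact,
                env_rate = cfg$env_rate)
  structure(list(photometry = phot$raw, tracking = trk$tracking,
                 events = events, annotations = annotations,
                 truth = truth, config = cfg),
            class = "photometry_session")
}

#' Synthesize a speed-coupled signal/speed session
#'
#' A lightweight generator for testing the speed-bin regression: locomotor
#' bouts at speeds spanning `speed_range` are laid on a frame-accurate
#' speed trace, and the companion signal is `slope * speed` (speed linearly
#' interpolated onto the signal grid) plus white noise — i.e. neural
#' activity linearly coupled to locomotor speed. No carrier synthesis or
#' demodulation is involved.
#'
#' @param slope Programmed signal change per cm/s.
#' @param n_bouts Number of bouts.
#' @param duration Session length in seconds.
#' @param speed_range Range of bout speeds in cm/s (all > 3).
#' @param bout_duration Bout length in seconds.
#' @param noise_sd SD of the white noise added to the signal.
#' @param signal_rate Signal sampling rate in Hz.
#' @param fps Frame rate of the speed trace.
#' @param seed Optional RNG seed.
#' @return A list: `signal` (a [processed_signal()]), `speed`
#'   (a `speed_trace`), `bouts` (true [bout_set()]), `slope`.
#' @export
synthesize_speed_coupled <- function(slope = 0.1, n_bouts = 12,
                                     duration = 300,
                                     speed_range = c(4, 20),
                                     bout_duration = 2, noise_sd = 0.5,
                                     signal_rate = 100, fps = 20,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  slots <- seq(5, duration - bout_duration - 5, length.out = n_bouts)
  plan <- data.frame(onset = slots,
                     duration = rep(bout_duration, n_bouts),
                     speed = runif(n_bouts, speed_range[1], speed_range[2]))
  trk <- synthesize_tracking(plan, duration = duration, fps = fps)
  scale <- compute_calibration(tracked_corners(trk$tracking))
  qc <- qc_filter_positions(trk$tracking, scale)
  speed <- compute_speed(trk$tracking, qc, scale)
  n <- round(duration * signal_rate)
  t_sig <- (0:(n - 1)) / signal_rate
  sp <- speed$speed
  sp[is.na(sp)] <- 0
  coupled <- approx(speed$time, sp, xout = t_sig, rule = 2)$y * slope
  z <- coupled + rnorm(n, 0, noise_sd)
  list(signal = processed_signal(z, signal_rate),
       speed = speed, bouts = trk$true_bouts, slope = slope)
}

#' @export
print.photometry_session <- function(x, ...) {
  cat(sprintf(
    "<photometry_session> %.0f s, %d trials (%s), %d true bouts, %d transients\n",
    x$config$duration, nrow(x$events), x$config$modality,
    nrow(x$truth$true_bouts), length(x$truth$transient_times)))
  invisible(x)
}
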