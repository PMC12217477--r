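# Trial alignment: raw-time epochs around stimuli, duration-normalized
# epochs around motor bouts, and per-trial window means.

#' Extract stimulus-aligned raw-time epochs
#'
#' Per trial, the Z-scored signal is sampled onto a common relative time
#' axis spanning `window` (default -5 s to +10 s) at the signal rate; the
#' alignment point is `onset + alignment_offset` (0.803 s for visual
#' looming). Locomotor speed, when supplied, is averaged into 50 ms bins
#' over the same span. Trials whose window extends beyond the recording are
#' dropped with a warning.
#'
#' @param signal A `processed_signal`.
#' @param events An [event_table()].
#' @param speed Optional `speed_trace` companion.
#' @param window Numeric length-2 epoch span in seconds (default
#'   `c(-5, 10)`).
#' @param speed_bin_s Speed bin width in seconds (default 0.05).
#' @return An object of class `"aligned_epochs"`: `matrix` (trials x time
#'   samples), `time_axis` (left edge convention, `[window[1], window[2])`),
#'   `speed` (trials x bins or `NULL`), `speed_bin_centers`, `meta`
#'   (per-trial modality/series/trial_index/onset), `dropped`.
#' @export
extract_stimulus_epochs <- function(signal, events, speed = NULL,
                                    window = c(-5, 10), speed_bin_s = 0.05) {
  stopifnot(inherits(signal, "processed_signal"))
  rate <- signal$rate
  nw <- round((window[2] - window[1]) * rate)
  time_axis <- window[1] + (0:(nw - 1)) / rate
  n_sig <- length(signal$z)
  nb <- round((window[2] - window[1]) / speed_bin_s)
  bin_edges <- window[1] + speed_bin_s * (0:nb)

  t_sig <- trace_time(signal)
  t_end <- t_sig[n_sig]
  rows <- list(); srows <- list(); keep <- logical(nrow(events))
  for (i in seq_len(nrow(events))) {
    a <- events$onset[i] + events$alignment_offset[i]
    if (a + window[1] < signal$t0 - 1e-9 ||
        a + time_axis[nw] > t_end + 1e-9) next
    keep[i] <- TRUE
    # resample onto the exact relative axis (alignment points need not
    # fall on the sample grid)
    rows[[length(rows) + 1]] <- approx(t_sig, signal$z,
                                       xout = a + time_axis)$y
    if (!is.null(speed)) {
      rel <- speed$time - a
      sel <- rel >= window[1] & rel < window[2] & !is.na(speed$speed)
      b <- findInterval(rel[sel], bin_edges, rightmost.closed = FALSE)
      m <- rep(NA_real_, nb)
      if (any(sel)) {
        agg <- tapply(speed$speed[sel], b, mean)
        m[as.integer(names(agg))] <- agg
      }
      srows[[length(srows) + 1]] <- m
    }
  }
  if (any(!keep))
    warning(sum(!keep), " trial(s) dropped: epoch window outside recording")
  if (!length(rows))
    stop("no usable trials: every epoch window falls outside the recording",
         call. = FALSE)
  structure(list(
    matrix = do.call(rbind, rows),
    time_axis = time_axis,
    speed = if (length(srows)) do.call(rbind, srows) else NULL,
    speed_bin_centers = bin_edges[-(nb + 1)] + speed_bin_s / 2,
    meta = events[keep, , drop = FALSE],
    dropped = events[!keep, , drop = FALSE]),
    class = "aligned_epochs")
}

#' Extract duration-normalized epochs around motor bouts
#'
#' Time is rescaled per bout so onset maps to 0 and offset to 1
#' (`u = (t - onset) / duration`); samples with `u` in `[-0.5, 1.5)` are
#' averaged into fixed bins — 0.002 of normalized time for the photometry
#' signal (1000 bins) and 0.05 for the companion motor parameter (40 bins).
#' Bin edges land exactly on 0 and 1. Empty bins are `NA`.
#'
#' @param signal A `processed_signal`.
#' @param bouts A [bout_set()].
#' @param motor Optional `speed_trace` companion.
#' @param window Normalized-time span (default `c(-0.5, 1.5)`).
#' @param signal_bin,motor_bin Bin widths in normalized time.
#' @return An object of class `"normalized_epochs"`: `matrix` (bouts x
#'   signal bins), `bin_centers`, `motor` (bouts x motor bins or `NULL`),
#'   `motor_bin_centers`, `meta` (kind, onset, duration).
#' @export
extract_normalized_epochs <- function(signal, bouts, motor = NULL,
                                      window = c(-0.5, 1.5),
                                      signal_bin = 0.002, motor_bin = 0.05) {
  stopifnot(inherits(signal, "processed_signal"), inherits(bouts, "bout_set"))
  nb_s <- round((window[2] - window[1]) / signal_bin)
  nb_m <- round((window[2] - window[1]) / motor_bin)
  edges_s <- window[1] + signal_bin * (0:nb_s)
  edges_m <- window[1] + motor_bin * (0:nb_m)
  t_sig <- trace_time(signal)

  bin_means <- function(u, v, edges, nb) {
    sel <- u >= edges[1] & u < edges[nb + 1] & !is.na(v)
    out <- rep(NA_real_, nb)
    if (any(sel)) {
      b <- findInterval(u[sel], edges, rightmost.closed = FALSE)
      agg <- tapply(v[sel], b, mean)
      out[as.integer(names(agg))] <- agg
    }
    out
  }

  mat <- matrix(NA_real_, nrow(bouts), nb_s)
  mot <- if (!is.null(motor)) matrix(NA_real_, nrow(bouts), nb_m) else NULL
  for (i in seq_len(nrow(bouts))) {
    D <- bouts$offset[i] - bouts$onset[i]
    if (D <= 0) stop("bout with non-positive duration", call. = FALSE)
    u <- (t_sig - bouts$onset[i]) / D
    mat[i, ] <- bin_means(u, signal$z, edges_s, nb_s)
    if (!is.null(motor)) {
      um <- (motor$time - bouts$onset[i]) / D
      mot[i, ] <- bin_means(um, motor$speed, edges_m, nb_m)
    }
  }
  structure(list(
    matrix = mat,
    bin_centers = edges_s[-(nb_s + 1)] + signal_bin / 2,
    motor = mot,
    motor_bin_centers = edges_m[-(nb_m + 1)] + motor_bin / 2,
    meta = data.frame(kind = bouts$kind, onset = bouts$onset,
                      duration = bouts$offset - bouts$onset)),
    class = "normalized_epochs")
}

# Named window schemes: stimulus epochs in seconds, motor epochs in
# normalized time. Left-closed, right-open so shared edges are not
# double-counted.
epoch_window_scheme <- function(scheme = c("stimulus", "motor")) {
  scheme <- match.arg(scheme)
  if (scheme == "stimulus")
    list(pre = c(-5, 0), during = c(0, 5), post = c(5, 10))
  else
    list(pre = c(-0.5, 0), first_half = c(0, 0.5),
         second_half = c(0.5, 1), post = c(1, 1.5))
}

#' Per-trial (or per-bout) window means
#'
#' Arithmetic mean of the samples whose axis position falls in each named
#' window (`[a, b)`). The stimulus scheme has windows pre (-5, 0), during
#' (0, 5) and post (5, 10) seconds; the motor scheme pre (-0.5, 0), first
#' half (0, 0.5), second half (0.5, 1) and post (1, 1.5) of normalized time.
#'
#' @param epochs An `aligned_epochs` or `normalized_epochs` object.
#' @param scheme `"stimulus"` or `"motor"`; defaults to the scheme matching
#'   the epoch type.
#' @return A data frame of class `"epoch_summary"`: one row per trial/bout,
#'   one column per window, plus the epoch metadata columns.
#' @export
summarize_epochs <- function(epochs, scheme = NULL) {
  if (is.null(scheme))
    scheme <- if (inherits(epochs, "aligned_epochs")) "stimulus" else "motor"
  wins <- epoch_window_scheme(scheme)
  axis <- if (inherits(epochs, "aligned_epochs")) epochs$time_axis
          else epochs$bin_centers
  out <- lapply(wins, function(w) {
    sel <- axis >= w[1] & axis < w[2]
    if (!any(sel)) {
      warning("window [", w[1], ", ", w[2], ") contains no samples")
      return(rep(NA_real_, nrow(epochs$matrix)))
    }
    rowMeans(epochs$matrix[, sel, drop = FALSE], na.rm = TRUE)
  })
  df <- cbind(as.data.frame(out), epochs$meta)
  attr(df, "scheme") <- scheme
  attr(df, "windows") <- wins
  class(df) <- c("epoch_summary", "data.frame")
  df
}

#' Split per-trial means into response vs no-response per mouse
#'
#' For each mouse, the mean during-window Z-score over responsive trials and
#' over non-responsive trials. Mice lacking either class are excluded, as
#' are mice where all trials fall in one class.
#'
#' @param during Numeric vector of per-trial during-window means.
#' @param flags Logical vector: locomotor response on that trial.
#' @param mouse Mouse identifier per trial (single-session input may omit
#'   it).
#' @return A data frame with one row per retained mouse: `mouse`,
#'   `mean_response`, `mean_no_response`, `n_response`, `n_no_response`.
#'   Empty (with a warning) when no mouse has both classes.
#' @export
split_by_response <- function(during, flags, mouse = NULL) {
  stopifnot(length(during) == length(flags))
  if (is.null(mouse)) mouse <- rep("mouse1", length(during))
  res <- lapply(split(seq_along(during), mouse), function(idx) {
    f <- flags[idx]
    if (!any(f) || all(f)) return(NULL)  # excluded: one class missing
    data.frame(mouse = mouse[idx[1]],
               mean_response = mean(during[idx][f]),
               mean_no_response = mean(during[idx][!f]),
               n_response = sum(f), n_no_response = sum(!f))
  })
  res <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(res)) {
    warning("no mouse has both responsive and non-responsive trials")
    res <- data.frame(mouse = character(), mean_response = numeric(),
                      mean_no_response = numeric(), n_response = integer(),
                      n_no_response = integer())
  }
  rownames(res) <- NULL
  res
}
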