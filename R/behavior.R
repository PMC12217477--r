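# Pose-tracking QC, speed computation, bout detection and stimulus-response
# classification.

#' Arena distance calibration from tracked corners
#'
#' The camera scale is estimated from the four tracked arena corners:
#' `scale = arena_side_cm / mean(side lengths in pixels)`. Corners are
#' re-ordered around their centroid, and the quadrilateral must be convex
#' and non-degenerate.
#'
#' @param arena_corners 4 x 2 numeric matrix of corner pixel coordinates
#'   (any order).
#' @param arena_side_cm Physical arena side length in cm (default 40).
#' @return Scale in cm per pixel, with the ordered corner polygon attached
#'   as attribute `"corners"`.
#' @export
compute_calibration <- function(arena_corners, arena_side_cm = 40) {
  arena_corners <- as.matrix(arena_corners)
  stopifnot(nrow(arena_corners) == 4, ncol(arena_corners) == 2)
  ctr <- colMeans(arena_corners)
  ord <- order(atan2(arena_corners[, 2] - ctr[2], arena_corners[, 1] - ctr[1]))
  p <- arena_corners[ord, , drop = FALSE]
  sides <- sqrt(rowSums((p - p[c(2:4, 1), , drop = FALSE])^2))
  # convexity: all cross products of consecutive edges share a sign
  e <- p[c(2:4, 1), ] - p
  cr <- e[, 1] * e[c(2:4, 1), 2] - e[, 2] * e[c(2:4, 1), 1]
  if (any(sides < 1e-9) || abs(sum(cr)) < 1e-9 ||
      !(all(cr > 0) || all(cr < 0)))
    stop("arena corners do not form a convex quadrilateral", call. = FALSE)
  scale <- arena_side_cm / mean(sides)
  attr(scale, "corners") <- p
  scale
}

# Points inside (or on) a convex polygon given in traversal order.
points_in_polygon <- function(x, y, poly) {
  nv <- nrow(poly)
  inside <- rep(TRUE, length(x))
  # orientation of the polygon
  e <- poly[c(2:nv, 1), ] - poly
  orient <- sign(sum(e[, 1] * e[c(2:nv, 1), 2] - e[, 2] * e[c(2:nv, 1), 1]))
  for (k in seq_len(nv)) {
    k2 <- if (k == nv) 1L else k + 1L
    cr <- (poly[k2, 1] - poly[k, 1]) * (y - poly[k, 2]) -
      (poly[k2, 2] - poly[k, 2]) * (x - poly[k, 1])
    inside <- inside & (orient * cr >= -1e-9)
  }
  inside
}

#' Arena corner positions of a tracking table
#'
#' Median pixel position of each tracked corner across frames.
#'
#' @param tracking A `tracking_table`.
#' @return A 4 x 2 matrix of corner pixel coordinates.
#' @export
tracked_corners <- function(tracking) {
  cn <- paste0("corner", 1:4)
  if (!all(cn %in% names(tracking$parts)))
    stop("tracking table lacks corner1..corner4 parts", call. = FALSE)
  t(vapply(cn, function(p)
    c(median(tracking$parts[[p]]$x), median(tracking$parts[[p]]$y)),
    numeric(2)))
}

#' Quality-control filter for tracked positions
#'
#' A frame's body-center position is excluded if (in this order, each frame
#' counted against the first rule it fails): its detection likelihood is
#' below `likelihood_min` (strict `<`); it lies outside the arena polygon
#' formed by the tracked corners; or the step from the previous retained
#' frame implies a speed above `speed_max` (the fastest locomotion recorded
#' in mice, 334 cm/s).
#'
#' @param tracking A `tracking_table`.
#' @param scale Camera scale in cm/px, from [compute_calibration()]; its
#'   `"corners"` attribute supplies the arena polygon.
#' @param likelihood_min Minimum detection likelihood (default 0.8).
#' @param speed_max Maximum biologically plausible speed in cm/s
#'   (default 334).
#' @param part Body part to QC (default `"bodycenter"`).
#' @return Logical vector of retained frames, with attribute `"counts"`:
#'   excluded-by-rule and retained tallies summing to the frame count.
#' @export
qc_filter_positions <- function(tracking, scale, likelihood_min = 0.8,
                                speed_max = 334, part = "bodycenter") {
  p <- tracking$parts[[part]]
  if (is.null(p)) stop("no tracked part '", part, "'", call. = FALSE)
  n <- nrow(p)
  poly <- attr(scale, "corners")
  if (is.null(poly))
    stop("scale must carry the corner polygon (use compute_calibration)",
         call. = FALSE)
  fail_lik <- p$likelihood < likelihood_min
  in_arena <- points_in_polygon(p$x, p$y, poly)
  fail_arena <- !fail_lik & !in_arena
  valid <- !fail_lik & in_arena
  # sequential speed rule against the last retained frame
  fail_speed <- rep(FALSE, n)
  last_ok <- NA_integer_
  for (i in seq_len(n)) {
    if (!valid[i]) next
    if (!is.na(last_ok)) {
      d_cm <- sqrt((p$x[i] - p$x[last_ok])^2 +
                     (p$y[i] - p$y[last_ok])^2) * as.numeric(scale)
      v <- d_cm / (tracking$time[i] - tracking$time[last_ok])
      if (v > speed_max) {
        fail_speed[i] <- TRUE
        valid[i] <- FALSE
        next
      }
    }
    last_ok <- i
  }
  counts <- c(likelihood = sum(fail_lik), arena = sum(fail_arena),
              speed = sum(fail_speed), retained = sum(valid))
  stopifnot(sum(counts) == n)
  structure(valid, counts = counts)
}

#' Locomotor speed from body-center positions
#'
#' Frame-to-frame speed: `speed[i] = scale * ||pos[i] - pos[i-1]|| /
#' (t[i] - t[i-1])`, defined only when frames `i` and `i - 1` are both
#' valid; otherwise missing. QC gaps are not interpolated, so the first
#' frame after a gap has no speed.
#'
#' @param tracking A `tracking_table`.
#' @param valid Logical mask from [qc_filter_positions()].
#' @param scale cm/px scale.
#' @param part Body part (default `"bodycenter"`).
#' @return An object of class `"speed_trace"`: list with `time`, `speed`
#'   (`NA` where missing), `valid`, `fps`, `scale`.
#' @export
compute_speed <- function(tracking, valid, scale, part = "bodycenter") {
  p <- tracking$parts[[part]]
  tvec <- tracking$time
  if (any(diff(tvec) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  n <- nrow(p)
  stopifnot(length(valid) == n)
  speed <- rep(NA_real_, n)
  ok <- which(valid[-1] & valid[-n]) + 1L
  if (length(ok)) {
    d <- sqrt((p$x[ok] - p$x[ok - 1])^2 + (p$y[ok] - p$y[ok - 1])^2)
    speed[ok] <- as.numeric(scale) * d / (tvec[ok] - tvec[ok - 1])
  }
  structure(list(time = tvec, speed = speed, valid = !is.na(speed),
                 fps = tracking$fps, scale = as.numeric(scale)),
            class = "speed_trace")
}

#' Construct a speed trace directly
#'
#' Used when speed arrives from a source other than [compute_speed()]
#' (e.g. treadmill encoders) or when building traces programmatically.
#'
#' @param speed Speed in cm/s per frame, `NA` where missing.
#' @param fps Frame rate in Hz.
#' @param time Frame times in seconds (default `(0:(n-1))/fps`).
#' @param scale cm/px scale used, if any.
#' @return A `speed_trace`.
#' @export
speed_trace <- function(speed, fps, time = NULL, scale = NA_real_) {
  if (is.null(time)) time <- (seq_along(speed) - 1) / fps
  stopifnot(length(time) == length(speed))
  if (any(speed < 0, na.rm = TRUE))
    stop("speed must be non-negative", call. = FALSE)
  structure(list(time = time, speed = as.numeric(speed),
                 valid = !is.na(speed), fps = fps, scale = scale),
            class = "speed_trace")
}

#' @export
print.speed_trace <- function(x, ...) {
  cat(sprintf("<speed_trace> %d frames @ %g fps, %d with speed (max %.1f cm/s)\n",
              length(x$time), x$fps, sum(x$valid),
              suppressWarnings(max(x$speed, na.rm = TRUE))))
  invisible(x)
}

#' Detect locomotor bouts from a speed trace
#'
#' A locomotor bout is a maximal run of consecutive valid frames with speed
#' strictly above `threshold` whose duration is at least `min_duration`.
#' Each frame represents one frame period, so a run of frames
#' `first..last` has duration `(t[last] - t[first]) + 1/fps`: ten frames at
#' 20 fps make exactly 0.5 s. Missing or sub-threshold frames terminate a
#' run; runs are never bridged.
#'
#' @param speed A [compute_speed()] result.
#' @param threshold Speed threshold in cm/s (default 3, strict `>`).
#' @param min_duration Minimum bout duration in seconds (default 0.5).
#' @return A [bout_set()] of `locomotion` bouts with `onset = t[first]`,
#'   `offset = t[last] + 1/fps`.
#' @export
detect_bouts <- function(speed, threshold = 3, min_duration = 0.5) {
  stopifnot(inherits(speed, "speed_trace"))
  supra <- !is.na(speed$speed) & speed$speed > threshold
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  onsets <- offsets <- numeric(0)
  dt <- 1 / speed$fps
  for (k in keep) {
    t_first <- speed$time[starts[k]]
    t_last <- speed$time[ends[k]]
    if ((t_last - t_first) + dt >= min_duration - 1e-9) {
      onsets <- c(onsets, t_first)
      offsets <- c(offsets, t_last + dt)
    }
  }
  bout_set(onsets, offsets, rep("locomotion", length(onsets)),
           source = "detected")
}

#' Classify trials by locomotor response
#'
#' A trial is responsive when a locomotor bout *starts* within the
#' `response_window` after the stimulus onset (interval
#' `(onset, onset + window]`); the bout may extend past the window. With
#' `mode = "overlap"` any bout overlapping the window counts instead.
#' Trials whose window extends past the end of the speed trace are dropped
#' with a warning.
#'
#' @param events An [event_table()].
#' @param speed A [compute_speed()] result.
#' @param response_window Window length in seconds (default 5).
#' @param threshold,min_duration Bout definition, see [detect_bouts()].
#' @param mode `"onset"` (default) or `"overlap"`.
#' @return A list: `flags` (data frame with `onset`, `responsive`),
#'   `proportion` (responsive / classified trials), `n_dropped`.
#' @export
classify_stimulus_responses <- function(events, speed, response_window = 5,
                                        threshold = 3, min_duration = 0.5,
                                        mode = c("onset", "overlap")) {
  mode <- match.arg(mode)
  bouts <- detect_bouts(speed, threshold, min_duration)
  t_end <- max(speed$time) + 1 / speed$fps
  usable <- events$onset + response_window <= t_end + 1e-9
  if (any(!usable))
    warning(sum(!usable), " trial(s) dropped: response window extends past ",
            "the recording end")
  ev <- events[usable, , drop = FALSE]
  responsive <- vapply(ev$onset, function(o) {
    if (mode == "onset")
      any(bouts$onset > o & bouts$onset <= o + response_window)
    else
      any(bouts$onset < o + response_window & bouts$offset > o)
  }, logical(1))
  list(flags = data.frame(onset = ev$onset, trial_index = ev$trial_index,
                          responsive = responsive),
       proportion = if (nrow(ev)) mean(responsive) else NA_real_,
       n_dropped = sum(!usable))
}

#' Load manual grooming/rearing annotations
#'
#' Reads a CSV with columns `onset_s`, `offset_s`, `behavior` and validates
#' it into a [bout_set()]. Unknown behavior labels, non-positive durations
#' and overlapping same-kind intervals are rejected with the offending line
#' number.
#'
#' @param path Path to the annotations CSV.
#' @return A `bout_set` with `source = "manual"`; empty if the file has no
#'   rows.
#' @export
load_annotations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("onset_s", "offset_s", "behavior")
  if (!all(need %in% names(df)))
    stop("annotations file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!nrow(df)) return(bout_set(source = "manual"))
  bad <- which(df$offset_s <= df$onset_s)
  if (length(bad))
    stop("annotation offset <= onset at data row ", bad[1], call. = FALSE)
  unknown <- which(!df$behavior %in% c("grooming", "rearing"))
  if (length(unknown))
    stop("unknown behavior label '", df$behavior[unknown[1]],
         "' at data row ", unknown[1], call. = FALSE)
  bout_set(df$onset_s, df$offset_s, df$behavior, source = "manual")
}
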