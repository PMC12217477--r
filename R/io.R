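# Plain-text readers and writers for the pipeline's interchange formats.
# Raw voltage traces go to CSV with a JSON sidecar carrying the sampling
# metadata; pose tracking uses the three-header-row CSV dialect produced by
# markerless pose estimation (scorer / bodyparts / coords).

sidecar_path <- function(path) paste0(path, ".json")

#' Write / read a raw photometry recording
#'
#' The voltage trace is written as a one-column CSV; sampling rate, carrier
#' frequencies and time origin go to a JSON sidecar (`<path>.json`).
#'
#' @param raw A [raw_photometry()].
#' @param path CSV path.
#' @return `write_raw_photometry`: `path`, invisibly.
#' @export
write_raw_photometry <- function(raw, path) {
  stopifnot(inherits(raw, "raw_photometry"))
  data.table::fwrite(data.table::data.table(voltage = raw$voltage), path)
  jsonlite::write_json(list(fs = raw$fs, carrier_hz = as.list(raw$carrier_hz),
                            t0 = raw$t0),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_raw_photometry
#' @export
read_raw_photometry <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  v <- data.table::fread(path)$voltage
  raw_photometry(v, fs = meta$fs, carrier_hz = unlist(meta$carrier_hz),
                 t0 = meta$t0)
}

#' Write / read demodulated channel traces
#'
#' CSV with columns `time_s`, `ca`, `iso`.
#'
#' @param channels List with `ca` and `iso` [channel_trace()]s (as returned
#'   by [demodulate_recording()]).
#' @param path CSV path.
#' @param settle_s Settling span restored on read (default 1 s).
#' @return `read_demodulated`: list of `ca` and `iso` channel traces.
#' @export
write_demodulated <- function(channels, path) {
  stopifnot(inherits(channels$ca, "channel_trace"))
  data.table::fwrite(data.table::data.table(
    time_s = trace_time(channels$ca),
    ca = channels$ca$value, iso = channels$iso$value), path)
  invisible(path)
}

#' @rdname write_demodulated
#' @export
read_demodulated <- function(path, settle_s = 1) {
  df <- data.table::fread(path)
  rate <- 1 / median(diff(df$time_s))
  list(ca = channel_trace(df$ca, rate, "ca", t0 = df$time_s[1],
                          settle_s = settle_s),
       iso = channel_trace(df$iso, rate, "iso", t0 = df$time_s[1],
                           settle_s = settle_s))
}

#' Write a processed signal
#'
#' CSV with columns `time_s`, `z`; the processing provenance (filter spec,
#' subtraction method and fit, Z-score statistics) goes to a JSON sidecar.
#'
#' @param signal A `processed_signal`.
#' @param path CSV path.
#' @export
write_processed <- function(signal, path) {
  stopifnot(inherits(signal, "processed_signal"))
  data.table::fwrite(data.table::data.table(time_s = trace_time(signal),
                                            z = signal$z), path)
  jsonlite::write_json(signal$provenance, sidecar_path(path),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}

#' Write / read a pose-tracking table
#'
#' The three-header-row CSV dialect of markerless pose estimation: a
#' `scorer` row, a `bodyparts` row and a `coords` row (`x`, `y`,
#' `likelihood` per part), with the frame index in the first column.
#'
#' @param tracking A `tracking_table`.
#' @param path CSV path.
#' @param scorer Scorer label written in the first header row.
#' @param fps Frame rate used to reconstruct time on read when the table
#'   has no timestamps (default 20).
#' @return `read_tracking`: a `tracking_table`.
#' @export
write_tracking <- function(tracking, path, scorer = "synthetic") {
  parts <- names(tracking$parts)
  h1 <- c("scorer", rep(scorer, 3 * length(parts)))
  h2 <- c("bodyparts", rep(parts, each = 3))
  h3 <- c("coords", rep(c("x", "y", "likelihood"), length(parts)))
  body <- do.call(cbind, lapply(tracking$parts, function(p)
    cbind(p$x, p$y, p$likelihood)))
  body <- cbind(seq_len(nrow(body)) - 1, body)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste(h1, collapse = ","), paste(h2, collapse = ","),
               paste(h3, collapse = ",")), con)
  write.table(body, con, sep = ",", col.names = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracking
#' @export
read_tracking <- function(path, fps = 20) {
  hdr <- readLines(path, n = 3)
  h2 <- strsplit(hdr[2], ",")[[1]][-1]
  h3 <- strsplit(hdr[3], ",")[[1]][-1]
  df <- read.csv(path, skip = 3, header = FALSE)
  parts <- list()
  for (p in unique(h2)) {
    cols <- which(h2 == p) + 1  # +1 for the frame-index column
    sub <- df[, cols, drop = FALSE]
    names(sub) <- h3[cols - 1]
    parts[[p]] <- sub[, c("x", "y", "likelihood")]
  }
  structure(list(time = (seq_len(nrow(df)) - 1) / fps, parts = parts,
                 fps = fps, arena_cm = NA_real_),
            class = "tracking_table")
}

#' Write / read a stimulus event table
#'
#' CSV with columns `onset_s`, `modality` (and `series_id`, `trial_index`,
#' `alignment_offset` when present).
#'
#' @param events An [event_table()].
#' @param path CSV path.
#' @return `read_events`: an `event_table`.
#' @export
write_events <- function(events, path) {
  df <- as.data.frame(events)
  names(df)[names(df) == "onset"] <- "onset_s"
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  event_table(df$onset_s, modality = df$modality,
              series_id = if ("series_id" %in% names(df)) df$series_id else 1L,
              trial_index = if ("trial_index" %in% names(df))
                df$trial_index else NULL,
              alignment_offset = if ("alignment_offset" %in% names(df))
                df$alignment_offset else NULL)
}

#' Write a bout set
#'
#' CSV with columns `onset_s`, `offset_s`, `kind`, `source`. The manual
#' annotation dialect read back by [load_annotations()] uses
#' `onset_s`, `offset_s`, `behavior`.
#'
#' @param bouts A [bout_set()].
#' @param path CSV path.
#' @param dialect `"bouts"` (full) or `"annotations"`.
#' @export
write_bouts <- function(bouts, path, dialect = c("bouts", "annotations")) {
  dialect <- match.arg(dialect)
  df <- as.data.frame(bouts)
  if (dialect == "bouts") {
    out <- data.frame(onset_s = df$onset, offset_s = df$offset,
                      kind = df$kind, source = df$source)
  } else {
    out <- data.frame(onset_s = df$onset, offset_s = df$offset,
                      behavior = df$kind)
  }
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a speed trace
#'
#' CSV with columns `time_s`, `speed_cms`, `valid`.
#'
#' @param speed A `speed_trace`.
#' @param path CSV path.
#' @export
write_speed <- function(speed, path) {
  write.csv(data.frame(time_s = speed$time, speed_cms = speed$speed,
                       valid = speed$valid),
            path, row.names = FALSE)
  invisible(path)
}

#' Export session ground truth as JSON
#'
#' @param session A `photometry_session`.
#' @param path JSON path.
#' @export
write_truth <- function(session, path) {
  tr <- session$truth
  jsonlite::write_json(
    list(transient_times = tr$transient_times,
         transient_amplitudes = tr$transient_amplitudes,
         transient_peak_times = tr$transient_peak_times,
         true_bouts = as.data.frame(tr$true_bouts),
         true_response_flags = tr$true_response_flags,
         mixing_coefficient = tr$mixing_coefficient,
         habituation = tr$habituation),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a complete synthetic session to a directory
#'
#' Emits the raw photometry CSV (+ JSON sidecar), tracking CSV, events CSV,
#' annotations CSV and ground-truth JSON.
#'
#' @param session A `photometry_session`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_raw_photometry(session$photometry, file.path(dir, "raw.csv"))
  write_tracking(session$tracking, file.path(dir, "tracking.csv"))
  write_events(session$events, file.path(dir, "events.csv"))
  write_bouts(session$annotations, file.path(dir, "annotations.csv"),
              dialect = "annotations")
  write_truth(session, file.path(dir, "truth.json"))
  invisible(dir)
}
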