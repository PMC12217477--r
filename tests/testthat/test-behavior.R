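# Tracking QC, speed, bout detection, response classification, annotations.

square_scale <- function(side_px = 400, arena_cm = 40) {
  compute_calibration(matrix(c(0, 0, side_px, 0, side_px, side_px, 0,
                               side_px), ncol = 2, byrow = TRUE), arena_cm)
}

make_tracking <- function(x, y, likelihood = 1, fps = 20, side_px = 400) {
  n <- length(x)
  corners <- matrix(c(0, 0, side_px, 0, side_px, side_px, 0, side_px),
                    ncol = 2, byrow = TRUE)
  parts <- list(bodycenter = data.frame(x = x, y = y,
                                        likelihood = rep_len(likelihood, n)))
  for (k in 1:4)
    parts[[paste0("corner", k)]] <- data.frame(
      x = rep(corners[k, 1], n), y = rep(corners[k, 2], n),
      likelihood = rep(1, n))
  structure(list(time = (0:(n - 1)) / fps, parts = parts, fps = fps,
                 arena_cm = 40),
            class = "tracking_table")
}

test_that("arena calibration handles order, scale and degeneracy", {
  c1 <- matrix(c(0, 0, 400, 0, 400, 400, 0, 400), ncol = 2, byrow = TRUE)
  expect_equal(as.numeric(compute_calibration(c1, 40)), 0.1)
  # shuffled corner order
  expect_equal(as.numeric(compute_calibration(c1[c(3, 1, 4, 2), ], 40)), 0.1)
  c2 <- matrix(c(0, 0, 100, 0, 100, 100, 0, 100), ncol = 2, byrow = TRUE)
  expect_equal(as.numeric(compute_calibration(c2, 40)), 0.4)
  # uneven sides (396, 404, 396, 404) average to 400 px
  c3 <- matrix(c(0, 0, 396, 0, 396, 404, 0, 404), ncol = 2, byrow = TRUE)
  expect_equal(as.numeric(compute_calibration(c3, 40)), 0.1)
  expect_error(compute_calibration(matrix(c(0, 0, 1, 1, 2, 2, 3, 3),
                                          ncol = 2, byrow = TRUE)),
               "convex")
})

test_that("QC excludes by likelihood (strict), arena and speed, in order", {
  trk <- make_tracking(x = c(200, 200, 200, 500, 200, 200),
                       y = rep(200, 6),
                       likelihood = c(1, 0.79, 0.80, 1, 1, 1))
  scale <- square_scale()
  v <- qc_filter_positions(trk, scale)
  expect_false(v[2])                 # likelihood 0.79 < 0.8 excluded
  expect_true(v[3])                  # 0.80 retained (strict <)
  expect_false(v[4])                 # x = 500 outside the arena
  counts <- attr(v, "counts")
  expect_equal(unname(counts["likelihood"]), 1)
  expect_equal(unname(counts["arena"]), 1)
  expect_equal(sum(counts), 6)

  # a jump implying 400 cm/s at 20 fps: 400/20 = 20 cm = 200 px per frame
  trk2 <- make_tracking(x = c(100, 100, 301, 100, 100), y = rep(100, 5))
  v2 <- qc_filter_positions(trk2, scale)
  # the jump frame is excluded; the return frame is checked against the
  # last retained frame and passes
  expect_equal(unname(attr(v2, "counts")["speed"]), 1)
  expect_false(v2[3])
  expect_true(v2[4])
})

test_that("speed is frame-to-frame and gaps propagate one frame", {
  # 0.5 cm = 5 px per frame at 20 fps -> 10 cm/s
  trk <- make_tracking(x = c(100, 105, 110, 110), y = rep(100, 4))
  scale <- square_scale()
  sp <- compute_speed(trk, rep(TRUE, 4), scale)
  expect_true(is.na(sp$speed[1]))
  expect_equal(sp$speed[2:4], c(10, 10, 0))

  valid <- c(TRUE, FALSE, TRUE, TRUE)
  sp2 <- compute_speed(trk, valid, scale)
  expect_true(is.na(sp2$speed[2]))
  expect_true(is.na(sp2$speed[3]))  # frame after the gap has no speed
  expect_equal(sp2$speed[4], 0)

  bad <- make_tracking(x = 1:3, y = 1:3)
  bad$time <- c(0, 0.1, 0.1)
  expect_error(compute_speed(bad, rep(TRUE, 3), scale), "increasing")
})

test_that("bout duration convention: 10 frames qualify, 9 do not", {
  mk <- function(n_fast) speed_trace(c(rep(1, 5), rep(5, n_fast), rep(1, 5)),
                                     fps = 20)
  b10 <- detect_bouts(mk(10))
  expect_equal(nrow(b10), 1)
  expect_equal(b10$offset - b10$onset, 0.5)
  expect_equal(b10$onset, 5 / 20)
  expect_equal(nrow(detect_bouts(mk(9))), 0)

  # strict threshold: exactly 3.0 cm/s never counts
  at3 <- speed_trace(rep(3, 40), fps = 20)
  expect_equal(nrow(detect_bouts(at3)), 0)
  above3 <- speed_trace(rep(3.0001, 40), fps = 20)
  expect_equal(nrow(detect_bouts(above3)), 1)

  # a missing frame terminates the run
  gap <- speed_trace(c(rep(5, 6), NA, rep(5, 6)), fps = 20)
  expect_equal(nrow(detect_bouts(gap)), 0)
})

test_that("bout detector equals the brute-force oracle on random traces", {
  set.seed(1234)
  for (rep_ in 1:200) {
    sp <- random_speed_trace()
    det <- detect_bouts(sp)
    orc <- oracle_bouts(sp$speed, sp$time, sp$fps)
    expect_equal(nrow(det), nrow(orc))
    if (nrow(orc)) {
      expect_equal(det$onset, orc[, 1])
      expect_equal(det$offset, orc[, 2])
    }
  }
})

test_that("raising threshold or minimum duration never adds bouts", {
  set.seed(99)
  for (rep_ in 1:50) {
    sp <- random_speed_trace(n = 100)
    n0 <- nrow(detect_bouts(sp, threshold = 3, min_duration = 0.5))
    expect_lte(nrow(detect_bouts(sp, threshold = 4, min_duration = 0.5)), n0)
    expect_lte(nrow(detect_bouts(sp, threshold = 3, min_duration = 1)), n0)
  }
})

test_that("stimulus-response classification follows bout onsets", {
  # 60 s trace: bout at 12 s (onset +2 after stim at 10), none near 30,
  # bout at 41.5 (onset +6 after stim at 35.5 -> not responsive)
  v <- rep(1, 1200)
  v[241:280] <- 10   # 12.0 .. 13.95 s
  v[831:870] <- 10   # 41.5 .. 43.45 s
  sp <- speed_trace(v, fps = 20)
  ev <- event_table(c(10, 25, 35.5))
  res <- classify_stimulus_responses(ev, sp)
  expect_equal(res$flags$responsive, c(TRUE, FALSE, FALSE))
  expect_equal(res$proportion, 1 / 3)

  # overlap mode: a bout already running at stimulus onset counts
  ev2 <- event_table(c(12.5))
  expect_false(classify_stimulus_responses(ev2, sp)$flags$responsive)
  expect_true(classify_stimulus_responses(ev2, sp,
                                          mode = "overlap")$flags$responsive)

  # windows past the recording end are dropped with a warning
  ev3 <- event_table(c(10, 58))
  expect_warning(res3 <- classify_stimulus_responses(ev3, sp), "dropped")
  expect_equal(nrow(res3$flags), 1)
  expect_equal(res3$n_dropped, 1)
})

test_that("annotations load, validate and reject bad rows", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("onset_s,offset_s,behavior\n10.0,16.8,grooming\n20,22,rearing", f)
  b <- load_annotations(f)
  expect_s3_class(b, "bout_set")
  expect_equal(b$offset[1] - b$onset[1], 6.8)
  expect_equal(b$kind, c("grooming", "rearing"))
  expect_equal(unique(b$source), "manual")

  writeLines("onset_s,offset_s,behavior\n5.0,4.0,rearing", f)
  expect_error(load_annotations(f), "row 1")
  writeLines("onset_s,offset_s,behavior\n1,2,sleeping", f)
  expect_error(load_annotations(f), "sleeping")
  writeLines("onset_s,offset_s,behavior", f)
  expect_equal(nrow(load_annotations(f)), 0)
})

test_that("bout sets reject overlap and inverted intervals", {
  expect_error(bout_set(5, 4, "rearing"), "onset < offset")
  expect_error(bout_set(c(1, 2), c(3, 4), "grooming"), "overlapping")
  # overlap across kinds is allowed
  b <- bout_set(c(1, 2), c(3, 4), c("grooming", "rearing"))
  expect_equal(nrow(b), 2)
})
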