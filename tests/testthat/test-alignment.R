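# Epoch extraction in raw and normalized time, window summaries,
# response splits.

ramp_signal <- function(duration = 300, rate = 100) {
  # z equals time: window means readable by inspection
  processed_signal(z = (0:(duration * rate - 1)) / rate, rate = rate)
}

test_that("stimulus epochs span -5..10 s and drop incomplete trials", {
  sig <- ramp_signal()
  ev <- event_table(c(3, 100, 297))  # first and last have no full window
  expect_warning(ep <- extract_stimulus_epochs(sig, ev), "dropped")
  expect_equal(nrow(ep$matrix), 1)
  expect_equal(nrow(ep$dropped), 2)
  expect_equal(nrow(ep$matrix) + nrow(ep$dropped), nrow(ev))
  expect_equal(ncol(ep$matrix), 1500)
  expect_equal(range(ep$time_axis), c(-5, 10 - 0.01))
  # z = t, so the epoch row is 95..110 s
  expect_equal(ep$matrix[1, 1], 95, tolerance = 1e-9)
  expect_equal(ep$matrix[1, 1500], 109.99, tolerance = 1e-9)
  expect_error(suppressWarnings(extract_stimulus_epochs(sig, event_table(1))),
               "no usable")
})

test_that("looming alignment offset shifts the epoch window", {
  sig <- ramp_signal()
  ep <- extract_stimulus_epochs(sig, event_table(100, modality = "looming"))
  expect_equal(ep$matrix[1, 1], 95.803, tolerance = 1e-9)
})

test_that("companion speed is averaged into 300 bins of 50 ms", {
  sig <- ramp_signal()
  sp <- speed_trace(rep(c(1, 5), 3000), fps = 20)
  # off-grid event time: frames fall strictly inside the 50 ms bins,
  # exactly one frame per bin
  ep <- extract_stimulus_epochs(sig, event_table(100.013), speed = sp)
  expect_equal(ncol(ep$speed), 300)
  expect_equal(ep$speed_bin_centers[1], -5 + 0.025)
  expect_true(all(ep$speed[1, ] %in% c(1, 5)))
  expect_setequal(unique(ep$speed[1, ]), c(1, 5))
})

test_that("normalized epochs map onset to 0, offset to 1, with fixed grids", {
  sig <- ramp_signal()
  bouts <- bout_set(10, 12, "locomotion")
  ne <- extract_normalized_epochs(sig, bouts)
  expect_equal(ncol(ne$matrix), 1000)
  expect_equal(length(ne$bin_centers), 1000)
  # bout 10-12 s: window covers 9..13 s; z = t so first bin ~ 9.0 s
  expect_equal(ne$matrix[1, 1], mean(c(9.00, 9.0033, 9.0067, 9.01)[1:1]),
               tolerance = 0.01)
  # bin edges land exactly on 0 and 1
  expect_true(any(abs(ne$bin_centers - (0 + 0.001)) < 1e-12))
  expect_true(any(abs(ne$bin_centers - (1 + 0.001)) < 1e-12))
  # sample exactly at onset -> u = 0 -> bin just right of 0
  bin_of_onset <- findInterval(0, -0.5 + 0.002 * (0:1000),
                               rightmost.closed = FALSE)
  expect_equal(ne$bin_centers[bin_of_onset], 0.001)
})

test_that("a normalized-time ramp reconstructs bin centers", {
  rate <- 100
  dur <- 100
  t <- (0:(dur * rate - 1)) / rate
  onset <- 40; offset <- 50; D <- offset - onset
  sig <- processed_signal((t - onset) / D, rate = rate)
  ne <- extract_normalized_epochs(sig, bout_set(onset, offset, "locomotion"))
  got <- ne$matrix[1, ]
  ok <- !is.na(got)
  expect_gt(mean(ok), 0.99)
  rmse <- sqrt(mean((got[ok] - ne$bin_centers[ok])^2))
  expect_lt(rmse, 0.001)  # half a photometry bin width
  # motor grid is 40 bins
  sp <- speed_trace(rep(2, dur * 20), fps = 20)
  nem <- extract_normalized_epochs(sig, bout_set(onset, offset, "locomotion"),
                                   motor = sp)
  expect_equal(ncol(nem$motor), 40)
})

test_that("window means follow the left-closed right-open schemes", {
  # step trace: z = 0 before onset, 1 after
  rate <- 100
  z <- c(rep(0, 500), rep(1, 1000))
  ep <- structure(list(matrix = matrix(z, nrow = 1),
                       time_axis = -5 + (0:1499) / rate,
                       meta = data.frame(trial_index = 1L)),
                  class = "aligned_epochs")
  sm <- summarize_epochs(ep, "stimulus")
  expect_equal(unname(unlist(sm[1, c("pre", "during", "post")])), c(0, 1, 1))
  expect_equal(attr(sm, "scheme"), "stimulus")
  expect_length(attr(sm, "windows"), 3)

  # constant trace: all windows equal the constant
  epc <- ep; epc$matrix[] <- 2.5
  smc <- summarize_epochs(epc, "stimulus")
  expect_equal(unname(unlist(smc[1, c("pre", "during", "post")])),
               rep(2.5, 3))

  # motor scheme has 4 windows
  ne <- structure(list(matrix = matrix(rep(1, 1000), nrow = 1),
                       bin_centers = -0.5 + 0.002 * (0:999) + 0.001,
                       meta = data.frame(kind = "locomotion")),
                  class = "normalized_epochs")
  smm <- summarize_epochs(ne)
  expect_equal(attr(smm, "scheme"), "motor")
  expect_length(attr(smm, "windows"), 4)
  expect_true(all(c("pre", "first_half", "second_half", "post") %in%
                    names(smm)))
})

test_that("boundary samples are never double-counted", {
  rate <- 1  # one sample per second: samples at -5..9 relative
  z <- rep(1, 15)
  ep <- structure(list(matrix = matrix(z, nrow = 1),
                       time_axis = -5:9,
                       meta = data.frame(trial_index = 1L)),
                  class = "aligned_epochs")
  sm <- summarize_epochs(ep, "stimulus")
  # pre gets -5..-1 (5 samples), during 0..4, post 5..9; total 15
  wins <- attr(sm, "windows")
  counts <- vapply(wins, function(w)
    sum(ep$time_axis >= w[1] & ep$time_axis < w[2]), numeric(1))
  expect_equal(unname(counts), c(5, 5, 5))
  expect_equal(sum(counts), length(ep$time_axis))
})

test_that("response splits pair per-mouse means and apply exclusions", {
  during <- c(1, 2, 3, 0, 1)
  flags <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  res <- split_by_response(during, flags)
  expect_equal(res$mean_response, 2.0)
  expect_equal(res$mean_no_response, 0.5)
  expect_equal(res$n_response, 3)

  # a mouse with only responsive trials is excluded
  mouse <- c(rep("a", 5), rep("b", 2))
  during2 <- c(during, 5, 6)
  flags2 <- c(flags, TRUE, TRUE)
  res2 <- split_by_response(during2, flags2, mouse)
  expect_equal(res2$mouse, "a")

  expect_warning(empty <- split_by_response(c(1, 2), c(TRUE, TRUE)),
                 "no mouse")
  expect_equal(nrow(empty), 0)
})

test_that("stimulus-locked pulses average to their true latency", {
  rate <- 100
  dur <- 200
  z <- numeric(dur * rate)
  onsets <- c(30, 80, 130)
  latency <- 1
  for (o in onsets) {
    i <- round((o + latency) * rate) + 1
    z[i:(i + 20)] <- eval_kernel(transient_kernel(), (0:20) / rate)
  }
  sig <- processed_signal(z, rate = rate)
  ep <- extract_stimulus_epochs(sig, event_table(onsets))
  avg <- colMeans(ep$matrix)
  peak_rel <- ep$time_axis[which.max(avg)]
  expect_lt(abs(peak_rel - (latency + kernel_peak_time(transient_kernel()))),
            1 / rate + 1e-9)
})
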