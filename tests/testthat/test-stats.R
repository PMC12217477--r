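# Assumption-gated omnibus tests, SNK post hoc, paired comparisons,
# regressions.

test_that("identical window values give a null omnibus and no post hoc", {
  x <- matrix(rep(c(1, 2, 3, 4, 5), 3), ncol = 3)
  res <- compare_epoch_windows(x)
  expect_equal(res$p_value, 1)
  expect_equal(res$statistic, 0)
  expect_null(res$posthoc)
})

test_that("branching is assumption-gated and deterministic", {
  set.seed(5)
  xn <- matrix(rnorm(30), ncol = 3)
  rn <- compare_epoch_windows(xn)
  expect_equal(rn$branch, "parametric")
  expect_true(all(rn$assumptions$shapiro_p > 0.05))

  # heavy-tailed data fail Shapiro-Wilk -> Friedman
  set.seed(6)
  xt <- matrix(rcauchy(30)^3, ncol = 3)
  rt <- compare_epoch_windows(xt)
  expect_equal(rt$branch, "nonparametric")
  expect_equal(rt$test_name, "Friedman ANOVA on ranks")

  # same data, same branch, same numbers
  expect_identical(compare_epoch_windows(xn)$p_value, rn$p_value)
})

test_that("a strong window effect is detected with an SNK table", {
  set.seed(7)
  n <- 10
  x <- cbind(pre = rnorm(n, 0, 0.3), during = rnorm(n, 3, 0.3),
             post = rnorm(n, 0.2, 0.3))
  res <- compare_epoch_windows(x)
  expect_lt(res$p_value, 0.001)
  expect_s3_class(res$posthoc, "data.frame")
  # during differs from both; pre vs post likely not
  ph <- res$posthoc
  row_of <- function(a, b) ph[(ph$group_hi == a & ph$group_lo == b) |
                                (ph$group_hi == b & ph$group_lo == a), ]
  expect_true(row_of("during", "pre")$significant)
  expect_true(row_of("during", "post")$significant)
})

test_that("missing cells are listwise-deleted with a warning", {
  set.seed(8)
  x <- matrix(rnorm(30), ncol = 3)
  x[2, 3] <- NA
  expect_warning(res <- compare_epoch_windows(x), "listwise")
  expect_equal(res$n, 9)
  expect_error(compare_epoch_windows(matrix(rnorm(4), ncol = 2)),
               "3 complete subjects")
})

test_that("SNK stepwise matches the table-lookup oracle on 3 groups", {
  set.seed(11)
  n <- 8
  for (rep_ in 1:60) {
    shift <- sample(c(0, 0.3, 1, 3), 3, replace = TRUE)
    x <- sapply(1:3, function(j) rnorm(n, shift[j], 1))
    colnames(x) <- c("a", "b", "c")
    # error term exactly as the RM-ANOVA computes it
    long <- data.frame(value = as.vector(x),
                       window = factor(rep(colnames(x), each = n)),
                       subject = factor(rep(seq_len(n), 3)))
    tab <- summary(aov(value ~ window + Error(subject),
                       data = long))[["Error: Within"]][[1]]
    se <- sqrt(tab["Residuals", "Mean Sq"] / n)
    df_err <- tab["Residuals", "Df"]
    got <- photomotor:::snk_stepwise(colMeans(x), colnames(x), se, df_err)
    orc <- snk3_oracle(colMeans(x), se, df_err)
    lab_sorted <- colnames(x)[orc$order]
    for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
      want <- orc$significant[pair[1], pair[2]]
      row <- got[(got$group_lo == lab_sorted[pair[1]] &
                    got$group_hi == lab_sorted[pair[2]]) |
                   (got$group_lo == lab_sorted[pair[2]] &
                      got$group_hi == lab_sorted[pair[1]]), ]
      expect_equal(row$significant, want)
    }
  }
})

test_that("paired comparisons gate on the normality of differences", {
  a <- c(1, 2, 3, 4, 5)
  res0 <- paired_group_comparison(a, a)
  expect_equal(res0$p_value, 1)
  expect_equal(res0$statistic, 0)

  set.seed(13)
  b <- rnorm(8)
  res1 <- paired_group_comparison(b + 5 + rnorm(8, 0, 0.5), b)
  expect_equal(res1$branch, "parametric")
  expect_lt(res1$p_value, 0.001)

  # an extreme outlier in the differences forces the rank branch
  d_out <- c(0.1, -0.2, 0.15, -0.05, 0.1, -0.1, 0.2, 50)
  res2 <- paired_group_comparison(b + d_out, b)
  expect_equal(res2$branch, "nonparametric")
  expect_equal(res2$test_name, "Wilcoxon signed-rank test")

  expect_error(paired_group_comparison(1:2, 2:3), "3 pairs")
  expect_error(paired_group_comparison(1:4, 1:5), "equal length")
})

test_that("paired t-test has high power at a 5-SD shift with n = 8", {
  set.seed(14)
  hits <- mean(replicate(200, {
    b <- rnorm(8, 0, 1)
    a <- b + 5 + rnorm(8, 0, 1)
    paired_group_comparison(a, b, branch = "parametric")$p_value < 0.05
  }))
  expect_gte(hits, 0.95)
})

test_that("speed-binned regression recovers an exact linear coupling", {
  # bouts whose mean speeds sit exactly on bin centers
  fps <- 20; rate <- 100; dur <- 120
  speeds <- c(3.5, 4.5, 5.5, 6.5, 7.5)
  onsets <- seq(10, by = 20, length.out = 5)
  v <- rep(0, dur * fps)
  z <- rep(0, dur * rate)
  for (i in seq_along(onsets)) {
    fr <- (onsets[i] * fps + 1):(onsets[i] * fps + 2 * fps)
    v[fr] <- speeds[i]
    sm <- (onsets[i] * rate + 1):(onsets[i] * rate + 2 * rate)
    z[sm] <- 0.1 * speeds[i]
  }
  sp <- speed_trace(v, fps = fps)
  sig <- processed_signal(z, rate = rate)
  bouts <- bout_set(onsets, onsets + 2, "locomotion")
  res <- suppressWarnings(speed_binned_regression(bouts, sig, sp))
  expect_equal(res$slope, 0.1, tolerance = 1e-9)
  expect_equal(res$r_squared, 1, tolerance = 1e-9)
  expect_equal(res$n_points, 5)

  # binning arithmetic: 3.2, 3.7 -> [3,4); 4.1 -> [4,5)
  bouts2 <- bout_set(onsets[1:4], onsets[1:4] + 2, "locomotion")
  v2 <- rep(0, dur * fps)
  for (i in 1:4) {
    fr <- (onsets[i] * fps + 1):(onsets[i] * fps + 2 * fps)
    v2[fr] <- c(3.2, 3.7, 4.1, 6.3)[i]
  }
  res2 <- speed_binned_regression(bouts2, sig, speed_trace(v2, fps = fps))
  expect_equal(res2$data$n_bouts, c(2, 1, 1))
  expect_equal(res2$data$bin_center, c(3.5, 4.5, 6.5))

  expect_error(speed_binned_regression(bout_set(10, 12, "locomotion"),
                                       sig, sp),
               "3 non-empty speed bins")
})

test_that("habituation regression reads percent change off the fitted line", {
  res <- habituation_regression(1:9, seq(10, 2, by = -1))
  expect_equal(res$slope, -1)
  expect_equal(res$r_squared, 1)
  expect_equal(res$percent_change, -80)
  expect_equal(res$change_between, c(1, 9))

  resc <- habituation_regression(1:5, rep(4, 5))
  expect_equal(resc$slope, 0)
  expect_equal(resc$percent_change, 0)

  expect_error(habituation_regression(c(1, 2), c(1, 2)), "3 trial indices")

  # replicate observations per index are averaged before fitting
  res2 <- habituation_regression(c(1, 1, 2, 2, 3, 3),
                                 c(9, 11, 7, 9, 5, 7))
  expect_equal(res2$slope, -2)
  expect_equal(res2$data$mean, c(10, 8, 6))
})
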