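# Assumption-gated statistical layer: repeated-measures omnibus tests with
# Student-Newman-Keuls post hoc, paired comparisons, speed-bin regression
# and habituation regression.

new_stat_result <- function(test_name, statistic, p_value, df = NULL,
                            n = NULL, branch, posthoc = NULL,
                            assumptions = NULL, alpha = 0.05) {
  structure(list(test_name = test_name, statistic = statistic,
                 p_value = p_value, df = df, n = n, branch = branch,
                 posthoc = posthoc, assumptions = assumptions,
                 alpha = alpha),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s (%s): statistic = %.4g, p = %.4g\n",
              x$test_name, x$branch, x$statistic, x$p_value))
  if (!is.null(x$posthoc)) {
    cat("post hoc (Student-Newman-Keuls):\n")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}

# Student-Newman-Keuls stepwise procedure on ordered means.
#
# `stats` are the group summary values (means, or rank sums); `se` the
# standard error entering the studentized-range statistic; `df_err` the
# error degrees of freedom (Inf on the rank branch). The classic stepwise
# rule: the full range is tested first at span k; a non-significant range
# protects (leaves untested) every comparison it encloses.
snk_stepwise <- function(stats, labels, se, df_err, alpha = 0.05) {
  k <- length(stats)
  ord <- order(stats)
  s <- stats[ord]
  lab <- labels[ord]
  sig <- matrix(NA, k, k)      # TRUE/FALSE once decided
  tested <- matrix(FALSE, k, k)
  qmat <- pmat <- matrix(NA_real_, k, k)
  recurse <- function(i, j) {
    if (j - i < 1 || !is.na(sig[i, j])) return()
    span <- j - i + 1
    q <- (s[j] - s[i]) / se
    p <- ptukey(q, span, df_err, lower.tail = FALSE)
    qmat[i, j] <<- q; pmat[i, j] <<- p; tested[i, j] <<- TRUE
    if (p < alpha) {
      sig[i, j] <<- TRUE
      recurse(i, j - 1)
      recurse(i + 1, j)
    } else {
      for (a in i:(j - 1)) for (b in (a + 1):j) {
        if (is.na(sig[a, b])) sig[a, b] <<- FALSE
      }
    }
  }
  recurse(1, k)
  rows <- list()
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    rows[[length(rows) + 1]] <- data.frame(
      group_hi = lab[j], group_lo = lab[i], span = j - i + 1,
      diff = s[j] - s[i], q = qmat[i, j],
      p_value = pmat[i, j], tested = tested[i, j],
      significant = isTRUE(sig[i, j]))
  }
  do.call(rbind, rows)
}

#' Compare repeated-measures window means across subjects
#'
#' The omnibus comparison behind the pre/during/post (and bout-phase)
#' figures: each subject contributes one mean per window. Normality of each
#' window (Shapiro-Wilk) and equality of variances across windows (Levene)
#' gate the branch: both passing (p > 0.05) selects a one-way
#' repeated-measures ANOVA, otherwise a Friedman ANOVA on ranks. A
#' significant omnibus (p < alpha) is followed by the Student-Newman-Keuls
#' stepwise procedure on ordered means (on the rank branch: on within-
#' subject rank sums with infinite error df).
#'
#' @param x Numeric matrix or data frame, subjects in rows, windows in
#'   columns (an [summarize_epochs()] window block works directly).
#' @param branch `"auto"` (assumption-gated, default), or force
#'   `"parametric"` / `"nonparametric"`.
#' @param alpha Significance level (default 0.05).
#' @return A `stat_result`; `posthoc` is the SNK pairwise table when the
#'   omnibus is significant, otherwise `NULL`.
#' @export
compare_epoch_windows <- function(x, branch = c("auto", "parametric",
                                                "nonparametric"),
                                  alpha = 0.05) {
  branch <- match.arg(branch)
  x <- as.matrix(x)
  if (anyNA(x)) {
    keep <- complete.cases(x)
    warning(sum(!keep), " subject(s) with missing cells removed ",
            "(listwise deletion)")
    x <- x[keep, , drop = FALSE]
  }
  n <- nrow(x); k <- ncol(x)
  if (n < 3) stop("need at least 3 complete subjects", call. = FALSE)
  if (k < 2) stop("need at least 2 windows", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("w", seq_len(k))
  # degenerate case: every subject identical across windows -> no effect
  if (max(abs(x - x[, 1])) == 0)
    return(new_stat_result("one-way repeated-measures ANOVA", 0, 1,
                           df = c(k - 1, (k - 1) * (n - 1)), n = n,
                           branch = "parametric", alpha = alpha))

  assumptions <- NULL
  if (branch == "auto") {
    shapiro_p <- apply(x, 2, function(col) {
      if (sd(col) == 0) return(1)  # constant column: nothing to reject
      shapiro.test(col)$p.value
    })
    long <- data.frame(value = as.vector(x),
                       window = factor(rep(colnames(x), each = n)))
    levene_p <- car::leveneTest(value ~ window, data = long,
                                center = "mean")[1, "Pr(>F)"]
    if (!is.finite(levene_p)) levene_p <- 1  # no dispersion to compare
    assumptions <- list(shapiro_p = shapiro_p, levene_p = levene_p)
    branch <- if (all(shapiro_p > 0.05) && levene_p > 0.05)
      "parametric" else "nonparametric"
  }

  long <- data.frame(value = as.vector(x),
                     window = factor(rep(colnames(x), each = n)),
                     subject = factor(rep(seq_len(n), k)))
  if (branch == "parametric") {
    fit <- aov(value ~ window + Error(subject), data = long)
    tab <- summary(fit)[["Error: Within"]][[1]]
    stat <- tab["window", "F value"]
    p <- tab["window", "Pr(>F)"]
    ms_err <- tab["Residuals", "Mean Sq"]
    df_err <- tab["Residuals", "Df"]
    posthoc <- NULL
    if (is.finite(p) && p < alpha)
      posthoc <- snk_stepwise(colMeans(x), colnames(x),
                              se = sqrt(ms_err / n), df_err = df_err,
                              alpha = alpha)
    new_stat_result("one-way repeated-measures ANOVA", stat, p,
                    df = c(tab["window", "Df"], df_err), n = n,
                    branch = "parametric", posthoc = posthoc,
                    assumptions = assumptions, alpha = alpha)
  } else {
    ft <- friedman.test(x)
    posthoc <- NULL
    if (is.finite(ft$p.value) && ft$p.value < alpha) {
      ranks <- t(apply(x, 1, rank))
      rank_sums <- colSums(ranks)
      se <- sqrt(n * k * (k + 1) / 12)
      posthoc <- snk_stepwise(rank_sums, colnames(x), se = se,
                              df_err = Inf, alpha = alpha)
    }
    new_stat_result("Friedman ANOVA on ranks",
                    unname(ft$statistic), ft$p.value,
                    df = unname(ft$parameter), n = n,
                    branch = "nonparametric", posthoc = posthoc,
                    assumptions = assumptions, alpha = alpha)
  }
}

#' Paired comparison of two dependent groups
#'
#' Shapiro-Wilk on the paired differences gates a two-tailed paired t-test
#' (normal) against a Wilcoxon signed-rank test (non-normal). All-zero
#' differences are reported as statistic 0, p = 1.
#'
#' @param a,b Numeric vectors of per-mouse means, paired by position.
#' @param branch `"auto"`, `"parametric"` or `"nonparametric"`.
#' @param alpha Significance level.
#' @return A `stat_result`.
#' @export
paired_group_comparison <- function(a, b, branch = c("auto", "parametric",
                                                     "nonparametric"),
                                    alpha = 0.05) {
  branch <- match.arg(branch)
  if (length(a) != length(b))
    stop("groups must be paired (equal length)", call. = FALSE)
  if (length(a) < 3) stop("need at least 3 pairs", call. = FALSE)
  d <- a - b
  if (sd(d) == 0) {
    if (all(d == 0))
      return(new_stat_result("paired t-test", 0, 1, df = length(d) - 1,
                             n = length(d), branch = "parametric",
                             alpha = alpha))
    # constant non-zero shift: difference has no variance to test against
    return(new_stat_result("paired t-test", sign(mean(d)) * Inf, 0,
                           df = length(d) - 1, n = length(d),
                           branch = "parametric", alpha = alpha))
  }
  assumptions <- NULL
  if (branch == "auto") {
    sp <- shapiro.test(d)$p.value
    assumptions <- list(shapiro_p = sp)
    branch <- if (sp > 0.05) "parametric" else "nonparametric"
  }
  if (branch == "parametric") {
    tt <- t.test(a, b, paired = TRUE)
    new_stat_result("paired t-test", unname(tt$statistic), tt$p.value,
                    df = unname(tt$parameter), n = length(d),
                    branch = branch, assumptions = assumptions,
                    alpha = alpha)
  } else {
    wt <- suppressWarnings(wilcox.test(a, b, paired = TRUE))
    new_stat_result("Wilcoxon signed-rank test", unname(wt$statistic),
                    wt$p.value, n = length(d), branch = branch,
                    assumptions = assumptions, alpha = alpha)
  }
}

new_regression_result <- function(slope, intercept, r_squared, p_value,
                                  n_points, x_label, y_label, data = NULL) {
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r_squared, p_value = p_value,
                 n_points = n_points, x_label = x_label, y_label = y_label,
                 data = data),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(
    "<regression_result> %s ~ %s: slope = %.4g, R^2 = %.3f, p = %.4g (n = %d)\n",
    x$y_label, x$x_label, x$slope, x$r_squared, x$p_value, x$n_points))
  invisible(x)
}

# Fit an OLS line and package the result.
ols_result <- function(xv, yv, x_label, y_label, data = NULL) {
  fit <- lm(yv ~ xv)
  sm <- summary(fit)
  p <- if (nrow(sm$coefficients) > 1) sm$coefficients[2, 4] else NA_real_
  new_regression_result(slope = unname(coef(fit)[2]),
                        intercept = unname(coef(fit)[1]),
                        r_squared = sm$r.squared, p_value = p,
                        n_points = length(xv),
                        x_label = x_label, y_label = y_label, data = data)
}

#' Regression of Ca2+ signal on locomotor speed across speed bins
#'
#' Per locomotor bout, the Z-score and the speed are averaged over the bout;
#' bouts are sorted into speed bins of `bin_width` cm/s (`[k, k+1)`), the
#' Z-score is averaged per bin, and the per-bin means are regressed on the
#' bin-center speed by ordinary least squares.
#'
#' @param bouts A [bout_set()]; only `locomotion` bouts are used.
#' @param signal A `processed_signal`.
#' @param speed A `speed_trace`.
#' @param bin_width Speed bin width in cm/s (default 1).
#' @return A `regression_result`; `data` holds the per-bin means and counts.
#' @export
speed_binned_regression <- function(bouts, signal, speed, bin_width = 1) {
  stopifnot(inherits(bouts, "bout_set"))
  loco <- bouts[bouts$kind == "locomotion", , drop = FALSE]
  t_sig <- trace_time(signal)
  per_bout <- lapply(seq_len(nrow(loco)), function(i) {
    on <- loco$onset[i]; off <- loco$offset[i]
    zs <- signal$z[t_sig >= on & t_sig < off]
    sel <- speed$time >= on & speed$time < off & !is.na(speed$speed)
    if (!length(zs) || !any(sel)) return(NULL)
    data.frame(mean_z = mean(zs), mean_speed = mean(speed$speed[sel]))
  })
  per_bout <- do.call(rbind, per_bout[!vapply(per_bout, is.null, logical(1))])
  if (is.null(per_bout) || !nrow(per_bout))
    stop("no locomotor bouts with usable signal and speed", call. = FALSE)
  bin <- factor(floor(per_bout$mean_speed / bin_width),
                levels = sort(unique(floor(per_bout$mean_speed / bin_width))))
  agg <- data.frame(
    bin_center = (as.numeric(levels(bin)) + 0.5) * bin_width,
    mean_z = as.numeric(tapply(per_bout$mean_z, bin, mean)),
    n_bouts = as.integer(table(bin)))
  if (nrow(agg) < 3)
    stop("need at least 3 non-empty speed bins (got ", nrow(agg), ")",
         call. = FALSE)
  ols_result(agg$bin_center, agg$mean_z,
             x_label = "speed_bin_center_cms", y_label = "mean_z",
             data = agg)
}

#' Habituation regression of response amplitude on trial number
#'
#' Mean during-window response per trial index, averaged across mice, is
#' regressed on the trial index by ordinary least squares. The percent
#' change between two trial indices is read off the fitted line:
#' `100 * (fit(j) - fit(i)) / fit(i)`.
#'
#' @param trial_index Integer vector of 1-based trial indices.
#' @param value Per-trial during-window means (same length).
#' @param mouse Optional mouse identifier per observation (used only for
#'   bookkeeping; aggregation averages across all observations at a trial
#'   index).
#' @param change_between Length-2 trial indices for the reported percent
#'   change (default first and last observed index).
#' @return A `regression_result` with extra fields `percent_change` and
#'   `change_between`; `data` holds the per-index means.
#' @export
habituation_regression <- function(trial_index, value, mouse = NULL,
                                   change_between = NULL) {
  stopifnot(length(trial_index) == length(value))
  ok <- is.finite(value)
  trial_index <- trial_index[ok]; value <- value[ok]
  idx <- sort(unique(trial_index))
  if (length(idx) < 3)
    stop("need data at >= 3 trial indices", call. = FALSE)
  means <- as.numeric(tapply(value, factor(trial_index, levels = idx), mean))
  res <- ols_result(idx, means, x_label = "trial_index",
                    y_label = "mean_response",
                    data = data.frame(trial_index = idx, mean = means))
  if (is.null(change_between)) change_between <- range(idx)
  fit_at <- function(i) res$intercept + res$slope * i
  f1 <- fit_at(change_between[1]); f2 <- fit_at(change_between[2])
  pc <- if (abs(f1) < .Machine$double.eps) {
    warning("fitted value at the reference trial is 0; percent change ",
            "undefined")
    NA_real_
  } else 100 * (f2 - f1) / f1
  res$percent_change <- pc
  res$change_between <- change_between
  res
}
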