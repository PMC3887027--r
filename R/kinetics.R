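# Derived cell-kinetics statistics: percent-of-reference normalization,
# dual-label marginals, the stochastic (independence) re-entry prediction and
# its test, cumulative recruitment, per-cell insulin normalization, and
# two-sample t-tests computed from summary statistics (mean, SEM, n).

#' Summary statistic (mean, SEM, n)
#'
#' @param mean Mean value.
#' @param sem Standard error of the mean, `>= 0`.
#' @param n Number of independent experiments, `>= 1`.
#' @return A `summary_stat` object.
#' @export
summary_stat <- function(mean, sem, n) {
  check_scalar(mean, "mean")
  check_scalar(sem, "sem", lower = 0)
  check_scalar(n, "n", lower = 1)
  structure(list(mean = mean, sem = sem, n = as.integer(n)),
            class = "summary_stat")
}

#' @export
print.summary_stat <- function(x, ...) {
  cat(sprintf("%.4g +/- %.4g (n = %d)\n", x$mean, x$sem, x$n))
  invisible(x)
}

#' Dual-label (EdU/BrdU) contingency fractions
#'
#' Holds the single- and double-positive percentages among counted cells,
#' with derived marginals `f_E = f_E_only + f_EB` and `f_B = f_B_only + f_EB`.
#' All values are on the percent scale.
#'
#' @param f_E_only,f_B_only,f_EB Percent EdU+BrdU-, BrdU+EdU- and EdU+BrdU+
#'   cells; each `>= 0`, summing to at most 100.
#' @param sem Optional named list/vector of SEMs for the three fields.
#' @param n Optional number of independent experiments.
#' @return A `dual_label_table` object.
#' @export
dual_label_table <- function(f_E_only, f_B_only, f_EB, sem = NULL, n = NULL) {
  check_scalar(f_E_only, "f_E_only", lower = 0)
  check_scalar(f_B_only, "f_B_only", lower = 0)
  check_scalar(f_EB, "f_EB", lower = 0)
  if (f_E_only + f_B_only + f_EB > 100 + 1e-9) {
    stop_data("label fractions sum to more than 100%")
  }
  structure(list(
    f_E_only = f_E_only, f_B_only = f_B_only, f_EB = f_EB,
    f_E = f_E_only + f_EB, f_B = f_B_only + f_EB,
    sem = sem, n = if (!is.null(n)) as.integer(n) else NULL
  ), class = "dual_label_table")
}

#' @export
print.dual_label_table <- function(x, ...) {
  cat(sprintf(
    "dual-label fractions (%%): E+B- %.2f | B+E- %.2f | E+B+ %.2f  (f_E %.2f, f_B %.2f)\n",
    x$f_E_only, x$f_B_only, x$f_EB, x$f_E, x$f_B))
  invisible(x)
}

#' Percent of a reference count
#'
#' Normalizes a count to a reference count (typically day 1 of culture),
#' on the percent scale: `100 * count_day / count_reference`.
#'
#' @param count_day Count at the day of interest.
#' @param count_reference Reference count, `> 0`.
#' @return Percent, scalar.
#' @export
percent_of_reference <- function(count_day, count_reference) {
  if (!is.finite(count_reference) || count_reference <= 0) {
    stop_undefined_fraction("reference count must be > 0")
  }
  100 * count_day / count_reference
}

#' Marginal labeled fractions of a dual-label table
#'
#' @param table A [dual_label_table()].
#' @return Named numeric `c(f_E =, f_B =)`, percent scale.
#' @export
marginal_fractions <- function(table) {
  stopifnot(inherits(table, "dual_label_table"))
  c(f_E = table$f_E, f_B = table$f_B)
}

#' Predicted double-positive fraction under stochastic replication
#'
#' The independence null model: if recruitment into the second labeling
#' window is independent of labeling in the first, the expected
#' double-positive percentage is the product of the marginals,
#' `f_E * f_B / 100`.
#'
#' @param f_E,f_B Marginal labeled percentages, each in `[0, 100]`.
#' @return Predicted percent double-positive.
#' @export
predicted_double <- function(f_E, f_B) {
  check_scalar(f_E, "f_E", lower = 0, upper = 100)
  check_scalar(f_B, "f_B", lower = 0, upper = 100)
  f_E * f_B / 100
}

#' Cell-cycle re-entry fraction
#'
#' Percent of first-window-labeled (EdU+) cells that were relabeled (BrdU+)
#' in the second window: `100 * f_EB / f_E`. This is the readout of a
#' daughter cell entering a second cycle.
#'
#' @param table A [dual_label_table()] with `f_E > 0`.
#' @return Percent of EdU+ cells that are also BrdU+.
#' @export
reentry_fraction <- function(table) {
  stopifnot(inherits(table, "dual_label_table"))
  if (table$f_E <= 0) stop_undefined_fraction("f_E is zero; re-entry fraction undefined")
  100 * table$f_EB / table$f_E
}

#' Two-sample t-test from summary statistics
#'
#' Recovers per-arm standard deviations as `sem * sqrt(n)` and computes the
#' two-tailed unpaired t-test, pooled-variance (Student) by default or Welch.
#'
#' @param a,b [summary_stat()] objects, each with `n >= 2`.
#' @param welch Use the Welch (unequal-variance) form.
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
t_test_from_summary <- function(a, b, welch = FALSE) {
  stopifnot(inherits(a, "summary_stat"), inherits(b, "summary_stat"))
  if (a$n < 2 || b$n < 2) stop_data("t-test needs n >= 2 in both arms")
  va <- (a$sem * sqrt(a$n))^2
  vb <- (b$sem * sqrt(b$n))^2
  if (va == 0 && vb == 0) {
    if (isTRUE(all.equal(a$mean, b$mean))) {
      return(list(t = 0, df = a$n + b$n - 2, p = 1))
    }
    warning("zero variance in both arms with unequal means; p = 0")
    return(list(t = sign(a$mean - b$mean) * Inf, df = a$n + b$n - 2, p = 0))
  }
  if (welch) {
    se2a <- va / a$n
    se2b <- vb / b$n
    tstat <- (a$mean - b$mean) / sqrt(se2a + se2b)
    df <- (se2a + se2b)^2 /
      (se2a^2 / (a$n - 1) + se2b^2 / (b$n - 1))
  } else {
    sp2 <- ((a$n - 1) * va + (b$n - 1) * vb) / (a$n + b$n - 2)
    tstat <- (a$mean - b$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
  }
  list(t = tstat, df = df, p = 2 * pt(-abs(tstat), df))
}

#' Test counted vs predicted double-positive fractions
#'
#' Compares the counted percent EdU+BrdU+ cells with the prediction of the
#' stochastic (independence) model. A counted value significantly below the
#' prediction indicates a post-mitotic refractory period.
#'
#' @param counted,predicted [summary_stat()] objects for the counted and
#'   predicted double-positive percentages.
#' @param alpha Significance level for the reported direction.
#' @param welch Passed to [t_test_from_summary()].
#' @return List with `t`, `df`, `p` and `direction` (one of `"lower"`,
#'   `"higher"`, `"indistinguishable"`), where direction refers to counted
#'   relative to predicted.
#' @export
stochastic_reentry_test <- function(counted, predicted, alpha = 0.05,
                                    welch = FALSE) {
  res <- t_test_from_summary(counted, predicted, welch = welch)
  res$direction <- if (res$p >= alpha) "indistinguishable" else {
    if (counted$mean < predicted$mean) "lower" else "higher"
  }
  res
}

#' Cumulative recruitment over successive labeling intervals
#'
#' Plain sum of per-interval labeled percentages over non-overlapping,
#' chronologically ordered intervals. Because an interval's percentage may
#' count both daughters of a cell activated in a prior interval, the sum can
#' overestimate the percent of distinct recruited cells; the result carries
#' an `overestimates` attribute documenting this.
#'
#' @param series data.frame with columns `start_day`, `end_day`,
#'   `percent_labeled`.
#' @return Summed percent with attribute `overestimates = TRUE`.
#' @export
cumulative_recruitment <- function(series) {
  if (nrow(series) == 0) {
    out <- 0
  } else {
    if (!all(c("start_day", "end_day", "percent_labeled") %in% names(series))) {
      stop_config("series needs columns start_day, end_day, percent_labeled")
    }
    series <- series[order(series$start_day), ]
    if (any(series$end_day <= series$start_day)) {
      stop_config("intervals must have start_day < end_day")
    }
    if (nrow(series) > 1 &&
        any(series$start_day[-1] < series$end_day[-nrow(series)] - 1e-9)) {
      stop_config("labeling intervals overlap")
    }
    out <- sum(series$percent_labeled)
  }
  attr(out, "overestimates") <- TRUE
  out
}

#' Hourly fractional insulin release
#'
#' Converts insulin released over a 72-hour collection into percent of
#' cellular insulin content discharged per hour:
#' `100 * release / (72 * content)`.
#'
#' @param release_per_72h Insulin released, ng per 10^3 cells per 72 h.
#' @param content Cellular insulin content, ng per 10^3 cells; `> 0`.
#' @return Percent of content per hour.
#' @export
hourly_fractional_release <- function(release_per_72h, content) {
  if (!is.finite(content) || content <= 0) {
    stop_undefined_fraction("insulin content must be > 0")
  }
  100 * release_per_72h / (72 * content)
}

#' Percent-of-reference across replicates, mean-of-ratios and ratio-of-means
#'
#' Given per-replicate counts at a day and at the reference day, computes the
#' per-replicate percentages and their mean +/- SEM (the mean-of-ratios
#' presentation) and, for transparency, the ratio of the mean counts.
#'
#' @param counts_day,counts_reference Equal-length numeric vectors of
#'   per-replicate counts; references must all be `> 0`.
#' @return List with `per_replicate`, `mean`, `sem`, `n`,
#'   `ratio_of_means`.
#' @export
percent_of_reference_replicates <- function(counts_day, counts_reference) {
  if (length(counts_day) != length(counts_reference)) {
    stop_data("replicate vectors must have equal length")
  }
  pr <- mapply(percent_of_reference, counts_day, counts_reference)
  n <- length(pr)
  list(per_replicate = pr,
       mean = mean(pr),
       sem = if (n > 1) sd(pr) / sqrt(n) else NA_real_,
       n = n,
       ratio_of_means = 100 * mean(counts_day) / mean(counts_reference))
}
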