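#' Two-sample t-test from summary statistics
#'
#' Independent two-sample t-test computed directly from per-group means,
#' SDs and sizes, as needed when only published "mean +/- SD, n" summaries
#' are available. `"pooled"` is the classical Student test (pooled variance,
#' df = n1 + n2 - 2); `"welch"` uses the Welch-Satterthwaite approximation.
#' Two-sided.
#'
#' @param mean1,sd1,n1 First group's mean, SD and size.
#' @param mean2,sd2,n2 Second group's mean, SD and size.
#' @param method `"pooled"` (default) or `"welch"`.
#' @return An object of class `htest` with the t statistic, degrees of
#'   freedom and two-sided p-value.
#' @examples
#' # days to post-breakfast target, 89 vs 93 patients
#' t_test_from_summary(2.9, 1.5, 89, 3.4, 1.4, 93)
#' @export
t_test_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                method = c("pooled", "welch")) {
  method <- match.arg(method)
  mean1 <- unname(mean1); sd1 <- unname(sd1); n1 <- unname(n1)
  mean2 <- unname(mean2); sd2 <- unname(sd2); n2 <- unname(n2)
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2")
  if (!is.finite(sd1) || !is.finite(sd2) || sd1 < 0 || sd2 < 0) {
    stop("SDs must be finite and >= 0")
  }
  if (method == "pooled") {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  tstat <- if (se == 0) 0 else (mean1 - mean2) / se
  p <- 2 * stats::pt(-abs(tstat), df)
  structure(
    list(
      statistic = c(t = tstat), parameter = c(df = df), p.value = p,
      estimate = c(`mean difference` = mean1 - mean2),
      method = sprintf("Two-sample t-test from summaries (%s)", method),
      alternative = "two.sided",
      data.name = sprintf("%.4g+/-%.4g (n=%d) vs %.4g+/-%.4g (n=%d)",
                          mean1, sd1, as.integer(n1), mean2, sd2,
                          as.integer(n2))
    ),
    class = "htest"
  )
}

#' Chi-square test for two proportions
#'
#' 2x2 chi-square test of x1/n1 vs x2/n2, by default without Yates
#' continuity correction (the trial's reported cells are all >= 5). A
#' degenerate table (a zero margin) returns statistic 0 and p = 1 with a
#' `degenerate` attribute.
#'
#' @param x1,n1 Events and size in group 1.
#' @param x2,n2 Events and size in group 2.
#' @param correct Apply the Yates continuity correction.
#' @return An `htest` with the X-squared statistic (1 df) and two-sided
#'   p-value.
#' @examples
#' two_proportion_test(10, 89, 13, 93)  # morning hypoglycemia rates
#' @export
two_proportion_test <- function(x1, n1, x2, n2, correct = FALSE) {
  stopifnot(x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2, n1 >= 1, n2 >= 1)
  o <- matrix(c(x1, n1 - x1, x2, n2 - x2), nrow = 2, byrow = TRUE)
  rs <- rowSums(o); cs <- colSums(o); tot <- sum(o)
  degenerate <- any(cs == 0) || any(rs == 0)
  if (degenerate) {
    stat <- 0; p <- 1
  } else {
    e <- outer(rs, cs) / tot
    dev <- abs(o - e)
    if (correct) dev <- pmax(dev - 0.5, 0)
    stat <- sum(dev^2 / e)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  structure(
    list(
      statistic = c(`X-squared` = stat), parameter = c(df = 1),
      p.value = p,
      estimate = c(prop1 = x1 / n1, prop2 = x2 / n2),
      method = paste0("Chi-square test for two proportions",
                      if (correct) " (Yates-corrected)"),
      alternative = "two.sided",
      data.name = sprintf("%d/%d vs %d/%d", x1, n1, x2, n2),
      degenerate = degenerate
    ),
    class = "htest"
  )
}

#' Enrollment size inflated for dropout
#'
#' @param n_per_group Evaluable patients required per group.
#' @param dropout_rate Anticipated dropout fraction in `[0, 1)`.
#' @return Total patients to recruit: `ceiling(2 * n_per_group /
#'   (1 - dropout_rate))`.
#' @examples
#' sample_size_with_dropout(86, 0.20)  # 215
#' @export
sample_size_with_dropout <- function(n_per_group, dropout_rate) {
  stopifnot(n_per_group >= 1)
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("`dropout_rate` must be in [0, 1)")
  }
  as.integer(ceiling(2 * n_per_group / (1 - dropout_rate)))
}

mean_sd_row <- function(x) {
  x <- x[!is.na(x)]
  c(n = length(x), mean = if (length(x)) mean(x) else NA_real_,
    sd = if (length(x) > 1) stats::sd(x) else NA_real_)
}

#' Arm-level endpoint report for a simulated trial
#'
#' Summarizes each arm the way the trial's results section is laid out:
#' mean +/- SD days to target for the fasting and three post-meal readings
#' (censored patients excluded from the mean and counted separately),
#' mean +/- SD final administered doses in units/day, and per-period,
#' per-level hypoglycemia percentages — each with a cross-arm p-value
#' (summary t-test for means, 2x2 chi-square for proportions).
#'
#' @param trial A `wit2_trial` from [run_trial()].
#' @param method t-test variant, `"pooled"` (default) or `"welch"`.
#' @return A `wit2_report` list of data frames: `days_to_target` (4 rows),
#'   `final_doses` (4 rows), `hypoglycemia` (one row per period x level
#'   with both arms' counts) — plus `meta` echoing the trial metadata.
#' @export
arm_report <- function(trial, method = "pooled") {
  stopifnot(inherits(trial, "wit2_trial"))
  rec <- trial$records
  arms <- names(trial$meta$n_arms)
  if (!all(table(rec$arm) > 0)) stop("both arms must be non-empty")
  a1 <- rec[rec$arm == arms[1], ]
  a2 <- rec[rec$arm == arms[2], ]

  endpoint_tab <- function(cols, labels) {
    do.call(rbind, lapply(seq_along(cols), function(i) {
      x1 <- a1[[cols[i]]]; x2 <- a2[[cols[i]]]
      s1 <- mean_sd_row(x1); s2 <- mean_sd_row(x2)
      p <- if (s1["n"] >= 2 && s2["n"] >= 2 && s1["sd"] > 0 && s2["sd"] > 0) {
        t_test_from_summary(s1["mean"], s1["sd"], s1["n"],
                            s2["mean"], s2["sd"], s2["n"],
                            method = method)$p.value
      } else NA_real_
      data.frame(
        endpoint = labels[i],
        mean_1 = unname(s1["mean"]), sd_1 = unname(s1["sd"]),
        n_1 = unname(s1["n"]), n_censored_1 = sum(is.na(x1)),
        mean_2 = unname(s2["mean"]), sd_2 = unname(s2["sd"]),
        n_2 = unname(s2["n"]), n_censored_2 = sum(is.na(x2)),
        p_value = p
      )
    }))
  }
  days <- endpoint_tab(
    c("days_fbg", "days_breakfast", "days_lunch", "days_dinner"),
    c("days to FBG target", "days to 2hBG target (breakfast)",
      "days to 2hBG target (lunch)", "days to 2hBG target (dinner)"))
  doses <- endpoint_tab(
    c("final_basal_units", "final_breakfast_units", "final_lunch_units",
      "final_dinner_units"),
    c("final basal (units/day)", "final pre-breakfast bolus (units/day)",
      "final pre-lunch bolus (units/day)", "final pre-dinner bolus (units/day)"))

  hb <- hypo_by_period(trial)
  h1 <- hb[hb$arm == arms[1], ]
  h2 <- hb[hb$arm == arms[2], ]
  key <- c("period", "level")
  hypo <- merge(h1[, c(key, "n_patients", "n_arm", "pct")],
                h2[, c(key, "n_patients", "n_arm", "pct")],
                by = key, suffixes = c("_1", "_2"), sort = FALSE)
  hypo$p_value <- mapply(function(x1, n1, x2, n2) {
    two_proportion_test(x1, n1, x2, n2)$p.value
  }, hypo$n_patients_1, hypo$n_arm_1, hypo$n_patients_2, hypo$n_arm_2)
  hypo <- hypo[order(match(hypo$period, PERIODS), hypo$level), ]

  structure(
    list(days_to_target = days, final_doses = doses, hypoglycemia = hypo,
         arms = arms, meta = trial$meta),
    class = "wit2_report"
  )
}

#' @export
print.wit2_report <- function(x, digits = 2, ...) {
  cat(sprintf("Endpoint report: arm 1 = %s, arm 2 = %s\n", x$arms[1], x$arms[2]))
  cat("\nDays to target (mean +/- SD, censored excluded):\n")
  print(format_num_df(x$days_to_target, digits), row.names = FALSE)
  cat("\nFinal administered doses:\n")
  print(format_num_df(x$final_doses, digits), row.names = FALSE)
  cat("\nPatients with hypoglycemia (any-level and by level):\n")
  print(x$hypoglycemia[x$hypoglycemia$level %in% c("any", "1", "2"), ],
        row.names = FALSE)
  invisible(x)
}

format_num_df <- function(df, digits) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, digits + 1))
  df
}
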