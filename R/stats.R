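#' Unpaired two-sample t-test
#'
#' Classical pooled-variance (Student) t-test by default, Welch when
#' `equal_variance = FALSE`; two-sided p-value. Degenerate inputs where
#' both groups have zero variance resolve by convention: p = 1 when the
#' means agree, p = 0 otherwise.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param equal_variance pool the variances (Student) or not (Welch).
#' @param group_labels length-2 character vector naming the groups.
#' @return Object of class `GroupComparison`: `group_labels`, `n`,
#'   `means`, `sds`, `t_statistic`, `degrees_of_freedom`, `p_value`,
#'   `method`.
#' @export
unpaired_t_test <- function(a, b, equal_variance = TRUE,
                            group_labels = c("a", "b")) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("podoquant_insufficient_n: each group needs n >= 2")
  if (var(a) == 0 && var(b) == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    res <- list(t = if (eq) 0 else sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2,
                p = if (eq) 1 else 0)
  } else {
    tt <- stats::t.test(a, b, var.equal = equal_variance)
    res <- list(t = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value)
  }
  structure(list(group_labels = group_labels,
                 n = c(length(a), length(b)),
                 means = c(mean(a), mean(b)),
                 sds = c(sd(a), sd(b)),
                 t_statistic = res$t, degrees_of_freedom = res$df,
                 p_value = res$p,
                 method = if (equal_variance) "student" else "welch"),
            class = "GroupComparison")
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat(sprintf("%s vs %s: %.4g +/- %.4g (n=%d) vs %.4g +/- %.4g (n=%d)\n",
              x$group_labels[1], x$group_labels[2],
              x$means[1], x$sds[1], x$n[1], x$means[2], x$sds[2], x$n[2]))
  cat(sprintf("%s t = %.4g, df = %.4g, p = %.4g\n", x$method,
              x$t_statistic, x$degrees_of_freedom, x$p_value))
  invisible(x)
}

#' t-test from group summary statistics
#'
#' Computes the same unpaired t-test as [unpaired_t_test()] from
#' sufficient statistics (mean, dispersion, n per group), enabling checks
#' against published summary tables. With `dispersion = "sem"` the given
#' dispersions are standard errors of the mean and are converted to SDs.
#'
#' @param mean_a,mean_b group means.
#' @param disp_a,disp_b group dispersions (SD, or SEM if
#'   `dispersion = "sem"`); non-negative.
#' @param n_a,n_b group sizes (>= 2).
#' @param equal_variance pooled (Student) or Welch.
#' @param dispersion how to read `disp_a`/`disp_b`: `"sd"` or `"sem"`.
#' @inheritParams unpaired_t_test
#' @return A `GroupComparison`, identical (to numerical precision) to
#'   [unpaired_t_test()] on any raw data with these sufficient statistics.
#' @export
t_test_from_summary <- function(mean_a, disp_a, n_a, mean_b, disp_b, n_b,
                                equal_variance = TRUE,
                                dispersion = c("sd", "sem"),
                                group_labels = c("a", "b")) {
  dispersion <- match.arg(dispersion)
  if (disp_a < 0 || disp_b < 0)
    stop("podoquant_bad_dispersion: dispersions must be non-negative")
  if (n_a < 2L || n_b < 2L)
    stop("podoquant_insufficient_n: each group needs n >= 2")
  sd_a <- if (dispersion == "sem") disp_a * sqrt(n_a) else disp_a
  sd_b <- if (dispersion == "sem") disp_b * sqrt(n_b) else disp_b
  if (sd_a == 0 && sd_b == 0) {
    eq <- isTRUE(all.equal(mean_a, mean_b))
    t <- if (eq) 0 else sign(mean_a - mean_b) * Inf
    df <- n_a + n_b - 2
    p <- if (eq) 1 else 0
  } else if (equal_variance) {
    sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)
    t <- (mean_a - mean_b) / sqrt(sp2 * (1 / n_a + 1 / n_b))
    df <- n_a + n_b - 2
    p <- 2 * pt(-abs(t), df)
  } else {
    va <- sd_a^2 / n_a; vb <- sd_b^2 / n_b
    t <- (mean_a - mean_b) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
    p <- 2 * pt(-abs(t), df)
  }
  structure(list(group_labels = group_labels, n = c(n_a, n_b),
                 means = c(mean_a, mean_b), sds = c(sd_a, sd_b),
                 t_statistic = t, degrees_of_freedom = df, p_value = p,
                 method = if (equal_variance) "student" else "welch"),
            class = "GroupComparison")
}

#' Ordinary least-squares regression of y on x
#'
#' Simple linear regression with the two-sided slope p-value, as used for
#' relating image-derived metrics to continuous clinical parameters.
#'
#' @param x,y numeric vectors of equal length, n >= 3; `x` not constant.
#' @return Object of class `RegressionResult`: `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n`.
#' @export
linear_regression <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L)
    stop("podoquant_insufficient_n: regression needs n >= 3")
  if (var(x) == 0)
    stop("podoquant_constant_x: x must vary")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients[2, 4],
                 n = length(x)),
            class = "RegressionResult")
}

#' @export
print.RegressionResult <- function(x, ...) {
  cat(sprintf("OLS: y = %.4g + %.4g x, r^2 = %.3f, p = %.4g, n = %d\n",
              x$intercept, x$slope, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Grade-stratified cohort report from raw per-case values
#'
#' Merges case summaries with clinical metadata, stratifies by
#' `grade_group` (early I/II vs late III/IV), and for every numeric
#' variable reports group means, SDs and sizes, a pairwise Student
#' t-test, the equal-weight pooled mean of the two group means, and the
#' late/early ratio in percent. Groups with n < 2 yield `NA` comparisons
#' (flagged missing, never dropped rows).
#'
#' @param cases data frame of per-case values carrying `case_id`.
#' @param metadata data frame from [read_case_metadata()] (must carry
#'   `case_id` and `grade_group`); pass `NULL` if `cases` already has a
#'   `grade_group` column.
#' @param variables which numeric columns to report; default: all numeric
#'   columns except identifiers.
#' @param equal_variance see [unpaired_t_test()].
#' @return Data frame with one row per variable: `variable`,
#'   `mean_early`, `sd_early`, `n_early`, `mean_late`, `sd_late`,
#'   `n_late`, `pooled_mean`, `ratio_late_over_early_pct`, `t_statistic`,
#'   `degrees_of_freedom`, `p_value`.
#' @export
grade_stratified_report <- function(cases, metadata = NULL, variables = NULL,
                                    equal_variance = TRUE) {
  if (!is.null(metadata)) {
    cases <- merge(cases, metadata[, c("case_id",
                                       setdiff(names(metadata), names(cases)))],
                   by = "case_id")
  }
  if (!"grade_group" %in% names(cases))
    stop("podoquant_missing_grade: cases need a grade_group column")
  if (is.null(variables)) {
    variables <- names(cases)[vapply(cases, is.numeric, logical(1))]
    variables <- setdiff(variables, c("case_id", "n_glomeruli"))
  }
  early <- cases[cases$grade_group == "I/II", , drop = FALSE]
  late <- cases[cases$grade_group == "III/IV", , drop = FALSE]
  out <- do.call(rbind, lapply(variables, function(v) {
    ea <- early[[v]][!is.na(early[[v]])]
    la <- late[[v]][!is.na(late[[v]])]
    m1 <- if (length(ea)) mean(ea) else NA_real_
    m2 <- if (length(la)) mean(la) else NA_real_
    tt <- if (length(ea) >= 2 && length(la) >= 2)
      unpaired_t_test(ea, la, equal_variance, c("I/II", "III/IV"))
    else NULL
    data.frame(variable = v,
               mean_early = m1, sd_early = if (length(ea) > 1) sd(ea) else NA_real_,
               n_early = length(ea),
               mean_late = m2, sd_late = if (length(la) > 1) sd(la) else NA_real_,
               n_late = length(la),
               pooled_mean = mean(c(m1, m2)),
               ratio_late_over_early_pct =
                 if (!is.na(m1) && m1 != 0) 100 * m2 / m1 else NA_real_,
               t_statistic = if (is.null(tt)) NA_real_ else tt$t_statistic,
               degrees_of_freedom = if (is.null(tt)) NA_real_ else tt$degrees_of_freedom,
               p_value = if (is.null(tt)) NA_real_ else tt$p_value)
  }))
  rownames(out) <- NULL
  out
}

#' Grade-stratified report from published group summaries
#'
#' Same report surface as [grade_stratified_report()] but computed from
#' group-level summary statistics (mean, dispersion, n) such as a printed
#' clinical table, via [t_test_from_summary()]. Count variables (rows
#' with missing dispersion) get a combined sum instead of a t-test.
#'
#' @param summary data frame with columns `variable`, `group` (values
#'   `"I/II"` / `"III/IV"`), `mean`, `dispersion`, `n` — the layout of
#'   [load_cohort_summary()].
#' @param dispersion how to read the dispersion column (`"sd"`/`"sem"`).
#' @param equal_variance see [unpaired_t_test()].
#' @return Data frame with one row per variable: group means/dispersions,
#'   `pooled_mean` (equal-weight mean of group means), `group_sum`,
#'   `ratio_late_over_early_pct`, `t_statistic`, `degrees_of_freedom`,
#'   `p_value`.
#' @export
cohort_summary_report <- function(summary, dispersion = c("sd", "sem"),
                                  equal_variance = TRUE) {
  dispersion <- match.arg(dispersion)
  need <- c("variable", "group", "mean", "dispersion", "n")
  if (!all(need %in% names(summary)))
    stop("podoquant_bad_summary: need columns ", paste(need, collapse = ", "))
  out <- do.call(rbind, lapply(unique(summary$variable), function(v) {
    ea <- summary[summary$variable == v & summary$group == "I/II", ]
    la <- summary[summary$variable == v & summary$group == "III/IV", ]
    if (nrow(ea) != 1L || nrow(la) != 1L)
      stop("podoquant_bad_summary: variable ", v, " must appear once per group")
    have_disp <- !is.na(ea$dispersion) && !is.na(la$dispersion)
    tt <- if (have_disp)
      t_test_from_summary(ea$mean, ea$dispersion, ea$n,
                          la$mean, la$dispersion, la$n,
                          equal_variance, dispersion, c("I/II", "III/IV"))
    else NULL
    data.frame(variable = v,
               mean_early = ea$mean, disp_early = ea$dispersion, n_early = ea$n,
               mean_late = la$mean, disp_late = la$dispersion, n_late = la$n,
               pooled_mean = mean(c(ea$mean, la$mean)),
               group_sum = ea$mean + la$mean,
               ratio_late_over_early_pct =
                 if (ea$mean != 0) 100 * la$mean / ea$mean else NA_real_,
               t_statistic = if (is.null(tt)) NA_real_ else tt$t_statistic,
               degrees_of_freedom = if (is.null(tt)) NA_real_ else tt$degrees_of_freedom,
               p_value = if (is.null(tt)) NA_real_ else tt$p_value)
  }))
  rownames(out) <- NULL
  out
}
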