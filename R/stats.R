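#' Distribution-gated two-group comparison
#'
#' Tests each group for normality with the Kolmogorov-Smirnov test
#' (Lilliefors correction for estimated parameters, at the 0.05 level).
#' If both groups pass, a Student's t-test (pooled variance) is used;
#' otherwise a Mann-Whitney U test (normal approximation with average
#' ranks, no continuity correction, the SPSS asymptotic convention).
#'
#' @param table data.frame of morphometry records.
#' @param variable name of the numeric column to compare.
#' @param group name of the two-level grouping column.
#' @param alpha_normality significance level of the normality gate.
#' @return List with `test` ("t" or "mann-whitney"), `statistic`, `p`,
#'   per-group `normal_p`, and group summaries.
#' @export
compare_groups <- function(table, variable, group,
                           alpha_normality = 0.05) {
  x <- table[[variable]]
  g <- factor(table[[group]])
  if (nlevels(g) != 2) stop("grouping column must have exactly two levels")
  xs <- split(x, g)
  if (any(vapply(xs, length, 0L) < 3)) stop("need n >= 3 per group")
  if (any(vapply(xs, stats::sd, 0) == 0)) {
    stop("variable '", variable, "' is constant within a group")
  }
  norm_p <- vapply(xs, function(v) nortest::lillie.test(v)$p.value, 0)
  if (all(norm_p > alpha_normality)) {
    tt <- stats::t.test(xs[[1]], xs[[2]], var.equal = TRUE)
    res <- list(test = "t", statistic = unname(tt$statistic),
                p = tt$p.value)
  } else {
    wt <- stats::wilcox.test(xs[[1]], xs[[2]], exact = FALSE,
                             correct = FALSE)
    res <- list(test = "mann-whitney", statistic = unname(wt$statistic),
                p = wt$p.value)
  }
  res$normal_p <- norm_p
  res$summary <- data.frame(
    group = names(xs),
    n = vapply(xs, length, 0L),
    mean = vapply(xs, mean, 0),
    sd = vapply(xs, stats::sd, 0),
    min = vapply(xs, min, 0),
    max = vapply(xs, max, 0), row.names = NULL)
  res
}

#' Pearson correlations for declared variable pairs
#'
#' @param table data.frame of records.
#' @param pairs list of length-2 character vectors, e.g.
#'   `list(c("alpha", "NSA"))`.
#' @return data.frame with `x`, `y`, `r`, `p`, `n` per pair.
#' @export
correlate <- function(table, pairs) {
  if (!is.list(pairs)) pairs <- list(pairs)
  do.call(rbind, lapply(pairs, function(p) {
    ct <- stats::cor.test(table[[p[1]]], table[[p[2]]], method = "pearson")
    data.frame(x = p[1], y = p[2], r = unname(ct$estimate),
               p = ct$p.value, n = sum(stats::complete.cases(
                 table[[p[1]]], table[[p[2]]])))
  }))
}

#' Simple linear regression (OLS)
#'
#' @param table data.frame of records.
#' @param predictor,response column names.
#' @return data.frame with `response`, `predictor`, `intercept`, `slope`,
#'   `r_squared` (one row, same layout as [pct_models()]).
#' @export
fit_line <- function(table, predictor, response) {
  x <- table[[predictor]]
  y <- table[[response]]
  if (length(x) < 3) stop("need n >= 3")
  if (stats::sd(x) == 0) stop("predictor is constant")
  fit <- stats::lm(y ~ x)
  data.frame(response = response, predictor = predictor,
             intercept = unname(stats::coef(fit)[1]),
             slope = unname(stats::coef(fit)[2]),
             r_squared = summary(fit)$r.squared,
             stringsAsFactors = FALSE)
}

#' Intraclass correlation coefficient
#'
#' Two-way random-effects, absolute-agreement, single-measures ICC(2,1)
#' (default), or two-way mixed consistency ICC(3,1), computed from the
#' two-way ANOVA mean squares with the F-based 95% confidence interval.
#' This is the reliability measure used for intra-/inter-observer
#' agreement of repeated morphometry measurements.
#'
#' @param ratings numeric matrix, cases in rows, raters/sessions in columns;
#'   complete (no missing cells).
#' @param model `"ICC2"` (two-way random, absolute agreement) or
#'   `"ICC3"` (two-way mixed, consistency).
#' @param conf confidence level.
#' @return List with `icc`, `lower`, `upper`, `model`.
#' @examples
#' set.seed(1)
#' truth <- rnorm(20, 0, 4.23)
#' m <- cbind(truth + rnorm(20, 0, 1.5), truth + rnorm(20, 0, 1.5))
#' icc(m)$icc
#' @export
icc <- function(ratings, model = c("ICC2", "ICC3"), conf = 0.95) {
  model <- match.arg(model)
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("ratings grid has missing cells")
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (k < 2 || n < 5) stop("need >= 2 raters and >= 5 cases")
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  grand <- mean(ratings)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((ratings - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  a <- (1 - conf) / 2
  if (model == "ICC3") {
    est <- (msr - mse) / (msr + (k - 1) * mse)
    f_obs <- msr / mse
    fl <- f_obs / stats::qf(1 - a, n - 1, (n - 1) * (k - 1))
    fu <- f_obs * stats::qf(1 - a, (n - 1) * (k - 1), n - 1)
    lower <- (fl - 1) / (fl + k - 1)
    upper <- (fu - 1) / (fu + k - 1)
  } else {
    est <- (msr - mse) /
      (msr + (k - 1) * mse + k * (msc - mse) / n)
    # Shrout-Fleiss approximate CI for ICC(2,1)
    fj <- msc / mse
    vn <- (k - 1) * (n - 1) *
      (k * est * fj + n * (1 + (k - 1) * est) - k * est)^2
    vd <- (n - 1) * k^2 * est^2 * fj^2 +
      (n * (1 + (k - 1) * est) - k * est)^2
    v <- vn / vd
    f_obs <- msr / mse
    fl <- f_obs / stats::qf(1 - a, n - 1, v)
    fu <- f_obs * stats::qf(1 - a, v, n - 1)
    lower <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
  }
  list(icc = est, lower = min(lower, upper), upper = max(lower, upper),
       model = model)
}

#' Cohort statistics report
#'
#' Summarizes a morphometry table the way the source analysis does:
#' per-variable mean, SD and range by group and in total with the
#' distribution-gated group test; Pearson correlations for the declared
#' pairs; simple OLS regressions; and radius-standardized boundary lengths
#' (L_bottom / R, L_top / R).
#'
#' @param table morphometry data.frame (one row per case).
#' @param group grouping column name (default `"gender"`).
#' @param variables numeric columns to summarize.
#' @param pairs correlation pairs, as in [correlate()].
#' @param regressions list of `c(response, predictor)` pairs to fit.
#' @return List of class `cohort_report` with elements `summary`,
#'   `correlations`, `regressions`, `standardized`.
#' @export
cohort_report <- function(table, group = "gender",
                          variables = c("R", "meanHU", "NSA", "alpha",
                                        "beta", "delta", "L_bottom",
                                        "L_top"),
                          pairs = list(c("alpha", "NSA"), c("delta", "NSA"),
                                       c("L_top", "R"), c("L_bottom", "R")),
                          regressions = list(c("alpha", "NSA"),
                                             c("beta", "NSA"),
                                             c("delta", "NSA"),
                                             c("L_top", "R"),
                                             c("L_bottom", "R"))) {
  variables <- intersect(variables, names(table))
  summ <- do.call(rbind, lapply(variables, function(v) {
    cg <- compare_groups(table, v, group)
    tot <- table[[v]]
    data.frame(variable = v,
               total_mean = mean(tot), total_sd = stats::sd(tot),
               total_min = min(tot), total_max = max(tot),
               test = cg$test, p = cg$p)
  }))
  reg <- do.call(rbind, lapply(regressions, function(rp) {
    fit_line(table, rp[2], rp[1])
  }))
  std <- data.frame(
    L_bottom_over_R = mean(table$L_bottom / table$R),
    L_bottom_over_R_sd = stats::sd(table$L_bottom / table$R),
    L_top_over_R = mean(table$L_top / table$R),
    L_top_over_R_sd = stats::sd(table$L_top / table$R))
  structure(list(summary = summ, correlations = correlate(table, pairs),
                 regressions = reg, standardized = std),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Cohort morphometry report\n\nPer-variable summary (total):\n")
  s <- x$summary
  s[sapply(s, is.numeric)] <- lapply(s[sapply(s, is.numeric)], round, 2)
  print(s, row.names = FALSE)
  cat("\nCorrelations:\n")
  cc <- x$correlations
  cc$r <- round(cc$r, 3)
  print(cc, row.names = FALSE)
  cat("\nRegressions:\n")
  r <- x$regressions
  r[c("intercept", "slope", "r_squared")] <-
    lapply(r[c("intercept", "slope", "r_squared")], round, 3)
  print(r, row.names = FALSE)
  invisible(x)
}
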