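test_that("identical samples give p = 1 under the rank test", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  tab <- data.frame(v = c(x, x), g = rep(c("a", "b"), each = 8))
  # identical samples are non-normal-gated or not; force the rank branch
  # by making the data clearly non-normal
  tab$v <- rep(c(1, 1, 1, 1, 1, 1, 1, 50), 2)
  res <- compare_groups(tab, "v", "g")
  expect_equal(res$test, "mann-whitney")
  expect_equal(res$p, 1)
})

test_that("the normality gate selects t for normal and rank test for
           skewed data", {
  set.seed(42)
  tab <- data.frame(v = rnorm(200), g = rep(c("a", "b"), 100))
  expect_equal(compare_groups(tab, "v", "g")$test, "t")
  tab$v <- rexp(200)^3
  expect_equal(compare_groups(tab, "v", "g")$test, "mann-whitney")
  tab$v <- 1
  expect_error(compare_groups(tab, "v", "g"), "constant")
})

test_that("gender difference in head radius is detected with near-full
           power at the published effect size", {
  hits <- 0
  for (s in 1:200) {
    tab <- simulate_cohort(cohort_params(125), seed = s)
    if (compare_groups(tab, "R", "gender")$p < 0.05) hits <- hits + 1
  }
  expect_gt(hits / 200, 0.99)
})

test_that("the test holds its nominal level under the null", {
  set.seed(99)
  rej <- 0
  n_rep <- 800
  for (s in 1:n_rep) {
    tab <- data.frame(v = rnorm(125, 126.85, 5.85),
                      g = rep(c("m", "f"), length.out = 125))
    if (compare_groups(tab, "v", "g")$p < 0.05) rej <- rej + 1
  }
  expect_lt(abs(rej / n_rep - 0.05), 0.025)
})

test_that("correlation: exact, null, and cohort-structured cases", {
  tab <- data.frame(x = 1:20, y = 2 * (1:20) + 5)
  expect_equal(correlate(tab, list(c("x", "y")))$r, 1, tolerance = 1e-12)
  set.seed(2)
  tabi <- data.frame(x = rnorm(3000), y = rnorm(3000))
  expect_lt(abs(correlate(tabi, list(c("x", "y")))$r), 0.05)
})

test_that("OLS recovers exact lines and obeys the r^2 identity", {
  tab <- data.frame(x = seq(0, 10, by = 0.5))
  tab$y <- 2 * tab$x + 1
  f <- fit_line(tab, "x", "y")
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 1, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  set.seed(3)
  tab$y <- tab$y + rnorm(nrow(tab))
  f <- fit_line(tab, "x", "y")
  r <- correlate(tab, list(c("y", "x")))$r
  # algebraic identities of simple OLS
  expect_equal(f$r_squared, r^2, tolerance = 1e-9)
  expect_equal(f$slope * sd(tab$x) / sd(tab$y), r, tolerance = 1e-9)
})

test_that("ICC: perfect agreement, variance components, and pure noise", {
  set.seed(4)
  truth <- rnorm(20, 50, 4.23)
  dup <- cbind(truth, truth)
  expect_equal(icc(dup)$icc, 1, tolerance = 1e-9)
  # variance-components expectation: 4.23^2 / (4.23^2 + 1.5^2) = 0.888
  reps <- replicate(400, {
    t0 <- rnorm(20, 0, 4.23)
    icc(cbind(t0 + rnorm(20, 0, 1.5), t0 + rnorm(20, 0, 1.5)))$icc
  })
  expect_equal(mean(reps), 4.23^2 / (4.23^2 + 1.5^2), tolerance = 0.02)
  noise <- matrix(rnorm(60), 20, 3)
  expect_lt(abs(icc(noise)$icc), 0.35)
  expect_error(icc(matrix(c(1, NA, 2, 3, 4, 5, 6, 7, 8, 9), 5, 2)),
               "missing")
  # CI brackets the estimate
  r <- icc(cbind(truth + rnorm(20), truth + rnorm(20)))
  expect_true(r$lower <= r$icc && r$icc <= r$upper)
  r3 <- icc(dup, model = "ICC3")
  expect_equal(r3$icc, 1, tolerance = 1e-9)
})

test_that("cohort report assembles summaries, correlations, regressions
           and standardized lengths", {
  tab <- simulate_cohort(cohort_params(500), seed = 7)
  rep_ <- cohort_report(tab)
  expect_s3_class(rep_, "cohort_report")
  expect_equal(nrow(rep_$regressions), 5)
  a <- rep_$regressions[rep_$regressions$response == "alpha", ]
  expect_equal(a$slope, -0.498, tolerance = 0.1)
  expect_equal(rep_$correlations$r[1], -0.689, tolerance = 0.1)
  expect_gt(rep_$standardized$L_top_over_R, 0.5)
  expect_output(print(rep_), "Correlations")
})
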