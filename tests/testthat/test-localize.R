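fig8_annotation <- function(R = 26.51, NSA = 126.68) {
  th <- (180 - NSA) * pi / 180
  hn <- c(sin(th), cos(th))
  radiograph_annotation(O = c(0, 0), R = R, hn_dir = hn,
                        pfs_point = c(-48, -30), pfs_dir = c(0, -1),
                        tangent_point = 19 * c(cos(th), -sin(th)),
                        tangent_dir = hn)
}

test_that("regression predictions reproduce the published worked example", {
  p <- predict_params(NSA = 126.68, R = 26.51)
  expect_equal(round(p$alpha, 2), 37.42)
  expect_equal(round(p$delta, 2), 0.47)
  expect_equal(round(p$L_bottom, 2), 22.02)
  expect_equal(round(p$L_top, 2), 26.93)
})

test_that("regression predictions at other operating points (hand
           arithmetic on the published coefficients)", {
  p <- predict_params(NSA = 140, R = 20)
  expect_equal(round(p$alpha, 2), 30.79)
  expect_equal(round(p$delta, 2), -0.88)
  expect_equal(round(p$L_bottom, 2), 16.82)
  expect_equal(p$L_top, 18.425, tolerance = 1e-9)  # 18.43 half-up
  expect_error(predict_params(NSA = 80, R = 20), "NSA")
})

test_that("the two beta readings differ by exactly 0.002 * NSA", {
  for (nsa in c(112.7, 126.85, 143.06)) {
    p <- predict_params(nsa, 22)
    expect_equal(abs(p$beta_discrepancy), 0.002 * nsa, tolerance = 1e-9)
  }
})

test_that("localization satisfies its geometric invariants", {
  loc <- localize_pct(fig8_annotation())
  p <- loc$params
  expect_equal(vnorm(loc$A - loc$B), p$L_bottom, tolerance = 1e-9)
  expect_equal(vnorm(loc$C - loc$D), p$L_top, tolerance = 1e-9)
  # C and D on the head circle
  expect_equal(vnorm(loc$C - loc$O), loc$R, tolerance = 1e-9)
  expect_equal(vnorm(loc$D - loc$O), loc$R, tolerance = 1e-9)
  # the PCT-axis bisects both boundaries
  expect_lt(abs(signed_dist2((loc$A + loc$B) / 2, loc$axis_point,
                             loc$axis_dir)), 1e-9)
  expect_lt(abs(signed_dist2((loc$C + loc$D) / 2, loc$axis_point,
                             loc$axis_dir)), 1e-9)
  # chord midpoint sits sqrt(R^2 - (L_top/2)^2) = 22.84 mm from O
  expect_equal(vnorm((loc$C + loc$D) / 2 - loc$O),
               sqrt(26.51^2 - (p$L_top / 2)^2), tolerance = 1e-9)
  expect_equal(round(vnorm((loc$C + loc$D) / 2 - loc$O), 2), 22.84)
  # axis at alpha to the HN-axis, offset delta from O
  th <- (180 - 126.68) * pi / 180
  expect_equal(angle_between(loc$axis_dir, c(sin(th), cos(th))),
               p$alpha, tolerance = 1e-9)
  expect_equal(abs(signed_dist2(loc$O, loc$axis_point, loc$axis_dir)),
               abs(p$delta), tolerance = 1e-9)
})

test_that("zero offset puts the PCT-axis through the head center", {
  ann <- fig8_annotation()
  models <- pct_models()
  models$intercept[models$response == "delta"] <-
    0.101 * ann$NSA            # force predicted delta = 0
  loc <- localize_pct(ann, models)
  expect_lt(abs(signed_dist2(ann$O, loc$axis_point, loc$axis_dir)), 1e-9)
})

test_that("localization is equivariant under image rotation", {
  ann <- fig8_annotation()
  loc <- localize_pct(ann)
  phi <- 33 * pi / 180
  Rm <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  rot <- function(v) as.numeric(Rm %*% v)
  ann2 <- radiograph_annotation(O = rot(ann$O), R = ann$R,
                                hn_dir = rot(ann$hn_dir),
                                pfs_point = rot(ann$pfs_point),
                                pfs_dir = rot(ann$pfs_dir),
                                tangent_point = rot(ann$tangent_point),
                                tangent_dir = rot(ann$tangent_dir))
  loc2 <- localize_pct(ann2)
  for (nm in c("A", "B", "C", "D")) {
    expect_vector_equal(loc2[[nm]], rot(loc[[nm]]), 1e-8)
  }
})

test_that("impossible chords are reported", {
  ann <- fig8_annotation(R = 10)   # L_top prediction only slightly
  # below 2R, but delta may still be feasible; force failure via models
  models <- pct_models()
  models$intercept[models$response == "L_top"] <- 25   # L_top > 2R = 20
  expect_error(localize_pct(ann, models), "chord")
})

test_that("round trip: cohort alpha residuals around the model
           predictions have mean 0 and the residual SD", {
  tab <- simulate_cohort(cohort_params(4000), seed = 21)
  pred <- predict_params(tab$NSA, rep(22, nrow(tab)))
  res <- tab$alpha - pred$alpha
  expect_lt(abs(mean(res)), 0.15)
  expect_equal(sd(res), 3.07, tolerance = 0.12)
})
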