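test_that("ground truth echoes the generating parameters", {
  gt <- default_phantom()$ground_truth
  expect_equal(gt$R, 22.25)
  expect_equal(gt$NSA, 126.85)
  expect_equal(gt$alpha, 37.33)
  expect_equal(gt$delta, 0.39)
  expect_equal(gt$L_bottom, 18.62)
  expect_equal(gt$L_top, 21.37)
  expect_equal(gt$beta, 180 - 126.85 - 37.33)
  # quadrilateral self-consistency in world coordinates
  expect_equal(vnorm(gt$A - gt$B), gt$L_bottom, tolerance = 1e-9)
  expect_equal(vnorm(gt$C - gt$D), gt$L_top, tolerance = 1e-9)
  expect_equal(vnorm(gt$C - gt$O), gt$R, tolerance = 1e-9)
  expect_equal(vnorm(gt$D - gt$O), gt$R, tolerance = 1e-9)
  # U, L lie on the head sphere, M on the neck axis through O
  expect_equal(vnorm(gt$U - gt$O), gt$R, tolerance = 1e-9)
  expect_equal(vnorm(gt$L - gt$O), gt$R, tolerance = 1e-9)
  expect_lt(vnorm(pctmorph:::cross3(gt$M - gt$O, gt$hn_dir)), 1e-9)
})

test_that("the head-center voxel is cancellous or PCT, never soft", {
  ph <- default_phantom()
  spec <- ph$ground_truth$spec
  v <- sample_world(ph$volume, matrix(ph$ground_truth$O, 1))
  expect_true(v >= spec$hu_cancellous - 1)
  expect_true(v <= spec$hu_pct + 1)
})

test_that("same spec and seed reproduce the identical volume", {
  s <- phantom_spec(noise_sd = 25, spacing = 2)
  a <- build_phantom(s, seed = 11)
  b <- build_phantom(s, seed = 11)
  expect_identical(a$volume$values, b$volume$values)
})

test_that("two noise seeds differ only by a noise field of SD sqrt(2)*sd", {
  s <- phantom_spec(noise_sd = 30, spacing = 1.5)
  a <- build_phantom(s, seed = 1)
  b <- build_phantom(s, seed = 2)
  d <- as.vector(a$volume$values - b$volume$values)
  expect_lt(abs(mean(d)), 0.5)
  expect_equal(sd(d), sqrt(2) * 30, tolerance = 0.02)
})

test_that("infeasible slab geometry is rejected", {
  # offset beyond the chord-midpoint circle of the requested L_top
  expect_error(build_phantom(phantom_spec(L_top = 44, delta = 6,
                                          R = 22.25)),
               "infeasible")
  expect_error(phantom_spec(L_top = 50, R = 22.25))  # L_top > 2R
})

test_that("posed and mirrored phantoms transform the ground truth", {
  pose <- rigid_transform(list(axis = c(0.2, 1, 0.5), angle_deg = 25),
                          c(10, -5, 20))
  s0 <- phantom_spec(spacing = 2)
  s1 <- phantom_spec(spacing = 2, pose = pose)
  g0 <- build_phantom(s0, seed = 1)$ground_truth
  g1 <- build_phantom(s1, seed = 1)$ground_truth
  for (nm in c("O", "O1", "O2", "O3", "A", "C")) {
    expect_vector_equal(apply_rigid(pose, g0[[nm]]), g1[[nm]], 1e-9)
  }
  gl <- build_phantom(phantom_spec(spacing = 2, side = "left"),
                      seed = 1)$ground_truth
  expect_vector_equal(gl$O1, g0$O1 * c(-1, 1, 1), 1e-9)
  # volume value at a mirrored world point matches
  phr <- build_phantom(s0, seed = 1)
  phl <- build_phantom(phantom_spec(spacing = 2, side = "left"), seed = 1)
  p <- g0$O2 + c(3, 2, 1)
  expect_equal(sample_world(phl$volume, matrix(p * c(-1, 1, 1), 1)),
               sample_world(phr$volume, matrix(p, 1)), tolerance = 25)
})

test_that("cortical defects remove shell but keep the rest intact", {
  s0 <- phantom_spec(spacing = 1.5)
  s1 <- phantom_spec(spacing = 1.5, defect_fraction = 0.25)
  v0 <- build_phantom(s0, seed = 1)$volume
  v1 <- build_phantom(s1, seed = 1)$volume
  dif <- v0$values - v1$values
  expect_gt(sum(dif > 0), 50)                       # some shell removed
  expect_true(all(dif %in% c(0, s0$hu_cortex - s0$hu_cancellous)))
})

test_that("phantom specs survive a JSON round trip", {
  s <- phantom_spec(NSA = 131, alpha = 33.5, noise_sd = 12,
                    side = "left",
                    pose = rigid_transform(list(axis = c(0, 0, 1),
                                                angle_deg = 10),
                                           c(1, 2, 3)))
  path <- tempfile(fileext = ".json")
  write_phantom_spec(s, path)
  s2 <- read_phantom_spec(path)
  expect_equal(s2$NSA, s$NSA)
  expect_equal(s2$side, "left")
  expect_vector_equal(s2$pose$R, s$pose$R, 1e-9)
  expect_vector_equal(s2$pose$t, s$pose$t, 1e-9)
  unlink(path)
})
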