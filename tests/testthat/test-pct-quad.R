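# build a synthetic binarized projection directly from a binary matrix
synthetic_proj <- function(binary, u, v, O2d, R, hn_dir, aux_point,
                           aux_dir, pfs_dir = c(0, -1)) {
  structure(list(sum = binary * 100, count = binary * 10,
                 count_raw = binary * 10, binary = binary,
                 u = u, v = v, spacing = u[2] - u[1], n_layers = 10,
                 peel_mm = 0, peel_vox = -0.5,   # no erosion to compensate
                 O2d = O2d, R = R,
                 O1_2d = c(-40, -30), O3_2d = c(-40, -80),
                 hn2 = list(point = c(0, 0), direction = hn_dir),
                 pfs2 = list(point = c(-40, -30), direction = pfs_dir),
                 aux2 = list(point = aux_point, direction = aux_dir)),
            class = "pct_projection")
}

test_that("a rectangle crossing the aux line gives |AB| equal to its
           width exactly", {
  u <- seq(-2, 30, by = 0.5)
  v <- seq(-20, 20, by = 0.5)
  w <- 14
  binary <- outer(u, rep(1, length(v))) >= 1 &
    outer(rep(1, length(u)), v) >= -w / 2 &
    outer(rep(1, length(u)), v) <= w / 2 &
    outer(u, rep(1, length(v))) <= 25
  proj <- synthetic_proj(binary, u, v, O2d = c(15, 0), R = 40,
                         hn_dir = c(0, 1), aux_point = c(0, 0),
                         aux_dir = c(0, 1))
  bb <- bottom_boundary(proj, pct_config(gap_tol = 2))
  expect_equal(vnorm(bb$A - bb$B), w, tolerance = 1e-6)
  # A and B sit on the aux line
  expect_lt(abs(bb$A[1]), 1e-6)
  expect_lt(abs(bb$B[1]), 1e-6)
})

test_that("an exact trapezoid with top vertices on the head circle is
           recovered corner for corner", {
  spec <- phantom_spec()
  geo <- pctmorph:::phantom_geometry(spec)
  u <- seq(-45, 30, by = 0.25)
  v <- seq(-45, 30, by = 0.25)
  UU <- outer(u, rep(1, length(v)))
  VV <- outer(rep(1, length(u)), v)
  binary <- matrix(pctmorph:::in_convex_poly(as.vector(UU), as.vector(VV),
                                             geo$quad),
                   nrow = length(u))
  h2 <- geo$h[c(1, 3)]
  proj <- synthetic_proj(binary, u, v, O2d = c(0, 0), R = spec$R,
                         hn_dir = h2, aux_point = geo$aux_pt[c(1, 3)],
                         aux_dir = h2)
  bb <- bottom_boundary(proj, pct_config())
  tb <- top_boundary(proj, bb$A, bb$B, bb$edges)
  expect_lt(vnorm(bb$A - geo$quad["A", ]), 0.35)
  expect_lt(vnorm(bb$B - geo$quad["B", ]), 0.35)
  expect_lt(vnorm(tb$C - geo$quad["C", ]), 0.5)
  expect_lt(vnorm(tb$D - geo$quad["D", ]), 0.5)
  m <- measure_pct(proj, bb$A, bb$B, tb$C, tb$D)
  expect_equal(m$L_bottom, spec$L_bottom, tolerance = 0.5)
  expect_equal(m$L_top, spec$L_top, tolerance = 0.7)
  expect_equal(m$alpha, spec$alpha, tolerance = 0.5)
  expect_equal(m$delta, spec$delta, tolerance = 0.3)
  expect_equal(m$NSA, spec$NSA, tolerance = 1e-6)
  expect_equal(m$beta, 180 - m$NSA - m$alpha, tolerance = 1e-9)
})

test_that("an axis through the head center measures delta = 0 and the
           sign follows the lateral offset", {
  for (d0 in c(-2, 0, 3)) {
    spec <- phantom_spec(delta = if (d0 == 0) 1e-9 else d0)
    geo <- pctmorph:::phantom_geometry(spec)
    u <- seq(-45, 30, by = 0.25)
    v <- seq(-45, 30, by = 0.25)
    UU <- outer(u, rep(1, length(v)))
    VV <- outer(rep(1, length(u)), v)
    binary <- matrix(pctmorph:::in_convex_poly(as.vector(UU),
                                               as.vector(VV), geo$quad),
                     nrow = length(u))
    h2 <- geo$h[c(1, 3)]
    proj <- synthetic_proj(binary, u, v, c(0, 0), spec$R, h2,
                           geo$aux_pt[c(1, 3)], h2)
    bb <- bottom_boundary(proj, pct_config())
    tb <- top_boundary(proj, bb$A, bb$B, bb$edges)
    m <- measure_pct(proj, bb$A, bb$B, tb$C, tb$D)
    expect_equal(m$delta, spec$delta, tolerance = 0.3)
    if (abs(d0) >= 1) expect_equal(sign(m$delta), sign(d0))
  }
})

test_that("coincident axis midpoints are rejected", {
  proj <- synthetic_proj(matrix(TRUE, 4, 4), 1:4, 1:4, c(0, 0), 10,
                         c(0, 1), c(-2, 0), c(0, 1))
  expect_error(measure_pct(proj, c(0, 0), c(2, 0), c(-1, 0.5), c(3, -0.5)),
               "coincident")
})

test_that("a component that stops short of the aux line reports the gap", {
  u <- seq(-2, 30, by = 0.5)
  v <- seq(-20, 20, by = 0.5)
  binary <- outer(u, rep(1, length(v))) >= 10 &
    outer(rep(1, length(u)), v) >= -6 &
    outer(rep(1, length(u)), v) <= 6 &
    outer(u, rep(1, length(v))) <= 25
  proj <- synthetic_proj(binary, u, v, c(15, 0), 40, c(0, 1), c(0, 0),
                         c(0, 1))
  expect_error(bottom_boundary(proj, pct_config(gap_tol = 5)), "gap")
})

test_that("records assemble into the canonical table layout", {
  rec <- default_record()
  tab <- records_to_table(list(rec))
  expect_named(tab, c("case", "side", "R_mm", "meanHU", "NSA_deg",
                      "alpha_deg", "beta_deg", "delta_mm", "Lbottom_mm",
                      "Ltop_mm"))
  expect_equal(tab$beta_deg, 180 - tab$NSA_deg - tab$alpha_deg,
               tolerance = 1e-9)
})
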