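# Shared fixtures, built once per test run and cached.

.cache <- new.env(parent = emptyenv())

# default Table-1-mean phantom at 1 mm spacing, with its measurement
default_phantom <- function() {
  if (is.null(.cache$ph)) .cache$ph <- build_phantom(phantom_spec(), seed = 1)
  .cache$ph
}

default_record <- function() {
  if (is.null(.cache$rec)) {
    .cache$rec <- measure_case(default_phantom()$volume,
                               keep_intermediates = TRUE)
  }
  .cache$rec
}

# a small homogeneous ball volume for projection/mean-HU unit tests
ball_volume <- function(radius = 15, hu = 200, spacing = 1, pad = 5) {
  half <- radius + pad
  ax <- seq(-half, half, by = spacing)
  g <- expand.grid(x = ax, y = ax, z = ax)
  v <- ifelse(g$x^2 + g$y^2 + g$z^2 <= radius^2, hu, 0)
  ct_volume(array(v, c(length(ax), length(ax), length(ax))),
            spacing = rep(spacing, 3), origin = c(-half, -half, -half))
}

# minimal synthetic midcoronal frame for projection-level unit tests
synthetic_frame <- function(O = c(0, 0, 0), R = 15,
                            hn_dir = c(sin(53 * pi / 180),
                                       cos(53 * pi / 180)),
                            aux_point = c(12, -16),
                            pfs_point = c(-40, -30)) {
  structure(list(
    O = O, R = R, O1 = O + c(pfs_point[1], 0, pfs_point[2]),
    O2 = O, O3 = O + c(pfs_point[1], 0, pfs_point[2] - 50),
    basis = cbind(c(1, 0, 0), c(0, 0, 1), c(0, -1, 0)),  # (x, z, -y)
    hn2 = list(point = c(0, 0), direction = hn_dir),
    pfs2 = list(point = pfs_point, direction = c(0, -1)),
    aux2 = list(point = aux_point, direction = hn_dir),
    NSA = angle_between(hn_dir, c(0, -1)),
    config = pct_config()), class = "femur_frame")
}

expect_vector_equal <- function(a, b, tol = 1e-8) {
  expect_lt(max(abs(a - b)), tol)
}
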