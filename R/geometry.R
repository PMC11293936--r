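# Small 2D/3D vector-geometry helpers used throughout the pipeline.
# All world coordinates are in mm, LPS orientation (see read_volume).

vnorm <- function(v) sqrt(sum(v^2))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps^0.5) stop("cannot normalize a zero vector")
  v / n
}

#' @noRd
deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# Angle between two vectors, degrees in [0, 180].
angle_between <- function(a, b) {
  ca <- sum(unitv(a) * unitv(b))
  rad2deg(acos(max(-1, min(1, ca))))
}

# A world line as a point and a unit direction.
world_line <- function(point, direction) {
  list(point = as.numeric(point), direction = unitv(as.numeric(direction)))
}

# 2D perpendicular (rotate 90 deg counter-clockwise).
perp2 <- function(v) c(-v[2], v[1])

# Signed area test: >0 if p is on the counter-clockwise side of line(a, dir).
side_of_line2 <- function(p, point, direction) {
  d <- unitv(direction)
  d[1] * (p[2] - point[2]) - d[2] * (p[1] - point[1])
}

# Perpendicular distance from 2D point(s) to a 2D line; p may be an N x 2
# matrix. Returns signed distance along perp2(direction).
signed_dist2 <- function(p, point, direction) {
  d <- unitv(direction)
  if (is.matrix(p)) {
    d[1] * (p[, 2] - point[2]) - d[2] * (p[, 1] - point[1])
  } else {
    d[1] * (p[2] - point[2]) - d[2] * (p[1] - point[1])
  }
}

# Foot of the perpendicular from p onto the 2D line.
project_on_line2 <- function(p, point, direction) {
  d <- unitv(direction)
  point + sum((p - point) * d) * d
}

# Intersection of two 2D lines (point + direction); errors if parallel.
intersect_lines2 <- function(p1, d1, p2, d2) {
  d1 <- unitv(d1); d2 <- unitv(d2)
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(den) < 1e-12) stop("lines are parallel; no unique intersection")
  dp <- p2 - p1
  t <- (dp[1] * d2[2] - dp[2] * d2[1]) / den
  p1 + t * d1
}

# Intersections of a 2D line with a circle; returns 2 x 2 matrix (rows are
# points) or errors when the line misses the circle.
intersect_line_circle2 <- function(point, direction, center, radius) {
  d <- unitv(direction)
  f <- point - center
  b <- sum(f * d)
  c0 <- sum(f * f) - radius^2
  disc <- b^2 - c0
  if (disc < 0) stop("line misses the circle (gap ",
                     format(sqrt(-disc), digits = 3), " mm)")
  s <- sqrt(disc)
  rbind(point + (-b - s) * d, point + (-b + s) * d)
}

# Rotation matrix about a unit axis by angle degrees (Rodrigues).
rotation_about_axis <- function(axis, angle_deg) {
  k <- unitv(axis)
  th <- deg2rad(angle_deg)
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rigid (rotation + translation) transform
#'
#' A proper rigid motion in world coordinates, applied as
#' \code{x -> R x + t}. Used to pose synthetic phantoms arbitrarily.
#'
#' @param rotation 3x3 proper rotation matrix (orthonormal, det +1), or a
#'   list with `axis` (length-3) and `angle_deg` to build one.
#' @param translation length-3 translation, mm.
#' @return An object of class `rigid_transform`.
#' @examples
#' tr <- rigid_transform(list(axis = c(0, 0, 1), angle_deg = 30), c(5, 0, 0))
#' apply_rigid(tr, c(1, 0, 0))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  if (is.list(rotation)) {
    rotation <- rotation_about_axis(rotation$axis, rotation$angle_deg)
  }
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3, 3)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
      det(rotation) < 0) {
    stop("rotation must be a proper orthonormal 3x3 matrix")
  }
  structure(list(R = rotation, t = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply or invert a rigid transform
#'
#' @param transform a [rigid_transform()].
#' @param points length-3 vector or N x 3 matrix of world points (mm).
#' @return Transformed points with the same shape.
#' @export
apply_rigid <- function(transform, points) {
  stopifnot(inherits(transform, "rigid_transform"))
  if (is.matrix(points)) {
    sweep(points %*% t(transform$R), 2, transform$t, "+")
  } else {
    as.numeric(transform$R %*% points + transform$t)
  }
}

#' @rdname apply_rigid
#' @export
invert_rigid <- function(transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  rigid_transform(t(transform$R),
                  as.numeric(-t(transform$R) %*% transform$t))
}

# Complete a unit vector into a right-handed orthonormal basis (columns).
complete_basis <- function(e1) {
  e1 <- unitv(e1)
  probe <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e2 <- unitv(probe - sum(probe * e1) * e1)
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  cbind(e1, e2, e3)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
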