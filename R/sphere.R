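#' Least-squares sphere fit
#'
#' Fits a sphere to 3D points: an algebraic (linear) fit provides the
#' starting values, followed by geometric Gauss-Newton refinement that
#' minimizes the sum of squared radial residuals \eqn{(|p_i - c| - r)^2}.
#' This is the estimator used to approximate the articular surface of the
#' femoral head and recover its center and radius.
#'
#' @param points N x 3 matrix of world points (mm), N >= 4, non-coplanar.
#' @param max_iter Gauss-Newton iteration cap.
#' @return List with `center` (length 3), `radius`, `rms` (root mean square
#'   radial residual) and `residuals`.
#' @examples
#' u <- matrix(rnorm(300), ncol = 3)
#' u <- u / sqrt(rowSums(u^2))
#' f <- fit_sphere(sweep(25 * u, 2, c(10, 20, 30), "+"))
#' f$center; f$radius
#' @export
fit_sphere <- function(points, max_iter = 30) {
  points <- as.matrix(points)
  if (ncol(points) != 3 || nrow(points) < 4) {
    stop("need at least 4 points (N x 3 matrix)")
  }
  ctr <- scale(points, scale = FALSE)
  sv <- svd(ctr, nu = 0, nv = 0)$d
  if (sv[3] < 1e-9 * max(sv[1], 1)) {
    stop("degenerate point set: points are (nearly) coplanar")
  }
  # algebraic fit: |p|^2 = 2 p . c + (r^2 - |c|^2)
  A <- cbind(2 * points, 1)
  b <- rowSums(points^2)
  beta <- qr.solve(A, b)
  center <- beta[1:3]
  radius <- sqrt(max(beta[4] + sum(center^2), .Machine$double.eps))
  # geometric refinement
  for (it in seq_len(max_iter)) {
    d <- sweep(points, 2, center, "-")
    dist <- sqrt(rowSums(d^2))
    res <- dist - radius
    J <- cbind(-d / dist, -1)
    step <- tryCatch(qr.solve(J, -res), error = function(e) rep(0, 4))
    center <- center + step[1:3]
    radius <- radius + step[4]
    if (max(abs(step)) < 1e-12) break
  }
  d <- sweep(points, 2, center, "-")
  res <- sqrt(rowSums(d^2)) - radius
  list(center = as.numeric(center), radius = as.numeric(radius),
       rms = sqrt(mean(res^2)), residuals = res)
}

#' Least-squares circle fit (2D)
#'
#' Kasa algebraic fit with Gauss-Newton refinement; used for the
#' medullary-cavity circles at the lesser trochanter and on the distal
#' shaft, and for the neck-isthmus inscribed circle.
#'
#' @param points N x 2 matrix, N >= 3, non-collinear.
#' @return List with `center` (length 2), `radius`, `rms`.
#' @export
fit_circle2 <- function(points, max_iter = 30) {
  points <- as.matrix(points)
  if (ncol(points) != 2 || nrow(points) < 3) {
    stop("need at least 3 points (N x 2 matrix)")
  }
  ctr <- scale(points, scale = FALSE)
  sv <- svd(ctr, nu = 0, nv = 0)$d
  if (sv[2] < 1e-9 * max(sv[1], 1)) stop("degenerate point set: collinear")
  A <- cbind(2 * points, 1)
  b <- rowSums(points^2)
  beta <- qr.solve(A, b)
  center <- beta[1:2]
  radius <- sqrt(max(beta[3] + sum(center^2), .Machine$double.eps))
  for (it in seq_len(max_iter)) {
    d <- sweep(points, 2, center, "-")
    dist <- sqrt(rowSums(d^2))
    res <- dist - radius
    J <- cbind(-d / dist, -1)
    step <- tryCatch(qr.solve(J, -res), error = function(e) rep(0, 3))
    center <- center + step[1:2]
    radius <- radius + step[3]
    if (max(abs(step)) < 1e-12) break
  }
  d <- sweep(points, 2, center, "-")
  res <- sqrt(rowSums(d^2)) - radius
  list(center = as.numeric(center), radius = as.numeric(radius),
       rms = sqrt(mean(res^2)))
}
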