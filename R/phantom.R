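#' Synthetic proximal-femur phantom specification
#'
#' Defines a voxel-level synthetic CT phantom of a proximal femur with a
#' known, analytically constructed primary-compressive-trabeculae (PCT)
#' slab. The construction (in canonical right-femur coordinates, head
#' center at the origin, midcoronal plane y = 0):
#' spherical head of radius `R` with a cortical shell; a neck whose
#' in-plane (midcoronal) silhouette is a constant-width corridor around the
#' head-neck axis (so the medial-cortex tangent line is exact) and whose
#' antero-posterior width has a unique minimum (the neck isthmus); a
#' vertical shaft with cortex and medullary canal meeting the neck axis at
#' the neck-shaft angle `NSA`; a lesser trochanter modeled as a medial
#' hemispherical cortical bump; and a high-HU PCT slab whose midcoronal
#' cross-section is the quadrilateral ABCD with axis at angle `alpha` to
#' the head-neck axis, signed offset `delta` from the head center
#' (positive = lateral), bottom length `L_bottom` on the medial-cortex
#' tangent line and top length `L_top` as a chord of the head sphere,
#' extruded to \eqn{\pm 25\%} of the neck width antero-posteriorly.
#'
#' @param R head radius, mm (> 0).
#' @param NSA neck-shaft angle, degrees, in (90, 180).
#' @param alpha PCT-axis angle to the head-neck axis, degrees, in (0, 90).
#' @param delta signed PCT-axis offset from the head center, mm
#'   (positive = lateral).
#' @param L_bottom,L_top PCT boundary lengths, mm (`L_top < 2 R`).
#' @param hu_cortex,hu_pct,hu_cancellous,hu_soft,hu_marrow HU levels of
#'   cortical bone, the PCT slab, cancellous bone, soft tissue, and the
#'   medullary canal (`hu_pct > hu_cancellous` required).
#' @param noise_sd Gaussian HU noise SD (applied last, before pose).
#' @param cortex_thickness cortical shell thickness, mm.
#' @param defect_fraction fraction of the head cortical shell deleted in a
#'   band adjacent to the head-neck junction (0-1); emulates the weak or
#'   defect areas commonly seen in the head-neck junction cortex.
#' @param spacing isotropic voxel spacing, mm.
#' @param side `"right"` or `"left"` (left is a mirrored right femur).
#' @param pose a [rigid_transform()] applied to the anatomy.
#' @param neck_radius_frac in-plane neck half-width as a fraction of `R`.
#' @param neck_length distance from head center to the neck/shaft axis
#'   intersection, mm.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(R = 22.25, NSA = 126.85, alpha = 37.33,
                         delta = 0.39, L_bottom = 18.62, L_top = 21.37,
                         hu_cortex = 800, hu_pct = 350, hu_cancellous = 80,
                         hu_soft = 0, hu_marrow = 30,
                         noise_sd = 0, cortex_thickness = 2,
                         defect_fraction = 0, spacing = 1.0,
                         side = c("right", "left"),
                         pose = rigid_transform(),
                         neck_radius_frac = 0.72, neck_length = 50) {
  side <- match.arg(side)
  stopifnot(R > 0, NSA > 90, NSA < 180, alpha > 0, alpha < 90,
            L_bottom > 0, L_top > 0, L_top < 2 * R,
            hu_pct > hu_cancellous, spacing > 0,
            defect_fraction >= 0, defect_fraction <= 1,
            cortex_thickness > 0, noise_sd >= 0)
  structure(list(R = R, NSA = NSA, alpha = alpha, delta = delta,
                 L_bottom = L_bottom, L_top = L_top,
                 hu_cortex = hu_cortex, hu_pct = hu_pct,
                 hu_cancellous = hu_cancellous, hu_soft = hu_soft,
                 hu_marrow = hu_marrow, noise_sd = noise_sd,
                 cortex_thickness = cortex_thickness,
                 defect_fraction = defect_fraction, spacing = spacing,
                 side = side, pose = pose,
                 neck_radius_frac = neck_radius_frac,
                 neck_length = neck_length),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @param path JSON file path.
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  x <- unclass(spec)
  x$pose <- list(rotation = spec$pose$R, translation = spec$pose$t)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname phantom_spec
#' @param spec a `phantom_spec` (for writing).
#' @export
read_phantom_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rot <- x$pose$rotation
  if (!is.matrix(rot)) rot <- matrix(unlist(rot), 3, 3, byrow = TRUE)
  pose <- rigid_transform(rot, unlist(x$pose$translation))
  x$pose <- NULL
  do.call(phantom_spec, c(x, list(pose = pose)))
}

# Analytic geometry shared by the phantom field and its ground truth.
# All in canonical right-femur coordinates: +x medial, +z superior,
# y antero-posterior, head center at the origin.
phantom_geometry <- function(spec) {
  th <- deg2rad(180 - spec$NSA)
  h <- c(sin(th), 0, cos(th))               # HN-axis direction, neck -> head
  n_med <- c(cos(th), 0, -sin(th))          # in-plane, medial-distal side
  r_n <- spec$neck_radius_frac * spec$R     # in-plane neck half-width
  tc <- spec$cortex_thickness
  c_int <- -spec$neck_length * h            # neck/shaft axis intersection
  r_shaft <- 13.5
  r_canal <- 8
  r_lt <- 9
  z_lt <- c_int[3] - 35
  lt_center <- c(c_int[1] + r_shaft, 0, z_lt)
  z_edge <- z_lt - sqrt(r_lt^2 - 2^2)       # lower edge: bulge = 2 mm
  z_top <- c_int[3] + 18
  z_bot <- z_edge - 56
  t_isth <- 26                              # isthmus position along -h, mm
  # PCT quadrilateral in the midcoronal plane (x, z)
  phg <- deg2rad(180 - spec$NSA - spec$alpha)
  g <- c(sin(phg), 0, cos(phg))             # PCT-axis direction, bottom -> top
  n_lat_ax <- c(-cos(phg), 0, sin(phg))     # lateral normal of the PCT-axis
  q0 <- spec$delta * n_lat_ax               # point on the PCT-axis
  aux_pt <- r_n * n_med                     # medial-cortex tangent line
  f_mid <- intersect_lines2(q0[c(1, 3)], g[c(1, 3)],
                            aux_pt[c(1, 3)], h[c(1, 3)])
  ends <- rbind(f_mid + spec$L_bottom / 2 * h[c(1, 3)],
                f_mid - spec$L_bottom / 2 * h[c(1, 3)])
  s_lat <- signed_dist2(ends, q0[c(1, 3)], g[c(1, 3)]) *
    sign(sum(perp2(g[c(1, 3)]) * n_lat_ax[c(1, 3)]))
  A <- ends[which.max(s_lat), ]
  B <- ends[which.min(s_lat), ]
  m_d <- sqrt(spec$R^2 - (spec$L_top / 2)^2)
  if (abs(spec$delta) > m_d) {
    stop("infeasible PCT geometry: L_top chord midpoint circle (radius ",
         round(m_d, 2), " mm) is missed by the PCT-axis at offset ",
         round(abs(spec$delta), 2), " mm")
  }
  cand <- intersect_line_circle2(q0[c(1, 3)], g[c(1, 3)], c(0, 0), m_d)
  mid_cd <- cand[which.max(cand %*% g[c(1, 3)]), ]
  cdir <- unitv(perp2(mid_cd))
  ends_t <- rbind(mid_cd + spec$L_top / 2 * cdir,
                  mid_cd - spec$L_top / 2 * cdir)
  s_lat_t <- signed_dist2(ends_t, q0[c(1, 3)], g[c(1, 3)]) *
    sign(sum(perp2(g[c(1, 3)]) * n_lat_ax[c(1, 3)]))
  C <- ends_t[which.max(s_lat_t), ]
  D <- ends_t[which.min(s_lat_t), ]
  # feasibility: the quad bottom must stay within the neck corridor
  for (p in list(A, B)) {
    if (abs(signed_dist2(p, c(0, 0), h[c(1, 3)])) > 2.2 * r_n) {
      stop("infeasible PCT geometry: bottom boundary extends ",
           "far beyond the neck corridor")
    }
  }
  list(h = h, n_med = n_med, r_n = r_n, tc = tc, c_int = c_int,
       r_shaft = r_shaft, r_canal = r_canal, r_lt = r_lt,
       lt_center = lt_center, z_edge = z_edge, z_top = z_top,
       z_bot = z_bot, z_canal_top = z_lt, t_isth = t_isth,
       g = g, n_lat_ax = n_lat_ax, q0 = q0, aux_pt = aux_pt,
       quad = rbind(A = A, B = B, D = D, C = C),  # polygon order
       half_thick = 0.5 * r_n)
}

# antero-posterior neck half-width profile (mm) at distance t from the head
# center along -h; a distinct waist (unique minimum) at t_isth, flaring to
# the full corridor width over ~13 mm on either side.
neck_ap_halfwidth <- function(t, r_n, t_isth) {
  pmin(r_n * (0.85 + 0.5 * ((t - t_isth) / 24)^2), r_n)
}

# point-in-convex-polygon (vectorized); poly is k x 2, consistent order
in_convex_poly <- function(px, pz, poly) {
  k <- nrow(poly)
  inside <- rep(TRUE, length(px))
  cx <- mean(poly[, 1]); cz <- mean(poly[, 2])
  for (i in seq_len(k)) {
    j <- if (i == k) 1L else i + 1L
    ex <- poly[j, 1] - poly[i, 1]; ez <- poly[j, 2] - poly[i, 2]
    sc <- ex * (cz - poly[i, 2]) - ez * (cx - poly[i, 1])
    sp <- ex * (pz - poly[i, 2]) - ez * (px - poly[i, 1])
    inside <- inside & (sp * sign(sc) >= 0)
  }
  inside
}

# Evaluate the noise-free canonical HU field at canonical points (N x 3).
phantom_field <- function(spec, geo, P) {
  x <- P[, 1]; y <- P[, 2]; z <- P[, 3]
  hu <- rep(spec$hu_soft, nrow(P))
  r2_head <- x^2 + y^2 + z^2
  R <- spec$R; tc <- geo$tc
  head_solid <- r2_head <= R^2
  head_int <- r2_head <= (R - tc)^2
  # neck (t along -h from the head center; s in-plane medial offset)
  t <- -(x * geo$h[1] + z * geo$h[3])
  s <- x * geo$n_med[1] + z * geo$n_med[3]
  rz <- neck_ap_halfwidth(t, geo$r_n, geo$t_isth)
  t_ok <- t >= 0 & t <= spec$neck_length + 5
  rho2 <- (s / geo$r_n)^2 + (y / rz)^2
  neck_solid <- t_ok & rho2 <= 1
  neck_int <- t_ok & rho2 <= (1 - tc / geo$r_n)^2
  # shaft
  d2 <- (x - geo$c_int[1])^2 + y^2
  z_ok <- z >= geo$z_bot & z <= geo$z_top
  shaft_solid <- z_ok & d2 <= geo$r_shaft^2
  shaft_int <- z_ok & d2 <= geo$r_canal^2
  # lesser trochanter: cortical bump outside the canal
  lt_solid <- ((x - geo$lt_center[1])^2 + y^2 +
                 (z - geo$lt_center[3])^2) <= geo$r_lt^2 & !shaft_int
  interior <- head_int | neck_int | shaft_int
  solid <- head_solid | neck_solid | shaft_solid | lt_solid
  hu[solid & !interior] <- spec$hu_cortex
  hu[interior] <- spec$hu_cancellous
  hu[shaft_int & z <= geo$z_canal_top & !head_int & !neck_int] <-
    spec$hu_marrow
  # PCT slab replaces cancellous bone inside the quadrilateral prism
  canc <- interior & hu == spec$hu_cancellous
  pct <- canc & abs(y) <= geo$half_thick &
    in_convex_poly(x, z, geo$quad)
  hu[pct] <- spec$hu_pct
  # head-neck junction cortical defect band
  if (spec$defect_fraction > 0) {
    psi0 <- asin(min(geo$r_n / R, 1))
    cpsi1 <- cos(psi0) - spec$defect_fraction * (1 + cos(psi0))
    shell <- head_solid & !head_int & !neck_int & !shaft_int
    cpsi <- -(x * geo$h[1] + z * geo$h[3]) / pmax(sqrt(r2_head), 1e-9)
    band <- shell & cpsi <= cos(psi0) & cpsi >= cpsi1
    hu[band] <- spec$hu_cancellous
  }
  hu
}

#' Build a synthetic proximal-femur CT volume with ground truth
#'
#' Rasterizes the phantom described by a [phantom_spec()] onto an
#' axis-aligned voxel grid. The analytic anatomy is evaluated directly at
#' the (inverse-posed) voxel centers, so the pose introduces no
#' interpolation; Gaussian HU noise is added last. Left femurs are
#' generated by mirroring the right-side construction.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed for the noise field.
#' @return List with `volume` (a [ct_volume()]) and `ground_truth`, a list
#'   of the generative parameters plus the analytic world positions of the
#'   landmarks (O, O1, O2, O3, U, L, M), the axes, the medial-cortex
#'   tangent line, the quadrilateral corners, and the analytic mean head
#'   HU over the measurement disc.
#' @examples
#' ph <- build_phantom(phantom_spec(spacing = 2), seed = 1)
#' ph$volume
#' @export
build_phantom <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "phantom_spec"))
  geo <- phantom_geometry(spec)
  mirror <- spec$side == "left"
  msign <- if (mirror) -1 else 1
  # canonical bounding box
  m <- 5
  xr <- c(geo$c_int[1] - geo$r_shaft - m, spec$R + m)
  yr <- c(-spec$R - m, spec$R + m)
  zr <- c(geo$z_bot - m, spec$R + m)
  corners <- as.matrix(expand.grid(x = xr, y = yr, z = zr))
  corners[, 1] <- msign * corners[, 1]
  wc <- apply_rigid(spec$pose, corners)
  # snap to the global lattice (integer multiples of the spacing) so a
  # mirrored construction lands on the mirrored lattice exactly
  lo <- (floor(apply(wc, 2, min) / spec$spacing) - 1) * spec$spacing
  hi <- (ceiling(apply(wc, 2, max) / spec$spacing) + 1) * spec$spacing
  dims <- pmax(2L, as.integer(round((hi - lo) / spec$spacing)) + 1L)
  ax <- lapply(1:3, function(i) lo[i] + (seq_len(dims[i]) - 1) * spec$spacing)
  W <- cbind(rep(ax[[1]], times = dims[2] * dims[3]),
             rep(rep(ax[[2]], each = dims[1]), times = dims[3]),
             rep(ax[[3]], each = dims[1] * dims[2]))
  P <- apply_rigid(invert_rigid(spec$pose), W)
  P[, 1] <- msign * P[, 1]
  hu <- phantom_field(spec, geo, P)
  if (spec$noise_sd > 0) {
    set.seed(seed)
    hu <- hu + stats::rnorm(length(hu), 0, spec$noise_sd)
  }
  vol <- ct_volume(array(hu, dims), spacing = rep(spec$spacing, 3),
                   origin = lo, direction = diag(3))
  # ground truth, mirrored then posed into world coordinates
  to_world <- function(p) {
    p[1] <- msign * p[1]
    apply_rigid(spec$pose, p)
  }
  dir_world <- function(d) {
    d[1] <- msign * d[1]
    as.numeric(spec$pose$R %*% d)
  }
  t_ul <- sqrt(spec$R^2 - (geo$r_n - geo$tc)^2)
  q3 <- function(v2) c(v2[1], 0, v2[2])
  gt <- list(
    spec = spec,
    O = to_world(c(0, 0, 0)), R = spec$R,
    O1 = to_world(c(geo$c_int[1], 0, geo$z_edge)),
    O2 = to_world(-geo$t_isth * geo$h),
    O3 = to_world(c(geo$c_int[1], 0, geo$z_edge - 50)),
    U = to_world(-t_ul * geo$h - (geo$r_n - geo$tc) * geo$n_med),
    L = to_world(-t_ul * geo$h + (geo$r_n - geo$tc) * geo$n_med),
    M = to_world(-t_ul * geo$h),
    hn_dir = dir_world(geo$h),
    pfs_dir = dir_world(c(0, 0, -1)),
    aux_point = to_world(geo$aux_pt), aux_dir = dir_world(geo$h),
    pct_axis_point = to_world(geo$q0), pct_axis_dir = dir_world(geo$g),
    A = to_world(q3(geo$quad["A", ])), B = to_world(q3(geo$quad["B", ])),
    C = to_world(q3(geo$quad["C", ])), D = to_world(q3(geo$quad["D", ])),
    NSA = spec$NSA, alpha = spec$alpha, beta = 180 - spec$NSA - spec$alpha,
    delta = spec$delta, L_bottom = spec$L_bottom, L_top = spec$L_top,
    mean_head_hu = phantom_disc_mean(spec, geo)
  )
  list(volume = vol, ground_truth = gt)
}

# analytic mean HU over the head-measurement disc (plane through the head
# center perpendicular to the HN-axis, radius R), by fine-grid quadrature
# of the noise-free canonical field.
phantom_disc_mean <- function(spec, geo, step = 0.2) {
  B <- complete_basis(geo$h)
  b1 <- B[, 2]; b2 <- B[, 3]
  s <- seq(-spec$R, spec$R, by = step)
  gr <- expand.grid(a = s, b = s)
  gr <- gr[gr$a^2 + gr$b^2 <= spec$R^2, ]
  P <- outer(gr$a, b1) + outer(gr$b, b2)
  mean(phantom_field(spec, geo, P))
}
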