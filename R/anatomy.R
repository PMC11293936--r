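# Landmark construction for the proximal femur: head sphere (O, R),
# medullary centers O1/O3, neck isthmus O2, HN- and PFS-axes, the
# midcoronal plane and the medial-cortex tangent (aux) line.

#' Measurement configuration
#'
#' Tunable parameters of the morphometry pipeline, with defaults chosen
#' for adult proximal-femur CT at about 0.5-1 mm voxel spacing.
#'
#' @param cortical_threshold HU threshold for cortical bone used by the
#'   landmarking steps (surface tracing, cavity fits, tangencies).
#' @param soft_max HU below which a voxel is treated as soft tissue when
#'   classifying the outer bone surface.
#' @param proj_spacing in-plane raster spacing of the coronal projection, mm.
#' @param min_voxels column-count threshold of [binarize()].
#' @param peel_mm cortical rim peeled off the projection mask before column
#'   counting, mm; isolates the trabecular compartment.
#' @param gap_tol maximum gap between the binarized PCT component and the
#'   medial-cortex tangent line, mm (the peeled cortex plus half a voxel).
#' @param include_rim whether the mean-head-HU disc includes the cortical
#'   rim (full disc of radius R) or stops at `R - cortex estimate`.
#' @param supersample in-plane sampling step for tangency/boundary tracing
#'   on the midcoronal plane, mm.
#' @return A list of class `pct_config`.
#' @export
pct_config <- function(cortical_threshold = 300, soft_max = 40,
                       proj_spacing = 0.5, min_voxels = 2, peel_mm = 3,
                       gap_tol = 5.5, include_rim = TRUE,
                       supersample = 0.25) {
  structure(list(cortical_threshold = cortical_threshold,
                 soft_max = soft_max, proj_spacing = proj_spacing,
                 min_voxels = min_voxels, peel_mm = peel_mm,
                 gap_tol = gap_tol, include_rim = include_rim,
                 supersample = supersample),
            class = "pct_config")
}

# principal-axis analysis of the bone mask: provisional shaft direction
# (pointing proximally, toward the head) and a seed point inside the head.
find_head_seed <- function(vol, threshold = 300) {
  idx <- which(vol$values >= threshold)
  if (length(idx) < 1000) stop("too little bone above the cortical threshold")
  if (length(idx) > 2e5) idx <- idx[seq(1, length(idx), length.out = 2e5)]
  d <- dim(vol$values)
  i <- (idx - 1) %% d[1]
  j <- ((idx - 1) %/% d[1]) %% d[2]
  k <- (idx - 1) %/% (d[1] * d[2])
  X <- index_to_world(vol, cbind(i, j, k))
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr, "-")
  e <- svd(crossprod(Xc) / nrow(Xc))$u[, 1]
  tau <- Xc %*% e
  rad <- sqrt(rowSums((Xc - tau %*% t(e))^2))
  qs <- stats::quantile(tau, c(0.15, 0.85))
  r_lo <- stats::quantile(rad[tau <= qs[1]], 0.99)
  r_hi <- stats::quantile(rad[tau >= qs[2]], 0.99)
  head_hi <- r_hi > r_lo
  w_prox <- if (head_hi) e else -e       # proximal = toward the head end
  in_slab <- if (head_hi) tau >= qs[2] else tau <= qs[1]
  seed <- colMeans(X[in_slab, , drop = FALSE])
  # the whole-bone principal axis is pulled toward the head/neck mass;
  # refine on the distal (shaft-dominated) voxels, twice
  for (qq in c(0.4, 0.2)) {
    tau_h <- X %*% w_prox
    distal <- tau_h <= stats::quantile(tau_h, qq)
    Xd <- X[distal, , drop = FALSE]
    cd <- colMeans(Xd)
    ed <- svd(crossprod(sweep(Xd, 2, cd, "-")) / nrow(Xd))$u[, 1]
    if (sum(ed * w_prox) < 0) ed <- -ed
    w_prox <- ed
    ctr <- cd
  }
  list(seed = seed, axis_point = ctr, proximal = as.numeric(w_prox))
}

#' Locate the femoral head sphere
#'
#' Extracts candidate articular-surface points near a seed (outer cortical
#' boundary voxels, i.e. bone voxels adjacent to soft tissue), fits a
#' sphere ([fit_sphere()]), rejects points with radial residual above 3x
#' the RMS and refits once, then refines by casting rays from the fitted
#' center and relocating the outer cortical crossing at sub-voxel
#' precision. Robust to moderate cortical defects at the head-neck
#' junction (defect rays yield no crossing and drop out).
#'
#' @param vol a [ct_volume()].
#' @param seed approximate head-center world position (default: automatic,
#'   from the principal-axis analysis of the bone mask).
#' @param seed_radius radius of the search region, mm.
#' @param config a [pct_config()].
#' @return List with `O` (center, world mm), `R` (radius, mm), `rms`,
#'   `n_points`.
#' @export
locate_head <- function(vol, seed = NULL, seed_radius = 35,
                        config = pct_config()) {
  if (is.null(seed)) seed <- find_head_seed(vol, config$cortical_threshold)$seed
  v <- vol$values
  mask <- v >= config$cortical_threshold
  d <- dim(v)
  # 6-neighbour minimum HU (edge-padded), to find bone voxels facing soft
  nb_min <- array(Inf, d)
  shift_min <- function(m, arr) {
    out <- array(Inf, dim(arr))
    n <- dim(arr)
    if (m == 1) out[2:n[1], , ] <- arr[1:(n[1] - 1), , ]
    if (m == 2) out[1:(n[1] - 1), , ] <- arr[2:n[1], , ]
    if (m == 3) out[, 2:n[2], ] <- arr[, 1:(n[2] - 1), ]
    if (m == 4) out[, 1:(n[2] - 1), ] <- arr[, 2:n[2], ]
    if (m == 5) out[, , 2:n[3]] <- arr[, , 1:(n[3] - 1)]
    if (m == 6) out[, , 1:(n[3] - 1)] <- arr[, , 2:n[3]]
    out
  }
  for (m in 1:6) nb_min <- pmin(nb_min, shift_min(m, v))
  cand <- which(mask & nb_min < config$soft_max)
  if (length(cand) == 0) stop("no cortical surface points in the volume")
  i <- (cand - 1) %% d[1]
  j <- ((cand - 1) %/% d[1]) %% d[2]
  k <- (cand - 1) %/% (d[1] * d[2])
  P <- index_to_world(vol, cbind(i, j, k))
  keep <- sqrt(colSums((t(P) - seed)^2)) <= seed_radius
  P <- P[keep, , drop = FALSE]
  if (nrow(P) < 50) {
    stop("fewer than 50 articular-surface candidate points near the seed; ",
         "is the seed region inside the femoral head?")
  }
  f <- fit_sphere(P)
  inl <- abs(f$residuals) <= 3 * f$rms
  if (sum(inl) >= 50 && any(!inl)) f <- fit_sphere(P[inl, , drop = FALSE])
  # sub-voxel refinement by radial ray casting
  nd <- 600
  gold <- pi * (3 - sqrt(5))
  kk <- seq_len(nd) - 1
  zz <- 1 - 2 * (kk + 0.5) / nd
  rr <- sqrt(pmax(0, 1 - zz^2))
  dirs <- cbind(rr * cos(gold * kk), rr * sin(gold * kk), zz)
  rs <- seq(f$radius - 6, f$radius + 6, by = 0.2)
  pts <- dirs[rep(seq_len(nd), each = length(rs)), ] * rep(rs, times = nd)
  pts <- sweep(pts, 2, f$center, "+")
  hu <- matrix(sample_world(vol, pts, fill = -1000),
               nrow = length(rs), ncol = nd)
  surf <- matrix(NA_real_, 0, 3)
  th <- config$cortical_threshold
  nr <- length(rs)
  for (q in seq_len(nd)) {
    prof <- hu[, q]
    above <- which(prof >= th)
    if (length(above) == 0) next
    l <- max(above)
    if (l >= nr) next   # still cortical at the window edge
    # local mid-level crossing of the outer cortical edge (unbiased
    # against the interpolation blur)
    hi <- max(prof[max(1, l - 5):l])
    lo <- min(prof[(l + 1):min(nr, l + 5)])
    lev <- max((hi + lo) / 2, th / 2)
    m <- l
    while (m < nr && prof[m + 1] >= lev) m <- m + 1
    while (m > 1 && prof[m] < lev) m <- m - 1
    if (m >= nr || prof[m] < lev) next
    r_star <- rs[m] + 0.2 * (prof[m] - lev) / (prof[m] - prof[m + 1])
    surf <- rbind(surf, f$center + r_star * dirs[q, ])
  }
  if (nrow(surf) < 50) stop("head surface refinement failed (", nrow(surf),
                            " usable rays)")
  f2 <- fit_sphere(surf)
  inl <- abs(f2$residuals) <= 3 * f2$rms
  if (sum(inl) >= 50 && any(!inl)) f2 <- fit_sphere(surf[inl, , drop = FALSE])
  list(O = f2$center, R = f2$radius, rms = f2$rms, n_points = nrow(surf))
}

# ray-cast circle fit of an enclosed medullary cavity on a 2D resampled
# slice; origin/e1/e2 define the slice plane, c0 is a 2D start point
# inside the cavity.
medullary_circle <- function(vol, origin, e1, e2, c0, threshold,
                             r_max = 12) {
  ang <- seq(0, 2 * pi, length.out = 181)[-181]
  rs <- seq(0.5, r_max, by = 0.1)
  ua <- c0[1] + outer(rs, cos(ang))
  va <- c0[2] + outer(rs, sin(ang))
  P <- sweep(outer(as.vector(ua), e1) + outer(as.vector(va), e2),
             2, origin, "+")
  hu <- matrix(sample_world(vol, P, fill = -1000), nrow = length(rs))
  bnd <- matrix(NA_real_, 0, 2)
  for (q in seq_along(ang)) {
    prof <- hu[, q]
    hit <- which(prof >= threshold)
    if (length(hit) == 0 || hit[1] == 1) next
    l <- hit[1]
    r_star <- rs[l - 1] + 0.1 * (threshold - prof[l - 1]) /
      (prof[l] - prof[l - 1])
    bnd <- rbind(bnd, c(c0[1] + r_star * cos(ang[q]),
                        c0[2] + r_star * sin(ang[q])))
  }
  if (nrow(bnd) < 20) stop("medullary cavity boundary not found")
  fit_circle2(bnd)
}

#' Locate the medullary center at the lesser trochanter's lower edge
#'
#' Scans axial (shaft-perpendicular) slices from distal to proximal for
#' the most distal slice whose medial cortical profile bulges more than
#' 2 mm beyond the shaft cylinder (the lower edge of the lesser
#' trochanter), then fits a circle to the medullary-cavity boundary on
#' that slice. Also returns the shaft-calibration center `O3` on the
#' slice 50 mm further distal.
#'
#' @param vol a [ct_volume()].
#' @param frame_hint list with `origin` (head center), `proximal` (unit
#'   direction along the shaft toward the head) and `medial` (unit
#'   direction, perpendicular, pointing medially).
#' @param config a [pct_config()].
#' @return List with world points `O1`, `O3` and `w_edge` (the lower-edge
#'   offset along the shaft, mm, relative to the head center).
#' @export
locate_lt_center <- function(vol, frame_hint, config = pct_config()) {
  O <- frame_hint$origin
  ew <- unitv(frame_hint$proximal)
  eu <- unitv(frame_hint$medial - sum(frame_hint$medial * ew) * ew)
  ev <- cross3(ew, eu)
  th <- config$cortical_threshold
  us <- seq(-70, 5, by = 0.5)
  vs <- seq(-22, 22, by = 0.5)
  ws <- seq(-130, -30, by = 0.5)
  # one 3D resampling of the trochanteric/shaft region
  blk <- resample_to_frame(
    vol, origin = O + us[1] * eu + vs[1] * ev + ws[1] * ew,
    basis = cbind(eu, ev, ew), spacing = 0.5,
    dims = c(length(us), length(vs), length(ws)), fill = -1000)
  bone <- blk$values >= th
  medial_max <- apply(bone, 3, function(sl) {
    hit <- which(sl, arr.ind = TRUE)
    if (nrow(hit) == 0) return(NA_real_)
    us[max(hit[, 1])]
  })
  have <- which(!is.na(medial_max))
  if (length(have) < 60) {
    stop("shaft not found below the head; volume may be cropped above ",
         "the lesser trochanter")
  }
  # baseline shaft surface: robust linear trend over the distal reference
  # stretch (tolerates residual tilt of the provisional axis)
  ref <- have[seq_len(min(50, length(have)))]
  trend <- stats::lm(m ~ w, data.frame(w = ws[ref], m = medial_max[ref]))
  baseline <- stats::predict(trend, newdata = data.frame(w = ws))
  bulge <- medial_max - baseline
  cand <- which(!is.na(bulge) & bulge > 2)
  cand <- cand[cand > max(ref)]
  if (length(cand) == 0) {
    stop("no medial bulge > 2 mm found along the shaft: lesser trochanter ",
         "not detected; supply the slice manually")
  }
  k_edge <- min(cand)
  # sub-slice interpolation of the 2 mm crossing
  w_edge <- ws[k_edge]
  if (k_edge > 1 && is.finite(bulge[k_edge - 1]) &&
      bulge[k_edge - 1] < 2 && bulge[k_edge] > bulge[k_edge - 1]) {
    fr <- (2 - bulge[k_edge - 1]) / (bulge[k_edge] - bulge[k_edge - 1])
    w_edge <- ws[k_edge - 1] + fr * (ws[k_edge] - ws[k_edge - 1])
  }
  center_guess <- c(baseline[k_edge] - 12, 0)
  slice_origin <- function(w) O + w * ew
  c1 <- medullary_circle(vol, slice_origin(w_edge), eu, ev, center_guess, th)
  O1 <- slice_origin(w_edge) + c1$center[1] * eu + c1$center[2] * ev
  w3 <- w_edge - 50
  c3 <- medullary_circle(vol, slice_origin(w3), eu, ev, center_guess, th)
  O3 <- slice_origin(w3) + c3$center[1] * eu + c3$center[2] * ev
  list(O1 = O1, O3 = O3, w_edge = w_edge)
}

#' Locate the femoral neck isthmus
#'
#' On the midsagittal plane of the neck (the plane through the provisional
#' neck axis perpendicular to the provisional coronal plane), finds the
#' position of minimum antero-posterior outer cortical width; O2 is the
#' center of the inscribed circle tangent to the anterior and posterior
#' cortices there. A flat (constant-width) stretch is resolved at its
#' midpoint. The provisional in-plane neck direction is estimated first
#' from the angular position of the head-neck opening on a circle just
#' outside the head sphere.
#'
#' @param vol a [ct_volume()].
#' @param O,R head center and radius.
#' @param pfs list with `point` and `direction` (distal) of the
#'   provisional shaft axis.
#' @param config a [pct_config()].
#' @return List with `O2` (world), `neck_dir` (unit, pointing toward the
#'   head) and `t_isthmus` (distance from O along the neck, mm).
#' @export
locate_neck_isthmus <- function(vol, O, R, pfs, config = pct_config()) {
  pd <- unitv(pfs$direction)
  foot <- pfs$point + sum((O - pfs$point) * pd) * pd
  if (vnorm(O - foot) < 5) stop("head center lies on the shaft axis")
  e_m <- unitv(O - foot)
  e_p <- -pd
  n0 <- unitv(cross3(pd, e_m))
  # provisional neck direction from the head-neck opening
  ang <- seq(0, 2 * pi, length.out = 721)[-721]
  Pc <- t(O + outer(e_m, cos(ang)) * (R + 2) + outer(e_p, sin(ang)) * (R + 2))
  hu <- sample_world(vol, Pc, fill = -1000)
  # circular moving average (~5 mm of arc) so HU noise cannot splinter
  # the neck-opening arc into fragments
  hu <- as.numeric(stats::filter(hu, rep(1 / 25, 25), circular = TRUE))
  non_soft <- hu > config$soft_max
  if (!any(non_soft)) stop("no neck found adjacent to the head sphere")
  # longest circular run of non-soft samples
  r <- rle(c(non_soft, non_soft))
  ends <- cumsum(r$lengths)
  runs <- which(r$values & r$lengths <= length(ang))
  best <- runs[which.max(r$lengths[runs])]
  mid_i <- (ends[best] - (r$lengths[best] - 1) / 2 - 1) %% length(ang) + 1
  mid_ang <- ang[round(mid_i)]
  h1 <- -unitv(cos(mid_ang) * e_m + sin(mid_ang) * e_p)  # toward the head
  # distance from O along -h1 to the closest approach of the shaft axis
  w <- O - pfs$point
  a_ <- -h1
  ab <- sum(a_ * pd)
  t_int <- (ab * sum(pd * w) - sum(a_ * w)) / (1 - ab^2)
  if (!is.finite(t_int) || t_int < 15) t_int <- vnorm(O - foot) /
      max(sin(angle_between(h1, pd) * pi / 180), 0.3)
  ts <- seq(max(8, 0.3 * t_int), 0.85 * t_int, by = 0.5)
  ys <- seq(-26, 26, by = 0.25)
  P <- sweep(outer(rep(ys, times = length(ts)), n0) -
               outer(rep(ts, each = length(ys)), h1), 2, O, "+")
  hu <- matrix(sample_world(vol, P, fill = -1000), nrow = length(ys))
  th <- config$cortical_threshold
  wmax <- wmin <- rep(NA_real_, length(ts))
  dy <- ys[2] - ys[1]
  for (q in seq_along(ts)) {
    b <- which(hu[, q] >= th)
    if (length(b) < 2) next
    i0 <- min(b); i1 <- max(b)
    # sub-sample wall positions: interpolate the threshold crossing of
    # the outer cortical edge on both sides
    wmin[q] <- if (i0 > 1) {
      ys[i0 - 1] + dy * (th - hu[i0 - 1, q]) / (hu[i0, q] - hu[i0 - 1, q])
    } else ys[i0]
    wmax[q] <- if (i1 < length(ys)) {
      ys[i1] + dy * (hu[i1, q] - th) / (hu[i1, q] - hu[i1 + 1, q])
    } else ys[i1]
  }
  W <- wmax - wmin
  ok <- which(is.finite(W))
  if (length(ok) < 5) stop("neck cross-sections not found")
  i_min <- ok[which(W[ok] <= min(W[ok]) + 1e-9)]
  if (min(i_min) == ok[1] || max(i_min) == ok[length(ok)]) {
    stop("neck width profile is monotonic over the search range: ",
         "no isthmus found")
  }
  i_star <- round(mean(i_min))           # flat plateau -> midpoint
  t_star <- mean(ts[i_min])
  # quadratic refinement of the (possibly shallow) width minimum
  win <- ok[abs(ts[ok] - t_star) <= 6]
  if (length(win) >= 7) {
    tt <- ts[win] - t_star
    fit <- stats::lm(W[win] ~ tt + I(tt^2))
    a2 <- stats::coef(fit)[3]
    a1 <- stats::coef(fit)[2]
    if (is.finite(a2) && a2 > 0) {
      t_ref <- t_star - a1 / (2 * a2)
      if (abs(t_ref - t_star) <= 6) t_star <- t_ref
    }
  }
  y_mid <- (wmax + wmin) / 2
  y_c <- stats::approx(ts[ok], y_mid[ok], xout = t_star, rule = 2)$y
  list(O2 = O - t_star * h1 + y_c * n0, neck_dir = h1, t_isthmus = t_star)
}

#' Neck-shaft angle from the two axes
#'
#' The angle opening between the head-directed HN-axis direction and the
#' distal PFS-axis direction, optionally after projecting both into the
#' midcoronal plane.
#'
#' @param hn_dir HN-axis direction pointing from neck toward head.
#' @param pfs_dir PFS-axis direction pointing distally.
#' @param normal optional plane normal to project both directions into.
#' @return NSA in degrees, in (0, 180).
#' @export
compute_nsa <- function(hn_dir, pfs_dir, normal = NULL) {
  if (!is.null(normal) && length(hn_dir) == 3) {
    n <- unitv(normal)
    hn_dir <- hn_dir - sum(hn_dir * n) * n
    pfs_dir <- pfs_dir - sum(pfs_dir * n) * n
  }
  a <- angle_between(hn_dir, pfs_dir)
  if (a < 1e-6 || a > 180 - 1e-6) stop("axes are parallel; NSA undefined")
  a
}

#' Mean Hounsfield unit value of the femoral head
#'
#' Mean HU over the disc of radius R centered at the head center in the
#' plane perpendicular to the HN-axis (on which the head contour is always
#' a circle), sampled on a sub-voxel grid.
#'
#' @param vol a [ct_volume()].
#' @param O,R head center (world mm) and radius (mm).
#' @param hn_dir HN-axis direction.
#' @param step sampling step, mm (default half the smallest voxel side).
#' @param radius disc radius (default the full head radius R).
#' @return Mean HU (scalar).
#' @export
mean_head_hu <- function(vol, O, R, hn_dir, step = min(vol$spacing) / 2,
                         radius = R) {
  B <- complete_basis(unitv(hn_dir))
  s <- seq(-radius, radius, by = step)
  gr <- expand.grid(a = s, b = s)
  gr <- gr[gr$a^2 + gr$b^2 <= radius^2, ]
  P <- sweep(outer(gr$a, B[, 2]) + outer(gr$b, B[, 3]), 2, O, "+")
  idx <- world_to_index(vol, P)
  d <- dim(vol$values)
  inside <- idx[, 1] >= 0 & idx[, 1] <= d[1] - 1 &
    idx[, 2] >= 0 & idx[, 2] <= d[2] - 1 &
    idx[, 3] >= 0 & idx[, 3] <= d[3] - 1
  if (!all(inside)) stop("measurement disc exits the volume")
  mean(sample_world(vol, P, fill = NA_real_))
}

#' Build the anatomical frame of a proximal femur
#'
#' Runs the full landmark chain: head sphere, lesser-trochanter and
#' distal-shaft medullary centers, neck isthmus, midcoronal plane
#' (through O, O1, O2), the U/L/M construction of the HN-axis, the
#' PFS-axis, the neck-shaft angle, and the medial-cortex tangent (aux)
#' line, all at sub-voxel precision.
#'
#' @param vol a [ct_volume()] containing one proximal femur (right
#'   orientation; mirror left femurs first, see [mirror_sagittal()]).
#' @param config a [pct_config()].
#' @param seed optional approximate head-center world position.
#' @return An object of class `femur_frame`: landmarks `O`, `R`, `O1`,
#'   `O2`, `O3`, `U`, `L`, `M` (world mm), `basis` (columns: medial,
#'   proximal, normal), 2D in-plane entities `hn2`, `pfs2`, `aux2` (each
#'   point + direction in midcoronal (medial, proximal) coordinates with
#'   origin O), `NSA` (degrees) and `mean_hu`.
#' @export
build_frame <- function(vol, config = pct_config(), seed = NULL) {
  th <- config$cortical_threshold
  hint <- find_head_seed(vol, th)
  if (is.null(seed)) seed <- hint$seed
  head <- locate_head(vol, seed = seed, config = config)
  O <- head$O
  medial0 <- O - (hint$axis_point +
                    sum((O - hint$axis_point) * hint$proximal) * hint$proximal)
  lt <- locate_lt_center(vol, list(origin = O, proximal = hint$proximal,
                                   medial = medial0), config = config)
  pfs_dir <- unitv(lt$O3 - lt$O1)              # distal
  pfs <- list(point = lt$O1, direction = pfs_dir)
  isth <- locate_neck_isthmus(vol, O, head$R, pfs, config = config)
  O1 <- lt$O1; O2 <- isth$O2; O3 <- lt$O3
  n_raw <- cross3(O1 - O, O2 - O)
  if (vnorm(n_raw) < 1e-6 * vnorm(O1 - O) * vnorm(O2 - O)) {
    stop("O, O1, O2 are collinear; midcoronal plane undefined")
  }
  n <- unitv(n_raw)
  f2 <- unitv((O1 - O3) - sum((O1 - O3) * n) * n)   # proximal, in-plane
  f1 <- cross3(f2, n)
  if (sum(f1 * medial0) < 0) {
    f1 <- -f1
    n <- -n
  }
  basis <- cbind(f1, f2, n)
  to2 <- function(p) c(sum((p - O) * f1), sum((p - O) * f2))
  # --- midcoronal 2D slice at supersampled resolution ---
  ss <- config$supersample
  us <- seq(-80, head$R + 8, by = ss)
  vs <- seq(-100, head$R + 8, by = ss)
  P <- sweep(outer(rep(us, times = length(vs)), f1) +
               outer(rep(vs, each = length(us)), f2), 2, O, "+")
  hu2 <- matrix(sample_world(vol, P, fill = -1000), nrow = length(us))
  h_prov <- unitv(c(sum(unitv(O - O2) * f1), sum(unitv(O - O2) * f2)))
  # U/L: crossings of the head circle with the inner neck cortex
  ang0 <- atan2(-h_prov[2], -h_prov[1])
  dang <- seq(0, pi / 2, by = 2 * pi / 7200)
  arc_profile <- function(sgn) {
    a <- ang0 + sgn * dang
    pts <- cbind(head$R * cos(a), head$R * sin(a))
    Pw <- sweep(outer(pts[, 1], f1) + outer(pts[, 2], f2), 2, O, "+")
    list(a = a, prof = sample_world(vol, Pw, fill = -1000))
  }
  arc1 <- arc_profile(1)
  arc2 <- arc_profile(-1)
  # the inner neck cortex must be traced at a dense-cortex level: dense
  # trabeculae (the PCT itself reaches the sphere near the calcar) sit
  # above the generic bone threshold but well below cortical HU
  peak <- stats::quantile(c(arc1$prof, arc2$prof), 0.99)
  th_cx <- max(th, 0.55 * peak)
  crossing <- function(arc) {
    hit <- which(arc$prof >= th_cx)
    if (length(hit) == 0 || hit[1] == 1) {
      stop("U/L not found within 1.5 R of the head center: inner neck ",
           "cortex does not intersect the head sphere in the search arc")
    }
    l <- hit[1]
    # local mid-level crossing: unbiased against the edge blur regardless
    # of the tissue level on the interior side (cancellous or PCT)
    n <- length(arc$prof)
    w <- ceiling(3 / (head$R * 2 * pi / 7200))   # ~3 mm of arc
    lo <- min(arc$prof[max(1, l - w):(l - 1)])
    hi <- max(arc$prof[l:min(n, l + w)])
    lev <- (lo + hi) / 2
    m <- which(arc$prof >= lev)[1]
    if (is.na(m) || m < 2) {
      m <- l
      lev <- th_cx
    }
    fr <- (lev - arc$prof[m - 1]) / (arc$prof[m] - arc$prof[m - 1])
    a_star <- arc$a[m - 1] + fr * (arc$a[m] - arc$a[m - 1])
    c(head$R * cos(a_star), head$R * sin(a_star))
  }
  cr1 <- crossing(arc1)
  cr2 <- crossing(arc2)
  n_med2 <- perp2(h_prov)
  if (n_med2[1] < 0) n_med2 <- -n_med2       # medial = +f1 side
  if (sum(cr1 * n_med2) < sum(cr2 * n_med2)) {
    U2 <- cr1; L2 <- cr2
  } else {
    U2 <- cr2; L2 <- cr1
  }
  M2 <- (U2 + L2) / 2
  hn2_dir <- unitv(-M2)                        # M -> O in 2D, O at (0,0)
  # PFS axis in 2D
  p1 <- to2(O1); p3 <- to2(O3)
  pfs2_dir <- unitv(p3 - p1)                   # distal
  nsa <- compute_nsa(hn2_dir, pfs2_dir)
  # aux line: tangent to the medial neck cortex, parallel to the HN-axis
  n_med2 <- perp2(hn2_dir)
  if (n_med2[1] < 0) n_med2 <- -n_med2
  t_int2 <- tryCatch({
    x <- intersect_lines2(c(0, 0), -hn2_dir, p1, pfs2_dir)
    vnorm(x)
  }, error = function(e) vnorm(p1))
  UU <- rep(us, times = length(vs))
  VV <- rep(vs, each = length(us))
  bone <- as.vector(hu2) >= th
  # de-noise at the voxel scale: require bone 1 mm away in >= 3 of 4
  # in-plane directions
  shift_px <- max(1L, round(1 / ss))
  bmat <- matrix(bone, nrow = length(us))
  cnt <- matrix(0L, nrow(bmat), ncol(bmat))
  nr <- nrow(bmat); nc <- ncol(bmat)
  cnt[(shift_px + 1):nr, ] <- cnt[(shift_px + 1):nr, ] +
    bmat[1:(nr - shift_px), ]
  cnt[1:(nr - shift_px), ] <- cnt[1:(nr - shift_px), ] +
    bmat[(shift_px + 1):nr, ]
  cnt[, (shift_px + 1):nc] <- cnt[, (shift_px + 1):nc] +
    bmat[, 1:(nc - shift_px)]
  cnt[, 1:(nc - shift_px)] <- cnt[, 1:(nc - shift_px)] +
    bmat[, (shift_px + 1):nc]
  bone_clean <- bone & as.vector(cnt >= 3)
  tt <- -(UU * hn2_dir[1] + VV * hn2_dir[2])
  mm <- UU * n_med2[1] + VV * n_med2[2]
  # start the search distal to the head sphere so the inferomedial head
  # overhang cannot masquerade as the medial neck cortex
  t_lo <- max(0.9 * head$R, 0.25 * t_int2)
  sel <- bone_clean & tt >= t_lo & tt <= 0.8 * t_int2 & mm > 0
  if (!any(sel)) stop("medial neck cortex not found for the tangent line")
  r_tan <- max(mm[sel])
  structure(list(
    O = O, R = head$R, head_rms = head$rms,
    O1 = O1, O2 = O2, O3 = O3,
    U = O + U2[1] * f1 + U2[2] * f2,
    L = O + L2[1] * f1 + L2[2] * f2,
    M = O + M2[1] * f1 + M2[2] * f2,
    basis = basis,
    hn2 = list(point = c(0, 0), direction = hn2_dir),
    pfs2 = list(point = p1, direction = pfs2_dir),
    aux2 = list(point = r_tan * n_med2, direction = hn2_dir),
    NSA = nsa, t_isthmus = isth$t_isthmus,
    config = config), class = "femur_frame")
}

#' @export
print.femur_frame <- function(x, ...) {
  cat("<femur_frame> head R ", round(x$R, 2), " mm at (",
      paste(round(x$O, 1), collapse = ", "), "); NSA ",
      round(x$NSA, 2), " deg\n", sep = "")
  invisible(x)
}
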