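# Quadrilateral extraction on the binarized coronal projection:
# bottom boundary AB on the medial-cortex tangent line, top boundary CD
# on the head circle via the tangent lines AC / BD along the component's
# lateral and medial edges, then the PCT-axis and the scalar measures
# (delta, L-bottom, L-top, alpha, beta, NSA).

#' Side edges of the binarized PCT component
#'
#' Finds the supporting lines of the component's lateral and medial edges
#' (the tangent lines of the quadrilateral construction): long convex-hull
#' edges running up the trabecular column are refined by a principal-axis
#' fit to the nearby boundary pixels, then shifted outward by the known
#' peel-erosion depth so they coincide with the unpeeled PCT boundary.
#'
#' @param proj a binarized projection ([binarize()]).
#' @return List with `lat` and `med`, each `list(point, dir)` in 2D
#'   midcoronal mm; `dir` points from bottom to top.
#' @export
pct_side_edges <- function(proj) {
  if (is.null(proj$binary)) stop("projection is not binarized")
  idx <- which(proj$binary, arr.ind = TRUE)
  pts <- cbind(proj$u[idx[, 1]], proj$v[idx[, 2]])
  if (nrow(pts) < 30) stop("binarized PCT component too small")
  aux <- proj$aux2
  hhat <- unitv(aux$direction)
  n_in <- perp2(hhat)
  if (sum(n_in * (proj$O2d - aux$point)) < 0) n_in <- -n_in
  depth <- signed_dist2(pts, aux$point, hhat) *
    sign(sum(perp2(hhat) * n_in))
  g0 <- unitv(colMeans(pts[depth >= stats::quantile(depth, 0.85), ,
                           drop = FALSE]) -
                colMeans(pts[depth <= stats::quantile(depth, 0.15), ,
                             drop = FALSE]))
  # lateral = side of the HN-axis opposite the medial tangent line
  s_med <- side_of_line2(aux$point, proj$O2d, proj$hn2$direction)
  n_lat_h <- perp2(unitv(proj$hn2$direction)) * (-sign(s_med))
  n_lat0 <- perp2(g0)
  if (sum(n_lat0 * n_lat_h) < 0) n_lat0 <- -n_lat0
  ctr <- colMeans(pts)
  # boundary pixels (4-neighbour boundary) for the refinement fit
  b <- proj$binary
  inner <- b
  inner[-1, ] <- inner[-1, ] & b[-nrow(b), ]
  inner[-nrow(b), ] <- inner[-nrow(b), ] & b[-1, ]
  inner[, -1] <- inner[, -1] & b[, -ncol(b)]
  inner[, -ncol(b)] <- inner[, -ncol(b)] & b[, -1]
  bidx <- which(b & !inner, arr.ind = TRUE)
  bpts <- cbind(proj$u[bidx[, 1]], proj$v[bidx[, 2]])
  bdepth <- signed_dist2(bpts, aux$point, hhat) *
    sign(sum(perp2(hhat) * n_in))
  pick_edge <- function(side_sign) {
    # per-depth-bin extreme boundary points on the requested side; the
    # true straight edge carries most of them, while the head-neck
    # junction wedge (low depth, protruding) and the rounded corners
    # (high depth, receding) contaminate only the ends. A pairwise
    # RANSAC over the extremes with consensus counting recovers the
    # edge even when it is concave relative to the convex hull.
    lat_coord <- as.numeric(bpts %*% (side_sign * n_lat0))
    bins <- floor(bdepth / 2)
    use <- bdepth > 5 & bdepth < max(bdepth) - 1
    ext <- vapply(split(which(use), bins[use]), function(ii) {
      ii[which.max(lat_coord[ii])]
    }, integer(1))
    # drop extremes sitting on boundary stretches parallel to the
    # HN-axis: those belong to the inner-cortex / junction wall that
    # merges with the PCT bottom, not to the quadrilateral side edge
    cortex_like <- vapply(ext, function(k) {
      nb <- which(abs(bpts[, 1] - bpts[k, 1]) < 2 &
                    abs(bpts[, 2] - bpts[k, 2]) < 2)
      if (length(nb) < 5) return(FALSE)
      d <- stats::prcomp(bpts[nb, , drop = FALSE])$rotation[, 1]
      a <- angle_between(d, hhat)
      min(a, 180 - a) < 10
    }, logical(1))
    E <- bpts[ext[!cortex_like], , drop = FALSE]
    cortex_pts <- bpts[ext[cortex_like], , drop = FALSE]
    if (nrow(E) < 5) {
      stop("tangent undefined: no straight ",
           if (side_sign > 0) "lateral" else "medial",
           " edge found on the PCT component")
    }
    best <- NULL
    best_score <- -1
    ne <- nrow(E)
    for (i in seq_len(ne - 1)) {
      for (j in (i + 1):ne) {
        e <- E[j, ] - E[i, ]
        len <- vnorm(e)
        if (len < 8) next
        d <- e / len
        if (sum(d * g0) < 0) d <- -d
        if (sum(d * g0) < cos(50 * pi / 180)) next
        score <- sum(abs(signed_dist2(E, E[i, ], d)) < 0.3)
        if (score > best_score) {
          best_score <- score
          best <- list(p0 = E[i, ], dir = d)
        }
      }
    }
    if (is.null(best) || best_score < 5) {
      stop("tangent undefined: no straight ",
           if (side_sign > 0) "lateral" else "medial",
           " edge found on the PCT component")
    }
    # refit on the consensus extremes, then once more with a tighter
    # tolerance
    line <- best
    for (tol in c(0.45, 0.3)) {
      keep <- abs(signed_dist2(E, line$p0, line$dir)) < tol
      if (sum(keep) < 5) break
      pc <- stats::prcomp(E[keep, , drop = FALSE])
      d <- pc$rotation[, 1]
      if (sum(d * g0) < 0) d <- -d
      line <- list(p0 = as.numeric(pc$center), dir = unitv(d))
    }
    # final polish on all boundary pixels grazing the line, which
    # averages out the pixel-center quantization of the extremes;
    # pixels near the cortex-parallel wall stretches are excluded
    nearb <- abs(signed_dist2(bpts, line$p0, line$dir)) < 0.35 &
      bdepth > 8
    if (nrow(cortex_pts) > 0) {
      for (q in seq_len(nrow(cortex_pts))) {
        nearb <- nearb & (abs(bpts[, 1] - cortex_pts[q, 1]) > 2.5 |
                            abs(bpts[, 2] - cortex_pts[q, 2]) > 2.5)
      }
    }
    if (sum(nearb) >= 12) {
      pc <- stats::prcomp(bpts[nearb, , drop = FALSE])
      d <- pc$rotation[, 1]
      if (sum(d * g0) < 0) d <- -d
      line <- list(p0 = as.numeric(pc$center), dir = unitv(d))
    }
    line <- list(point = line$p0, dir = line$dir)
    # compensate the peel erosion: for the L1 (city-block) peel metric a
    # straight face with in-plane unit normal n is eroded by
    # (peel_vox + 0.5) * spacing * max(|n_u|, |n_v|)
    n_out <- perp2(line$dir)
    if (sum(n_out * (line$point - ctr)) < 0) n_out <- -n_out
    comp <- (proj$peel_vox + 0.5) * proj$spacing * max(abs(n_out))
    line$point <- line$point + comp * n_out
    line
  }
  list(lat = pick_edge(1), med = pick_edge(-1), g0 = g0)
}

#' Bottom boundary of the PCT (points A and B)
#'
#' The intersection of the PCT structure with the medial-cortex tangent
#' (aux) line: the component's lateral and medial edge lines
#' ([pct_side_edges()]) are intersected with the aux line. A is the
#' endpoint on the lateral side (toward the shaft), B the medial one.
#' Errors if the component does not approach the line within `gap_tol`
#' (reporting the gap).
#'
#' @param proj a binarized projection ([binarize()]).
#' @param config a [pct_config()].
#' @param edges optional precomputed [pct_side_edges()] result.
#' @return List with 2D points `A`, `B` (midcoronal mm), `gap` (closest
#'   approach of the component to the aux line, mm) and `edges`.
#' @export
bottom_boundary <- function(proj, config = pct_config(), edges = NULL) {
  if (is.null(proj$binary)) stop("projection is not binarized")
  aux <- proj$aux2
  hhat <- unitv(aux$direction)
  n_in <- perp2(hhat)
  if (sum(n_in * (proj$O2d - aux$point)) < 0) n_in <- -n_in
  idx <- which(proj$binary, arr.ind = TRUE)
  pts <- cbind(proj$u[idx[, 1]], proj$v[idx[, 2]])
  depth <- signed_dist2(pts, aux$point, hhat) *
    sign(sum(perp2(hhat) * n_in))
  gap <- min(depth)
  if (gap > config$gap_tol) {
    stop("gap of ", round(gap, 2), " mm between the PCT component and ",
         "the aux line exceeds gap_tol = ", config$gap_tol, " mm")
  }
  if (is.null(edges)) edges <- pct_side_edges(proj)
  A <- intersect_lines2(edges$lat$point, edges$lat$dir, aux$point, hhat)
  B <- intersect_lines2(edges$med$point, edges$med$dir, aux$point, hhat)
  list(A = A, B = B, gap = gap, edges = edges)
}

#' Top boundary of the PCT (points C and D)
#'
#' Lines AC and BD are tangent to the lateral and medial edges of the PCT
#' component (anchored at A and B, which lie on those edge lines); C and D
#' are their proximal intersections with the projected head circle.
#'
#' @param proj a binarized projection.
#' @param A,B bottom-boundary endpoints from [bottom_boundary()].
#' @param edges optional precomputed [pct_side_edges()] result.
#' @return List with 2D points `C`, `D`.
#' @export
top_boundary <- function(proj, A, B, edges = NULL) {
  if (is.null(proj$binary)) stop("projection is not binarized")
  if (is.null(edges)) edges <- pct_side_edges(proj)
  far_intersection <- function(anchor, dir) {
    hits <- intersect_line_circle2(anchor, dir, proj$O2d, proj$R)
    tpar <- (hits - matrix(anchor, 2, 2, byrow = TRUE)) %*% dir
    hits[which.max(tpar), ]
  }
  C <- far_intersection(A, edges$lat$dir)
  D <- far_intersection(B, edges$med$dir)
  list(C = C, D = D)
}

#' Measure the PCT quadrilateral
#'
#' From the quadrilateral corners, constructs the PCT-axis through the
#' midpoints E = mid(CD) and F = mid(AB) and measures: `delta`, the
#' perpendicular distance from the head center O to the PCT-axis, signed
#' positive when the axis lies lateral to O; `L_bottom` = |AB|;
#' `L_top` = |CD|; `alpha`, the acute angle between the PCT-axis and the
#' HN-axis; `NSA` from the projected axes; and `beta = 180 - NSA - alpha`
#' (the identity holds exactly by construction).
#'
#' @param proj a binarized projection (provides O, the axes and the aux
#'   line).
#' @param A,B,C,D quadrilateral corners, 2D midcoronal mm.
#' @return Object of class `pct_measures`.
#' @export
measure_pct <- function(proj, A, B, C, D) {
  E <- (C + D) / 2
  F <- (A + B) / 2
  if (vnorm(E - F) < 1e-6) stop("coincident PCT-axis midpoints E and F")
  g <- unitv(E - F)                      # bottom -> top
  hhat <- unitv(proj$hn2$direction)      # toward the head
  # lateral = side of the HN-axis opposite the medial tangent line
  s_med <- side_of_line2(proj$aux2$point, proj$O2d, hhat)
  n_lat <- perp2(hhat) * (-sign(s_med))
  n_ax <- perp2(g)
  if (sum(n_ax * n_lat) < 0) n_ax <- -n_ax
  foot <- project_on_line2(proj$O2d, F, g)
  delta <- sum((foot - proj$O2d) * n_ax)
  a <- angle_between(g, hhat)
  alpha <- min(a, 180 - a)
  nsa <- compute_nsa(hhat, proj$pfs2$direction)
  structure(list(A = A, B = B, C = C, D = D, E = E, F = F,
                 axis_point = F, axis_dir = g,
                 delta = delta, L_bottom = vnorm(A - B),
                 L_top = vnorm(C - D),
                 NSA = nsa, alpha = alpha, beta = 180 - nsa - alpha),
            class = "pct_measures")
}

#' @export
print.pct_measures <- function(x, ...) {
  cat(sprintf(paste0("<pct_measures> NSA %.2f deg  alpha %.2f deg  ",
                     "beta %.2f deg\n  delta %+.2f mm  L-bottom %.2f mm  ",
                     "L-top %.2f mm\n"),
              x$NSA, x$alpha, x$beta, x$delta, x$L_bottom, x$L_top))
  invisible(x)
}

#' Measure one proximal femur end-to-end
#'
#' Full pipeline: anatomy ([build_frame()]), mean head HU
#' ([mean_head_hu()]), personalized threshold segmentation ([segment()]),
#' coronal sum-projection ([project_coronal()]), binarization
#' ([binarize()]), quadrilateral extraction and measurement. The pipeline
#' is deterministic: the same volume gives the same record.
#'
#' @param vol a [ct_volume()] of a proximal femur.
#' @param config a [pct_config()].
#' @param side `"right"` or `"left"`; left femurs are mirrored across the
#'   sagittal plane before processing so all signs are defined once.
#' @param case case identifier for the output record.
#' @param keep_intermediates if `TRUE`, attach frame/projection/measures
#'   objects for QC.
#' @return A list of class `morphometry_record` with fields `case`,
#'   `side`, `R_mm`, `meanHU`, `NSA_deg`, `alpha_deg`, `beta_deg`,
#'   `delta_mm`, `Lbottom_mm`, `Ltop_mm` (and `$qc` when requested).
#' @export
measure_case <- function(vol, config = pct_config(),
                         side = c("right", "left"), case = "case",
                         keep_intermediates = FALSE) {
  side <- match.arg(side)
  if (side == "left") vol <- mirror_sagittal(vol)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }
  frame <- stage("anatomy", build_frame(vol, config))
  hn_dir3 <- as.numeric(frame$basis %*% c(frame$hn2$direction, 0))
  mhu <- stage("mean_head_hu",
               mean_head_hu(vol, frame$O, frame$R, hn_dir3))
  seg <- stage("segment", segment(vol, mhu, head_point = frame$O))
  proj <- stage("project", project_coronal(vol, seg, frame, config))
  proj <- stage("binarize", binarize(proj, config$min_voxels))
  bb <- stage("bottom_boundary", bottom_boundary(proj, config))
  tb <- stage("top_boundary", top_boundary(proj, bb$A, bb$B, bb$edges))
  meas <- stage("measure", measure_pct(proj, bb$A, bb$B, tb$C, tb$D))
  rec <- structure(list(case = case, side = side,
                        R_mm = frame$R, meanHU = mhu,
                        NSA_deg = meas$NSA, alpha_deg = meas$alpha,
                        beta_deg = meas$beta, delta_mm = meas$delta,
                        Lbottom_mm = meas$L_bottom,
                        Ltop_mm = meas$L_top),
                   class = "morphometry_record")
  if (keep_intermediates) {
    rec$qc <- list(frame = frame, projection = proj, measures = meas)
  }
  rec
}

#' @export
print.morphometry_record <- function(x, ...) {
  cat("<morphometry_record> ", x$case, " (", x$side, ")\n", sep = "")
  cat(sprintf("  R %.2f mm  meanHU %.1f  NSA %.2f deg\n",
              x$R_mm, x$meanHU, x$NSA_deg))
  cat(sprintf("  alpha %.2f  beta %.2f deg  delta %+.2f mm  L-bottom %.2f  L-top %.2f mm\n",
              x$alpha_deg, x$beta_deg, x$delta_mm, x$Lbottom_mm, x$Ltop_mm))
  invisible(x)
}

#' @rdname measure_case
#' @param records list of `morphometry_record`s.
#' @return `records_to_table`: a data.frame, one row per record, with the
#'   column layout `case, side, R_mm, meanHU, NSA_deg, alpha_deg,
#'   beta_deg, delta_mm, Lbottom_mm, Ltop_mm`.
#' @export
records_to_table <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    data.frame(case = r$case, side = r$side, R_mm = r$R_mm,
               meanHU = r$meanHU, NSA_deg = r$NSA_deg,
               alpha_deg = r$alpha_deg, beta_deg = r$beta_deg,
               delta_mm = r$delta_mm, Lbottom_mm = r$Lbottom_mm,
               Ltop_mm = r$Ltop_mm, stringsAsFactors = FALSE)
  }))
}

#' Plot a measured projection with the quadrilateral overlay
#'
#' @param x a [project_coronal()] result (binarized), typically from the
#'   `$qc` slot of [measure_case()].
#' @param measures optional [measure_pct()] result to overlay A-F.
#' @param ... passed to [graphics::image()].
#' @export
plot.pct_projection <- function(x, measures = NULL, ...) {
  graphics::image(x$u, x$v, x$sum, col = grDevices::gray.colors(256),
                  asp = 1, xlab = "medial (mm)", ylab = "proximal (mm)",
                  ...)
  th <- seq(0, 2 * pi, length.out = 181)
  graphics::lines(x$R * cos(th), x$R * sin(th), col = "cyan")
  if (!is.null(x$binary)) {
    graphics::contour(x$u, x$v, x$binary * 1, levels = 0.5, add = TRUE,
                      col = "yellow", drawlabels = FALSE)
  }
  if (!is.null(measures)) {
    pts <- rbind(measures$A, measures$B, measures$D, measures$C,
                 measures$A)
    graphics::lines(pts, col = "red", lwd = 2)
    graphics::points(rbind(measures$E, measures$F), col = "red", pch = 3)
  }
  invisible(x)
}
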