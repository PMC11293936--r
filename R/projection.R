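#' Personalized threshold segmentation
#'
#' Thresholds the volume at `tmin` (typically the measured mean head HU)
#' and keeps the connected component containing the femoral head,
#' separating the proximal femur from pelvis and soft tissue.
#'
#' @param vol a [ct_volume()].
#' @param tmin minimum HU threshold.
#' @param head_point world point inside the femoral head (used to select
#'   the component); if `NULL` the largest component is kept.
#' @return Object of class `seg_mask`: logical array `mask` aligned to
#'   `vol`, plus `threshold`.
#' @export
segment <- function(vol, tmin, head_point = NULL) {
  stopifnot(inherits(vol, "ct_volume"), is.finite(tmin))
  raw <- vol$values >= tmin
  if (!any(raw)) stop("empty segmentation mask at threshold ", tmin)
  lab <- label_components_cpp(as.vector(raw), dim(vol$values))
  pick <- 1L
  if (!is.null(head_point)) {
    idx <- round(as.numeric(world_to_index(vol, head_point)))
    d <- dim(vol$values)
    idx <- pmin(pmax(idx, 0), d - 1)
    l0 <- lab[idx[1] + 1, idx[2] + 1, idx[3] + 1]
    if (l0 > 0) {
      pick <- l0
    } else {
      # nearest labeled voxel to the head point
      on <- which(lab > 0)
      dd <- dim(vol$values)
      i <- (on - 1) %% dd[1]
      j <- ((on - 1) %/% dd[1]) %% dd[2]
      k <- (on - 1) %/% (dd[1] * dd[2])
      W <- index_to_world(vol, cbind(i, j, k))
      pick <- lab[on[which.min(colSums((t(W) - as.numeric(head_point))^2))]]
    }
  }
  structure(list(mask = array(lab == pick, dim(vol$values)),
                 threshold = tmin), class = "seg_mask")
}

#' Coronal sum-projection of a segmented volume
#'
#' Resamples HU and mask into the midcoronal frame and sums the masked HU
#' along the direction perpendicular to the midcoronal plane:
#' \deqn{Image(x, y) = \sum_i CT(x, y, i)}
#' over the masked voxels of each projection column. Besides the summed
#' image, per-column counts of masked voxels are recorded twice: from the
#' full mask and from the mask with the cortical rim peeled off (voxels
#' within `peel_mm` of the outer bone surface removed), the latter being
#' what [binarize()] thresholds to isolate the trabecular PCT.
#'
#' @param vol a [ct_volume()].
#' @param seg a [segment()] result aligned to `vol`.
#' @param frame a [build_frame()] result (provides the midcoronal basis,
#'   projected landmarks and the aux line).
#' @param config a [pct_config()].
#' @param full_sum if `TRUE`, sum all HU along each ray instead of only
#'   mask-passing HU.
#' @return Object of class `pct_projection` with `sum` (HU-sum image),
#'   `count`, `count_raw`, in-plane axes `u`/`v` (mm, midcoronal
#'   coordinates with origin at the head center O), `spacing`, the
#'   projected landmarks and the frame.
#' @export
project_coronal <- function(vol, seg, frame, config = pct_config(),
                            full_sum = FALSE) {
  stopifnot(inherits(seg, "seg_mask"), inherits(frame, "femur_frame"))
  sp <- config$proj_spacing
  us <- seq(-80, frame$R + 8, by = sp)
  vs <- seq(-100, frame$R + 8, by = sp)
  ws <- seq(-32, 32, by = sp)
  dims <- c(length(us), length(vs), length(ws))
  origin <- frame$O + us[1] * frame$basis[, 1] + vs[1] * frame$basis[, 2] +
    ws[1] * frame$basis[, 3]
  hu <- resample_to_frame(vol, origin, frame$basis, sp, dims, fill = -1000)
  mvol <- ct_volume(array(as.numeric(seg$mask), dim(vol$values)),
                    vol$spacing, vol$origin, vol$direction)
  mk <- resample_to_frame(mvol, origin, frame$basis, sp, dims, fill = 0)
  mask <- mk$values >= 0.5
  # majority-smoothed mask: unbiased for straight boundaries, and immune
  # to isolated noise dropouts that would otherwise seed the peel
  msm_v <- box_smooth_cpp(as.vector(mk$values), dims,
                          max(1L, as.integer(round(1 / sp))))
  msm <- array(msm_v >= 0.5, dims)
  # peel: remove mask voxels within peel_mm of the mask background, which
  # dissolves thin cortical shells (head, neck) entirely and strips the
  # faces of thicker compartments; the slab-like PCT interior survives
  peel_vox <- ceiling(config$peel_mm / sp)
  dist <- border_distance_cpp(as.vector(msm), dims)
  peeled <- msm & (array(dist, dims) > peel_vox)
  hu_eff <- if (full_sum) hu$values else hu$values * mask
  summed <- rowSums(hu_eff, dims = 2)
  count_raw <- rowSums(msm, dims = 2)
  count <- rowSums(peeled, dims = 2)
  structure(list(
    sum = summed, count = count, count_raw = count_raw,
    u = us, v = vs, spacing = sp, n_layers = length(ws),
    peel_mm = config$peel_mm, peel_vox = peel_vox,
    O2d = c(0, 0), R = frame$R,
    O1_2d = c(sum((frame$O1 - frame$O) * frame$basis[, 1]),
              sum((frame$O1 - frame$O) * frame$basis[, 2])),
    O3_2d = c(sum((frame$O3 - frame$O) * frame$basis[, 1]),
              sum((frame$O3 - frame$O) * frame$basis[, 2])),
    hn2 = frame$hn2, pfs2 = frame$pfs2, aux2 = frame$aux2,
    frame = frame), class = "pct_projection")
}

#' Binarize the coronal projection
#'
#' A pixel is foreground iff its projection column contained at least
#' `min_voxels` masked voxels. Among the resulting connected components
#' the one overlapping the projected femoral head disc the most is kept
#' (the PCT is the most prominent structure within the head); with no
#' head overlap anywhere, the largest component is kept.
#'
#' @param proj a [project_coronal()] result.
#' @param min_voxels column-count threshold (>= 1).
#' @param use_peeled threshold the rim-peeled counts (`TRUE`, the default;
#'   isolates the trabecular compartment) or the raw counts.
#' @return `proj` with logical matrix `$binary` added.
#' @export
binarize <- function(proj, min_voxels = 2, use_peeled = TRUE) {
  stopifnot(inherits(proj, "pct_projection"), min_voxels >= 1)
  cnt <- if (use_peeled) proj$count else proj$count_raw
  fg <- cnt >= min_voxels
  if (!any(fg)) stop("empty binarized foreground at min_voxels = ",
                     min_voxels)
  lab <- label_components_cpp(as.vector(fg), c(dim(fg), 1L))
  dim(lab) <- dim(fg)
  in_head <- outer(proj$u, rep(1, length(proj$v)))^2 +
    outer(rep(1, length(proj$u)), proj$v)^2 <= proj$R^2
  labs <- lab[lab > 0 & in_head]
  pick <- if (length(labs) > 0) {
    as.integer(names(which.max(table(labs))))
  } else 1L
  proj$binary <- lab == pick
  proj$min_voxels <- min_voxels
  proj
}

# bilinear sampling of a 2D image (u/v axes in mm) at arbitrary 2D points
sample_proj2 <- function(img, u, v, pts, fill = 0) {
  vol <- ct_volume(array(as.numeric(img), c(dim(img), 1L)),
                   spacing = c(u[2] - u[1], v[2] - v[1], 1),
                   origin = c(u[1], v[1], 0))
  sample_world(vol, cbind(pts, 0), fill = fill)
}
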