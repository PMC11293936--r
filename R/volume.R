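#' CT volume container
#'
#' A 3D scalar grid of Hounsfield units together with its world geometry.
#' World coordinates follow the DICOM patient convention (LPS: +x left,
#' +y posterior, +z superior), in mm. Voxel indices are 0-based with voxel
#' centers at integer indices; `origin` is the world position of voxel
#' (0, 0, 0) and the columns of `direction` are the world directions of the
#' three array axes.
#'
#' @param values 3D numeric array of HU values.
#' @param spacing per-axis voxel spacing, mm (length 3, all > 0).
#' @param origin world position of the first voxel center, mm.
#' @param direction 3x3 orthonormal direction-cosine matrix (det +1).
#' @return An object of class `ct_volume`.
#' @seealso [read_volume()], [write_volume()], [resample_to_frame()]
#' @export
ct_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      direction = diag(3)) {
  values <- as.array(values)
  if (length(dim(values)) != 3) stop("values must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(spacing <= 0)) {
    stop("spacing must be 3 positive values (mm)")
  }
  direction <- as.matrix(direction)
  if (max(abs(crossprod(direction) - diag(3))) > 1e-6 || det(direction) < 0) {
    stop("direction must be orthonormal with determinant +1")
  }
  structure(list(values = values, spacing = spacing,
                 origin = as.numeric(origin), direction = direction),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat("<ct_volume> ", paste(dim(x$values), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "/"),
      " mm\n  HU range [", round(min(x$values)), ", ",
      round(max(x$values)), "], origin (",
      paste(signif(x$origin, 4), collapse = ", "), ") mm\n", sep = "")
  invisible(x)
}

#' Convert between world coordinates and continuous voxel indices
#'
#' @param vol a [ct_volume()].
#' @param points length-3 vector or N x 3 matrix (world mm, or 0-based
#'   voxel indices for the inverse direction).
#' @return Same shape as `points`.
#' @export
world_to_index <- function(vol, points) {
  if (!is.matrix(points)) points <- matrix(points, ncol = 3)
  rel <- sweep(points, 2, vol$origin, "-") %*% vol$direction
  sweep(rel, 2, vol$spacing, "/")
}

#' @rdname world_to_index
#' @export
index_to_world <- function(vol, points) {
  if (!is.matrix(points)) points <- matrix(points, ncol = 3)
  sweep(sweep(points, 2, vol$spacing, "*") %*% t(vol$direction),
        2, vol$origin, "+")
}

#' Sample a volume at arbitrary world points (trilinear)
#'
#' @param vol a [ct_volume()].
#' @param points N x 3 matrix of world points, mm.
#' @param fill value for points outside the grid.
#' @return Numeric vector of interpolated HU values.
#' @export
sample_world <- function(vol, points, fill = 0) {
  idx <- world_to_index(vol, points)
  trilinear_sample_cpp(vol$values, dim(vol$values), idx, fill)
}

#' Resample a CT volume into an arbitrary oriented frame
#'
#' Multiplanar reslicing: the volume is trilinearly interpolated onto a new
#' regular grid whose axes are the columns of `basis`, reproducing the
#' re-slicing used to construct oblique anatomical planes. World positions
#' are preserved: a fixed world point has the same (interpolated) HU before
#' and after.
#'
#' @param vol a [ct_volume()].
#' @param origin world position of the first voxel center of the new grid.
#' @param basis 3x3 orthonormal matrix; columns are the new grid axes.
#' @param spacing new per-axis spacing, mm (length 3 or scalar).
#' @param dims integer dimensions of the new grid.
#' @param fill HU value for out-of-field voxels (default `0`, soft tissue).
#' @return A new [ct_volume()] in the requested frame.
#' @export
resample_to_frame <- function(vol, origin, basis, spacing, dims, fill = 0) {
  basis <- as.matrix(basis)
  if (max(abs(crossprod(basis) - diag(3))) > 1e-6) {
    stop("target basis must be orthonormal")
  }
  spacing <- rep(as.numeric(spacing), length.out = 3)
  dims <- as.integer(dims)
  i1 <- seq_len(dims[1]) - 1L
  i2 <- seq_len(dims[2]) - 1L
  i3 <- seq_len(dims[3]) - 1L
  grid <- cbind(rep(i1, times = dims[2] * dims[3]),
                rep(rep(i2, each = dims[1]), times = dims[3]),
                rep(i3, each = dims[1] * dims[2]))
  pts <- sweep(sweep(grid, 2, spacing, "*") %*% t(basis), 2, origin, "+")
  vals <- sample_world(vol, pts, fill = fill)
  ct_volume(array(vals, dims), spacing = spacing, origin = origin,
            direction = basis)
}

#' Apply the DICOM modality rescale to stored pixel values
#'
#' @param stored numeric stored values.
#' @param slope,intercept rescale slope and intercept; HU =
#'   `slope * stored + intercept`.
#' @return Numeric HU values.
#' @examples
#' hu_rescale(1024, 1, -1024)  # 0 HU
#' @export
hu_rescale <- function(stored, slope = 1, intercept = 0) {
  slope * stored + intercept
}

# ---- NIfTI I/O (world geometry converted RAS <-> LPS) ----------------------

ras_to_lps <- function(affine) diag(c(-1, -1, 1, 1)) %*% affine

#' Read a CT volume
#'
#' Reads a NIfTI file (`.nii` / `.nii.gz`) or an uncompressed DICOM CT
#' series directory into a [ct_volume()] in Hounsfield units. NIfTI affines
#' (RAS) are converted to the package's LPS world convention; the DICOM
#' modality rescale (slope/intercept) is applied on read.
#'
#' @param path path to a NIfTI file or a directory containing a DICOM series.
#' @return A [ct_volume()].
#' @export
read_volume <- function(path) {
  if (dir.exists(path)) return(read_dicom_series(path))
  img <- RNifti::readNifti(path)
  aff <- ras_to_lps(structure(RNifti::xform(img), dimnames = NULL))
  M <- aff[1:3, 1:3]
  spacing <- sqrt(colSums(M^2))
  direction <- sweep(M, 2, spacing, "/")
  if (det(direction) < 0) {
    # flip the third axis to restore a right-handed frame
    n3 <- dim(img)[3]
    img <- img[, , n3:1, drop = FALSE]
    aff[1:3, 4] <- aff[1:3, 4] + aff[1:3, 3] * (n3 - 1)
    aff[1:3, 3] <- -aff[1:3, 3]
    M <- aff[1:3, 1:3]
    direction <- sweep(M, 2, spacing, "/")
  }
  ct_volume(array(as.numeric(img), dim(img)[1:3]), spacing = spacing,
            origin = aff[1:3, 4], direction = direction)
}

#' Write a CT volume as NIfTI
#'
#' @param vol a [ct_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  aff_lps <- rbind(cbind(sweep(vol$direction, 2, vol$spacing, "*"),
                         vol$origin), c(0, 0, 0, 1))
  aff_ras <- ras_to_lps(aff_lps)  # involution: LPS -> RAS is the same flip
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing    # must precede the xform update
  RNifti::qform(img) <- structure(aff_ras, code = 2L)
  RNifti::sform(img) <- structure(aff_ras, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Mirror a volume across the sagittal plane
#'
#' Used for side normalization: left femurs are mirrored into right-femur
#' orientation before measurement so that "medial"/"lateral" and the sign
#' of delta are defined once.
#'
#' @param vol a [ct_volume()].
#' @return The mirrored [ct_volume()].
#' @export
mirror_sagittal <- function(vol) {
  stopifnot(inherits(vol, "ct_volume"))
  n1 <- dim(vol$values)[1]
  # world x -> -x, realized as an array flip plus origin/direction update
  vals <- vol$values[n1:1, , , drop = FALSE]
  last <- vol$origin + vol$direction[, 1] * vol$spacing[1] * (n1 - 1)
  origin <- c(-last[1], last[2], last[3])
  direction <- vol$direction
  direction[1, ] <- -direction[1, ]    # mirror world x
  direction[, 1] <- -direction[, 1]    # then reverse axis 1 (the flip)
  ct_volume(vals, vol$spacing, origin, direction)
}
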