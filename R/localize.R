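#' Annotation of an AP hip radiograph
#'
#' The manual annotations needed to localize the PCT on a true
#' anteroposterior radiograph: the analytical circle approximating the
#' femoral head contour, the head-neck (HN) axis, the proximal femoral
#' shaft (PFS) axis, and the line tangent to the medial cortex of the
#' femoral neck (parallel to the HN-axis). All coordinates in image mm
#' (pixels times the mm-per-pixel scale).
#'
#' @param O femoral head circle center, length-2, mm.
#' @param R head circle radius, mm.
#' @param hn_dir HN-axis direction pointing from neck toward head.
#' @param pfs_point,pfs_dir a point on the PFS-axis and its direction
#'   pointing distally (away from the hip).
#' @param tangent_point,tangent_dir a point on the medial-cortex tangent
#'   line and its direction (approximately parallel to the HN-axis).
#' @return Object of class `radiograph_annotation`. The neck-shaft angle
#'   implied by the two axes is stored as `$NSA`.
#' @export
radiograph_annotation <- function(O, R, hn_dir, pfs_point, pfs_dir,
                                  tangent_point, tangent_dir) {
  if (R <= 0) stop("head radius must be positive")
  hn_dir <- unitv(as.numeric(hn_dir))
  pfs_dir <- unitv(as.numeric(pfs_dir))
  if (abs(hn_dir[1] * pfs_dir[2] - hn_dir[2] * pfs_dir[1]) < 1e-9) {
    stop("HN-axis and PFS-axis are parallel")
  }
  nsa <- angle_between(hn_dir, pfs_dir)
  structure(list(O = as.numeric(O), R = R, hn_dir = hn_dir,
                 pfs_point = as.numeric(pfs_point), pfs_dir = pfs_dir,
                 tangent_point = as.numeric(tangent_point),
                 tangent_dir = unitv(as.numeric(tangent_dir)),
                 NSA = nsa),
            class = "radiograph_annotation")
}

#' Localize the PCT quadrilateral on an AP radiograph
#'
#' Applies the published regression models to the annotated NSA and head
#' radius, then constructs the PCT quadrilateral geometrically: the
#' PCT-axis is drawn at angle `alpha` to the HN-axis, offset `|delta|` to
#' the lateral (`delta > 0`) or medial (`delta < 0`) side of the head
#' center; the bottom boundary AB lies on the medial-cortex tangent line
#' with length `L_bottom`, bisected by the PCT-axis; the top boundary CD is
#' the chord of the head circle with length `L_top` whose midpoint lies on
#' the PCT-axis, taking the proximal of the two candidate chords.
#'
#' @param annot a [radiograph_annotation()].
#' @param models regression table, see [pct_models()].
#' @return Object of class `pct_localization`: predicted parameters plus
#'   the quadrilateral corners `A`, `B` (bottom, lateral/medial), `C`, `D`
#'   (top, lateral/medial) and the PCT-axis (`axis_point`, `axis_dir`).
#' @examples
#' ann <- radiograph_annotation(
#'   O = c(0, 0), R = 26.51,
#'   hn_dir = c(sin(53.32 * pi / 180), cos(53.32 * pi / 180)),
#'   pfs_point = c(-48, -30), pfs_dir = c(0, -1),
#'   tangent_point = c(19.1, -25.5),
#'   tangent_dir = c(sin(53.32 * pi / 180), cos(53.32 * pi / 180)))
#' loc <- localize_pct(ann)
#' loc$params$alpha   # 37.42 for NSA 126.68
#' @export
localize_pct <- function(annot, models = pct_models()) {
  stopifnot(inherits(annot, "radiograph_annotation"))
  pr <- predict_params(annot$NSA, annot$R, models)
  hhat <- annot$hn_dir
  # lateral = side of the HN-axis opposite the medial-cortex tangent line
  s_med <- side_of_line2(annot$tangent_point, annot$O, hhat)
  if (abs(s_med) < 1e-9) stop("tangent line passes through the head center")
  n_lat <- perp2(hhat) * (-sign(s_med))
  a_r <- deg2rad(pr$alpha)
  g <- cos(a_r) * hhat + sin(a_r) * n_lat
  n_ax <- perp2(g)
  if (sum(n_ax * n_lat) < 0) n_ax <- -n_ax
  q0 <- annot$O + pr$delta * n_ax
  # bottom boundary on the tangent line
  f_mid <- intersect_lines2(q0, g, annot$tangent_point, annot$tangent_dir)
  tdir <- annot$tangent_dir
  ends <- rbind(f_mid + pr$L_bottom / 2 * tdir, f_mid - pr$L_bottom / 2 * tdir)
  lat_side <- sign(sum(perp2(g) * n_ax))
  s_ends <- lat_side * signed_dist2(ends, q0, g)
  A <- ends[which.max(s_ends), ]
  B <- ends[which.min(s_ends), ]
  # top boundary: chord of the head circle bisected by the PCT-axis
  if (pr$L_top > 2 * annot$R) {
    stop("predicted L_top (", round(pr$L_top, 2),
         " mm) exceeds the head diameter; no chord exists")
  }
  m <- sqrt(annot$R^2 - (pr$L_top / 2)^2)
  if (abs(pr$delta) > m) {
    stop("PCT-axis misses the chord-midpoint circle (offset ",
         round(abs(pr$delta), 2), " mm > ", round(m, 2),
         " mm); nearest feasible L_top is ",
         round(2 * sqrt(annot$R^2 - pr$delta^2), 2), " mm")
  }
  cand <- intersect_line_circle2(q0, g, annot$O, m)
  mid_cd <- cand[which.max(cand %*% g), ]
  cdir <- unitv(perp2(mid_cd - annot$O))
  ends_t <- rbind(mid_cd + pr$L_top / 2 * cdir, mid_cd - pr$L_top / 2 * cdir)
  s_t <- lat_side * signed_dist2(ends_t, q0, g)
  C <- ends_t[which.max(s_t), ]
  D <- ends_t[which.min(s_t), ]
  structure(list(params = pr, A = A, B = B, C = C, D = D,
                 axis_point = q0, axis_dir = g,
                 O = annot$O, R = annot$R, NSA = annot$NSA),
            class = "pct_localization")
}

#' @export
print.pct_localization <- function(x, ...) {
  cat("<pct_localization> NSA ", round(x$NSA, 2), " deg, R ",
      round(x$R, 2), " mm\n", sep = "")
  cat(sprintf("  alpha %.2f deg  delta %+.2f mm  L-bottom %.2f mm  L-top %.2f mm\n",
              x$params$alpha, x$params$delta, x$params$L_bottom,
              x$params$L_top))
  invisible(x)
}
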