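#' Principal axes and aspect ratio of the chamber
#'
#' Applies principal component analysis to the coordinates of all pixels
#' inside the convex hull. The chamber aspect ratio is the ratio of the
#' standard deviations of the pixel coordinates projected on the major and
#' minor axes; unlike bounding-box lengths, projected SDs are robust to
#' localized boundary changes and image tilt.
#'
#' @param hull a `nuclei_segmentation` from [hull_and_area()] or
#'   [segment_chamber()].
#' @return A `chamber_geometry` object: list with `centroid` (x, y pixel
#'   coordinates), `major_axis` and `minor_axis` (orthonormal unit
#'   vectors), `sd_major`, `sd_minor` (px), `ratio` (`sd_major/sd_minor`,
#'   >= 1), `pa_direction` (`NA` until oriented by [orient_pa_axis()]),
#'   `oriented = FALSE`, and `isotropic` (flag for the degenerate
#'   equal-eigenvalue case, where image axes are used).
#' @export
pca_axes <- function(hull) {
  pts <- mask_coords(hull$hull_mask)
  if (nrow(pts) < 3) stop("pca_axes: degenerate hull mask")
  centroid <- colMeans(pts)
  cv <- cov(pts)
  eg <- eigen(cv, symmetric = TRUE)
  isotropic <- FALSE
  if (eg$values[2] <= 0 || diff(range(eg$values)) < 1e-9 * eg$values[1]) {
    if (eg$values[2] <= 0) stop("pca_axes: collinear hull pixels")
    isotropic <- TRUE
    major <- c(1, 0); minor <- c(0, 1)
  } else {
    major <- eg$vectors[, 1]
    minor <- eg$vectors[, 2]
  }
  # deterministic sign convention until the P-A orientation is assigned
  if (major[1] < 0 || (major[1] == 0 && major[2] < 0)) major <- -major
  minor <- c(-major[2], major[1])
  sds <- sqrt(eg$values)
  structure(list(
    centroid = centroid,
    major_axis = major,
    minor_axis = minor,
    sd_major = sds[1],
    sd_minor = sds[2],
    ratio = sds[1] / sds[2],
    pa_direction = c(NA_real_, NA_real_),
    oriented = FALSE,
    isotropic = isotropic
  ), class = "chamber_geometry")
}

#' @export
print.chamber_geometry <- function(x, ...) {
  cat(sprintf("<chamber_geometry> ratio %.3f (sd %.1f / %.1f px), %s\n",
              x$ratio, x$sd_major, x$sd_minor,
              if (isTRUE(x$oriented)) sprintf("P->A (%.2f, %.2f)",
                                              x$pa_direction[1],
                                              x$pa_direction[2])
              else "unoriented"))
  invisible(x)
}

#' Radially shrink the chamber boundary
#'
#' Maps each convex-hull vertex `v` to `centroid + factor * (v - centroid)`
#' and rasterizes the filled shrunken polygon. The shrunken boundary keeps
#' the thin peripheral band of follicle-cell nuclei on the exterior while
#' the large nurse-cell nuclei remain (at least partly) inside.
#'
#' @param hull a `nuclei_segmentation`.
#' @param shrink_factor radial scale in `(0, 1)`.
#' @return A `shrunken_boundary` object: list with `mask` ([binary_mask()]),
#'   `polygon` (shrunken vertices), `shrink_factor` and `centroid`.
#' @export
shrink_boundary <- function(hull, shrink_factor = 0.85) {
  if (!is.numeric(shrink_factor) || shrink_factor <= 0 || shrink_factor >= 1)
    stop("shrink_boundary: shrink_factor must be in (0, 1)")
  pts <- mask_coords(hull$hull_mask)
  centroid <- colMeans(pts)
  poly <- hull$hull_polygon
  shrunk <- sweep(sweep(poly, 2, centroid, `-`) * shrink_factor,
                  2, centroid, `+`)
  m <- rasterize_convex_polygon(shrunk, nrow(hull$hull_mask$pixels),
                                ncol(hull$hull_mask$pixels))
  if (sum(m) < 3)
    stop("shrink_boundary: shrunken polygon collapsed (< 3 px)")
  structure(list(mask = binary_mask(m, "shrunken_boundary"),
                 polygon = shrunk,
                 shrink_factor = shrink_factor,
                 centroid = centroid),
            class = "shrunken_boundary")
}

#' Orient the posterior-anterior axis
#'
#' PCA gives an axis but not a direction. The anterior end is the side of
#' the chamber containing more nurse-cell material: nuclei pixels inside
#' the shrunken boundary (interior nuclei are the large nurse cells) are
#' split by the hyperplane through the centroid normal to the major axis,
#' and the P-A direction points from the half with fewer interior nuclei
#' pixels (posterior, oocyte side) to the half with more (anterior).
#'
#' @param nuclei a [binary_mask()] of all nuclei.
#' @param geom a `chamber_geometry` from [pca_axes()].
#' @param shrunk a `shrunken_boundary` from [shrink_boundary()].
#' @return The geometry with `pa_direction` set (`major_axis` or its
#'   negation), `oriented = TRUE`, and `orientation_tie` flagging an exact
#'   count tie (orientation then arbitrary).
#' @export
orient_pa_axis <- function(nuclei, geom, shrunk) {
  m <- as_mask_matrix(nuclei) & as_mask_matrix(shrunk$mask)
  pts <- mask_coords(m)
  if (!nrow(pts)) stop("orient_pa_axis: no interior nuclei pixels")
  s <- (pts[, 1] - geom$centroid[1]) * geom$major_axis[1] +
       (pts[, 2] - geom$centroid[2]) * geom$major_axis[2]
  n_pos <- sum(s > 0)
  n_neg <- sum(s < 0)
  tie <- n_pos == n_neg
  if (tie) warning("orient_pa_axis: exact tie, orientation arbitrary")
  geom$pa_direction <- if (n_pos >= n_neg) geom$major_axis else -geom$major_axis
  geom$oriented <- TRUE
  geom$orientation_tie <- tie
  geom
}

#' Sample the middle axis
#'
#' The segment of the line through the centroid along the oriented P-A
#' direction, clipped to the convex hull, sampled at `n_points` equally
#' spaced positions ordered from the posterior end (Q1) to the anterior
#' end.
#'
#' @param geom an oriented `chamber_geometry`.
#' @param hull a `nuclei_segmentation`.
#' @param n_points number of sample points (default 30).
#' @return A `middle_axis` object: list with `points` (`n_points` x 2 matrix
#'   of pixel coordinates, posterior first), `s` (signed positions along
#'   `pa_direction` relative to the centroid) and `spacing` (px).
#' @export
middle_axis <- function(geom, hull, n_points = 30L) {
  if (!isTRUE(geom$oriented)) stop("middle_axis: geometry not oriented")
  n_points <- as.integer(n_points)
  if (n_points < 2) stop("middle_axis: need at least 2 points")
  tr <- clip_line_to_convex(geom$centroid, geom$pa_direction,
                            hull$hull_polygon)
  if (any(is.na(tr)))
    stop("middle_axis: internal error, P-A line misses the hull")
  s <- seq(tr[1], tr[2], length.out = n_points)  # posterior = smallest s
  pts <- cbind(geom$centroid[1] + s * geom$pa_direction[1],
               geom$centroid[2] + s * geom$pa_direction[2])
  colnames(pts) <- c("x", "y")
  structure(list(points = pts, s = s, spacing = diff(tr) / (n_points - 1)),
            class = "middle_axis")
}
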