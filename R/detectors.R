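#' Detect blob-like polytene chromosomes in nurse-cell nuclei
#'
#' At stage 4, nurse-cell nuclei show several discrete chromosome blobs. A
#' watershed transform of the nuclear intensity relief, restricted to each
#' nucleus, splits every nucleus into the catchment basins of its intensity
#' maxima; maxima whose relative depth is below `tolerance` are merged
#' first (so dim texture and noise do not fragment a smooth nucleus). A
#' chamber is called blob-positive when the median number of fragments per
#' nucleus reaches `median_fragments`.
#'
#' @param nurse_image a [chamber_image()] or matrix: the original
#'   intensities restricted to the nurse-cell nuclei (zero elsewhere).
#' @param nurse_mask a [binary_mask()] of the nurse-cell nuclei.
#' @param median_fragments decision threshold on the median fragments per
#'   nucleus (default 3).
#' @param tolerance minimum intensity depth separating two fragments
#'   (default 0.07); shallower maxima are merged into one basin.
#' @param smooth_sigma Gaussian pre-smoothing sd in px (default 1), for
#'   pixel-level noise suppression.
#' @return A `polytene_result` object: list with `nucleus_labels` (integer
#'   raster, one label per nucleus), `fragment_labels` (integer raster of
#'   watershed regions), `fragments_per_nucleus` (named integer vector),
#'   `median_fragments` and `is_blob_positive`.
#' @export
detect_polytene <- function(nurse_image, nurse_mask, median_fragments = 3,
                            tolerance = 0.07, smooth_sigma = 1) {
  img <- as_image_matrix(nurse_image)
  m <- as_mask_matrix(nurse_mask)
  if (!any(m)) stop("detect_polytene: empty nurse mask")
  nucleus_labels <- label_components8(m)
  n_nuc <- max(nucleus_labels)
  if (smooth_sigma > 0) {
    brush <- EBImage::makeBrush(2L * ceiling(3 * smooth_sigma) + 1L,
                                "gaussian", sigma = smooth_sigma)
    img <- as.matrix(EBImage::filter2(img, brush, boundary = "replicate"))
  }
  ws <- EBImage::watershed(EBImage::Image(img * m), tolerance = tolerance,
                           ext = 1)
  fragment_labels <- as.matrix(ws)
  storage.mode(fragment_labels) <- "integer"
  frags <- integer(n_nuc)
  for (k in seq_len(n_nuc)) {
    lab_k <- fragment_labels[nucleus_labels == k]
    frags[k] <- max(1L, length(unique(lab_k[lab_k > 0L])))
  }
  names(frags) <- seq_len(n_nuc)
  med <- median(frags)
  structure(list(
    nucleus_labels = nucleus_labels,
    fragment_labels = fragment_labels,
    fragments_per_nucleus = frags,
    median_fragments = med,
    is_blob_positive = med >= median_fragments
  ), class = "polytene_result")
}

#' Detect centripetally migrating follicle cells (stage 10B)
#'
#' At stage 10B, follicle cells migrate inward along the nurse-cell/oocyte
#' boundary. A band of width `bandwidth_sds` times the SD along the major
#' axis, normal to the P-A direction and anchored at the detected oocyte
#' boundary, is wide enough to capture migrating cells but narrower than a
#' nurse-cell nucleus. Candidate cells are nuclei components lying entirely
#' within the band (nurse cells straddle it and are excluded); centripetal
#' cells are the candidates whose centroid lies close to the outer chamber
#' boundary.
#'
#' @param nuclei a [binary_mask()] of all nuclei.
#' @param geom an oriented `chamber_geometry`.
#' @param oocyte an `oocyte_estimate` from [oocyte_boundary()].
#' @param hull a `nuclei_segmentation`.
#' @param bandwidth_sds band width as a multiple of `sd_major`
#'   (default 0.8).
#' @param rim_frac rim-proximity threshold as a fraction of `sd_minor`
#'   (default 0.15).
#' @param min_cells centripetal-cell count at or above which the chamber is
#'   called stage 10B (default 2).
#' @return A `centripetal_result` object: list with `applicable`, `band_mask`
#'   ([binary_mask()]), `candidate_labels`, `centripetal_labels` (integer
#'   vectors of component labels), `n_centripetal` and `is_stage_10B`.
#'   When the oocyte boundary is undefined the detector is inapplicable and
#'   flags are `FALSE`/`NA`.
#' @export
detect_centripetal <- function(nuclei, geom, oocyte, hull,
                               bandwidth_sds = 0.8, rim_frac = 0.15,
                               min_cells = 2L) {
  m <- as_mask_matrix(nuclei)
  if (isTRUE(oocyte$undefined) || is.na(oocyte$boundary_s)) {
    warning("detect_centripetal: no oocyte boundary, detector inapplicable")
    return(structure(list(applicable = FALSE,
                          band_mask = binary_mask(matrix(FALSE, nrow(m), ncol(m)),
                                                  "centripetal_band"),
                          candidate_labels = integer(0),
                          centripetal_labels = integer(0),
                          n_centripetal = NA_integer_,
                          is_stage_10B = NA),
                     class = "centripetal_result"))
  }
  if (!isTRUE(geom$oriented)) stop("detect_centripetal: geometry not oriented")
  half <- bandwidth_sds * geom$sd_major / 2
  nr <- nrow(m); nc <- ncol(m)
  xs <- rep(0:(nc - 1L), each = nr)
  ys <- rep(0:(nr - 1L), times = nc)
  s_all <- (xs - geom$centroid[1]) * geom$pa_direction[1] +
           (ys - geom$centroid[2]) * geom$pa_direction[2]
  band <- matrix(abs(s_all - oocyte$boundary_s) <= half, nr, nc)
  lab <- label_components8(m)
  n_lab <- max(lab)
  candidates <- integer(0)
  centripetal <- integer(0)
  for (k in seq_len(n_lab)) {
    idx <- which(lab == k)
    if (!all(band[idx])) next  # partially in the band: excluded (nurse cells)
    candidates <- c(candidates, k)
    r <- (idx - 1L) %% nr
    c <- (idx - 1L) %/% nr
    ctr <- c(mean(c), mean(r))
    if (point_polygon_distance(ctr, hull$hull_polygon) <=
        rim_frac * geom$sd_minor)
      centripetal <- c(centripetal, k)
  }
  structure(list(applicable = TRUE,
                 band_mask = binary_mask(band, "centripetal_band"),
                 candidate_labels = candidates,
                 centripetal_labels = centripetal,
                 n_centripetal = length(centripetal),
                 is_stage_10B = length(centripetal) >= min_cells),
            class = "centripetal_result")
}
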