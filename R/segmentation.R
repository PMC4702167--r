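#' Otsu's threshold
#'
#' Computes Otsu's global threshold of an intensity image by exhaustive
#' maximization of the between-class variance over a fixed histogram
#' binning of `[0, 1]`. Ties are broken toward the lowest threshold.
#'
#' @param x numeric matrix or vector of intensities in `[0, 1]`.
#' @param levels number of histogram bins (default 256, i.e. 8-bit binning).
#' @return The threshold, the upper edge of the optimal cut bin; foreground
#'   is `x > threshold`.
#' @export
otsu_threshold <- function(x, levels = 256L) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  if (!length(x)) stop("otsu_threshold: no finite intensities")
  x <- pmin(pmax(x, 0), 1)
  bin <- pmin(levels, floor(x * levels) + 1L)
  counts <- tabulate(bin, nbins = levels)
  mids <- (seq_len(levels) - 0.5) / levels
  n <- length(x)
  counts <- as.numeric(counts)  # avoid integer overflow in w0 * w1
  w0 <- cumsum(counts)[seq_len(levels - 1L)]
  s0 <- cumsum(counts * mids)[seq_len(levels - 1L)]
  total <- sum(counts * mids)
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  if (!any(valid)) stop("otsu_threshold: constant image, threshold undefined")
  sb <- rep(-Inf, levels - 1L)
  sb[valid] <- w0[valid] * w1[valid] *
    (s0[valid] / w0[valid] - (total - s0[valid]) / w1[valid])^2
  k <- which.max(sb)
  k / levels
}

#' Binarize an image at a fraction of Otsu's threshold
#'
#' Initial foreground extraction of the pipeline: the image is thresholded
#' at `scale` times Otsu's threshold, by default 20% of it, so that dim
#' nuclei are retained in the foreground.
#'
#' @param image a [chamber_image()] or numeric matrix in `[0, 1]`.
#' @param scale fraction of Otsu's threshold in `(0, 1]` (default 0.2;
#'   `scale = 1` is plain Otsu binarization).
#' @return A [binary_mask()]; foreground pixels have intensity strictly
#'   greater than `scale * otsu_threshold(image)`.
#' @export
#' @examples
#' img <- matrix(0, 20, 20); img[8:12, 8:12] <- 0.8
#' mask <- scaled_otsu_binarize(chamber_image(img, 1), scale = 0.2)
#' sum(mask$pixels)
scaled_otsu_binarize <- function(image, scale = 0.2) {
  if (!is.numeric(scale) || length(scale) != 1 || scale <= 0 || scale > 1)
    stop("scaled_otsu_binarize: scale must be in (0, 1]")
  px <- as_image_matrix(image)
  if (var(as.numeric(px)) == 0)
    stop("scaled_otsu_binarize: constant image (degenerate input), ",
         "Otsu's threshold undefined")
  thr <- scale * otsu_threshold(px)
  binary_mask(px > thr, provenance = sprintf("scaled_otsu(%.3g)", scale))
}

#' Average filter with replicate border padding
#'
#' Replaces each pixel by the mean of its `window x window` neighborhood
#' (borders replicated). Applied to a binary mask this produces a grayscale
#' image in which nearby foreground regions bleed into each other, so a
#' subsequent re-thresholding connects the egg chamber while leaving small
#' isolated noise regions disconnected.
#'
#' @param mask a [binary_mask()], or a numeric/logical matrix.
#' @param window odd neighborhood size, >= 3 (default 15).
#' @param pixel_size calibration to attach to the result (default 1).
#' @return A [chamber_image()] with intensities in `[0, 1]`.
#' @export
average_filter <- function(mask, window = 15L, pixel_size = 1) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("average_filter: window must be odd and >= 3")
  m <- as_mask_matrix(mask)
  x <- matrix(as.numeric(m), nrow(m), ncol(m))
  kern <- matrix(1 / window^2, window, window)
  out <- EBImage::filter2(x, kern, boundary = "replicate")
  out <- pmin(pmax(as.matrix(out), 0), 1)  # clip FFT ringing
  chamber_image(out, pixel_size)
}

#' Keep the largest connected foreground component
#'
#' Retains the 8-connected component with the most pixels (the egg chamber,
#' which occupies the largest area); smaller regions are treated as noise.
#' Ties are broken toward the component encountered first in raster-scan
#' order.
#'
#' @param mask a [binary_mask()] or logical matrix with at least one
#'   foreground pixel.
#' @return A [binary_mask()] containing only the largest component.
#' @export
largest_component <- function(mask) {
  m <- as_mask_matrix(mask)
  if (!any(m)) stop("largest_component: empty mask, segmentation failed")
  lab <- label_components8(m)
  sizes <- tabulate(lab[lab > 0L])
  winner <- which(sizes == max(sizes))[1L]  # labels follow raster-scan order
  binary_mask(lab == winner, provenance = "largest_component")
}

#' Fill mask holes and apply to the original image
#'
#' Fills interior holes of the mask, then retains original intensities on
#' the filled foreground and sets everything else to zero, yielding the
#' denoised chamber image.
#'
#' @param mask a [binary_mask()] or logical matrix.
#' @param image a [chamber_image()] (same shape).
#' @return A [chamber_image()] of the masked intensities.
#' @export
fill_and_apply_mask <- function(mask, image) {
  m <- as_mask_matrix(mask)
  px <- as_image_matrix(image)
  if (!all(dim(m) == dim(px)))
    stop("fill_and_apply_mask: mask and image shapes differ")
  filled <- as.matrix(EBImage::fillHull(matrix(as.integer(m), nrow(m)))) > 0
  ps <- if (inherits(image, "chamber_image")) image$pixel_size else 1
  out <- chamber_image(px * filled, ps)
  attr(out, "filled_mask") <- filled
  out
}

# signed distance-like initialization: grid of circles of radius r spaced d
chanvese_init_phi <- function(nr, nc, radius, spacing) {
  x <- 0:(nc - 1L)
  y <- 0:(nr - 1L)
  ux <- (x - spacing / 2) %% spacing
  uy <- (y - spacing / 2) %% spacing
  dx <- pmin(ux, spacing - ux)
  dy <- pmin(uy, spacing - uy)
  dist <- sqrt(outer(dy^2, dx^2, `+`))
  # clamp amplitude: keeps the regularized delta appreciable everywhere so
  # the level set evolves at a useful rate away from the initial interface
  pmin(pmax(radius - dist, -0.5), 0.5)
}

#' Segment nuclei with Chan-Vese active contours
#'
#' Runs a level-set Chan-Vese evolution on the denoised chamber image,
#' initialized from a regular grid of small circles (a set of small loops
#' approximates the many closed nuclear boundaries). The returned
#' foreground is oriented so that it covers the brighter region (the
#' nuclei). Deterministic for fixed inputs and parameters.
#'
#' @param image a [chamber_image()] or numeric matrix (the denoised,
#'   masked chamber).
#' @param params parameter list from [chamber_params()]; uses `cv_mu`,
#'   `cv_lambda1`, `cv_lambda2`, `cv_max_iter`, `cv_init_radius`,
#'   `cv_init_spacing`.
#' @param domain optional logical matrix restricting the evolution to a
#'   region of interest (e.g. the filled chamber mask); pixels outside it
#'   are frozen background and excluded from the region means. Restricting
#'   the domain makes the two-phase split unambiguous (nuclei versus
#'   intra-chamber background) instead of chamber versus black exterior.
#' @return A [binary_mask()] of the nuclei with attributes `converged`
#'   (logical), `iterations`, and `degenerate` (`TRUE` when the input had
#'   no boundary to find or the foreground collapsed to empty/full).
#' @export
chan_vese_nuclei <- function(image, params = chamber_params(), domain = NULL) {
  px <- as_image_matrix(image)
  if (is.null(domain)) domain <- matrix(TRUE, nrow(px), ncol(px))
  else domain <- as_mask_matrix(domain)
  if (var(as.numeric(px[domain])) < 1e-12) {
    warning("chan_vese_nuclei: uniform image, degenerate segmentation")
    out <- binary_mask(matrix(FALSE, nrow(px), ncol(px)), "chan_vese")
    attr(out, "converged") <- TRUE
    attr(out, "iterations") <- 0L
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  phi0 <- chanvese_init_phi(nrow(px), ncol(px),
                            params$cv_init_radius, params$cv_init_spacing)
  phi0[!domain] <- -1
  # warm-start the region means from an Otsu split of the domain, so the
  # bright phase is anchored to the nuclei even when they are a small
  # minority of the region of interest
  thr <- otsu_threshold(px[domain])
  hi <- domain & px > thr
  lo <- domain & px <= thr
  c1_init <- if (any(hi)) mean(px[hi]) else mean(px[domain])
  c2_init <- if (any(lo)) mean(px[lo]) else 0
  res <- chanvese_evolve(px, phi0, mu = params$cv_mu,
                         lambda1 = params$cv_lambda1,
                         lambda2 = params$cv_lambda2,
                         max_iter = params$cv_max_iter,
                         dt = 2, eps = 1, tol = 1e-5, domain = domain,
                         c1_init = c1_init, c2_init = c2_init,
                         warm_iters = 40L)
  fg <- res$foreground
  n_fg <- sum(fg)
  if (n_fg > 0 && n_fg < sum(domain) &&
      mean(px[fg]) < mean(px[domain & !fg])) {
    fg <- !fg & domain  # foreground = bright phase
  }
  degenerate <- sum(fg) == 0 || sum(fg) == sum(domain)
  if (!res$converged)
    warning("chan_vese_nuclei: iteration cap reached before convergence")
  if (degenerate)
    warning("chan_vese_nuclei: degenerate (empty or full) foreground")
  out <- binary_mask(fg, "chan_vese")
  attr(out, "converged") <- res$converged
  attr(out, "iterations") <- res$iterations
  attr(out, "degenerate") <- degenerate
  out
}

#' Convex hull of segmented nuclei and chamber area
#'
#' The egg chamber is modeled as the convex hull of its segmented nuclei;
#' its area is the number of hull pixels times the area of one pixel.
#'
#' @param nuclei a [binary_mask()] of nuclei with at least 3 non-collinear
#'   foreground pixels.
#' @param pixel_size physical pixel size, micrometres.
#' @return A `nuclei_segmentation` object: list with `nuclei_mask`,
#'   `hull_mask` (both [binary_mask()]), `hull_area` (square micrometres),
#'   `hull_polygon` (matrix of CCW vertices in pixel-center coordinates),
#'   and `pixel_size`.
#' @export
hull_and_area <- function(nuclei, pixel_size) {
  m <- as_mask_matrix(nuclei)
  pts <- mask_coords(m)
  if (nrow(pts) < 3)
    stop("hull_and_area: need at least 3 foreground pixels")
  poly <- convex_hull_polygon(pts)
  if (nrow(poly) < 3 || abs(polygon_signed_area(poly)) < 1e-9)
    stop("hull_and_area: foreground is collinear/degenerate")
  hull <- rasterize_convex_polygon(poly, nrow(m), ncol(m))
  hull <- hull | m  # every nucleus pixel belongs to the hull raster
  structure(list(
    nuclei_mask = binary_mask(m, "nuclei"),
    hull_mask = binary_mask(hull, "convex_hull"),
    hull_area = sum(hull) * pixel_size^2,
    hull_polygon = poly,
    pixel_size = pixel_size
  ), class = "nuclei_segmentation")
}

#' @export
print.nuclei_segmentation <- function(x, ...) {
  cat(sprintf("<nuclei_segmentation> hull area %.1f um^2 (%d px), %d nuclei px\n",
              x$hull_area, sum(x$hull_mask$pixels), sum(x$nuclei_mask$pixels)))
  invisible(x)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Segment an egg chamber end to end
#'
#' Runs the full denoising and segmentation workflow: binarization at a
#' fraction of Otsu's threshold, average filtering and Otsu
#' re-thresholding, largest-component extraction, hole filling and masking
#' of the original intensities, Chan-Vese nucleus segmentation, and convex
#' hull area measurement. All intermediates are returned for audit.
#'
#' @param image a [chamber_image()].
#' @param params parameter list from [chamber_params()].
#' @return A `nuclei_segmentation` (see [hull_and_area()]) with an extra
#'   element `intermediates`: a named list of the per-stage outputs
#'   (`binary_initial`, `filtered`, `binary_refiltered`, `largest`,
#'   `denoised`, `nuclei`).
#' @export
#' @examples
#' \donttest{
#' sim <- render_chamber(chamber_spec(stage = 6, seed = 1))
#' seg <- segment_chamber(sim$image)
#' seg$hull_area
#' }
segment_chamber <- function(image, params = chamber_params()) {
  stopifnot(inherits(image, "chamber_image"))
  bw1 <- run_stage("scaled_otsu_binarize",
                   scaled_otsu_binarize(image, params$otsu_scale))
  smooth <- run_stage("average_filter",
                      average_filter(bw1, params$filter_window,
                                     image$pixel_size))
  bw2 <- run_stage("rebinarize_otsu", scaled_otsu_binarize(smooth, 1))
  largest <- run_stage("largest_component", largest_component(bw2))
  denoised <- run_stage("fill_and_apply_mask",
                        fill_and_apply_mask(largest, image))
  nuclei <- run_stage("chan_vese_nuclei",
                      suppressWarnings(chan_vese_nuclei(
                        denoised, params,
                        domain = attr(denoised, "filled_mask"))))
  seg <- run_stage("hull_and_area", hull_and_area(nuclei, image$pixel_size))
  seg$intermediates <- list(binary_initial = bw1, filtered = smooth,
                            binary_refiltered = bw2, largest = largest,
                            denoised = denoised, nuclei = nuclei)
  seg
}
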