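#' Detect the oocyte boundary along the middle axis
#'
#' The oocyte occupies the posterior of the chamber and is DAPI-sparse. For
#' consecutive middle-axis points Qi, Qi+1 the hull pixels between the two
#' lines normal to the P-A axis form a band; the oocyte boundary is the
#' band closest to the posterior end whose nuclei (foreground) fraction
#' reaches `frac_threshold`. Everything posterior to that boundary is the
#' oocyte region.
#'
#' @param nuclei a [binary_mask()] of the interior (nurse-cell) nuclei,
#'   i.e. segmented nuclei restricted to the shrunken chamber boundary; the
#'   rim epithelium also covers the oocyte, so it must not count as band
#'   foreground.
#' @param axis a `middle_axis` from [middle_axis()].
#' @param geom an oriented `chamber_geometry`.
#' @param hull a `nuclei_segmentation`.
#' @param frac_threshold minimum band foreground fraction (default 0.10).
#' @return An `oocyte_estimate` object: list with `boundary_index` (index i
#'   of the axis point Qi defining the boundary, `NA` when undefined),
#'   `boundary_s` (signed position of the boundary along the P-A direction
#'   relative to the centroid), `area_fraction` (oocyte px / chamber px),
#'   `axis_fraction` (middle-axis length in the oocyte region / whole
#'   length) and `undefined` (`TRUE` when no band reaches the threshold,
#'   which is legitimate for early stages; fractions are then 0).
#' @export
oocyte_boundary <- function(nuclei, axis, geom, hull, frac_threshold = 0.10) {
  if (!isTRUE(geom$oriented)) stop("oocyte_boundary: geometry not oriented")
  if (length(axis$s) < 2) stop("oocyte_boundary: need at least 2 axis points")
  hm <- as_mask_matrix(hull$hull_mask)
  nm <- as_mask_matrix(nuclei) & hm
  pts <- mask_coords(hm)
  s <- (pts[, 1] - geom$centroid[1]) * geom$pa_direction[1] +
       (pts[, 2] - geom$centroid[2]) * geom$pa_direction[2]
  fg <- nm[hm]  # per hull pixel, aligned with `pts` rows
  qs <- axis$s
  n_bands <- length(qs) - 1L
  boundary <- NA_integer_
  for (i in seq_len(n_bands)) {
    # half-open bands [Q_i, Q_{i+1}) partition the hull; the last band is
    # closed above so the anterior tip pixel is not orphaned
    in_band <- if (i < n_bands) s >= qs[i] & s < qs[i + 1L]
               else s >= qs[i] & s <= qs[i + 1L]
    n_band <- sum(in_band)
    if (n_band == 0) next
    if (sum(fg[in_band]) / n_band >= frac_threshold) {
      boundary <- i
      break
    }
  }
  if (is.na(boundary)) {
    warning("oocyte_boundary: no band reaches the foreground threshold; ",
            "oocyte undefined")
    return(structure(list(boundary_index = NA_integer_, boundary_s = NA_real_,
                          area_fraction = 0, axis_fraction = 0,
                          undefined = TRUE),
                     class = "oocyte_estimate"))
  }
  s_bound <- qs[boundary]
  area_fraction <- sum(s < s_bound) / length(s)
  axis_fraction <- (s_bound - qs[1]) / (qs[length(qs)] - qs[1])
  structure(list(boundary_index = boundary, boundary_s = s_bound,
                 area_fraction = area_fraction, axis_fraction = axis_fraction,
                 undefined = FALSE),
            class = "oocyte_estimate")
}

#' Positions splitting given fractions of chamber area
#'
#' For each fraction `f`, finds the position along the P-A direction whose
#' posterior half-plane contains fraction `f` of the hull pixels (used for
#' the 1/3, 1/2, 2/3 area reference lines).
#'
#' @param hull a `nuclei_segmentation`.
#' @param geom an oriented `chamber_geometry`.
#' @param fractions numeric vector of fractions in `(0, 1)`.
#' @return Numeric vector of signed positions along `pa_direction` relative
#'   to the centroid, monotone in `fractions`.
#' @export
area_quantile_lines <- function(hull, geom, fractions = c(1/3, 1/2, 2/3)) {
  if (any(fractions <= 0 | fractions >= 1))
    stop("area_quantile_lines: fractions must lie in (0, 1)")
  if (!isTRUE(geom$oriented)) stop("area_quantile_lines: geometry not oriented")
  pts <- mask_coords(hull$hull_mask)
  s <- sort((pts[, 1] - geom$centroid[1]) * geom$pa_direction[1] +
            (pts[, 2] - geom$centroid[2]) * geom$pa_direction[2])
  n <- length(s)
  vapply(fractions, function(f) s[max(1L, ceiling(f * n))], numeric(1))
}

#' Separate follicle-cell nuclei from nurse-cell nuclei
#'
#' Follicle cells are much smaller than nurse cells, so after radially
#' shrinking the chamber boundary only follicle-cell nuclei lie completely
#' outside the shrunken region. Connected nuclei components that intersect
#' the shrunken mask (nurse cells) are removed entirely.
#'
#' @param nuclei a [binary_mask()] of all nuclei.
#' @param shrunk a `shrunken_boundary` computed with the follicle shrink
#'   factor (see [chamber_params()]`$shrink_follicle`).
#' @return A [binary_mask()] of follicle-cell nuclei with attribute `empty`
#'   flagging the case of zero follicle components (distribution
#'   undefined).
#' @export
separate_follicle_cells <- function(nuclei, shrunk) {
  m <- as_mask_matrix(nuclei)
  inner <- as_mask_matrix(shrunk$mask)
  lab <- label_components8(m)
  n_lab <- max(lab)
  if (n_lab == 0) {
    out <- binary_mask(matrix(FALSE, nrow(m), ncol(m)), "follicle_cells")
    attr(out, "empty") <- TRUE
    warning("separate_follicle_cells: no nuclei components")
    return(out)
  }
  touching <- unique(lab[inner & lab > 0L])
  keep <- setdiff(seq_len(n_lab), touching)
  out_m <- matrix(lab %in% keep & lab > 0L, nrow(m), ncol(m))
  out <- binary_mask(out_m, "follicle_cells")
  empty <- !any(out_m)
  if (empty)
    warning("separate_follicle_cells: zero follicle components, ",
            "distribution undefined")
  attr(out, "empty") <- empty
  out
}

#' Follicle-cell density per angular sector
#'
#' Splits the plane around the chamber centroid into `n_sectors`
#' equal-width sectors in the coordinate frame spanned by the P-A direction
#' and its normal, with sector 1 starting at the anterior end and
#' proceeding counterclockwise. Each sector's average follicle-cell
#' density is the number of follicle foreground pixels in the sector
#' divided by the length of the chamber (hull) boundary inside the sector.
#'
#' @param follicle a [binary_mask()] of follicle-cell nuclei (non-empty).
#' @param geom an oriented `chamber_geometry`.
#' @param hull a `nuclei_segmentation`.
#' @param n_sectors number of sectors (default 12).
#' @return A `sector_distribution` object: list with `densities`
#'   (length-`n_sectors`, px per boundary px), `normalized` (sums to 1),
#'   `counts`, `boundary_length` and `delta_to_uniform` (the
#'   [delta_distance()] between `normalized` and the uniform distribution).
#' @export
sector_densities <- function(follicle, geom, hull, n_sectors = 12L) {
  if (!isTRUE(geom$oriented)) stop("sector_densities: geometry not oriented")
  n_sectors <- as.integer(n_sectors)
  m <- as_mask_matrix(follicle)
  if (!any(m)) stop("sector_densities: empty follicle mask")
  ctr <- geom$centroid
  pa <- geom$pa_direction
  nv <- c(-pa[2], pa[1])  # normal, counterclockwise from the anterior ray
  sector_of <- function(px, py) {
    u <- (px - ctr[1]) * pa[1] + (py - ctr[2]) * pa[2]
    v <- (px - ctr[1]) * nv[1] + (py - ctr[2]) * nv[2]
    th <- atan2(v, u) %% (2 * pi)
    pmin(n_sectors, floor(th / (2 * pi / n_sectors)) + 1L)
  }
  pts <- mask_coords(m)
  counts <- tabulate(sector_of(pts[, 1], pts[, 2]), nbins = n_sectors)
  # boundary arc length per sector: densely resample the hull polygon and
  # attribute each sub-segment to the sector of its midpoint
  poly <- hull$hull_polygon
  nverts <- nrow(poly)
  lens <- numeric(n_sectors)
  for (i in seq_len(nverts)) {
    j <- if (i == nverts) 1L else i + 1L
    a <- poly[i, ]; b <- poly[j, ]
    elen <- sqrt(sum((b - a)^2))
    if (elen < 1e-12) next
    npiece <- max(1L, ceiling(elen / 0.5))
    t0 <- (seq_len(npiece) - 0.5) / npiece
    mx <- a[1] + t0 * (b[1] - a[1])
    my <- a[2] + t0 * (b[2] - a[2])
    k <- sector_of(mx, my)
    add <- tabulate(k, nbins = n_sectors) * (elen / npiece)
    lens <- lens + add
  }
  if (any(lens <= 0))
    stop("sector_densities: internal error, sector with zero boundary length")
  dens <- counts / lens
  if (sum(dens) <= 0) stop("sector_densities: zero total density")
  normalized <- dens / sum(dens)
  structure(list(
    densities = dens,
    normalized = normalized,
    counts = counts,
    boundary_length = lens,
    delta_to_uniform = delta_distance(normalized,
                                      rep(1 / n_sectors, n_sectors))
  ), class = "sector_distribution")
}

#' Delta-distance between two discrete distributions
#'
#' Triangular-discrimination form: `sum_i (p_i - q_i)^2 / (p_i + q_i)`,
#' with terms where `p_i + q_i = 0` contributing 0. Symmetric,
#' non-negative, zero iff `p == q`, and bounded above by 2.
#'
#' @param p,q non-negative numeric vectors of equal length, each summing to
#'   1 (tolerance 1e-9).
#' @return A non-negative scalar.
#' @export
#' @examples
#' delta_distance(c(1, 0), c(0.5, 0.5))  # 2/3
delta_distance <- function(p, q) {
  if (length(p) != length(q)) stop("delta_distance: length mismatch")
  if (any(p < 0) || any(q < 0)) stop("delta_distance: negative entries")
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9)
    stop("delta_distance: inputs must each sum to 1")
  denom <- p + q
  terms <- ifelse(denom == 0, 0, (p - q)^2 / ifelse(denom == 0, 1, denom))
  sum(terms)
}

#' Extract the per-chamber feature vector from an image
#'
#' Runs segmentation, geometry and feature computation end to end and
#' returns the scalar features consumed by the staging models.
#'
#' @param image a [chamber_image()].
#' @param params parameter list from [chamber_params()].
#' @return A `feature_vector` object: list with `log_size` (natural log of
#'   the hull area in square micrometres), `oocyte_fraction` (`NA` when the
#'   oocyte boundary is undefined), `chamber_ratio`, `delta_to_uniform`
#'   (`NA` when no follicle component is found), plus `hull_area_um2` and
#'   the underlying `segmentation`, `geometry`, `oocyte` and `sectors`
#'   objects.
#' @export
extract_features <- function(image, params = chamber_params()) {
  seg <- segment_chamber(image, params)
  geom <- pca_axes(seg)
  shr_or <- shrink_boundary(seg, params$shrink_orient)
  geom <- orient_pa_axis(seg$nuclei_mask, geom, shr_or)
  axis <- middle_axis(geom, seg, params$n_axis_points)
  # the oocyte rule scans the interior (nurse-cell) nuclei: the rim
  # epithelium covers the oocyte too, so it must not count as foreground
  interior <- binary_mask(seg$nuclei_mask$pixels & shr_or$mask$pixels,
                          "interior_nuclei")
  ooc <- suppressWarnings(
    oocyte_boundary(interior, axis, geom, seg,
                    params$oocyte_frac_threshold))
  shr_fc <- shrink_boundary(seg, params$shrink_follicle)
  fol <- suppressWarnings(separate_follicle_cells(seg$nuclei_mask, shr_fc))
  sect <- if (isTRUE(attr(fol, "empty"))) NULL
          else sector_densities(fol, geom, seg, params$n_sectors)
  structure(list(
    log_size = log(seg$hull_area),
    oocyte_fraction = if (isTRUE(ooc$undefined)) NA_real_ else ooc$area_fraction,
    chamber_ratio = geom$ratio,
    delta_to_uniform = if (is.null(sect)) NA_real_ else sect$delta_to_uniform,
    hull_area_um2 = seg$hull_area,
    segmentation = seg,
    geometry = geom,
    oocyte = ooc,
    sectors = sect
  ), class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf(paste0("<feature_vector> log size %.3f (%.0f um^2), ",
                     "oocyte %.3f, ratio %.3f, delta %.4f\n"),
              x$log_size, x$hull_area_um2,
              if (is.na(x$oocyte_fraction)) NA else x$oocyte_fraction,
              x$chamber_ratio,
              if (is.na(x$delta_to_uniform)) NA else x$delta_to_uniform))
  invisible(x)
}
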