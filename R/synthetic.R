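# Synthetic DAPI-like egg chamber generator. Renders an elliptical chamber
# with a rim of small follicle-cell nuclei, large nurse-cell nuclei in the
# anterior interior, a DAPI-sparse posterior oocyte region, optional
# stage-specific signals, distractor blobs and background noise, together
# with the ground truth the rendering was built from.

# posterior area fraction of an ellipse cut at s = t * a (s along the
# major axis, anterior positive): F(t) = 1/2 + (asin t + t sqrt(1-t^2)) / pi
ellipse_cut_fraction <- function(t) 0.5 + (asin(t) + t * sqrt(1 - t^2)) / pi

#' Specification of a synthetic egg chamber
#'
#' Draws the stochastic morphology of one chamber at a target stage from
#' the generative model: log-area linear in stage (slope 0.38 per stage,
#' about log(1500 um^2) at stage 2, Gaussian noise sd 0.15), aspect ratio
#' drifting from ~1 toward ~3 by stage 12, oocyte fraction 0 before stage 6
#' then increasing with late-stage acceleration, anterior follicle thinning
#' from stage 9, and blobby (polytene) nurse texture at stage 4. Any field
#' can be overridden.
#'
#' @param stage target stage, integer 2-12.
#' @param seed RNG seed; the same seed and overrides give a bit-identical
#'   spec and, via [render_chamber()], a bit-identical image.
#' @param ... overrides: `area_um2`, `ratio`, `oocyte_fraction` (in
#'   `[0, 0.9]`), `n_follicle`, `follicle_uniformity` (0 = uniform ring,
#'   larger = stage-9-like anterior thinning), `nurse_texture` (`"smooth"`
#'   or `"blobby"`), `centripetal` (plant migrating cells at the oocyte
#'   boundary), `noise_level`, `n_distractors`, `pixel_size` (um/px).
#' @return A `chamber_spec` object (named list, including derived ellipse
#'   semi-axes `a_um`, `b_um`).
#' @export
chamber_spec <- function(stage, seed, ...) {
  stage <- as.integer(stage)
  if (stage < 2L || stage > 12L) stop("chamber_spec: stage must be 2-12")
  spec <- with_local_seed(seed, {
    log_area <- log(1500) + 0.38 * (stage - 2) + rnorm(1, 0, 0.15)
    ratio <- max(1.02, 1 + 2 * (stage - 2) / 10 + rnorm(1, 0, 0.08))
    ooc_means <- c(`6` = 0.12, `7` = 0.18, `8` = 0.25, `9` = 0.33,
                   `10` = 0.42, `11` = 0.55, `12` = 0.70)
    oocyte_fraction <- if (stage < 6) 0 else
      min(0.9, max(0.05, ooc_means[[as.character(stage)]] + rnorm(1, 0, 0.03)))
    list(
      stage = stage,
      seed = as.integer(seed),
      area_um2 = exp(log_area),
      ratio = ratio,
      oocyte_fraction = oocyte_fraction,
      n_follicle = NA_integer_,
      follicle_uniformity = if (stage >= 9) 2.5 else 0,
      nurse_texture = if (stage == 4L) "blobby" else "smooth",
      centripetal = FALSE,
      noise_level = 0.02,
      n_distractors = 3L,
      pixel_size = NA_real_
    )
  })
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(spec))
    if (length(bad)) stop("chamber_spec: unknown field(s): ",
                          paste(bad, collapse = ", "))
    spec <- modifyList(spec, overrides)
  }
  if (spec$oocyte_fraction < 0 || spec$oocyte_fraction > 0.9)
    stop("chamber_spec: oocyte_fraction must lie in [0, 0.9]")
  if (spec$ratio < 1) stop("chamber_spec: ratio must be >= 1")
  spec$b_um <- sqrt(spec$area_um2 / (pi * spec$ratio))
  spec$a_um <- spec$ratio * spec$b_um
  if (is.na(spec$pixel_size))
    spec$pixel_size <- min(1.5, max(0.35, spec$a_um / 105))
  if (is.na(spec$n_follicle)) {
    # one nucleus per ~8 um of perimeter: distinct, well-separated rim dots
    # as in a midsagittal DAPI section
    ab <- c(spec$a_um, spec$b_um)
    perim <- pi * (3 * sum(ab) - sqrt((3 * ab[1] + ab[2]) *
                                        (ab[1] + 3 * ab[2])))
    spec$n_follicle <- max(20L, as.integer(round(perim / 8)))
  }
  structure(spec, class = "chamber_spec")
}

# add a Gaussian-profile blob to an intensity accumulator (by reference
# semantics: returns the updated matrix)
add_blob <- function(img, cx, cy, sigma, amp, cutoff = 3) {
  nr <- nrow(img); nc <- ncol(img)
  x0 <- max(0L, floor(cx - cutoff * sigma))
  x1 <- min(nc - 1L, ceiling(cx + cutoff * sigma))
  y0 <- max(0L, floor(cy - cutoff * sigma))
  y1 <- min(nr - 1L, ceiling(cy + cutoff * sigma))
  if (x1 < x0 || y1 < y0) return(img)
  xs <- x0:x1; ys <- y0:y1
  d2 <- outer((ys - cy)^2, (xs - cx)^2, `+`)
  img[ys + 1L, xs + 1L] <- img[ys + 1L, xs + 1L] + amp * exp(-d2 / (2 * sigma^2))
  img
}

add_disk <- function(mask, cx, cy, radius) {
  nr <- nrow(mask); nc <- ncol(mask)
  x0 <- max(0L, floor(cx - radius)); x1 <- min(nc - 1L, ceiling(cx + radius))
  y0 <- max(0L, floor(cy - radius)); y1 <- min(nr - 1L, ceiling(cy + radius))
  if (x1 < x0 || y1 < y0) return(mask)
  xs <- x0:x1; ys <- y0:y1
  d2 <- outer((ys - cy)^2, (xs - cx)^2, `+`)
  mask[ys + 1L, xs + 1L] <- mask[ys + 1L, xs + 1L] | (d2 <= radius^2)
  mask
}

#' Render a synthetic chamber image with ground truth
#'
#' @param spec a [chamber_spec()].
#' @return A list with `image` (a [chamber_image()]) and `truth`, a
#'   `ground_truth` list with `hull_area_um2` (convex-hull area of the
#'   noise-free nuclei), `true_ratio` (generating semi-axis ratio),
#'   `pa_direction` (unit vector, posterior to anterior), `oocyte_fraction`
#'   (posterior hull-area fraction of the oocyte region), `boundary_s`
#'   (oocyte boundary position along the P-A axis relative to the chamber
#'   center), `follicle_mask`, `nurse_mask`, `nuclei_mask` (logical
#'   matrices), `sector_normalized` (12-sector follicle distribution),
#'   `centripetal_centers`, `centroid`, `axes_px`, `stage` and `pixel_size`.
#' @export
#' @examples
#' sim <- render_chamber(chamber_spec(stage = 8, seed = 42))
#' sim$truth$hull_area_um2
render_chamber <- function(spec) {
  stopifnot(inherits(spec, "chamber_spec"))
  with_local_seed(spec$seed + 1L, render_chamber_impl(spec))
}

render_chamber_impl <- function(spec) {
  ps <- spec$pixel_size
  a <- spec$a_um / ps
  b <- spec$b_um / ps
  n <- 2L * ceiling(a) + 40L
  if (n > 4096L) stop("render_chamber: chamber too large for the canvas")
  ctr <- c((n - 1) / 2, (n - 1) / 2)
  theta <- runif(1, 0, 2 * pi)
  u <- c(cos(theta), sin(theta))       # posterior -> anterior unit vector
  nv <- c(-u[2], u[1])
  r_f <- max(1.8, 2.5 / ps)            # follicle nucleus radius ~2.5 um
  r_n <- min(0.26 * b, max(4, 0.22 * b))  # nurse nucleus radius
  f <- spec$oocyte_fraction
  s_cut <- if (f > 0) a * uniroot(function(t) ellipse_cut_fraction(t) - f,
                                  c(-1, 1), tol = 1e-10)$root
           else -a

  img <- matrix(0, n, n)
  follicle_mask <- matrix(FALSE, n, n)
  nurse_mask <- matrix(FALSE, n, n)

  # diffuse cytoplasmic background inside the chamber: DAPI tissue glow,
  # well below nuclear intensity but above the off-chamber background; this
  # is what makes the low (20%-of-Otsu) initial threshold pick up the whole
  # chamber as one region, as in real images
  xs_all <- rep(0:(n - 1L), each = n)
  ys_all <- rep(0:(n - 1L), times = n)
  su_all <- (xs_all - ctr[1]) * u[1] + (ys_all - ctr[2]) * u[2]
  sv_all <- (xs_all - ctr[1]) * nv[1] + (ys_all - ctr[2]) * nv[2]
  rho_el <- sqrt((su_all / a)^2 + (sv_all / b)^2)
  glow <- 0.07 * pmax(0, pmin(1, (1.02 - rho_el) / 0.05))
  img <- img + matrix(glow, n, n)

  # follicle ring: angular positions are quantiles of arc length weighted
  # by the anterior-thinning profile exp(-u0 * (1 + cos(phi)) / 2)
  rho <- 0.94
  phi_grid <- seq(0, 2 * pi, length.out = 1441L)[-1441L]
  ds <- sqrt((a * sin(phi_grid))^2 + (b * cos(phi_grid))^2)
  # thinning floor: even strongly stretched anterior epithelium retains
  # sparse cells (and the border-cell cluster) at the anterior tip
  thin <- 0.3 + 0.7 * exp(-spec$follicle_uniformity * (1 + cos(phi_grid)) / 2)
  wgt <- ds * thin
  cdf <- cumsum(wgt) / sum(wgt)
  targets <- ((seq_len(spec$n_follicle) - 0.5) / spec$n_follicle +
                runif(1)) %% 1
  idx <- pmin(length(phi_grid), findInterval(sort(targets), cdf) + 1L)
  phis <- phi_grid[idx]
  phis <- phis + rnorm(length(phis), 0, 0.12 * 2 * pi / spec$n_follicle)
  fol_centers <- cbind(
    ctr[1] + rho * (a * cos(phis) * u[1] + b * sin(phis) * nv[1]),
    ctr[2] + rho * (a * cos(phis) * u[2] + b * sin(phis) * nv[2]))
  for (i in seq_len(nrow(fol_centers))) {
    amp <- runif(1, 0.75, 0.95)
    img <- add_blob(img, fol_centers[i, 1], fol_centers[i, 2], r_f / 1.6, amp)
    follicle_mask <- add_disk(follicle_mask, fol_centers[i, 1],
                              fol_centers[i, 2], r_f)
  }

  # nurse nuclei: polydisperse dart packing of the anterior (non-oocyte)
  # interior. Nurse cells tile their compartment almost completely, so
  # radii vary and disks pack until ~3/4 of the region area is covered;
  # nuclei stay clear of the rim epithelium but squeeze toward the tips.
  nurse_centers <- matrix(numeric(0), ncol = 3)  # (s, w, radius)
  a_in0 <- 0.94 * a - r_f - 3
  b_in0 <- 0.94 * b - r_f - 3
  if (b_in0 > r_n + 2) {
    frac_cut <- if (f > 0) ellipse_cut_fraction(
      min(1, max(-1, s_cut / a_in0))) else 0
    region_area <- pi * a_in0 * b_in0 * (1 - frac_cut)
    target_area <- 0.75 * region_area
    placed_area <- 0
    # a row of nurse cells tiles directly against the oocyte boundary
    if (f > 0) {
      r_row <- 0.45 * r_n
      s_row <- s_cut + 0.55 * r_row
      w_max <- b_in0 * sqrt(max(0, 1 - (s_row / a_in0)^2)) - r_row
      if (w_max > 0) {
        n_row <- max(1L, floor(2 * w_max / (2.15 * r_row)) + 1L)
        for (wk in seq(-w_max, w_max, length.out = n_row)) {
          nurse_centers <- rbind(nurse_centers,
                                 c(s_row, wk + rnorm(1, 0, 0.1 * r_row),
                                   r_row))
          placed_area <- placed_area + pi * r_row^2
        }
      }
    }
    tries <- 0L
    while (placed_area < target_area && tries < 4000L &&
           nrow(nurse_centers) < 24L) {
      tries <- tries + 1L
      r_i <- r_n * runif(1, 0.7, 1.1)
      a_in <- a_in0 - 0.6 * r_i
      b_in <- b_in0 - r_i
      sx <- runif(1, -a_in, a_in)
      wx <- runif(1, -b_in, b_in)
      if ((sx / a_in)^2 + (wx / b_in)^2 > 1) next
      if (f > 0 && sx < s_cut + 0.7 * r_i) next
      if (nrow(nurse_centers) > 0) {
        d <- sqrt((nurse_centers[, 1] - sx)^2 + (nurse_centers[, 2] - wx)^2)
        if (any(d < 1.02 * (nurse_centers[, 3] + r_i))) next
      }
      nurse_centers <- rbind(nurse_centers, c(sx, wx, r_i))
      placed_area <- placed_area + pi * r_i^2
    }
  }
  if (nrow(nurse_centers)) {
    nxy <- cbind(ctr[1] + nurse_centers[, 1] * u[1] + nurse_centers[, 2] * nv[1],
                 ctr[2] + nurse_centers[, 1] * u[2] + nurse_centers[, 2] * nv[2])
    for (i in seq_len(nrow(nxy))) {
      r_i <- nurse_centers[i, 3]
      if (spec$nurse_texture == "blobby") {
        # polytene texture: weakly staining nucleoplasm holding the nucleus
        # together as one component, with discrete bright chromosome blobs
        img <- add_blob(img, nxy[i, 1], nxy[i, 2], r_i / 1.7, 0.5)
        n_sub <- sample(4:6, 1)
        ang <- runif(1, 0, 2 * pi) + 2 * pi * seq_len(n_sub) / n_sub +
          rnorm(n_sub, 0, 0.25)
        rad <- runif(n_sub, 0.4, 0.6) * r_i
        for (j in seq_len(n_sub))
          img <- add_blob(img, nxy[i, 1] + rad[j] * cos(ang[j]),
                          nxy[i, 2] + rad[j] * sin(ang[j]),
                          r_i / 6.5, runif(1, 0.4, 0.5))
      } else {
        img <- add_blob(img, nxy[i, 1], nxy[i, 2], r_i / 1.7,
                        runif(1, 0.65, 0.85))
      }
      nurse_mask <- add_disk(nurse_mask, nxy[i, 1], nxy[i, 2], r_i)
    }
  }

  # centripetal follicle cells at the oocyte boundary, touching the rim
  centripetal_centers <- NULL
  if (isTRUE(spec$centripetal) && f > 0) {
    t0 <- s_cut / a
    w_loc <- rho * b * sqrt(max(0, 1 - t0^2))
    for (side in c(-1, 1)) {
      cc <- ctr + s_cut * u + side * (w_loc - r_f) * nv
      img <- add_blob(img, cc[1], cc[2], r_f / 1.6, 0.9)
      follicle_mask <- add_disk(follicle_mask, cc[1], cc[2], r_f)
      centripetal_centers <- rbind(centripetal_centers, cc)
    }
  }

  nuclei_mask <- follicle_mask | nurse_mask

  # ground truth measured from the noise-free rendering
  pts <- mask_coords(nuclei_mask)
  poly <- convex_hull_polygon(pts)
  hull <- rasterize_convex_polygon(poly, n, n) | nuclei_mask
  hull_area_um2 <- sum(hull) * ps^2
  hpts <- mask_coords(hull)
  s_hull <- (hpts[, 1] - ctr[1]) * u[1] + (hpts[, 2] - ctr[2]) * u[2]
  oocyte_fraction_truth <- if (f > 0) mean(s_hull < s_cut) else 0
  # self-consistent aspect ratio: SD-ratio of the truth hull raster (the
  # generating semi-axis ratio is kept in `axis_ratio`)
  ev <- eigen(cov(hpts), symmetric = TRUE)$values
  true_ratio <- sqrt(ev[1] / ev[2])

  # 12-sector follicle distribution of the truth mask: counts per sector
  # over boundary arc length per sector (fine polygonal ellipse boundary)
  n_sec <- 12L
  fpts <- mask_coords(follicle_mask)
  su <- (fpts[, 1] - ctr[1]) * u[1] + (fpts[, 2] - ctr[2]) * u[2]
  sv <- (fpts[, 1] - ctr[1]) * nv[1] + (fpts[, 2] - ctr[2]) * nv[2]
  th <- atan2(sv, su) %% (2 * pi)
  counts <- tabulate(pmin(n_sec, floor(th / (2 * pi / n_sec)) + 1L), n_sec)
  phi_mid <- phi_grid + diff(phi_grid[1:2]) / 2
  arc <- ds * diff(phi_grid[1:2]) * rho
  # sectors are defined by the geometric angle around the centroid, not by
  # the ellipse parameter
  th_mid <- atan2(b * sin(phi_mid), a * cos(phi_mid)) %% (2 * pi)
  sec_of_mid <- pmin(n_sec, floor(th_mid / (2 * pi / n_sec)) + 1L)
  arc_len <- vapply(seq_len(n_sec), function(k) sum(arc[sec_of_mid == k]),
                    numeric(1))
  dens <- counts / arc_len
  sector_normalized <- dens / sum(dens)

  # distractor blobs well outside the chamber, then background noise
  r_d <- max(2, 2.5 / ps)
  placed <- 0L; tries <- 0L
  while (placed < spec$n_distractors && tries < 200L) {
    tries <- tries + 1L
    px <- runif(1, 3, n - 4); py <- runif(1, 3, n - 4)
    su0 <- (px - ctr[1]) * u[1] + (py - ctr[2]) * u[2]
    sv0 <- (px - ctr[1]) * nv[1] + (py - ctr[2]) * nv[2]
    rho_d <- sqrt((su0 / a)^2 + (sv0 / b)^2)
    # distractors stay clear of the chamber so the average filter cannot
    # bridge them into the chamber component
    if (rho_d < 1.3 || (rho_d - 1) * b < 25) next
    img <- add_blob(img, px, py, r_d / 1.7, runif(1, 0.5, 0.8))
    placed <- placed + 1L
  }
  if (spec$noise_level > 0)
    img <- img + matrix(rnorm(n * n, 0, spec$noise_level), n, n)
  img <- pmin(pmax(img, 0), 1)

  truth <- structure(list(
    hull_area_um2 = hull_area_um2,
    true_ratio = true_ratio,
    axis_ratio = spec$ratio,
    pa_direction = u,
    oocyte_fraction = oocyte_fraction_truth,
    target_oocyte_fraction = f,
    boundary_s = if (f > 0) s_cut else NA_real_,
    follicle_mask = follicle_mask,
    nurse_mask = nurse_mask,
    nuclei_mask = nuclei_mask,
    sector_normalized = sector_normalized,
    centripetal_centers = centripetal_centers,
    centroid = ctr,
    axes_px = c(a = a, b = b),
    stage = spec$stage,
    pixel_size = ps
  ), class = "ground_truth")
  list(image = chamber_image(img, ps), truth = truth)
}

#' Generate a synthetic per-chamber feature table
#'
#' Draws feature vectors per stage from the stated generative model:
#' log chamber size linear in stage with Gaussian noise; oocyte fraction 0
#' before stage 6, then increasing with a late-stage acceleration (nurse
#' cell dumping); chamber ratio drifting from ~1 toward ~3; Delta-distance
#' to uniform around 0.12 through stage 8 and around 0.30 from stage 9
#' (SD 0.05, the stage-8/9 separation).
#'
#' @param n_per_stage samples per stage (stages 2-12).
#' @param growth list with `slope` (default 0.38), `intercept` (default
#'   `log(1500)`, the stage-2 log area in um^2) and `sigma` (default 0.15).
#' @param seed RNG seed.
#' @param stages stage labels to generate (default 2:12).
#' @return A list with `table` (data frame: `stage`, `area_um2`,
#'   `log_size`, `oocyte_fraction`, `chamber_ratio`, `delta_to_uniform`)
#'   and `params` (the generating parameters, for recovery tests:
#'   `growth`, `delta_mean_8`, `delta_mean_9`, `delta_sd`).
#' @export
generate_feature_table <- function(n_per_stage, growth = list(), seed = 1,
                                   stages = 2:12) {
  growth <- modifyList(list(slope = 0.38, intercept = log(1500),
                            sigma = 0.15), growth)
  if (n_per_stage < 1) stop("generate_feature_table: n_per_stage >= 1")
  ooc_means <- c(`6` = 0.12, `7` = 0.18, `8` = 0.25, `9` = 0.33,
                 `10` = 0.42, `11` = 0.55, `12` = 0.70)
  delta_mean <- function(s) if (s <= 8) 0.12 else 0.30
  tab <- with_local_seed(seed, {
    rows <- lapply(stages, function(s) {
      n <- n_per_stage
      log_size <- growth$intercept + growth$slope * (s - 2) +
        rnorm(n, 0, growth$sigma)
      ooc <- if (s < 6) rep(0, n) else
        pmin(0.9, pmax(0, ooc_means[[as.character(s)]] + rnorm(n, 0, 0.03)))
      ratio <- pmax(1, 1 + 2 * (s - 2) / 10 + rnorm(n, 0, 0.08))
      delta <- pmax(0.001, rnorm(n, delta_mean(s), 0.05))
      data.frame(stage = s, area_um2 = exp(log_size), log_size = log_size,
                 oocyte_fraction = ooc, chamber_ratio = ratio,
                 delta_to_uniform = delta)
    })
    do.call(rbind, rows)
  })
  list(table = tab,
       params = list(growth = growth, delta_mean_8 = 0.12,
                     delta_mean_9 = 0.30, delta_sd = 0.05,
                     oocyte_means = ooc_means))
}
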