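# build an oriented elliptical test segmentation with controllable interior
# nuclei: posterior fraction `empty_frac` of the hull is left without
# foreground, the rest is filled with a dense dot lattice
ellipse_fixture <- function(a = 70, b = 28, empty_frac = 0.3, n = 181) {
  xs <- 0:(n - 1)
  c0 <- (n - 1) / 2
  ell <- outer(((xs - c0) / b)^2, ((xs - c0) / a)^2, `+`) <= 1
  ring <- ell & !(outer(((xs - c0) / (b - 3))^2, ((xs - c0) / (a - 3))^2,
                        `+`) <= 1)
  cut <- quantile((which(ell, arr.ind = TRUE)[, 2] - 1 - c0), empty_frac)
  lattice <- matrix(FALSE, n, n)
  cents <- expand.grid(x = seq(6, n - 6, by = 7), y = seq(6, n - 6, by = 7))
  for (k in seq_len(nrow(cents)))
    lattice <- lattice | disk_mask(n, cents$x[k], cents$y[k], 2.4)
  interior <- ell & lattice
  interior[, seq_len(floor(cut + c0 + 1))] <- FALSE  # empty posterior (left)
  nuclei <- interior | ring
  seg <- hull_and_area(binary_mask(nuclei), 1)
  g <- pca_axes(seg)
  sh <- shrink_boundary(seg, 0.85)
  g <- suppressWarnings(orient_pa_axis(binary_mask(interior), g, sh))
  if (g$pa_direction[1] < 0) {  # anterior should be +x by construction
    g$pa_direction <- -g$pa_direction
  }
  list(seg = seg, geom = g, interior = binary_mask(interior),
       empty_frac = empty_frac)
}

test_that("the oocyte boundary lands at the posterior empty fraction", {
  for (f in c(0.3, 0.5)) {
    fx <- ellipse_fixture(empty_frac = f)
    ax <- middle_axis(fx$geom, fx$seg)
    est <- oocyte_boundary(fx$interior, ax, fx$geom, fx$seg)
    expect_false(est$undefined)
    expect_lt(abs(est$area_fraction - f), 0.05)
    expect_gte(est$boundary_index, 1)
    expect_lte(est$boundary_index, 30)
    expect_gte(est$axis_fraction, 0)
    expect_lte(est$axis_fraction, 1)
  }
})

test_that("dense chambers give a first-band boundary, empty ones are flagged", {
  fx <- ellipse_fixture(empty_frac = 0)
  ax <- middle_axis(fx$geom, fx$seg)
  dense <- oocyte_boundary(binary_mask(fx$seg$hull_mask$pixels), ax,
                           fx$geom, fx$seg)
  expect_equal(dense$boundary_index, 1L)
  expect_lt(dense$area_fraction, 0.05)

  none <- matrix(FALSE, nrow(fx$seg$hull_mask$pixels),
                 ncol(fx$seg$hull_mask$pixels))
  expect_warning(
    est0 <- oocyte_boundary(binary_mask(none), ax, fx$geom, fx$seg),
    "undefined")
  expect_true(est0$undefined)
  expect_equal(est0$area_fraction, 0)
})

test_that("oocyte area fraction is monotone non-increasing in the threshold", {
  fx <- ellipse_fixture(empty_frac = 0.4)
  ax <- middle_axis(fx$geom, fx$seg)
  fracs <- vapply(c(0.05, 0.1, 0.2, 0.4), function(th)
    suppressWarnings(oocyte_boundary(fx$interior, ax, fx$geom, fx$seg,
                                     frac_threshold = th))$area_fraction,
    numeric(1))
  expect_true(all(diff(fracs) >= -1e-12))
})

test_that("area quantile lines split the chamber area as requested", {
  fx <- ellipse_fixture(empty_frac = 0)
  pos <- area_quantile_lines(fx$seg, fx$geom, c(1/3, 1/2, 2/3))
  expect_true(all(diff(pos) > 0))
  # fraction of hull pixels posterior to each returned position
  pts <- which(fx$seg$hull_mask$pixels, arr.ind = TRUE)
  s <- (pts[, 2] - 1 - fx$geom$centroid[1]) * fx$geom$pa_direction[1] +
       (pts[, 1] - 1 - fx$geom$centroid[2]) * fx$geom$pa_direction[2]
  got <- vapply(pos, function(p) mean(s <= p), numeric(1))
  expect_equal(got, c(1/3, 1/2, 2/3), tolerance = 0.02)
  # symmetric shape: the median line passes near the centroid
  expect_lt(abs(pos[2]), 1)
  expect_error(area_quantile_lines(fx$seg, fx$geom, c(0, 0.5)), "fractions")
})

test_that("follicle separation keeps exactly the components outside the shrunken boundary", {
  n <- 161
  ring_cells <- matrix(FALSE, n, n)
  ang <- seq(0, 2 * pi, length.out = 21)[-21]
  for (t in ang)
    ring_cells <- ring_cells | disk_mask(n, 80 + 72 * cos(t), 80 + 72 * sin(t), 3)
  big <- disk_mask(n, 80, 80, 20) | disk_mask(n, 45, 80, 18) |
    disk_mask(n, 115, 80, 18)
  # boundary-straddling blobs
  strad <- disk_mask(n, 80 + 56, 80, 8) | disk_mask(n, 80 - 56, 80, 8)
  nuclei <- ring_cells | big | strad
  seg <- hull_and_area(binary_mask(nuclei), 1)
  sh <- shrink_boundary(seg, 0.80)
  fol <- separate_follicle_cells(binary_mask(nuclei), sh)
  lab <- oracle_flood_fill(fol$pixels)
  expect_equal(max(lab), 20L)                 # exactly the 20 ring blobs
  expect_false(any(fol$pixels & sh$mask$pixels))  # disjoint from interior
  expect_true(all(nuclei[fol$pixels]))            # subset of the input

  # all blobs inside -> empty, flagged
  inner_only <- binary_mask(big)
  seg2 <- hull_and_area(inner_only, 1)
  expect_warning(f2 <- separate_follicle_cells(inner_only,
                                               shrink_boundary(seg2, 0.5)),
                 "zero follicle")
  expect_true(attr(f2, "empty"))
})

test_that("separation partitions components: kept plus removed equals input", {
  for (i in 1:5) {
    sim <- render_chamber(chamber_spec(stage = 7 + i %% 3, seed = 60000 + i))
    seg <- suppressWarnings(segment_chamber(sim$image))
    sh <- shrink_boundary(seg, 0.80)
    fol <- suppressWarnings(separate_follicle_cells(seg$nuclei_mask, sh))
    lab <- oracle_flood_fill(seg$nuclei_mask$pixels)
    kept_labels <- unique(lab[fol$pixels])
    removed <- seg$nuclei_mask$pixels & !fol$pixels
    expect_identical(fol$pixels | removed, seg$nuclei_mask$pixels)
    # no component is split between kept and removed
    expect_length(intersect(kept_labels, unique(lab[removed & lab > 0])), 0)
  }
})

test_that("sector densities: uniform rings are near-uniform, one-hot is extreme", {
  n <- 161
  ring_cells <- matrix(FALSE, n, n)
  ang <- seq(0, 2 * pi, length.out = 49)[-49]
  for (t in ang)
    ring_cells <- ring_cells | disk_mask(n, 80 + 70 * cos(t), 80 + 70 * sin(t), 2.2)
  interior <- disk_mask(n, 80, 80, 15) | disk_mask(n, 50, 80, 12)
  seg <- hull_and_area(binary_mask(ring_cells | interior), 1)
  g <- pca_axes(seg)
  g <- orient_pa_axis(binary_mask(interior), g, shrink_boundary(seg, 0.85))
  sd_u <- sector_densities(binary_mask(ring_cells), g, seg)
  expect_equal(sum(sd_u$normalized), 1, tolerance = 1e-9)
  expect_lt(sd_u$delta_to_uniform, 0.05)
  expect_equal(sum(sd_u$counts), sum(ring_cells))  # sectors partition the px

  # all follicle pixels in one sector -> one-hot distribution
  one <- matrix(FALSE, n, n)
  one <- one | disk_mask(n, 80 + 70 * cos(0.2), 80 + 70 * sin(0.2), 2.2)
  sd_1 <- sector_densities(binary_mask(one), g, seg)
  expect_equal(sum(sd_1$normalized > 1e-12), 1L)
  uni <- rep(1 / 12, 12)
  onehot <- as.numeric(sd_1$normalized > 1e-12)
  expect_equal(sd_1$delta_to_uniform, delta_distance(onehot, uni),
               tolerance = 1e-9)
})

test_that("rotating the scene cyclically shifts the sector densities", {
  # follicle pixels at known angles in the oriented frame; rotating the
  # geometry frame by one sector width shifts the density vector by one
  n <- 161
  seg_ring <- matrix(FALSE, n, n)
  ang <- (0:11) * pi / 6 + pi / 12
  w <- c(3, 5, 2, 7, 4, 6, 2, 3, 5, 4, 6, 3)
  for (k in 1:12) for (j in seq_len(w[k]))
    seg_ring <- seg_ring | disk_mask(n, 80 + 70 * cos(ang[k] + 0.02 * j),
                                     80 + 70 * sin(ang[k] + 0.02 * j), 1.4)
  hull <- hull_and_area(binary_mask(disk_mask(n, 80, 80, 73)), 1)
  g <- pca_axes(hull)
  g$pa_direction <- c(1, 0); g$oriented <- TRUE
  d0 <- sector_densities(binary_mask(seg_ring), g, hull)
  g2 <- g
  g2$pa_direction <- c(cos(pi / 6), sin(pi / 6))  # rotate frame one sector
  d1 <- sector_densities(binary_mask(seg_ring), g2, hull)
  expect_equal(d1$normalized, d0$normalized[c(2:12, 1)], tolerance = 0.05)
})

test_that("delta distance follows the triangular-discrimination formula", {
  expect_equal(delta_distance(c(1, 0), c(0.5, 0.5)), 2 / 3)
  p <- c(0.2, 0.3, 0.5)
  expect_equal(delta_distance(p, p), 0)
  for (i in 1:20) {
    pq <- with_seed_restore(300 + i, {
      a <- runif(6); b <- runif(6)
      list(p = a / sum(a), q = b / sum(b))
    })
    expect_equal(delta_distance(pq$p, pq$q), delta_distance(pq$q, pq$p))
    expect_gte(delta_distance(pq$p, pq$q), 0)
    expect_lte(delta_distance(pq$p, pq$q), 2)
  }
  # disjoint supports attain the maximum of 2
  expect_equal(delta_distance(c(1, 0), c(0, 1)), 2)
  expect_error(delta_distance(c(1, 0), c(0.5, 0.4)), "sum")
  expect_error(delta_distance(c(1, 0), c(0.2, 0.3, 0.5)), "length")
  expect_error(delta_distance(c(1.2, -0.2), c(0.5, 0.5)), "negative")
})

test_that("stage-9-like anterior thinning raises the delta distance", {
  sep <- logical(0)
  for (i in 1:12) {
    s8 <- render_chamber(chamber_spec(stage = 8, seed = 70000 + i))
    s9 <- render_chamber(chamber_spec(stage = 9, seed = 70000 + i))
    f8 <- suppressWarnings(extract_features(s8$image))
    f9 <- suppressWarnings(extract_features(s9$image))
    sep <- c(sep, isTRUE(f9$delta_to_uniform > f8$delta_to_uniform))
  }
  expect_gte(mean(sep), 0.9)
})

test_that("extract_features returns a complete, consistent feature vector", {
  sim <- render_chamber(chamber_spec(stage = 10, seed = 99))
  fv <- suppressWarnings(extract_features(sim$image))
  expect_s3_class(fv, "feature_vector")
  expect_equal(fv$log_size, log(fv$hull_area_um2))
  expect_gte(fv$chamber_ratio, 1)
  expect_gte(fv$oocyte_fraction, 0)
  expect_gte(fv$delta_to_uniform, 0)
})
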