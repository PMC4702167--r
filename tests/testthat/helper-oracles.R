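# Independent oracles used across the suite. These deliberately use naive,
# brute-force formulations so they share no code path with the package.

# Otsu threshold by exhaustive between-class-variance maximization over all
# histogram cut points (naive O(levels^2) loop).
oracle_otsu <- function(x, levels = 256L) {
  x <- pmin(pmax(as.numeric(x), 0), 1)
  bin <- pmin(levels, floor(x * levels) + 1L)
  counts <- as.numeric(tabulate(bin, nbins = levels))
  mids <- (seq_len(levels) - 0.5) / levels
  best <- -Inf
  best_k <- NA_integer_
  for (k in seq_len(levels - 1L)) {
    n0 <- sum(counts[1:k])
    n1 <- sum(counts[(k + 1):levels])
    if (n0 == 0 || n1 == 0) next
    m0 <- sum(counts[1:k] * mids[1:k]) / n0
    m1 <- sum(counts[(k + 1):levels] * mids[(k + 1):levels]) / n1
    sb <- n0 * n1 * (m0 - m1)^2
    if (sb > best) {
      best <- sb
      best_k <- k
    }
  }
  best_k / levels
}

# 8-connected components by queue-based flood fill (pure R).
oracle_flood_fill <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || lab[r0, c0] > 0L) next
    nxt <- nxt + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r <- p[1] + dr; c <- p[2] + dc
        if (r < 1 || r > nr || c < 1 || c > nc) next
        if (mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- nxt
          queue[[length(queue) + 1]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# two-sided permutation test on the difference of means
oracle_permutation_p <- function(a, b, n_perm = 1e5, seed = 1) {
  v <- c(a, b)
  na <- length(a)
  obs <- mean(a) - mean(b)
  sims <- with_seed_restore(seed, replicate(n_perm, {
    idx <- sample.int(length(v), na)
    mean(v[idx]) - mean(v[-idx])
  }))
  mean(abs(sims) >= abs(obs) - 1e-12)
}

# intersection of two Gaussian densities between the means by grid search
oracle_gaussian_root <- function(ma, sa, mb, sb, n_grid = 200001L) {
  lo <- min(ma, mb); hi <- max(ma, mb)
  xs <- seq(lo, hi, length.out = n_grid)
  d <- dnorm(xs, ma, sa) - dnorm(xs, mb, sb)
  xs[which.min(abs(d))]
}

# run code under a seed, restoring RNG state (tests must not perturb
# each other's randomness)
with_seed_restore <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# filled disk mask on an n x n canvas, center (cx, cy) and radius in 0-based
# pixel coordinates
disk_mask <- function(n, cx, cy, radius) {
  xs <- 0:(n - 1)
  d2 <- outer((xs - cy)^2, (xs - cx)^2, `+`)
  d2 <= radius^2
}

iou <- function(a, b) sum(a & b) / sum(a | b)

# distance from a point to a closed polygon boundary (naive per-edge)
point_polygon_distance_test <- function(p, poly) {
  n <- nrow(poly)
  dmin <- Inf
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a <- poly[i, ]; b <- poly[j, ]
    ab <- b - a
    t0 <- if (sum(ab^2) < 1e-12) 0 else
      max(0, min(1, sum((p - a) * ab) / sum(ab^2)))
    q <- a + t0 * ab
    dmin <- min(dmin, sqrt(sum((p - q)^2)))
  }
  dmin
}

# a constructed 10B-like scene: elliptical hull, nurse nuclei straddling the
# band, and (optionally) two small cells planted fully inside the band right
# against the rim at the detected oocyte boundary
centripetal_fixture <- function(plant = TRUE) {
  n <- 181
  xs <- 0:(n - 1)
  c0 <- (n - 1) / 2
  a <- 80; b <- 42
  ell <- outer(((xs - c0) / b)^2, ((xs - c0) / a)^2, `+`) <= 1
  ring0 <- ell & !(outer(((xs - c0) / (b - 3))^2, ((xs - c0) / (a - 3))^2,
                         `+`) <= 1)
  # oocyte = left ~40%; nurse cells fill the right side
  nurse <- disk_mask(n, c0 + 28, c0, 16) | disk_mask(n, c0 + 55, c0 + 10, 14) |
    disk_mask(n, c0 + 55, c0 - 12, 13) | disk_mask(n, c0 + 20, c0 + 24, 12) |
    disk_mask(n, c0 + 14, c0 - 4, 11)
  build <- function(ring, extra = NULL) {
    nuclei <- (nurse & ell) | ring
    if (!is.null(extra)) nuclei <- nuclei | extra
    seg <- hull_and_area(binary_mask(nuclei), 1)
    g <- pca_axes(seg)
    g$pa_direction <- c(1, 0); g$oriented <- TRUE
    interior <- binary_mask(nuclei & shrink_boundary(seg, 0.85)$mask$pixels)
    ooc <- oocyte_boundary(interior, middle_axis(g, seg), g, seg)
    list(seg = seg, geom = g, oocyte = ooc, nuclei = binary_mask(nuclei))
  }
  base <- build(ring0)
  s_b <- base$oocyte$boundary_s
  # clear the ring near the planting sites so planted cells stay distinct
  xs_g <- matrix(rep(xs, each = n), n, n)   # column (x) coordinate
  ys_g <- matrix(rep(xs, times = n), n, n)  # row (y) coordinate
  notch <- abs(xs_g - (c0 + s_b)) < 9 & abs(abs(ys_g - c0) - b) < 12
  ring <- ring0 & !notch
  planted <- list()
  extra <- NULL
  if (plant) {
    for (side in c(-1, 1)) {
      cc <- c(c0 + s_b, c0 + side * (b - 2.5))
      extra <- if (is.null(extra)) disk_mask(n, cc[1], cc[2], 2.5)
               else extra | disk_mask(n, cc[1], cc[2], 2.5)
      planted[[length(planted) + 1]] <- cc
    }
  }
  out <- build(ring, extra)
  out$planted <- planted
  out
}
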