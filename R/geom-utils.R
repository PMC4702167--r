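# Internal geometry helpers. Pixel-coordinate convention throughout:
# a pixel at matrix position [r, c] has center (x, y) = (c - 1, r - 1),
# i.e. 0-based, x along columns, y along rows, each pixel a unit square.

# (n x 2) matrix of (x, y) centers of foreground pixels, raster-scan order
mask_coords <- function(mask) {
  m <- as_mask_matrix(mask)
  idx <- which(m)
  if (!length(idx)) return(matrix(numeric(0), ncol = 2,
                                  dimnames = list(NULL, c("x", "y"))))
  r <- (idx - 1L) %% nrow(m)
  c <- (idx - 1L) %/% nrow(m)
  cbind(x = c, y = r)
}

# signed area of a polygon (positive = counterclockwise in (x, y))
polygon_signed_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(seq_len(nrow(poly))[-1], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

ensure_ccw <- function(poly) {
  if (polygon_signed_area(poly) < 0) poly[rev(seq_len(nrow(poly))), , drop = FALSE]
  else poly
}

# convex hull polygon (vertices, CCW, not closed) of an (n x 2) point set
convex_hull_polygon <- function(pts) {
  idx <- chull(pts[, 1], pts[, 2])
  ensure_ccw(pts[idx, , drop = FALSE])
}

# rasterize a convex polygon into an nr x nc logical matrix; a pixel is
# foreground when its center lies inside or on the polygon
rasterize_convex_polygon <- function(poly, nr, nc, eps = 1e-9) {
  poly <- ensure_ccw(poly)
  n <- nrow(poly)
  xmin <- max(0L, floor(min(poly[, 1])))
  xmax <- min(nc - 1L, ceiling(max(poly[, 1])))
  ymin <- max(0L, floor(min(poly[, 2])))
  ymax <- min(nr - 1L, ceiling(max(poly[, 2])))
  out <- matrix(FALSE, nr, nc)
  if (xmax < xmin || ymax < ymin) return(out)
  xs <- xmin:xmax
  ys <- ymin:ymax
  px <- rep(xs, each = length(ys))
  py <- rep(ys, times = length(xs))
  inside <- rep(TRUE, length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cross <- (poly[j, 1] - poly[i, 1]) * (py - poly[i, 2]) -
             (poly[j, 2] - poly[i, 2]) * (px - poly[i, 1])
    inside <- inside & (cross >= -eps)
    if (!any(inside)) break
  }
  out[cbind(py + 1L, px + 1L)] <- inside
  out
}

# clip the line point + t * dir (unit dir) to a convex polygon; returns
# c(tmin, tmax). Uses the ordered half-plane representation.
clip_line_to_convex <- function(point, dir, poly) {
  poly <- ensure_ccw(poly)
  n <- nrow(poly)
  tmin <- -Inf; tmax <- Inf
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- poly[j, ] - poly[i, ]
    # inward normal of a CCW polygon edge
    nrm <- c(-e[2], e[1])
    denom <- sum(nrm * dir)
    num <- sum(nrm * (poly[i, ] - point))
    if (abs(denom) < 1e-12) {
      if (num > 0) return(c(NA_real_, NA_real_))  # line outside this half-plane
    } else {
      t0 <- num / denom
      if (denom > 0) tmin <- max(tmin, t0) else tmax <- min(tmax, t0)
    }
  }
  if (!is.finite(tmin) || !is.finite(tmax) || tmin > tmax)
    return(c(NA_real_, NA_real_))
  c(tmin, tmax)
}

# minimal Euclidean distance from a point to a closed polygon boundary
point_polygon_distance <- function(point, poly) {
  n <- nrow(poly)
  dmin <- Inf
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a <- poly[i, ]; b <- poly[j, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t0 <- if (len2 < 1e-12) 0 else max(0, min(1, sum((point - a) * ab) / len2))
    p <- a + t0 * ab
    dmin <- min(dmin, sqrt(sum((point - p)^2)))
  }
  dmin
}

# run code with a temporary RNG seed, restoring global RNG state afterwards
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
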