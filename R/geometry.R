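# Planar polygon and raster helpers shared by the phantom generator, the
# segmentation stack and the landmark logic.  Coordinate convention
# throughout the package: images are matrices indexed [row, col], a point
# is (x, y) = (col, row), pixel centers sit at integer coordinates, the
# origin is the top-left pixel and y increases downward.  All geometry is
# kept in floating point at sub-pixel precision.

#' Rasterize a closed polygon
#'
#' Scanline rasterization with the even-odd rule: a pixel is inside when
#' its center is inside the polygon.
#'
#' @param poly two-column matrix of (x, y) vertices of a closed polygon
#'   (last vertex implicitly joins the first).
#' @param nrow,ncol dimensions of the target raster.
#' @return logical matrix of the given dimensions.
#' @keywords internal
#' @noRd
raster_polygon <- function(poly, nrow, ncol) {
  x <- poly[, 1]; y <- poly[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  keep <- y != y2
  x1 <- x[keep]; y1 <- y[keep]; x2 <- x2[keep]; y2 <- y2[keep]
  mask <- matrix(FALSE, nrow, ncol)
  for (r in seq_len(nrow)) {
    cross <- (y1 <= r & y2 > r) | (y2 <= r & y1 > r)
    if (!any(cross)) next
    xc <- sort(x1[cross] + (r - y1[cross]) / (y2[cross] - y1[cross]) *
                 (x2[cross] - x1[cross]))
    for (k in seq(1, length(xc) - 1, by = 2)) {
      a <- max(1L, ceiling(xc[k])); b <- min(ncol, floor(xc[k + 1]))
      if (b >= a) mask[r, a:b] <- TRUE
    }
  }
  mask
}

# shoelace area (absolute)
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  abs(sum(x * y2 - x2 * y)) / 2
}

# area-weighted polygon centroid; degenerates to the vertex mean for
# (numerically) zero-area polygons
polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x + x2) * cr) / (6 * a), sum((y + y2) * cr) / (6 * a))
}

polygon_perimeter <- function(poly) {
  d <- diff(rbind(poly, poly[1, , drop = FALSE]))
  sum(sqrt(rowSums(d^2)))
}

# resample a closed polygon uniformly in arc length (step px, or exactly n
# points when n is given)
resample_closed <- function(poly, step = 1.5, n = NULL) {
  p <- rbind(poly, poly[1, , drop = FALSE])
  s <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
  total <- s[length(s)]
  if (is.null(n)) n <- max(16L, round(total / step))
  t0 <- seq(0, total, length.out = n + 1)[-(n + 1)]
  cbind(stats::approx(s, p[, 1], xout = t0)$y,
        stats::approx(s, p[, 2], xout = t0)$y)
}

# circular moving-average smoothing of a closed polygon
smooth_closed <- function(poly, window = 7) {
  if (window <= 1) return(poly)
  k <- rep(1 / window, window)
  cbind(as.numeric(stats::filter(poly[, 1], k, circular = TRUE)),
        as.numeric(stats::filter(poly[, 2], k, circular = TRUE)))
}

# signed curvature of a closed polygon sampled ~uniformly in arc length
closed_curvature <- function(poly) {
  n <- nrow(poly)
  ip <- c(n, seq_len(n - 1)); in_ <- c(seq_len(n - 1) + 1, 1)
  dx <- (poly[in_, 1] - poly[ip, 1]) / 2
  dy <- (poly[in_, 2] - poly[ip, 2]) / 2
  ddx <- poly[in_, 1] - 2 * poly[, 1] + poly[ip, 1]
  ddy <- poly[in_, 2] - 2 * poly[, 2] + poly[ip, 2]
  den <- (dx^2 + dy^2)^1.5
  den[den < 1e-12] <- 1e-12
  (dx * ddy - dy * ddx) / den
}

# orient a closed polygon so convex regions carry positive curvature
# (anchored at the bottom-most vertex, which is always convex)
orient_convex_positive <- function(poly) {
  i <- which.max(poly[, 2])
  if (closed_curvature(poly)[i] < 0)
    poly[rev(seq_len(nrow(poly))), , drop = FALSE] else poly
}

# offset every vertex along its outward normal (sub-pixel edge correction:
# traced boundaries run through pixel centers, half a pixel inside the
# physical intensity edge)
offset_outward <- function(poly, d = 0.5) {
  n <- nrow(poly)
  ip <- c(n, seq_len(n - 1)); in_ <- c(seq_len(n - 1) + 1, 1)
  tx <- poly[in_, 1] - poly[ip, 1]
  ty <- poly[in_, 2] - poly[ip, 2]
  len <- sqrt(tx^2 + ty^2); len[len < 1e-12] <- 1e-12
  nx <- ty / len; ny <- -tx / len
  cen <- polygon_centroid(poly)
  flip <- (poly[, 1] - cen[1]) * nx + (poly[, 2] - cen[2]) * ny < 0
  nx[flip] <- -nx[flip]; ny[flip] <- -ny[flip]
  cbind(poly[, 1] + d * nx, poly[, 2] + d * ny)
}

# intersection extent of an infinite line (point p, direction u) with a
# closed polygon: the two extreme crossings and their separation
line_polygon_chord <- function(poly, p, u) {
  u <- u / sqrt(sum(u^2))
  nrm <- c(-u[2], u[1])
  s <- (poly[, 1] - p[1]) * nrm[1] + (poly[, 2] - p[2]) * nrm[2]
  n <- nrow(poly)
  j <- c(seq_len(n - 1) + 1, 1)
  cross <- (s <= 0 & s[j] > 0) | (s[j] <= 0 & s > 0)
  if (!any(cross)) return(NULL)
  i <- which(cross)
  f <- s[i] / (s[i] - s[j][i])
  px <- poly[i, 1] + f * (poly[j, 1][i] - poly[i, 1])
  py <- poly[i, 2] + f * (poly[j, 2][i] - poly[i, 2])
  t <- (px - p[1]) * u[1] + (py - p[2]) * u[2]
  a <- which.min(t); b <- which.max(t)
  list(p1 = c(px[a], py[a]), p2 = c(px[b], py[b]), length = t[b] - t[a])
}

# principal axes of a point set (eigen decomposition of the covariance)
principal_axes <- function(poly) {
  cen <- colMeans(poly)
  cc <- sweep(poly, 2, cen)
  e <- eigen(crossprod(cc) / nrow(poly), symmetric = TRUE)
  list(center = cen, major = e$vectors[, 1], minor = e$vectors[, 2],
       values = e$values)
}

# integer pixels of the straight segment p -> q
bresenham <- function(p, q) {
  n <- max(abs(q[1] - p[1]), abs(q[2] - p[2]))
  if (n == 0) return(matrix(round(p), 1, 2))
  t <- seq(0, 1, length.out = n + 1)
  cbind(round(p[1] + t * (q[1] - p[1])), round(p[2] + t * (q[2] - p[2])))
}

# piecewise-linear upper convex hull of (x, y) evaluated at x0 (Andrew
# monotone chain); used to bridge inward break dents, since the bone
# border is locally the outermost convex envelope
upper_hull_eval <- function(x, y, x0) {
  o <- order(x, -y)
  x <- x[o]; y <- y[o]
  hx <- numeric(0); hy <- numeric(0)
  for (i in seq_along(x)) {
    while (length(hx) >= 2) {
      n <- length(hx)
      cr <- (hx[n] - hx[n - 1]) * (y[i] - hy[n - 1]) -
        (hy[n] - hy[n - 1]) * (x[i] - hx[n - 1])
      if (cr >= 0) { hx <- hx[-n]; hy <- hy[-n] } else break
    }
    hx <- c(hx, x[i]); hy <- c(hy, y[i])
  }
  if (length(hx) == 1) return(hy[1])
  stats::approx(hx, hy, xout = x0, rule = 2)$y
}

# 4-neighbour binary erosion/dilation (used for cortical rim construction)
erode4 <- function(mask, times = 1) {
  for (i in seq_len(times)) {
    nr <- nrow(mask); nc <- ncol(mask)
    mask <- mask &
      rbind(mask[-1, ], FALSE) & rbind(FALSE, mask[-nr, ]) &
      cbind(mask[, -1], FALSE) & cbind(FALSE, mask[, -nc])
  }
  mask
}

dilate4 <- function(mask, times = 1) {
  for (i in seq_len(times)) {
    nr <- nrow(mask); nc <- ncol(mask)
    mask <- mask |
      rbind(mask[-1, ], FALSE) | rbind(FALSE, mask[-nr, ]) |
      cbind(mask[, -1], FALSE) | cbind(FALSE, mask[, -nc])
  }
  mask
}
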