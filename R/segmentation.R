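# Silhouette segmentation: adaptive local thresholding, border-candidate
# filtering by topological potential, structural break reconstruction,
# contour tracing and quality-based contour classification.

#' Bone image container
#'
#' @param pixels numeric matrix of intensities (rows = image rows, y
#'   increases downward; intensities nominally in `[0, 1]`).
#' @param spacing physical pixel spacing in cm/pixel.
#' @param kind `"manubrium"`, `"corpus"` or `"unknown"`.
#' @param id identifier used in tables and logs.
#' @return object of class `bone_image`.
#' @export
bone_image <- function(pixels, spacing, kind = "unknown", id = "image") {
  pixels <- as.matrix(pixels)
  stopifnot(is.numeric(pixels), length(dim(pixels)) == 2L,
            all(is.finite(pixels)))
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("spacing must be a single positive number (cm/pixel)")
  kind <- match.arg(kind, c("manubrium", "corpus", "unknown"))
  structure(list(pixels = pixels, spacing = spacing, kind = kind, id = id),
            class = "bone_image")
}

as_pixel_matrix <- function(image) {
  if (inherits(image, "bone_image")) image$pixels else as.matrix(image)
}

#' @export
print.bone_image <- function(x, ...) {
  cat("<bone_image>", x$id, "-", x$kind, "\n ",
      nrow(x$pixels), "x", ncol(x$pixels), "px at", x$spacing, "cm/px\n")
  invisible(x)
}

#' Segmentation parameters
#'
#' Tunables of the segmentation phase, one field per pipeline stage.
#' Defaults were selected by the grid-training protocol on corrupted
#' phantoms (see [tune_parameters()]).
#'
#' @param window odd local-window size (px) of the adaptive threshold.
#' @param offset intensity offset above the local mean.
#' @param potential_sigma Gaussian kernel scale (px) of the border
#'   potential.
#' @param potential_threshold minimum potential for a border pixel to
#'   survive filtering.
#' @param min_chain minimum pixel count of a retained border chain.
#' @param max_gap maximum bridgeable gap between chain endpoints (px).
#' @param tangent_cos_min minimum cosine between endpoint tangents and
#'   the bridge direction.
#' @param min_area,max_area accepted contour area bounds (px^2).
#' @param min_intensity minimum mean interior intensity.
#' @param min_contrast minimum interior-minus-surround intensity
#'   contrast (bone is brighter than its background).
#' @param max_elongation maximum major/minor axis ratio.
#' @param min_solidity minimum area / convex-hull-area ratio.
#' @return object of class `segmentation_params`.
#' @export
segmentation_params <- function(window = 31L, offset = 0.07,
                                potential_sigma = 2.5,
                                potential_threshold = 3,
                                min_chain = 8L, max_gap = 24,
                                tangent_cos_min = 0.5,
                                min_area = 1500, max_area = Inf,
                                min_intensity = 0.35, min_contrast = 0.15,
                                max_elongation = 6, min_solidity = 0.75) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("window must be odd and >= 3")
  if (max_gap < 0) stop("max_gap must be >= 0")
  if (min_area > max_area) stop("min_area must not exceed max_area")
  structure(as.list(environment()), class = "segmentation_params")
}

# local mean over a window x window box clipped at the image edges,
# computed with an integral image
local_mean <- function(pix, window) {
  k <- (window - 1L) %/% 2L
  nr <- nrow(pix); nc <- ncol(pix)
  S <- matrix(0, nr + 1, nc + 1)
  S[-1, -1] <- t(apply(apply(pix, 2, cumsum), 1, cumsum))
  r1 <- pmax(seq_len(nr) - k, 1); r2 <- pmin(seq_len(nr) + k, nr)
  c1 <- pmax(seq_len(nc) - k, 1); c2 <- pmin(seq_len(nc) + k, nc)
  A <- S[r2 + 1, c2 + 1] - S[r1, c2 + 1] - S[r2 + 1, c1] + S[r1, c1]
  A / outer(r2 - r1 + 1, c2 - c1 + 1)
}

#' Adaptive threshold on local areas
#'
#' A pixel is foreground iff its intensity exceeds the mean of its local
#' window by more than `offset`.  Windows are clipped at the image edges.
#'
#' @param image [bone_image()] or numeric matrix.
#' @param params [segmentation_params()].
#' @return logical foreground mask of the same dimensions.
#' @export
adaptive_threshold <- function(image, params = segmentation_params()) {
  pix <- as_pixel_matrix(image)
  if (params$window > min(dim(pix)))
    stop("threshold window (", params$window,
         ") larger than the image (", paste(dim(pix), collapse = " x "), ")")
  pix > local_mean(pix, params$window) + params$offset
}

shift_mat <- function(m, dr, dc, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

# border pixels: foreground with at least one 4-neighbour background
border_pixels <- function(mask) {
  mask & !(shift_mat(mask, 1, 0) & shift_mat(mask, -1, 0) &
             shift_mat(mask, 0, 1) & shift_mat(mask, 0, -1))
}

# banded Toeplitz matrix of a (max-normalized) Gaussian kernel; the
# separable product K_r %*% X %*% K_c is the kernel-weighted count of
# neighbouring border pixels
gaussian_band <- function(n, sigma) {
  h <- ceiling(3 * sigma)
  g <- stats::dnorm(-h:h, sd = sigma); g <- g / max(g)
  K <- matrix(0, n, n)
  for (d in -h:h) {
    idx <- seq_len(max(n - abs(d), 0))
    if (length(idx) == 0) next
    if (d >= 0) K[cbind(idx + d, idx)] <- g[d + h + 1]
    else K[cbind(idx, idx - d)] <- g[-d + h + 1]
  }
  K
}

border_potential <- function(bmask, sigma) {
  gaussian_band(nrow(bmask), sigma) %*% (bmask * 1) %*%
    gaussian_band(ncol(bmask), sigma)
}

# 8-connected components of a pixel set (pix = cbind(row, col)) via
# union-find on neighbour matches
label8 <- function(pix, nr) {
  id <- pix[, 1] + (pix[, 2] - 1) * nr
  o <- order(id); id <- id[o]; pix <- pix[o, , drop = FALSE]
  n <- nrow(pix)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  for (off in list(c(1, 0), c(0, 1), c(1, 1), c(-1, 1))) {
    j <- match((pix[, 1] + off[1]) + (pix[, 2] + off[2] - 1) * nr, id)
    for (a in which(!is.na(j))) {
      ra <- find(a); rb <- find(j[a])
      if (ra != rb) parent[ra] <- rb
    }
  }
  root <- vapply(seq_len(n), find, 1L)
  list(pix = pix, comp = match(root, unique(root)))
}

#' Filter border candidates by topological potential
#'
#' Border pixels of the mask are scored with a Gaussian-kernel-weighted
#' count of nearby border pixels ("topological potential"); pixels whose
#' potential falls below the acceptance threshold -- isolated speckles and
#' frayed fragments -- are removed, and the survivors are grouped into
#' 8-connected chains.
#'
#' @param mask logical mask from [adaptive_threshold()].
#' @param params [segmentation_params()].
#' @return list of chains, each a 2-column matrix of (row, col) pixels;
#'   empty list for an empty mask.
#' @export
filter_border_candidates <- function(mask, params = segmentation_params()) {
  bp <- border_pixels(mask)
  if (!any(bp)) return(list())
  pot <- border_potential(bp, params$potential_sigma)
  keep <- bp & (pot >= params$potential_threshold)
  if (!any(keep)) return(list())
  lab <- label8(which(keep, arr.ind = TRUE), nrow(mask))
  chains <- lapply(split(seq_len(nrow(lab$pix)), lab$comp),
                   function(ix) lab$pix[ix, , drop = FALSE])
  unname(chains[vapply(chains, nrow, 1L) >= params$min_chain])
}

# a chain is closed when its pixels enclose an interior
chain_is_closed <- function(chain) {
  m <- matrix(FALSE, max(chain[, 1]) + 1, max(chain[, 2]) + 1)
  m[chain] <- TRUE
  sum(EBImage::fillHull(m * 1) > 0) > sum(m)
}

# true path ends of an open chain by graph diameter (double BFS on the
# 8-neighbour graph): robust to pixel-thick clumps and frayed offshoots
chain_tips <- function(chain) {
  n <- nrow(chain)
  if (n <= 2) return(seq_len(n))
  base <- max(chain[, 1]) + 2
  id <- chain[, 1] + (chain[, 2] - 1) * base
  edges <- NULL
  for (off in list(c(1, 0), c(0, 1), c(1, 1), c(-1, 1))) {
    j <- match((chain[, 1] + off[1]) + (chain[, 2] + off[2] - 1) * base, id)
    ok <- !is.na(j)
    if (any(ok)) edges <- rbind(edges, cbind(which(ok), j[ok]))
  }
  if (is.null(edges)) return(c(1L, n))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  far <- function(from) {
    d <- igraph::distances(g, v = from)[1, ]
    which.max(ifelse(is.finite(d), d, -1))
  }
  e1 <- far(1L)
  e2 <- far(e1)
  unique(c(e1, e2))
}

# outward tangent at an endpoint: direction from the centroid of the
# nearest chain pixels toward the endpoint
endpoint_tangent <- function(chain, i, k = 6) {
  p <- chain[i, ]
  d2 <- (chain[, 1] - p[1])^2 + (chain[, 2] - p[2])^2
  q <- colMeans(chain[order(d2)[seq_len(min(k + 1, nrow(chain)))], ,
                      drop = FALSE])
  v <- p - q
  n <- sqrt(sum(v^2))
  if (n < 1e-9) c(1, 0) else v / n
}

#' Reconstruct breaks along borders
#'
#' Bridges pairs of chain endpoints that lie within the maximum gap and
#' whose tangent directions are compatible with the bridge (outward
#' tangent cosine at both ends at least `tangent_cos_min`).  Bridging is
#' greedy nearest-pair-first and no endpoint is used twice; bridged chains
#' are merged and the straight bridge pixels added.  Closed chains carry
#' no endpoints; the endpoints of an open chain are its two
#' graph-diameter extremes, which is robust to pixel-thick tips and to
#' frayed noise offshoots.
#'
#' @param chains list of border chains from [filter_border_candidates()].
#' @param params [segmentation_params()].
#' @return list of merged chains.
#' @export
connect_breaks <- function(chains, params = segmentation_params()) {
  if (length(chains) == 0) return(chains)
  reps <- seq_along(chains)
  findc <- function(i) { while (reps[i] != i) i <- reps[i]; i }
  eps <- list()
  for (ci in seq_along(chains)) {
    if (chain_is_closed(chains[[ci]])) next
    for (i in chain_tips(chains[[ci]]))
      eps[[length(eps) + 1]] <- list(chain = ci, p = chains[[ci]][i, ],
                                     t = endpoint_tangent(chains[[ci]], i))
  }
  if (length(eps) < 2) return(chains)
  cand <- NULL
  for (a in seq_len(length(eps) - 1)) for (b in (a + 1):length(eps)) {
    g <- sqrt(sum((eps[[a]]$p - eps[[b]]$p)^2))
    if (g == 0 || g > params$max_gap) next
    u <- (eps[[b]]$p - eps[[a]]$p) / g
    if (sum(eps[[a]]$t * u) < params$tangent_cos_min) next
    if (sum(eps[[b]]$t * -u) < params$tangent_cos_min) next
    cand <- rbind(cand, c(a, b, g))
  }
  bridges <- list()
  if (!is.null(cand)) {
    cand <- cand[order(cand[, 3]), , drop = FALSE]
    used <- logical(length(eps))
    for (k in seq_len(nrow(cand))) {
      a <- cand[k, 1]; b <- cand[k, 2]
      if (used[a] || used[b]) next
      used[a] <- used[b] <- TRUE
      bridges[[length(bridges) + 1]] <-
        list(chain = eps[[a]]$chain,
             seg = bresenham(eps[[a]]$p, eps[[b]]$p))
      ra <- findc(eps[[a]]$chain); rb <- findc(eps[[b]]$chain)
      if (ra != rb) reps[ra] <- rb
    }
  }
  groups <- vapply(seq_along(chains), findc, 1L)
  out <- list()
  for (g in unique(groups)) {
    m <- do.call(rbind, chains[groups == g])
    for (br in bridges) if (findc(br$chain) == g) m <- rbind(m, br$seg)
    out[[length(out) + 1]] <- unique(m)
  }
  out
}

#' Trace closed chains into contours
#'
#' Each chain whose pixels enclose an interior becomes a closed contour
#' polygon with quality features: shoelace area, area-weighted centroid,
#' perimeter, mean interior intensity, elongation (major/minor axis
#' ratio) and solidity (area / convex hull area).  Open chains are
#' discarded; their count is reported in the `dropped_open` attribute.
#'
#' @param chains list of (bridged) chains.
#' @param image the source [bone_image()] (for interior intensity).
#' @return list of `bone_contour` objects.
#' @export
trace_contours <- function(chains, image) {
  pix <- as_pixel_matrix(image)
  nr <- nrow(pix); nc <- ncol(pix)
  out <- list(); dropped <- 0L
  for (ch in chains) {
    m <- matrix(FALSE, nr, nc)
    ok <- ch[, 1] >= 1 & ch[, 1] <= nr & ch[, 2] >= 1 & ch[, 2] <= nc
    m[ch[ok, , drop = FALSE]] <- TRUE
    filled <- EBImage::fillHull(m * 1) > 0
    interior <- filled & !m
    if (sum(interior) < 4) { dropped <- dropped + 1L; next }
    surround <- dilate4(filled, 4) & !filled
    oc <- EBImage::ocontour(filled * 1)[[1]]
    poly <- cbind(oc[, 2] + 1, oc[, 1] + 1)     # 0-based (row, col) -> (x, y)
    if (nrow(poly) < 8) { dropped <- dropped + 1L; next }
    area <- polygon_area(poly)
    if (area <= 0) { dropped <- dropped + 1L; next }
    ax <- principal_axes(poly)
    hull <- poly[grDevices::chull(poly[, 1], poly[, 2]), , drop = FALSE]
    out[[length(out) + 1]] <- structure(list(
      poly = poly, centroid = polygon_centroid(poly), area = area,
      perimeter = polygon_perimeter(poly),
      mean_intensity = mean(pix[interior]),
      contrast = mean(pix[interior]) -
        (if (any(surround)) mean(pix[surround]) else 0),
      elongation = sqrt(max(ax$values) / max(min(ax$values), 1e-9)),
      solidity = area / polygon_area(hull),
      accepted = NA), class = "bone_contour")
  }
  attr(out, "dropped_open") <- dropped
  out
}

#' Classify contours by bone-likeness
#'
#' A contour is accepted iff every quality feature lies within the
#' configured bounds; the `accepted` flag is set on all inputs and the
#' input ordering is preserved.
#'
#' @param contours list of `bone_contour` from [trace_contours()].
#' @param params [segmentation_params()].
#' @return the contours with `accepted` flags set.
#' @export
classify_contours <- function(contours, params = segmentation_params()) {
  for (i in seq_along(contours)) {
    ct <- contours[[i]]
    contours[[i]]$accepted <-
      ct$area >= params$min_area && ct$area <= params$max_area &&
      ct$mean_intensity >= params$min_intensity &&
      ct$contrast >= params$min_contrast &&
      ct$elongation <= params$max_elongation &&
      ct$solidity >= params$min_solidity
  }
  contours
}

# Closing rescue for borders whose breaks leave no traceable path ends
# (a break detour can form a closed network that still leaks through
# pin-hole gaps): morphological closing of the chain pixels seals small
# leaks, and the borders of the sealed regions are re-traced.
close_and_retrace <- function(chains, image, radius = 3, min_size = 64L) {
  pix <- as_pixel_matrix(image)
  # only substantial chains can seed the rescue: scattered speckle
  # fragments must not be sealed into fake silhouettes
  chains <- chains[vapply(chains, nrow, 1L) >= min_size]
  if (length(chains) == 0) return(list())
  m <- matrix(FALSE, nrow(pix), ncol(pix))
  for (ch in chains) {
    ok <- ch[, 1] >= 1 & ch[, 1] <= nrow(pix) &
      ch[, 2] >= 1 & ch[, 2] <= ncol(pix)
    m[ch[ok, , drop = FALSE]] <- TRUE
  }
  closed <- erode4(EBImage::fillHull(dilate4(m, radius) * 1) > 0, radius)
  if (!any(closed)) return(list())
  bp <- border_pixels(closed)
  lab <- label8(which(bp, arr.ind = TRUE), nrow(pix))
  rescue <- lapply(split(seq_len(nrow(lab$pix)), lab$comp),
                   function(ix) lab$pix[ix, , drop = FALSE])
  trace_contours(unname(rescue), image)
}

#' Segment the bone silhouette of an image
#'
#' Composes the four segmentation stages (threshold, border filtering,
#' break reconstruction, contour tracing) and the contour classifier.
#' When no contour survives -- typically when a border break leaves a
#' closed but leaking chain network with no endpoints to bridge -- a
#' morphological-closing rescue pass seals small leaks and re-traces.
#' When several contours are accepted the largest-area one is returned;
#' exact area ties are broken by higher mean interior intensity, then by
#' the smaller centroid row.
#'
#' @param image a [bone_image()].
#' @param params [segmentation_params()].
#' @return a single accepted `bone_contour` (with centroid).
#' @export
segment_bone <- function(image, params = segmentation_params()) {
  mask <- adaptive_threshold(image, params)
  chains <- filter_border_candidates(mask, params)
  if (length(chains) == 0)
    stop("segmentation failed: no border candidates survive ",
         "potential filtering (last non-empty stage: adaptive threshold)")
  chains <- connect_breaks(chains, params)
  contours <- trace_contours(chains, image)
  if (length(contours) > 0)
    contours <- classify_contours(contours, params)
  acc <- contours[vapply(contours, function(ct) isTRUE(ct$accepted), TRUE)]
  if (length(acc) == 0) {
    contours <- classify_contours(close_and_retrace(chains, image), params)
    acc <- contours[vapply(contours, function(ct) isTRUE(ct$accepted),
                           TRUE)]
  }
  if (length(acc) == 0)
    stop("segmentation failed: all ",
         max(length(contours), length(chains)),
         " contour candidates rejected ",
         "(last non-empty stage: break reconstruction)")
  o <- order(-vapply(acc, function(ct) ct$area, 1),
             -vapply(acc, function(ct) ct$mean_intensity, 1),
             vapply(acc, function(ct) ct$centroid[2], 1))
  acc[[o[1]]]
}

#' @export
print.bone_contour <- function(x, ...) {
  cat(sprintf(paste0("<bone_contour> %d points, area %.0f px^2, ",
                     "centroid (%.1f, %.1f), accepted: %s\n"),
              nrow(x$poly), x$area, x$centroid[1], x$centroid[2],
              ifelse(is.na(x$accepted), "untested", x$accepted)))
  invisible(x)
}
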