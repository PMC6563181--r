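# Landmark detection on accepted contours and computation of the five
# standard sternal measurements, the three indices, and the
# parameter-training loop.

#' Landmark-detection control parameters
#'
#' @param resample_step arc-length resampling step of the contour (px).
#' @param smooth_geom,smooth_curv moving-average windows (samples) for the
#'   geometry polygon and the curvature polygon.
#' @param edge_offset outward sub-pixel edge correction (px); traced
#'   boundaries run through pixel centers, half a pixel inside the
#'   intensity edge.
#' @param kappa_thresh curvature threshold below which a local minimum
#'   counts as a notch (1/px, negative = concave).
#' @param corpus_notch_frac expected positions of costal notches 2-5 along
#'   the corpus axis (fractions of the length); used to label detected
#'   notch pairs and as fallback levels when a notch is obliterated.
#' @param manubrium_ic1_frac expected position of the first costal notch
#'   along the manubrium axis.
#' @param pair_tol maximum left/right axial mismatch for notch pairing
#'   (fraction of the bone length).
#' @param assign_tol maximum distance between a notch pair and its
#'   expected position for slot assignment (fraction).
#' @param confidence_floor configurations below this confidence are
#'   flagged (not fatal).
#' @return list of control parameters.
#' @export
landmark_control <- function(resample_step = 1.25, smooth_geom = 3,
                             smooth_curv = 9, edge_offset = 0.5,
                             kappa_thresh = -0.025,
                             corpus_notch_frac = c(0.18, 0.42, 0.66, 0.90),
                             manubrium_ic1_frac = 0.76,
                             pair_tol = 0.07, assign_tol = 0.10,
                             confidence_floor = 0.2) {
  as.list(environment())
}

# local minima of curvature below a threshold, one representative per
# contiguous run (runs separated by more than min_sep samples)
curvature_notches <- function(kappa, thresh, min_sep = 6) {
  cand <- which(kappa < thresh)
  if (length(cand) == 0) return(integer(0))
  gaps <- diff(cand)
  groups <- split(cand, cumsum(c(0, gaps > min_sep)))
  n <- length(kappa)
  if (length(groups) > 1) {        # merge the wrap-around run
    g1 <- groups[[1]]; gl <- groups[[length(groups)]]
    if ((n - max(gl)) + min(g1) <= min_sep) {
      groups[[1]] <- c(gl, g1)
      groups[[length(groups)]] <- NULL
    }
  }
  unname(vapply(groups, function(g) g[which.min(kappa[g])], 1L))
}

# Anatomical frame of a bone contour.  The corpus sterni is elongated
# along the cranio-caudal axis (principal major axis); the manubrium is
# broader than long (cranio-caudal axis = principal minor axis).  Both
# bones are wider superiorly, which orients u superior -> inferior.
bone_frame <- function(poly, kind) {
  ax <- principal_axes(poly)
  cc <- sweep(poly, 2, ax$center)
  if (kind == "corpus") { a_u <- ax$major; a_v <- ax$minor }
  else { a_u <- ax$minor; a_v <- ax$major }
  u <- as.vector(cc %*% a_u); v <- as.vector(cc %*% a_v)
  ext <- diff(range(u))
  band <- if (kind == "corpus") 0.08 else 0.15
  wlo <- diff(range(v[u < min(u) + band * ext]))
  whi <- diff(range(v[u > max(u) - band * ext]))
  if (whi > wlo) { a_u <- -a_u; u <- -u }
  list(center = ax$center, a_u = a_u, a_v = a_v, u = u, v = v)
}

#' Locate measurement landmarks on an accepted contour
#'
#' The contour is resampled to uniform arc length, smoothed, and split
#' into superior/inferior/left/right sections by its anatomical principal
#' frame.  Notches are found as local curvature extrema within their
#' sections; measurement endpoints follow the standard definitions:
#' `M` from the superior border midpoint between the jugular and
#' clavicular notches to the manubriosternal junction, `MW` as the width
#' along the line through the first costal notches, `B` between the
#' manubriosternal and mesoxiphoid junctions (the extreme end midpoints
#' of the corpus), and `CSW1`/`CSW2` as the widths at the levels midway
#' between costal notches 2/3 and 4/5.  Width lines are clipped to the
#' contour; end caps and width chords are measured with inward-dent
#' rejection (outer convex envelope) so border-break artifacts do not
#' bite into the measurements.
#'
#' @param contour an accepted `bone_contour` from [segment_bone()].
#' @param kind `"corpus"` or `"manubrium"` (taken from the contour's
#'   image when available).
#' @param control [landmark_control()] parameters.
#' @return object of class `landmark_configuration`: `kind` plus a named
#'   list `landmarks`, one entry per measurement with sub-pixel `p1`,
#'   `p2`, a `confidence` in `[0, 1]` and possible lower-confidence
#'   `alternates`.
#' @export
find_landmarks <- function(contour, kind = c("corpus", "manubrium"),
                           control = landmark_control()) {
  kind <- match.arg(kind)
  ctl <- control
  poly0 <- orient_convex_positive(
    resample_closed(contour$poly, ctl$resample_step))
  poly0 <- offset_outward(poly0, ctl$edge_offset)
  geom <- smooth_closed(poly0, ctl$smooth_geom)
  pc <- smooth_closed(poly0, ctl$smooth_curv)
  kappa <- closed_curvature(smooth_closed(pc, ctl$smooth_curv))
  fr <- bone_frame(geom, kind)
  u <- fr$u; v <- fr$v
  ulo <- min(u); urange <- diff(range(u))
  uf <- (u - ulo) / urange
  from_frame <- function(uu, vv) fr$center + uu * fr$a_u + vv * fr$a_v

  # Apex of an end cap.  The transverse midline is the midpoint of the
  # full-width chord 10 px inside the extreme (insensitive to cap dents);
  # the axial position is the outer convex hull of the cap evaluated at
  # that midline, which bridges inward break dents.
  extreme_point <- function(top, vhalf = 12, depth = 8) {
    sgn <- if (top) -1 else 1
    ue <- if (top) min(u) else max(u)
    ch <- line_polygon_chord(geom, from_frame(ue - sgn * 10, 0), fr$a_v)
    vstar <- if (is.null(ch))
      stats::median(v[sgn * (ue - u) <= 3])
    else
      (sum((ch$p1 - fr$center) * fr$a_v) +
         sum((ch$p2 - fr$center) * fr$a_v)) / 2
    band <- which(sgn * (ue - u) <= depth & abs(v - vstar) <= vhalf)
    if (length(band) < 4) return(from_frame(ue, vstar))
    from_frame(sgn * upper_hull_eval(v[band], sgn * u[band], vstar), vstar)
  }
  # plain extreme-band midpoint (low-confidence alternate)
  extreme_simple <- function(top) {
    band <- if (top) which(u <= min(u) + 1.5) else which(u >= max(u) - 1.5)
    from_frame(if (top) min(u) else max(u), mean(v[band]))
  }
  notch_ids <- curvature_notches(kappa, ctl$kappa_thresh)
  conf_of <- function(ids) pmin(1, -kappa[ids] / 0.08)

  # Robust bone midline: straight-line fit of full-width chord midpoints
  # along the axis, trimming levels distorted by notches or artifacts.
  # More reliable than the principal-frame origin, which a deep one-sided
  # artifact can shift.
  bone_midline <- function() {
    pts <- NULL
    for (f in seq(0.08, 0.92, by = 0.06)) {
      uu <- ulo + f * urange
      chn <- line_polygon_chord(geom, from_frame(uu, 0), fr$a_v)
      if (is.null(chn)) next
      pts <- rbind(pts, c(uu, (sum((chn$p1 - fr$center) * fr$a_v) +
                                 sum((chn$p2 - fr$center) * fr$a_v)) / 2))
    }
    if (is.null(pts) || nrow(pts) < 4) return(function(x) 0)
    fit <- NULL
    for (it in 1:3) {
      fit <- stats::lm.fit(cbind(1, pts[, 1]), pts[, 2])
      keep <- abs(fit$residuals) <= 1.2
      if (all(keep) || sum(keep) < 5) break
      pts <- pts[keep, , drop = FALSE]
    }
    b <- fit$coefficients
    function(x) b[1] + b[2] * x
  }
  midline <- NULL

  # Outer width at an axial level: exact line-polygon chord, stepped over
  # local inward dents (border-break artifacts) by falling back to the
  # outermost border position in a +-6 px band, and to a +-18 px window
  # when the dent swallows the whole band.  A dent can swallow even the
  # wide window on a short corpus; since the sternum is bilaterally
  # symmetric, a strongly one-sided residual (sides differing by more
  # than `sym_tol` relative to the fitted midline) is resolved by
  # mirroring the intact side.
  width_line <- function(ufrac, hb1 = 6, hb2 = 18,
                         dent_tol1 = 1.5, dent_tol2 = 2.5, sym_tol = 3.5) {
    lu <- ulo + ufrac * urange
    ch <- line_polygon_chord(geom, from_frame(lu, 0), fr$a_v)
    if (is.null(ch)) return(NULL)
    side_est <- function(sgn) {
      cc <- sgn * sum(((if (sgn < 0) ch$p1 else ch$p2) - fr$center) * fr$a_v)
      b1 <- sgn * v[abs(u - lu) <= hb1 & sgn * v > 0]
      b2 <- sgn * v[abs(u - lu) <= hb2 & sgn * v > 0]
      if (length(b1) == 0 || length(b2) == 0) return(NA_real_)
      est <- cc
      if (max(b1) - est > dent_tol1) est <- max(b1)
      if (max(b2) - est > dent_tol2) est <- max(b2)
      sgn * est
    }
    lo <- side_est(-1); hi <- side_est(1)
    if (is.na(lo) || is.na(hi)) return(NULL)
    if (is.null(midline)) midline <<- bone_midline()
    mid <- midline(lu)
    a <- hi - mid; b <- mid - lo
    if (abs(a - b) > sym_tol) {
      m <- max(a, b)
      lo <- mid - m; hi <- mid + m
    }
    list(p1 = from_frame(lu, lo), p2 = from_frame(lu, hi))
  }
  lmk <- function(pts, confidence, alternates = NULL) {
    stopifnot(!is.null(pts))
    out <- list(p1 = pts$p1, p2 = pts$p2, confidence = confidence)
    out$alternates <- alternates
    out
  }

  # one-to-one nearest-first assignment of notch pairs to the expected
  # slots; returns the slot vector and the mean matching cost (unmatched
  # slots cost the assignment tolerance)
  assign_slots <- function(pos) {
    slots <- rep(NA_integer_, 4)
    if (length(pos) > 0) {
      d <- abs(outer(pos, ctl$corpus_notch_frac, "-"))
      repeat {
        if (all(is.na(d)) || min(d, na.rm = TRUE) > ctl$assign_tol) break
        ij <- which(d == min(d, na.rm = TRUE), arr.ind = TRUE)[1, ]
        slots[ij[2]] <- ij[1]
        d[ij[1], ] <- NA; d[, ij[2]] <- NA
      }
    }
    costs <- rep(ctl$assign_tol, 4)
    for (s in which(!is.na(slots)))
      costs[s] <- abs(pos[slots[s]] - ctl$corpus_notch_frac[s])
    list(slots = slots, cost = mean(costs))
  }

  if (kind == "corpus") {
    lat <- notch_ids[uf[notch_ids] > 0.03 & uf[notch_ids] < 0.97]
    left <- lat[v[lat] < 0]; right <- lat[v[lat] > 0]
    pairs <- NULL
    for (l in left) {
      if (length(right) == 0) break
      r <- right[which.min(abs(uf[right] - uf[l]))]
      if (abs(uf[r] - uf[l]) < ctl$pair_tol)
        pairs <- rbind(pairs, c(uf = (uf[l] + uf[r]) / 2,
                                conf = mean(conf_of(c(l, r)))))
    }
    # the end-width orientation cue can fail on strongly flaring bones;
    # the costal notches 2-5 are spaced asymmetrically along the axis,
    # so prefer the orientation whose notch layout matches the expected
    # positions better
    asg <- assign_slots(if (is.null(pairs)) numeric(0) else pairs[, 1])
    if (!is.null(pairs) && nrow(pairs) >= 2) {
      asg_flip <- assign_slots(1 - pairs[, 1])
      if (asg_flip$cost < asg$cost - 0.01) {
        fr$a_u <- -fr$a_u
        u <- -u; ulo <- min(u); uf <- 1 - uf
        pairs[, 1] <- 1 - pairs[, 1]
        asg <- asg_flip
      }
    }
    slots <- asg$slots
    level <- function(s1, s2) {
      us <- c(if (!is.na(slots[s1])) pairs[slots[s1], 1] else
        ctl$corpus_notch_frac[s1],
        if (!is.na(slots[s2])) pairs[slots[s2], 1] else
          ctl$corpus_notch_frac[s2])
      mean(us)
    }
    conf_lv <- function(s1, s2) {
      cs <- c(if (!is.na(slots[s1])) pairs[slots[s1], 2] else 0,
              if (!is.na(slots[s2])) pairs[slots[s2], 2] else 0)
      mean(cs)
    }
    if (all(is.na(slots)))
      warning("no costal notch pairs found on the corpus contour; ",
              "width levels fall back to their expected positions ",
              "(CSW1, CSW2 flagged with confidence 0)")
    w1 <- width_line(level(1, 2)); w2 <- width_line(level(3, 4))
    w1p <- width_line(mean(ctl$corpus_notch_frac[1:2]))
    w2p <- width_line(mean(ctl$corpus_notch_frac[3:4]))
    if (is.null(w1) || is.null(w2))
      stop("landmarks not found: width section line does not intersect ",
           "the contour (missing: ",
           paste(c("CSW1", "CSW2")[c(is.null(w1), is.null(w2))],
                 collapse = ", "), ")")
    cfg <- list(
      B = lmk(list(p1 = extreme_point(TRUE), p2 = extreme_point(FALSE)), 0.9,
              alternates = list(lmk(list(p1 = extreme_simple(TRUE),
                                         p2 = extreme_simple(FALSE)), 0.3))),
      CSW1 = lmk(w1, conf_lv(1, 2),
                 alternates = if (!is.null(w1p)) list(lmk(w1p, 0.25))),
      CSW2 = lmk(w2, conf_lv(3, 4),
                 alternates = if (!is.null(w2p)) list(lmk(w2p, 0.25))))
  } else {
    sup_ids <- notch_ids[uf[notch_ids] < 0.22]
    if (length(sup_ids) < 2)
      stop("landmarks not found on the manubrium contour (missing: ",
           "incisura jugularis, incisura clavicularis)")
    jug <- sup_ids[which.min(abs(v[sup_ids]))]
    side <- sup_ids[abs(v[sup_ids]) > abs(v[jug]) + 2]
    if (length(side) == 0)
      stop("landmarks not found on the manubrium contour (missing: ",
           "incisura clavicularis)")
    clav <- side[which.max(abs(v[side]))]
    vm <- (v[jug] + v[clav]) / 2
    supband <- which(uf < 0.2 & abs(v - vm) <= 10)
    if (length(supband) == 0)
      stop("landmarks not found: superior border not resolved near the ",
           "M start point")
    p_start <- from_frame(-upper_hull_eval(v[supband], -u[supband], vm), vm)
    inf <- extreme_point(FALSE)
    # first costal notches: best-matching lateral pair
    lat_ids <- notch_ids[uf[notch_ids] >= 0.35 & uf[notch_ids] <= 0.95]
    left <- lat_ids[v[lat_ids] < 0]; right <- lat_ids[v[lat_ids] > 0]
    pl <- pr <- NULL; best <- Inf
    for (l in left) for (r in right) {
      dd <- abs(uf[l] - uf[r])
      if (dd < best && dd < ctl$pair_tol) { best <- dd; pl <- l; pr <- r }
    }
    if (is.null(pl)) {
      one <- c(left, right)
      if (length(one) == 0)
        stop("landmarks not found on the manubrium contour (missing: ",
             "incisura costalis 1)")
      one <- one[which.min(abs(uf[one] - ctl$manubrium_ic1_frac))]
      wch <- line_polygon_chord(
        geom, from_frame(ulo + uf[one] * urange, 0), fr$a_v)
      conf_w <- 0.4
    } else {
      # the defining section line runs through the two notch midpoints,
      # which self-corrects any residual frame tilt
      wch <- line_polygon_chord(geom, geom[pl, ], geom[pr, ] - geom[pl, ])
      conf_w <- mean(conf_of(c(pl, pr)))
    }
    wprior <- line_polygon_chord(
      geom, from_frame(ulo + ctl$manubrium_ic1_frac * urange, 0), fr$a_v)
    if (is.null(wch))
      stop("landmarks not found: MW section line does not intersect the ",
           "contour")
    cfg <- list(
      M = lmk(list(p1 = p_start, p2 = inf), mean(conf_of(c(jug, clav)))),
      MW = lmk(wch, conf_w,
               alternates = if (!is.null(wprior)) list(lmk(wprior, 0.25))))
  }
  flagged <- names(cfg)[vapply(cfg, function(l)
    l$confidence < ctl$confidence_floor, TRUE)]
  structure(list(kind = kind, landmarks = cfg, flagged = flagged),
            class = "landmark_configuration")
}

#' Reduce candidate lengths by single-linkage clustering
#'
#' One-dimensional single-linkage clustering with a gap threshold
#' (default 5 percent of the median candidate length): candidates whose
#' neighbouring gap exceeds the threshold start a new cluster.  Within
#' each cluster the highest-confidence candidate wins; the final choice
#' is the winner of the most populous cluster, with population ties
#' resolved toward the higher-confidence winner.
#'
#' @param lengths numeric vector of candidate lengths.
#' @param confidence numeric vector of confidences in `[0, 1]` (defaults
#'   to all equal).
#' @param gap absolute gap threshold; default `0.05 * median(lengths)`.
#' @return list with `value` (chosen length), `index` (its position in
#'   the input), `cluster` (integer cluster id per candidate, in input
#'   order) and `winners` (per-cluster winning indices).
#' @export
cluster_candidates <- function(lengths, confidence = NULL, gap = NULL) {
  n <- length(lengths)
  if (n == 0) stop("no candidates to cluster")
  if (is.null(confidence)) confidence <- rep(1, n)
  stopifnot(length(confidence) == n)
  if (is.null(gap)) gap <- 0.05 * stats::median(lengths)
  o <- order(lengths)
  cl_sorted <- cumsum(c(1, diff(lengths[o]) > gap))
  cluster <- integer(n)
  cluster[o] <- cl_sorted
  winners <- vapply(seq_len(max(cluster)), function(k) {
    ix <- which(cluster == k)
    ix[order(-confidence[ix], ix)[1]]
  }, 1L)
  sizes <- tabulate(cluster)
  best_k <- order(-sizes, -confidence[winners])[1]
  idx <- winners[best_k]
  list(value = lengths[idx], index = idx, cluster = cluster,
       winners = winners)
}

#' Measure a bone from its landmark configuration
#'
#' Each measurement is the Euclidean distance between its landmark pair
#' multiplied by the pixel spacing.  When a landmark carries alternate
#' (lower-confidence) candidates, the candidate lengths are reduced with
#' [cluster_candidates()] before reporting.
#'
#' @param landmarks a `landmark_configuration` from [find_landmarks()].
#' @param spacing pixel spacing in cm/pixel.
#' @param subject_id,source bookkeeping columns of the output record.
#' @return one-row data frame with columns `subject_id`, `source`, `M`,
#'   `MW`, `B`, `CSW1`, `CSW2` (cm; `NA` for measurements not defined on
#'   this bone).
#' @export
measure_bone <- function(landmarks, spacing, subject_id = "subject",
                         source = "automatic") {
  stopifnot(inherits(landmarks, "landmark_configuration"))
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("spacing must be a single positive number (cm/pixel)")
  dist_cm <- function(l) sqrt(sum((l$p1 - l$p2)^2)) * spacing
  vals <- stats::setNames(rep(NA_real_, 5), MEASURES)
  for (m in names(landmarks$landmarks)) {
    l <- landmarks$landmarks[[m]]
    cand <- c(dist_cm(l),
              vapply(l$alternates %||% list(), dist_cm, 1))
    conf <- c(l$confidence,
              vapply(l$alternates %||% list(),
                     function(a) a$confidence, 1))
    vals[m] <- if (length(cand) > 1)
      cluster_candidates(cand, conf)$value else cand
  }
  data.frame(subject_id = subject_id, source = source, t(vals))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compute the three sternal indices
#'
#' Sternal index `SI = 100 * M / B`; sternal area
#' `SA = (M + B) * (MW + CSW1 + CSW2) / 3` (cm^2); combined length
#' `CL = M + B` (cm).
#'
#' @param record a list, named vector or data frame (one or more rows)
#'   containing all five measurements `M`, `MW`, `B`, `CSW1`, `CSW2` in
#'   cm.
#' @return data frame with columns `SI`, `SA`, `CL` (one row per input
#'   row).
#' @examples
#' compute_indices(c(M = 5, MW = 3, B = 10, CSW1 = 3, CSW2 = 3))
#' @export
compute_indices <- function(record) {
  if (!is.data.frame(record)) record <- as.data.frame(as.list(record))
  missing <- setdiff(MEASURES, names(record))
  if (length(missing) == 0) {
    bad <- MEASURES[vapply(record[MEASURES],
                           function(x) any(is.na(x)), TRUE)]
    missing <- bad
  }
  if (length(missing) > 0)
    stop("cannot compute indices, missing measurement(s): ",
         paste(missing, collapse = ", "))
  data.frame(SI = 100 * record$M / record$B,
             SA = (record$M + record$B) *
               (record$MW + record$CSW1 + record$CSW2) / 3,
             CL = record$M + record$B)
}

#' Default segmentation-parameter grid for training
#'
#' Crossed grid over the threshold window, the intensity offset and the
#' maximum bridgeable gap; the first entry holds the package defaults.
#'
#' @return list of [segmentation_params()] objects.
#' @export
default_param_grid <- function() {
  combos <- expand.grid(window = c(31L, 25L, 37L),
                        offset = c(0.07, 0.05, 0.10),
                        KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(combos)), function(i)
    segmentation_params(window = combos$window[i],
                        offset = combos$offset[i]))
}

#' Train segmentation parameters on reference images
#'
#' Exhaustive grid evaluation: for every parameter set, every training
#' image is segmented and measured, and the image counts as a success
#' when all of its measurements fall within the relative tolerance of the
#' reference values.  Efficiency is the success fraction; the argmax
#' parameter set is returned (ties resolved toward the earlier grid
#' entry).
#'
#' @param training list of training cases, each a list with `image` (a
#'   [bone_image()]) and `reference`: either a `phantom_truth` or a named
#'   vector/one-row data frame of reference lengths in cm.
#' @param grid list of [segmentation_params()]; see
#'   [default_param_grid()].
#' @param tolerance relative tolerance (default 0.05).
#' @param control [landmark_control()] parameters.
#' @return object of class `training_result`: `params` (selected),
#'   `efficiency`, `efficiencies` (per grid entry), `tolerance`, `grid`.
#' @export
tune_parameters <- function(training, grid = default_param_grid(),
                            tolerance = 0.05,
                            control = landmark_control()) {
  if (length(training) == 0) stop("empty training set")
  if (length(grid) == 0) stop("empty parameter grid")
  ref_lengths <- function(ref) {
    if (inherits(ref, "phantom_truth")) return(ref$lengths)
    if (is.data.frame(ref)) ref <- unlist(ref[1, , drop = TRUE])
    keep <- intersect(names(ref), MEASURES)
    vals <- suppressWarnings(as.numeric(ref[keep]))
    stats::setNames(vals, keep)[!is.na(vals)]
  }
  eff <- vapply(grid, function(par) {
    ok <- vapply(training, function(case) {
      ref <- ref_lengths(case$reference)
      res <- try({
        ct <- segment_bone(case$image, par)
        lm <- suppressWarnings(
          find_landmarks(ct, case$image$kind, control))
        measure_bone(lm, case$image$spacing)
      }, silent = TRUE)
      if (inherits(res, "try-error")) return(FALSE)
      got <- unlist(res[1, names(ref)])
      all(is.finite(got)) && all(abs(got - ref) <= tolerance * ref)
    }, TRUE)
    mean(ok)
  }, 1)
  best <- which.max(eff)            # first maximum = earliest grid entry
  structure(list(params = grid[[best]], efficiency = eff[best],
                 efficiencies = eff, tolerance = tolerance, grid = grid),
            class = "training_result")
}

#' @export
print.training_result <- function(x, ...) {
  cat(sprintf(paste0("<training_result> efficiency %.3f at %.0f%% ",
                     "tolerance (grid of %d)\n  selected: window %d, ",
                     "offset %.3f\n"),
              x$efficiency, 100 * x$tolerance, length(x$grid),
              x$params$window, x$params$offset))
  invisible(x)
}

#' @export
print.landmark_configuration <- function(x, ...) {
  cat("<landmark_configuration>", x$kind, "\n")
  for (m in names(x$landmarks)) {
    l <- x$landmarks[[m]]
    cat(sprintf("  %-5s (%.1f, %.1f) -> (%.1f, %.1f)  conf %.2f\n",
                m, l$p1[1], l$p1[2], l$p2[1], l$p2[2], l$confidence))
  }
  if (length(x$flagged))
    cat("  flagged:", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}
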