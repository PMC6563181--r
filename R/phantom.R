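# Synthetic phantom generator: per-bone 2D projection images with exactly
# known landmark coordinates and measurement lengths, plus a corruption
# model (noise, border breaks, distractors, intensity gradient) emulating
# the failure modes of clinical projections.


#' Population specification for ground-truth sampling
#'
#' Defines the sex-structured multivariate distribution of the five
#' sternal measurements (cm): manubrium length `M`, manubrium width `MW`,
#' sternal body length `B` and corpus widths `CSW1`, `CSW2`.  Measurements
#' share a single equicorrelation coefficient.
#'
#' The defaults reproduce published pooled means and standard deviations
#' of an adult European reference sample (`M` 5.25 +- 0.57, `MW` 5.63 +-
#' 0.53, `B` 9.46 +- 1.60, `CSW1` 2.66 +- 0.37, `CSW2` 3.11 +- 0.59 cm;
#' 73 men, 55 women).  Only pooled moments are published, so the split
#' into sex-specific means and a common within-sex SD is derived from
#' per-measurement standardized effect sizes chosen to match the reported
#' single-variable classification accuracies (see the methods vignette);
#' mixing the two sexes at the default sample sizes recovers the pooled
#' moments exactly.
#'
#' @param mean_male,mean_female named numeric vectors of per-sex means
#'   (cm) for `M`, `MW`, `B`, `CSW1`, `CSW2`.
#' @param sd_male,sd_female named numeric vectors of per-sex SDs (cm).
#' @param n_male,n_female sample sizes per sex.
#' @param correlation scalar inter-measurement correlation in `[0, 1)`.
#' @param seed integer random seed used by [sample_ground_truth()].
#' @return an object of class `population_spec`.
#' @seealso [sample_ground_truth()]
#' @export
population_spec <- function(mean_male = NULL, mean_female = NULL,
                            sd_male = NULL, sd_female = NULL,
                            n_male = 73L, n_female = 55L,
                            correlation = 0.5, seed = 1L) {
  if (is.null(mean_male) || is.null(mean_female) ||
      is.null(sd_male) || is.null(sd_female)) {
    pooled_mean <- c(M = 5.25, MW = 5.63, B = 9.46, CSW1 = 2.66, CSW2 = 3.11)
    pooled_sd <- c(M = 0.57, MW = 0.53, B = 1.60, CSW1 = 0.37, CSW2 = 0.59)
    # standardized male-female separation per measurement, back-solved
    # from published single-variable classification rates r via
    # delta = 2 * qnorm(r)
    rates <- c(M = 0.68, MW = 0.789, B = 0.828, CSW1 = 0.734, CSW2 = 0.672)
    delta <- 2 * stats::qnorm(rates)
    p_m <- n_male / (n_male + n_female); p_f <- 1 - p_m
    sd_within <- pooled_sd / sqrt(1 + p_m * p_f * delta^2)
    d <- delta * sd_within
    if (is.null(mean_male)) mean_male <- pooled_mean + p_f * d
    if (is.null(mean_female)) mean_female <- pooled_mean - p_m * d
    if (is.null(sd_male)) sd_male <- sd_within
    if (is.null(sd_female)) sd_female <- sd_within
  }
  for (v in list(mean_male, mean_female, sd_male, sd_female))
    stopifnot(is.numeric(v), length(v) == 5L, all(MEASURES %in% names(v)))
  if (any(mean_male[MEASURES] <= 0) || any(mean_female[MEASURES] <= 0))
    stop("all means must be positive")
  if (any(sd_male[MEASURES] < 0) || any(sd_female[MEASURES] < 0))
    stop("standard deviations must be non-negative")
  if (correlation < 0 || correlation >= 1)
    stop("correlation must lie in [0, 1)")
  if (n_male < 0 || n_female < 0) stop("sample sizes must be >= 0")
  structure(list(mean_male = mean_male[MEASURES],
                 mean_female = mean_female[MEASURES],
                 sd_male = sd_male[MEASURES], sd_female = sd_female[MEASURES],
                 n_male = as.integer(n_male), n_female = as.integer(n_female),
                 correlation = correlation, seed = as.integer(seed)),
            class = "population_spec")
}

#' Sample ground-truth measurement records from a population
#'
#' Draws multivariate normal measurement vectors per sex with the
#' equicorrelation structure of the specification.  Negative draws (deep
#' tail events) are rejected and redrawn so that all lengths are positive.
#'
#' @param spec a [population_spec()].
#' @return data frame with columns `subject_id`, `sex` (`"male"` /
#'   `"female"`) and the five measurements in cm.
#' @export
sample_ground_truth <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  R <- matrix(spec$correlation, 5, 5); diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("implied covariance is not positive definite (correlation = ",
         spec$correlation, ")")
  draw <- function(n, mu, sd) {
    if (n == 0)
      return(matrix(numeric(0), 0, 5, dimnames = list(NULL, MEASURES)))
    Sigma <- diag(sd) %*% R %*% diag(sd)
    x <- MASS::mvrnorm(n, mu, Sigma)
    x <- matrix(x, ncol = 5, dimnames = list(NULL, MEASURES))
    for (i in seq_len(n)) {          # rejection step for negative tails
      tries <- 0
      while (any(x[i, ] <= 0) && tries < 100) {
        x[i, ] <- MASS::mvrnorm(1, mu, Sigma)
        tries <- tries + 1
      }
    }
    x
  }
  set.seed(spec$seed)
  males <- draw(spec$n_male, spec$mean_male, spec$sd_male)
  females <- draw(spec$n_female, spec$mean_female, spec$sd_female)
  out <- data.frame(
    subject_id = sprintf("S%03d", seq_len(nrow(males) + nrow(females))),
    sex = rep(c("male", "female"), c(nrow(males), nrow(females))),
    rbind(males, females))
  rownames(out) <- NULL
  out
}

# cos^2 indentation bump, zero outside |s| > r
notch_bump <- function(s, depth, r) {
  out <- numeric(length(s))
  ins <- abs(s) < r
  out[ins] <- depth * cos(pi * s[ins] / (2 * r))^2
  out
}

#' Shape parameters of the phantom outlines
#'
#' All values in pixels.  Notches are smooth cos^2 indentations; end caps
#' are half-ellipses passing exactly through the length landmarks.
#'
#' @param notch_depth,notch_r depth and half-height of the lateral costal
#'   notches.
#' @param jug_depth,jug_r depth and half-width of the jugular notch.
#' @param clav_depth,clav_r depth and half-width of the clavicular
#'   notches.
#' @param cap vertical depth of the end caps.
#' @param corpus_notch_frac positions of costal notches 2-5 along the
#'   corpus, as fractions of `B`.
#' @param corpus_top_scale,corpus_bot_scale end widths of the corpus
#'   relative to `CSW1` and `CSW2`.
#' @param ic1_frac position of the first costal notch along the
#'   manubrium.
#' @param manubrium_slope lateral taper of the manubrium border.
#' @return list of shape parameters.
#' @export
phantom_shape <- function(notch_depth = 6, notch_r = 9,
                          jug_depth = 9, jug_r = 13,
                          clav_depth = 6, clav_r = 9, cap = 7,
                          corpus_notch_frac = c(0.18, 0.42, 0.66, 0.90),
                          corpus_top_scale = 1.3, corpus_bot_scale = 0.62,
                          ic1_frac = 0.76, manubrium_slope = 0.18) {
  as.list(environment())
}

# Corpus sterni outline: vertical blade between elliptic caps, lateral
# costal notches 2..5, half-width profile splined through the two width
# constraints so the outer chord at the IC2/3 midpoint level equals CSW1
# and at the IC4/5 level equals CSW2.  All arguments in pixels.
corpus_outline <- function(B, csw1, csw2, cx, ytop, shape = phantom_shape(),
                           step = 0.75) {
  sh <- shape
  ybot <- ytop + B
  y1 <- ytop + mean(sh$corpus_notch_frac[1:2]) * B
  y2 <- ytop + mean(sh$corpus_notch_frac[3:4]) * B
  yk <- c(ytop, y1, y2, ybot)
  wk <- c(sh$corpus_top_scale * csw1 / 2, csw1 / 2, csw2 / 2,
          sh$corpus_bot_scale * csw2 / 2)
  wfun <- stats::splinefun(yk, wk, method = "natural")
  ync <- ytop + sh$corpus_notch_frac * B
  half <- function(y) {
    w <- wfun(y)
    for (yc in ync) w <- w - notch_bump(y - yc, sh$notch_depth, sh$notch_r)
    w
  }
  cap <- sh$cap
  ys <- seq(ytop + cap, ybot - cap, by = step)
  thb <- seq(0, pi, length.out = 41)[-c(1, 41)]
  poly <- rbind(
    cbind(cx + half(ys), ys),                                    # right
    cbind(cx + half(ybot - cap) * cos(thb),
          (ybot - cap) + cap * sin(thb)),                        # bottom cap
    cbind(cx - half(rev(ys)), rev(ys)),                          # left
    cbind(cx - half(ytop + cap) * cos(thb),
          (ytop + cap) - cap * sin(thb)))                        # top cap
  list(poly = poly,
       landmarks = list(
         B = rbind(c(cx, ytop), c(cx, ybot)),
         CSW1 = rbind(c(cx - csw1 / 2, y1), c(cx + csw1 / 2, y1)),
         CSW2 = rbind(c(cx - csw2 / 2, y2), c(cx + csw2 / 2, y2))))
}

# Manubrium outline: trapezoid narrowing inferiorly.  The superior border
# carries a central jugular notch and two clavicular notches; the first
# costal notches indent the lateral borders, and MW is the chord through
# their floors.  M runs from the superior border point midway between the
# jugular and clavicular notch to the inferior (manubriosternal) midpoint;
# the vertical extent is solved so that this distance is exactly M.
manubrium_outline <- function(M, MW, cx, ytop, shape = phantom_shape(),
                              step = 0.75) {
  sh <- shape
  cap <- sh$cap
  H <- 0.95 * M
  for (i in 1:12) {                  # fixed point: wtop depends on H
    wtop <- MW / 2 + sh$notch_depth + sh$manubrium_slope * sh$ic1_frac * H
    xc <- wtop - cap - sh$clav_r - 1   # clavicular notch center offset
    xm <- xc / 2                       # M start offset from the midline
    H <- sqrt(max(M^2 - xm^2, (0.4 * M)^2))
  }
  if (xm - sh$jug_r < 2 || xc - sh$clav_r - xm < 2)
    stop("manubrium proportions leave no flat superior border; ",
         "adjust shape parameters")
  ybot <- ytop + H
  y_ic1 <- ytop + sh$ic1_frac * H
  half <- function(y) wtop - sh$manubrium_slope * (y - ytop) -
    notch_bump(y - y_ic1, sh$notch_depth, sh$notch_r)
  topedge <- function(x) ytop + notch_bump(x, sh$jug_depth, sh$jug_r) +
    notch_bump(x - xc, sh$clav_depth, sh$clav_r) +
    notch_bump(x + xc, sh$clav_depth, sh$clav_r)
  xs <- seq(-(wtop - cap), wtop - cap, by = step)
  ys <- seq(ytop + cap, ybot - cap, by = step)
  thb <- seq(0, pi, length.out = 41)[-c(1, 41)]
  qa <- seq(0, pi / 2, length.out = 12)[-c(1, 12)]
  wt <- half(ytop + cap)
  corner_r <- cbind(cx + (wtop - cap) + (wt - wtop + cap) * (1 - cos(qa)),
                    ytop + cap * (1 - cos(qa)))
  corner_r <- corner_r[order(corner_r[, 2]), , drop = FALSE]
  corner_l <- cbind(2 * cx - corner_r[, 1], corner_r[, 2])
  poly <- rbind(
    cbind(cx + xs, topedge(xs)),                                 # top edge
    corner_r,
    cbind(cx + half(ys), ys),                                    # right
    cbind(cx + half(ybot - cap) * cos(thb),
          (ybot - cap) + cap * sin(thb)),                        # bottom cap
    cbind(cx - half(rev(ys)), rev(ys)),                          # left
    corner_l[rev(seq_len(nrow(corner_l))), ])
  list(poly = poly,
       landmarks = list(
         M = rbind(c(cx + xm, ytop), c(cx, ybot)),
         MW = rbind(c(cx - MW / 2, y_ic1), c(cx + MW / 2, y_ic1))))
}

#' Render a synthetic bone projection with known ground truth
#'
#' Draws a bright bone-like silhouette on a dark background: trabecular
#' interior at an intermediate intensity, cortical rim brighter (as in CT
#' projections), plus mild speckle.  The returned truth object carries the
#' outline polygon and sub-pixel landmark coordinates whose pairwise
#' distances reproduce the requested lengths exactly.
#'
#' @param lengths named numeric vector of true lengths in cm: `B`, `CSW1`,
#'   `CSW2` for a corpus phantom; `M`, `MW` for a manubrium phantom.
#' @param kind `"corpus"` or `"manubrium"`.
#' @param spacing pixel spacing in cm/pixel.
#' @param seed integer seed for the speckle noise.
#' @param canvas optional `c(nrow, ncol)`; auto-sized when `NULL`.
#' @param shape [phantom_shape()] parameters.
#' @param margin margin around the bone in pixels (auto-sizing).
#' @param background,interior,rim,speckle_sd intensity model (intensities
#'   in `[0, 1]`).
#' @param rim_width cortical rim width in pixels.
#' @return a list of class `phantom` with elements `image` (a
#'   [bone_image()]) and `truth` (class `phantom_truth`: `kind`,
#'   `lengths`, `landmarks`, `spacing`, `outline`, `seed`).
#' @examples
#' ph <- render_phantom(c(B = 9.5, CSW1 = 2.7, CSW2 = 3.1), "corpus")
#' ph$truth$lengths
#' @export
render_phantom <- function(lengths, kind = c("corpus", "manubrium"),
                           spacing = 0.05, seed = 1L, canvas = NULL,
                           shape = phantom_shape(), margin = 28,
                           background = 0.12, interior = 0.55, rim = 0.86,
                           speckle_sd = 0.02, rim_width = 4) {
  kind <- match.arg(kind)
  stopifnot(spacing > 0, all(lengths > 0))
  px <- lengths / spacing
  if (kind == "corpus") {
    need <- CORPUS_MEASURES
    if (!all(need %in% names(lengths)))
      stop("corpus phantom needs lengths B, CSW1, CSW2")
    W <- ceiling(shape$corpus_top_scale * max(px["CSW1"], px["CSW2"]) +
                   2 * margin)
    H <- ceiling(px["B"] + 2 * margin)
  } else {
    need <- MANUBRIUM_MEASURES
    if (!all(need %in% names(lengths)))
      stop("manubrium phantom needs lengths M, MW")
    W <- ceiling(px["MW"] + 2 * shape$notch_depth +
                   2 * shape$manubrium_slope * 0.8 * px["M"] + 2 * margin)
    H <- ceiling(px["M"] + 2 * margin)
  }
  H <- max(H, 64L); W <- max(W, 64L)
  if (!is.null(canvas)) {
    if (canvas[1] < H || canvas[2] < W)
      stop("lengths exceed the requested canvas at spacing ", spacing,
           " (need at least ", H, " x ", W, " pixels)")
    H <- canvas[1]; W <- canvas[2]
  }
  out <- if (kind == "corpus")
    corpus_outline(px["B"], px["CSW1"], px["CSW2"], cx = W / 2,
                   ytop = margin, shape = shape)
  else
    manubrium_outline(px["M"], px["MW"], cx = W / 2, ytop = margin,
                      shape = shape)
  set.seed(seed)
  fill <- raster_polygon(out$poly, H, W)
  rimmask <- fill & !erode4(fill, rim_width)
  pix <- matrix(background, H, W)
  pix[fill] <- interior
  pix[rimmask] <- rim
  if (speckle_sd > 0) pix <- pix + matrix(stats::rnorm(H * W, 0, speckle_sd), H, W)
  truth <- structure(list(
    kind = kind, lengths = lengths[need], landmarks = out$landmarks,
    spacing = spacing, outline = out$poly, seed = as.integer(seed),
    background = background), class = "phantom_truth")
  img <- bone_image(pix, spacing = spacing, kind = kind,
                    id = paste0("phantom_", kind))
  structure(list(image = img, truth = truth), class = "phantom")
}

#' Image corruption specification
#'
#' Artifact model applied on top of a clean phantom: additive Gaussian
#' intensity noise, border breaks (arcs of the outline erased to
#' background, the classic failure mode of low-contrast projections),
#' bright distractor blobs away from the bone, and a linear intensity
#' gradient.  An all-zero specification leaves the image untouched.
#'
#' @param noise_sd additive noise SD (intensity units, image range 0-1).
#' @param n_breaks number of border breaks.
#' @param break_len arc length of each break in pixels.
#' @param break_halfwidth half-width of the erased band in pixels.
#' @param n_blobs number of distractor blobs.
#' @param blob_radius,blob_intensity distractor geometry and intensity.
#' @param gradient_amp amplitude of the linear intensity gradient.
#' @param seed integer seed; the same spec and seed give identical output.
#' @return object of class `corruption_spec`.
#' @export
corruption_spec <- function(noise_sd = 0.035, n_breaks = 2, break_len = 12,
                            break_halfwidth = 5, n_blobs = 2,
                            blob_radius = 5, blob_intensity = 0.8,
                            gradient_amp = 0.06, seed = 1L) {
  if (any(c(noise_sd, n_breaks, break_len, break_halfwidth, n_blobs,
            blob_radius, gradient_amp) < 0))
    stop("corruption parameters must be non-negative")
  structure(list(noise_sd = noise_sd, n_breaks = as.integer(n_breaks),
                 break_len = break_len, break_halfwidth = break_halfwidth,
                 n_blobs = as.integer(n_blobs), blob_radius = blob_radius,
                 blob_intensity = blob_intensity,
                 gradient_amp = gradient_amp, seed = as.integer(seed)),
            class = "corruption_spec")
}

#' Apply artifacts to a phantom image
#'
#' @param image a [bone_image()] (typically `phantom$image`).
#' @param truth the matching `phantom_truth` (supplies the outline along
#'   which border breaks are placed); unchanged by this call.
#' @param spec a [corruption_spec()].
#' @return corrupted [bone_image()].
#' @export
corrupt_image <- function(image, truth, spec = corruption_spec()) {
  stopifnot(inherits(spec, "corruption_spec"),
            inherits(truth, "phantom_truth"))
  pix <- as_pixel_matrix(image)
  nr <- nrow(pix); nc <- ncol(pix)
  poly <- truth$outline
  if (spec$n_breaks > 0 &&
      spec$break_len >= polygon_perimeter(poly) / 2)
    stop("break arc length must be below half the contour perimeter")
  bg <- if (!is.null(truth$background)) truth$background
        else stats::quantile(pix, 0.05)
  set.seed(spec$seed)
  if (spec$n_breaks > 0 && spec$break_len > 0) {
    dense <- resample_closed(poly, step = 1)
    np <- nrow(dense)
    starts <- sample.int(np, spec$n_breaks)
    r <- round(spec$break_halfwidth)
    off <- expand.grid(dr = -r:r, dc = -r:r)
    off <- off[off$dr^2 + off$dc^2 <= spec$break_halfwidth^2, ]
    for (s in starts) {
      idx <- ((s - 1) + seq_len(round(spec$break_len))) %% np + 1
      for (i in idx) {
        rr <- round(dense[i, 2]) + off$dr
        cc <- round(dense[i, 1]) + off$dc
        ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
        pix[cbind(rr[ok], cc[ok])] <- bg
      }
    }
  }
  if (spec$n_blobs > 0) {
    r <- round(spec$blob_radius)
    off <- expand.grid(dr = -r:r, dc = -r:r)
    off <- off[off$dr^2 + off$dc^2 <= spec$blob_radius^2, ]
    placed <- 0; tries <- 0
    while (placed < spec$n_blobs && tries < 200) {
      tries <- tries + 1
      p <- c(stats::runif(1, r + 2, nc - r - 2),
             stats::runif(1, r + 2, nr - r - 2))
      d2min <- min((poly[, 1] - p[1])^2 + (poly[, 2] - p[2])^2)
      if (sqrt(d2min) < spec$blob_radius + 12) next
      pix[cbind(round(p[2]) + off$dr, round(p[1]) + off$dc)] <-
        spec$blob_intensity
      placed <- placed + 1
    }
  }
  if (spec$gradient_amp > 0) {
    th <- stats::runif(1, 0, 2 * pi)
    ramp <- outer(seq_len(nr) - nr / 2, rep(1, nc)) * sin(th) +
      outer(rep(1, nr), seq_len(nc) - nc / 2) * cos(th)
    pix <- pix + spec$gradient_amp * ramp / max(abs(ramp))
  }
  if (spec$noise_sd > 0)
    pix <- pix + matrix(stats::rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
  bone_image(pix, spacing = image$spacing, kind = image$kind,
             id = image$id)
}

#' Generate a batch of phantoms from a population
#'
#' Samples ground-truth records, renders one bone per phantom (the first
#' `n_corpus` as corpus, the rest as manubrium), optionally corrupts each
#' image, and optionally writes TIFF + truth-JSON pairs.
#'
#' @param n_corpus,n_manubrium number of phantoms per bone kind.
#' @param population a [population_spec()]; its seed is re-derived from
#'   `seed`.
#' @param corruption a [corruption_spec()] or `NULL` for clean images.
#' @param spacing pixel spacing (cm/pixel).
#' @param seed master seed; per-image seeds are derived from it.
#' @param out_dir optional output directory for
#'   `<id>_<kind>.tif` / `.truth.json` pairs.
#' @return list with `phantoms` (list of `phantom` objects, images
#'   corrupted when requested) and `records` (the sampled truth table).
#' @export
generate_phantoms <- function(n_corpus, n_manubrium,
                              population = population_spec(),
                              corruption = corruption_spec(),
                              spacing = 0.05, seed = 1L, out_dir = NULL) {
  n <- n_corpus + n_manubrium
  pop <- population
  pop$n_male <- ceiling(n / 2); pop$n_female <- n - pop$n_male
  pop$seed <- as.integer(seed)
  rec <- sample_ground_truth(pop)
  rec <- rec[sample.int(nrow(rec)), , drop = FALSE]  # interleave sexes
  rec$kind <- rep(c("corpus", "manubrium"), c(n_corpus, n_manubrium))
  phantoms <- vector("list", n)
  for (i in seq_len(n)) {
    kind <- rec$kind[i]
    need <- if (kind == "corpus") CORPUS_MEASURES else MANUBRIUM_MEASURES
    lens <- unlist(rec[i, need])
    ph <- render_phantom(lens, kind, spacing = spacing,
                         seed = seed + 1000L + i)
    if (!is.null(corruption)) {
      cs <- corruption
      cs$seed <- seed + 2000L + i
      ph$image <- corrupt_image(ph$image, ph$truth, cs)
    }
    ph$image$id <- paste0(rec$subject_id[i], "_", kind)
    phantoms[[i]] <- ph
    if (!is.null(out_dir)) write_phantom(ph, out_dir)
  }
  list(phantoms = phantoms, records = rec)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("<phantom_truth>", x$kind, "\n  lengths (cm):",
      paste(names(x$lengths), round(x$lengths, 3), sep = "=",
            collapse = ", "),
      "\n  spacing:", x$spacing, "cm/px\n")
  invisible(x)
}
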