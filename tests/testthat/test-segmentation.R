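# Segmentation stack: adaptive threshold, border potential filtering,
# break bridging, contour tracing, classification, composition.

test_that("constant image thresholds to all-background", {
  img <- bone_image(matrix(0.5, 40, 40), spacing = 0.05)
  mask <- adaptive_threshold(img, segmentation_params(window = 9,
                                                      offset = 0.05))
  expect_false(any(mask))
})

test_that("adaptive threshold matches the per-pixel rule on a step image", {
  pix <- cbind(matrix(0, 20, 10), matrix(1, 20, 10))
  par <- segmentation_params(window = 7, offset = 0.1)
  mask <- adaptive_threshold(bone_image(pix, 0.05), par)
  # brute-force oracle: clipped-window local mean per pixel
  k <- 3
  oracle <- matrix(NA, 20, 20)
  for (r in 1:20) for (cc in 1:20) {
    win <- pix[max(1, r - k):min(20, r + k), max(1, cc - k):min(20, cc + k)]
    oracle[r, cc] <- pix[r, cc] > mean(win) + 0.1
  }
  expect_identical(mask, oracle)
  # foreground only in the bright band adjacent to the step
  expect_true(all(which(mask, arr.ind = TRUE)[, 2] %in% 11:13))
})

test_that("threshold rejects windows larger than the image", {
  expect_error(adaptive_threshold(bone_image(matrix(0, 10, 10), 0.05),
                                  segmentation_params(window = 11)),
               "larger than the image")
  expect_error(segmentation_params(window = 10), "odd")
})

test_that("clean phantom threshold fires along the silhouette border", {
  ph <- clean_corpus()
  mask <- adaptive_threshold(ph$image)
  fill <- sternometry:::raster_polygon(ph$truth$outline,
                                       nrow(ph$image$pixels),
                                       ncol(ph$image$pixels))
  ring <- fill & !sternometry:::erode4(fill, 8)
  near_ring <- sternometry:::dilate4(ring, 2)
  expect_gt(sum(mask & near_ring) / sum(mask), 0.98)  # mask is border band
  rim <- fill & !sternometry:::erode4(fill, 3)
  expect_gt(sum(mask & rim) / sum(rim), 0.85)         # band covers the rim
})

test_that("monotonicity: higher offset never grows the foreground", {
  set.seed(8)
  pix <- matrix(runif(900), 30, 30)
  img <- bone_image(pix, 0.05)
  prev <- adaptive_threshold(img, segmentation_params(window = 7,
                                                      offset = 0.0))
  for (off in c(0.05, 0.1, 0.2)) {
    cur <- adaptive_threshold(img, segmentation_params(window = 7,
                                                       offset = off))
    expect_true(all(prev | !cur))   # cur subset of prev
    prev <- cur
  }
})

test_that("thin binary structures are reproduced by thresholding", {
  # local-mean thresholding is idempotent on structures thinner than the
  # window: inside a thin bright band the window still sees background
  m <- matrix(0, 40, 40)
  m[18:21, 5:35] <- 1
  mask <- adaptive_threshold(bone_image(m, 0.05),
                             segmentation_params(window = 15, offset = 0.2))
  expect_identical(mask, m > 0)
})

test_that("potential filtering keeps dense borders and drops speckles", {
  mask <- matrix(FALSE, 40, 40)
  th <- seq(0, 2 * pi, length.out = 200)
  mask[cbind(round(20 + 12 * sin(th)), round(20 + 12 * cos(th)))] <- TRUE
  speckles <- rbind(c(3, 3), c(5, 36), c(36, 4))
  mask_s <- mask; mask_s[speckles] <- TRUE
  par <- segmentation_params()
  chains <- filter_border_candidates(mask_s, par)
  expect_length(chains, 1)                 # circle survives, speckles drop
  pts <- chains[[1]]
  rad <- sqrt((pts[, 1] - 20)^2 + (pts[, 2] - 20)^2)
  expect_true(all(abs(rad - 12) < 2.2))
  # solid disk: uniformly dense border, nothing removed
  disk <- matrix(FALSE, 40, 40)
  for (r in 1:40) for (cc in 1:40)
    if ((r - 20)^2 + (cc - 20)^2 <= 144) disk[r, cc] <- TRUE
  chains_d <- filter_border_candidates(disk, par)
  expect_length(chains_d, 1)
  expect_equal(nrow(chains_d[[1]]), sum(sternometry:::border_pixels(disk)))
})

test_that("empty mask yields an empty chain set, not an error", {
  expect_identical(filter_border_candidates(matrix(FALSE, 20, 20),
                                            segmentation_params()),
                   list())
})

test_that("potential filter matches exhaustive computation on small images", {
  par <- segmentation_params(min_chain = 1)
  set.seed(17)
  for (rep in 1:8) {
    mask <- matrix(runif(32 * 32) < 0.12, 32, 32)
    bp <- sternometry:::border_pixels(mask)
    pot_fast <- sternometry:::border_potential(bp, par$potential_sigma)
    # exhaustive per-pixel kernel sum
    idx <- which(bp, arr.ind = TRUE)
    keep_oracle <- matrix(FALSE, 32, 32)
    h <- ceiling(3 * par$potential_sigma)
    for (i in seq_len(nrow(idx))) {
      # oracle potential: truncated separable Gaussian weighted count
      dd <- cbind(idx[, 1] - idx[i, 1], idx[, 2] - idx[i, 2])
      ww <- exp(-(dd[, 1]^2) / (2 * par$potential_sigma^2)) *
        exp(-(dd[, 2]^2) / (2 * par$potential_sigma^2))
      ww[abs(dd[, 1]) > h | abs(dd[, 2]) > h] <- 0
      keep_oracle[idx[i, , drop = FALSE]] <-
        sum(ww) >= par$potential_threshold
    }
    keep_fast <- bp & (pot_fast >= par$potential_threshold)
    expect_identical(keep_fast, keep_oracle)
  }
})

test_that("bridging joins admissible gaps and respects the bound", {
  seg1 <- cbind(5:14, 10)       # (row, col): column 10, rows 5..14
  seg2 <- cbind(18:27, 10)      # 3 px gap (rows 15..17)
  par5 <- segmentation_params(max_gap = 5)
  out <- connect_breaks(list(seg1, seg2), par5)
  expect_length(out, 1)
  expect_true(all(paste(15:17, 10) %in% paste(out[[1]][, 1], out[[1]][, 2])))
  seg3 <- cbind(25:34, 10)      # 10 px gap from seg1
  out2 <- connect_breaks(list(seg1, seg3), par5)
  expect_length(out2, 2)
  expect_identical(sort(paste(out2[[1]][, 1], out2[[1]][, 2])),
                   sort(paste(seg1[, 1], seg1[, 2])))
})

test_that("a circle cut into four arcs is re-closed into one chain", {
  th <- seq(0, 2 * pi, length.out = 400)
  circ <- unique(cbind(round(30 + 20 * sin(th)), round(30 + 20 * cos(th))))
  # cut 4 arcs of ~4 px at the four compass points
  cutout <- function(pts, center, r = 2.2) {
    keep <- sqrt((pts[, 1] - center[1])^2 + (pts[, 2] - center[2])^2) > r
    pts[keep, , drop = FALSE]
  }
  pts <- circ
  for (cen in list(c(10, 30), c(50, 30), c(30, 10), c(30, 50)))
    pts <- cutout(pts, cen)
  lab <- sternometry:::label8(pts, 64)
  chains <- lapply(split(seq_len(nrow(lab$pix)), lab$comp),
                   function(ix) lab$pix[ix, , drop = FALSE])
  expect_length(chains, 4)
  merged <- connect_breaks(chains, segmentation_params(max_gap = 6))
  expect_length(merged, 1)
  # closed: tracing now finds an interior
  cts <- trace_contours(merged, bone_image(matrix(0.5, 64, 64), 0.05))
  expect_length(cts, 1)
  expect_gt(cts[[1]]$area, pi * 17^2)
})

test_that("bridging never moves existing chain pixels", {
  seg1 <- cbind(5:14, 10); seg2 <- cbind(18:27, 10)
  out <- connect_breaks(list(seg1, seg2), segmentation_params(max_gap = 5))
  keys <- paste(out[[1]][, 1], out[[1]][, 2])
  expect_true(all(paste(seg1[, 1], seg1[, 2]) %in% keys))
  expect_true(all(paste(seg2[, 1], seg2[, 2]) %in% keys))
})

test_that("traced square chain has exact area and centroid", {
  m <- matrix(FALSE, 30, 30)
  m[10:20, 8:18] <- TRUE                 # 11 x 11 block: side length 10
  chain <- which(sternometry:::border_pixels(m), arr.ind = TRUE)
  cts <- trace_contours(list(chain), bone_image(matrix(1, 30, 30), 0.05))
  expect_length(cts, 1)
  expect_equal(cts[[1]]$area, 100)
  expect_equal(cts[[1]]$centroid, c(13, 15))   # (x, y) center of block
  expect_equal(cts[[1]]$solidity, 1, tolerance = 1e-9)
})

test_that("polygon metric helpers are exact on closed forms", {
  tri <- rbind(c(0, 0), c(3, 0), c(0, 4))
  expect_equal(sternometry:::polygon_area(tri), 6)
  expect_equal(sternometry:::polygon_perimeter(tri), 12)
  sq <- rbind(c(1, 1), c(11, 1), c(11, 11), c(1, 11))
  expect_equal(sternometry:::polygon_area(sq), 100)
  expect_equal(sternometry:::polygon_centroid(sq), c(6, 6))
})

test_that("open chains are discarded with a logged count", {
  open_chain <- cbind(5:25, 10)
  cts <- trace_contours(list(open_chain),
                        bone_image(matrix(0.5, 30, 30), 0.05))
  expect_length(cts, 0)
  expect_equal(attr(cts, "dropped_open"), 1L)
})

test_that("phantom contour centroid matches the truth polygon centroid", {
  ph <- clean_corpus()
  ct <- corpus_contour()
  truth_cen <- sternometry:::polygon_centroid(ph$truth$outline)
  expect_lt(sqrt(sum((ct$centroid - truth_cen)^2)), 2)
})

test_that("contour classification enforces every feature bound", {
  ct <- corpus_contour()
  par <- segmentation_params()
  out <- classify_contours(list(ct), par)
  expect_true(out[[1]]$accepted)
  # tiny speck below min area
  m <- matrix(FALSE, 20, 20); m[9:11, 9:11] <- TRUE
  speck <- trace_contours(list(which(m, arr.ind = TRUE)),
                          bone_image(matrix(1, 20, 20), 0.05))
  if (length(speck)) {
    out2 <- classify_contours(speck, par)
    expect_false(out2[[1]]$accepted)
  }
  # dark hollow distractor of bone-like size: rejected on interior
  # intensity
  img <- matrix(0.1, 120, 120)
  th <- seq(0, 2 * pi, length.out = 600)
  ring <- unique(cbind(round(60 + 40 * sin(th)), round(60 + 40 * cos(th))))
  for (d in 0:2) img[cbind(pmin(ring[, 1] + d, 120), ring[, 2])] <- 0.9
  cts <- trace_contours(list(ring), bone_image(img, 0.05))
  expect_length(cts, 1)
  out3 <- classify_contours(cts, par)
  expect_false(out3[[1]]$accepted)
  expect_lt(cts[[1]]$mean_intensity, par$min_intensity)
})

test_that("segment_bone recovers the clean phantom silhouette", {
  for (fix in list(list(ph = clean_corpus(), ct = corpus_contour()),
                   list(ph = clean_manubrium(),
                        ct = manubrium_contour()))) {
    iou <- polygon_iou(fix$ct$poly, fix$ph$truth$outline,
                       nrow(fix$ph$image$pixels),
                       ncol(fix$ph$image$pixels))
    expect_gt(iou, 0.95)
  }
})

test_that("segmentation is deterministic and survives corruption", {
  ph <- clean_corpus()
  cs <- corruption_spec(n_breaks = 2, n_blobs = 3, seed = 5)
  img <- corrupt_image(ph$image, ph$truth, cs)
  ct1 <- segment_bone(img)
  ct2 <- segment_bone(img)
  expect_identical(ct1$poly, ct2$poly)     # fully deterministic
  iou <- polygon_iou(ct1$poly, ph$truth$outline, nrow(img$pixels),
                     ncol(img$pixels))
  expect_gt(iou, 0.9)
})

test_that("blank and hopeless images raise stage-naming errors", {
  blank <- bone_image(matrix(0.2, 80, 80), 0.05)
  expect_error(segment_bone(blank), "adaptive threshold")
  # speckle-only image: candidates survive nowhere after classification
  set.seed(2)
  noisy <- bone_image(matrix(runif(6400), 80, 80), 0.05)
  expect_error(segment_bone(noisy), "segmentation failed")
})
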