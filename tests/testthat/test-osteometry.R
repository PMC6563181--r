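# Landmark detection, candidate clustering, measurement, indices,
# parameter training.

make_rect_contour <- function(h = 190, w = 53, nr = 240, nc = 100) {
  m <- matrix(FALSE, nr, nc)
  r0 <- (nr - h) %/% 2; c0 <- (nc - w) %/% 2
  m[r0:(r0 + h), c0:(c0 + w)] <- TRUE       # (h+1) x (w+1) block: side h, w
  chain <- which(sternometry:::border_pixels(m), arr.ind = TRUE)
  trace_contours(list(chain), bone_image(matrix(1, nr, nc), 0.05))[[1]]
}

test_that("axis-aligned rectangle as corpus: B spans the long side", {
  ct <- make_rect_contour()
  lm <- suppressWarnings(find_landmarks(ct, "corpus"))
  rec <- measure_bone(lm, 0.05)
  expect_equal(rec$B, 190 * 0.05, tolerance = 0.02)    # 9.50 cm
  # endpoints at the midpoints of the two short sides
  b <- lm$landmarks$B
  expect_equal(sort(c(b$p1[2], b$p2[2])), c(25, 215), tolerance = 1.5)
  expect_equal(b$p1[1], 50, tolerance = 1.5)
  expect_equal(b$p2[1], 50, tolerance = 1.5)
  # plain rectangle has no costal notches: widths fall back, flagged
  expect_warning(find_landmarks(ct, "corpus"), "costal notch")
  expect_true(all(c("CSW1", "CSW2") %in% lm$flagged))
  expect_equal(rec$CSW1, 53 * 0.05, tolerance = 0.1)
})

test_that("convex ellipse as manubrium raises a missing-landmark error", {
  th <- seq(0, 2 * pi, length.out = 400)
  m <- matrix(FALSE, 120, 160)
  pts <- unique(cbind(round(60 + 40 * sin(th)), round(80 + 65 * cos(th))))
  m[pts] <- TRUE
  filled <- EBImage::fillHull(m * 1) > 0
  chain <- which(sternometry:::border_pixels(filled), arr.ind = TRUE)
  ct <- trace_contours(list(chain), bone_image(matrix(1, 120, 160),
                                               0.05))[[1]]
  expect_error(find_landmarks(ct, "manubrium"), "incisura")
})

test_that("noise-free phantom landmarks sit within 2 px of the truth", {
  cases <- list(list(ph = clean_corpus(), ct = corpus_contour(),
                     kind = "corpus"),
                list(ph = clean_manubrium(), ct = manubrium_contour(),
                     kind = "manubrium"))
  for (cs in cases) {
    lm <- find_landmarks(cs$ct, cs$kind)
    for (m in names(cs$ph$truth$lengths)) {
      det <- lm$landmarks[[m]]
      tru <- cs$ph$truth$landmarks[[m]]
      d1 <- sqrt(sum((det$p1 - tru[1, ])^2))
      d2 <- sqrt(sum((det$p2 - tru[2, ])^2))
      # symmetric landmarks may legitimately come back mirrored
      d1m <- sqrt(sum((det$p1 - tru[2, ])^2))
      d2m <- sqrt(sum((det$p2 - tru[1, ])^2))
      expect_lt(min(max(d1, d2), max(d1m, d2m)), 2)
    }
  }
})

test_that("single candidate passes through clustering unchanged", {
  out <- cluster_candidates(9.4)
  expect_equal(out$value, 9.4)
  expect_equal(out$index, 1L)
  expect_error(cluster_candidates(numeric(0)), "no candidates")
})

test_that("clustering isolates the outlier and keeps the dense cluster", {
  out <- cluster_candidates(c(9.4, 9.5, 9.45, 12.0))
  expect_equal(sort(unique(out$cluster)), 1:2)
  expect_equal(out$cluster[4], max(out$cluster))       # 12.0 isolated
  expect_true(out$value %in% c(9.4, 9.45, 9.5))
  # independent oracle: single-linkage tree cut at the gap threshold
  x <- c(9.4, 9.5, 9.45, 12.0)
  hc <- hclust(dist(x), method = "single")
  oracle <- cutree(hc, h = 0.05 * median(x))
  expect_equal(length(unique(out$cluster)), length(unique(oracle)))
})

test_that("population tie between clusters resolves by confidence", {
  out <- cluster_candidates(c(5.0, 5.02, 8.0, 8.02),
                            confidence = c(0.5, 0.4, 0.9, 0.2))
  expect_equal(out$value, 8.0)
  out2 <- cluster_candidates(c(5.0, 5.02, 8.0, 8.02),
                             confidence = c(0.95, 0.4, 0.9, 0.2))
  expect_equal(out2$value, 5.0)
})

test_that("clustering equals the single-linkage oracle on random sweeps", {
  set.seed(99)
  for (rep in 1:60) {
    n <- sample(2:6, 1)
    x <- round(runif(n, 2, 12), 2)
    gap <- 0.05 * median(x)
    out <- cluster_candidates(x, gap = gap)
    if (length(unique(x)) == 1) next
    hc <- hclust(dist(x), method = "single")
    oracle <- cutree(hc, h = gap + 1e-12)
    expect_equal(length(unique(out$cluster)), length(unique(oracle)))
    # same partition up to relabeling
    expect_equal(unname(split(seq_len(n), out$cluster)[order(
      vapply(split(x, out$cluster), min, 1))]),
      unname(split(seq_len(n), oracle)[order(
        vapply(split(x, oracle), min, 1))]))
  }
})

test_that("measurement converts landmark pixels to centimeters", {
  lm <- structure(list(kind = "corpus", landmarks = list(
    B = list(p1 = c(0, 0), p2 = c(3, 4), confidence = 1)),
    flagged = character(0)), class = "landmark_configuration")
  expect_equal(measure_bone(lm, 1)$B, 5)
  expect_error(measure_bone(lm, 0), "spacing")
  expect_error(measure_bone(lm, -1), "spacing")
})

test_that("phantom round trip recovers B within one pixel", {
  ph <- render_phantom(c(B = 9.46, CSW1 = 2.66, CSW2 = 3.11), "corpus",
                       seed = 33)
  rec <- measure_bone(find_landmarks(segment_bone(ph$image), "corpus"),
                      ph$image$spacing)
  expect_lt(abs(rec$B - 9.46), 0.05)
})

test_that("indices follow their defining formulas", {
  expect_equal(compute_indices(c(M = 7, MW = 3, B = 7, CSW1 = 3,
                                 CSW2 = 3))$SI, 100)
  idx <- compute_indices(c(M = 5, MW = 3, B = 10, CSW1 = 3, CSW2 = 3))
  expect_equal(idx$SI, 50)
  expect_equal(idx$CL, 15)
  expect_equal(idx$SA, 45)
  # published mean automatic values
  idx2 <- compute_indices(c(M = 5.25, MW = 5.63, B = 9.46, CSW1 = 2.66,
                            CSW2 = 3.11))
  expect_equal(idx2$SI, 55.4968, tolerance = 1e-4)
  expect_equal(idx2$CL, 14.71)
  expect_equal(idx2$SA, 55.898, tolerance = 1e-3)
  expect_error(compute_indices(c(M = 5, MW = 3, B = 10, CSW1 = 3)),
               "CSW2")
})

test_that("index invariants hold over a thousand random records", {
  recs <- random_records(1000, seed = 7)
  idx <- compute_indices(recs)
  expect_true(all(abs(idx$SI - 100 * recs$M / recs$B) < 1e-9))
  expect_true(all(abs(idx$CL - (recs$M + recs$B)) < 1e-9))
  expect_true(all(abs(idx$SA - (recs$M + recs$B) *
                        (recs$MW + recs$CSW1 + recs$CSW2) / 3) < 1e-9))
  expect_true(all(idx$SI > 0 & idx$SA > 0 & idx$CL > 0))
})

test_that("training on clean phantoms reaches full efficiency", {
  ph1 <- render_phantom(c(B = 9.0, CSW1 = 2.6, CSW2 = 3.0), "corpus",
                        seed = 41)
  ph2 <- render_phantom(c(B = 10.0, CSW1 = 2.9, CSW2 = 3.4), "corpus",
                        seed = 42)
  training <- lapply(list(ph1, ph2), function(p)
    list(image = p$image, reference = p$truth))
  grid <- list(segmentation_params())
  res <- tune_parameters(training, grid)
  expect_s3_class(res, "training_result")
  expect_equal(res$efficiency, 1)
  expect_identical(res$params, grid[[1]])
})

test_that("an absurd singleton grid still returns with zero efficiency", {
  ph <- render_phantom(c(B = 9.0, CSW1 = 2.6, CSW2 = 3.0), "corpus",
                       seed = 43)
  grid <- list(segmentation_params(offset = 10))   # above max intensity
  res <- tune_parameters(list(list(image = ph$image,
                                   reference = ph$truth)), grid)
  expect_equal(res$efficiency, 0)
  expect_identical(res$params, grid[[1]])
  expect_error(tune_parameters(list(), grid), "empty training")
  expect_error(tune_parameters(list(list(image = ph$image,
                                         reference = ph$truth)),
                               list()), "empty parameter grid")
})

test_that("measurements are invariant under 90-degree rotation", {
  ph <- clean_corpus()
  rec <- measure_bone(find_landmarks(corpus_contour(), "corpus"),
                      ph$image$spacing)
  rot <- bone_image(rot90cw(ph$image$pixels), ph$image$spacing,
                    kind = "corpus")
  rec_rot <- measure_bone(find_landmarks(segment_bone(rot), "corpus"),
                          ph$image$spacing)
  for (m in c("B", "CSW1", "CSW2"))
    expect_lt(abs(rec[[m]] - rec_rot[[m]]), 1 * ph$image$spacing)
})

test_that("measurements are equivariant under upsampling", {
  ph <- clean_manubrium()
  rec <- measure_bone(find_landmarks(manubrium_contour(), "manubrium"),
                      ph$image$spacing)
  # bilinear 2x upsampling with halved spacing
  pix <- ph$image$pixels
  up <- matrix(0, 2 * nrow(pix), 2 * ncol(pix))
  r_src <- pmin(pmax((seq_len(2 * nrow(pix)) + 0.5) / 2, 1), nrow(pix))
  c_src <- pmin(pmax((seq_len(2 * ncol(pix)) + 0.5) / 2, 1), ncol(pix))
  r0 <- floor(r_src); r1 <- pmin(r0 + 1, nrow(pix)); fr <- r_src - r0
  c0 <- floor(c_src); c1 <- pmin(c0 + 1, ncol(pix)); fc <- c_src - c0
  up <- (1 - fr) * ((1 - matrix(fc, length(r0), length(c0),
                                byrow = TRUE)) * pix[r0, c0] +
                      matrix(fc, length(r0), length(c0),
                             byrow = TRUE) * pix[r0, c1]) +
    fr * ((1 - matrix(fc, length(r0), length(c0), byrow = TRUE)) *
            pix[r1, c0] +
            matrix(fc, length(r0), length(c0), byrow = TRUE) * pix[r1, c1])
  img2 <- bone_image(up, ph$image$spacing / 2, kind = "manubrium")
  rec2 <- measure_bone(find_landmarks(segment_bone(img2), "manubrium"),
                       img2$spacing)
  for (m in c("M", "MW"))
    expect_lt(abs(rec[[m]] - rec2[[m]]), 2 * img2$spacing)
})
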