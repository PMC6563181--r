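# Shared fixtures, memoized so expensive renders/segmentations run once
# per test session.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (is.null(.fixture_cache[[name]])) assign(name, fn(), .fixture_cache)
  .fixture_cache[[name]]
}

clean_corpus <- function()
  fixture("clean_corpus", function()
    render_phantom(c(B = 9.46, CSW1 = 2.66, CSW2 = 3.11), "corpus",
                   seed = 11))

clean_manubrium <- function()
  fixture("clean_manubrium", function()
    render_phantom(c(M = 5.25, MW = 5.63), "manubrium", seed = 12))

corpus_contour <- function()
  fixture("corpus_contour", function() segment_bone(clean_corpus()$image))

manubrium_contour <- function()
  fixture("manubrium_contour", function()
    segment_bone(clean_manubrium()$image))

truth_length <- function(truth, m) {
  lm <- truth$landmarks[[m]]
  sqrt(sum((lm[1, ] - lm[2, ])^2)) * truth$spacing
}

# intersection-over-union of two polygons on a shared raster
polygon_iou <- function(poly1, poly2, nr, nc) {
  r1 <- sternometry:::raster_polygon(poly1, nr, nc)
  r2 <- sternometry:::raster_polygon(poly2, nr, nc)
  sum(r1 & r2) / sum(r1 | r2)
}

# 90-degree clockwise rotation of a matrix (image)
rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

# random measurement record tables for round-trip tests
random_records <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    source = rep("automatic", n),
    sex = rep(sample(c("male", "female"), max(n, 1), replace = TRUE), length.out = n),
    M = runif(n, 4, 7), MW = runif(n, 4.5, 7), B = runif(n, 7, 12),
    CSW1 = runif(n, 2, 3.5), CSW2 = runif(n, 2.2, 4.2))
}
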