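test_that("spread statistic matches hand-enumerated cases", {
  # all intensity in one pixel
  w <- matrix(0, 5, 5); w[3, 3] <- 7
  expect_equal(spread_statistic(w, w > 0)$spread, 0)
  # unit masses at x = 1 and x = 3 in the same row: centroid x = 2,
  # spread = 1^2 + 1^2 = 2
  w2 <- matrix(0, 3, 3); w2[1, 1] <- 1; w2[1, 3] <- 1
  res <- spread_statistic(w2, w2 > 0)
  expect_equal(res$spread, 2)
  expect_equal(res$normalized_spread, 1)
  # doubling weights doubles spread, normalized unchanged
  res2 <- spread_statistic(2 * w2, w2 > 0)
  expect_equal(res2$spread, 2 * res$spread)
  expect_equal(res2$normalized_spread, res$normalized_spread)
})

test_that("two-point symmetric mass at distance 2r has normalized spread r^2", {
  for (r in c(1, 2, 5)) {
    w <- matrix(0, 3, 20); w[2, 3] <- 4; w[2, 3 + 2 * r] <- 4
    expect_equal(spread_statistic(w, w > 0)$normalized_spread, r^2)
  }
})

test_that("spread is invariant under joint translation of mask and signal", {
  set.seed(1)
  w <- matrix(0, 60, 60)
  w[20:30, 20:30] <- runif(121)
  m <- w > 0
  base <- spread_statistic(w, m)
  shifted <- matrix(0, 60, 60); shifted[35:45, 25:35] <- w[20:30, 20:30]
  res <- spread_statistic(shifted, shifted > 0)
  expect_equal(res$spread, base$spread)
  expect_equal(res$normalized_spread, base$normalized_spread)
})

test_that("degenerate spread inputs raise errors", {
  w <- matrix(0, 4, 4)
  expect_error(spread_statistic(w, w > 0), "empty signal")
  expect_error(spread_statistic(w, matrix(TRUE, 4, 4)), "empty signal")
})

test_that("puncta summaries count and average per group", {
  img <- matrix(0, 40, 40)
  img[5:7, 5:7] <- 10 / 9      # total 10
  img[15:17, 5:7] <- 20 / 9    # total 20
  img[25:27, 5:7] <- 30 / 9    # total 30
  pun <- segment_by_intensity_threshold(img, threshold = 0.5, min_area = 5)
  s <- puncta_summary(pun, "image")
  expect_equal(s$n_puncta, 3)
  expect_equal(s$mean_total_intensity, 20)
  # all in cell 0 (no partition): per-cell view groups them together
  sc <- puncta_summary(pun, "cell")
  expect_equal(sc$n_puncta, 3)
  # empty set
  empty <- segment_by_intensity_threshold(matrix(0, 10, 10), threshold = 1)
  expect_equal(puncta_summary(empty, "image")$n_puncta, 0)
  expect_true(is.na(puncta_summary(empty, "image")$mean_total_intensity))
  expect_equal(nrow(puncta_summary(empty, "cell")), 0)
})

test_that("fixed colocalization counts pixel-overlapping puncta", {
  sq <- function(r0, c0, size = 3) {
    img <- matrix(0, 50, 50); img[r0:(r0 + size - 1), c0:(c0 + size - 1)] <- 10
    img
  }
  # channel 1: 4 puncta; channel 2: one overlapping the first ch1 punctum
  ch1 <- sq(5, 5) + sq(5, 20) + sq(20, 5) + sq(20, 20)
  ch2 <- sq(6, 6)
  p1 <- segment_by_intensity_threshold(ch1, 5, min_area = 5)
  p2 <- segment_by_intensity_threshold(ch2, 5, min_area = 5)
  res <- colocalize_fixed(p1, p2)
  expect_equal(res$n_puncta_ch1, 4)
  expect_equal(res$n_overlapping, 1)
  expect_equal(res$percent, 25)
  # identical sets -> 100%; asymmetry: ch2 vs ch1 is also 100% here,
  # but 1-vs-4 swapped gives 100 not 25
  expect_equal(colocalize_fixed(p1, p1)$percent, 100)
  expect_equal(colocalize_fixed(p2, p1)$percent, 100)
  # disjoint -> 0
  p3 <- segment_by_intensity_threshold(sq(40, 40), 5, min_area = 5)
  expect_equal(colocalize_fixed(p1, p3)$percent, 0)
})

test_that("cells without reference puncta give missing, not zero, percent", {
  empty <- segment_by_intensity_threshold(matrix(0, 20, 20), 5)
  img <- matrix(0, 20, 20); img[5:7, 5:7] <- 10
  p2 <- segment_by_intensity_threshold(img, 5, min_area = 5)
  res <- colocalize_fixed(empty, p2)
  expect_true(is.na(res$percent))
  expect_equal(res$n_puncta_ch1, 0)
})

test_that("zone quantification assigns centroids to half-open rectangles", {
  px_nm <- 110
  # a 300 um^2 rectangle: width * height * (0.11 um)^2 = 300
  side_px <- sqrt(300) / 0.11          # square option
  w_px <- round(side_px); h_px <- (300 / 0.11^2) / w_px
  img <- matrix(0, 400, 400)
  # 3 puncta in the "apical" zone, 5 in "upper_basal"
  for (cx in c(20, 40, 60)) img[10:12, (cx):(cx + 2)] <- 10
  for (cx in c(20, 50, 80, 110, 140)) img[200:202, cx:(cx + 2)] <- 10
  pun <- segment_by_intensity_threshold(img, 5, min_area = 5)
  zones <- list(zone_rect("apical", 1, 1, w_px, h_px),
                zone_rect("upper_basal", 1, 190, w_px, h_px))
  res <- quantify_zones(pun, zones, pixel_size_nm = px_nm)
  expect_equal(res$n_puncta, c(3, 5))
  # wrong-area rectangle errors with the measured area
  bad <- list(zone_rect("yolk", 1, 1, 10, 10))
  expect_error(quantify_zones(pun, bad, pixel_size_nm = px_nm), "area")
  # a punctum on a shared boundary is counted exactly once
  zb <- list(zone_rect("a", 1, 1, w_px, h_px),
             zone_rect("b", 1, 1 + h_px, w_px, h_px))
  img2 <- matrix(0, 400, 400); img2[round(1 + h_px) + (-1:1), 30:32] <- 10
  pun2 <- segment_by_intensity_threshold(img2, 5, min_area = 5)
  res2 <- quantify_zones(pun2, zb, pixel_size_nm = px_nm)
  expect_equal(sum(res2$n_puncta), 1)
})
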