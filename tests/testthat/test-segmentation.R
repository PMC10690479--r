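test_that("well-separated nuclei are segmented one label each", {
  set.seed(1)
  centers <- rbind(c(25, 25), c(75, 30), c(50, 80))
  img <- disk_image(100, 100, centers, radius = 8, noise_sd = 3)
  nuc <- segment_nuclei(img, rolling_ball_radius = 15, pfa = 1e-3)
  expect_equal(max(nuc$labels), 3)
  # labels contiguous
  expect_setequal(unique(as.integer(nuc$labels[nuc$labels > 0])), 1:3)
})

test_that("PFA thresholds realize their nominal false-alarm rates", {
  set.seed(2)
  img <- matrix(rnorm(2000 * 2000, 100, 5), 2000, 2000)
  for (pfa in c(1e-2, 1e-3, 1e-4)) {
    thr <- threshold_pfa(img, pfa)
    emp <- mean(img > thr)
    se <- sqrt(pfa * (1 - pfa) / length(img))
    expect_lt(abs(emp - pfa), 3 * se + 0.05 * pfa)
  }
})

test_that("watershed splits touching nuclei, and can be disabled", {
  set.seed(3)
  img <- disk_image(80, 80, rbind(c(32, 40), c(48, 40)), radius = 9,
                    noise_sd = 2)
  on <- segment_nuclei(img, rolling_ball_radius = 15, watershed = TRUE)
  off <- segment_nuclei(img, rolling_ball_radius = 15, watershed = FALSE)
  expect_equal(max(on$labels), 2)
  expect_equal(max(off$labels), 1)
})

test_that("a constant image has no defined threshold", {
  expect_error(segment_nuclei(matrix(5, 50, 50)), "degenerate background")
  expect_error(threshold_pfa(matrix(5, 50, 50), 1e-3), "degenerate")
})

test_that("regions touching the border are discarded", {
  L <- matrix(0L, 40, 40)
  L[10:15, 10:15] <- 1L     # interior
  L[1:5, 20:25] <- 2L       # touches row 1
  L[30:40, 38:40] <- 3L     # touches last row/col
  out <- discard_border_regions(labeled_mask(L))
  expect_equal(max(out$labels), 1)
  expect_true(all(out$labels[10:15, 10:15] == 1))
  all_border <- labeled_mask(rbind(rep(1L, 10), matrix(0L, 9, 10)))
  expect_equal(max(discard_border_regions(all_border)$labels), 0)
})

test_that("foreground mask thresholds at the intensity quantile", {
  img <- cbind(matrix(0, 40, 20), matrix(10, 40, 20))
  m <- foreground_mask(img, smooth_sigma = 0, quantile = 0.5)
  expect_identical(m, img > 5)
  # shift-equivariance of the quantile: adding a constant changes nothing
  m2 <- foreground_mask(img + 37, smooth_sigma = 0, quantile = 0.5)
  expect_identical(m, m2)
  # quantile -> 0 keeps everything
  m3 <- foreground_mask(img + 1, smooth_sigma = 0, quantile = 1e-9)
  expect_true(all(m3))
})

test_that("EDT cell assignment matches brute-force nearest-nucleus search", {
  for (seed in 1:3) {
    set.seed(seed)
    centers <- cbind(sample(10:54, 3), sample(10:54, 3))
    nuclei <- disk_mask(64, 64, centers, radius = 5)
    fg <- matrix(runif(64 * 64) < 0.7, 64, 64)
    part <- assign_cells_by_edt(nuclei, fg)
    oracle <- brute_force_edt_assign(nuclei$labels, part$foreground_mask)
    expect_identical(part$cell_of_pixel, oracle)
  }
})

test_that("EDT assignment basics: single nucleus, proximity, no-cell error", {
  nuclei <- disk_mask(50, 50, rbind(c(25, 25)), radius = 6)
  fg <- matrix(TRUE, 50, 50)
  part <- assign_cells_by_edt(nuclei, fg)
  expect_true(all(part$cell_of_pixel == 1))
  two <- disk_mask(50, 50, rbind(c(10, 25), c(40, 25)), radius = 4)
  part2 <- assign_cells_by_edt(two, fg)
  expect_equal(part2$cell_of_pixel[25, 12], 1L)  # near nucleus A
  expect_equal(part2$cell_of_pixel[25, 38], 2L)  # near nucleus B
  empty <- labeled_mask(matrix(0L, 20, 20))
  expect_error(assign_cells_by_edt(empty, matrix(TRUE, 20, 20)), "no cells")
})

test_that("LoG puncta detection finds rendered spots and ignores offsets", {
  spec <- scene_spec(image_shape = c(128, 128), n_cells = 0,
                     puncta_per_cell = 0, background_level = 100,
                     noise_model = list(type = "poisson"), seed = 7)
  set.seed(7)
  x <- runif(12, 10, 118); y <- runif(12, 10, 118)
  img <- punctatrack:::render_gaussians(128, 128, x, y, 3000, 1.5) + 100
  img <- matrix(rpois(length(img), img), 128, 128)
  pun <- detect_puncta_log(img, log_sigma = 1.5, threshold = 8,
                           threshold_mode = "mad")
  expect_equal(nrow(pun$table), 12)
  err <- vapply(seq_along(x), function(i)
    min(sqrt((pun$table$centroid_x_px - x[i])^2 +
             (pun$table$centroid_y_px - y[i])^2)), numeric(1))
  expect_true(all(err < 1))
  # LoG kills constants: offset leaves the result unchanged
  pun2 <- detect_puncta_log(img + 500, log_sigma = 1.5, threshold = 8,
                            threshold_mode = "mad")
  expect_equal(pun$table, pun2$table, tolerance = 1e-8)
  # blank image: nothing detected with an absolute threshold
  expect_equal(nrow(detect_puncta_log(matrix(0, 64, 64), threshold = 1)$table), 0)
})

test_that("small particles are removed by the 5-pixel area filter", {
  img <- matrix(0, 40, 40)
  img[5:6, 5:6] <- 10          # 4 px
  img[20:22, 20:21] <- 10      # 6 px
  pun <- segment_by_intensity_threshold(img, threshold = 5, min_area = 5)
  expect_equal(nrow(pun$table), 1)
  expect_equal(pun$table$area_px, 6)
  # a 9-px square survives with its full area
  img2 <- matrix(0, 30, 30); img2[10:12, 10:12] <- 7
  pun2 <- segment_by_intensity_threshold(img2, threshold = 5, min_area = 5)
  expect_equal(pun2$table$area_px, 9)
  # uniform image below threshold -> empty
  expect_equal(nrow(segment_by_intensity_threshold(matrix(1, 20, 20), 5)$table), 0)
})

test_that("puncta components are 8-connected", {
  img <- matrix(0, 20, 20)
  # a diagonal chain of pixels: one object under 8-connectivity
  for (i in 1:6) img[5 + i, 5 + i] <- 10
  pun <- segment_by_intensity_threshold(img, threshold = 5, min_area = 5)
  expect_equal(nrow(pun$table), 1)
  expect_equal(pun$table$area_px, 6)
})
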