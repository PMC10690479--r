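test_that("a noise-free Gaussian spot is recovered with subpixel accuracy", {
  img <- punctatrack:::render_gaussians(41, 41, 20.37, 21.62,
                                        2 * pi * 100 * 1.5^2, 1.5) + 10
  spots <- detect_spots(img, pfa = 1e-4)
  expect_equal(nrow(spots), 1)
  expect_lt(abs(spots$x - 20.37), 0.05)
  expect_lt(abs(spots$y - 21.62), 0.05)
  expect_lt(abs(spots$sigma - 1.5) / 1.5, 0.05)
  # integrated intensity = 2 pi A sigma^2 by construction of the fit
  expect_equal(spots$integrated_intensity,
               2 * pi * spots$amplitude * spots$sigma^2)
})

test_that("two well-separated spots give exactly two detections", {
  set.seed(1)
  img <- punctatrack:::render_gaussians(64, 64, c(20, 40), c(20, 40),
                                        4000, 1.5) + 100
  img <- matrix(rpois(length(img), img), 64, 64)
  spots <- detect_spots(img, pfa = 1e-4)
  expect_equal(nrow(spots), 2)
})

test_that("false detections on pure noise scale with the requested pfa", {
  set.seed(2)
  n_det <- n_cand <- 0
  for (i in 1:100) {
    fr <- matrix(rnorm(96 * 96, 100, 5), 96, 96)
    d <- detect_spots(fr, pfa = 0.01)
    n_det <- n_det + nrow(d) + attr(d, "n_failed_fits")
    n_cand <- n_cand + attr(d, "n_candidates")
  }
  expected <- 0.01 * n_cand
  # the null level is estimated from the candidates themselves; allow a
  # factor-2 band around the nominal rate
  expect_gt(n_det, expected / 2)
  expect_lt(n_det, expected * 2)
})

test_that("linking follows a drifting spot and keeps separate spots apart", {
  drift <- do.call(rbind, lapply(1:20, function(f)
    data.frame(frame = f, x = 10 + f, y = 15)))
  tr <- link_tracks(drift, max_disp = 3)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), 20)
  two <- do.call(rbind, lapply(1:15, function(f)
    data.frame(frame = f, x = c(10, 60), y = c(10, 10))))
  tr2 <- link_tracks(two, max_disp = 5)
  expect_equal(length(unique(tr2$track_id)), 2)
  expect_true(all(table(tr2$track_id) == 15))
})

test_that("linking recovers ground-truth correspondences of diffusing spots", {
  tr <- simulate_trajectories(motion_spec("diffusive", n_particles = 10,
                                          n_frames = 50, D = 1e4,
                                          origin_spread_nm = 2e4, seed = 6))
  spots <- data.frame(frame = tr$frame, x = tr$x_nm / 110, y = tr$y_nm / 110,
                      gt = tr$track_id)
  linked <- link_tracks(spots, max_disp = 5)
  # every reconstructed track must stay on one ground-truth particle
  purity <- vapply(split(linked$gt, linked$track_id),
                   function(g) max(table(g)) / length(g), numeric(1))
  correct <- sum(vapply(split(linked, linked$track_id), function(t1)
    sum(diff(t1$gt) == 0), numeric(1)))
  total <- nrow(spots) - 10
  expect_gte(correct / total, 0.9)
  expect_true(mean(purity) > 0.9)
})

test_that("gap closing bridges a missed detection when memory allows", {
  spots <- data.frame(frame = c(1, 2, 4, 5), x = c(10, 11, 13, 14), y = 5)
  no_mem <- link_tracks(spots, max_disp = 3, memory = 0)
  expect_equal(length(unique(no_mem$track_id)), 2)
  mem <- link_tracks(spots, max_disp = 3, memory = 1)
  expect_equal(length(unique(mem$track_id)), 1)
})

test_that("tracks below 10 points are discarded, 10-point tracks kept", {
  nine <- make_track(1, 1:9, rep(1, 9))
  ten <- make_track(2, 1:10, rep(2, 10))
  both <- rbind(nine, ten)
  out <- filter_tracks(both, min_points = 10)
  expect_equal(unique(out$track_id), 2)
  expect_equal(nrow(filter_tracks(both[0, ], 10)), 0)
})

test_that("tracks outside the region of interest are removed", {
  inside <- make_track(1, rep(5, 12), rep(5, 12))
  outside <- make_track(2, rep(50, 12), rep(50, 12))
  roi <- cbind(x = c(0, 10, 10, 0), y = c(0, 0, 10, 10))
  out <- filter_tracks(rbind(inside, outside), min_points = 10, roi = roi)
  expect_equal(unique(out$track_id), 1)
})

test_that("track mean intensity averages the integrated Gaussian areas", {
  tr <- data.frame(track_id = 1, frame = 1:2, x = 0, y = 0,
                   integrated_intensity = 2 * pi * c(1, 3) * 1^2)
  expect_equal(track_mean_intensity(tr)$mean_intensity, 4 * pi)
})
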