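test_that("empty scene is a constant background with empty ground truth", {
  spec <- scene_spec(n_cells = 0, puncta_per_cell = 0, background_level = 10,
                     noise_model = list(type = "gaussian", sd = 0))
  out <- render_fixed_cell_scene(spec)
  expect_true(all(out$scene$data == 10))
  expect_equal(nrow(out$truth$nuclei), 0)
  expect_equal(nrow(out$truth$puncta), 0)
})

test_that("scene rendering is a pure function of its spec", {
  spec <- scene_spec(n_cells = 2, puncta_per_cell = 8, seed = 42)
  a <- render_fixed_cell_scene(spec)
  b <- render_fixed_cell_scene(spec)
  expect_identical(a$scene$data, b$scene$data)
  expect_identical(a$truth, b$truth)
  # and does not disturb the session RNG
  set.seed(7); before <- rnorm(3)
  set.seed(7); invisible(render_fixed_cell_scene(spec)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("puncta dispersion around the nucleus matches the spec value", {
  # large count so the mean squared radial deviation (2 * sigma^2 for an
  # isotropic Gaussian) is estimated with small error
  spec <- scene_spec(image_shape = c(512, 512), n_cells = 1,
                     puncta_per_cell = 400, dispersion_px = 30, seed = 3)
  out <- render_fixed_cell_scene(spec)
  p <- out$truth$puncta
  nuc <- out$truth$nuclei
  d2 <- (p$x - nuc$x)^2 + (p$y - nuc$y)^2
  # d2 / sigma^2 ~ chi^2(2): mean 2 sigma^2, sd of the mean = 2 sigma^2 / sqrt(n)
  expect_lt(abs(mean(d2) - 2 * 30^2), 3 * 2 * 30^2 / sqrt(nrow(p)))
})

test_that("nucleus placement failure is reported, not silent", {
  spec <- scene_spec(image_shape = c(64, 64), n_cells = 30,
                     nucleus_radius_px = 12)
  expect_error(render_fixed_cell_scene(spec), "non-overlapping nuclei")
})

test_that("bead movies render identical positions in both channels", {
  spec <- scene_spec(image_shape = c(96, 96),
                     noise_model = list(type = "none"), seed = 5)
  out <- render_bead_movie(n_beads = 10, n_frames = 6, spec = spec)
  expect_equal(dim(out$scene$data), c(6, 2, 96, 96))
  # noise-free: channels bit-identical, beads immobile => frames identical
  expect_identical(out$scene$data[, 1, , ], out$scene$data[, 2, , ])
  expect_identical(out$scene$data[1, 1, , ], out$scene$data[6, 1, , ])
  expect_equal(nrow(out$truth), 10)
})

test_that("a single rendered bead is detected at its true position", {
  spec <- scene_spec(image_shape = c(64, 64),
                     puncta_intensity = c(mean = 5000, sd = 0),
                     noise_model = list(type = "poisson"), seed = 8)
  out <- render_bead_movie(n_beads = 1, n_frames = 5, spec = spec)
  for (ch in 1:2) {
    spots <- detect_spots_movie(out$scene, channel = ch, pfa = 1e-6)
    expect_equal(nrow(spots), 5)   # exactly one per frame
    err <- sqrt((spots$x - out$truth$x)^2 + (spots$y - out$truth$y)^2)
    expect_true(all(err < 0.2))
  }
})

test_that("movies rendered from trajectories honour the track positions", {
  spec <- scene_spec(image_shape = c(48, 48),
                     noise_model = list(type = "none"), seed = 2)
  empty <- data.frame(track_id = integer(0), frame = integer(0),
                      x_nm = numeric(0), y_nm = numeric(0))
  mov <- render_movie_from_trajectories(empty, spec, n_frames = 3)
  expect_true(all(mov$data == spec$background_level))
  still <- data.frame(track_id = 1L, frame = 1:4,
                      x_nm = rep(24 * 110, 4), y_nm = rep(24 * 110, 4))
  mov2 <- render_movie_from_trajectories(still, spec)
  for (t in 2:4)
    expect_identical(mov2$data[t, 1, , ], mov2$data[1, 1, , ])
  outside <- data.frame(track_id = 1L, frame = 1L, x_nm = 1e6, y_nm = 0)
  expect_error(render_movie_from_trajectories(outside, spec), "bounds")
})

test_that("Poisson renders preserve the noise-free per-pixel mean", {
  spec <- scene_spec(image_shape = c(256, 256), n_cells = 0,
                     puncta_per_cell = 0, background_level = 50,
                     noise_model = list(type = "poisson"), seed = 6)
  out <- render_fixed_cell_scene(spec)
  px <- as.numeric(out$scene$data[1, 1, , ])
  expect_lt(abs(mean(px) - 50), 3 * sqrt(50 / length(px)))
})
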