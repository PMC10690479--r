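## Synthetic fixed-cell scenes and movies with known ground truth.
##
## Every generator is a pure function of its spec (including the seed): the
## same spec always yields bit-identical output, and ground truth is emitted
## alongside every artifact so downstream estimators can be scored exactly.

#' Specification of a synthetic fixed-cell scene
#'
#' Describes a field of view containing disk-shaped nuclei (channel 1) and
#' diffraction-limited puncta (channel 2) scattered around each nucleus.
#' The point-spread function is an isotropic 2D Gaussian integrated over
#' each pixel, so a punctum's summed pixel values equal its integrated
#' intensity in photons.
#'
#' @param image_shape integer (H, W) in pixels.
#' @param pixel_size_nm physical pixel size, nm/px.
#' @param n_cells number of cells (nuclei) to place.
#' @param nucleus_radius_px nucleus disk radius in pixels.
#' @param puncta_per_cell puncta rendered per cell.
#' @param puncta_intensity c(mean, sd) of per-punctum integrated intensity
#'   (photons).
#' @param puncta_sigma_px PSF standard deviation in pixels.
#' @param dispersion_px standard deviation of puncta placement around the
#'   nucleus centroid, pixels.
#' @param background_level constant background, photons.
#' @param noise_model list(type = "none" | "poisson" | "gaussian", sd = ...).
#' @param seed integer RNG seed.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(image_shape = c(256L, 256L), pixel_size_nm = 110,
                       n_cells = 3L, nucleus_radius_px = 15,
                       puncta_per_cell = 20L,
                       puncta_intensity = c(mean = 2000, sd = 200),
                       puncta_sigma_px = 1.5, dispersion_px = 25,
                       background_level = 100,
                       noise_model = list(type = "poisson"),
                       seed = 1L) {
  stopifnot(length(image_shape) == 2L, all(image_shape >= 8),
            pixel_size_nm > 0, n_cells >= 0, nucleus_radius_px > 0,
            puncta_per_cell >= 0, puncta_sigma_px > 0, dispersion_px >= 0,
            background_level >= 0)
  if (is.character(noise_model)) noise_model <- list(type = noise_model)
  stopifnot(noise_model$type %in% c("none", "poisson", "gaussian"))
  structure(list(image_shape = as.integer(image_shape),
                 pixel_size_nm = pixel_size_nm, n_cells = as.integer(n_cells),
                 nucleus_radius_px = nucleus_radius_px,
                 puncta_per_cell = as.integer(puncta_per_cell),
                 puncta_intensity = puncta_intensity,
                 puncta_sigma_px = puncta_sigma_px,
                 dispersion_px = dispersion_px,
                 background_level = background_level,
                 noise_model = noise_model, seed = as.integer(seed)),
            class = "scene_spec")
}

## Place n_cells nucleus centers so that nucleus disks do not overlap;
## bounded rejection sampling, errors out naming the constraint.
place_nuclei <- function(h, w, n, radius, max_tries = 2000L) {
  if (n == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  margin <- radius + 2
  if (2 * margin >= min(h, w))
    stop("nucleus radius too large for image: cannot place non-overlapping nuclei")
  cx <- numeric(0); cy <- numeric(0)
  tries <- 0L
  while (length(cx) < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("overlapping-nuclei placement failure: could not place ", n,
           " non-overlapping nuclei of radius ", radius, " after ", max_tries,
           " tries")
    x <- runif(1, margin, w - margin); y <- runif(1, margin, h - margin)
    if (all(((x - cx)^2 + (y - cy)^2) > (2.2 * radius)^2)) {
      cx <- c(cx, x); cy <- c(cy, y)
    }
  }
  cbind(x = cx, y = cy)
}

## Antialiased disk: pixel coverage approximated by a smooth radial ramp.
render_disk <- function(h, w, x0, y0, radius, level) {
  r <- ceiling(radius + 2)
  c0 <- max(1L, round(x0) - r); c1 <- min(w, round(x0) + r)
  r0 <- max(1L, round(y0) - r); r1 <- min(h, round(y0) + r)
  px <- c0:c1; py <- r0:r1
  dist <- sqrt(outer((py - y0)^2, (px - x0)^2, "+"))
  patch <- level * pmin(1, pmax(0, radius + 0.5 - dist))
  out <- matrix(0, h, w)
  out[py, px] <- patch
  out
}

#' Render a synthetic fixed-cell scene with ground truth
#'
#' Channel 1 holds disk nuclei; channel 2 holds Gaussian puncta placed
#' around each nucleus centroid with isotropic Gaussian dispersion. Both
#' channels share the constant background and the configured noise model.
#'
#' @param spec a [scene_spec].
#' @return list with `scene` (an [image_scene], 1 x 2 x H x W) and
#'   `truth`: `nuclei` (data.frame x, y, cell_id) and `puncta` (data.frame
#'   x, y, intensity, cell_id) with exact subpixel positions.
#' @examples
#' out <- render_fixed_cell_scene(scene_spec(n_cells = 1, puncta_per_cell = 5))
#' nrow(out$truth$puncta)
#' @export
render_fixed_cell_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  h <- spec$image_shape[1]; w <- spec$image_shape[2]
  with_seed(spec$seed, {
    centers <- place_nuclei(h, w, spec$n_cells, spec$nucleus_radius_px)
    nuc <- matrix(0, h, w)
    for (i in seq_len(nrow(centers)))
      nuc <- nuc + render_disk(h, w, centers[i, "x"], centers[i, "y"],
                               spec$nucleus_radius_px, 1000)
    npp <- spec$puncta_per_cell
    if (nrow(centers) > 0L && npp > 0L) {
      cell_id <- rep(seq_len(nrow(centers)), each = npp)
      px <- rep(centers[, "x"], each = npp) + rnorm(length(cell_id), 0, spec$dispersion_px)
      py <- rep(centers[, "y"], each = npp) + rnorm(length(cell_id), 0, spec$dispersion_px)
      px <- pmin(pmax(px, 2), w - 1); py <- pmin(pmax(py, 2), h - 1)
      pint <- pmax(rnorm(length(cell_id), spec$puncta_intensity[["mean"]],
                         spec$puncta_intensity[["sd"]]), 1)
    } else {
      cell_id <- integer(0); px <- py <- pint <- numeric(0)
    }
    pun <- render_gaussians(h, w, px, py, pint, spec$puncta_sigma_px)
    ch1 <- apply_noise(nuc + spec$background_level, spec$noise_model)
    ch2 <- apply_noise(pun + spec$background_level, spec$noise_model)
    data <- array(0, c(1L, 2L, h, w))
    data[1, 1, , ] <- ch1; data[1, 2, , ] <- ch2
    list(scene = image_scene(data, spec$pixel_size_nm),
         truth = list(
           nuclei = data.frame(x = centers[, "x"], y = centers[, "y"],
                               cell_id = seq_len(nrow(centers))),
           puncta = data.frame(x = px, y = py, intensity = pint,
                               cell_id = cell_id)))
  })
}

#' Render a two-channel movie of immobile diffraction-limited beads
#'
#' The control used to validate live colocalization: the same subpixel bead
#' positions are rendered in both channels in every frame, so an end-to-end
#' detection + linking + colocalization run must report 100%. Beads are
#' placed at least 6 PSF sigmas apart so each is individually resolvable
#' by a single-emitter fit.
#'
#' @param n_beads number of beads (>= 1).
#' @param n_frames number of frames.
#' @param spec a [scene_spec]; supplies image shape, intensity, PSF width,
#'   background, noise model and seed.
#' @return list with `scene` (T x 2 x H x W [image_scene]) and `truth`
#'   (data.frame bead_id, x, y, intensity — identical in both channels and
#'   constant over time).
#' @export
render_bead_movie <- function(n_beads = 10L, n_frames = 60L, spec = scene_spec()) {
  stopifnot(n_beads >= 1L, n_frames >= 1L, inherits(spec, "scene_spec"))
  h <- spec$image_shape[1]; w <- spec$image_shape[2]
  with_seed(spec$seed, {
    margin <- 6
    # beads must be individually resolvable: enforce a minimum separation
    # of several PSF widths so single-emitter fits are unbiased
    min_sep <- 6 * spec$puncta_sigma_px
    x <- y <- numeric(0)
    tries <- 0L
    while (length(x) < n_beads) {
      tries <- tries + 1L
      if (tries > 5000L)
        stop("bead placement failure: cannot fit ", n_beads,
             " beads at minimum separation ", min_sep, " px")
      xn <- runif(1, margin, w - margin); yn <- runif(1, margin, h - margin)
      if (all(((xn - x)^2 + (yn - y)^2) > min_sep^2)) {
        x <- c(x, xn); y <- c(y, yn)
      }
    }
    intensity <- pmax(rnorm(n_beads, spec$puncta_intensity[["mean"]],
                            spec$puncta_intensity[["sd"]]), 1)
    clean <- render_gaussians(h, w, x, y, intensity, spec$puncta_sigma_px) +
      spec$background_level
    data <- array(0, c(n_frames, 2L, h, w))
    for (t in seq_len(n_frames)) for (ch in 1:2)
      data[t, ch, , ] <- apply_noise(clean, spec$noise_model)
    list(scene = image_scene(data, spec$pixel_size_nm),
         truth = data.frame(bead_id = seq_len(n_beads), x = x, y = y,
                            intensity = intensity))
  })
}

#' Render a movie from ground-truth trajectories
#'
#' Each particle is drawn as an integrated Gaussian at its per-frame
#' position; trajectory positions are in nm (as produced by
#' [simulate_trajectories]) and are converted to pixels with the spec's
#' pixel size.
#'
#' @param tracks data.frame with columns track_id, frame, x_nm, y_nm (a
#'   ground-truth track set).
#' @param spec a [scene_spec]; `puncta_intensity` gives the per-particle
#'   integrated intensity (constant over a track, drawn once per particle).
#' @param n_frames number of frames; defaults to max(tracks$frame).
#' @return an [image_scene] (T x 1 x H x W).
#' @export
render_movie_from_trajectories <- function(tracks, spec = scene_spec(),
                                           n_frames = NULL) {
  stopifnot(inherits(spec, "scene_spec"))
  h <- spec$image_shape[1]; w <- spec$image_shape[2]
  if (nrow(tracks) > 0) {
    xpx <- tracks$x_nm / spec$pixel_size_nm
    ypx <- tracks$y_nm / spec$pixel_size_nm
    if (any(xpx < 1 | xpx > w | ypx < 1 | ypx > h))
      stop("track positions fall outside the image bounds")
  }
  if (is.null(n_frames))
    n_frames <- if (nrow(tracks) > 0) max(tracks$frame) else 1L
  with_seed(spec$seed, {
    ids <- unique(tracks$track_id)
    amp <- pmax(rnorm(length(ids), spec$puncta_intensity[["mean"]],
                      spec$puncta_intensity[["sd"]]), 1)
    names(amp) <- as.character(ids)
    data <- array(0, c(n_frames, 1L, h, w))
    frame_interval <- if (!is.null(attr(tracks, "frame_interval_s")))
      attr(tracks, "frame_interval_s") else 0.057
    for (t in seq_len(n_frames)) {
      sel <- tracks$frame == t
      img <- render_gaussians(h, w,
                              tracks$x_nm[sel] / spec$pixel_size_nm,
                              tracks$y_nm[sel] / spec$pixel_size_nm,
                              amp[as.character(tracks$track_id[sel])],
                              spec$puncta_sigma_px) + spec$background_level
      data[t, 1, , ] <- apply_noise(img, spec$noise_model)
    }
    image_scene(data, spec$pixel_size_nm, frame_interval)
  })
}
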