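## Threshold-free subpixel spot detection by 2D Gaussian fitting, greedy
## nearest-neighbour trajectory linking, and track filtering.

## Local maxima of a matrix: pixels strictly greater than all 8 neighbours
## (interior pixels only). Returns an index matrix (row, col).
local_maxima <- function(img, border = 3L) {
  h <- nrow(img); w <- ncol(img)
  core <- img[(border + 1):(h - border), (border + 1):(w - border)]
  is_max <- rep(TRUE, length(core))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- img[(border + 1 + dr):(h - border + dr),
              (border + 1 + dc):(w - border + dc)]
    is_max <- is_max & (core > nb)
  }
  idx <- which(matrix(is_max, nrow(core), ncol(core)), arr.ind = TRUE)
  cbind(row = idx[, 1] + border, col = idx[, 2] + border)
}

## Symmetric 2D Gaussian least-squares fit in a square window.
## Returns NULL when the fit fails to converge.
fit_gaussian_2d <- function(img, r0, c0, half) {
  h <- nrow(img); w <- ncol(img)
  rows <- max(1L, r0 - half):min(h, r0 + half)
  cols <- max(1L, c0 - half):min(w, c0 + half)
  patch <- img[rows, cols]
  df <- data.frame(z = as.vector(patch),
                   y = rep(rows, times = length(cols)),
                   x = rep(cols, each = length(rows)))
  b0 <- min(df$z); a0 <- max(df$z) - b0
  if (a0 <= 0) return(NULL)
  wgt <- pmax(df$z - b0, 0)
  x0 <- sum(df$x * wgt) / sum(wgt); y0 <- sum(df$y * wgt) / sum(wgt)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      z ~ b + A * exp(-((x - mx)^2 + (y - my)^2) / (2 * s^2)),
      data = df,
      start = list(b = b0, A = a0, mx = x0, my = y0, s = 1.3),
      lower = c(b = -Inf, A = 0, mx = min(df$x) - 1, my = min(df$y) - 1,
                s = 0.3),
      upper = c(b = Inf, A = Inf, mx = max(df$x) + 1, my = max(df$y) + 1,
                s = 2 * half),
      control = minpack.lm::nls.lm.control(maxiter = 60)),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit)) return(NULL)
  p <- as.list(coef(fit))
  if (p$A <= 0 || p$s <= 0) return(NULL)
  list(amplitude = p$A, x = p$mx, y = p$my, sigma = p$s, offset = p$b)
}

#' Detect spots in one frame by threshold-free 2D Gaussian fitting
#'
#' Candidate positions are local maxima of a matched-filter response (the
#' frame convolved with a unit-norm Gaussian of width `psf_sigma`).
#' Candidates are accepted when their response exceeds a noise-calibrated
#' level: a robust Gaussian model (median + MAD * 1.4826) of the candidate
#' responses themselves sets the 1 - pfa quantile, so no user intensity
#' threshold is involved. Accepted candidates are refined by least-squares
#' symmetric 2D Gaussian fits giving subpixel position, amplitude and
#' sigma; the integrated intensity is the area under the fitted Gaussian,
#' 2 * pi * amplitude * sigma^2. Non-convergent fits are dropped and
#' counted in the `n_failed_fits` attribute.
#'
#' @param frame 2D numeric matrix.
#' @param pfa probability that a background candidate is accepted
#'   (default 1e-4).
#' @param fit_window fit window side, px (>= 5; odd).
#' @param psf_sigma expected PSF sigma for the matched filter, px.
#' @return data.frame x, y (subpixel px), amplitude, sigma,
#'   integrated_intensity, response.
#' @export
detect_spots <- function(frame, pfa = 1e-4, fit_window = 7L, psf_sigma = 1.5) {
  stopifnot(is.matrix(frame), fit_window >= 5, pfa > 0, pfa < 0.5)
  half <- as.integer(fit_window) %/% 2L
  kern <- log_kernel(psf_sigma) # mean-zero blob filter: offset-invariant
  kern <- -kern / sqrt(sum(kern^2))
  resp <- as.matrix(EBImage::filter2(frame, kern))
  cand <- local_maxima(resp, border = max(2L, half - 1L))
  empty <- data.frame(x = numeric(0), y = numeric(0), amplitude = numeric(0),
                      sigma = numeric(0), integrated_intensity = numeric(0),
                      response = numeric(0))
  if (nrow(cand) == 0L) return(empty)
  rv <- resp[cand]
  null_fit <- robust_gaussian(rv)
  keep <- if (null_fit$sd == 0) {
    # degenerate (noise-free) background: any positive blob response counts
    which(rv > 0)
  } else {
    which(rv > null_fit$center + qnorm(1 - pfa) * null_fit$sd)
  }
  if (length(keep) == 0L) {
    attr(empty, "n_failed_fits") <- 0L
    attr(empty, "n_candidates") <- nrow(cand)
    return(empty)
  }
  fits <- lapply(keep, function(i)
    fit_gaussian_2d(frame, cand[i, "row"], cand[i, "col"], half))
  ok <- !vapply(fits, is.null, logical(1))
  failed <- sum(!ok)
  fits <- fits[ok]
  out <- if (length(fits) == 0L) empty else data.frame(
    x = vapply(fits, `[[`, numeric(1), "x"),
    y = vapply(fits, `[[`, numeric(1), "y"),
    amplitude = vapply(fits, `[[`, numeric(1), "amplitude"),
    sigma = vapply(fits, `[[`, numeric(1), "sigma"),
    integrated_intensity = vapply(fits, function(f)
      2 * pi * f$amplitude * f$sigma^2, numeric(1)),
    response = rv[keep][ok])
  attr(out, "n_failed_fits") <- failed
  attr(out, "n_candidates") <- nrow(cand)
  out
}

#' Detect spots in every frame/channel of a movie
#'
#' @param scene an [image_scene].
#' @param channel channel index.
#' @param ... passed to [detect_spots].
#' @return data.frame frame, t_s, x, y, amplitude, sigma,
#'   integrated_intensity, channel.
#' @export
detect_spots_movie <- function(scene, channel = 1L, ...) {
  stopifnot(inherits(scene, "image_scene"))
  nt <- n_frames(scene)
  out <- vector("list", nt)
  for (t in seq_len(nt)) {
    s <- detect_spots(scene_frame(scene, t, channel), ...)
    if (nrow(s) > 0) {
      s$frame <- t
      s$t_s <- (t - 1) * scene$frame_interval_s
      s$channel <- channel
      out[[t]] <- s
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(x = numeric(0), y = numeric(0), amplitude = numeric(0),
                      sigma = numeric(0), integrated_intensity = numeric(0),
                      response = numeric(0), frame = integer(0),
                      t_s = numeric(0), channel = integer(0))
  attr(res, "pixel_size_nm") <- scene$pixel_size_nm
  attr(res, "frame_interval_s") <- scene$frame_interval_s
  res
}

#' Link per-frame spots into trajectories
#'
#' Frame-to-frame greedy minimal-displacement assignment: all candidate
#' links between the previous frame's active track ends and the current
#' frame's spots are sorted by distance, and accepted shortest-first while
#' both end-points are unused; links longer than `max_disp` are forbidden.
#' Unmatched spots start new tracks. With `memory > 0`, a track end stays
#' eligible for linking for that many missed frames (gap closing).
#'
#' @param spots data.frame as from [detect_spots_movie] (columns frame, x,
#'   y at minimum).
#' @param max_disp maximum per-step displacement, px.
#' @param memory number of frames a lost track remains linkable.
#' @return the spots data.frame with a `track_id` column, ordered by
#'   track_id then frame; class `track_set`. Attributes of the input
#'   (pixel size, frame interval) are carried over.
#' @export
link_tracks <- function(spots, max_disp = 5, memory = 0L) {
  stopifnot(max_disp > 0)
  if (nrow(spots) == 0L) {
    spots$track_id <- integer(0)
    class(spots) <- c("track_set", class(spots))
    return(spots)
  }
  spots <- spots[order(spots$frame), , drop = FALSE]
  spots$track_id <- NA_integer_
  frames <- sort(unique(spots$frame))
  next_id <- 1L
  # active track ends: data.frame track_id, x, y, last_frame
  active <- data.frame(track_id = integer(0), x = numeric(0), y = numeric(0),
                       last_frame = integer(0))
  for (f in frames) {
    idx <- which(spots$frame == f)
    active <- active[f - active$last_frame <= memory + 1L, , drop = FALSE]
    if (nrow(active) > 0L && length(idx) > 0L) {
      dx <- outer(active$x, spots$x[idx], "-")
      dy <- outer(active$y, spots$y[idx], "-")
      dist <- sqrt(dx^2 + dy^2)
      ord <- order(dist)
      used_a <- rep(FALSE, nrow(active)); used_s <- rep(FALSE, length(idx))
      for (o in ord) {
        if (dist[o] > max_disp) break
        ai <- (o - 1L) %% nrow(active) + 1L
        si <- (o - 1L) %/% nrow(active) + 1L
        if (used_a[ai] || used_s[si]) next
        used_a[ai] <- TRUE; used_s[si] <- TRUE
        spots$track_id[idx[si]] <- active$track_id[ai]
        active$x[ai] <- spots$x[idx[si]]
        active$y[ai] <- spots$y[idx[si]]
        active$last_frame[ai] <- f
      }
      new_spots <- idx[!used_s]
    } else new_spots <- idx
    if (length(new_spots) > 0L) {
      ids <- next_id + seq_along(new_spots) - 1L
      spots$track_id[new_spots] <- ids
      next_id <- next_id + length(new_spots)
      active <- rbind(active,
                      data.frame(track_id = ids, x = spots$x[new_spots],
                                 y = spots$y[new_spots], last_frame = f))
    }
  }
  spots <- spots[order(spots$track_id, spots$frame), , drop = FALSE]
  rownames(spots) <- NULL
  class(spots) <- unique(c("track_set", class(spots)))
  spots
}

#' Filter tracks by length and region of interest
#'
#' Short tracks make MSD estimates unreliable: tracks with fewer than
#' `min_points` time points (default 10) are discarded. When an `roi`
#' polygon is given, tracks whose mean position falls outside it are also
#' removed (e.g. objects not located in cells).
#'
#' @param tracks a `track_set` (data.frame with track_id, frame, x, y).
#' @param min_points minimum number of points per track.
#' @param roi optional polygon, data.frame/matrix with columns x, y (px).
#' @return filtered `track_set`.
#' @export
filter_tracks <- function(tracks, min_points = 10L, roi = NULL) {
  stopifnot(min_points >= 1)
  if (nrow(tracks) == 0L) return(tracks)
  n <- table(tracks$track_id)
  keep_ids <- as.integer(names(n)[n >= min_points])
  if (!is.null(roi)) {
    roi <- as.matrix(roi)
    mx <- tapply(tracks$x, tracks$track_id, mean)
    my <- tapply(tracks$y, tracks$track_id, mean)
    inside <- point_in_polygon(mx, my, roi[, 1], roi[, 2])
    keep_ids <- intersect(keep_ids, as.integer(names(mx))[inside])
  }
  out <- tracks[tracks$track_id %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Even-odd ray-casting point-in-polygon test.
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- (vy[i] > py) != (vy[j] > py)
    xint <- (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]
    inside <- xor(inside, cross & (px < xint))
    j <- i
  }
  inside
}

#' Mean integrated intensity of a track
#'
#' Averages the per-spot integrated Gaussian intensities
#' (2 * pi * amplitude * sigma^2) over the spots of each track.
#'
#' @param tracks a `track_set` with an `integrated_intensity` column.
#' @return data.frame track_id, n_points, mean_intensity.
#' @export
track_mean_intensity <- function(tracks) {
  stopifnot("integrated_intensity" %in% names(tracks))
  ids <- sort(unique(tracks$track_id))
  do.call(rbind, lapply(ids, function(id) {
    s <- tracks$track_id == id
    data.frame(track_id = id, n_points = sum(s),
               mean_intensity = mean(tracks$integrated_intensity[s]))
  })) %||% data.frame(track_id = integer(0), n_points = integer(0),
                      mean_intensity = numeric(0))
}
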