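# Shared fixture builders: all fixtures are generated in code.

# Flat image with antialiased bright disks at given centers.
disk_image <- function(h, w, centers, radius, level = 500, background = 100,
                       noise_sd = 0) {
  img <- matrix(background, h, w)
  for (i in seq_len(nrow(centers))) {
    y <- matrix(seq_len(h), h, w); x <- matrix(seq_len(w), h, w, byrow = TRUE)
    d <- sqrt((x - centers[i, 1])^2 + (y - centers[i, 2])^2)
    img <- img + level * pmin(1, pmax(0, radius + 0.5 - d))
  }
  if (noise_sd > 0) img <- img + matrix(rnorm(h * w, 0, noise_sd), h, w)
  img
}

# labeled_mask with disk nuclei (label i = i-th center).
disk_mask <- function(h, w, centers, radius) {
  L <- matrix(0L, h, w)
  for (i in seq_len(nrow(centers))) {
    y <- matrix(seq_len(h), h, w); x <- matrix(seq_len(w), h, w, byrow = TRUE)
    inside <- (x - centers[i, 1])^2 + (y - centers[i, 2])^2 <= radius^2
    L[inside] <- i
  }
  labeled_mask(L)
}

# Minimal track data.frame in pixel coordinates.
make_track <- function(id, x, y, frames = seq_along(x)) {
  data.frame(track_id = id, frame = frames, x = x, y = y)
}

# Exhaustive-pair MSD oracle, independent of msd_per_track.
brute_force_msd <- function(x_nm, y_nm, dt) {
  n <- length(x_nm)
  do.call(rbind, lapply(seq_len(n - 1), function(k) {
    d2 <- vapply(seq_len(n - k), function(i)
      (x_nm[i + k] - x_nm[i])^2 + (y_nm[i + k] - y_nm[i])^2, numeric(1))
    data.frame(delay_s = k * dt, msd_nm2 = mean(d2), weight = n - k)
  }))
}

# Brute-force nearest-nucleus assignment: for each pixel, scan every
# nucleus pixel (ties -> lowest label).
brute_force_edt_assign <- function(labels, foreground) {
  h <- nrow(labels); w <- ncol(labels)
  nuc <- which(labels > 0L, arr.ind = TRUE)
  nuc_lab <- labels[nuc]
  out <- matrix(0L, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (!foreground[r, c] && labels[r, c] == 0L) next
    d2 <- (nuc[, 1] - r)^2 + (nuc[, 2] - c)^2
    best <- min(d2)
    out[r, c] <- min(nuc_lab[d2 == best])
  }
  out
}
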