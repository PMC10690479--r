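## Mean-square-displacement analysis of linked trajectories: per-track MSD
## over all ordered point pairs at each delay, and the pair-count-weighted
## mean MSD across tracks.

#' Per-track mean square displacement
#'
#' For each delay tau = k * dt, averages the squared displacement over all
#' ordered pairs of points k frames apart: msd(tau) = mean over i of
#' |p(i+k) - p(i)|^2, in nm^2; the weight at each delay is the number of
#' contributing pairs (non-increasing in delay). Delays are limited to
#' `max_delay_fraction` of the track duration to bound estimator variance.
#'
#' @param track data.frame with columns frame, x, y for one track (px), or
#'   x_nm/y_nm (then `pixel_size_nm` is ignored).
#' @param pixel_size_nm conversion from px to nm.
#' @param frame_interval_s frame interval, s.
#' @param max_delay_fraction largest delay as a fraction of the track
#'   duration (default 0.25; 1 uses all delays).
#' @return data.frame delay_s, msd_nm2, weight; class `msd_curve`.
#' @export
msd_per_track <- function(track, pixel_size_nm = 110,
                          frame_interval_s = 0.057,
                          max_delay_fraction = 0.25) {
  if (all(c("x_nm", "y_nm") %in% names(track))) {
    x <- track$x_nm; y <- track$y_nm
  } else {
    x <- track$x * pixel_size_nm; y <- track$y * pixel_size_nm
  }
  ord <- order(track$frame)
  x <- x[ord]; y <- y[ord]; fr <- track$frame[ord]
  n <- length(x)
  stopifnot(n >= 2, !anyDuplicated(fr))
  max_k <- max(1L, floor((n - 1) * max_delay_fraction))
  out <- lapply(seq_len(max_k), function(k) {
    # pairs k frames apart (handles gaps from memory-linked tracks)
    j <- match(fr + k, fr)
    ok <- !is.na(j)
    if (!any(ok)) return(NULL)
    d2 <- (x[j[ok]] - x[ok])^2 + (y[j[ok]] - y[ok])^2
    data.frame(delay_s = k * frame_interval_s, msd_nm2 = mean(d2),
               weight = sum(ok))
  })
  res <- do.call(rbind, out)
  class(res) <- c("msd_curve", class(res))
  res
}

#' Weighted mean MSD across tracks
#'
#' Per delay, averages the per-track MSD values weighted by each track's
#' pair count at that delay. Delays covered by no track are omitted.
#'
#' @param curves list of `msd_curve`s (from [msd_per_track]).
#' @return data.frame delay_s, msd_nm2, weight (total pairs); class
#'   `msd_curve`.
#' @export
weighted_mean_msd <- function(curves) {
  stopifnot(length(curves) >= 1)
  all <- do.call(rbind, curves)
  delays <- sort(unique(all$delay_s))
  res <- do.call(rbind, lapply(delays, function(d) {
    s <- all$delay_s == d
    data.frame(delay_s = d,
               msd_nm2 = sum(all$msd_nm2[s] * all$weight[s]) / sum(all$weight[s]),
               weight = sum(all$weight[s]))
  }))
  class(res) <- c("msd_curve", class(res))
  res
}

#' MSD analysis of a whole track set
#'
#' Convenience wrapper: computes per-track MSD curves and their weighted
#' mean for a linked, filtered `track_set`.
#'
#' @param tracks a `track_set` (columns track_id, frame, x, y).
#' @inheritParams msd_per_track
#' @return list(per_track = named list of curves, mean = weighted mean
#'   curve).
#' @export
msd_analysis <- function(tracks, pixel_size_nm = 110,
                         frame_interval_s = 0.057,
                         max_delay_fraction = 0.25) {
  ids <- unique(tracks$track_id)
  stopifnot(length(ids) >= 1)
  curves <- lapply(ids, function(id)
    msd_per_track(tracks[tracks$track_id == id, , drop = FALSE],
                  pixel_size_nm, frame_interval_s, max_delay_fraction))
  names(curves) <- as.character(ids)
  list(per_track = curves, mean = weighted_mean_msd(curves))
}

#' Fit a diffusion coefficient from an MSD curve
#'
#' Weighted least-squares fit of msd = 4 D tau over the first `n_delays`
#' delays (2D diffusion; slope/4 = D in nm^2/s).
#'
#' @param curve an `msd_curve`.
#' @param n_delays number of initial delays used (default 10).
#' @return list(D = nm^2/s, slope = nm^2/s).
#' @export
fit_diffusion <- function(curve, n_delays = 10L) {
  k <- seq_len(min(n_delays, nrow(curve)))
  fit <- lm(msd_nm2 ~ 0 + delay_s, data = curve[k, ], weights = curve$weight[k])
  slope <- unname(coef(fit)[1])
  list(D = slope / 4, slope = slope)
}

#' Plot an MSD curve
#'
#' @param x an `msd_curve`.
#' @param ... passed to [plot.default].
#' @export
plot.msd_curve <- function(x, ...) {
  plot(x$delay_s, x$msd_nm2, xlab = "delay (s)", ylab = expression(MSD~(nm^2)),
       type = "b", pch = 16, ...)
  invisible(x)
}
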