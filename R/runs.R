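## Classification of bidirectional transport: each trajectory is segmented
## into apical runs, basal runs and stationary periods from its smoothed
## axial velocity, and per-movie aggregates (% of trajectory time per
## class, run velocities and run lengths) are computed.

#' Classify apical/basal runs in trajectories
#'
#' The per-frame velocity is projected on the apical axis and smoothed with
#' a centered moving average over `smooth_window` frames. Frames with axial
#' velocity >= `v_min` are classed as apical movement, <= -`v_min` as
#' basal, the rest as stationary; contiguous same-class frames are merged
#' into segments, and apical/basal segments whose net axial excursion is
#' shorter than `min_run_length` are reclassified as stationary (so
#' excluded runs can only lower the moving percentages). Aggregates are
#' computed over all tracks of the movie.
#'
#' @param tracks data.frame with track_id, frame and either x/y (px) or
#'   x_nm/y_nm columns.
#' @param axis apical unit vector (x, y); default (0, -1): apical is toward
#'   the image top.
#' @param v_min minimum axial speed for a run, nm/s.
#' @param min_run_length minimum net axial run excursion, nm.
#' @param smooth_window smoothing window, frames (odd; tracks shorter than
#'   the window are classified unsmoothed and flagged).
#' @param pixel_size_nm px-to-nm conversion (ignored for x_nm/y_nm input).
#' @param frame_interval_s frame interval, s.
#' @return list with `segments` (data.frame track_id, class, start_frame,
#'   end_frame, duration_s, length_nm, mean_velocity_nm_s), `aggregates`
#'   (data.frame percent_apical, percent_basal, percent_stationary,
#'   apical_velocity_nm_s, basal_velocity_nm_s, apical_run_length_um,
#'   basal_run_length_um) and `parameters`; class `run_segmentation`.
#' @export
classify_runs <- function(tracks, axis = c(0, -1), v_min = 100,
                          min_run_length = 500, smooth_window = 3L,
                          pixel_size_nm = 110, frame_interval_s = 0.057) {
  stopifnot(v_min > 0, min_run_length > 0, smooth_window >= 1)
  axis <- axis / sqrt(sum(axis^2))
  ids <- unique(tracks$track_id)
  seg_list <- vector("list", length(ids))
  flagged <- integer(0)
  for (i in seq_along(ids)) {
    tr <- tracks[tracks$track_id == ids[i], , drop = FALSE]
    tr <- tr[order(tr$frame), , drop = FALSE]
    if (all(c("x_nm", "y_nm") %in% names(tr))) {
      x <- tr$x_nm; y <- tr$y_nm
    } else {
      x <- tr$x * pixel_size_nm; y <- tr$y * pixel_size_nm
    }
    n <- length(x)
    if (n < 2) next
    proj <- x * axis[1] + y * axis[2]
    v <- diff(proj) / frame_interval_s      # axial velocity per step
    if (n - 1 >= smooth_window && smooth_window > 1) {
      v_s <- as.numeric(stats::filter(v, rep(1 / smooth_window, smooth_window),
                                      sides = 2))
      v_s[is.na(v_s)] <- v[is.na(v_s)]      # edges: unsmoothed
    } else {
      v_s <- v
      if (smooth_window > 1) flagged <- c(flagged, ids[i])
    }
    cls <- ifelse(v_s >= v_min, "apical", ifelse(v_s <= -v_min, "basal",
                                                 "stationary"))
    r <- rle(cls)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    segs <- data.frame(track_id = ids[i], class = r$values,
                       start_frame = tr$frame[starts],
                       end_frame = tr$frame[ends + 1L],
                       duration_s = r$lengths * frame_interval_s,
                       length_nm = abs(proj[ends + 1L] - proj[starts]),
                       mean_velocity_nm_s = vapply(seq_along(starts),
                         function(j) mean(abs(v_s[starts[j]:ends[j]])),
                         numeric(1)))
    # runs too short for inclusion become stationary
    short <- segs$class != "stationary" & segs$length_nm < min_run_length
    segs$class[short] <- "stationary"
    seg_list[[i]] <- segs
  }
  segments <- do.call(rbind, seg_list)
  if (is.null(segments))
    stop("no classifiable tracks (need >= 2 points per track)")
  tt <- tapply(segments$duration_s, segments$class, sum)
  total <- sum(segments$duration_s)
  pct <- function(cl) 100 * (if (!is.na(tt[cl])) tt[[cl]] else 0) / total
  vel <- function(cl) {
    s <- segments$class == cl
    if (any(s)) weighted.mean(segments$mean_velocity_nm_s[s],
                              segments$duration_s[s]) else NA_real_
  }
  runlen <- function(cl) {
    s <- segments$class == cl
    if (any(s)) mean(segments$length_nm[s]) / 1000 else NA_real_
  }
  aggregates <- data.frame(
    percent_apical = pct("apical"), percent_basal = pct("basal"),
    percent_stationary = pct("stationary"),
    apical_velocity_nm_s = vel("apical"), basal_velocity_nm_s = vel("basal"),
    apical_run_length_um = runlen("apical"),
    basal_run_length_um = runlen("basal"))
  structure(list(segments = segments, aggregates = aggregates,
                 parameters = list(axis = axis, v_min = v_min,
                                   min_run_length = min_run_length,
                                   smooth_window = smooth_window,
                                   pixel_size_nm = pixel_size_nm,
                                   frame_interval_s = frame_interval_s,
                                   flagged_short_tracks = flagged)),
            class = "run_segmentation")
}

#' @export
print.run_segmentation <- function(x, ...) {
  a <- x$aggregates
  cat(sprintf(paste0("run_segmentation: %d segment(s) from %d track(s)\n",
                     "  %% apical %.1f, %% basal %.1f, %% stationary %.1f\n"),
              nrow(x$segments), length(unique(x$segments$track_id)),
              a$percent_apical, a$percent_basal, a$percent_stationary))
  invisible(x)
}
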