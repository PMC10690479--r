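#' Multi-channel image or movie container
#'
#' An `image_scene` wraps a numeric array in canonical T x C x Y x X axis
#' order together with the physical calibration needed downstream: pixel
#' size in nanometres per pixel and frame interval in seconds. Pixel centers
#' sit at integer coordinates with x = column, y = row and origin at the
#' top-left; subpixel positions are real numbers on that grid.
#'
#' @param data numeric array; a 2D matrix (Y x X), 3D array (C x Y x X) or
#'   4D array (T x C x Y x X). Lower-dimensional inputs gain singleton
#'   leading axes.
#' @param pixel_size_nm physical pixel size, nm per pixel (> 0).
#' @param frame_interval_s time between frames, seconds (> 0).
#' @return an object of class `image_scene` with elements `data` (4D array),
#'   `pixel_size_nm` and `frame_interval_s`.
#' @examples
#' sc <- image_scene(matrix(0, 16, 16))
#' dim(sc$data)   # 1 1 16 16
#' @export
image_scene <- function(data, pixel_size_nm = 110, frame_interval_s = 0.057) {
  stopifnot(is.numeric(data), pixel_size_nm > 0, frame_interval_s > 0)
  d <- dim(data)
  if (is.null(d)) stop("data must be a matrix or array")
  if (length(d) == 2L) dim(data) <- c(1L, 1L, d)
  else if (length(d) == 3L) dim(data) <- c(1L, d)
  else if (length(d) != 4L) stop("data must have 2, 3 or 4 dimensions")
  structure(list(data = data, pixel_size_nm = pixel_size_nm,
                 frame_interval_s = frame_interval_s),
            class = "image_scene")
}

#' Extract one frame/channel of a scene as a Y x X matrix
#' @param scene an [image_scene].
#' @param frame time index (1-based).
#' @param channel channel index (1-based).
#' @return numeric matrix (Y x X).
#' @export
scene_frame <- function(scene, frame = 1L, channel = 1L) {
  stopifnot(inherits(scene, "image_scene"))
  d <- dim(scene$data)
  if (frame > d[1] || channel > d[2]) stop("frame/channel out of range")
  matrix(scene$data[frame, channel, , ], d[3], d[4])
}

#' @export
print.image_scene <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("image_scene: %d frame(s) x %d channel(s) x %d x %d px, %.1f nm/px, %.4g s/frame\n",
              d[1], d[2], d[3], d[4], x$pixel_size_nm, x$frame_interval_s))
  invisible(x)
}

#' Number of frames / channels in a scene
#' @rdname scene_frame
#' @export
n_frames <- function(scene) dim(scene$data)[1]

#' @rdname scene_frame
#' @export
n_channels <- function(scene) dim(scene$data)[2]
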