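## Classical segmentation chain for immunofluorescence images: nuclei by
## median filter + rolling-ball background + false-alarm-rate calibrated
## threshold + watershed; per-cell partition by Euclidean distance to the
## nearest nucleus; foreground by a quantile threshold of the smoothed
## max-projection; puncta by Laplacian-of-Gaussian or raw-intensity
## thresholding.

#' Noise-calibrated threshold with a given probability of false alarm
#'
#' Fits a robust Gaussian model to the background of an image (median and
#' MAD * 1.4826, so bright objects do not bias the estimate) and returns the
#' value a background pixel exceeds with probability `pfa`:
#' median + qnorm(1 - pfa) * sigma.
#'
#' @param image numeric matrix.
#' @param pfa probability of false alarm, 0 < pfa < 0.5.
#' @return numeric threshold.
#' @export
threshold_pfa <- function(image, pfa) {
  stopifnot(pfa > 0, pfa < 0.5)
  bg <- robust_gaussian(image)
  if (bg$sd == 0) stop("degenerate background: image has zero robust variance")
  bg$center + qnorm(1 - pfa) * bg$sd
}

## Rolling-ball background subtraction realized as grayscale morphological
## opening with a flat disc structuring element of the given radius.
rolling_ball <- function(image, radius) {
  if (radius < 1) return(image)
  side <- 2L * as.integer(radius) + 1L
  if (side %% 2L == 0L) side <- side + 1L
  brush <- EBImage::makeBrush(side, shape = "disc")
  bg <- EBImage::opening(image, brush)
  image - bg
}

## Median filter on an arbitrary-range image (EBImage expects [0,1]).
median_filter <- function(image, radius) {
  lo <- min(image); hi <- max(image)
  if (hi == lo) return(image)
  scaled <- (image - lo) / (hi - lo)
  out <- EBImage::medianFilter(scaled, as.integer(radius))
  as.matrix(out) * (hi - lo) + lo
}

#' Segment nuclei with the classical filter chain
#'
#' Median filter, rolling-ball background subtraction, a threshold
#' controlled by a probability of false alarm, optional watershed splitting
#' of touching objects, and extraction of 8-connected components. Labels
#' are contiguous 1..K.
#'
#' @param image 2D numeric matrix (the nuclear stain channel).
#' @param median_radius median filter radius, px.
#' @param rolling_ball_radius background structuring-element radius, px.
#' @param pfa probability of false alarm for the threshold (0 < pfa < 0.5).
#' @param watershed split touching nuclei with a distance-transform
#'   watershed.
#' @param min_area discard components smaller than this many pixels.
#' @return a `labeled_mask`: list(labels = integer matrix, parameters).
#' @export
segment_nuclei <- function(image, median_radius = 2, rolling_ball_radius = 50,
                           pfa = 1e-3, watershed = TRUE, min_area = 20L) {
  stopifnot(is.matrix(image), pfa > 0, pfa < 0.5, median_radius >= 1,
            rolling_ball_radius >= 1)
  if (max(image) == min(image))
    stop("degenerate background: constant image, threshold undefined")
  filtered <- median_filter(image, median_radius)
  filtered <- rolling_ball(filtered, rolling_ball_radius)
  thr <- threshold_pfa(filtered, pfa)
  binary <- filtered > thr
  labels <- if (watershed) {
    dm <- EBImage::distmap(binary)
    ws <- EBImage::watershed(dm)
    matrix(as.integer(round(ws)), nrow(image), ncol(image))
  } else {
    label8(binary)
  }
  if (min_area > 1L) {
    sizes <- tabulate(labels[labels > 0L])
    drop <- which(sizes < min_area)
    labels[labels %in% drop] <- 0L
  }
  labeled_mask(relabel_contiguous(labels),
               parameters = list(median_radius = median_radius,
                                 rolling_ball_radius = rolling_ball_radius,
                                 pfa = pfa, watershed = watershed,
                                 min_area = min_area))
}

#' Labeled object mask
#'
#' @param labels integer matrix; 0 = background, k >= 1 = object k (labels
#'   contiguous after construction).
#' @param parameters record of the filter sizes/thresholds that produced it.
#' @return a `labeled_mask` object.
#' @export
labeled_mask <- function(labels, parameters = list()) {
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  structure(list(labels = relabel_contiguous(labels), parameters = parameters),
            class = "labeled_mask")
}

#' @export
print.labeled_mask <- function(x, ...) {
  cat(sprintf("labeled_mask: %d object(s), %d x %d px\n",
              max(x$labels), nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Discard regions touching the image border
#'
#' Removes any label whose pixel set intersects the first/last row or
#' column (incomplete cells); remaining labels are renumbered contiguously.
#'
#' @param mask a [labeled_mask].
#' @return filtered [labeled_mask].
#' @export
discard_border_regions <- function(mask) {
  stopifnot(inherits(mask, "labeled_mask"))
  L <- mask$labels
  border <- unique(c(L[1, ], L[nrow(L), ], L[, 1], L[, ncol(L)]))
  border <- border[border > 0L]
  L[L %in% border] <- 0L
  labeled_mask(L, mask$parameters)
}

#' Foreground mask from the smoothed multi-channel max-projection
#'
#' The maximum projection over channels is Gaussian-smoothed and
#' thresholded at a quantile of its own intensity distribution; pixels
#' above the quantile are foreground. Adding a constant to the image leaves
#' the mask unchanged.
#'
#' @param scene an [image_scene] (first frame used) or a 2D/3D array.
#' @param smooth_sigma Gaussian smoothing sigma, px.
#' @param quantile threshold quantile in (0, 1).
#' @return logical matrix.
#' @export
foreground_mask <- function(scene, smooth_sigma = 2, quantile = 0.5) {
  stopifnot(quantile > 0, quantile < 1)
  if (inherits(scene, "image_scene")) {
    d <- dim(scene$data)
    chans <- lapply(seq_len(d[2]), function(ch) scene_frame(scene, 1L, ch))
  } else if (is.matrix(scene)) {
    chans <- list(scene)
  } else stop("scene must be an image_scene or a matrix")
  proj <- Reduce(pmax, chans)
  sm <- if (smooth_sigma > 0)
    as.matrix(EBImage::gblur(proj, sigma = smooth_sigma)) else proj
  # inclusive comparison so the mask tends to the full image as quantile -> 0
  sm >= stats::quantile(sm, quantile)
}

#' Assign foreground pixels to the nearest nucleus
#'
#' Computes, for every nucleus label, the Euclidean distance transform to
#' that nucleus's pixel set, and assigns each foreground pixel the label of
#' the nearest nucleus (pixels inside a nucleus have distance 0 and keep
#' their own label). Ties are broken toward the lowest label.
#'
#' @param nuclei a [labeled_mask] with >= 1 label.
#' @param foreground logical matrix of the same size.
#' @return a `cell_partition`: list(nucleus_mask, cell_of_pixel
#'   (integer matrix, 0 outside foreground), foreground_mask).
#' @export
assign_cells_by_edt <- function(nuclei, foreground) {
  stopifnot(inherits(nuclei, "labeled_mask"),
            all(dim(foreground) == dim(nuclei$labels)))
  K <- max(nuclei$labels)
  if (K == 0L) stop("no cells: nucleus mask is empty")
  # foreground must cover the nuclei themselves
  foreground <- foreground | nuclei$labels > 0L
  best_d <- matrix(Inf, nrow(foreground), ncol(foreground))
  assign <- matrix(0L, nrow(foreground), ncol(foreground))
  for (k in seq_len(K)) {
    # distance from every pixel to the nearest pixel of nucleus k
    dk <- as.matrix(EBImage::distmap(matrix(
      as.numeric(nuclei$labels != k), nrow(foreground), ncol(foreground))))
    upd <- dk < best_d           # strict: ties keep the lower label
    best_d[upd] <- dk[upd]
    assign[upd] <- k
  }
  assign[!foreground] <- 0L
  structure(list(nucleus_mask = nuclei, cell_of_pixel = assign,
                 foreground_mask = foreground),
            class = "cell_partition")
}

#' @export
print.cell_partition <- function(x, ...) {
  cat(sprintf("cell_partition: %d cell(s), %.1f%% foreground\n",
              max(x$nucleus_mask$labels), 100 * mean(x$foreground_mask)))
  invisible(x)
}

## Shared component-extraction for the two puncta detectors. `weights`
## supplies the intensity readout per pixel (raw image for the
## intensity-threshold path; background-subtracted image for the LoG path,
## keeping the whole detection offset-invariant).
components_to_puncta <- function(response, weights, threshold, min_area,
                                 channel, partition) {
  image <- weights
  labels <- label8(response > threshold)
  K <- max(labels)
  if (K == 0L) return(empty_puncta())
  idx <- which(labels > 0L)
  lab <- labels[idx]
  rows <- (idx - 1L) %% nrow(image) + 1L
  cols <- (idx - 1L) %/% nrow(image) + 1L
  w <- pmax(image[idx], 0)
  area <- tabulate(lab, K)
  tot <- vapply(seq_len(K), function(k) sum(w[lab == k]), numeric(1))
  cx <- vapply(seq_len(K), function(k) {
    s <- lab == k; if (tot[k] > 0) sum(cols[s] * w[s]) / tot[k] else mean(cols[s])
  }, numeric(1))
  cy <- vapply(seq_len(K), function(k) {
    s <- lab == k; if (tot[k] > 0) sum(rows[s] * w[s]) / tot[k] else mean(rows[s])
  }, numeric(1))
  keep <- which(area >= min_area)
  if (length(keep) == 0L) return(empty_puncta())
  cell <- integer(length(keep))
  if (!is.null(partition)) {
    r <- pmin(pmax(round(cy[keep]), 1L), nrow(image))
    c <- pmin(pmax(round(cx[keep]), 1L), ncol(image))
    cell <- partition$cell_of_pixel[cbind(r, c)]
  }
  pix <- lapply(keep, function(k) idx[lab == k])
  structure(list(
    table = data.frame(punctum_id = seq_along(keep), channel = channel,
                       cell_id = cell, area_px = area[keep],
                       total_intensity = tot[keep],
                       centroid_x_px = cx[keep], centroid_y_px = cy[keep]),
    pixels = pix, labels = labels, dim = dim(image)),
    class = "puncta_set")
}

empty_puncta <- function() {
  structure(list(
    table = data.frame(punctum_id = integer(0), channel = integer(0),
                       cell_id = integer(0), area_px = integer(0),
                       total_intensity = numeric(0),
                       centroid_x_px = numeric(0), centroid_y_px = numeric(0)),
    pixels = list(), labels = NULL, dim = NULL),
    class = "puncta_set")
}

#' @export
print.puncta_set <- function(x, ...) {
  cat(sprintf("puncta_set: %d puncta\n", nrow(x$table)))
  invisible(x)
}

## Laplacian-of-Gaussian kernel, normalized so response to a constant is 0.
log_kernel <- function(sigma) {
  r <- ceiling(4 * sigma)
  g <- outer(-r:r, -r:r, function(y, x)
    ((x^2 + y^2) / sigma^4 - 2 / sigma^2) *
      exp(-(x^2 + y^2) / (2 * sigma^2)))
  g - mean(g)
}

#' Detect puncta with a Laplacian-of-Gaussian filter
#'
#' The image is convolved with a LoG kernel at scale `log_sigma`; bright
#' blobs give strong negative responses, so puncta are the 8-connected
#' components where -LoG exceeds the threshold, after removal of components
#' smaller than `min_area` pixels. Each punctum is tagged with the cell id
#' of its intensity-weighted centroid (0 outside the foreground). The LoG
#' response is invariant to constant offsets.
#'
#' @param image 2D numeric matrix.
#' @param log_sigma LoG scale, px (matched to the spot radius).
#' @param threshold response threshold; interpreted per `threshold_mode`.
#' @param min_area minimum component area, px.
#' @param partition optional [cell_partition] for per-cell tagging.
#' @param channel channel index recorded in the output.
#' @param threshold_mode "absolute" uses `threshold` as-is on the -LoG
#'   response; "mad" uses threshold * 1.4826 * MAD of the response above
#'   its median (noise-scaled).
#' @return a `puncta_set` (table + per-punctum pixel lists).
#' @export
detect_puncta_log <- function(image, log_sigma = 2, threshold = 1,
                              min_area = 5L, partition = NULL, channel = 1L,
                              threshold_mode = c("absolute", "mad")) {
  stopifnot(is.matrix(image), log_sigma > 0, min_area >= 1)
  threshold_mode <- match.arg(threshold_mode)
  resp <- -as.matrix(EBImage::filter2(image, log_kernel(log_sigma)))
  thr <- if (threshold_mode == "mad") {
    bg <- robust_gaussian(resp)
    bg$center + threshold * bg$sd
  } else threshold
  # intensities measured above the robust image background, so the whole
  # result (masks and intensities) is invariant to constant offsets
  components_to_puncta(resp, image - median(image), thr, min_area, channel,
                       partition)
}

#' Segment particles by a raw intensity threshold
#'
#' The particle-count path: the unadjusted channel is thresholded directly
#' and 8-connected components smaller than `min_area` pixels (default 5)
#' are removed.
#'
#' @inheritParams detect_puncta_log
#' @param threshold absolute intensity threshold.
#' @return a `puncta_set`.
#' @export
segment_by_intensity_threshold <- function(image, threshold, min_area = 5L,
                                           partition = NULL, channel = 1L) {
  stopifnot(is.matrix(image), min_area >= 1)
  components_to_puncta(image, image, threshold, min_area, channel, partition)
}
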