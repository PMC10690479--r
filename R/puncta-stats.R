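## Per-cell and per-region statistics of fluorescent signal and detected
## puncta: the intensity-weighted spread statistic, count/intensity
## summaries, object-overlap colocalization, and embryo-zone quantification.

#' Intensity-weighted spread of a signal within a mask
#'
#' The spread of a fluorescent signal away from its own centroid: the
#' intensity-weighted centroid of the masked signal is computed, and spread
#' is the sum over masked pixels of intensity times squared distance to
#' that centroid (a.u. * px^2). `normalized_spread` divides by the total
#' intensity, giving the intensity-weighted mean squared deviation (px^2) —
#' invariant to rescaling the signal. Spread is 0 iff all signal sits at a
#' single point, and is invariant to translating mask and signal together.
#'
#' @param weights non-negative intensity matrix.
#' @param mask logical matrix selecting the region (e.g. one cell of a
#'   [cell_partition]).
#' @param cell_id optional id echoed into the result.
#' @return data.frame cell_id, total_intensity, spread, normalized_spread.
#' @examples
#' w <- matrix(0, 3, 3); w[1, 1] <- 1; w[1, 3] <- 1
#' spread_statistic(w, w > 0)   # two unit masses 2 px apart: spread 2
#' @export
spread_statistic <- function(weights, mask, cell_id = NA_integer_) {
  stopifnot(all(dim(weights) == dim(mask)))
  idx <- which(mask)
  if (length(idx) == 0L) stop("empty signal: mask selects no pixels")
  w <- weights[idx]
  if (any(w < 0)) stop("weights must be non-negative")
  tot <- sum(w)
  if (tot <= 0) stop("empty signal: zero total intensity in mask")
  y <- (idx - 1L) %% nrow(weights) + 1L
  x <- (idx - 1L) %/% nrow(weights) + 1L
  cx <- sum(x * w) / tot
  cy <- sum(y * w) / tot
  sp <- sum(w * ((x - cx)^2 + (y - cy)^2))
  data.frame(cell_id = cell_id, total_intensity = tot, spread = sp,
             normalized_spread = sp / tot)
}

#' Per-cell spread of a signal channel
#'
#' Applies [spread_statistic] to each cell of a partition, masking by the
#' cell's assigned pixels.
#'
#' @param weights intensity matrix.
#' @param partition a [cell_partition].
#' @return data.frame, one row per cell.
#' @export
spread_by_cell <- function(weights, partition) {
  stopifnot(inherits(partition, "cell_partition"))
  K <- max(partition$nucleus_mask$labels)
  do.call(rbind, lapply(seq_len(K), function(k)
    spread_statistic(weights, partition$cell_of_pixel == k, cell_id = k)))
}

#' Summarize puncta counts and intensities
#'
#' Counts puncta and averages their total intensities, grouped per cell or
#' over the whole image. Cells with no puncta report count 0 and missing
#' mean intensity.
#'
#' @param puncta a `puncta_set`.
#' @param by "cell" or "image".
#' @param cell_ids optional integer vector of cells to report (so that
#'   empty cells appear with count 0); defaults to the ids present.
#' @return data.frame cell_id (if by = "cell"), n_puncta,
#'   mean_total_intensity.
#' @export
puncta_summary <- function(puncta, by = c("cell", "image"), cell_ids = NULL) {
  by <- match.arg(by)
  tab <- puncta$table
  if (by == "image") {
    return(data.frame(n_puncta = nrow(tab),
                      mean_total_intensity =
                        if (nrow(tab) > 0) mean(tab$total_intensity) else NA_real_))
  }
  ids <- cell_ids %||% sort(unique(tab$cell_id))
  do.call(rbind, lapply(ids, function(k) {
    s <- tab$cell_id == k
    data.frame(cell_id = k, n_puncta = sum(s),
               mean_total_intensity =
                 if (any(s)) mean(tab$total_intensity[s]) else NA_real_)
  })) %||% data.frame(cell_id = integer(0), n_puncta = integer(0),
                      mean_total_intensity = numeric(0))
}

#' Object-based colocalization of fixed-cell puncta
#'
#' A channel-1 punctum counts as overlapping when its pixel set intersects
#' the pixel set of any channel-2 punctum; per cell, the overlapping count
#' is reported as a percentage of the channel-1 puncta in that cell. The
#' measure is asymmetric by design — channel 1 is the reference channel and
#' swapping channels can change the percentage. Cells without channel-1
#' puncta report a missing percentage (not 0).
#'
#' @param puncta_ch1,puncta_ch2 `puncta_set`s detected on the same
#'   partition/image.
#' @param cell_ids optional cells to report; defaults to cells present in
#'   either channel.
#' @return data.frame cell_id, n_puncta_ch1, n_puncta_ch2, n_overlapping,
#'   percent.
#' @export
colocalize_fixed <- function(puncta_ch1, puncta_ch2, cell_ids = NULL) {
  t1 <- puncta_ch1$table; t2 <- puncta_ch2$table
  ch2_pix <- unique(unlist(puncta_ch2$pixels))
  overlaps <- vapply(puncta_ch1$pixels, function(p) any(p %in% ch2_pix),
                     logical(1))
  ids <- cell_ids %||% sort(unique(c(t1$cell_id, t2$cell_id)))
  do.call(rbind, lapply(ids, function(k) {
    s1 <- t1$cell_id == k
    n1 <- sum(s1)
    data.frame(cell_id = k, n_puncta_ch1 = n1,
               n_puncta_ch2 = sum(t2$cell_id == k),
               n_overlapping = sum(overlaps[s1]),
               percent = if (n1 > 0) 100 * sum(overlaps[s1]) / n1 else NA_real_)
  })) %||% data.frame(cell_id = integer(0), n_puncta_ch1 = integer(0),
                      n_puncta_ch2 = integer(0), n_overlapping = integer(0),
                      percent = numeric(0))
}

#' Define a rectangular analysis zone of fixed physical area
#'
#' @param zone name, one of "apical", "upper_basal", "lower_basal", "yolk"
#'   (free-form names are allowed).
#' @param x0,y0 top-left corner, px (pixel-center coordinates; the
#'   rectangle is half-open: [x0, x1) x [y0, y1)).
#' @param width_px,height_px rectangle size, px.
#' @return a `zone_rect` list.
#' @export
zone_rect <- function(zone, x0, y0, width_px, height_px) {
  structure(list(zone = zone, x0 = x0, y0 = y0,
                 width_px = width_px, height_px = height_px),
            class = "zone_rect")
}

#' Quantify puncta within fixed-area zones
#'
#' Counts puncta (by centroid membership, half-open rectangles so boundary
#' puncta land in exactly one zone) and averages their total intensities in
#' each rectangular zone. Every rectangle must measure `zone_area_um2`
#' within a 1 px^2 tolerance, matching the fixed-region convention for
#' embryo quantification.
#'
#' @param puncta a `puncta_set`.
#' @param zones list of [zone_rect]s.
#' @param pixel_size_nm physical pixel size.
#' @param zone_area_um2 required zone area in um^2 (default 300).
#' @return data.frame zone, region_area_um2, n_puncta, mean_total_intensity.
#' @export
quantify_zones <- function(puncta, zones, pixel_size_nm = 110,
                           zone_area_um2 = 300) {
  px_um2 <- (pixel_size_nm / 1000)^2
  tab <- puncta$table
  do.call(rbind, lapply(zones, function(z) {
    stopifnot(inherits(z, "zone_rect"))
    area_um2 <- z$width_px * z$height_px * px_um2
    if (abs(area_um2 - zone_area_um2) > px_um2)
      stop(sprintf("zone '%s' has area %.2f um^2; expected %.2f um^2",
                   z$zone, area_um2, zone_area_um2))
    inz <- tab$centroid_x_px >= z$x0 & tab$centroid_x_px < z$x0 + z$width_px &
      tab$centroid_y_px >= z$y0 & tab$centroid_y_px < z$y0 + z$height_px
    data.frame(zone = z$zone, region_area_um2 = area_um2, n_puncta = sum(inz),
               mean_total_intensity =
                 if (any(inz)) mean(tab$total_intensity[inz]) else NA_real_)
  }))
}
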