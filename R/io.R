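## File I/O: TIFF stacks in canonical T x C x Y x X order, 16-bit label
## masks, CSV/TSV tables, YAML configs.

#' Write an image scene as a multi-page TIFF
#'
#' Pages are written frame-major, channel-minor (frame 1 channels 1..C,
#' then frame 2, ...). Intensities are stored as 16-bit samples scaled by
#' `scale`; integer photon counts below `scale` round-trip exactly.
#'
#' @param scene an [image_scene].
#' @param path output file.
#' @param scale intensity corresponding to the maximal 16-bit value
#'   (default 65535, i.e. raw counts stored verbatim).
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(scene, path, scale = 65535) {
  stopifnot(inherits(scene, "image_scene"))
  d <- dim(scene$data)
  pages <- vector("list", d[1] * d[2])
  i <- 0L
  for (t in seq_len(d[1])) for (ch in seq_len(d[2])) {
    i <- i + 1L
    pages[[i]] <- pmin(pmax(scene_frame(scene, t, ch) / scale, 0), 1)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF as an image scene
#'
#' The page sequence is folded into T x C x Y x X using the supplied
#' channel count (pages must be frame-major, channel-minor, as written by
#' [write_image_stack]); a single page becomes a 1 x 1 x H x W scene.
#' Physical metadata is supplied by the caller/config, as TIFF rarely
#' carries it reliably.
#'
#' @param path TIFF file.
#' @param n_channels number of channels interleaved in the page sequence.
#' @param pixel_size_nm,frame_interval_s calibration metadata.
#' @param scale intensity scale used when writing (see
#'   [write_image_stack]).
#' @return an [image_scene].
#' @export
read_image_stack <- function(path, n_channels = 1L, pixel_size_nm = 110,
                             frame_interval_s = 0.057, scale = 65535) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  np <- length(pages)
  if (np %% n_channels != 0L)
    stop("axis ambiguity: ", np, " pages are not divisible by ", n_channels,
         " channels")
  nt <- np %/% n_channels
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  data <- array(0, c(nt, n_channels, h, w))
  i <- 0L
  for (t in seq_len(nt)) for (ch in seq_len(n_channels)) {
    i <- i + 1L
    data[t, ch, , ] <- pages[[i]] * scale
  }
  image_scene(data, pixel_size_nm, frame_interval_s)
}

#' Write a labeled mask as a 16-bit label TIFF
#'
#' @param mask a [labeled_mask].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_label_mask <- function(mask, path) {
  stopifnot(inherits(mask, "labeled_mask"), max(mask$labels) < 65536)
  tiff::writeTIFF(mask$labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a 16-bit label TIFF as a labeled mask
#' @param path TIFF file written by [write_label_mask].
#' @return a [labeled_mask].
#' @export
read_label_mask <- function(path) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  labeled_mask(matrix(as.integer(round(m * 65535)), nrow(m), ncol(m)))
}

#' Write a puncta table as CSV
#' @param puncta a `puncta_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_puncta_csv <- function(puncta, path) {
  utils::write.csv(puncta$table, path, row.names = FALSE)
  invisible(path)
}

#' Write a track set (or any table) as CSV
#' @param tracks data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tracks_csv <- function(tracks, path) {
  utils::write.csv(as.data.frame(tracks), path, row.names = FALSE)
  invisible(path)
}

#' Read a protein-group intensity TSV
#'
#' Expected layout: one row per protein; a `protein` id column, one column
#' per sample intensity, a `peptides` column, and optional logical
#' `reverse` / `contaminant` columns. Empty cells and 0 are treated as
#' missing.
#'
#' @param path TSV file.
#' @param groups factor/character of per-sample group labels, in column
#'   order.
#' @return an [intensity_matrix].
#' @export
read_proteomics_tsv <- function(path, groups) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  df <- utils::read.delim(path, check.names = FALSE)
  stopifnot("protein" %in% names(df), "peptides" %in% names(df))
  meta <- intersect(c("protein", "peptides", "reverse", "contaminant"),
                    names(df))
  samp <- setdiff(names(df), meta)
  stopifnot(length(samp) == length(groups))
  m <- as.matrix(df[, samp, drop = FALSE])
  m[m == 0] <- NA
  rownames(m) <- df$protein
  intensity_matrix(m, groups = factor(groups), peptides = df$peptides,
                   reverse = if ("reverse" %in% meta) as.logical(df$reverse),
                   contaminant = if ("contaminant" %in% meta)
                     as.logical(df$contaminant))
}

#' Write an intensity matrix as TSV
#' @param m an [intensity_matrix].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_proteomics_tsv <- function(m, path) {
  df <- data.frame(protein = rownames(m$intensities), m$intensities,
                   peptides = m$peptides, reverse = m$reverse,
                   contaminant = m$contaminant, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
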