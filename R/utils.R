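## Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the caller's RNG state so that seeded generators are
#' pure functions of their arguments and never disturb the session RNG.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' 8-connected component labeling
#'
#' EBImage::bwlabel labels 4-connected components; components touching only
#' diagonally must be merged to obtain the 8-connectivity used throughout
#' the pipeline. Merging is done with a union-find over diagonally adjacent
#' label pairs, then labels are relabeled to a contiguous 1..K in order of
#' first appearance (deterministic).
#' @noRd
label8 <- function(mask) {
  L <- EBImage::bwlabel(mask != 0)
  L <- matrix(as.integer(round(L)), nrow(mask), ncol(mask))
  K <- max(L)
  if (K <= 1L) return(L)
  parent <- seq_len(K)
  findp <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unite <- function(a, b) { ra <- findp(a); rb <- findp(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
  H <- nrow(L); W <- ncol(L)
  # diagonal neighbour pairs: (r, c) vs (r + 1, c + 1) and (r + 1, c - 1)
  a <- L[-H, -W]; b <- L[-1, -1]
  sel <- a > 0L & b > 0L & a != b
  if (any(sel)) { pr <- unique(cbind(a[sel], b[sel])); for (i in seq_len(nrow(pr))) unite(pr[i, 1], pr[i, 2]) }
  a <- L[-H, -1]; b <- L[-1, -W]
  sel <- a > 0L & b > 0L & a != b
  if (any(sel)) { pr <- unique(cbind(a[sel], b[sel])); for (i in seq_len(nrow(pr))) unite(pr[i, 1], pr[i, 2]) }
  roots <- vapply(seq_len(K), findp, integer(1))
  relab <- match(roots, unique(roots))
  out <- L
  out[L > 0L] <- relab[L[L > 0L]]
  out
}

#' Relabel a label image to contiguous 1..K preserving label order
#' @noRd
relabel_contiguous <- function(labels) {
  u <- sort(unique(labels[labels > 0L]))
  if (length(u) == 0L) return(labels)
  out <- labels
  out[labels > 0L] <- match(labels[labels > 0L], u)
  out
}

#' Render integrated 2D Gaussian spots into an image matrix
#'
#' Pixel centers sit at integer coordinates (x = column, y = row, 1-based,
#' origin top-left); each pixel integrates the Gaussian over its unit area,
#' so a spot's summed pixel values equal its nominal integrated intensity
#' (up to boundary truncation).
#' @noRd
render_gaussians <- function(h, w, x, y, intensity, sigma) {
  img <- matrix(0, h, w)
  if (length(x) == 0L) return(img)
  sigma <- rep_len(sigma, length(x))
  intensity <- rep_len(intensity, length(x))
  for (i in seq_along(x)) {
    s <- sigma[i]
    r <- ceiling(5 * s)
    cx <- round(x[i]); cy <- round(y[i])
    c0 <- max(1L, cx - r); c1 <- min(w, cx + r)
    r0 <- max(1L, cy - r); r1 <- min(h, cy + r)
    if (c0 > c1 || r0 > r1) next
    px <- c0:c1; py <- r0:r1
    fx <- pnorm(px + 0.5, x[i], s) - pnorm(px - 0.5, x[i], s)
    fy <- pnorm(py + 0.5, y[i], s) - pnorm(py - 0.5, y[i], s)
    img[py, px] <- img[py, px] + intensity[i] * outer(fy, fx)
  }
  img
}

#' Apply the configured noise model to a noise-free image
#' @noRd
apply_noise <- function(img, noise_model) {
  if (is.null(noise_model) || identical(noise_model$type, "none")) return(img)
  if (identical(noise_model$type, "poisson")) {
    out <- matrix(rpois(length(img), lambda = pmax(img, 0)), nrow(img), ncol(img))
    return(out * 1.0)
  }
  if (identical(noise_model$type, "gaussian")) {
    sd <- noise_model$sd %||% 1
    if (sd == 0) return(img)
    return(img + matrix(rnorm(length(img), sd = sd), nrow(img), ncol(img)))
  }
  stop("unknown noise model: ", noise_model$type)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Robust Gaussian background fit (median and 1.4826 * MAD)
#' @noRd
robust_gaussian <- function(x) {
  x <- x[is.finite(x)]
  m <- median(x)
  s <- mad(x, center = m)    # mad() already applies the 1.4826 consistency factor
  list(center = m, sd = s)
}
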