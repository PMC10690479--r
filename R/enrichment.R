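## Label-free pull-down enrichment statistics: identification filtering,
## median normalization, log2 transform with normal imputation, the
## S0-moderated Welch test, permutation-based FDR, and enrichment calls.

#' Protein-group intensity matrix
#'
#' Container for a proteins x samples matrix of positive (iBAQ-like)
#' intensities with missing values, per-protein peptide counts, per-sample
#' group labels, and optional reverse-database / contaminant flags.
#'
#' @param intensities numeric matrix, proteins x samples; NA = missing;
#'   present values must be > 0. Row names identify proteins.
#' @param groups factor of length ncol(intensities) with >= 2 levels.
#' @param peptides integer vector of per-protein peptide counts (default 2,
#'   i.e. unconstrained by the peptide filter).
#' @param reverse,contaminant logical per-protein flags.
#' @param log2 whether `intensities` is already on the log2 scale.
#' @return an `intensity_matrix` object.
#' @export
intensity_matrix <- function(intensities, groups, peptides = NULL,
                             reverse = NULL, contaminant = NULL,
                             log2 = FALSE) {
  stopifnot(is.matrix(intensities), length(groups) == ncol(intensities))
  if (!log2 && any(intensities[is.finite(intensities)] <= 0))
    stop("linear-scale intensities must be positive where present")
  groups <- as.factor(groups)
  np <- nrow(intensities)
  peptides <- if (is.null(peptides)) rep(2L, np) else as.integer(peptides)
  reverse <- if (is.null(reverse)) rep(FALSE, np) else reverse
  contaminant <- if (is.null(contaminant)) rep(FALSE, np) else contaminant
  stopifnot(length(peptides) == np, length(reverse) == np,
            length(contaminant) == np)
  if (is.null(rownames(intensities)))
    rownames(intensities) <- sprintf("P%04d", seq_len(np))
  structure(list(intensities = intensities, groups = groups,
                 peptides = peptides, reverse = reverse,
                 contaminant = contaminant, log2 = log2),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("intensity_matrix: %d proteins x %d samples (%s scale), groups: %s\n",
              nrow(x$intensities), ncol(x$intensities),
              if (x$log2) "log2" else "linear",
              paste(sprintf("%s=%d", levels(x$groups), table(x$groups)),
                    collapse = ", ")))
  cat(sprintf("  missing: %.1f%%\n", 100 * mean(is.na(x$intensities))))
  invisible(x)
}

#' Filter protein identifications
#'
#' Keeps proteins identified by at least `min_peptides` peptides and with at
#' least `min_events` quantification events (non-missing intensities) in at
#' least one experimental group; drops reverse-database hits and common
#' contaminants.
#'
#' @param m an [intensity_matrix].
#' @param min_peptides minimum peptide count (default 2).
#' @param min_events minimum per-group quantification events (default 3).
#' @return the filtered [intensity_matrix].
#' @export
filter_proteins <- function(m, min_peptides = 2L, min_events = 3L) {
  stopifnot(inherits(m, "intensity_matrix"))
  ev <- sapply(levels(m$groups), function(g)
    rowSums(!is.na(m$intensities[, m$groups == g, drop = FALSE])))
  if (is.null(dim(ev))) ev <- matrix(ev, nrow = 1)
  keep <- m$peptides >= min_peptides &
    apply(ev, 1, max) >= min_events &
    !m$reverse & !m$contaminant
  intensity_matrix(m$intensities[keep, , drop = FALSE], m$groups,
                   m$peptides[keep], m$reverse[keep], m$contaminant[keep],
                   log2 = m$log2)
}

#' Median normalization on complete cases
#'
#' Each sample is divided by the median intensity of the proteins
#' quantified in every sample (complete rows), so that after normalization
#' every sample's complete-row median equals 1. Using only complete rows
#' keeps the reference set identical across samples; the result is
#' invariant to per-sample multiplicative scaling of the input.
#'
#' @param m an [intensity_matrix] on the linear scale.
#' @return normalized [intensity_matrix].
#' @export
normalize_median <- function(m) {
  stopifnot(inherits(m, "intensity_matrix"), !m$log2)
  complete <- rowSums(is.na(m$intensities)) == 0
  if (!any(complete)) stop("no complete cases for normalization")
  med <- apply(m$intensities[complete, , drop = FALSE], 2, median)
  scaled <- sweep(m$intensities, 2, med, "/")
  intensity_matrix(scaled, m$groups, m$peptides, m$reverse, m$contaminant)
}

#' Log2 transform and normal-distribution imputation
#'
#' Missing values are filled per sample with draws from a normal
#' distribution derived from that sample's observed log2 intensities: mean
#' shifted down by `downshift` standard deviations and width shrunk to
#' `width` of the observed sd — emulating the fact that missing values
#' arise predominantly from low-abundance proteins.
#'
#' @param m an [intensity_matrix] (linear scale).
#' @param width imputation width as a fraction of the observed sd.
#' @param downshift imputation center downshift in observed sds.
#' @param seed integer RNG seed (imputation is seed-reproducible).
#' @return complete [intensity_matrix] on the log2 scale.
#' @export
log2_and_impute <- function(m, width = 0.3, downshift = 1.8, seed = 1L) {
  stopifnot(inherits(m, "intensity_matrix"), !m$log2, width > 0)
  lg <- log2(m$intensities)
  with_seed(seed, {
    for (j in seq_len(ncol(lg))) {
      obs <- lg[, j][!is.na(lg[, j])]
      nmiss <- sum(is.na(lg[, j]))
      if (nmiss == 0) next
      if (length(obs) < 2)
        stop("cannot estimate imputation distribution: sample ", j,
             " has fewer than 2 observed values")
      mu <- mean(obs); sd_s <- sd(obs)
      lg[is.na(lg[, j]), j] <- rnorm(nmiss, mu - downshift * sd_s, width * sd_s)
    }
  })
  intensity_matrix(lg, m$groups, m$peptides, m$reverse, m$contaminant,
                   log2 = TRUE)
}

## Vectorized S0-moderated Welch statistic for a proteins x samples log2
## matrix given a logical group-1 membership over columns.
welch_s0_stat <- function(x, in1, s0) {
  x1 <- x[, in1, drop = FALSE]; x2 <- x[, !in1, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  d <- sqrt(v1 / n1 + v2 / n2)
  if (s0 == 0 && any(d == 0)) stop("undefined statistic: zero variance with s0 = 0")
  (m1 - m2) / (d + s0)
}

#' S0-moderated Welch test
#'
#' For each protein computes the Welch two-sample statistic with a constant
#' S0 added to the denominator, t = (mean1 - mean2) / (sqrt(s1^2/n1 +
#' s2^2/n2) + S0), damping the significance of small-effect, tiny-variance
#' proteins, plus a median-based log2 fold change, median(group1) -
#' median(group2). Group 1 is the enrichment group (e.g. bait pull-down),
#' group 2 the control.
#'
#' @param m a complete log2-scale [intensity_matrix].
#' @param group1 level of `m$groups` treated as group 1; default the second
#'   level (the first level is the reference/control).
#' @param s0 the moderation constant (default 0.1); s0 = 0 recovers the
#'   textbook Welch statistic.
#' @param fc_method "median" (default) or "mean" log2 fold change.
#' @return data.frame with columns protein, t_s0, log2fc.
#' @export
welch_s0 <- function(m, group1 = NULL, s0 = 0.1, fc_method = c("median", "mean")) {
  stopifnot(inherits(m, "intensity_matrix"), m$log2,
            !any(is.na(m$intensities)))
  fc_method <- match.arg(fc_method)
  group1 <- group1 %||% levels(m$groups)[2]
  in1 <- m$groups == group1
  if (sum(in1) < 2 || sum(!in1) < 2) stop("each group needs >= 2 samples")
  x <- m$intensities
  t_s0 <- welch_s0_stat(x, in1, s0)
  fcfun <- if (fc_method == "median") median else mean
  log2fc <- apply(x[, in1, drop = FALSE], 1, fcfun) -
    apply(x[, !in1, drop = FALSE], 1, fcfun)
  data.frame(protein = rownames(x), t_s0 = t_s0, log2fc = log2fc,
             row.names = NULL)
}

## All distinct two-group partitions of the samples with the observed group
## sizes, excluding the observed partition. Each partition is returned as a
## logical group-1 membership over columns. Partitions, not labelings: a
## labeling and its mirror give the same |t|, so only one is kept.
distinct_partitions <- function(in1) {
  n <- length(in1); n1 <- sum(in1)
  combs <- combn(n, n1)
  keep <- rep(TRUE, ncol(combs))
  if (2 * n1 == n) {
    # balanced: partition {A,B} equals {B,A}; canonicalize by requiring
    # sample 1 in group 1
    keep <- combs[1, ] == 1L
  }
  obs <- which(in1)
  out <- list()
  for (j in which(keep)) {
    g <- combs[, j]
    if (identical(g, obs) || identical(sort(setdiff(seq_len(n), g)), obs)) next
    v <- rep(FALSE, n); v[g] <- TRUE
    out[[length(out) + 1L]] <- v
  }
  out
}

#' Permutation-based FDR for the S0-moderated Welch test
#'
#' Group labels are permuted and the statistic recomputed under each
#' permutation. For every threshold on |t|, FDR(threshold) = (mean permuted
#' count of |t| >= threshold) / (observed count >= threshold), capped at 1;
#' a protein's q-value is the minimum FDR over thresholds at or below its
#' own |t|, which makes q monotone non-increasing in |t|. When fewer
#' distinct group partitions exist than `n_perm` (e.g. 3 vs 3 samples), all
#' distinct partitions are enumerated and used with equal weight instead of
#' sampling; the observed partition is excluded from the null.
#'
#' @param m complete log2-scale [intensity_matrix].
#' @param group1 enrichment group level (default second level).
#' @param n_perm number of permutations (default 250).
#' @param s0 moderation constant (default 0.1).
#' @param seed RNG seed for permutation sampling.
#' @return data.frame protein, t_s0, log2fc, q; attribute `n_perm_used`
#'   records how many permutations were actually evaluated.
#' @export
permutation_fdr <- function(m, group1 = NULL, n_perm = 250L, s0 = 0.1,
                            seed = 1L) {
  stopifnot(inherits(m, "intensity_matrix"), m$log2)
  group1 <- group1 %||% levels(m$groups)[2]
  in1 <- m$groups == group1
  res <- welch_s0(m, group1 = group1, s0 = s0)
  parts <- distinct_partitions(in1)
  if (length(parts) < 1) stop("no distinct label permutations exist")
  perms <- with_seed(seed, {
    if (length(parts) > n_perm) sample(parts, n_perm) else parts
  })
  x <- m$intensities
  abs_obs <- abs(res$t_s0)
  perm_abs <- vapply(perms, function(p) abs(welch_s0_stat(x, p, s0)),
                     numeric(nrow(x)))
  # FDR at each observed |t| taken as a threshold
  ord <- order(abs_obs, decreasing = TRUE)
  thr <- abs_obs[ord]
  obs_count <- seq_along(thr)                       # |t_obs| >= thr, sorted
  pa <- sort(as.numeric(perm_abs), decreasing = TRUE)
  # counts of permuted |t| >= thr via merge on the sorted vector
  perm_count <- findInterval(-thr, -pa)             # number of pa >= thr
  fdr <- pmin(perm_count / length(perms) / obs_count, 1)
  # q = min FDR over thresholds at or below own |t|: a suffix minimum in
  # the decreasing-|t| order (a protein passes exactly the thresholds not
  # exceeding its own |t|)
  q_sorted <- rev(cummin(rev(fdr)))
  q <- numeric(length(thr)); q[ord] <- q_sorted
  res$q <- q
  attr(res, "n_perm_used") <- length(perms)
  res
}

#' Call enriched proteins
#'
#' A protein is enriched when its log2 fold change strictly exceeds
#' `fc_threshold_log2` (default log2(10) = 3.322, i.e. more than 10-fold)
#' and its permutation q-value is strictly below `q_threshold`.
#'
#' @param table output of [permutation_fdr] (columns log2fc, q).
#' @param fc_threshold_log2 log2 fold-change threshold (default log2(10)).
#' @param q_threshold q-value threshold (default 0.05).
#' @return the table with an added logical `enriched` column.
#' @export
classify_enriched <- function(table, fc_threshold_log2 = log2(10),
                              q_threshold = 0.05) {
  stopifnot(all(c("log2fc", "q") %in% names(table)))
  table$enriched <- table$log2fc > fc_threshold_log2 & table$q < q_threshold
  table
}

#' Volcano-plot table
#'
#' Plot-ready export: log2 fold change against -log10 q with the enrichment
#' flag and protein label.
#'
#' @param table output of [classify_enriched].
#' @return data.frame label, log2fc, neg_log10_q, enriched.
#' @export
volcano_table <- function(table) {
  stopifnot(all(c("protein", "log2fc", "q", "enriched") %in% names(table)))
  data.frame(label = table$protein, log2fc = table$log2fc,
             neg_log10_q = -log10(table$q), enriched = table$enriched,
             row.names = NULL)
}

#' Full enrichment screen
#'
#' Convenience wrapper chaining [filter_proteins], [normalize_median],
#' [log2_and_impute], [permutation_fdr] and [classify_enriched].
#'
#' @param m an [intensity_matrix] (linear scale, NAs allowed).
#' @param group1 enrichment group level.
#' @param s0,n_perm,fc_threshold_log2,q_threshold,width,downshift,seed see
#'   the individual stages.
#' @return classified enrichment table (see [classify_enriched]).
#' @export
enrichment_screen <- function(m, group1 = NULL, s0 = 0.1, n_perm = 250L,
                              fc_threshold_log2 = log2(10), q_threshold = 0.05,
                              width = 0.3, downshift = 1.8, seed = 1L) {
  m <- filter_proteins(m)
  m <- normalize_median(m)
  m <- log2_and_impute(m, width = width, downshift = downshift, seed = seed)
  tab <- permutation_fdr(m, group1 = group1, n_perm = n_perm, s0 = s0,
                         seed = seed)
  classify_enriched(tab, fc_threshold_log2, q_threshold)
}
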