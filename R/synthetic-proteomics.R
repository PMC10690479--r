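## Synthetic label-free proteomics matrices with spiked-in enriched
## proteins and intensity-dependent (missing-not-at-random) dropout.

#' Specification of a synthetic proteomics experiment
#'
#' Per-protein log2 intensity means are drawn from a normal distribution;
#' replicate values add normal noise; a chosen number of proteins is
#' "spiked" — their group-2 log2 mean raised by a fixed effect, emulating
#' bait-specific enrichment in a pull-down. Dropout is missing-not-at-random:
#' the probability that a measurement is missing decreases with its log2
#' intensity through a logistic curve.
#'
#' @param n_proteins number of proteins.
#' @param n_per_group replicates per group (>= 2).
#' @param base_log2_mean,base_log2_sd distribution of per-protein log2 mean
#'   intensities.
#' @param rep_log2_sd replicate-to-replicate sd on the log2 scale.
#' @param n_spiked number of truly enriched proteins (<= n_proteins).
#' @param spike_log2_effect log2 shift added to group 2 for spiked proteins.
#' @param dropout_midpoint,dropout_scale logistic dropout: a value at log2
#'   intensity z is missing with probability
#'   plogis(-(z - dropout_midpoint) / dropout_scale). Set
#'   `dropout_midpoint = -Inf` for no dropout.
#' @param peptides_range range of simulated per-protein peptide counts.
#' @param seed integer RNG seed.
#' @return a `proteomics_sim_spec` list.
#' @export
proteomics_sim_spec <- function(n_proteins = 1000L, n_per_group = 3L,
                                base_log2_mean = 25, base_log2_sd = 2,
                                rep_log2_sd = 0.5,
                                n_spiked = 0L, spike_log2_effect = 5,
                                dropout_midpoint = -Inf, dropout_scale = 1,
                                peptides_range = c(1L, 20L), seed = 1L) {
  stopifnot(n_proteins >= 1, n_per_group >= 2, n_spiked >= 0,
            n_spiked <= n_proteins, base_log2_sd >= 0, rep_log2_sd >= 0,
            dropout_scale > 0)
  structure(list(n_proteins = as.integer(n_proteins),
                 n_per_group = as.integer(n_per_group),
                 base_log2_mean = base_log2_mean, base_log2_sd = base_log2_sd,
                 rep_log2_sd = rep_log2_sd, n_spiked = as.integer(n_spiked),
                 spike_log2_effect = spike_log2_effect,
                 dropout_midpoint = dropout_midpoint,
                 dropout_scale = dropout_scale,
                 peptides_range = as.integer(peptides_range),
                 seed = as.integer(seed)),
            class = "proteomics_sim_spec")
}

#' Simulate a protein-group intensity matrix with known enriched proteins
#'
#' @param spec a [proteomics_sim_spec].
#' @return list with `matrix` (an [intensity_matrix]: linear-scale
#'   intensities with NAs for dropout, per-protein peptide counts, group
#'   labels) and `truth` (integer ids of the spiked proteins).
#' @examples
#' sim <- simulate_proteomics_matrix(proteomics_sim_spec(n_proteins = 50,
#'                                                       n_spiked = 5))
#' length(sim$truth)
#' @export
simulate_proteomics_matrix <- function(spec) {
  stopifnot(inherits(spec, "proteomics_sim_spec"))
  with_seed(spec$seed, {
    np <- spec$n_proteins; k <- spec$n_per_group
    groups <- factor(rep(c("control", "tail"), each = k),
                     levels = c("control", "tail"))
    base <- rnorm(np, spec$base_log2_mean, spec$base_log2_sd)
    log2m <- matrix(rep(base, 2 * k), np, 2 * k) +
      matrix(rnorm(np * 2 * k, 0, spec$rep_log2_sd), np, 2 * k)
    spiked <- if (spec$n_spiked > 0) sort(sample.int(np, spec$n_spiked)) else integer(0)
    if (length(spiked) > 0)
      log2m[spiked, groups == "tail"] <-
        log2m[spiked, groups == "tail"] + spec$spike_log2_effect
    if (is.finite(spec$dropout_midpoint)) {
      p_miss <- plogis(-(log2m - spec$dropout_midpoint) / spec$dropout_scale)
      log2m[matrix(runif(np * 2 * k), np, 2 * k) < p_miss] <- NA
    }
    intens <- 2^log2m
    rownames(intens) <- sprintf("P%04d", seq_len(np))
    colnames(intens) <- paste0(rep(c("control", "tail"), each = k), "_", seq_len(k))
    peptides <- sample(spec$peptides_range[1]:spec$peptides_range[2], np,
                       replace = TRUE)
    list(matrix = intensity_matrix(intens, groups = groups,
                                   peptides = peptides),
         truth = spiked)
  })
}
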