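make_matrix <- function(values, groups = rep(c("control", "tail"), each = 3),
                        peptides = NULL, ...) {
  intensity_matrix(values, groups = factor(groups, c("control", "tail")),
                   peptides = peptides, ...)
}

test_that("identification filters follow the peptide and event rules", {
  v <- matrix(2^rnorm(5 * 6, 25), 5, 6)
  v[2, ] <- c(10, 20, NA, 30, NA, NA)   # events (2, 1)
  v[3, ] <- c(1, 2, NA, NA, NA, NA)     # events (2, 0)
  v[4, 4:6] <- NA; v[4, 1:3] <- c(5, 6, 7)  # events (3, 0): kept
  m <- make_matrix(v, peptides = c(1L, 3L, 3L, 2L, 5L),
                   reverse = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  out <- filter_proteins(m)
  kept <- rownames(out$intensities)
  expect_setequal(kept, rownames(m$intensities)[c(4)])
  # protein 1: single peptide; 2 and 3: < 3 events in every group;
  # 5: reverse hit
})

test_that("median normalization equalizes complete-row medians and is scale invariant", {
  set.seed(1)
  v <- matrix(2^rnorm(60, 25, 1), 10, 6)
  v[1, 2] <- NA                      # one incomplete row
  m <- make_matrix(v)
  out <- normalize_median(m)
  med <- apply(out$intensities[-1, ], 2, median)
  expect_equal(max(med) / min(med), 1, tolerance = 1e-12)
  # multiplying one sample by 7 changes nothing after normalization
  v2 <- v; v2[, 3] <- v2[, 3] * 7
  out2 <- normalize_median(make_matrix(v2))
  expect_equal(out$intensities, out2$intensities)
  # no complete rows -> error
  v3 <- v; v3[, 1] <- NA
  expect_error(normalize_median(make_matrix(v3)), "no complete cases")
})

test_that("log2 transform is exact and imputation has the configured moments", {
  v <- matrix(2^matrix(rnorm(24, 25, 1), 4), 4, 6)
  m <- make_matrix(v)
  out <- log2_and_impute(m, seed = 1)
  expect_equal(unname(out$intensities), unname(log2(v)))
  # with missing values: seed-reproducible
  set.seed(42)
  big <- matrix(2^rnorm(4e4, 25, 1), 2e4, 2)
  miss <- sample(2e4, 8e3)
  bigNA <- big; bigNA[miss, 1] <- NA
  mb <- intensity_matrix(bigNA, groups = factor(c("a", "b")))
  i1 <- log2_and_impute(mb, seed = 9)
  i2 <- log2_and_impute(mb, seed = 9)
  expect_identical(i1$intensities, i2$intensities)
  # imputed draws: mean ~= observed mean - 1.8 sd, sd ~= 0.3 sd
  obs <- log2(big[-miss, 1]); imp <- i1$intensities[miss, 1]
  n <- length(imp)
  expect_lt(abs(mean(imp) - (mean(obs) - 1.8 * sd(obs))),
            3 * 0.3 * sd(obs) / sqrt(n))
  expect_lt(abs(sd(imp) - 0.3 * sd(obs)), 3 * 0.3 * sd(obs) / sqrt(2 * n))
})

test_that("the moderated Welch statistic matches its closed forms", {
  # identical groups -> t = 0, fc = 0
  v <- matrix(rep(c(1, 2, 3), 2 * 3), 3, 6)
  m <- make_matrix(v, log2 = TRUE)
  res <- welch_s0(m)
  expect_true(all(res$t_s0 == 0) && all(res$log2fc == 0))
  # zero-variance hand case: group means 2 and 0, d = 0, s0 = 0.1 -> t = 20
  v2 <- matrix(c(0, 0, 0, 2, 2, 2), 1, 6)
  res2 <- welch_s0(make_matrix(v2, log2 = TRUE), s0 = 0.1)
  expect_equal(res2$t_s0, 20)
  expect_equal(res2$log2fc, 2)
  # s0 = 0 with zero variance is undefined
  expect_error(welch_s0(make_matrix(v2, log2 = TRUE), s0 = 0), "undefined")
})

test_that("s0 = 0 reduces to the textbook Welch statistic", {
  set.seed(5)
  v <- matrix(rnorm(50 * 8, 25, 1), 50, 8)
  m <- make_matrix(v, groups = rep(c("control", "tail"), each = 4),
                   log2 = TRUE)
  res <- welch_s0(m, s0 = 0)
  ref <- apply(v, 1, function(r)
    t.test(r[5:8], r[1:4])$statistic)
  expect_equal(res$t_s0, unname(ref), tolerance = 1e-10)
})

test_that("permutation q-values are valid and rank the clear signal first", {
  set.seed(6)
  v <- matrix(rnorm(200 * 6, 25, 1), 200, 6)
  v[1, 4:6] <- v[1, 4:6] + 10        # one protein separated by 10 sd
  m <- make_matrix(v, log2 = TRUE)
  res <- permutation_fdr(m, seed = 3)
  expect_true(all(res$q >= 0 & res$q <= 1))
  expect_equal(which.min(res$q), 1)
  expect_true(res$q[1] == min(res$q))
  # q monotone non-increasing in |t|
  ord <- order(abs(res$t_s0), decreasing = TRUE)
  expect_true(all(diff(res$q[ord]) >= 0))
  # seed-reproducible
  expect_identical(res, permutation_fdr(m, seed = 3))
})

test_that("exchangeable groups yield no mass of small q-values", {
  set.seed(7)
  v <- matrix(rnorm(500 * 6, 25, 1), 500, 6)
  res <- permutation_fdr(make_matrix(v, log2 = TRUE), seed = 1)
  expect_lte(mean(res$q < 0.05), 0.05)
})

test_that("enrichment calls use strict 10-fold and q < 0.05 rules", {
  tab <- data.frame(protein = c("a", "b", "c", "d"),
                    t_s0 = c(5, 5, 5, 5),
                    log2fc = c(4.0, 3.0, 4.0, log2(10)),
                    q = c(0.01, 0.01, 0.2, 0.01))
  out <- classify_enriched(tab)
  expect_equal(out$enriched, c(TRUE, FALSE, FALSE, FALSE))
  # fold-change threshold is log2(10) = 3.322 to 3 decimals
  expect_equal(round(log2(10), 3), 3.322)
})

test_that("the volcano table mirrors the classified results", {
  tab <- classify_enriched(data.frame(protein = c("a", "b"),
                                      t_s0 = c(3, -1),
                                      log2fc = c(5, 0), q = c(0.001, 1)))
  v <- volcano_table(tab)
  expect_equal(nrow(v), 2)
  expect_equal(v$neg_log10_q, c(3, 0))
  expect_equal(v$enriched, tab$enriched)
})

test_that("the screen is invariant to per-sample multiplicative scaling", {
  sim <- simulate_proteomics_matrix(proteomics_sim_spec(
    n_proteins = 150, n_spiked = 10, peptides_range = c(2, 20), seed = 8))
  m <- sim$matrix
  scaled <- m
  scaled$intensities <- sweep(m$intensities, 2, c(1, 7, 0.5, 3, 2, 10), "*")
  a <- enrichment_screen(m, seed = 2)
  b <- enrichment_screen(scaled, seed = 2)
  expect_equal(a$t_s0, b$t_s0, tolerance = 1e-8)
  expect_equal(a$enriched, b$enriched)
})
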