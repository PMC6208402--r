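# Latent-factor association, genomic control, FDR, covariance model and the
# cross-validation statistic.

toy_freqs <- function(n_snps, n_pops, seed) {
  set.seed(seed)
  f <- matrix(runif(n_snps * n_pops, 0.05, 0.95), n_snps, n_pops)
  snps <- data.frame(snp_id = sprintf("s%04d", seq_len(n_snps)), chrom = "c",
                     pos = seq_len(n_snps), ref = "A", alt = "T",
                     stringsAsFactors = FALSE)
  colnames(f) <- sprintf("P%02d", seq_len(n_pops))
  freq_matrix(snps, f)
}

test_that("K = 0 reduces to per-SNP ordinary least squares (closed-form oracle)", {
  fr <- toy_freqs(20, 12, seed = 1)
  set.seed(2)
  env <- rnorm(12)
  fit <- fit_latent_association(fr, env, K = 0, n_restarts = 1, seed = 1,
                                ridge = 0, calibrate = FALSE)
  x <- as.vector(scale(env))
  for (j in 1:20) {
    ols <- summary(lm(fr$freq[j, ] ~ x))$coefficients["x", "t value"]
    expect_lt(abs(fit$snps$t[j] - ols), 1e-8)
  }
  # the z column is the df-calibrated normal-scale map of the same statistic
  df <- 12 - 0 - 2
  z_expect <- sign(fit$snps$t) *
    qnorm(pt(abs(fit$snps$t), df, lower.tail = FALSE, log.p = TRUE),
          lower.tail = FALSE, log.p = TRUE)
  expect_equal(fit$snps$z, z_expect, tolerance = 1e-10)
})

test_that("association input contracts are enforced", {
  fr <- toy_freqs(50, 8, seed = 3)
  expect_error(fit_latent_association(fr, rep(1, 8), K = 2), "constant")
  expect_error(fit_latent_association(fr, rnorm(5), K = 2), "length")
  expect_error(fit_latent_association(fr, rnorm(8), K = 6), "degrees of freedom")
})

test_that("null environments give centred z and restart-stable medians", {
  p <- small_sim_params(seed = 20, prop_adaptive = 0, sweep_genes = 0)
  sim <- simulate_pool_seq(p)
  fr <- filtered_freqs(sim, p)
  set.seed(4)
  env <- rnorm(p$n_pops)
  fit <- suppressWarnings(
    fit_latent_association(fr, env, K = 3, n_restarts = 6, seed = 5))
  expect_true(abs(median(fit$snps$z)) < 0.1)
  # restart-count invariance when restarts agree (same seed stream prefix)
  fit2 <- suppressWarnings(
    fit_latent_association(fr, env, K = 3, n_restarts = 12, seed = 5))
  expect_gt(cor(fit$snps$z, fit2$snps$z), 0.98)
})

test_that("genomic inflation follows its definition and null behaviour", {
  # median z^2 exactly at the chi-square median -> lambda = 1
  z <- c(rep(sqrt(qchisq(0.5, 1)), 11), rep(0.1, 5), rep(2, 5))
  expect_equal(genomic_inflation(z), 1.0)
  expect_equal(genomic_inflation(2 * z), 4.0)
  set.seed(6)
  z10k <- rnorm(10000)
  expect_true(genomic_inflation(z10k) > 0.93 && genomic_inflation(z10k) < 1.07)
  expect_error(genomic_inflation(rnorm(5)), "at least 10")
  expect_warning(l0 <- genomic_inflation(rep(0, 100)), "zero")
  expect_equal(l0, 0)
})

test_that("lambda correction and BH behave as specified", {
  set.seed(7)
  z <- rnorm(50)
  res <- correct_pvalues(z, lambda = 1, fdr = 0.05)
  expect_equal(res$snps$p_adj, 2 * pnorm(-abs(z)), tolerance = 1e-12)
  # BH step-through: all four significant at fdr 0.05
  pvals <- c(0.001, 0.008, 0.039, 0.041)
  z4 <- qnorm(pvals / 2, lower.tail = FALSE)
  res4 <- correct_pvalues(z4, lambda = 1, fdr = 0.05)
  expect_true(all(res4$snps$significant))
  # q-values are monotone in p-rank; significance is a prefix of the sorted list
  set.seed(8)
  zr <- rnorm(200) * c(rep(3, 20), rep(1, 180))
  rr <- correct_pvalues(zr, lambda = genomic_inflation(zr), fdr = 0.1)
  ord <- order(rr$snps$p_adj)
  expect_true(all(diff(rr$snps$q[ord]) >= -1e-12))
  sig_ranks <- which(rr$snps$significant[ord])
  if (length(sig_ranks) > 0) {
    expect_equal(sig_ranks, seq_along(sig_ranks))
  }
  expect_error(correct_pvalues(z, lambda = 0), "lambda")
})

test_that("planted effects are recovered with the correct sign", {
  p <- sim_params(n_snps = 4000, n_genes = 100, n_pathways = 6,
                  genes_per_pathway = 10, seed = 21)
  sim <- simulate_pool_seq(p)
  fr <- filtered_freqs(sim, p)
  tr <- sim$truth$snps[match(fr$snps$snp_id, sim$truth$snps$snp_id), ]
  idx <- which(tr$is_adaptive & tr$driver == "Site_type")
  fit <- suppressWarnings(
    fit_latent_association(fr, sim$env$Site_type, K = 3, n_restarts = 12,
                           seed = 9))
  expect_gte(mean(fit$snps$z[idx] > 0), 0.95)
})

test_that("the pool covariance model captures shared structure", {
  # no structure: off-diagonals stay small
  fr <- toy_freqs(5000, 6, seed = 10)
  cm <- estimate_covariance(fr, subset_fraction = 0.5, seed = 1)
  expect_lt(max(abs(cm$omega[upper.tri(cm$omega)])), 0.1)
  expect_equal(cm$omega, t(cm$omega), tolerance = 1e-12)
  expect_true(all(eigen(cm$omega, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-10))
  # whitening really whitens the ridged covariance (omega itself is rank
  # n-1: standardized frequencies are centred across pools)
  w <- cm$whitening
  expect_equal(unname(w %*% (cm$omega + diag(1e-8, 6)) %*% t(w)), diag(6),
               tolerance = 1e-6)
  # duplicated pools produce near-identical covariance rows
  fr2 <- fr
  fr2$freq[, 2] <- fr2$freq[, 1]
  cm2 <- estimate_covariance(fr2, subset_fraction = 0.5, seed = 1)
  expect_lt(max(abs(cm2$omega[1, -c(1, 2)] - cm2$omega[2, -c(1, 2)])), 1e-10)
  expect_error(estimate_covariance(toy_freqs(300, 4, seed = 11),
                                   subset_fraction = 0.1), ">= 100")
})

test_that("the cross-validation statistic is half absolute Spearman, whitened", {
  fr <- toy_freqs(200, 4, seed = 12)
  cm <- estimate_covariance(fr, subset_fraction = 1, seed = 2)
  set.seed(13)
  env <- rnorm(4)
  # under an identity covariance model, a SNP monotone in env scores 0.5
  cm_id <- structure(list(omega = diag(4), whitening = diag(4),
                          snp_subset = 1:10), class = "covariance_model")
  fr_mono <- fr
  fr_mono$freq[1, ] <- 0.2 + 0.15 * rank(env)
  z_mono <- covariance_corrected_statistic(fr_mono, env, cm_id)
  expect_equal(z_mono$snps$Z[1], 0.5)
  zc <- covariance_corrected_statistic(fr, env, cm)
  expect_true(all(zc$snps$Z >= 0 & zc$snps$Z <= 0.5, na.rm = TRUE))
  # constant SNP -> missing marker
  fr$freq[1, ] <- 0.4
  zc2 <- covariance_corrected_statistic(fr, env, cm)
  expect_true(is.na(zc2$snps$Z[1]))
  # permuted-env null on 4 pools: mean Z in the documented band
  frn <- toy_freqs(5000, 4, seed = 14)
  cmn <- estimate_covariance(frn, subset_fraction = 0.5, seed = 3)
  zcn <- covariance_corrected_statistic(frn, rnorm(4), cmn)
  expect_gt(mean(zcn$snps$Z, na.rm = TRUE), 0.15)
  expect_lt(mean(zcn$snps$Z, na.rm = TRUE), 0.35)
})

test_that("distribution comparison handles identical, shifted, disjoint sets", {
  set.seed(15)
  a <- runif(500, 0, 0.5)
  same <- compare_statistic_distributions(a, a)
  expect_equal(same$ks_stat, 0)
  expect_equal(same$overlap, 1)
  expect_equal(same$median_diff, 0)
  lo <- runif(300, 0, 0.2)
  hi <- runif(300, 0.3, 0.5)
  disj <- compare_statistic_distributions(hi, lo)
  expect_equal(disj$overlap, 0)
  expect_gt(disj$median_diff, 0)
  expect_lt(disj$ks_p, 0.01)
  expect_error(compare_statistic_distributions(numeric(0), a), "non-empty")
})
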