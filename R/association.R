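# Latent-factor environmental association with genomic-control calibration,
# FDR, and covariance-corrected cross-validation.

# Map a t statistic with df residual degrees of freedom onto the standard
# normal scale. Keeps null z-scores N(0,1) for any design size, so the
# genomic inflation factor is ~1 under the null and lambda-corrected P
# values are uniform; done through log tail probabilities so extreme
# statistics do not underflow.
t_to_z <- function(t, df) {
  lp <- pt(abs(t), df = df, lower.tail = FALSE, log.p = TRUE)
  sign(t) * qnorm(lp, lower.tail = FALSE, log.p = TRUE)
}

# Empirical-null calibration of association statistics (Efron-style): the
# overwhelming majority of SNPs are null, so the genome-wide t distribution
# estimates the null itself. Pooled binomial sampling noise makes the
# statistic distribution depend strongly on the allele frequency (rare
# variants are nearly discrete), so SNPs are stratified by folded mean
# frequency and calibrated within strata. Within a stratum the body of the
# distribution (up to the 95th percentile of |t|) is mapped to the normal
# scale by mid-ranks — exactly uniform null P values by construction —
# while the tail beyond it follows a scaled-t reference whose scale and
# degrees of freedom are fitted to the stratum's shoulder quantiles (75th
# and 90th percentiles of |t| — central enough that a small fraction of
# genuine signals cannot contaminate them), with the degrees of freedom
# bounded below by the design's nominal residual df (the tail is never
# assumed heavier than the regression model itself implies). This
# generalizes genomic control: the anchor scale plays the role of
# sqrt(lambda), and the empirical body absorbs the shape heterogeneity
# that no single inflation factor can.
empirical_null_z <- function(t, df_nominal, strata = NULL, n_strata = 8,
                             body_q = 0.95) {
  m <- length(t)
  if (m < 50 || all(t == 0)) return(t_to_z(t, df_nominal))
  if (is.null(strata) || m < 500) {
    bin <- rep(1L, m)
  } else {
    br <- unique(quantile(strata, probs = seq(0, 1, length.out = n_strata + 1)))
    bin <- if (length(br) < 3) rep(1L, m) else
      as.integer(cut(strata, breaks = br, include.lowest = TRUE))
  }
  df_grid <- c(seq(max(3, df_nominal), 30), seq(32, 60, 2), 80, 120, 240)
  grid_ratio <- qt(0.95, df_grid) / qt(0.875, df_grid)
  z <- numeric(m)
  for (b in unique(bin)) {
    i <- which(bin == b)
    at <- abs(t[i])
    q_body <- quantile(at, body_q, names = FALSE)
    if (q_body <= 0) {
      z[i] <- t_to_z(t[i], df_nominal)
      next
    }
    # body: mid-rank two-sided quantile map (ties share a rank)
    u <- (rank(at, ties.method = "average") - 0.5) / length(at)
    z_mag <- qnorm((1 + u) / 2)
    # tail: scaled-t fitted to the shoulder, taking over beyond the body
    # wherever it exceeds the rank map
    in_tail <- at > q_body
    if (any(in_tail)) {
      q75 <- quantile(at, 0.75, names = FALSE)
      q90 <- quantile(at, 0.90, names = FALSE)
      if (q75 > 0 && q90 > q75) {
        df_hat <- df_grid[which.min(abs(log(grid_ratio) - log(q90 / q75)))]
        sigma <- q75 / qt(0.875, df_hat)
        zt <- t_to_z(at[in_tail] / sigma, df_hat)
        z_mag[in_tail] <- pmax(zt, z_mag[in_tail])
      }
    }
    z[i] <- sign(t[i]) * z_mag
  }
  z
}

#' Latent-factor association of allele frequencies with an environmental
#' variable
#'
#' Fits, per SNP, the model `freq = mu + x * beta + U V' + noise` where `x`
#' is the standardized environmental variable and `U V'` is a rank-K latent
#' structure term absorbing neutral population stratification. Estimation
#' alternates (a) a rank-K truncated SVD of the residual matrix to update
#' the latent term and (b) per-SNP ridge regression of the
#' latent-adjusted frequencies on `x`, until the largest change in any beta
#' falls below `tol` (or `max_iter` sweeps). The procedure is repeated from
#' `n_restarts` random initializations and per-SNP statistics are combined
#' as the median over restarts. The per-SNP statistic is the t ratio (beta
#' over its standard error, `n_pools - K - 2` residual degrees of freedom);
#' it is mapped onto the standard-normal z scale through an empirical-null
#' calibration of the genome-wide statistic distribution (see Details), and
#' raw P values are two-sided normal tails.
#'
#' @details The bulk of the genome-wide t distribution is dominated by
#' non-associated SNPs and therefore estimates the null distribution
#' itself. A scaled-t family is fitted to the bulk by quantile matching and
#' t statistics are transformed through it, which keeps null z-scores close
#' to standard normal even though pooled binomial sampling noise is not
#' Gaussian at small pool numbers. With `calibrate = FALSE` the nominal
#' Student-t distribution with `n_pools - K - 2` degrees of freedom is used
#' instead. The pre-calibration t statistics are returned in column `t`.
#'
#' @param freqs a `freq_matrix`.
#' @param env_values numeric vector, one value per pool (a 0/1 Site-type
#'   coding is used as-is).
#' @param K number of latent factors; must leave at least one residual
#'   degree of freedom (`K <= n_pools - 3`).
#' @param n_restarts random restarts combined by median z (default 12).
#' @param seed integer seed for the restart initializations.
#' @param ridge ridge penalty on the per-SNP regression (default 1e-8).
#' @param tol,max_iter convergence control.
#' @param calibrate use the empirical-null z calibration (default `TRUE`).
#' @return object of class `assoc_fit`: data.frame `snps` with `snp_id`,
#'   `z`, `p_raw`; attributes `K`, `n_restarts`, `converged`.
#' @export
fit_latent_association <- function(freqs, env_values, K, n_restarts = 12,
                                   seed = 1L, ridge = 1e-8, tol = 1e-6,
                                   max_iter = 100, calibrate = TRUE) {
  f <- freqs$freq
  n <- ncol(f)
  if (length(env_values) != n)
    stop_invalid("env_values has length %d but there are %d pools",
                 length(env_values), n)
  if (sd(env_values) == 0) stop_invalid("environmental variable is constant")
  if (K < 0) stop_invalid("K must be >= 0")
  df <- n - K - 2
  if (df < 1)
    stop_invalid(
      "K = %d leaves no residual degrees of freedom with %d pools (need K <= n_pools - 3)",
      K, n)

  Y <- t(f)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  x <- as.vector(scale(env_values))
  sxx <- sum(x^2)
  m <- ncol(Yc)

  one_fit <- function(restart_seed) {
    if (K == 0) {
      beta <- as.vector(crossprod(x, Yc)) / (sxx + ridge)
      return(list(beta = beta, L = matrix(0, n, m), converged = TRUE))
    }
    set.seed(restart_seed)
    U0 <- qr.Q(qr(matrix(rnorm(n * K), n, K)))
    L <- U0 %*% crossprod(U0, Yc)
    beta <- rep(0, m)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      beta_new <- as.vector(crossprod(x, Yc - L)) / (sxx + ridge)
      E <- Yc - tcrossprod(x, beta_new)
      G <- tcrossprod(E)
      Uk <- eigen(G, symmetric = TRUE)$vectors[, seq_len(K), drop = FALSE]
      L <- Uk %*% crossprod(Uk, E)
      if (max(abs(beta_new - beta)) < tol) {
        beta <- beta_new
        converged <- TRUE
        break
      }
      beta <- beta_new
    }
    list(beta = beta, L = L, converged = converged)
  }

  restart_seeds <- split_seed(seed, "restarts") + seq_len(n_restarts)
  ts <- matrix(NA_real_, m, n_restarts)
  conv <- logical(n_restarts)
  for (r in seq_len(n_restarts)) {
    fitr <- one_fit(restart_seeds[r])
    conv[r] <- fitr$converged
    resid <- Yc - tcrossprod(x, fitr$beta) - fitr$L
    rss <- colSums(resid^2)
    sigma2 <- pmax(rss / df, .Machine$double.xmin)
    ts[, r] <- fitr$beta / sqrt(sigma2 / sxx)
  }
  if (!all(conv))
    warning(sprintf("%d of %d restarts did not converge in %d iterations; last iterate used",
                    sum(!conv), n_restarts, max_iter))
  tstat <- apply(ts, 1, median)
  pbar <- colMeans(Y)
  z <- if (calibrate) {
    empirical_null_z(tstat, df, strata = pmin(pbar, 1 - pbar))
  } else {
    t_to_z(tstat, df)
  }
  out <- data.frame(snp_id = freqs$snps$snp_id, t = tstat, z = z,
                    p_raw = 2 * pnorm(-abs(z)), stringsAsFactors = FALSE)
  structure(list(snps = out), class = "assoc_fit",
            K = K, n_restarts = n_restarts, converged = all(conv))
}

#' Genomic inflation factor
#'
#' lambda = median(z^2) / qchisq(0.5, 1), the ratio of the observed median
#' association statistic to its theoretical null median (0.4549364).
#'
#' @param z numeric vector of z-scores (>= 10 required).
#' @return lambda (scalar).
#' @export
genomic_inflation <- function(z) {
  if (inherits(z, "assoc_fit")) z <- z$snps$z
  if (length(z) < 10) stop_invalid("need at least 10 SNPs to estimate lambda")
  if (all(z == 0)) {
    warning("all z-scores are zero; lambda set to 0")
    return(0)
  }
  median(z^2) / qchisq(0.5, df = 1)
}

#' Genomic-control correction and FDR
#'
#' Corrected P values are upper 1-df chi-square tails of z^2 / lambda
#' (standard genomic control); q-values are Benjamini-Hochberg, and a SNP is
#' significant iff its q-value is at most `fdr`.
#'
#' @param fit an `assoc_fit` (or numeric z vector).
#' @param lambda genomic inflation factor (> 0).
#' @param fdr false discovery rate (default 0.01).
#' @param variable optional label of the environmental variable.
#' @return object of class `assoc_result`: data.frame `snps` with `z`,
#'   `p_raw`, `p_adj`, `q`, `significant`; attributes `lambda`, `fdr`,
#'   `variable`.
#' @export
correct_pvalues <- function(fit, lambda, fdr = 0.01, variable = NA_character_) {
  if (lambda <= 0) stop_invalid("lambda must be > 0")
  snps <- if (inherits(fit, "assoc_fit")) fit$snps else
    data.frame(snp_id = sprintf("snp%06d", seq_along(fit)), z = fit,
               p_raw = 2 * pnorm(-abs(fit)), stringsAsFactors = FALSE)
  snps$p_adj <- pchisq(snps$z^2 / lambda, df = 1, lower.tail = FALSE)
  snps$q <- p.adjust(snps$p_adj, method = "BH")
  snps$significant <- snps$q <= fdr
  structure(list(snps = snps), class = "assoc_result",
            lambda = lambda, fdr = fdr, variable = variable)
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("assoc_result (%s): %d SNPs, lambda = %.3f, %d significant at FDR %.0f%%\n",
              attr(x, "variable"), nrow(x$snps), attr(x, "lambda"),
              sum(x$snps$significant), 100 * attr(x, "fdr")))
  invisible(x)
}

#' Association protocol for one environmental variable
#'
#' Runs [fit_latent_association()] for each candidate K, computes the
#' genomic inflation factor of each fit, selects K with
#' [choose_latent_count()], and returns the lambda-corrected result for the
#' chosen K.
#'
#' @param freqs a `freq_matrix`.
#' @param env environment table.
#' @param variable environment column name.
#' @param Ks candidate latent-factor counts (default 2:4).
#' @param n_restarts,seed,fdr passed through.
#' @return an `assoc_result` with extra attributes `K` (chosen) and
#'   `lambda_by_k`.
#' @export
associate_variable <- function(freqs, env, variable, Ks = 2:4,
                               n_restarts = 12, seed = 1L, fdr = 0.01) {
  fits <- lapply(Ks, function(k) {
    fit_latent_association(freqs, env[[variable]], K = k,
                           n_restarts = n_restarts,
                           seed = split_seed(seed, paste0(variable, k)))
  })
  lambdas <- setNames(vapply(fits, genomic_inflation, 0), Ks)
  K <- choose_latent_count(lambdas)
  res <- correct_pvalues(fits[[match(K, Ks)]], lambdas[[as.character(K)]],
                         fdr = fdr, variable = variable)
  attr(res, "K") <- K
  attr(res, "lambda_by_k") <- lambdas
  res
}

#' Pool covariance model of standardized allele frequencies
#'
#' Moment estimator of the pool-by-pool covariance of standardized
#' frequencies on a random SNP subset: per SNP, x = (p - pbar) /
#' sqrt(pbar (1 - pbar)) with pbar the across-pool mean, and Omega is the
#' average of x x' over the subset. SNPs fixed across all pools are
#' excluded. The whitening transform is the inverse Cholesky factor of
#' Omega + 1e-8 I.
#'
#' @param freqs a `freq_matrix`.
#' @param subset_fraction fraction of SNPs to use (default 0.2).
#' @param seed integer seed for the subset draw.
#' @return object of class `covariance_model`: `omega`, `whitening`,
#'   `snp_subset`.
#' @export
estimate_covariance <- function(freqs, subset_fraction = 0.2, seed = 1L) {
  f <- freqs$freq
  pbar <- rowMeans(f)
  usable <- which(pbar > 0 & pbar < 1)
  n_sub <- min(round(subset_fraction * nrow(f)), length(usable))
  if (n_sub < 100)
    stop_invalid("covariance subset has %d non-fixed SNPs; need >= 100", n_sub)
  idx <- with_seed(split_seed(seed, "covariance"), sort(sample(usable, n_sub)))
  x <- (f[idx, , drop = FALSE] - pbar[idx]) / sqrt(pbar[idx] * (1 - pbar[idx]))
  omega <- crossprod(x) / length(idx)
  w <- solve(t(chol(omega + diag(1e-8, ncol(omega)))))
  structure(list(omega = omega, whitening = w, snp_subset = idx),
            class = "covariance_model")
}

#' Covariance-corrected environmental correlation statistic
#'
#' For each SNP, standardized frequencies and the standardized environmental
#' variable are whitened with the pool covariance model, and Z is half the
#' absolute Spearman rank correlation between the two whitened vectors
#' (average ranks for ties), so Z lies in [0, 0.5] with 0.5 indicating a
#' perfect monotone environmental relationship after removing shared
#' population structure. SNPs constant across pools get `NA`.
#'
#' @param freqs a `freq_matrix`.
#' @param env_values numeric vector per pool.
#' @param model a [estimate_covariance()] result fitted on the same pools.
#' @return object of class `crossval_result`: data.frame `snps` with
#'   `snp_id`, `Z`.
#' @export
covariance_corrected_statistic <- function(freqs, env_values, model) {
  f <- freqs$freq
  if (ncol(f) != ncol(model$omega))
    stop_invalid("covariance model was fitted on a different number of pools")
  w <- model$whitening
  e <- as.vector(w %*% as.vector(scale(env_values)))
  pbar <- rowMeans(f)
  Z <- rep(NA_real_, nrow(f))
  ok <- which(pbar > 0 & pbar < 1 & apply(f, 1, function(r) length(unique(r)) > 1))
  if (length(ok) > 0) {
    xs <- (f[ok, , drop = FALSE] - pbar[ok]) / sqrt(pbar[ok] * (1 - pbar[ok]))
    u <- xs %*% t(w)
    Z[ok] <- 0.5 * abs(apply(u, 1, function(row) cor(row, e, method = "spearman")))
  }
  structure(list(snps = data.frame(snp_id = freqs$snps$snp_id, Z = Z,
                                   stringsAsFactors = FALSE)),
            class = "crossval_result")
}

#' Compare cross-validation statistic distributions
#'
#' Summarizes the shift between the Z statistics of association-significant
#' SNPs and of a random SNP set: Kolmogorov-Smirnov statistic and P value,
#' median difference, and the overlap coefficient of 20-bin histograms over
#' [0, 0.5].
#'
#' @param z_associated,z_random numeric Z vectors (NAs dropped).
#' @return list: `ks_stat`, `ks_p`, `median_diff`, `overlap`.
#' @export
compare_statistic_distributions <- function(z_associated, z_random) {
  if (inherits(z_associated, "crossval_result")) z_associated <- z_associated$snps$Z
  if (inherits(z_random, "crossval_result")) z_random <- z_random$snps$Z
  a <- z_associated[!is.na(z_associated)]
  b <- z_random[!is.na(z_random)]
  if (length(a) == 0 || length(b) == 0)
    stop_invalid("both Z sets must be non-empty")
  ks <- suppressWarnings(ks.test(a, b))
  breaks <- seq(0, 0.5, length.out = 21)
  ha <- tabulate(cut(a, breaks, include.lowest = TRUE), nbins = 20) / length(a)
  hb <- tabulate(cut(b, breaks, include.lowest = TRUE), nbins = 20) / length(b)
  list(ks_stat = unname(ks$statistic), ks_p = ks$p.value,
       median_diff = median(a) - median(b),
       overlap = sum(pmin(ha, hb)))
}
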