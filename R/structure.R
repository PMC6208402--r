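# Neutral population structure: PCA of pooled allele frequencies on a random
# SNP subset, and selection of the latent-factor count K from genomic
# inflation factors.

#' Neutral structure PCA on a random SNP subset
#'
#' PCA with pools as observations and SNP allele frequencies as variables,
#' centered but not scaled (the common Pool-seq choice: frequencies share a
#' scale already).
#'
#' @param freqs a `freq_matrix`.
#' @param n_random number of random SNPs to use (clipped with a warning if
#'   more than available).
#' @param seed integer seed for the subset draw.
#' @return object of class `structure_result`: `scores`, `var_explained`,
#'   `snp_subset` (indices used).
#' @export
neutral_structure_pca <- function(freqs, n_random = 500000, seed = 1L) {
  f <- freqs$freq
  if (ncol(f) < 2) stop_invalid("need at least 2 pools")
  if (n_random > nrow(f)) {
    warning(sprintf("n_random clipped from %d to the %d available SNPs",
                    n_random, nrow(f)))
    n_random <- nrow(f)
  }
  idx <- sample_random_snps(freqs, n_random, seed = seed)
  p <- prcomp(t(f[idx, , drop = FALSE]), center = TRUE, scale. = FALSE)
  flip <- apply(p$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  structure(list(scores = sweep(p$x, 2, flip, `*`),
                 var_explained = 100 * p$sdev^2 / sum(p$sdev^2),
                 snp_subset = idx),
            class = "structure_result")
}

#' @export
print.structure_result <- function(x, ...) {
  cat(sprintf("structure_result: %d pools, %d SNPs; PC1 %.1f%%, PC2 %.1f%%\n",
              nrow(x$scores), length(x$snp_subset),
              x$var_explained[1],
              if (length(x$var_explained) > 1) x$var_explained[2] else NA))
  invisible(x)
}

#' Choose the latent-factor count from genomic inflation factors
#'
#' Given one genomic inflation factor per candidate K, returns the K whose
#' lambda is closest to 1 from above if any lambda >= 1 exists, else the K
#' with the largest lambda (i.e. still closest to 1); ties break toward the
#' smaller K. When every lambda exceeds 1 — the usual situation — this
#' reduces to picking the smallest lambda.
#'
#' @param lambdas named numeric vector: names are candidate K values,
#'   entries the corresponding genomic inflation factors.
#' @return the chosen K (integer).
#' @export
choose_latent_count <- function(lambdas) {
  if (length(lambdas) == 0) stop_invalid("no candidate K values supplied")
  ks <- as.integer(names(lambdas))
  if (anyNA(ks)) stop_invalid("lambdas must be named by candidate K")
  ord <- order(ks)
  ks <- ks[ord]; lambdas <- lambdas[ord]
  ge1 <- lambdas >= 1
  if (any(ge1)) {
    pool <- which(ge1)
    best <- pool[which.min(lambdas[pool])]
  } else {
    best <- which.max(lambdas)
  }
  ks[best]
}
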