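# Per-gene, per-population diversity statistics from pooled allele counts:
# segregating sites, nucleotide diversity pi, Watterson's theta, Tajima's D,
# and genome-wide percentiles.

#' Constants for Tajima's D
#'
#' The classical normalization constants for a haploid sample of size n:
#' a1 = sum 1/i, a2 = sum 1/i^2 (i = 1..n-1), b1 = (n+1)/(3(n-1)),
#' b2 = 2(n^2+n+3)/(9n(n-1)), c1 = b1 - 1/a1,
#' c2 = b2 - (n+2)/(a1 n) + a2/a1^2, e1 = c1/a1, e2 = c2/(a1^2 + a2).
#'
#' @param n haploid sample size (chromosomes per pool; >= 4).
#' @return object of class `tajima_constants` (named list incl. `n`).
#' @export
tajima_constants <- function(n) {
  if (n < 4) stop_invalid("Tajima's D needs a haploid sample size >= 4 (got %d)", n)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  structure(list(n = n, a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
                 e1 = c1 / a1, e2 = c2 / (a1^2 + a2)),
            class = "tajima_constants")
}

#' Map a pooled allele frequency to a chromosome count
#'
#' count = round(frequency x pool_size) with round-half-even, clamped to
#' [0, pool_size]. Sub-resolution variants (frequency below half a
#' chromosome) become invariant and are excluded from S downstream.
#'
#' @param frequency numeric in [0,1] (vectorized).
#' @param pool_size haploid chromosomes in the pool.
#' @return integer counts.
#' @export
freq_to_pool_counts <- function(frequency, pool_size) {
  if (any(frequency < 0 | frequency > 1, na.rm = TRUE))
    stop_invalid("frequencies must lie in [0,1]")
  pmin(pmax(as.integer(round(frequency * pool_size)), 0L), as.integer(pool_size))
}

#' Diversity statistics for one gene in one population
#'
#' From per-site derived-allele chromosome counts k (0..n): S is the number
#' of polymorphic sites (0 < k < n); pi is the sum over sites of the
#' unbiased per-site heterozygosity 2 k (n - k) / (n (n - 1)); theta_W =
#' S / a1; Tajima's D = (pi - theta_W) / sqrt(e1 S + e2 S (S - 1)), with
#' `NA` when S = 0. All quantities are invariant under swapping
#' derived/ancestral labels (k -> n - k).
#'
#' @param k integer vector of per-site derived-allele counts within the gene.
#' @param constants a [tajima_constants()] object (fixes n).
#' @return list: `S`, `pi`, `theta_w`, `D`.
#' @export
gene_diversity_stats <- function(k, constants) {
  n <- constants$n
  if (any(k < 0 | k > n))
    stop_invalid("counts must lie in [0, %d] (pool size mismatch with constants?)", n)
  poly <- k > 0 & k < n
  S <- sum(poly)
  pi <- sum(2 * k[poly] * (n - k[poly])) / (n * (n - 1))
  theta_w <- S / constants$a1
  D <- if (S == 0) NA_real_ else
    (pi - theta_w) / sqrt(constants$e1 * S + constants$e2 * S * (S - 1))
  list(S = S, pi = pi, theta_w = theta_w, D = D)
}

#' Genome-wide percentile of Tajima's D per gene
#'
#' Mid-rank percentile within one population: (number of genes with strictly
#' smaller D + half the ties) / number of genes with defined D. Genes with
#' S = 0 (undefined D) are excluded from the denominator.
#'
#' @param d numeric vector of per-gene D values (NA = undefined).
#' @return numeric vector of percentiles in [0,1] (`NA` where D is `NA`).
#' @export
diversity_percentiles <- function(d) {
  ok <- !is.na(d)
  if (sum(ok) < 2) stop_invalid("need >= 2 genes with defined D for percentiles")
  out <- rep(NA_real_, length(d))
  dv <- d[ok]
  out[ok] <- vapply(dv, function(x) {
    (sum(dv < x) + 0.5 * sum(dv == x)) / length(dv)
  }, 0)
  out
}

#' Per-gene, per-population diversity table
#'
#' Maps SNPs to genes, converts pooled frequencies to chromosome counts
#' (default: rounding, see [freq_to_pool_counts()]) and computes S, pi,
#' theta_W, Tajima's D and the genome-wide percentile of D for every gene in
#' every pool. With `estimator = "read_counts"` pi uses the read-depth-aware
#' unbiased pooled estimator (factor n/(n-1) x d/(d-1) on 2 p (1-p)) instead
#' of rounded chromosome counts; the default matches plain per-gene
#' Tajima's D computed from frequencies.
#'
#' @param freqs a `freq_matrix`.
#' @param models a [gene_models()] object.
#' @param pool_size haploid chromosomes per pool (default 60).
#' @param estimator `"rounded"` (default) or `"read_counts"`.
#' @param counts an [allele_counts()] object, required for
#'   `estimator = "read_counts"`.
#' @return data.frame (one row per gene x pool): `gene_id`, `pool`, `S`,
#'   `pi`, `theta_w`, `D`, `percentile`, plus `pi_per_bp` convenience.
#' @export
gene_diversity_table <- function(freqs, models, pool_size = 60,
                                 estimator = c("rounded", "read_counts"),
                                 counts = NULL) {
  estimator <- match.arg(estimator)
  consts <- tajima_constants(pool_size)
  mapping <- map_snps_to_genes(freqs$snps, models)
  mapping <- mapping[!is.na(mapping$gene_id), ]
  glen <- setNames(models$genes$end - models$genes$start0, models$genes$gene_id)
  pools <- freqs$pools
  rows <- list()
  for (g in unique(mapping$gene_id)) {
    idx <- match(mapping$snp_id[mapping$gene_id == g], freqs$snps$snp_id)
    for (j in seq_along(pools)) {
      p <- freqs$freq[idx, j]
      k <- freq_to_pool_counts(p, pool_size)
      st <- gene_diversity_stats(k, consts)
      if (estimator == "read_counts") {
        if (is.null(counts)) stop_invalid("read_counts estimator needs `counts`")
        d <- counts$depth[idx, j]
        ph <- counts$alt[idx, j] / d
        poly <- k > 0 & k < pool_size
        st$pi <- sum((pool_size / (pool_size - 1)) * (d[poly] / (d[poly] - 1)) *
                       2 * ph[poly] * (1 - ph[poly]))
        st$D <- if (st$S == 0) NA_real_ else
          (st$pi - st$theta_w) /
          sqrt(consts$e1 * st$S + consts$e2 * st$S * (st$S - 1))
      }
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = g, pool = pools[j], S = st$S, pi = st$pi,
        theta_w = st$theta_w, D = st$D,
        pi_per_bp = st$pi / glen[[g]], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$percentile <- NA_real_
  for (j in pools) {
    sel <- out$pool == j
    if (sum(!is.na(out$D[sel])) >= 2)
      out$percentile[sel] <- diversity_percentiles(out$D[sel])
  }
  rownames(out) <- NULL
  out
}
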