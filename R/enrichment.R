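# Polygenic gene-set enrichment: per-gene max-|z| scores, SNP-count bias
# adjustment, resampling null, empirical P/Q, and overlap pruning.

#' Per-gene association scores
#'
#' score = max |z| over the SNPs mapped to the gene (all SNPs, not only the
#' significant ones); genes without SNPs are absent from the table.
#'
#' @param z numeric z-scores named by (or ordered as) `mapping$snp_id`, or an
#'   `assoc_result`/`assoc_fit`.
#' @param mapping data.frame `snp_id`, `gene_id` (from
#'   [map_snps_to_genes()]); intergenic rows (`NA` gene) are ignored.
#' @return data.frame of class `gene_scores`: `gene_id`, `n_snps`, `raw`.
#' @export
score_genes <- function(z, mapping) {
  if (inherits(z, c("assoc_result", "assoc_fit"))) {
    z <- setNames(z$snps$z, z$snps$snp_id)
  }
  m <- mapping[!is.na(mapping$gene_id), ]
  if (nrow(m) == 0 || length(unique(m$gene_id)) < 1)
    stop_invalid("mapping covers no genes")
  zv <- if (!is.null(names(z))) z[m$snp_id] else z[match(m$snp_id, names(z))]
  agg <- tapply(abs(zv), m$gene_id, max)
  cnt <- tapply(zv, m$gene_id, length)
  out <- data.frame(gene_id = names(agg), n_snps = as.integer(cnt),
                    raw = as.numeric(agg), stringsAsFactors = FALSE)
  out <- out[order(out$gene_id), ]
  rownames(out) <- NULL
  class(out) <- c("gene_scores", "data.frame")
  out
}

#' Remove the SNP-count bias of max-|z| gene scores
#'
#' The maximum of |z| over a gene's SNPs grows with the SNP count, so raw
#' scores would favour long genes. Genes are binned by SNP-count deciles and
#' scores standardized within bins: adjusted = (raw - bin mean) / bin SD
#' (0 where the bin SD is 0).
#'
#' @param table a `gene_scores` table.
#' @param n_bins number of SNP-count bins (default 10).
#' @return the table with `bin` and `adjusted` columns added.
#' @export
adjust_scores <- function(table, n_bins = 10) {
  if (nrow(table) < n_bins)
    stop_invalid("need at least %d genes for %d bins", n_bins, n_bins)
  br <- unique(quantile(table$n_snps, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 2) {
    table$bin <- 1L
  } else {
    table$bin <- as.integer(cut(table$n_snps, breaks = br, include.lowest = TRUE))
  }
  mu <- tapply(table$raw, table$bin, mean)
  sg <- tapply(table$raw, table$bin, sd)
  sg[is.na(sg)] <- 0
  b <- as.character(table$bin)
  table$adjusted <- ifelse(sg[b] > 0, (table$raw - mu[b]) / sg[b], 0)
  table
}

#' Gene-set enrichment by resampled SUMSTAT
#'
#' For each gene set (restricted to scored genes; sets smaller than
#' `min_size` are skipped with a warning), SUMSTAT is the sum of the
#' members' adjusted scores. The null is the SUMSTAT of `n_perm` random gene
#' sets of identical size drawn without replacement from all scored genes;
#' the empirical P value is (1 + #null >= observed) / (n_perm + 1) and Q
#' values are Benjamini-Hochberg over the tested sets.
#'
#' @param table an adjusted `gene_scores` table (see [adjust_scores()]).
#' @param pathways named list of gene-id sets.
#' @param n_perm resampling count (>= 100).
#' @param seed integer seed.
#' @param min_size smallest set size tested (default 5).
#' @return data.frame of class `enrichment_result`: `set`, `size`,
#'   `sumstat`, `p_empirical`, `q`.
#' @export
enrich_gene_sets <- function(table, pathways, n_perm = 10000, seed = 1L,
                             min_size = 5) {
  if (n_perm < 100) stop_invalid("n_perm must be >= 100")
  scores <- setNames(table$adjusted, table$gene_id)
  members <- lapply(pathways, function(g) intersect(g, names(scores)))
  small <- lengths(members) < min_size
  if (any(small)) {
    warning(sprintf("skipping %d set(s) with fewer than %d scored genes: %s",
                    sum(small), min_size,
                    paste(names(pathways)[small], collapse = ",")))
    members <- members[!small]
  }
  if (length(members) == 0)
    stop_invalid("no gene set has >= %d scored genes", min_size)
  obs <- vapply(members, function(g) sum(scores[g]), 0)
  sizes <- lengths(members)
  with_seed(split_seed(seed, "enrichment"), {
    pvals <- vapply(seq_along(members), function(i) {
      null <- vapply(seq_len(n_perm),
                     function(...) sum(sample(scores, sizes[i])), 0)
      # tolerance guards against summation-order noise when a set spans
      # (nearly) all scored genes
      tol <- 1e-9 * max(1, abs(obs[i]))
      (1 + sum(null >= obs[i] - tol)) / (n_perm + 1)
    }, 0)
  })
  out <- data.frame(set = names(members), size = sizes, sumstat = obs,
                    p_empirical = pvals,
                    q = p.adjust(pvals, method = "BH"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Prune overlapping gene sets and re-test
#'
#' Iteratively accepts the set with the lowest empirical P among those with
#' Q <= `q_cutoff`, removes its member genes from all remaining sets,
#' recomputes SUMSTAT, empirical P and Q for the remainder, and repeats
#' until no set passes. This prevents a pathway from appearing enriched only
#' through genes it shares with an already-accepted pathway.
#'
#' @param table an adjusted `gene_scores` table.
#' @param pathways named list of gene-id sets.
#' @param q_cutoff post-pruning Q cutoff (default 0.10).
#' @param n_perm,seed,min_size passed to [enrich_gene_sets()].
#' @return list with `accepted` (data.frame in acceptance order: `set`,
#'   `size`, `sumstat`, `p_empirical`, `q`) and `initial` (the pre-pruning
#'   `enrichment_result`).
#' @export
prune_and_retest <- function(table, pathways, q_cutoff = 0.10,
                             n_perm = 10000, seed = 1L, min_size = 5) {
  initial <- suppressWarnings(
    enrich_gene_sets(table, pathways, n_perm = n_perm, seed = seed,
                     min_size = min_size))
  remaining <- pathways
  used <- character(0)
  accepted <- list()
  round <- 0L
  repeat {
    round <- round + 1L
    pruned <- lapply(remaining, function(g) setdiff(g, used))
    res <- tryCatch(
      suppressWarnings(enrich_gene_sets(table, pruned,
                                        n_perm = n_perm,
                                        seed = split_seed(seed, paste0("prune", round)),
                                        min_size = min_size)),
      error = function(e) NULL)
    if (is.null(res)) break
    pass <- res[res$q <= q_cutoff, ]
    if (nrow(pass) == 0) break
    best <- pass[which.min(pass$p_empirical), ]
    accepted[[length(accepted) + 1]] <- best
    used <- union(used, pruned[[best$set]])
    remaining <- remaining[names(remaining) != best$set]
    if (length(remaining) == 0) break
  }
  acc <- if (length(accepted) > 0) do.call(rbind, accepted) else
    initial[0, , drop = FALSE]
  rownames(acc) <- NULL
  list(accepted = acc, initial = initial)
}
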