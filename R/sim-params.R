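#' Simulation parameters for synthetic Pool-seq data
#'
#' Bundles every knob of the synthetic-data generator: study design (pools,
#' site types, genetic clusters), genome layout, drift and selection
#' parameters, and sequencing depth. Defaults describe the desk-scale study
#' design used throughout the package's tests: 12 pools of 30 diploids
#' (60 chromosomes each) in three genetic clusters, each cluster holding two
#' metallicolous (M) and two non-metallicolous (NM) pools, 10,000 bi-allelic
#' SNPs over 500 genes, 1% of SNPs environmentally adaptive, and five genes
#' carrying a selective-sweep signature in the M pools.
#'
#' @param n_pops number of pools (populations).
#' @param site_type_labels character vector of `"M"`/`"NM"` labels, one per
#'   pool. M = metalliferous site, NM = non-metalliferous.
#' @param cluster_assignment integer cluster index per pool; neutral drift is
#'   hierarchical, first between clusters then between pools within cluster.
#' @param pool_size haploid chromosomes per pool (2 x diploids; default 60).
#' @param n_snps number of bi-allelic SNPs.
#' @param n_scaffolds,n_genes,genes_per_pathway,n_pathways genome and
#'   pathway-collection layout.
#' @param fst_within_cluster,fst_between_cluster Balding-Nichols drift
#'   parameters in (0,1).
#' @param prop_adaptive fraction of SNPs given an environmental effect.
#' @param effect_size logit-scale allele-frequency slope per unit of
#'   standardized environmental value for adaptive SNPs.
#' @param prop_adaptive_in_pathway fraction of adaptive SNPs placed inside
#'   genes of the designated adaptive pathway (the first pathway), so that
#'   gene-set enrichment has a planted positive.
#' @param sweep_genes number of genes whose site-frequency spectrum is skewed
#'   toward rare alleles in the M pools (selective-sweep signature).
#' @param sweep_prob per-SNP probability that a site in a sweep gene is
#'   redrawn to near-fixation in an affected pool.
#' @param coverage_mean expected per-pool read depth per SNP.
#' @param soil_shift_sd separation, in within-type standard deviations,
#'   between M and NM means of the five designated soil variables.
#' @param scaffold_length optional fixed scaffold length in bp; `NULL` sizes
#'   scaffolds to fit the generated genes. If given and the genes cannot be
#'   packed, generation fails.
#' @param seed master integer seed; every generator stage derives its own
#'   sub-stream from it.
#'
#' @return an object of class `sim_params` (a validated list).
#' @examples
#' p <- sim_params(n_snps = 1000, n_genes = 50, seed = 1)
#' p$n_pops
#' @export
sim_params <- function(n_pops = 12,
                       site_type_labels = rep(c("M", "M", "NM", "NM"), length.out = n_pops),
                       cluster_assignment = rep(seq_len(ceiling(n_pops / 4)), each = 4,
                                                length.out = n_pops),
                       pool_size = 60,
                       n_snps = 10000,
                       n_scaffolds = 10,
                       n_genes = 500,
                       genes_per_pathway = 10,
                       n_pathways = 20,
                       fst_within_cluster = 0.05,
                       fst_between_cluster = 0.1,
                       prop_adaptive = 0.01,
                       effect_size = 2.0,
                       prop_adaptive_in_pathway = 0.7,
                       sweep_genes = 5,
                       sweep_prob = 0.8,
                       coverage_mean = 100,
                       soil_shift_sd = 6,
                       scaffold_length = NULL,
                       seed = 1L) {
  p <- list(
    n_pops = as.integer(n_pops),
    site_type_labels = as.character(site_type_labels),
    cluster_assignment = as.integer(cluster_assignment),
    pool_size = as.integer(pool_size),
    n_snps = as.integer(n_snps),
    n_scaffolds = as.integer(n_scaffolds),
    n_genes = as.integer(n_genes),
    genes_per_pathway = as.integer(genes_per_pathway),
    n_pathways = as.integer(n_pathways),
    fst_within_cluster = fst_within_cluster,
    fst_between_cluster = fst_between_cluster,
    prop_adaptive = prop_adaptive,
    effect_size = effect_size,
    prop_adaptive_in_pathway = prop_adaptive_in_pathway,
    sweep_genes = as.integer(sweep_genes),
    sweep_prob = sweep_prob,
    coverage_mean = coverage_mean,
    soil_shift_sd = soil_shift_sd,
    scaffold_length = scaffold_length,
    seed = as.integer(seed)
  )
  class(p) <- "sim_params"
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  if (p$n_pops < 2)
    stop_invalid("n_pops must be >= 2 (got %d)", p$n_pops)
  if (length(p$site_type_labels) != p$n_pops)
    stop_invalid("site_type_labels must have one entry per pool")
  if (!all(p$site_type_labels %in% c("M", "NM")))
    stop_invalid("site_type_labels must be 'M' or 'NM'")
  if (length(unique(p$site_type_labels)) < 2)
    stop_invalid("need at least one pool per site type")
  if (length(p$cluster_assignment) != p$n_pops)
    stop_invalid("cluster_assignment must have one entry per pool")
  if (p$pool_size < 2)
    stop_invalid("pool_size must be >= 2 (got %d)", p$pool_size)
  for (f in c("fst_within_cluster", "fst_between_cluster")) {
    if (p[[f]] <= 0 || p[[f]] >= 1)
      stop_invalid("%s must lie in (0,1)", f)
  }
  if (p$prop_adaptive < 0 || p$prop_adaptive > 1)
    stop_invalid("prop_adaptive must lie in [0,1]")
  if (p$coverage_mean <= 0)
    stop_invalid("coverage_mean must be > 0")
  if (p$n_genes < p$n_pathways * p$genes_per_pathway)
    stop_invalid("n_genes (%d) < n_pathways * genes_per_pathway (%d)",
                 p$n_genes, p$n_pathways * p$genes_per_pathway)
  invisible(p)
}

#' Study-design parameters mirroring the original four-pool field design
#'
#' Four pools of 30 diploids: two metallicolous pools forming one genetic
#' cluster and two non-metallicolous pools forming one cluster each (three
#' clusters in total). Kept available for structure and diversity analyses;
#' note that with 4 pools and K = 3 latent factors the association model has
#' no residual degrees of freedom, so association tests use the 12-pool
#' desk-scale design instead.
#'
#' @param ... overrides passed on to [sim_params()].
#' @return a `sim_params` object with the 4-pool layout.
#' @export
sim_params_paper <- function(...) {
  sim_params(n_pops = 4,
             site_type_labels = c("M", "M", "NM", "NM"),
             cluster_assignment = c(1L, 1L, 2L, 3L),
             ...)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Pool-seq simulation parameters\n")
  cat(sprintf("  pools: %d (%s)\n", x$n_pops,
              paste(x$site_type_labels, collapse = ",")))
  cat(sprintf("  clusters: %s\n", paste(x$cluster_assignment, collapse = ",")))
  cat(sprintf("  pool size: %d chromosomes; coverage mean %.0fx\n",
              x$pool_size, x$coverage_mean))
  cat(sprintf("  SNPs: %d over %d genes / %d scaffolds\n",
              x$n_snps, x$n_genes, x$n_scaffolds))
  cat(sprintf("  adaptive: %.1f%% of SNPs, effect %.2f; sweep genes: %d\n",
              100 * x$prop_adaptive, x$effect_size, x$sweep_genes))
  invisible(x)
}
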