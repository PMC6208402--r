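# End-to-end orchestration of the analysis on a dataset (typically a
# synthetic scenario): filtering, environment, structure, association,
# cross-validation, diversity, enrichment, candidate cascade, report.

#' Filter thresholds scaled to a study design
#'
#' The canonical threshold set is calibrated for a four-pool design with
#' ~150x coverage per pool (expected total depth 600): total depth below
#' twice the expected total, per-pool depth above one read per chromosome,
#' and alternate-count bounds of 4 and (total - 4). This helper rescales the
#' depth-dependent bounds to an arbitrary design while keeping the quality
#' rules fixed.
#'
#' @param params a [sim_params()] object (or any list with `n_pops`,
#'   `pool_size`, `coverage_mean`).
#' @return a [filter_thresholds()] object.
#' @export
scaled_thresholds <- function(params) {
  total <- params$n_pops * params$coverage_mean
  filter_thresholds(max_depth = 2 * total,
                    min_pool_depth = params$pool_size,
                    min_alt_count = 4,
                    max_alt_count = round(2 * total) - 4)
}

#' Run the full Pool-seq landscape-genomics pipeline
#'
#' Chains every analysis stage on a synthetic scenario: simulate (or accept)
#' the data, filter variant records, derive pooled frequencies, test soil
#' variables for M/NM discrimination, infer neutral structure, run
#' latent-factor association for Site-type and the selected soil variables
#' (choosing K by genomic inflation), cross-validate significant SNPs with
#' the covariance-corrected statistic, compute per-gene diversity, run
#' max-|z| gene-set enrichment with pruning per variable, and assemble the
#' candidate-gene cascade and report.
#'
#' @param params a [sim_params()] object.
#' @param sim optional pre-generated [simulate_pool_seq()] result (generated
#'   from `params` if `NULL`).
#' @param fdr association false discovery rate (default 0.01).
#' @param q_cutoff post-pruning enrichment Q cutoff (default 0.10).
#' @param Ks candidate latent-factor counts (default 2:4).
#' @param n_restarts association restarts (default 12).
#' @param n_perm enrichment permutations (default 2000).
#' @param n_random_crossval size of the random cross-validation SNP set
#'   (default 2000).
#' @param percentile_cutoff strong-candidate percentile cutoff
#'   (default 0.01).
#' @param seed integer master seed for the analysis stages.
#' @return a list of class `poolscape_run` with every intermediate result
#'   and the final `report`.
#' @export
run_pipeline <- function(params, sim = NULL, fdr = 0.01, q_cutoff = 0.10,
                         Ks = 2:4, n_restarts = 12, n_perm = 2000,
                         n_random_crossval = 2000, percentile_cutoff = 0.01,
                         seed = params$seed) {
  if (is.null(sim)) sim <- simulate_pool_seq(params)

  # variant records from the simulated counts, then the filter cascade
  records <- as_variant_records(sim$counts)
  filt <- apply_site_filters(records, scaled_thresholds(params))
  freqs <- counts_to_frequencies(filt$counts)

  # environment: discriminating soil variables
  soil_reps <- generate_soil_replicates(sim$env, seed = split_seed(seed, "soilrep"))
  soil <- test_soil_discrimination(soil_reps, soil_var_names())
  soil_vars <- soil$selected

  structure_pca <- neutral_structure_pca(
    freqs, n_random = min(50000, nrow(freqs$freq)),
    seed = split_seed(seed, "structure"))

  variables <- c("Site_type", soil_vars)
  assoc <- lapply(setNames(variables, variables), function(v) {
    associate_variable(freqs, sim$env, v, Ks = Ks, n_restarts = n_restarts,
                       seed = split_seed(seed, paste0("assoc_", v)), fdr = fdr)
  })

  # cross-validation of the Site-type hits
  cov_model <- estimate_covariance(freqs, seed = split_seed(seed, "cov"))
  zstat <- covariance_corrected_statistic(freqs, sim$env$Site_type, cov_model)
  sig_ids <- assoc$Site_type$snps$snp_id[assoc$Site_type$snps$significant]
  rand_idx <- sample_random_snps(freqs,
                                 min(n_random_crossval,
                                     nrow(freqs$freq) - length(sig_ids)),
                                 exclude_ids = sig_ids,
                                 seed = split_seed(seed, "randsnps"))
  crossval <- if (length(sig_ids) > 0) {
    compare_statistic_distributions(
      zstat$snps$Z[match(sig_ids, zstat$snps$snp_id)],
      zstat$snps$Z[rand_idx])
  } else NULL

  diversity <- gene_diversity_table(freqs, sim$annotation$genes,
                                    pool_size = params$pool_size)

  mapping <- map_snps_to_genes(freqs$snps, sim$annotation$genes)
  enrich <- lapply(assoc, function(res) {
    tab <- adjust_scores(score_genes(res, mapping))
    prune_and_retest(tab, sim$annotation$pathways, q_cutoff = q_cutoff,
                     n_perm = n_perm,
                     seed = split_seed(seed, paste0("enrich_", attr(res, "variable"))))
  })
  accepted_sets <- unique(unlist(lapply(enrich, function(e) e$accepted$set)))
  accepted_pathways <- sim$annotation$pathways[accepted_sets]

  gene_lists <- associated_gene_lists(assoc, mapping)
  soil_overlap <- if (length(soil_vars) >= 2) {
    intersect_soil_genes(gene_lists[soil_vars])
  } else character(0)
  candidates <- select_pathway_candidates(gene_lists$Site_type, soil_overlap,
                                          accepted_pathways)
  m_pools <- sim$env$site[sim$env$Site_type == 1]
  candidates <- flag_selection(candidates, diversity, m_pools,
                               percentile_cutoff = percentile_cutoff)

  # per-gene report fields
  g <- sim$annotation$genes$genes
  n_snps_gene <- table(na.omit(mapping$gene_id))
  sig_site <- assoc$Site_type$snps$snp_id[assoc$Site_type$snps$significant]
  n_assoc_gene <- table(na.omit(mapping$gene_id[mapping$snp_id %in% sig_site]))
  idx <- match(candidates$gene_id, g$gene_id)
  candidates$ortholog <- g$ortholog[idx]
  candidates$env_variable <- candidates$source
  candidates$gene_length <- g$end[idx] - g$start0[idx]
  candidates$n_snps <- as.integer(n_snps_gene[candidates$gene_id])
  candidates$n_associated <- as.integer(n_assoc_gene[candidates$gene_id])
  candidates$n_associated[is.na(candidates$n_associated)] <- 0L
  candidates$gene_name <- g$name[idx]

  cand_snps <- freqs$snps[freqs$snps$snp_id %in%
                            mapping$snp_id[mapping$gene_id %in% candidates$gene_id], ]
  effects <- if (nrow(cand_snps) > 0) {
    classify_variant_effects(cand_snps, sim$annotation$genes, sim$annotation$genome)
  } else NULL
  report <- build_report(candidates, diversity, effects)

  structure(list(params = params, sim = sim, filter = filt, freqs = freqs,
                 soil = soil, soil_vars = soil_vars,
                 structure_pca = structure_pca, assoc = assoc,
                 cov_model = cov_model, zstat = zstat, crossval = crossval,
                 diversity = diversity, enrich = enrich,
                 accepted_pathways = accepted_pathways,
                 gene_lists = gene_lists, soil_overlap = soil_overlap,
                 candidates = candidates, report = report),
            class = "poolscape_run")
}

#' @export
print.poolscape_run <- function(x, ...) {
  cat("poolscape pipeline run\n")
  cat(sprintf("  SNPs retained after filtering: %d of %d\n",
              nrow(x$freqs$freq), length(x$filter$retained)))
  cat(sprintf("  discriminating soil variables: %s\n",
              paste(x$soil_vars, collapse = ", ")))
  for (v in names(x$assoc)) {
    cat(sprintf("  %s: K=%d, lambda=%.3f, %d significant SNPs\n", v,
                attr(x$assoc[[v]], "K"), attr(x$assoc[[v]], "lambda"),
                sum(x$assoc[[v]]$snps$significant)))
  }
  cat(sprintf("  accepted pathways: %s\n",
              paste(names(x$accepted_pathways), collapse = ", ")))
  cat(sprintf("  candidates: %d (%d strong)\n", nrow(x$candidates),
              sum(x$candidates$strong_candidate)))
  invisible(x)
}
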