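# Hierarchical allele-frequency simulation with planted adaptive loci and
# selective-sweep genes, plus the double-binomial Pool-seq read sampler.

# Neutral ancestral frequencies follow a rare-enriched site-frequency
# spectrum, density proportional to p^(-alpha) truncated to
# [1/pool_size, 1 - 1/pool_size]. The idealized neutral spectrum is
# alpha = 1; the default alpha = 2 compensates for the loss of rare
# variants through drift, pool sampling, finite read depth and count
# rounding (which absorb low-frequency sites into the invariant class), so
# that the OBSERVED drift-only spectrum is neutral-like — gene-level
# Tajima's D centred near zero, matching the slightly positive genome-wide
# medians typical of natural populations. A rare-enriched generating
# spectrum is also what recent population expansion produces.
rneutral_sfs <- function(n, pool_size, alpha = 2) {
  lo <- 1 / pool_size
  hi <- 1 - lo
  u <- runif(n)
  if (abs(alpha - 1) < 1e-12) {
    lo * (hi / lo)^u
  } else {
    (lo^(1 - alpha) + u * (hi^(1 - alpha) - lo^(1 - alpha)))^(1 / (1 - alpha))
  }
}

rbalding_nichols <- function(p, fst) {
  a <- p * (1 - fst) / fst
  b <- (1 - p) * (1 - fst) / fst
  pmin(pmax(rbeta(length(p), a, b), 1e-6), 1 - 1e-6)
}

#' Simulate true pool allele frequencies with planted structure
#'
#' Places SNPs on the synthetic genome (about 90% inside genes, in proportion
#' to gene length), draws ancestral frequencies from a neutral
#' site-frequency spectrum, and propagates them through two levels of
#' Balding-Nichols drift (cluster, then pool). A fraction of SNPs
#' (`prop_adaptive`) receives an environmental effect: their pool frequency
#' is shifted on the logit scale by `effect_size` times the standardized
#' value of a driving environmental variable (Site-type or one of the five
#' designated soil variables). Genes of the designated adaptive pathway
#' receive `prop_adaptive_in_pathway` of the adaptive SNPs. Finally,
#' `sweep_genes` genes among the adaptive-pathway genes get a
#' selective-sweep signature in the metallicolous pools: each of their SNPs
#' is, with probability `sweep_prob`, redrawn so that the minor-allele count
#' is at most 2 chromosomes (preserving which allele is the major one).
#'
#' @param annotation output of [generate_genome_annotation()].
#' @param env environment table from [generate_environment()].
#' @param params a [sim_params()] object.
#' @param seed integer seed.
#' @return list with `freq` (SNP x pool matrix of true alternate-allele
#'   frequencies), `snps` (SNP metadata with gene assignment), and `truth`
#'   (a `truth_table` recording all planted structure).
#' @export
simulate_frequencies <- function(annotation, env, params,
                                 seed = split_seed(params$seed, "frequencies")) {
  validate_sim_params(params)
  if (nrow(env) != params$n_pops)
    stop_invalid("env has %d rows but params$n_pops is %d", nrow(env), params$n_pops)
  genes <- annotation$genes$genes
  genome <- annotation$genome
  with_seed(seed, {
    n <- params$n_snps
    n_genic <- round(0.9 * n)

    # genic SNP positions, proportional to gene length, unique per gene
    span <- genes$end - genes$start0
    per_gene <- as.vector(stats::rmultinom(1, n_genic, prob = span))
    per_gene <- pmin(per_gene, span)
    snp_list <- vector("list", nrow(genes))
    for (i in seq_len(nrow(genes))) {
      if (per_gene[i] == 0) next
      pos <- sort(sample(seq.int(genes$start0[i], genes$end[i] - 1L), per_gene[i]))
      snp_list[[i]] <- data.frame(chrom = genes$chrom[i], pos = pos,
                                  gene_id = genes$gene_id[i],
                                  stringsAsFactors = FALSE)
    }
    genic <- do.call(rbind, snp_list)

    # intergenic SNPs: rejection-sample positions outside any gene span
    n_inter <- n - nrow(genic)
    scaff_len <- Biostrings::width(genome)
    names(scaff_len) <- names(genome)
    inter <- NULL
    while (is.null(inter) || nrow(inter) < n_inter) {
      m <- 2L * (n_inter - if (is.null(inter)) 0L else nrow(inter)) + 10L
      sc <- sample(names(scaff_len), m, replace = TRUE)
      pos <- floor(runif(m) * scaff_len[sc])
      cand <- data.frame(chrom = sc, pos = as.integer(pos), gene_id = NA_character_,
                         stringsAsFactors = FALSE)
      hit <- overlaps_any_gene(cand, genes)
      cand <- cand[!hit, ]
      inter <- unique(rbind(inter, cand))
    }
    inter <- inter[seq_len(n_inter), ]

    snps <- rbind(genic, inter)
    snps <- snps[order(snps$chrom, snps$pos), ]
    rownames(snps) <- NULL
    snps <- cbind(snp_id = sprintf("snp%06d", seq_len(n)), snps,
                  stringsAsFactors = FALSE)

    # alleles from the genome sequence
    refs <- extract_bases(genome, snps$chrom, snps$pos)
    alts <- vapply(refs, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    snps$ref <- refs
    snps$alt <- unname(alts)

    # choose adaptive SNPs first (they get standing-variation ancestral
    # frequencies), concentrated in the adaptive pathway's genes
    n_adapt <- round(params$prop_adaptive * n)
    is_adaptive <- rep(FALSE, n)
    driver <- rep(NA_character_, n)
    beta <- rep(0, n)
    if (n_adapt > 0) {
      path_genes <- annotation$pathways[[1]]
      in_path <- which(!is.na(snps$gene_id) & snps$gene_id %in% path_genes)
      other_genic <- which(!is.na(snps$gene_id) & !(snps$gene_id %in% path_genes))
      n_path <- min(round(params$prop_adaptive_in_pathway * n_adapt), length(in_path))
      pick <- c(sample(in_path, n_path),
                sample(other_genic, n_adapt - n_path))
      is_adaptive[pick] <- TRUE
      vars <- c("Site_type", designated_soil_vars())
      driver[pick] <- sample(vars, n_adapt, replace = TRUE)
      beta[pick] <- params$effect_size
    }

    # ancestral frequencies: rare-enriched neutral spectrum for the
    # background; selection acts on standing variation at usable
    # frequencies, so adaptive sites draw from Uniform(0.05, 0.95)
    p0 <- rneutral_sfs(n, params$pool_size)
    p0[is_adaptive] <- runif(sum(is_adaptive), 0.05, 0.95)

    # hierarchical drift: cluster level, then pool level
    clusters <- params$cluster_assignment
    uc <- sort(unique(clusters))
    p_cluster <- matrix(NA_real_, n, length(uc))
    for (j in seq_along(uc)) {
      p_cluster[, j] <- rbalding_nichols(p0, params$fst_between_cluster)
    }
    freq <- matrix(NA_real_, n, params$n_pops)
    for (j in seq_len(params$n_pops)) {
      freq[, j] <- rbalding_nichols(p_cluster[, match(clusters[j], uc)],
                                    params$fst_within_cluster)
    }

    # environmental effects: logit-scale shift by beta x standardized env
    if (n_adapt > 0) {
      vars <- c("Site_type", designated_soil_vars())
      env_std <- scale(as.matrix(env[, vars]))
      for (v in vars) {
        idx <- which(is_adaptive & driver == v)
        if (length(idx) == 0) next
        shift <- outer(beta[idx], env_std[, v])
        freq[idx, ] <- inv_logit(logit(freq[idx, , drop = FALSE]) + shift)
      }
    }

    # selective-sweep genes: excess of rare alleles in the affected (M) pools
    affected <- which(params$site_type_labels == "M")
    sweep_ids <- character(0)
    if (params$sweep_genes > 0) {
      cnt <- table(snps$gene_id)
      path_genes <- annotation$pathways[[1]]
      adaptive_genes <- unique(snps$gene_id[is_adaptive & !is.na(snps$gene_id)])
      cand <- intersect(path_genes, adaptive_genes)
      cand <- cand[order(-as.integer(cnt[cand]))]
      if (length(cand) < params$sweep_genes) {
        extra <- setdiff(names(sort(cnt, decreasing = TRUE)), cand)
        cand <- c(cand, extra)
      }
      sweep_ids <- cand[seq_len(min(params$sweep_genes, length(cand)))]
      # selection direction of each adaptive SNP in the affected pools: the
      # allele favoured there is the one its environmental effect pushes up
      env_std_all <- scale(as.matrix(env[, c("Site_type", designated_soil_vars())]))
      mean_env_affected <- colMeans(env_std_all[affected, , drop = FALSE])
      for (g in sweep_ids) {
        idx <- which(!is.na(snps$gene_id) & snps$gene_id == g)
        # the swept haplotype is shared by the affected pools; each site
        # carries whichever allele rode it — the locally beneficial allele
        # at adaptive sites, a random side at hitchhiking sites
        side_high <- runif(length(idx)) < 0.5
        adapt_here <- is_adaptive[idx]
        if (any(adapt_here)) {
          dir_up <- beta[idx[adapt_here]] *
            mean_env_affected[driver[idx[adapt_here]]] > 0
          side_high[adapt_here] <- dir_up
        }
        for (j in affected) {
          hit <- runif(length(idx)) < params$sweep_prob
          if (!any(hit)) next
          k_minor <- sample(0:2, sum(hit), replace = TRUE)
          freq[idx[hit], j] <- ifelse(side_high[hit],
                                      (params$pool_size - k_minor) / params$pool_size,
                                      k_minor / params$pool_size)
        }
      }
    }

    pools <- env$site
    dimnames(freq) <- list(snps$snp_id, pools)
    truth <- truth_table(
      snps = data.frame(snp_id = snps$snp_id, gene_id = snps$gene_id,
                        is_adaptive = is_adaptive, driver = driver,
                        beta = beta, p0 = p0, stringsAsFactors = FALSE),
      sweep = data.frame(gene_id = sweep_ids,
                         affected_pools = rep(paste(pools[affected], collapse = ","),
                                              length(sweep_ids)),
                         stringsAsFactors = FALSE),
      freq_true = freq)
    list(freq = freq, snps = snps, truth = truth)
  })
}

overlaps_any_gene <- function(cand, genes) {
  q <- GenomicRanges::GRanges(cand$chrom,
                              IRanges::IRanges(start = cand$pos + 1L, width = 1L))
  s <- GenomicRanges::GRanges(genes$chrom,
                              IRanges::IRanges(start = genes$start0 + 1L,
                                               end = genes$end))
  GenomicRanges::countOverlaps(q, s) > 0
}

extract_bases <- function(genome, chrom, pos0) {
  out <- character(length(chrom))
  for (sc in unique(chrom)) {
    i <- chrom == sc
    v <- Biostrings::extractAt(genome[[sc]],
                               IRanges::IRanges(start = pos0[i] + 1L, width = 1L))
    out[i] <- as.character(v)
  }
  out
}

#' Simulate Pool-seq read counts from true frequencies
#'
#' Double-binomial Pool-seq noise: per SNP and pool the depth is
#' `Poisson(coverage_mean)` (at least 1); a chromosome-sampling stage draws
#' `k ~ Binomial(pool_size, p_true)`; alternate reads are then
#' `Binomial(depth, k / pool_size)` and reference reads make up the rest.
#'
#' @param freq SNP x pool matrix of true alternate-allele frequencies (or the
#'   list returned by [simulate_frequencies()]).
#' @param params a [sim_params()] object.
#' @param seed integer seed.
#' @param snps optional SNP metadata data.frame; taken from `freq` if it is a
#'   [simulate_frequencies()] result.
#' @return an [allele_counts()] object.
#' @export
simulate_pool_reads <- function(freq, params,
                                seed = split_seed(params$seed, "reads"),
                                snps = NULL) {
  if (is.list(freq) && !is.matrix(freq)) {
    snps <- freq$snps
    freq <- freq$freq
  }
  if (any(freq < 0 | freq > 1))
    stop_invalid("frequencies must lie in [0,1]")
  if (is.null(snps)) {
    snps <- data.frame(snp_id = sprintf("snp%06d", seq_len(nrow(freq))),
                       chrom = "scf001", pos = seq_len(nrow(freq)) - 1L,
                       ref = "A", alt = "T", stringsAsFactors = FALSE)
  }
  n <- nrow(freq)
  m <- ncol(freq)
  pools <- colnames(freq)
  if (is.null(pools)) pools <- sprintf("pool%02d", seq_len(m))
  with_seed(seed, {
    depth <- matrix(pmax(rpois(n * m, params$coverage_mean), 1L), n, m)
    k <- matrix(rbinom(n * m, params$pool_size, as.vector(freq)), n, m)
    alt <- matrix(rbinom(n * m, as.vector(depth), as.vector(k) / params$pool_size),
                  n, m)
    allele_counts(snps, pools, ref = depth - alt, alt = alt, depth = depth)
  })
}

#' Run the full synthetic-data generator
#'
#' Convenience wrapper chaining [generate_environment()],
#' [generate_genome_annotation()], [simulate_frequencies()] and
#' [simulate_pool_reads()] under one master seed.
#'
#' @param params a [sim_params()] object.
#' @return list with `env`, `annotation`, `freq`, `snps`, `truth`, `counts`.
#' @export
simulate_pool_seq <- function(params) {
  env <- generate_environment(params)
  ann <- generate_genome_annotation(params)
  fr <- simulate_frequencies(ann, env, params)
  counts <- simulate_pool_reads(fr, params)
  list(env = env, annotation = ann, freq = fr$freq, snps = fr$snps,
       truth = fr$truth, counts = counts)
}
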