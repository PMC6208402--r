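# Synthetic-data generator: environment tables, annotations, frequencies,
# pool reads, and the planted ground truth.

test_that("parameter validation rejects impossible designs", {
  expect_error(sim_params(n_pops = 1), "n_pops")
  expect_error(sim_params(site_type_labels = rep("M", 12)), "site type")
  expect_error(sim_params(pool_size = 1), "pool_size")
  expect_error(sim_params(fst_within_cluster = 0), "fst_within_cluster")
  expect_error(sim_params(prop_adaptive = 1.5), "prop_adaptive")
  expect_error(sim_params(n_genes = 10, n_pathways = 5, genes_per_pathway = 10),
               "n_genes")
})

test_that("environment table carries site-type labels and is deterministic", {
  p <- sim_params(n_pops = 4, site_type_labels = c("M", "M", "NM", "NM"),
                  cluster_assignment = c(1, 1, 2, 3), seed = 1)
  env <- generate_environment(p)
  expect_equal(env$Site_type, c(1L, 1L, 0L, 0L))
  expect_equal(ncol(env), 2 + 16 + 15)
  expect_identical(env, generate_environment(p))
})

test_that("designated soil variables separate site types (ANOVA oracle)", {
  p <- sim_params(seed = 1)
  hits <- 0L
  n_rep <- 100L
  for (r in seq_len(n_rep)) {
    env <- generate_environment(p, seed = 5000 + r)
    ps <- vapply(designated_soil_vars(), function(v) {
      anova(lm(env[[v]] ~ factor(env$Site_type)))$`Pr(>F)`[1]
    }, 0)
    if (all(ps < 0.001)) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("genome annotation is valid and deterministic on disk", {
  p <- small_sim_params(seed = 2)
  ann <- generate_genome_annotation(p)
  expect_s3_class(ann$genes, "gene_models")
  # every pathway member is a generated gene id
  expect_true(all(unlist(ann$pathways) %in% ann$genes$genes$gene_id))
  expect_setequal(unique(ann$genes$genes$strand), c("+", "-"))
  # every CDS translates cleanly: starts with M, ends with stop, no internal stops
  for (gid in sample(ann$genes$genes$gene_id, 10)) {
    cds <- ann$genes$cds[ann$genes$cds$gene_id == gid, ]
    cds_asc <- cds[order(cds$start0), ]
    s <- paste(as.character(Biostrings::extractAt(
      ann$genome[[cds_asc$chrom[1]]],
      IRanges::IRanges(cds_asc$start0 + 1L, cds_asc$end))), collapse = "")
    d <- Biostrings::DNAString(s)
    if (cds_asc$strand[1] == "-") d <- Biostrings::reverseComplement(d)
    aa <- as.character(Biostrings::translate(d))
    expect_identical(substr(aa, 1, 1), "M")
    expect_identical(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
  }
  # byte-identical GFF3 and GMT under a fixed seed
  ann2 <- generate_genome_annotation(p)
  f1 <- tempfile(fileext = ".gff3"); f2 <- tempfile(fileext = ".gff3")
  write_gff3(ann$genes, f1); write_gff3(ann2$genes, f2)
  expect_identical(readLines(f1), readLines(f2))
  g1 <- tempfile(fileext = ".gmt"); g2 <- tempfile(fileext = ".gmt")
  write_gmt(ann$pathways, g1); write_gmt(ann2$pathways, g2)
  expect_identical(readLines(g1), readLines(g2))
})

test_that("annotation rejects impossible packing", {
  p <- sim_params(n_snps = 100, n_genes = 40, n_pathways = 4,
                  genes_per_pathway = 10, n_scaffolds = 2,
                  scaffold_length = 1000, seed = 3)
  expect_error(generate_genome_annotation(p), "packing")
})

test_that("frequency simulation plants the advertised structure", {
  p <- small_sim_params(seed = 4)
  env <- generate_environment(p)
  ann <- generate_genome_annotation(p)
  fr <- simulate_frequencies(ann, env, p)
  expect_equal(dim(fr$freq), c(p$n_snps, p$n_pops))
  expect_true(all(fr$freq >= 0 & fr$freq <= 1))
  tr <- fr$truth
  expect_equal(sum(tr$snps$is_adaptive), round(p$prop_adaptive * p$n_snps))
  expect_true(all(tr$snps$snp_id[tr$snps$is_adaptive] %in% rownames(fr$freq)))
  expect_true(all(tr$sweep$gene_id %in% ann$genes$genes$gene_id))
  # adaptive SNPs concentrate in the designated pathway
  ad_genes <- tr$snps$gene_id[tr$snps$is_adaptive]
  expect_gte(mean(ad_genes %in% ann$pathways[[1]]), 0.5)
})

test_that("no drift and no selection collapses across-pool variance", {
  p <- small_sim_params(seed = 5, fst_within_cluster = 1e-4,
                        fst_between_cluster = 1e-4, prop_adaptive = 0,
                        sweep_genes = 0)
  env <- generate_environment(p)
  ann <- generate_genome_annotation(p)
  fr <- simulate_frequencies(ann, env, p)
  expect_lt(median(apply(fr$freq, 1, var)), 1e-4)
})

test_that("a zero-effect 'adaptive' SNP is environmentally null", {
  p <- sim_params(n_snps = 4000, n_genes = 100, n_pathways = 6,
                  genes_per_pathway = 10, effect_size = 0, sweep_genes = 0,
                  seed = 6)
  sim <- simulate_pool_seq(p)
  fr <- filtered_freqs(sim, p)
  fit <- suppressWarnings(
    fit_latent_association(fr, sim$env$Site_type, K = 3, n_restarts = 4,
                           seed = 1))
  tr <- sim$truth$snps[match(fr$snps$snp_id, sim$truth$snps$snp_id), ]
  ks <- suppressWarnings(ks.test(fit$snps$z[tr$is_adaptive],
                                 fit$snps$z[!tr$is_adaptive]))
  expect_gt(ks$p.value, 0.01)
})

test_that("pool read sampling is a faithful double-binomial", {
  p <- sim_params(n_pops = 2, site_type_labels = c("M", "NM"),
                  cluster_assignment = c(1, 2), coverage_mean = 100, seed = 7)
  # degenerate: fixed alternate allele
  f1 <- matrix(1, 50, 2)
  ac <- simulate_pool_reads(f1, p, seed = 1)
  expect_true(all(ac$alt == ac$depth))
  expect_true(all(ac$ref == 0L))
  # determinism
  ac2 <- simulate_pool_reads(f1, p, seed = 1)
  expect_identical(ac$alt, ac2$alt)
  # unbiasedness at p = 0.5 over 10,000 replicate SNPs
  f2 <- matrix(0.5, 10000, 2)
  ac3 <- simulate_pool_reads(f2, p, seed = 2)
  expect_true(abs(mean(ac3$alt / ac3$depth) - 0.5) < 0.01)
  # variance exceeds read-binomial alone and matches the two-stage closed form
  est <- ac3$alt[, 1] / ac3$depth[, 1]
  v_obs <- var(est)
  v_two_stage <- 0.25 * (1 / p$pool_size + (1 - 1 / p$pool_size) / p$coverage_mean)
  v_reads_only <- 0.25 / p$coverage_mean
  expect_gt(v_obs, v_reads_only)
  expect_lt(abs(v_obs - v_two_stage) / v_two_stage, 0.10)
  # counts always consistent
  expect_true(all(ac3$alt + ac3$ref == ac3$depth))
})

test_that("truth tables round-trip bit-exactly", {
  p <- small_sim_params(seed = 8)
  sim <- simulate_pool_seq(p)
  d <- tempfile()
  write_truth_table(sim$truth, d)
  back <- read_truth_table(d)
  expect_identical(back$snps, sim$truth$snps)
  expect_identical(back$sweep, sim$truth$sweep)
  expect_identical(back$freq_true, sim$truth$freq_true)
})
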