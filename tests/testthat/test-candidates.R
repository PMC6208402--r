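# SNP-gene mapping conventions, the candidate cascade, variant effects and
# the report.

toy_models <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB", "gC"),
    ortholog = c("AT1G10000", "AT1G20000", "AT1G30000"),
    name = c("alpha", "beta", "gamma"),
    chrom = "scf001", strand = c("+", "+", "-"),
    start0 = c(100, 180, 400), end = c(200, 300, 500),
    stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = genes$gene_id, chrom = "scf001",
                      strand = genes$strand, start0 = genes$start0,
                      end = genes$end, stringsAsFactors = FALSE)
  cds <- data.frame(gene_id = genes$gene_id, chrom = "scf001",
                    strand = genes$strand, start0 = genes$start0 + 10,
                    end = genes$end - c(10, 21, 10) - c(0, 0, 0),
                    phase = 0L, stringsAsFactors = FALSE)
  cds$end <- cds$start0 + ((cds$end - cds$start0) %/% 3) * 3
  gene_models(genes, exons, cds)
}

test_that("SNP-to-gene mapping is half-open and keeps overlaps", {
  gm <- toy_models()
  snps <- data.frame(snp_id = c("s1", "s2", "s3", "s4"),
                     chrom = "scf001",
                     pos = c(150, 200, 190, 50),
                     stringsAsFactors = FALSE)
  m <- map_snps_to_genes(snps, gm)
  expect_equal(m$gene_id[m$snp_id == "s1"], "gA")       # internal position
  expect_equal(m$gene_id[m$snp_id == "s2"], "gB")       # gA end is exclusive
  expect_setequal(m$gene_id[m$snp_id == "s3"], c("gA", "gB"))  # overlap: both
  expect_true(is.na(m$gene_id[m$snp_id == "s4"]))       # intergenic
})

test_that("the associated-gene and intersection steps are plain set algebra", {
  mapping <- data.frame(snp_id = c("s1", "s2", "s3"),
                        gene_id = c("gA", "gB", NA), stringsAsFactors = FALSE)
  mk <- function(sig) {
    structure(list(snps = data.frame(
      snp_id = c("s1", "s2", "s3"), significant = sig)), class = "assoc_result")
  }
  lists <- associated_gene_lists(list(v1 = mk(c(TRUE, FALSE, TRUE)),
                                      v2 = mk(c(FALSE, FALSE, FALSE))),
                                 mapping)
  expect_equal(lists$v1, "gA")      # intergenic significance maps to no gene
  expect_length(lists$v2, 0)
  expect_equal(
    intersect_soil_genes(list(c("A", "B", "C"), c("A", "B"), c("A", "B", "D"),
                              c("A", "B"), c("A", "B"))),
    c("A", "B"))
  expect_length(intersect_soil_genes(list(c("A"), character(0))), 0)
  expect_error(intersect_soil_genes(list(c("A"))), "at least 2")
})

test_that("pathway-membership candidates carry pathway and source tags", {
  out <- select_pathway_candidates(
    site_genes = c("A", "B", "C"), soil_overlap = c("C", "E"),
    accepted_pathways = list(pw1 = c("B", "C", "D"), pw2 = c("E", "F")))
  expect_setequal(out$gene_id, c("B", "C", "E"))
  expect_equal(out$source[out$gene_id == "B"], "Site-type")
  expect_equal(out$source[out$gene_id == "C"], "Site-type+soil")
  expect_equal(out$source[out$gene_id == "E"], "soil")
  empty <- select_pathway_candidates(c("A"), c("B"), list())
  expect_equal(nrow(empty), 0)
})

test_that("selection flags follow the negative-D percentile rule", {
  cands <- data.frame(gene_id = c("RFC4", "MTPA2", "CTL1"),
                      pathway = "pw", stringsAsFactors = FALSE)
  div <- rbind(
    data.frame(gene_id = "RFC4", pool = c("M_PL22", "M_PL27"),
               D = c(-0.97, -0.92), percentile = c(0.0016, 0.00008)),
    data.frame(gene_id = "MTPA2", pool = c("M_PL22", "M_PL27"),
               D = c(0.69, -1.08), percentile = c(0.6, 0.00004)),
    data.frame(gene_id = "CTL1", pool = c("M_PL22", "M_PL27"),
               D = c(1.04, 1.80), percentile = c(0.8, 0.9)))
  out <- flag_selection(cands, div, m_pools = c("M_PL22", "M_PL27"))
  expect_equal(out$strong_candidate, c(TRUE, TRUE, FALSE))
  # undefined D never flags
  div2 <- div; div2$D[div2$gene_id == "RFC4"] <- NA
  out2 <- flag_selection(cands, div2, m_pools = c("M_PL22", "M_PL27"))
  expect_false(out2$strong_candidate[1])
})

test_that("coding effects are classified per codon on both strands", {
  # plus-strand gene: CDS = ATG (ATT)x200 TAA; variant in codon 138
  n_codon <- 202
  cds_seq <- paste0("ATG", strrep("ATT", 200), "TAA")
  genome_str <- paste0(strrep("G", 50), cds_seq, strrep("G", 50))
  genome <- Biostrings::DNAStringSet(c(scfP = genome_str))
  gm <- gene_models(
    genes = data.frame(gene_id = "gP", ortholog = "AT1", name = "p",
                       chrom = "scfP", strand = "+", start0 = 50,
                       end = 50 + nchar(cds_seq), stringsAsFactors = FALSE),
    exons = data.frame(gene_id = "gP", chrom = "scfP", strand = "+",
                       start0 = 50, end = 50 + nchar(cds_seq)),
    cds = data.frame(gene_id = "gP", chrom = "scfP", strand = "+",
                     start0 = 50, end = 50 + nchar(cds_seq), phase = 0L))
  # codon 138 starts at CDS offset 411; its first base A -> C gives ATT -> CTT
  pos138 <- 50 + 137 * 3
  eff <- classify_variant_effects(
    data.frame(snp_id = "v1", chrom = "scfP", pos = pos138, ref = "A",
               alt = "C", stringsAsFactors = FALSE), gm, genome)
  expect_equal(eff$effect, "missense")
  expect_equal(eff$impact, "moderate")
  expect_equal(eff$aa_change, "I138L")
  # third-position ATT -> ATC is synonymous
  eff2 <- classify_variant_effects(
    data.frame(snp_id = "v2", chrom = "scfP", pos = pos138 + 2, ref = "T",
               alt = "C", stringsAsFactors = FALSE), gm, genome)
  expect_equal(eff2$effect, "synonymous")
  expect_equal(eff2$impact, "low")
  # reference mismatch is an error naming the SNP
  expect_error(classify_variant_effects(
    data.frame(snp_id = "v3", chrom = "scfP", pos = pos138, ref = "T",
               alt = "C", stringsAsFactors = FALSE), gm, genome), "v3")

  # minus-strand gene with the complementary genome alleles gives the same
  # protein annotation
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds_seq)))
  genome_m <- Biostrings::DNAStringSet(c(scfM = paste0(strrep("G", 50), rc,
                                                       strrep("G", 50))))
  gm_m <- gene_models(
    genes = data.frame(gene_id = "gM", ortholog = "AT2", name = "m",
                       chrom = "scfM", strand = "-", start0 = 50,
                       end = 50 + nchar(rc), stringsAsFactors = FALSE),
    exons = data.frame(gene_id = "gM", chrom = "scfM", strand = "-",
                       start0 = 50, end = 50 + nchar(rc)),
    cds = data.frame(gene_id = "gM", chrom = "scfM", strand = "-",
                     start0 = 50, end = 50 + nchar(rc), phase = 0L))
  pos138_m <- 50 + nchar(rc) - 1 - 137 * 3
  eff_m <- classify_variant_effects(
    data.frame(snp_id = "w1", chrom = "scfM", pos = pos138_m, ref = "T",
               alt = "G", stringsAsFactors = FALSE), gm_m, genome_m)
  expect_equal(eff_m$effect, "missense")
  expect_equal(eff_m$aa_change, "I138L")
})

test_that("non-coding positions get modifier classes", {
  p <- small_sim_params(seed = 40)
  ann <- generate_genome_annotation(p)
  g <- ann$genes$genes[1, ]
  ex <- ann$genes$exons[ann$genes$exons$gene_id == g$gene_id, ]
  cds <- ann$genes$cds[ann$genes$cds$gene_id == g$gene_id, ]
  take_base <- function(pos) as.character(Biostrings::extractAt(
    ann$genome[[g$chrom]], IRanges::IRanges(pos + 1, width = 1)))
  # intergenic
  eff <- classify_variant_effects(
    data.frame(snp_id = "x0", chrom = g$chrom, pos = 0, ref = take_base(0),
               alt = "N", stringsAsFactors = FALSE), ann$genes, ann$genome)
  expect_equal(eff$effect, "intergenic")
  expect_equal(eff$impact, "modifier")
  # a UTR base: inside exon 1 but before the CDS (when a 5' UTR exists)
  utr_pos <- if (g$strand == "+") {
    if (min(cds$start0) > min(ex$start0)) min(ex$start0) else NA
  } else {
    if (max(cds$end) < max(ex$end)) max(ex$end) - 1 else NA
  }
  if (!is.na(utr_pos)) {
    eff_u <- classify_variant_effects(
      data.frame(snp_id = "x1", chrom = g$chrom, pos = utr_pos,
                 ref = take_base(utr_pos), alt = "N", stringsAsFactors = FALSE),
      ann$genes, ann$genome)
    expect_equal(eff_u$effect, "UTR")
  }
})

test_that("effect classification matches the full-CDS-translation oracle", {
  p <- small_sim_params(seed = 41)
  ann <- generate_genome_annotation(p)
  set.seed(42)
  checked <- 0
  tries <- 0
  while (checked < 60 && tries < 500) {
    tries <- tries + 1
    gi <- sample(nrow(ann$genes$genes), 1)
    g <- ann$genes$genes[gi, ]
    cds <- ann$genes$cds[ann$genes$cds$gene_id == g$gene_id, ]
    seg <- cds[sample(nrow(cds), 1), ]
    pos <- sample(seg$start0:(seg$end - 1), 1)
    ref <- as.character(Biostrings::extractAt(
      ann$genome[[g$chrom]], IRanges::IRanges(pos + 1, width = 1)))
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    snp <- data.frame(snp_id = sprintf("t%03d", tries), chrom = g$chrom,
                      pos = pos, ref = ref, alt = alt,
                      gene_id = g$gene_id, stringsAsFactors = FALSE)
    got <- classify_variant_effects(snp, ann$genes, ann$genome)
    got <- got[got$gene_id == g$gene_id, ]
    want <- oracle_effect(snp, ann$genes, ann$genome)
    if (is.null(want)) next
    checked <- checked + 1
    expect_equal(got$effect, want$effect)
    if (want$effect == "missense") expect_equal(got$aa_change, want$aa_change)
  }
  expect_gte(checked, 50)
})

test_that("the report orders rows deterministically and merges diversity", {
  cands <- data.frame(
    gene_id = c("g2", "g1"), ortholog = c("AT2", "AT1"),
    env_variable = "Site-type", gene_length = c(500L, 300L),
    n_snps = c(5L, 3L), n_associated = c(2L, 1L),
    gene_name = c("two", "one"), pathway = c("pwB", "pwA"),
    strong_candidate = c(FALSE, TRUE), stringsAsFactors = FALSE)
  div <- data.frame(gene_id = rep(c("g1", "g2"), 2),
                    pool = rep(c("M_P1", "NM_P2"), each = 2),
                    D = c(-1.2, 0.4, 0.8, 1.1),
                    percentile = c(0.001, 0.5, 0.7, 0.8))
  f <- tempfile(fileext = ".tsv")
  rep1 <- build_report(cands, div, path = f)
  expect_equal(rep1$gene_id, c("g1", "g2"))  # ordered by pathway then gene
  expect_equal(rep1$D_M_P1, c(-1.2, 0.4))
  # byte-identical re-run
  f2 <- tempfile(fileext = ".tsv")
  build_report(cands, div, path = f2)
  expect_identical(readLines(f), readLines(f2))
  # empty candidate set -> header-only file
  f3 <- tempfile(fileext = ".tsv")
  build_report(cands[integer(0), ], div, path = f3)
  expect_length(readLines(f3), 1)
})
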