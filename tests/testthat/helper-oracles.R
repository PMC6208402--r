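# Independent oracles and small scenario builders shared across tests.

# Direct-summation implementation of the diversity statistics, written
# independently of the package code paths: pi via explicit pairwise-difference
# counting, the normalization constants via plain loops.
oracle_tajima <- function(k, n) {
  a1 <- 0; a2 <- 0
  for (i in 1:(n - 1)) { a1 <- a1 + 1 / i; a2 <- a2 + 1 / i^2 }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  poly <- k[k > 0 & k < n]
  S <- length(poly)
  # pairwise differences: k derived among n chromosomes -> k*(n-k) of the
  # n*(n-1)/2 pairs differ at this site
  pi <- 0
  for (kk in poly) pi <- pi + (kk * (n - kk)) / (n * (n - 1) / 2)
  theta_w <- S / a1
  D <- if (S == 0) NA_real_ else
    (pi - theta_w) / sqrt(e1 * S + e2 * S * (S - 1))
  list(S = S, pi = pi, theta_w = theta_w, D = D,
       a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

# rank-based AUROC (Mann-Whitney form)
oracle_auc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# Full-CDS-translation effect oracle: rebuild the coding sequence from the
# genome, apply the substitution, translate both proteins with Biostrings,
# and classify from the protein diff.
oracle_effect <- function(snp, models, genome) {
  cds <- models$cds[models$cds$gene_id == snp$gene_id, ]
  cds_asc <- cds[order(cds$start0), ]
  seqs <- as.character(Biostrings::extractAt(
    genome[[cds_asc$chrom[1]]],
    IRanges::IRanges(start = cds_asc$start0 + 1L, end = cds_asc$end)))
  plus_ref <- paste(seqs, collapse = "")
  # locate the SNP within the concatenated plus-strand CDS
  off_plus <- NA_integer_
  acc <- 0L
  for (i in seq_len(nrow(cds_asc))) {
    if (snp$pos >= cds_asc$start0[i] && snp$pos < cds_asc$end[i]) {
      off_plus <- acc + (snp$pos - cds_asc$start0[i])
      break
    }
    acc <- acc + (cds_asc$end[i] - cds_asc$start0[i])
  }
  if (is.na(off_plus)) return(NULL)  # not coding
  plus_alt <- plus_ref
  substr(plus_alt, off_plus + 1L, off_plus + 1L) <- snp$alt
  strand <- cds_asc$strand[1]
  to_protein <- function(s) {
    d <- Biostrings::DNAString(s)
    if (strand == "-") d <- Biostrings::reverseComplement(d)
    as.character(Biostrings::translate(d, if.fuzzy.codon = "X", no.init.codon = TRUE))
  }
  p_ref <- to_protein(plus_ref)
  p_alt <- to_protein(plus_alt)
  if (p_ref == p_alt) return(list(effect = "synonymous", aa_change = NA))
  pos_aa <- which(strsplit(p_ref, "")[[1]] != strsplit(p_alt, "")[[1]])[1]
  from <- substr(p_ref, pos_aa, pos_aa)
  to <- substr(p_alt, pos_aa, pos_aa)
  eff <- if (to == "*") "stop_gained" else if (from == "*") "stop_lost" else "missense"
  list(effect = eff, aa_change = sprintf("%s%d%s", from, pos_aa, to))
}

# small default-structure scenario for unit tests (cheap but realistic)
small_sim_params <- function(seed, ...) {
  sim_params(n_snps = 2000, n_genes = 80, n_pathways = 6,
             genes_per_pathway = 10, n_scaffolds = 4, seed = seed, ...)
}

# filtered frequency matrix straight from a simulation
filtered_freqs <- function(sim, params) {
  filt <- apply_site_filters(as_variant_records(sim$counts),
                             scaled_thresholds(params))
  counts_to_frequencies(filt$counts)
}
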