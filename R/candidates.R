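# Candidate-gene cascade: SNP-to-gene mapping, per-variable associated gene
# lists, soil-variable overlap, enriched-pathway membership, selection flag,
# variant-effect classification, and the final report.

#' Map SNPs to genes by interval intersection
#'
#' A SNP is assigned to every gene whose span contains its position (0-based
#' half-open: a SNP at a gene's `end` coordinate is outside it). SNPs
#' contained in no gene are marked intergenic (`NA` gene id).
#'
#' @param snps data.frame with `snp_id`, `chrom`, `pos` (0-based).
#' @param models a [gene_models()] object.
#' @return data.frame `snp_id`, `gene_id` (one row per SNP-gene pair, plus
#'   one `NA` row for each intergenic SNP).
#' @export
map_snps_to_genes <- function(snps, models) {
  q <- GenomicRanges::GRanges(snps$chrom,
                              IRanges::IRanges(start = snps$pos + 1L, width = 1L))
  g <- models$genes
  s <- GenomicRanges::GRanges(g$chrom,
                              IRanges::IRanges(start = g$start0 + 1L, end = g$end))
  hits <- GenomicRanges::findOverlaps(q, s)
  hit_df <- data.frame(snp_id = snps$snp_id[S4Vectors::queryHits(hits)],
                       gene_id = g$gene_id[S4Vectors::subjectHits(hits)],
                       stringsAsFactors = FALSE)
  orphans <- setdiff(snps$snp_id, hit_df$snp_id)
  out <- rbind(hit_df,
               data.frame(snp_id = orphans,
                          gene_id = rep(NA_character_, length(orphans)),
                          stringsAsFactors = FALSE))
  out[order(match(out$snp_id, snps$snp_id)), , drop = FALSE]
}

#' Genes containing at least one significantly associated SNP
#'
#' @param results named list of `assoc_result` objects (one per
#'   environmental variable).
#' @param mapping SNP-to-gene mapping from [map_snps_to_genes()].
#' @return named list of character gene-id vectors, one per variable.
#' @export
associated_gene_lists <- function(results, mapping) {
  lapply(results, function(res) {
    sig <- res$snps$snp_id[res$snps$significant]
    sort(unique(na.omit(mapping$gene_id[mapping$snp_id %in% sig])))
  })
}

#' Strict intersection of per-soil-variable gene lists
#'
#' @param lists list of gene-id vectors (one per designated soil variable;
#'   at least 2).
#' @return character vector of genes present in every list.
#' @export
intersect_soil_genes <- function(lists) {
  if (length(lists) < 2)
    stop_invalid("need at least 2 soil-variable gene lists to intersect")
  sort(Reduce(intersect, lists))
}

#' Candidate genes: associated and member of an accepted pathway
#'
#' Candidates are the associated genes (union of the Site-type list and the
#' soil-variable overlap) that belong to at least one accepted (enriched,
#' pruning-surviving) pathway; each is tagged with its pathway and with its
#' source (Site-type, soil, or both).
#'
#' @param site_genes genes associated with Site-type.
#' @param soil_overlap genes in the soil-variable overlap
#'   ([intersect_soil_genes()]).
#' @param accepted_pathways named list of accepted pathways' member genes.
#' @return data.frame: `gene_id`, `pathway`, `source`.
#' @export
select_pathway_candidates <- function(site_genes, soil_overlap,
                                      accepted_pathways) {
  if (length(accepted_pathways) == 0)
    return(data.frame(gene_id = character(0), pathway = character(0),
                      source = character(0), stringsAsFactors = FALSE))
  assoc <- union(site_genes, soil_overlap)
  rows <- list()
  for (pw in names(accepted_pathways)) {
    hit <- intersect(assoc, accepted_pathways[[pw]])
    if (length(hit) == 0) next
    src <- ifelse(hit %in% site_genes & hit %in% soil_overlap, "Site-type+soil",
                  ifelse(hit %in% site_genes, "Site-type", "soil"))
    rows[[pw]] <- data.frame(gene_id = hit, pathway = pw, source = src,
                             stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(gene_id = character(0), pathway = character(0),
               source = character(0), stringsAsFactors = FALSE)
  out <- out[order(out$pathway, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag strong candidates by selective-sweep signature
#'
#' A candidate is flagged when its Tajima's D is negative in at least one
#' metallicolous pool and that pool's genome-wide percentile of D is at most
#' `percentile_cutoff`. Genes with undefined D (S = 0) in a pool are not
#' flagged through that pool.
#'
#' @param candidates data.frame with `gene_id` (e.g. from
#'   [select_pathway_candidates()]).
#' @param diversity per-gene, per-pool table from [gene_diversity_table()].
#' @param m_pools character vector of metallicolous pool names.
#' @param percentile_cutoff lower-tail percentile threshold (default 0.01).
#' @return the candidates data.frame with a logical `strong_candidate`
#'   column.
#' @export
flag_selection <- function(candidates, diversity, m_pools,
                           percentile_cutoff = 0.01) {
  flag <- vapply(candidates$gene_id, function(g) {
    d <- diversity[diversity$gene_id == g & diversity$pool %in% m_pools, ]
    any(!is.na(d$D) & d$D < 0 & !is.na(d$percentile) &
          d$percentile <= percentile_cutoff)
  }, TRUE)
  candidates$strong_candidate <- unname(flag)
  candidates
}

#' Classify the protein-level effect of SNPs
#'
#' SnpEff-style effect and impact classes from the gene models and genome
#' sequence: `intergenic`/`modifier` outside genes, `intron`/`modifier`
#' inside a gene but outside exons, `UTR`/`modifier` in an exon outside the
#' CDS, and within the CDS the reference and alternate codons are translated
#' (reverse-complementing on the minus strand): `synonymous`/`low`,
#' `missense`/`moderate` with an amino-acid change string such as `I138L`,
#' or `stop_gained`/`stop_lost` with `high` impact. A reference allele that
#' does not match the genome is an error naming the SNP; genes whose CDS
#' failed validation are annotated `modifier` with a warning.
#'
#' @param snps data.frame with `snp_id`, `chrom`, `pos` (0-based), `ref`,
#'   `alt` (single bases for coding classification).
#' @param models a [gene_models()] object.
#' @param genome a [Biostrings::DNAStringSet].
#' @return data.frame: `snp_id`, `gene_id`, `effect`, `impact`, `aa_change`.
#' @export
classify_variant_effects <- function(snps, models, genome) {
  code <- Biostrings::GENETIC_CODE
  g <- models$genes
  cds_len <- tapply(models$cds$end - models$cds$start0, models$cds$gene_id, sum)
  invalid_cds <- names(cds_len)[cds_len %% 3 != 0]
  mapping <- map_snps_to_genes(snps, models)
  cds_cache <- new.env(parent = emptyenv())

  cds_seq_of <- function(gid) {
    if (!is.null(cds_cache[[gid]])) return(cds_cache[[gid]])
    segs <- models$cds[models$cds$gene_id == gid, ]
    gseq <- as.character(Biostrings::extractAt(
      genome[[segs$chrom[1]]],
      IRanges::IRanges(start = segs$start0 + 1L, end = segs$end)))
    strand <- segs$strand[1]
    segs_asc <- order(segs$start0)
    plus_seq <- paste(gseq[segs_asc], collapse = "")
    seq <- if (strand == "-")
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(plus_seq)))
    else plus_seq
    cds_cache[[gid]] <- list(seq = seq, segs = segs, strand = strand)
    cds_cache[[gid]]
  }

  coding_offset <- function(info, pos) {
    segs <- info$segs  # stored in transcription order
    off <- 0L
    for (i in seq_len(nrow(segs))) {
      if (pos >= segs$start0[i] && pos < segs$end[i]) {
        within <- if (info$strand == "+") pos - segs$start0[i] else
          segs$end[i] - 1L - pos
        return(off + within)
      }
      off <- off + (segs$end[i] - segs$start0[i])
    }
    NA_integer_
  }

  rows <- list()
  for (i in seq_len(nrow(snps))) {
    sid <- snps$snp_id[i]
    pos <- snps$pos[i]
    chrom <- snps$chrom[i]
    ref <- snps$ref[i]
    alt <- snps$alt[i]
    genome_base <- as.character(Biostrings::extractAt(
      genome[[chrom]], IRanges::IRanges(start = pos + 1L, width = 1L)))
    if (genome_base != ref)
      stop_invalid("reference mismatch at SNP %s: VCF says %s, genome has %s",
                   sid, ref, genome_base)
    gids <- mapping$gene_id[mapping$snp_id == sid]
    if (all(is.na(gids))) {
      rows[[length(rows) + 1]] <- data.frame(
        snp_id = sid, gene_id = NA_character_, effect = "intergenic",
        impact = "modifier", aa_change = NA_character_,
        stringsAsFactors = FALSE)
      next
    }
    for (gid in gids[!is.na(gids)]) {
      if (gid %in% invalid_cds) {
        warning(sprintf("gene %s has an invalid CDS; SNP %s annotated modifier",
                        gid, sid))
        rows[[length(rows) + 1]] <- data.frame(
          snp_id = sid, gene_id = gid, effect = "intron", impact = "modifier",
          aa_change = NA_character_, stringsAsFactors = FALSE)
        next
      }
      info <- cds_seq_of(gid)
      off <- coding_offset(info, pos)
      if (is.na(off)) {
        ex <- models$exons[models$exons$gene_id == gid, ]
        in_exon <- any(pos >= ex$start0 & pos < ex$end)
        rows[[length(rows) + 1]] <- data.frame(
          snp_id = sid, gene_id = gid,
          effect = if (in_exon) "UTR" else "intron",
          impact = "modifier", aa_change = NA_character_,
          stringsAsFactors = FALSE)
        next
      }
      strand <- info$strand
      ref_cod_allele <- if (strand == "+") ref else chartr("ACGT", "TGCA", ref)
      alt_cod_allele <- if (strand == "+") alt else chartr("ACGT", "TGCA", alt)
      codon_idx <- off %/% 3L
      codon_pos <- off %% 3L
      ref_codon <- substr(info$seq, codon_idx * 3L + 1L, codon_idx * 3L + 3L)
      stopifnot(substr(ref_codon, codon_pos + 1L, codon_pos + 1L) == ref_cod_allele)
      alt_codon <- ref_codon
      substr(alt_codon, codon_pos + 1L, codon_pos + 1L) <- alt_cod_allele
      ref_aa <- code[[ref_codon]]
      alt_aa <- code[[alt_codon]]
      if (ref_aa == alt_aa) {
        eff <- "synonymous"; imp <- "low"; chg <- NA_character_
      } else if (alt_aa == "*") {
        eff <- "stop_gained"; imp <- "high"
        chg <- sprintf("%s%d*", ref_aa, codon_idx + 1L)
      } else if (ref_aa == "*") {
        eff <- "stop_lost"; imp <- "high"
        chg <- sprintf("*%d%s", codon_idx + 1L, alt_aa)
      } else {
        eff <- "missense"; imp <- "moderate"
        chg <- sprintf("%s%d%s", ref_aa, codon_idx + 1L, alt_aa)
      }
      rows[[length(rows) + 1]] <- data.frame(
        snp_id = sid, gene_id = gid, effect = eff, impact = imp,
        aa_change = chg, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble the candidate-gene report
#'
#' One row per candidate gene with the report columns of the study table:
#' environmental variable source, ortholog id, gene length, number of SNPs
#' in the gene, number of associated SNPs, gene name, enriched pathway, and
#' Tajima's D (with its genome-wide percentile) per population, plus the
#' strong-candidate flag and collapsed per-SNP effect annotations. Rows are
#' ordered by pathway, then gene id, so re-runs on identical inputs are
#' byte-identical.
#'
#' @param candidates data.frame with (at least) `gene_id`, `ortholog`,
#'   `env_variable`, `gene_length`, `n_snps`, `n_associated`, `gene_name`,
#'   `pathway` and optionally `strong_candidate`.
#' @param diversity long per-gene, per-pool table with `gene_id`, `pool`,
#'   `D`, `percentile` (e.g. from [gene_diversity_table()]); may be `NULL`.
#' @param effects optional effect table from [classify_variant_effects()].
#' @param path optional TSV output path.
#' @return the report data.frame (invisibly writes `path` if given).
#' @export
build_report <- function(candidates, diversity = NULL, effects = NULL,
                         path = NULL) {
  rep <- candidates
  if (!is.null(diversity) && nrow(rep) > 0) {
    for (p in unique(diversity$pool)) {
      dsub <- diversity[diversity$pool == p, ]
      rep[[paste0("D_", p)]] <- dsub$D[match(rep$gene_id, dsub$gene_id)]
      rep[[paste0("percentile_", p)]] <-
        dsub$percentile[match(rep$gene_id, dsub$gene_id)]
    }
  }
  if (!is.null(effects) && nrow(rep) > 0) {
    eff <- effects[!is.na(effects$gene_id), ]
    collapsed <- tapply(
      sprintf("%s:%s/%s", eff$snp_id, eff$effect, eff$impact),
      eff$gene_id, paste, collapse = ";")
    rep$effects <- as.character(collapsed[rep$gene_id])
  }
  rep <- rep[order(rep$pathway, rep$gene_id), , drop = FALSE]
  rownames(rep) <- NULL
  if (!is.null(path)) {
    write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  rep
}
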