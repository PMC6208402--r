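# GFF3 read/write via rtracklayer. GFF3 is 1-based closed; internal gene
# models are 0-based half-open — conversion happens only here.

#' Write gene models to GFF3
#'
#' Emits `gene`, `exon` and `CDS` features with `ID`/`Parent` attributes;
#' ortholog and display name travel as `ortholog` and `Name` attributes of
#' the gene feature. Output is deterministic for a given model set.
#'
#' @param models a [gene_models()] object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  g <- models$genes
  e <- models$exons
  cd <- models$cds
  gr_gene <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(g$start0 + 1L, g$end), strand = g$strand,
    type = "gene", ID = g$gene_id, Name = g$name, ortholog = g$ortholog)
  gr_exon <- GenomicRanges::GRanges(
    e$chrom, IRanges::IRanges(e$start0 + 1L, e$end), strand = e$strand,
    type = "exon", Parent = e$gene_id)
  gr_cds <- GenomicRanges::GRanges(
    cd$chrom, IRanges::IRanges(cd$start0 + 1L, cd$end), strand = cd$strand,
    type = "CDS", Parent = cd$gene_id, phase = cd$phase)
  gr <- suppressWarnings(c(gr_gene, gr_exon, gr_cds))
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Coordinates are converted to the internal 0-based half-open convention;
#' strand is preserved. Genes whose total CDS length is not a multiple of 3
#' trigger a validation warning and are flagged non-coding for effect
#' classification; an unknown strand is an error.
#'
#' @param path GFF3 file (gzip transparent).
#' @return a [gene_models()] object.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  if (any(df$strand == "*" & df$type %in% c("gene", "exon", "CDS")))
    stop_invalid("GFF3 %s: unknown strand '*' on a gene feature", path)
  gene_df <- df[df$type == "gene", ]
  first_chr <- function(x) vapply(x, function(v) as.character(v)[1], "")
  genes <- data.frame(
    gene_id = as.character(gene_df$ID),
    ortholog = if ("ortholog" %in% names(gene_df)) as.character(gene_df$ortholog) else NA_character_,
    name = if ("Name" %in% names(gene_df)) as.character(gene_df$Name) else NA_character_,
    chrom = as.character(gene_df$seqnames), strand = as.character(gene_df$strand),
    start0 = gene_df$start - 1L, end = gene_df$end, stringsAsFactors = FALSE)
  ex_df <- df[df$type == "exon", ]
  exons <- data.frame(gene_id = first_chr(ex_df$Parent),
                      chrom = as.character(ex_df$seqnames),
                      strand = as.character(ex_df$strand),
                      start0 = ex_df$start - 1L, end = ex_df$end,
                      stringsAsFactors = FALSE)
  cd_df <- df[df$type == "CDS", ]
  cds <- data.frame(gene_id = first_chr(cd_df$Parent),
                    chrom = as.character(cd_df$seqnames),
                    strand = as.character(cd_df$strand),
                    start0 = cd_df$start - 1L, end = cd_df$end,
                    phase = as.integer(as.character(cd_df$phase)),
                    stringsAsFactors = FALSE)
  # store CDS segments in transcription order (phase bookkeeping relies on it)
  ord <- order(cds$gene_id, ifelse(cds$strand == "-", -cds$start0, cds$start0))
  cds <- cds[ord, ]
  rownames(cds) <- NULL
  gene_models(genes, exons, cds)
}

#' Write / read a genome as FASTA
#' @param genome a [Biostrings::DNAStringSet].
#' @param path FASTA path.
#' @return `read_genome` returns a `DNAStringSet`.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' @rdname write_genome
#' @export
read_genome <- function(path) {
  Biostrings::readDNAStringSet(path)
}
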