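# Synthetic genome annotation: gene models, pathway collection, sequence.

SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Construct a gene-model set
#'
#' Internal coordinates are 0-based half-open throughout; conversion to the
#' 1-based closed GFF3 convention happens only in [write_gff3()] /
#' [read_gff3()].
#'
#' @param genes data.frame: `gene_id`, `ortholog`, `name`, `chrom`, `strand`,
#'   `start0`, `end`.
#' @param exons data.frame: `gene_id`, `chrom`, `strand`, `start0`, `end`.
#' @param cds data.frame: `gene_id`, `chrom`, `strand`, `start0`, `end`,
#'   `phase` (in transcription order).
#' @return object of class `gene_models`.
#' @export
gene_models <- function(genes, exons, cds) {
  obj <- structure(list(genes = genes, exons = exons, cds = cds),
                   class = "gene_models")
  validate_gene_models(obj)
  obj
}

validate_gene_models <- function(x) {
  stopifnot(all(c("gene_id", "chrom", "strand", "start0", "end") %in% names(x$genes)))
  if (!all(x$genes$strand %in% c("+", "-")))
    stop_invalid("unknown strand in gene models")
  for (g in unique(x$exons$gene_id)) {
    e <- x$exons[x$exons$gene_id == g, ]
    e <- e[order(e$start0), ]
    if (nrow(e) > 1 && any(e$start0[-1] < e$end[-nrow(e)]))
      stop_invalid("overlapping exons in gene %s", g)
  }
  cds_len <- tapply(x$cds$end - x$cds$start0, x$cds$gene_id, sum)
  bad <- names(cds_len)[cds_len %% 3 != 0]
  if (length(bad) > 0) {
    warning(sprintf("CDS length not divisible by 3 for: %s; flagged non-coding",
                    paste(bad, collapse = ",")))
  }
  x$genes$coding_valid <- !(x$genes$gene_id %in% bad)
  invisible(x)
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes, %d exons, %d CDS segments on %d scaffolds\n",
              nrow(x$genes), nrow(x$exons), nrow(x$cds),
              length(unique(x$genes$chrom))))
  invisible(x)
}

#' Generate a synthetic genome annotation
#'
#' Lays out non-overlapping gene models (1-3 exons, optional UTRs, CDS length
#' a multiple of 3, both strands represented) on scaffolds, builds a genome
#' sequence whose CDSs start with ATG, end with a stop codon and contain no
#' internal stops, and groups genes into named pathways. The first pathway is
#' the designated "adaptive" pathway later targeted by
#' [simulate_frequencies()].
#'
#' @param params a [sim_params()] object.
#' @param seed integer seed.
#' @return list with elements `genes` (a [gene_models()] object), `pathways`
#'   (named list of gene-id vectors with a `description` attribute), and
#'   `genome` (a [Biostrings::DNAStringSet]).
#' @export
generate_genome_annotation <- function(params,
                                       seed = split_seed(params$seed, "annotation")) {
  validate_sim_params(params)
  with_seed(seed, {
    ng <- params$n_genes
    gene_rows <- vector("list", ng)
    exon_rows <- vector("list", ng)
    cds_rows <- vector("list", ng)

    scaffold_of <- rep(seq_len(params$n_scaffolds), length.out = ng)
    scaffold_of <- sort(scaffold_of)
    cursor <- rep(0L, params$n_scaffolds)

    for (i in seq_len(ng)) {
      sc <- scaffold_of[i]
      chrom <- sprintf("scf%03d", sc)
      strand <- if (i %% 2 == 0) "-" else "+"
      n_codons <- sample(80:400, 1)
      cds_len <- 3L * n_codons
      utr5 <- sample(0:80, 1)
      utr3 <- sample(0:80, 1)
      n_exons <- sample(1:3, 1)
      # split the CDS into n_exons chunks of >= 30 bp (transcription order)
      if (n_exons == 1) {
        chunks <- cds_len
      } else {
        cuts <- sort(sample(seq(30, cds_len - 30), n_exons - 1))
        while (any(diff(c(0, cuts, cds_len)) < 30)) {
          cuts <- sort(sample(seq(30, cds_len - 30), n_exons - 1))
        }
        chunks <- diff(c(0, cuts, cds_len))
      }
      introns <- if (n_exons > 1) sample(60:200, n_exons - 1, replace = TRUE) else integer(0)

      # local layout in transcription order, 0-based half-open
      ex_start <- integer(n_exons); ex_end <- integer(n_exons)
      cd_start <- integer(n_exons); cd_end <- integer(n_exons)
      pos <- 0L
      for (e in seq_len(n_exons)) {
        ex_start[e] <- pos
        if (e == 1) pos <- pos + utr5
        cd_start[e] <- pos
        pos <- pos + chunks[e]
        cd_end[e] <- pos
        if (e == n_exons) pos <- pos + utr3
        ex_end[e] <- pos
        if (e < n_exons) pos <- pos + introns[e]
      }
      glen <- pos
      phase <- (3L - (cumsum(c(0L, chunks[-n_exons])) %% 3L)) %% 3L

      gstart <- cursor[sc] + sample(200:500, 1)
      cursor[sc] <- gstart + glen
      if (strand == "+") {
        g_ex_start <- gstart + ex_start; g_ex_end <- gstart + ex_end
        g_cd_start <- gstart + cd_start; g_cd_end <- gstart + cd_end
      } else {
        # mirror local coordinates so transcription runs genomically rightward
        # to leftward
        g_ex_start <- gstart + glen - ex_end; g_ex_end <- gstart + glen - ex_start
        g_cd_start <- gstart + glen - cd_end; g_cd_end <- gstart + glen - cd_start
      }
      ord <- order(g_ex_start)
      gid <- sprintf("g%04d", i)
      gene_rows[[i]] <- data.frame(
        gene_id = gid,
        ortholog = sprintf("AT%dG%05d", ((i - 1) %% 5) + 1, i * 10),
        name = sprintf("synthetic gene %d", i),
        chrom = chrom, strand = strand,
        start0 = gstart, end = gstart + glen,
        stringsAsFactors = FALSE)
      exon_rows[[i]] <- data.frame(gene_id = gid, chrom = chrom, strand = strand,
                                   start0 = g_ex_start[ord], end = g_ex_end[ord],
                                   stringsAsFactors = FALSE)
      # phase is attached in transcription order
      cord <- if (strand == "+") order(g_cd_start) else order(-g_cd_start)
      cds_rows[[i]] <- data.frame(gene_id = gid, chrom = chrom, strand = strand,
                                  start0 = g_cd_start[cord], end = g_cd_end[cord],
                                  phase = phase, stringsAsFactors = FALSE)
    }

    genes <- do.call(rbind, gene_rows)
    exons <- do.call(rbind, exon_rows)
    cds <- do.call(rbind, cds_rows)

    scaffold_len <- cursor + 500L
    if (!is.null(params$scaffold_length)) {
      if (any(scaffold_len > params$scaffold_length))
        stop_invalid(
          "impossible packing: genes need up to %d bp but scaffold_length is %d",
          max(scaffold_len), params$scaffold_length)
      scaffold_len <- rep(as.integer(params$scaffold_length), params$n_scaffolds)
    }

    # genome sequence: random background, CDSs overwritten with valid ORFs
    seqs <- lapply(scaffold_len, function(L) sample(c("A", "C", "G", "T"), L, replace = TRUE))
    names(seqs) <- sprintf("scf%03d", seq_len(params$n_scaffolds))
    for (i in seq_len(ng)) {
      gid <- genes$gene_id[i]
      strand <- genes$strand[i]
      chrom <- genes$chrom[i]
      segs <- cds[cds$gene_id == gid, ]
      cds_len <- sum(segs$end - segs$start0)
      n_codons <- cds_len %/% 3
      cds_nt <- c("A", "T", "G",
                  unlist(strsplit(sample(SENSE_CODONS, n_codons - 2, replace = TRUE), "")),
                  unlist(strsplit(sample(STOP_CODONS, 1), "")))
      if (strand == "-") {
        plus_nt <- rev(chartr("ACGT", "TGCA", cds_nt))
      } else {
        plus_nt <- cds_nt
      }
      segs <- segs[order(segs$start0), ]
      offset <- 0L
      for (k in seq_len(nrow(segs))) {
        len <- segs$end[k] - segs$start0[k]
        seqs[[chrom]][(segs$start0[k] + 1):segs$end[k]] <- plus_nt[(offset + 1):(offset + len)]
        offset <- offset + len
      }
    }
    genome <- Biostrings::DNAStringSet(vapply(seqs, paste, "", collapse = ""))

    # disjoint pathway memberships over a shuffled gene order
    shuffled <- sample(genes$gene_id)
    pathways <- list()
    for (p in seq_len(params$n_pathways)) {
      idx <- ((p - 1) * params$genes_per_pathway + 1):(p * params$genes_per_pathway)
      pathways[[sprintf("pw%02d", p)]] <- sort(shuffled[idx])
    }
    attr(pathways, "description") <- setNames(
      sprintf("synthetic pathway %d", seq_len(params$n_pathways)), names(pathways))

    list(genes = gene_models(genes, exons, cds), pathways = pathways,
         genome = genome)
  })
}
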