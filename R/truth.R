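# Ground-truth bookkeeping for synthetic scenarios: which SNPs are adaptive,
# which genes carry sweeps, and the true frequency matrix. Enables recovery
# tests of the full pipeline.

#' Construct a synthetic ground-truth table
#'
#' @param snps data.frame: `snp_id`, `gene_id`, `is_adaptive`, `driver`,
#'   `beta`, `p0`.
#' @param sweep data.frame: `gene_id`, `affected_pools` (comma-separated).
#' @param freq_true SNP x pool matrix of true frequencies.
#' @return object of class `truth_table`.
#' @export
truth_table <- function(snps, sweep, freq_true) {
  if (any(freq_true < 0 | freq_true > 1))
    stop_invalid("true frequencies must lie in [0,1]")
  if (!all(snps$snp_id[snps$is_adaptive] %in% rownames(freq_true)))
    stop_invalid("adaptive SNP ids must exist in the SNP panel")
  structure(list(snps = snps, sweep = sweep, freq_true = freq_true),
            class = "truth_table")
}

#' @export
print.truth_table <- function(x, ...) {
  cat(sprintf("truth_table: %d SNPs (%d adaptive), %d sweep genes\n",
              nrow(x$snps), sum(x$snps$is_adaptive), nrow(x$sweep)))
  invisible(x)
}

fmt_full <- function(x) {
  if (is.double(x)) sprintf("%.17g", x) else as.character(x)
}

#' Write / read a ground-truth table (bit-exact round trip)
#'
#' Three TSV files under `dir`: `truth_snps.tsv`, `truth_sweep.tsv`,
#' `truth_freq.tsv`. Doubles are serialized with 17 significant digits so the
#' round trip reproduces them bit-exactly.
#'
#' @param truth a [truth_table()] object.
#' @param dir output directory (created if needed).
#' @return `write_truth_table` returns `dir` invisibly; `read_truth_table`
#'   returns a `truth_table`.
#' @export
write_truth_table <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- truth$snps
  s$beta <- fmt_full(s$beta)
  s$p0 <- fmt_full(s$p0)
  write.table(s, file.path(dir, "truth_snps.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(truth$sweep, file.path(dir, "truth_sweep.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  f <- as.data.frame(apply(truth$freq_true, 2, fmt_full))
  f <- cbind(snp_id = rownames(truth$freq_true), f)
  write.table(f, file.path(dir, "truth_freq.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(dir) {
  s <- read.delim(file.path(dir, "truth_snps.tsv"), stringsAsFactors = FALSE,
                  colClasses = c(gene_id = "character", driver = "character"))
  s$beta <- as.numeric(s$beta)
  s$p0 <- as.numeric(s$p0)
  s$gene_id[s$gene_id %in% c("", "NA")] <- NA_character_
  s$driver[s$driver %in% c("", "NA")] <- NA_character_
  sw <- read.delim(file.path(dir, "truth_sweep.tsv"), stringsAsFactors = FALSE)
  f <- read.delim(file.path(dir, "truth_freq.tsv"), stringsAsFactors = FALSE,
                  check.names = FALSE)
  m <- as.matrix(f[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- f$snp_id
  truth_table(s, sw, m)
}
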