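# Post-calling SNP filter cascade and pooled allele-frequency derivation.

#' Filter thresholds for the post-calling SNP cascade
#'
#' Defaults follow the stringent post-calling filter set used for pooled
#' variant calls in metallicolous/non-metallicolous *Arabidopsis halleri*
#' Pool-seq designs: site quality (PHRED) > 30, mapping quality > 40, total
#' read depth < 1200, per-pool depth > 60 (one read per chromosome for pools
#' of 60), quality/depth ratio > 0.25, no missing pool data, total alternate
#' observation count within [4, 236], bi-allelic records only, and removal
#' of non-variant sites. Quality, depth and ratio bounds are strict
#' inequalities; the alternate-count bounds are inclusive.
#'
#' @param min_qual,min_mq,max_depth,min_pool_depth,min_qual_depth numeric
#'   thresholds as above.
#' @param require_complete drop records with missing pool data.
#' @param min_alt_count,max_alt_count inclusive bounds on the alternate
#'   observation count.
#' @param alt_count_scope `"total"` sums alternate observations over pools
#'   (default); `"per_pool"` applies the bounds to each pool separately.
#' @param biallelic_only,drop_nonvariant drop multi-allelic records and
#'   records with no alternate (or no reference) observations at all.
#' @return object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_qual = 30, min_mq = 40, max_depth = 1200,
                              min_pool_depth = 60, min_qual_depth = 0.25,
                              require_complete = TRUE,
                              min_alt_count = 4, max_alt_count = 236,
                              alt_count_scope = c("total", "per_pool"),
                              biallelic_only = TRUE, drop_nonvariant = TRUE) {
  if (min_alt_count > max_alt_count)
    stop_invalid("min_alt_count must not exceed max_alt_count")
  structure(list(min_qual = min_qual, min_mq = min_mq, max_depth = max_depth,
                 min_pool_depth = min_pool_depth,
                 min_qual_depth = min_qual_depth,
                 require_complete = require_complete,
                 min_alt_count = min_alt_count, max_alt_count = max_alt_count,
                 alt_count_scope = match.arg(alt_count_scope),
                 biallelic_only = biallelic_only,
                 drop_nonvariant = drop_nonvariant),
            class = "filter_thresholds")
}

filter_rule_names <- function() {
  c("min_qual", "min_mq", "max_depth", "min_pool_depth", "min_qual_depth",
    "missing_data", "min_alt_count", "max_alt_count", "multiallelic",
    "nonvariant")
}

#' Apply the site filter cascade
#'
#' A record is retained iff it passes every rule; removed records are
#' partitioned by the first failing rule, with rules tested in the threshold
#' order (site quality, mapping quality, total depth, per-pool depth,
#' quality/depth, missing data, minimum and maximum alternate count,
#' bi-allelic, non-variant). A missing field counts as a failure of the rule
#' that tests it. `retained + sum(drop_counts)` always equals the input
#' record count.
#'
#' @param records a [variant_records()] object.
#' @param thresholds a [filter_thresholds()] object.
#' @return list with `counts` (an [allele_counts()] of retained records),
#'   `drop_counts` (named integer vector per rule), `retained` (logical
#'   vector), `first_fail` (factor of first failing rule, `NA` if retained).
#' @export
apply_site_filters <- function(records, thresholds = filter_thresholds()) {
  s <- records$sites
  th <- thresholds
  n <- nrow(s)
  na_false <- function(x) !is.na(x) & x

  pool_na <- is.na(records$DP) | is.na(records$RO) | is.na(records$AO)
  alt_total <- rowSums(records$AO, na.rm = TRUE)
  alt_total[rowSums(!is.na(records$AO)) == 0] <- NA
  ref_total <- rowSums(records$RO, na.rm = TRUE)

  pass <- list(
    min_qual = na_false(s$qual > th$min_qual),
    min_mq = na_false(s$mq > th$min_mq),
    max_depth = na_false(s$dp < th$max_depth),
    min_pool_depth = apply(records$DP, 1, function(d) all(!is.na(d) & d > th$min_pool_depth)),
    min_qual_depth = na_false(s$qual / s$dp > th$min_qual_depth),
    missing_data = if (th$require_complete) rowSums(pool_na) == 0 else rep(TRUE, n),
    min_alt_count = if (th$alt_count_scope == "total") {
      na_false(alt_total >= th$min_alt_count)
    } else {
      apply(records$AO, 1, function(a) all(!is.na(a) & a >= th$min_alt_count))
    },
    max_alt_count = if (th$alt_count_scope == "total") {
      na_false(alt_total <= th$max_alt_count)
    } else {
      apply(records$AO, 1, function(a) all(!is.na(a) & a <= th$max_alt_count))
    },
    multiallelic = if (th$biallelic_only) !s$multiallelic else rep(TRUE, n),
    nonvariant = if (th$drop_nonvariant) {
      na_false(alt_total > 0) & na_false(ref_total > 0)
    } else rep(TRUE, n)
  )
  pass_mat <- do.call(cbind, pass)
  retained <- rowSums(!pass_mat) == 0
  first_fail_idx <- apply(pass_mat, 1, function(p) {
    w <- which(!p)
    if (length(w) == 0) NA_integer_ else w[1]
  })
  first_fail <- factor(filter_rule_names()[first_fail_idx],
                       levels = filter_rule_names())
  drop_counts <- table(first_fail)
  drop_counts <- setNames(as.integer(drop_counts), names(drop_counts))

  keep <- which(retained)
  ids <- if (!is.null(s$id)) s$id[keep] else sprintf("snp%06d", seq_along(keep))
  snps <- data.frame(snp_id = ids,
                     chrom = s$chrom[keep], pos = s$pos[keep],
                     ref = s$ref[keep], alt = s$alt[keep],
                     stringsAsFactors = FALSE)
  sub <- function(m) {
    m <- m[keep, , drop = FALSE]
    storage.mode(m) <- "integer"
    colnames(m) <- records$pools
    m
  }
  counts <- allele_counts(snps, records$pools, ref = sub(records$RO),
                          alt = sub(records$AO), depth = sub(records$DP))
  list(counts = counts, drop_counts = drop_counts, retained = retained,
       first_fail = first_fail)
}

#' Pooled allele frequencies from filtered counts
#'
#' The Pool-seq frequency estimator: alternate observations over depth per
#' SNP and pool. Zero depths are an error (impossible after the per-pool
#' depth filter).
#'
#' @param counts an [allele_counts()] object.
#' @return object of class `freq_matrix`: `snps` metadata plus a SNP x pool
#'   `freq` matrix in `[0,1]`.
#' @export
counts_to_frequencies <- function(counts) {
  validate_allele_counts(counts)
  if (any(is.na(counts$depth)) || any(counts$depth == 0))
    stop_invalid("zero or missing depth: filter before computing frequencies")
  freq <- counts$alt / counts$depth
  dimnames(freq) <- list(counts$snps$snp_id, counts$pools)
  freq_matrix(counts$snps, freq)
}

#' @rdname counts_to_frequencies
#' @param snps SNP metadata data.frame.
#' @param freq SNP x pool frequency matrix.
#' @export
freq_matrix <- function(snps, freq) {
  if (any(freq < 0 | freq > 1, na.rm = TRUE))
    stop_invalid("frequencies must lie in [0,1]")
  structure(list(snps = snps, pools = colnames(freq), freq = freq),
            class = "freq_matrix")
}

#' @export
print.freq_matrix <- function(x, ...) {
  cat(sprintf("freq_matrix: %d SNPs x %d pools\n", nrow(x$freq), ncol(x$freq)))
  invisible(x)
}

#' Draw a random SNP subset
#'
#' Uniform sample without replacement, deterministic under `seed`, honouring
#' an exclusion set (e.g. SNPs already significant in association).
#'
#' @param freqs a `freq_matrix`, `allele_counts`, or integer count of
#'   available SNPs.
#' @param n subset size.
#' @param exclude_ids SNP ids (or indices) to exclude from sampling.
#' @param seed integer seed.
#' @return integer vector of SNP indices.
#' @export
sample_random_snps <- function(freqs, n, exclude_ids = NULL, seed = 1L) {
  ids <- if (is.numeric(freqs)) sprintf("snp%06d", seq_len(freqs)) else freqs$snps$snp_id
  avail <- which(!(ids %in% exclude_ids) & !(seq_along(ids) %in% exclude_ids))
  if (n > length(avail))
    stop_invalid("requested %d SNPs but only %d available after exclusion",
                 n, length(avail))
  with_seed(seed, sort(sample(avail, n)))
}
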