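#' Per-SNP, per-pool allele count matrix
#'
#' The pipeline's central observable: for every SNP and pool, the read depth
#' and the number of reads supporting the reference and alternate allele.
#'
#' @param snps data.frame with columns `snp_id`, `chrom`, `pos` (0-based),
#'   `ref`, `alt`.
#' @param pools character vector of pool names.
#' @param ref,alt,depth integer matrices (SNP x pool).
#' @return object of class `allele_counts`.
#' @export
allele_counts <- function(snps, pools, ref, alt, depth) {
  obj <- structure(list(snps = snps, pools = pools,
                        ref = ref, alt = alt, depth = depth),
                   class = "allele_counts")
  validate_allele_counts(obj)
  obj
}

validate_allele_counts <- function(x) {
  stopifnot(all(c("snp_id", "chrom", "pos", "ref", "alt") %in% names(x$snps)))
  dims <- dim(x$depth)
  if (!identical(dim(x$ref), dims) || !identical(dim(x$alt), dims))
    stop_invalid("ref/alt/depth matrices must share dimensions")
  if (nrow(x$snps) != dims[1] || length(x$pools) != dims[2])
    stop_invalid("count matrix dimensions do not match SNP/pool metadata")
  ok <- is.na(x$ref) | is.na(x$alt) | is.na(x$depth) |
    (x$ref >= 0 & x$alt >= 0 & x$depth >= 0 & x$ref + x$alt <= x$depth)
  if (!all(ok))
    stop_invalid("invalid counts: need ref + alt <= depth and all >= 0")
  invisible(x)
}

#' @export
print.allele_counts <- function(x, ...) {
  cat(sprintf("allele_counts: %d SNPs x %d pools (median depth %.0f)\n",
              nrow(x$snps), length(x$pools),
              median(x$depth, na.rm = TRUE)))
  invisible(x)
}

#' @export
dim.allele_counts <- function(x) dim(x$depth)

#' Subset an allele-count matrix by SNP index
#' @param x an `allele_counts` object.
#' @param i integer or logical SNP index.
#' @param ... unused.
#' @return an `allele_counts` with the selected SNPs.
#' @export
`[.allele_counts` <- function(x, i, ...) {
  allele_counts(x$snps[i, , drop = FALSE], x$pools,
                x$ref[i, , drop = FALSE], x$alt[i, , drop = FALSE],
                x$depth[i, , drop = FALSE])
}
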