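# VCF 4.2 dialect carrying per-pool DP/RO/AO (the fields a pooled
# variant caller emits). Reading goes through vcfR with a strict structural
# pre-check; writing emits exactly the fields the pipeline needs.

#' Pooled variant records
#'
#' Container for VCF-derived pooled variant calls: per-site metadata (site
#' quality, mapping quality, total depth, multi-allelic flag) plus per-pool
#' depth and reference/alternate observation counts. Positions are 0-based
#' half-open internally.
#'
#' @param sites data.frame: `chrom`, `pos` (0-based), `ref`, `alt`
#'   (comma-separated if multi-allelic), `qual`, `mq`, `dp`, `multiallelic`.
#' @param pools character vector of pool names.
#' @param DP,RO,AO numeric matrices (site x pool); `NA` marks missing data.
#' @return object of class `variant_records`.
#' @export
variant_records <- function(sites, pools, DP, RO, AO) {
  stopifnot(all(c("chrom", "pos", "ref", "alt", "qual", "mq", "dp",
                  "multiallelic") %in% names(sites)))
  ok <- is.na(RO) | is.na(AO) | is.na(DP) | (RO + AO <= DP)
  if (!all(ok))
    stop_invalid("per-pool ref + alt observations exceed depth")
  structure(list(sites = sites, pools = pools, DP = DP, RO = RO, AO = AO),
            class = "variant_records")
}

#' Promote an allele-count matrix to variant records
#'
#' Adds site-level fields so the filter cascade can run on simulated counts:
#' site quality defaults to twice the total depth (confident pooled calls
#' have caller qualities well above their depth) and mapping quality to 60.
#'
#' @param counts an [allele_counts()] object.
#' @param qual per-site quality (scalar or vector); `NULL` = 2 x depth.
#' @param mq per-site mapping quality.
#' @return a [variant_records()] object.
#' @export
as_variant_records <- function(counts, qual = NULL, mq = 60) {
  dp <- rowSums(counts$depth)
  if (is.null(qual)) qual <- 2 * dp
  variant_records(
    sites = data.frame(id = counts$snps$snp_id,
                       chrom = counts$snps$chrom, pos = counts$snps$pos,
                       ref = counts$snps$ref, alt = counts$snps$alt,
                       qual = qual, mq = mq, dp = dp,
                       multiallelic = grepl(",", counts$snps$alt, fixed = TRUE),
                       stringsAsFactors = FALSE),
    pools = counts$pools, DP = counts$depth, RO = counts$ref, AO = counts$alt)
}

#' @export
print.variant_records <- function(x, ...) {
  cat(sprintf("variant_records: %d sites x %d pools (%d multi-allelic)\n",
              nrow(x$sites), length(x$pools), sum(x$sites$multiallelic)))
  invisible(x)
}

#' Write pooled variant records to VCF 4.2
#'
#' @param records a [variant_records()] object, or an [allele_counts()]
#'   object (site quality and mapping quality then default to `qual`, `mq`).
#' @param path output path.
#' @param qual,mq defaults used when writing an `allele_counts` object:
#'   site quality scales with the total depth (as caller-emitted qualities
#'   do) when `qual = NULL`.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path, qual = NULL, mq = 60) {
  if (inherits(records, "allele_counts")) {
    records <- as_variant_records(records, qual = qual, mq = mq)
  }
  s <- records$sites
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=poolscape",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=RO,Number=1,Type=Integer,Description=\"Reference observation count\">",
    "##FORMAT=<ID=AO,Number=A,Type=Integer,Description=\"Alternate observation count\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", records$pools), collapse = "\t"))
  fmt_cell <- function(d, r, a) {
    dot <- function(x) ifelse(is.na(x), ".", as.character(as.integer(x)))
    paste(dot(d), dot(r), dot(a), sep = ":")
  }
  ids <- if (!is.null(s$id)) s$id else sprintf("site%06d", seq_len(nrow(s)))
  body <- character(nrow(s))
  for (i in seq_len(nrow(s))) {
    cells <- fmt_cell(records$DP[i, ], records$RO[i, ],
                      as.character(as.integer(records$AO[i, ])))
    body[i] <- paste(c(s$chrom[i], s$pos[i] + 1L, ids[i],
                       s$ref[i], s$alt[i],
                       format(s$qual[i], trim = TRUE),
                       "PASS",
                       sprintf("DP=%d;MQ=%s", as.integer(s$dp[i]),
                               format(s$mq[i], trim = TRUE)),
                       "DP:RO:AO", cells), collapse = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read pooled variant records from VCF
#'
#' Requires the per-pool `DP`, `RO` and `AO` FORMAT fields (schema error
#' otherwise). A structural pre-scan rejects truncated or ragged files with a
#' parse error naming the offending line; nothing is silently dropped.
#' Multi-allelic records are read and flagged (they are excluded downstream
#' by the bi-allelic filter, not rejected at parse time).
#'
#' @param path VCF path (gzip transparent).
#' @return a [variant_records()] object.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop_invalid("VCF %s does not exist", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con)
  close(con)
  hdr_idx <- grep("^#CHROM", lines)
  if (length(hdr_idx) != 1)
    stop_invalid("VCF %s: missing #CHROM header line", path)
  n_fields <- length(strsplit(lines[hdr_idx], "\t", fixed = TRUE)[[1]])
  if (n_fields < 10)
    stop_invalid("VCF %s: no sample columns", path)
  data_lines <- which(seq_along(lines) > hdr_idx & nzchar(lines))
  widths <- lengths(strsplit(lines[data_lines], "\t", fixed = TRUE))
  bad <- data_lines[widths != n_fields]
  if (length(bad) > 0)
    stop_invalid("VCF %s: parse error at line %d (%d fields, expected %d)",
                 path, bad[1], widths[which(data_lines == bad[1])], n_fields)
  fmt_lines <- grep("^##FORMAT", lines, value = TRUE)
  fmt_ids <- sub("^##FORMAT=<ID=([A-Za-z0-9]+).*$", "\\1", fmt_lines)
  for (need in c("DP", "RO", "AO")) {
    if (!need %in% fmt_ids)
      stop_invalid("VCF %s: header does not declare required FORMAT field %s",
                   path, need)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  info <- fix[, "INFO"]
  grab_info <- function(key) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]+)"), info))
    as.numeric(vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, ""))
  }
  DP <- suppressWarnings(apply(vcfR::extract.gt(v, element = "DP"), 2, as.numeric))
  RO <- suppressWarnings(apply(vcfR::extract.gt(v, element = "RO"), 2, as.numeric))
  AO_raw <- vcfR::extract.gt(v, element = "AO")
  # multi-allelic AO is comma separated; summed for the per-pool observation
  AO <- apply(AO_raw, 2, function(col) {
    vapply(strsplit(col, ",", fixed = TRUE), function(x) {
      x <- suppressWarnings(as.numeric(x))
      if (all(is.na(x))) NA_real_ else sum(x, na.rm = TRUE)
    }, 0)
  })
  n <- nrow(fix)
  to_mat <- function(m) {
    m <- matrix(m, nrow = n)
    colnames(m) <- colnames(v@gt)[-1]
    m
  }
  sites <- data.frame(
    id = fix[, "ID"],
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]) - 1L,
    ref = fix[, "REF"], alt = fix[, "ALT"],
    qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
    mq = grab_info("MQ"), dp = grab_info("DP"),
    multiallelic = grepl(",", fix[, "ALT"], fixed = TRUE),
    stringsAsFactors = FALSE)
  variant_records(sites, colnames(v@gt)[-1], to_mat(DP), to_mat(RO), to_mat(AO))
}
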