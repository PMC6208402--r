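# Readers/writers for the plain-text table formats: per-pool allele-count
# TSV, environment TSV, and GMT gene sets. Positions are 1-based in files and
# 0-based half-open internally; conversion happens only here.

#' Write / read a per-pool allele-count table
#'
#' TSV with columns `chrom`, `pos` (1-based in the file), `ref`, `alt`, then
#' one column per pool holding `ref:alt:depth` triplets.
#'
#' @param counts an [allele_counts()] object.
#' @param path file path.
#' @return `write_count_table` returns `path` invisibly; `read_count_table`
#'   returns an [allele_counts()].
#' @export
write_count_table <- function(counts, path) {
  validate_allele_counts(counts)
  df <- data.frame(chrom = counts$snps$chrom, pos = counts$snps$pos + 1L,
                   ref = counts$snps$ref, alt = counts$snps$alt,
                   stringsAsFactors = FALSE)
  for (j in seq_along(counts$pools)) {
    df[[counts$pools[j]]] <- sprintf("%d:%d:%d", counts$ref[, j],
                                     counts$alt[, j], counts$depth[, j])
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  df <- tryCatch(
    read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
               colClasses = "character"),
    error = function(e) stop_invalid("cannot parse count table %s: %s",
                                     path, conditionMessage(e)))
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(df)))
    stop_invalid("count table %s lacks required columns %s", path,
                 paste(setdiff(need, names(df)), collapse = ","))
  pools <- setdiff(names(df), need)
  n <- nrow(df)
  ref <- alt <- depth <- matrix(0L, n, length(pools),
                                dimnames = list(NULL, pools))
  if (n > 0) {
    for (j in seq_along(pools)) {
      parts <- strsplit(df[[pools[j]]], ":", fixed = TRUE)
      if (any(lengths(parts) != 3))
        stop_invalid("ragged triplet in pool column '%s' of %s", pools[j], path)
      m <- matrix(suppressWarnings(as.numeric(unlist(parts))), ncol = 3, byrow = TRUE)
      if (any(is.na(m)) || any(m != floor(m)))
        stop_invalid("non-integer counts in pool column '%s' of %s", pools[j], path)
      ref[, j] <- as.integer(m[, 1]); alt[, j] <- as.integer(m[, 2])
      depth[, j] <- as.integer(m[, 3])
    }
  }
  pos <- as.integer(df$pos)
  snps <- data.frame(snp_id = if (n > 0) sprintf("snp%06d", seq_len(n)) else character(0),
                     chrom = df$chrom, pos = pos - 1L,
                     ref = df$ref, alt = df$alt, stringsAsFactors = FALSE)
  allele_counts(snps, pools, ref, alt, depth)
}

#' Write / read a per-pool environment table
#'
#' TSV with one row per pool: `site`, `Site_type` (1 = metalliferous, 0 =
#' non-metalliferous) and named numeric environmental variables. `Site-type`
#' is accepted as a column-name alias on input.
#'
#' @param env environment data.frame.
#' @param path file path.
#' @return `read_env_table` returns the validated data.frame.
#' @export
write_env_table <- function(env, path) {
  write.table(env, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_env_table
#' @export
read_env_table <- function(path) {
  env <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(env)[names(env) == "Site-type"] <- "Site_type"
  if (!"Site_type" %in% names(env))
    stop_invalid("environment table %s lacks a Site_type column", path)
  if (!all(env$Site_type %in% c(0L, 1L)))
    stop_invalid("Site_type must be coded 0/1")
  if (anyNA(env))
    stop_invalid("environment table %s contains missing values", path)
  env
}

#' Write / read gene sets in GMT format
#'
#' One set per line: name, free-text description, then member gene ids,
#' tab-separated. The reader keeps descriptions in a `description` attribute
#' (a named character vector), which is why a dedicated reader is used here.
#'
#' @param pathways named list of character vectors (optionally with a
#'   `description` attribute).
#' @param path file path.
#' @return `read_gmt` returns the named list of gene-id sets.
#' @export
write_gmt <- function(pathways, path) {
  desc <- attr(pathways, "description")
  if (is.null(desc)) desc <- setNames(rep("", length(pathways)), names(pathways))
  lines <- vapply(names(pathways), function(nm) {
    paste(c(nm, desc[[nm]], pathways[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad) > 0)
    stop_invalid("GMT %s: line %d has fewer than 3 fields (need >= 1 member)",
                 path, bad[1])
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, "", 1)
  dup <- vapply(sets, function(s) anyDuplicated(s) > 0, TRUE)
  if (any(dup))
    stop_invalid("GMT %s: duplicated gene ids within set '%s'",
                 path, names(sets)[dup][1])
  attr(sets, "description") <- setNames(vapply(parts, `[[`, "", 2), names(sets))
  sets
}
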