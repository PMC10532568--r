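#' Junction-evidence table dialect
#'
#' Splice-junction evidence is exchanged as a TSV with one row per
#' (junction, sample): columns `contig`, `donor0`, `acceptor0` (the removed
#' intron as a 0-based half-open interval, `donor0 < acceptor0`), `sample`,
#' `reads` (supporting split reads) and `clean_overhang` (TRUE when no
#' mismatch, insertion or deletion occurs within 6 bases of the junction
#' overhang; junctions failing this are excluded from event counting).
#'
#' @param path TSV file
#' @return data.frame in the junction dialect
#' @export
read_junctions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("contig", "donor0", "acceptor0", "sample", "reads", "clean_overhang")
  if (!all(need %in% names(df)))
    stop_fdrm("fdrm_format_error", "junction TSV %s missing columns: %s", path,
              paste(setdiff(need, names(df)), collapse = ","))
  df$clean_overhang <- as.logical(df$clean_overhang)
  if (any(df$donor0 >= df$acceptor0))
    stop_fdrm("fdrm_format_error", "junction with donor0 >= acceptor0 in %s", path)
  if (any(df$reads < 0))
    stop_fdrm("fdrm_format_error", "negative junction read count in %s", path)
  fdrm_log("read_junctions: %d rows from %s", nrow(df), path)
  df[need]
}

#' @rdname read_junctions
#' @param junctions data.frame in the junction dialect
#' @export
write_junctions <- function(junctions, path) {
  utils::write.table(junctions, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Region-coverage table dialect
#'
#' Mean read coverage over genomic regions (used as intron-retention
#' inclusion evidence): columns `contig`, `start0`, `end0`, `sample`,
#' `mean_cov`.
#'
#' @param path TSV file
#' @return data.frame in the region-coverage dialect
#' @export
read_region_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("contig", "start0", "end0", "sample", "mean_cov")
  if (!all(need %in% names(df)))
    stop_fdrm("fdrm_format_error", "region TSV %s missing columns: %s", path,
              paste(setdiff(need, names(df)), collapse = ","))
  df[need]
}

#' @rdname read_region_counts
#' @param regions data.frame in the region-coverage dialect
#' @export
write_region_counts <- function(regions, path) {
  utils::write.table(regions, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count matrix TSV (genes x samples)
#' @param path TSV with a `gene_id` first column
#' @return integer matrix with gene rownames
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "gene_id")
    stop_fdrm("fdrm_format_error", "count TSV %s must start with gene_id column", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_counts
#' @param counts matrix of counts
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a numeric matrix TSV with an id column
#' @param m matrix
#' @param path output path
#' @param id_name name for the rowname column
#' @export
write_matrix_tsv <- function(m, path, id_name = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column gene -> label map (e.g. phylostrata, terms)
#' @param path TSV with columns gene_id and a value column
#' @return for `read_strata`, a named numeric vector; for `read_term_map`,
#'   a data.frame with columns `gene_id`, `term`
#' @export
read_strata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  setNames(as.numeric(df[[2]]), df[[1]])
}

#' @rdname read_strata
#' @export
read_term_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df)[1:2] <- c("gene_id", "term")
  df[, 1:2]
}
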