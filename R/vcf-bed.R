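#' Write called editing sites as VCF 4.2
#'
#' POS is 1-based; REF/ALT are plus-strand bases. INFO carries EDTYPE (sense
#' editing type), FEAT (genic feature), EFFECT (coding consequence) and
#' STAGES (stage presence set); per-sample FORMAT fields are DP (filtered
#' depth), ED (edited reads) and EL (editing level, 3 decimals). FEAT/EFFECT
#' default to "." unless `annotation` supplies them.
#'
#' @param sites an `editing_sites` object
#' @param path output file
#' @param genome optional `genome_ref`; REF bases are validated against it
#' @param annotation optional data.frame aligned by `site_id` with columns
#'   `feature` and/or `effect`
#' @export
write_editing_vcf <- function(sites, path, genome = NULL, annotation = NULL) {
  s <- sites$sites
  if (!is.null(genome) && nrow(s)) {
    gref <- mapply(function(ct, p) genome_seq(genome, ct, p, p + 1),
                   s$contig, s$pos0)
    if (any(gref != s$ref_plus))
      stop_fdrm("fdrm_consistency_error", "site REF does not match genome")
  }
  feat <- eff <- rep(".", nrow(s))
  if (!is.null(annotation)) {
    m <- match(s$site_id, annotation$site_id)
    if ("feature" %in% names(annotation))
      feat <- ifelse(is.na(m), ".", as.character(annotation$feature[m]))
    if ("effect" %in% names(annotation))
      eff <- ifelse(is.na(m) | is.na(annotation$effect[m]), ".",
                    as.character(annotation$effect[m]))
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##source=fdrm",
           "##INFO=<ID=EDTYPE,Number=1,Type=String,Description=\"Editing type on transcript sense strand\">",
           "##INFO=<ID=FEAT,Number=1,Type=String,Description=\"Genic feature\">",
           "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Coding consequence\">",
           "##INFO=<ID=STAGES,Number=1,Type=String,Description=\"Stages where the site is present\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Quality-filtered depth\">",
           "##FORMAT=<ID=ED,Number=1,Type=Integer,Description=\"Edited reads\">",
           "##FORMAT=<ID=EL,Number=1,Type=Float,Description=\"Editing level\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sites$samples), collapse = "\t"))
  rows <- vapply(seq_len(nrow(s)), function(i) {
    fmt <- vapply(sites$samples, function(sm) {
      dp <- sites$depth[i, sm]; ed <- sites$edited[i, sm]
      el <- if (dp > 0) sprintf("%.3f", ed / dp) else "."
      sprintf("%d:%d:%s", dp, ed, el)
    }, character(1))
    info <- sprintf("EDTYPE=%s;FEAT=%s;EFFECT=%s;STAGES=%s",
                    s$ed_type[i], feat[i], eff[i],
                    gsub(",", "|", s$stages[i]))
    paste(c(s$contig[i], s$pos0[i] + 1, s$site_id[i], s$ref_plus[i],
            s$alt_plus[i], ".", "PASS", info, "DP:ED:EL", fmt),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an fdrm editing VCF back into a summary table
#'
#' Inverse of [write_editing_vcf()] for round-tripping: returns one row per
#' site with the INFO fields expanded plus per-sample DP/ED matrices.
#'
#' @param path VCF file
#' @return list with `sites` data.frame, `edited` and `depth` matrices
#' @export
read_editing_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  header <- strsplit(body[1], "\t")[[1]]
  samples <- header[-(1:9)]
  body <- body[-1]
  if (!length(body)) {
    m0 <- matrix(0L, 0, length(samples), dimnames = list(NULL, samples))
    return(list(sites = data.frame(), edited = m0, depth = m0))
  }
  fields <- do.call(rbind, strsplit(body, "\t"))
  info1 <- function(key) sub(sprintf(".*%s=([^;]*).*", key), "\\1", fields[, 8])
  sites <- data.frame(site_id = fields[, 3], contig = fields[, 1],
                      pos0 = as.numeric(fields[, 2]) - 1,
                      ref_plus = fields[, 4], alt_plus = fields[, 5],
                      ed_type = info1("EDTYPE"), feature = info1("FEAT"),
                      effect = info1("EFFECT"),
                      stages = gsub("\\|", ",", info1("STAGES")),
                      stringsAsFactors = FALSE)
  ed <- dp <- matrix(0L, nrow(fields), length(samples),
                     dimnames = list(sites$site_id, samples))
  for (j in seq_along(samples)) {
    parts <- strsplit(fields[, 9 + j], ":")
    dp[, j] <- as.integer(vapply(parts, `[`, character(1), 1))
    ed[, j] <- as.integer(vapply(parts, `[`, character(1), 2))
  }
  list(sites = sites, edited = ed, depth = dp)
}

#' Write AS events as a BED12-like table
#'
#' One row per event, 0-based half-open coordinates (BED convention,
#' ascending regardless of strand), with extra columns for gene, event type
#' and per-stage PSI.
#'
#' @param events an `as_events` object
#' @param path output file
#' @param psi optional event x stage PSI matrix (from [compute_psi()])
#' @export
write_as_events <- function(events, path, psi = NULL) {
  e <- events$events
  base <- data.frame(chrom = e$contig, chromStart = e$start0, chromEnd = e$end0,
                     name = e$event_id, score = 0, strand = e$strand,
                     thickStart = e$start0, thickEnd = e$end0, itemRgb = "0,0,0",
                     blockCount = 1, blockSizes = e$end0 - e$start0,
                     blockStarts = 0, gene = e$gene_id, as_type = e$as_type,
                     stringsAsFactors = FALSE)
  if (!is.null(psi)) {
    pm <- round(psi[e$event_id, , drop = FALSE], 4)
    colnames(pm) <- paste0("PSI_", colnames(pm))
    base <- cbind(base, pm)
  }
  names(base)[1] <- "#chrom"
  utils::write.table(base, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_as_events
#' @return `read_as_events` returns the table as a data.frame (PSI columns
#'   prefixed `PSI_`)
#' @export
read_as_events <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(df)[1] <- sub("^#", "", names(df)[1])
  df
}
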