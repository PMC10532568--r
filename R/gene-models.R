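#' Gene model container
#'
#' A `gene_model` stores one gene's structure on the genome: contig, strand,
#' exons, CDS and UTR intervals (all 0-based half-open, ascending genomic
#' order regardless of strand) plus optional phylostratum and divergence
#' stratum labels used by the phylotranscriptomic module.
#'
#' @param gene_id gene identifier
#' @param contig contig name
#' @param strand "+" or "-"
#' @param exons two-column matrix (start, end), 0-based half-open
#' @param cds,utr5,utr3 interval matrices or NULL
#' @param phylostratum integer 1..12 or NA
#' @param divergence_stratum integer or NA
#' @param complete logical; when TRUE the CDS must be a complete ORF whose
#'   total length is divisible by 3
#' @return object of class `gene_model`
#' @export
gene_model <- function(gene_id, contig, strand, exons, cds = NULL,
                       utr5 = NULL, utr3 = NULL, phylostratum = NA_integer_,
                       divergence_stratum = NA_integer_, complete = TRUE) {
  if (!strand %in% c("+", "-"))
    stop_fdrm("fdrm_format_error", "gene %s: unknown strand", gene_id)
  exons <- as_iv(exons)
  if (is.null(exons) || nrow(exons) == 0L)
    stop_fdrm("fdrm_model_error", "gene %s: no exons", gene_id)
  if (any(exons[, 1] >= exons[, 2]))
    stop_fdrm("fdrm_model_error", "gene %s: empty exon interval", gene_id)
  if (is.unsorted(exons[, 1], strictly = TRUE) ||
      any(exons[-1, 1] < exons[-nrow(exons), 2]))
    stop_fdrm("fdrm_model_error", "gene %s: exons unsorted or overlapping", gene_id)
  cds <- as_iv(cds); utr5 <- as_iv(utr5); utr3 <- as_iv(utr3)
  for (ivs in list(cds, utr5, utr3)) {
    if (!is.null(ivs) && nrow(ivs) > 0L && !iv_within(ivs, exons))
      stop_fdrm("fdrm_model_error", "gene %s: CDS/UTR outside exons", gene_id)
  }
  if (!is.null(cds) && nrow(cds) > 0L && complete &&
      sum(cds[, 2] - cds[, 1]) %% 3L != 0L)
    stop_fdrm("fdrm_model_error", "gene %s: complete CDS length not divisible by 3",
              gene_id)
  structure(list(gene_id = gene_id, contig = contig, strand = strand,
                 exons = exons, cds = cds, utr5 = utr5, utr3 = utr3,
                 phylostratum = as.integer(phylostratum),
                 divergence_stratum = as.integer(divergence_stratum)),
            class = "gene_model")
}

as_iv <- function(x) {
  if (is.null(x)) return(NULL)
  x <- matrix(as.numeric(x), ncol = 2, dimnames = list(NULL, c("start", "end")))
  x[order(x[, 1]), , drop = FALSE]
}

# every interval of a contained in the union of b
iv_within <- function(a, b) {
  all(apply(a, 1, function(r) {
    any(b[, 1] <= r[1] & r[2] <= b[, 2])
  }))
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s %s:%d-%d(%s) %d exon(s)%s\n", x$gene_id, x$contig,
              gene_span(x)[1], gene_span(x)[2], x$strand, nrow(x$exons),
              if (is.na(x$phylostratum)) "" else sprintf(" PS%d", x$phylostratum)))
  invisible(x)
}

#' Genomic span of a gene model
#' @param gm a `gene_model`
#' @return numeric (start0, end0)
#' @export
gene_span <- function(gm) c(min(gm$exons[, 1]), max(gm$exons[, 2]))

#' Annotated introns of a gene model
#' @param gm a `gene_model`
#' @return matrix (start, end) of intron intervals, 0-based half-open
#' @export
gene_introns <- function(gm) {
  n <- nrow(gm$exons)
  if (n < 2) return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  cbind(start = gm$exons[-n, 2], end = gm$exons[-1, 1])
}

#' Splice boundary cut coordinates of a set of gene models
#'
#' Each intron contributes two cut points (its start and end in half-open
#' coordinates); used for the splice-adjacent exclusion rule of the editing
#' caller.
#'
#' @param models list of `gene_model`
#' @return data.frame with columns `contig`, `cut`
#' @export
splice_boundary_cuts <- function(models) {
  out <- lapply(models, function(gm) {
    iv <- gene_introns(gm)
    if (nrow(iv) == 0) return(NULL)
    data.frame(contig = gm$contig, cut = c(iv[, 1], iv[, 2]))
  })
  res <- do.call(rbind, out)
  if (is.null(res)) data.frame(contig = character(0), cut = numeric(0)) else unique(res)
}

## ---- transcript-coordinate machinery ----

# exon blocks in transcript order with cumulative tx offsets
tx_blocks <- function(gm, ivs = gm$exons) {
  if (is.null(ivs) || nrow(ivs) == 0) return(NULL)
  if (gm$strand == "-") ivs <- ivs[rev(seq_len(nrow(ivs))), , drop = FALSE]
  w <- ivs[, 2] - ivs[, 1]
  cbind(start = ivs[, 1], end = ivs[, 2], tx0 = cumsum(c(0, w[-length(w)])), width = w)
}

# 0-based transcript-sense offset of genomic pos0 within interval set; NA if outside
genomic_to_offset <- function(gm, pos0, ivs = gm$exons) {
  bl <- tx_blocks(gm, ivs)
  if (is.null(bl)) return(NA_real_)
  hit <- which(bl[, "start"] <= pos0 & pos0 < bl[, "end"])
  if (length(hit) != 1) return(NA_real_)
  b <- bl[hit, ]
  if (gm$strand == "+") b[["tx0"]] + (pos0 - b[["start"]])
  else b[["tx0"]] + (b[["end"]] - 1 - pos0)
}

# spliced sense sequence over an interval set
spliced_seq <- function(gm, genome, ivs) {
  if (is.null(ivs) || nrow(ivs) == 0) return("")
  parts <- apply(ivs, 1, function(r) genome_seq(genome, gm$contig, r[1], r[2]))
  s <- paste(parts, collapse = "")
  if (gm$strand == "-") revcomp(s) else s
}

#' Spliced CDS sequence of a gene model (transcript sense)
#' @param gm a `gene_model`
#' @param genome a `genome_ref`
#' @return character scalar
#' @export
cds_seq <- function(gm, genome) spliced_seq(gm, genome, gm$cds)

#' Translate a CDS nucleotide sequence (standard code)
#' @param seq character scalar, length divisible by 3
#' @return character scalar amino-acid sequence (stop as `*`)
#' @export
translate_cds <- function(seq) {
  n <- nchar(seq)
  if (n %% 3 != 0)
    stop_fdrm("fdrm_model_error", "CDS length %d not divisible by 3", n)
  if (n == 0) return("")
  # codon lookup against the Biostrings standard code (table 1); positional
  # translation, so alternative initiators never read as M. Ambiguous or
  # non-ACGT codons come out as X.
  aa <- Biostrings::GENETIC_CODE[substring(toupper(seq), seq(1, n, 3),
                                           seq(3, n, 3))]
  paste(ifelse(is.na(aa), "X", aa), collapse = "")
}

## ---- GFF3 I/O ----

#' Read gene models from GFF3
#'
#' Parses gene/mRNA/exon/CDS/UTR features (1-based inclusive coordinates per
#' the GFF3 standard) into internal 0-based half-open `gene_model`s.
#' `phylostratum` and `divergence_stratum` attributes on gene features are
#' picked up when present. One isoform per gene is assumed; extra mRNAs are
#' ignored with a log entry.
#'
#' @param path GFF3 file
#' @param complete require complete CDS (length divisible by 3)
#' @return named list of `gene_model`
#' @export
read_gene_models <- function(path, complete = TRUE) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$type <- as.character(df$type)
  df$Parent <- vapply(df$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
                      character(1))
  genes <- df[df$type == "gene", , drop = FALSE]
  if (nrow(genes) == 0) stop_fdrm("fdrm_format_error", "no gene features in %s", path)
  mrna <- df[df$type == "mRNA", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (!g$strand %in% c("+", "-"))
      stop_fdrm("fdrm_format_error", "gene %s: unknown strand '%s'", g$ID, g$strand)
    tx <- mrna[!is.na(mrna$Parent) & mrna$Parent == g$ID, , drop = FALSE]
    if (nrow(tx) > 1) fdrm_log("gene %s: %d mRNAs, using first", g$ID, nrow(tx))
    parent_ids <- if (nrow(tx) >= 1) tx$ID[1] else g$ID
    kids <- df[!is.na(df$Parent) & df$Parent %in% parent_ids, , drop = FALSE]
    take <- function(ty) {
      k <- kids[kids$type %in% ty, , drop = FALSE]
      if (nrow(k) == 0) return(NULL)
      cbind(start = k$start - 1, end = k$end)   # GFF3 1-based inclusive -> 0-based half-open
    }
    ps <- suppressWarnings(as.integer(g[["phylostratum"]] %||% NA))
    dv <- suppressWarnings(as.integer(g[["divergence_stratum"]] %||% NA))
    out[[g$ID]] <- gene_model(
      gene_id = g$ID, contig = g$seqnames, strand = g$strand,
      exons = take("exon"), cds = take("CDS"),
      utr5 = take(c("five_prime_UTR", "5UTR")),
      utr3 = take(c("three_prime_UTR", "3UTR")),
      phylostratum = ps, divergence_stratum = dv, complete = complete)
  }
  fdrm_log("read_gene_models: %d genes from %s", length(out), path)
  out
}

#' Write gene models to GFF3
#' @param models named list of `gene_model`
#' @param path output file
#' @export
write_gene_models <- function(models, path) {
  lines <- c("##gff-version 3")
  fmt <- function(contig, type, s0, e0, strand, phase, attrs) {
    sprintf("%s\tfdrm\t%s\t%d\t%d\t.\t%s\t%s\t%s",
            contig, type, s0 + 1, e0, strand, phase, attrs)
  }
  for (gm in models) {
    sp <- gene_span(gm)
    gattr <- sprintf("ID=%s", gm$gene_id)
    if (!is.na(gm$phylostratum))
      gattr <- paste0(gattr, ";phylostratum=", gm$phylostratum)
    if (!is.na(gm$divergence_stratum))
      gattr <- paste0(gattr, ";divergence_stratum=", gm$divergence_stratum)
    txid <- paste0(gm$gene_id, ".t1")
    lines <- c(lines,
               fmt(gm$contig, "gene", sp[1], sp[2], gm$strand, ".", gattr),
               fmt(gm$contig, "mRNA", sp[1], sp[2], gm$strand, ".",
                   sprintf("ID=%s;Parent=%s", txid, gm$gene_id)))
    child <- function(ivs, type, phases = NULL) {
      if (is.null(ivs) || nrow(ivs) == 0) return(character(0))
      ph <- phases %||% rep(".", nrow(ivs))
      vapply(seq_len(nrow(ivs)), function(j)
        fmt(gm$contig, type, ivs[j, 1], ivs[j, 2], gm$strand, ph[j],
            sprintf("Parent=%s", txid)), character(1))
    }
    lines <- c(lines, child(gm$exons, "exon"),
               child(gm$cds, "CDS", cds_phases(gm)),
               child(gm$utr5, "five_prime_UTR"), child(gm$utr3, "three_prime_UTR"))
  }
  writeLines(lines, path)
  invisible(path)
}

# GFF3 phase per CDS interval, in genomic (ascending) order
cds_phases <- function(gm) {
  if (is.null(gm$cds) || nrow(gm$cds) == 0) return(NULL)
  w <- gm$cds[, 2] - gm$cds[, 1]
  tx_order <- if (gm$strand == "+") seq_along(w) else rev(seq_along(w))
  cum <- cumsum(c(0, w[tx_order][-length(w)]))
  ph <- (3 - cum %% 3) %% 3
  ph_genomic <- integer(length(w))
  ph_genomic[tx_order] <- ph
  as.character(ph_genomic)
}
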