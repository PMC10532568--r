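#' Locate sites relative to gene features
#'
#' Maps positions onto gene models with feature precedence CDS > UTR >
#' intron within a gene; positions hitting no gene are intergenic. When a
#' position falls into several overlapping genes, the CDS-bearing annotation
#' is primary and the others are reported in `secondary`. For CDS hits the
#' 1-based codon index and the codon position (1-3, transcript orientation)
#' are derived from the transcript-sense CDS offset.
#'
#' @param positions data.frame with columns `contig`, `pos0` (an
#'   `editing_sites` object is also accepted)
#' @param gene_models named list of `gene_model`
#' @param genome optional `genome_ref` used only for bounds checking
#' @return data.frame: contig, pos0, gene_id, feature, cds_offset,
#'   codon_index, codon_position, secondary
#' @export
locate_site <- function(positions, gene_models, genome = NULL) {
  if (inherits(positions, "editing_sites")) positions <- positions$sites
  out <- lapply(seq_len(nrow(positions)), function(i) {
    contig <- positions$contig[i]; pos0 <- positions$pos0[i]
    if (!is.null(genome)) {
      if (!contig %in% names(genome) || pos0 >= nchar(genome[[contig]]) || pos0 < 0)
        stop_fdrm("fdrm_consistency_error", "site %s:%d beyond contig", contig, pos0)
    }
    anns <- list()
    for (gm in gene_models) {
      sp <- gene_span(gm)
      if (gm$contig != contig || pos0 < sp[1] || pos0 >= sp[2]) next
      anns[[gm$gene_id]] <- annotate_in_gene(gm, pos0)
    }
    if (!length(anns)) {
      return(data.frame(contig = contig, pos0 = pos0, gene_id = NA_character_,
                        feature = "intergenic", cds_offset = NA_real_,
                        codon_index = NA_integer_, codon_position = NA_integer_,
                        secondary = NA_character_, stringsAsFactors = FALSE))
    }
    rank <- c(CDS = 1, UTR5 = 2, UTR3 = 2, intron = 3)
    o <- order(rank[vapply(anns, `[[`, character(1), "feature")],
               names(anns))
    prim <- anns[[o[1]]]
    sec <- if (length(anns) > 1) {
      paste(vapply(o[-1], function(j)
        sprintf("%s:%s", names(anns)[j], anns[[j]]$feature), character(1)),
        collapse = ";")
    } else NA_character_
    data.frame(contig = contig, pos0 = pos0, gene_id = names(anns)[o[1]],
               feature = prim$feature, cds_offset = prim$cds_offset,
               codon_index = prim$codon_index,
               codon_position = prim$codon_position,
               secondary = sec, stringsAsFactors = FALSE)
  })
  rbind_rows(out)
}

annotate_in_gene <- function(gm, pos0) {
  inside <- function(ivs) !is.null(ivs) && nrow(ivs) > 0 &&
    any(ivs[, 1] <= pos0 & pos0 < ivs[, 2])
  if (inside(gm$cds)) {
    off <- genomic_to_offset(gm, pos0, gm$cds)
    return(list(feature = "CDS", cds_offset = off,
                codon_index = as.integer(off %/% 3 + 1),
                codon_position = as.integer(off %% 3 + 1)))
  }
  feat <- if (inside(gm$utr5)) "UTR5" else if (inside(gm$utr3)) "UTR3"
  else if (inside(gm$exons)) {
    # exonic but unannotated UTR: side relative to CDS in transcript coords
    if (is.null(gm$cds) || nrow(gm$cds) == 0) "UTR5"
    else {
      txp <- genomic_to_offset(gm, pos0)
      tx_cds <- genomic_to_offset(gm, if (gm$strand == "+") gm$cds[1, 1]
                                  else gm$cds[nrow(gm$cds), 2] - 1)
      if (!is.na(txp) && txp < tx_cds) "UTR5" else "UTR3"
    }
  } else "intron"
  list(feature = feat, cds_offset = NA_real_, codon_index = NA_integer_,
       codon_position = NA_integer_)
}

#' Coding effect of a single-base substitution on a CDS
#'
#' Substitutes the alternative base at the given transcript-sense CDS offset
#' and classifies the consequence under the standard genetic code:
#' `synonymous`, `missense`, `stop_gained` or `stop_lost`. For `stop_gained`,
#' `residues_lost` counts the residues from the affected codon through the
#' original final residue (all of which are lost to the new stop).
#'
#' @param cds transcript-sense CDS nucleotide sequence (complete ORF; a
#'   terminal stop codon is allowed and excluded from the protein length)
#' @param cds_offset0 0-based offset of the edited base within the CDS
#' @param alt_sense alternative base on the transcript sense strand
#' @return list: effect, aa_ref, aa_alt, codon_index, codon_position,
#'   residues_lost (NA unless stop_gained)
#' @export
coding_effect_from_cds <- function(cds, cds_offset0, alt_sense) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3 != 0 || cds_offset0 < 0 || cds_offset0 >= nchar(cds))
    stop_fdrm("fdrm_model_error", "edit at incomplete codon or outside CDS")
  prot <- translate_cds(cds)
  L <- nchar(prot) - (substr(prot, nchar(prot), nchar(prot)) == "*")
  idx <- as.integer(cds_offset0 %/% 3 + 1)
  cpos <- as.integer(cds_offset0 %% 3 + 1)
  codon <- substr(cds, (idx - 1) * 3 + 1, idx * 3)
  ref_base <- substr(codon, cpos, cpos)
  if (ref_base == alt_sense)
    stop_fdrm("fdrm_data_error", "alt base equals reference")
  new_codon <- codon
  substr(new_codon, cpos, cpos) <- alt_sense
  aa_ref <- translate_cds(codon)
  aa_alt <- translate_cds(new_codon)
  effect <- if (aa_ref == aa_alt) "synonymous"
  else if (aa_alt == "*") "stop_gained"
  else if (aa_ref == "*") "stop_lost"
  else "missense"
  list(effect = effect, aa_ref = aa_ref, aa_alt = aa_alt,
       codon_index = idx, codon_position = cpos,
       residues_lost = if (effect == "stop_gained") L - idx + 1L else NA_integer_)
}

#' Coding effect of an editing site within a gene model
#'
#' @param gene_model a `gene_model` with a complete CDS
#' @param genome a `genome_ref`
#' @param pos0 0-based genomic position (must fall in the CDS)
#' @param alt_plus alternative base on the genomic plus strand
#' @return as [coding_effect_from_cds()]
#' @export
predict_coding_effect <- function(gene_model, genome, pos0, alt_plus) {
  off <- genomic_to_offset(gene_model, pos0, gene_model$cds)
  if (is.na(off))
    stop_fdrm("fdrm_model_error", "position %d not in CDS of %s", pos0,
              gene_model$gene_id)
  alt_sense <- if (gene_model$strand == "-") comp_base(alt_plus) else alt_plus
  coding_effect_from_cds(cds_seq(gene_model, genome), off, alt_sense)
}

#' Isoform-level consequence of an alternative-splicing event
#'
#' Builds the coding sequences of the two isoforms implied by the event and
#' compares their translations. Intron retention inserts the intron into the
#' CDS; cassette-exon and alternative splice-site events remove the
#' alternative segment; mutually exclusive exons swap the two exons'
#' CDS contributions. Consequences: `in_frame_insertion` /
#' `in_frame_deletion` (length change divisible by 3, no new stop; signed
#' `aa_delta` = inclusion minus exclusion length in residues), `frameshift`,
#' `premature_stop`, `utr_only` (CDS untouched) or `noncoding` (gene without
#' a CDS).
#'
#' @param event one-row data.frame (or list) with `as_type`, `start0`,
#'   `end0` as produced by [classify_as_events()]
#' @param gene_model the gene's `gene_model`
#' @param genome a `genome_ref`
#' @return list: consequence, aa_delta (NA unless in-frame)
#' @export
predict_isoform_effect <- function(event, gene_model, genome) {
  gm <- gene_model
  if (is.null(gm$cds) || nrow(gm$cds) == 0)
    return(list(consequence = "noncoding", aa_delta = NA_integer_))
  seg <- c(event$start0, event$end0)
  cds_len <- function(s, e) {
    ov <- pmin(gm$cds[, 2], e) - pmax(gm$cds[, 1], s)
    sum(pmax(ov, 0))
  }
  cds <- cds_seq(gm, genome)
  finish <- function(modified, delta_nt, sign) {
    if (delta_nt %% 3 != 0)
      return(list(consequence = "frameshift", aa_delta = NA_integer_))
    aa <- translate_cds(modified)
    internal_stop <- {
      star <- regexpr("*", aa, fixed = TRUE)
      star > 0 && star < nchar(aa)
    }
    if (internal_stop)
      return(list(consequence = "premature_stop", aa_delta = NA_integer_))
    list(consequence = if (sign >= 0) "in_frame_insertion" else "in_frame_deletion",
         aa_delta = as.integer(sign * delta_nt / 3))
  }

  if (event$as_type == "IR") {
    # intron retained inside the CDS region?
    ups <- if (gm$strand == "+") sum(pmax(pmin(gm$cds[, 2], seg[1]) - gm$cds[, 1], 0))
    else sum(pmax(gm$cds[, 2] - pmax(gm$cds[, 1], seg[2]), 0))
    within_cds <- seg[1] >= min(gm$cds[, 1]) && seg[2] <= max(gm$cds[, 2])
    if (!within_cds) return(list(consequence = "utr_only", aa_delta = NA_integer_))
    intron <- genome_seq(genome, gm$contig, seg[1], seg[2])
    if (gm$strand == "-") intron <- revcomp(intron)
    modified <- paste0(substr(cds, 1, ups), intron,
                       substr(cds, ups + 1, nchar(cds)))
    return(finish(modified, nchar(intron), +1))
  }
  if (event$as_type == "MXE") {
    ex <- gm$exons
    a <- which(ex[, 1] == event$start0)
    lenA <- if (length(a)) cds_len(ex[a, 1], ex[a, 2]) else 0
    b <- which(ex[, 2] == event$end0)
    lenB <- if (length(b)) cds_len(ex[b, 1], ex[b, 2]) else 0
    if (lenA == 0 && lenB == 0)
      return(list(consequence = "utr_only", aa_delta = NA_integer_))
    d <- lenA - lenB
    if (d %% 3 != 0) return(list(consequence = "frameshift", aa_delta = NA_integer_))
    iso <- function(drop_s, drop_e) delete_cds_segment(gm, genome, drop_s, drop_e)
    aaA <- translate_cds(iso(ex[b, 1], ex[b, 2]))   # uses exon A, drops B
    aaB <- translate_cds(iso(ex[a, 1], ex[a, 2]))
    internal <- function(aa) {
      star <- regexpr("*", aa, fixed = TRUE); star > 0 && star < nchar(aa)
    }
    if (internal(aaA) || internal(aaB))
      return(list(consequence = "premature_stop", aa_delta = NA_integer_))
    return(list(consequence = if (d >= 0) "in_frame_insertion" else "in_frame_deletion",
                aa_delta = as.integer(d / 3)))
  }
  # deletion semantics: exclusion isoform lacks the segment's CDS overlap
  del <- cds_len(seg[1], seg[2])
  if (del == 0) return(list(consequence = "utr_only", aa_delta = NA_integer_))
  modified <- delete_cds_segment(gm, genome, seg[1], seg[2])
  finish(modified, del, -1)
}

# CDS sequence with the genomic segment [s,e) removed
delete_cds_segment <- function(gm, genome, s, e) {
  keep <- list()
  for (j in seq_len(nrow(gm$cds))) {
    ivs <- gm$cds[j, 1]; ive <- gm$cds[j, 2]
    if (e <= ivs || s >= ive) { keep[[length(keep) + 1]] <- c(ivs, ive); next }
    if (s > ivs) keep[[length(keep) + 1]] <- c(ivs, min(s, ive))
    if (e < ive) keep[[length(keep) + 1]] <- c(max(e, ivs), ive)
  }
  ivs <- do.call(rbind, keep)
  spliced_seq(gm, genome, as_iv(ivs))
}

#' Hypergeometric term enrichment
#'
#' One-sided upper-tail hypergeometric test per term with BH adjustment:
#' given `k` term genes among the `n` genes of interest, `K` term genes in
#' the background of `N`, p = P(X >= k). Terms pass with p below `p_cutoff`
#' and q below `q_cutoff` (defaults 0.2/0.2).
#'
#' @param gene_set character vector of genes of interest (subset of
#'   `background`)
#' @param term_map data.frame with columns `gene_id`, `term`
#' @param background character vector of background gene ids
#' @param p_cutoff,q_cutoff reporting cutoffs
#' @return data.frame sorted by p-value: term, hits_k, set_size_n,
#'   term_size_K, background_N, pvalue, qvalue, significant
#' @export
enrich_terms <- function(gene_set, term_map, background,
                         p_cutoff = 0.2, q_cutoff = 0.2) {
  background <- unique(background)
  if (!length(background)) stop_fdrm("fdrm_data_error", "empty background")
  gene_set <- unique(gene_set)
  if (!all(gene_set %in% background))
    stop_fdrm("fdrm_data_error", "gene_set not a subset of background")
  term_map <- term_map[term_map$gene_id %in% background, , drop = FALSE]
  N <- length(background); n <- length(gene_set)
  terms <- unique(term_map$term)
  res <- lapply(terms, function(tm) {
    tg <- unique(term_map$gene_id[term_map$term == tm])
    K <- length(tg); k <- length(intersect(tg, gene_set))
    data.frame(term = tm, hits_k = k, set_size_n = n, term_size_K = K,
               background_N = N,
               pvalue = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  res <- rbind_rows(res)
  res$qvalue <- bh_adjust(res$pvalue)
  res$significant <- res$pvalue < p_cutoff & res$qvalue < q_cutoff
  res[order(res$pvalue, res$term), , drop = FALSE]
}
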