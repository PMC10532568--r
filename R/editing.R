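#' Classify an editing type from plus-strand bases and gene strand
#'
#' Editing types are named on the transcript sense strand (plus strand for
#' intergenic sites): bases are complemented for minus-strand genes, T is
#' written U, and A-to-G is reported as A-to-I(G) (inosine reads as G).
#' Twelve types are possible.
#'
#' @param ref_plus,alt_plus reference/alternative base on the genomic plus
#'   strand (vectorized)
#' @param strand "+" or "-" per site
#' @return character vector of type labels
#' @export
classify_editing_type <- function(ref_plus, alt_plus, strand) {
  stopifnot(length(ref_plus) == length(alt_plus))
  if (any(ref_plus == alt_plus))
    stop_fdrm("fdrm_data_error", "ref and alt base identical")
  ref <- ifelse(strand == "-", comp_base(ref_plus), ref_plus)
  alt <- ifelse(strand == "-", comp_base(alt_plus), alt_plus)
  show <- function(b) ifelse(b == "T", "U", b)
  ifelse(ref == "A" & alt == "G", "A-to-I(G)",
         sprintf("%s-to-%s", show(ref), show(alt)))
}

#' Call RNA-editing sites from paired DNA/RNA pileups
#'
#' Implements the five-rule caller: (i) pileups are expected to be built from
#' quality-filtered reads (base and mapping quality >= 25, multi-hit and
#' duplicate reads excluded — see [read_alignments_to_pileup()]); (ii) a
#' candidate substitution in a sample needs >= `min_alt_reads` supporting
#' reads, frequency >= `min_freq` and depth >= `min_depth` (defaults 3, 0.03,
#' 10); (iii) positions are discarded unless the DNA pileup has depth >=
#' `dna_min_depth` with no non-reference reads (a fractional tolerance is
#' configurable via `dna_alt_tol`); (iv) positions within `splice_dist`
#' (default 4) bases of any annotated intron boundary or observed junction
#' are discarded; (v) a site must be present — same position and substitution
#' — in >= `min_replicates` (default 2) replicates of at least one stage.
#'
#' With `merge_replicates = TRUE`, rule (ii) is applied to stage-pooled
#' tallies instead, and presence additionally requires >= `min_replicates`
#' replicates each contributing at least one edited read.
#'
#' @param dna_pileup DNA pileup data.frame (all samples pooled)
#' @param rna_pileup RNA pileup data.frame covering all design samples
#' @param gene_models named list of `gene_model` (strand/splice annotation)
#' @param design a `stage_design`
#' @param genome optional `genome_ref`; when given, pileup `ref` bases are
#'   checked against it (mismatch is a consistency error)
#' @param observed_junctions optional junction data.frame whose boundaries
#'   are added to the splice-exclusion set
#' @param min_alt_reads,min_freq,min_depth rule (ii) thresholds
#' @param dna_min_depth,dna_alt_tol rule (iii) thresholds
#' @param splice_dist rule (iv) distance in bases
#' @param min_replicates rule (v) replicate requirement
#' @param merge_replicates apply rule (ii) on stage-pooled tallies
#' @return an `editing_sites` object: `$sites` (one row per called site with
#'   sense ref/alt, type, feature strand and stage set), `$presence`
#'   (site x stage), `$candidate` (site x sample), `$edited`/`$depth`
#'   (site x sample support)
#' @export
call_editing_sites <- function(dna_pileup, rna_pileup, gene_models, design,
                               genome = NULL, observed_junctions = NULL,
                               min_alt_reads = 3, min_freq = 0.03,
                               min_depth = 10, dna_min_depth = 10,
                               dna_alt_tol = 0, splice_dist = 4,
                               min_replicates = 2, merge_replicates = FALSE) {
  bases <- c("A", "C", "G", "T")
  if (!is.null(genome)) {
    for (df in list(dna_pileup, rna_pileup)) {
      gref <- mapply(function(ct, p) genome_seq(genome, ct, p, p + 1),
                     df$contig, df$pos0)
      if (any(gref != df$ref))
        stop_fdrm("fdrm_consistency_error",
                  "pileup ref base disagrees with genome at %s:%d",
                  df$contig[gref != df$ref][1], df$pos0[gref != df$ref][1])
    }
  }

  # DNA summary per position (all DNA samples pooled)
  dkey <- paste0(dna_pileup$contig, ":", dna_pileup$pos0)
  dna_tal <- rowsum(as.matrix(dna_pileup[, bases]), dkey)
  dna_ref <- tapply(dna_pileup$ref, dkey, function(x) x[1])
  dna_depth <- rowSums(dna_tal)
  dref <- as.character(dna_ref[rownames(dna_tal)])
  dna_nonref <- ifelse(dref %in% bases,
                       dna_depth - dna_tal[cbind(rownames(dna_tal),
                                                 ifelse(dref %in% bases, dref, "A"))],
                       dna_depth)

  # splice-exclusion cuts
  cuts <- splice_boundary_cuts(gene_models)
  if (!is.null(observed_junctions) && nrow(observed_junctions)) {
    cuts <- unique(rbind(cuts,
                         data.frame(contig = observed_junctions$contig,
                                    cut = observed_junctions$donor0),
                         data.frame(contig = observed_junctions$contig,
                                    cut = observed_junctions$acceptor0)))
  }
  near_splice <- function(contig, pos0) {
    cc <- cuts$cut[cuts$contig == contig]
    length(cc) && any(pos0 >= cc - splice_dist & pos0 <= cc + splice_dist - 1)
  }

  samples <- design$samples
  rkey <- paste0(rna_pileup$contig, ":", rna_pileup$pos0)
  positions <- unique(rkey)
  out_rows <- list(); pres_l <- list(); cand_l <- list()
  ed_l <- list(); dp_l <- list()
  n_cand <- 0L

  for (pk in positions) {
    rows <- rna_pileup[rkey == pk, , drop = FALSE]
    contig <- rows$contig[1]; pos0 <- rows$pos0[1]; refb <- rows$ref[1]
    if (!refb %in% bases) next
    tal <- matrix(0L, nrow = length(samples), ncol = 4,
                  dimnames = list(samples, bases))
    hit <- rows$sample %in% samples
    tal[rows$sample[hit], ] <- as.matrix(rows[hit, bases])
    depth <- rowSums(tal)

    for (altb in setdiff(bases, refb)) {
      ed <- tal[, altb]
      if (!merge_replicates) {
        cand <- ed >= min_alt_reads & depth >= min_depth &
          ifelse(depth > 0, ed / depth, 0) >= min_freq
        pres <- vapply(design$stages, function(s)
          sum(cand[design$replicates[[s]]]) >= min_replicates, logical(1))
      } else {
        pres <- vapply(design$stages, function(s) {
          reps <- design$replicates[[s]]
          e <- sum(ed[reps]); d <- sum(depth[reps])
          e >= min_alt_reads && d >= min_depth && (d > 0 && e / d >= min_freq) &&
            sum(ed[reps] > 0) >= min_replicates
        }, logical(1))
        cand <- ed > 0
      }
      if (!any(pres)) next
      n_cand <- n_cand + 1L
      # rule (iii): DNA support
      drow <- match(pk, rownames(dna_tal))
      if (is.na(drow) || dna_depth[drow] < dna_min_depth ||
          dna_nonref[drow] > dna_alt_tol * dna_depth[drow]) {
        fdrm_log("editing: %s rejected by DNA rule", pk)
        next
      }
      # rule (iv): splice proximity
      if (near_splice(contig, pos0)) {
        fdrm_log("editing: %s rejected near splice site", pk)
        next
      }
      genes <- Filter(function(gm) {
        gm$contig == contig && gene_span(gm)[1] <= pos0 && pos0 < gene_span(gm)[2]
      }, gene_models)
      strands <- unique(vapply(genes, `[[`, character(1), "strand"))
      strand <- if (length(strands) >= 1) strands[1] else "+"
      ambiguous <- length(strands) > 1
      ref_sense <- if (strand == "-") comp_base(refb) else refb
      alt_sense <- if (strand == "-") comp_base(altb) else altb
      id <- sprintf("%s:%d:%s>%s", contig, pos0, refb, altb)
      out_rows[[id]] <- data.frame(
        site_id = id, contig = contig, pos0 = pos0, strand = strand,
        gene_id = if (length(genes)) genes[[1]]$gene_id else NA_character_,
        ref_plus = refb, alt_plus = altb, ref_sense = ref_sense,
        alt_sense = alt_sense,
        ed_type = classify_editing_type(refb, altb, strand),
        ed_type_alt = if (ambiguous)
          classify_editing_type(refb, altb, strands[2]) else NA_character_,
        ambiguous_strand = ambiguous,
        stages = paste(design$stages[pres], collapse = ","),
        n_stages = sum(pres), stringsAsFactors = FALSE)
      pres_l[[id]] <- pres
      cand_l[[id]] <- cand
      ed_l[[id]] <- ed
      dp_l[[id]] <- depth
    }
  }
  fdrm_log("call_editing_sites: %d positions screened, %d candidate substitutions, %d sites called",
           length(positions), n_cand, length(out_rows))
  sites <- rbind_rows(unname(out_rows))
  if (is.null(sites)) {
    sites <- data.frame(site_id = character(0), contig = character(0),
                        pos0 = numeric(0), strand = character(0),
                        gene_id = character(0), ref_plus = character(0),
                        alt_plus = character(0), ref_sense = character(0),
                        alt_sense = character(0), ed_type = character(0),
                        ed_type_alt = character(0), ambiguous_strand = logical(0),
                        stages = character(0), n_stages = integer(0))
    m0 <- function(nc, nm) matrix(0, 0, nc, dimnames = list(NULL, nm))
    return(structure(list(sites = sites,
                          presence = m0(length(design$stages), design$stages),
                          candidate = m0(length(samples), samples),
                          edited = m0(length(samples), samples),
                          depth = m0(length(samples), samples),
                          samples = samples, design = design),
                     class = "editing_sites"))
  }
  o <- order(sites$contig, sites$pos0)
  sites <- sites[o, , drop = FALSE]
  tomat <- function(l, nm) {
    m <- do.call(rbind, unname(l))[o, , drop = FALSE]
    dimnames(m) <- list(sites$site_id, nm)
    m
  }
  structure(list(sites = sites,
                 presence = tomat(pres_l, design$stages),
                 candidate = tomat(cand_l, samples),
                 edited = tomat(ed_l, samples),
                 depth = tomat(dp_l, samples),
                 samples = samples, design = design),
            class = "editing_sites")
}

#' @export
print.editing_sites <- function(x, ...) {
  cat(sprintf("editing_sites: %d sites; top types: %s\n", nrow(x$sites),
              paste(utils::head(names(sort(table(x$sites$ed_type),
                                           decreasing = TRUE)), 3),
                    collapse = ", ")))
  invisible(x)
}

#' Per-sample editing level
#'
#' Level = edited reads / depth; undefined (NA) at zero depth, never 0.
#'
#' @param sites an `editing_sites` object
#' @param sample optional sample id; when NULL a site x sample matrix is
#'   returned
#' @return numeric vector or matrix of levels
#' @export
editing_level <- function(sites, sample = NULL) {
  lv <- ifelse(sites$depth > 0, sites$edited / sites$depth, NA_real_)
  if (is.null(sample)) lv else lv[, sample]
}

#' Per-stage editing level (mean over replicates where present)
#' @param sites an `editing_sites` object
#' @return site x stage matrix (NA where the site is absent from the stage)
#' @export
stage_editing_level <- function(sites) {
  lv <- editing_level(sites)
  des <- sites$design
  out <- matrix(NA_real_, nrow(sites$sites), length(des$stages),
                dimnames = list(sites$sites$site_id, des$stages))
  for (s in des$stages) {
    reps <- des$replicates[[s]]
    use <- sites$candidate[, reps, drop = FALSE]
    v <- lv[, reps, drop = FALSE]
    v[!use] <- NA
    out[, s] <- ifelse(sites$presence[, s], rowMeans(v, na.rm = TRUE), NA)
  }
  out
}

#' Editing intensity per stage
#'
#' Events per million mapped reads: each replicate's intensity is its number
#' of candidate-carrying called sites divided by (mapped reads / 1e6); the
#' stage value is the mean over its replicates.
#'
#' @param sites an `editing_sites` object
#' @param mapped_totals named vector of mapped read totals per sample
#' @return named numeric vector stage -> intensity
#' @export
editing_intensity <- function(sites, mapped_totals) {
  des <- sites$design
  if (any(mapped_totals[des$samples] <= 0) || anyNA(mapped_totals[des$samples]))
    stop_fdrm("fdrm_data_error", "zero or missing mapped read total")
  per_rep <- colSums(sites$candidate[, des$samples, drop = FALSE]) /
    (mapped_totals[des$samples] / 1e6)
  vapply(des$stages, function(s) mean(per_rep[des$replicates[[s]]]), numeric(1))
}

#' Stage specificity of editing sites
#'
#' @param sites an `editing_sites` object
#' @return list with `presence` (site x stage logical matrix), `specific`
#'   (site ids present in exactly one stage), `per_stage_specific` (named
#'   counts) and `sharing` (counts per observed stage-set, UpSet-style)
#' @export
stage_specificity <- function(sites) {
  pres <- sites$presence > 0
  nst <- rowSums(pres)
  specific <- rownames(pres)[nst == 1]
  per_stage <- vapply(colnames(pres), function(s)
    sum(pres[, s] & nst == 1), integer(1))
  sets <- apply(pres, 1, function(r) paste(colnames(pres)[r], collapse = "+"))
  list(presence = pres, specific = specific,
       per_stage_specific = per_stage, sharing = table(sets))
}
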