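#' Transcriptome age index (TAI)
#'
#' Expression-weighted mean phylostratum per stage:
#' \eqn{TAI_k = \sum_i ps_i e_{i,k} / \sum_i e_{i,k}} over expressed genes
#' with a stratum label. Expression is expected on a linear scale (the
#' pipeline default is TMM-normalized CPM averaged over replicates). The
#' index is a convex combination, so it is bounded by the youngest and
#' oldest stratum present and invariant to uniform rescaling of a stage.
#'
#' @param expression gene x stage non-negative matrix
#' @param strata named numeric vector gene -> stratum (phylostratum 1..12
#'   for TAI; divergence stratum for TDI)
#' @return named numeric vector stage -> index
#' @export
compute_tai <- function(expression, strata) {
  genes <- intersect(rownames(expression), names(strata)[!is.na(strata)])
  if (!length(genes)) stop_fdrm("fdrm_data_error", "no genes with stratum labels")
  e <- expression[genes, , drop = FALSE]
  ps <- strata[genes]
  tot <- colSums(e)
  if (any(tot == 0)) stop_fdrm("fdrm_data_error", "stage with all-zero expression")
  colSums(e * ps) / tot
}

#' Transcriptome divergence index (TDI)
#'
#' Identical contract to [compute_tai()] with divergence strata.
#'
#' @inheritParams compute_tai
#' @export
compute_tdi <- function(expression, strata) compute_tai(expression, strata)

#' Relative value normalization of a stage series
#'
#' \eqn{RV_k = (v_k - min)/(max - min)}; a constant series maps to all zeros
#' by convention. Invariant under positive affine transforms; negating the
#' series flips it (RV(-v) = 1 - RV(v)) for non-constant input.
#'
#' @param series named numeric vector (e.g. TAI per stage)
#' @return vector of the same names in [0, 1]
#' @export
relative_value <- function(series) {
  rng <- range(series)
  if (diff(rng) == 0) return(setNames(rep(0, length(series)), names(series)))
  (series - rng[1]) / diff(rng)
}

#' Modification enrichment by phylostratum
#'
#' For each phylostratum and each class of modified genes (e.g. AS-affected,
#' RE-affected, or finer splits such as non-synonymous CDS edits vs
#' regulatory edits), computes the proportion of modified genes falling in
#' the stratum relative to the genome background:
#' \eqn{(m_{ps}/m) / (g_{ps}/g)}. Ratio 1 means no bias; empty strata give
#' NA.
#'
#' @param gene_sets named list of character vectors of modified gene ids
#' @param gene_models named list of `gene_model` carrying `phylostratum`
#' @return data.frame: phylostratum, class, n_modified, n_genome, ratio
#' @export
modification_by_phylostratum <- function(gene_sets, gene_models) {
  ps <- vapply(gene_models, `[[`, integer(1), "phylostratum")
  names(ps) <- vapply(gene_models, `[[`, character(1), "gene_id")
  ps <- ps[!is.na(ps)]
  strata <- sort(unique(ps))
  g_total <- length(ps)
  out <- list()
  for (cls in names(gene_sets)) {
    set <- intersect(gene_sets[[cls]], names(ps))
    m_total <- length(set)
    for (s in strata) {
      n_g <- sum(ps == s)
      n_m <- sum(ps[set] == s)
      ratio <- if (n_g == 0 || m_total == 0) NA_real_
      else (n_m / m_total) / (n_g / g_total)
      out[[length(out) + 1]] <- data.frame(
        phylostratum = s, class = cls, n_modified = n_m, n_genome = n_g,
        ratio = ratio, stringsAsFactors = FALSE)
    }
  }
  rbind_rows(out)
}

#' Stage-mean linear expression for phylotranscriptomics
#'
#' TMM-normalized CPM averaged over the replicates of each stage — the
#' default expression input to [compute_tai()] / [compute_tdi()].
#'
#' @param counts gene x sample count matrix
#' @param design a `stage_design`
#' @param tmm_factors optional precomputed factors
#' @return gene x stage matrix
#' @export
stage_mean_expression <- function(counts, design, tmm_factors = NULL) {
  if (is.null(tmm_factors)) tmm_factors <- tmm_normalize(counts)
  cpmm <- cpm_matrix(counts, tmm_factors)
  vapply(design$stages, function(s) {
    reps <- intersect(design$replicates[[s]], colnames(cpmm))
    rowMeans(cpmm[, reps, drop = FALSE])
  }, numeric(nrow(cpmm)))
}
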