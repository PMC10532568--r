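#' Benjamini-Hochberg adjusted p-values
#'
#' In-package implementation (step-up, with the usual cumulative-minimum
#' monotonicity enforcement) so that multiple-testing behaviour is part of
#' the tested surface rather than delegated.
#'
#' @param p numeric vector of p-values (NA allowed, passed through)
#' @return adjusted p-values, same length/order as `p`
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0) return(out)
  o <- order(p[ok], decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (m:1) * p[ok][o]))[ro]
  out[ok] <- adj
  out
}

#' Counts per million
#'
#' @param counts gene x sample count matrix
#' @param tmm_factors optional named TMM factors; when supplied, library
#'   sizes are replaced by effective sizes (library size x factor)
#' @return CPM matrix
#' @export
cpm_matrix <- function(counts, tmm_factors = NULL) {
  lib <- colSums(counts)
  if (any(lib == 0)) stop_fdrm("fdrm_data_error", "sample with zero total count")
  if (!is.null(tmm_factors)) lib <- lib * tmm_factors[colnames(counts)]
  t(t(counts) / lib) * 1e6
}

#' Trimmed mean of M-values normalization factors
#'
#' Computes between-sample scaling factors by the trimmed-mean-of-M-values
#' procedure: for each sample against the reference, per-gene log-ratios (M)
#' and average log-abundances (A) are computed on library-size-scaled counts;
#' genes in the top/bottom 30% of M or 5% of A are trimmed; the factor is 2
#' to the precision-weighted mean of the surviving M values. The reference is
#' the sample whose upper-quartile count fraction is closest to the mean
#' upper quartile, and its factor is exactly 1 (no rescaling of the factor
#' vector is applied).
#'
#' @param counts gene x sample count matrix (>= 2 samples)
#' @param logratio_trim,sum_trim trim fractions for M and A (defaults 0.30
#'   and 0.05)
#' @return named vector of positive factors, reference = 1
#' @export
tmm_normalize <- function(counts, logratio_trim = 0.30, sum_trim = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop_fdrm("fdrm_data_error", "TMM needs >= 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0)) stop_fdrm("fdrm_data_error", "sample with zero total count")
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  f75 <- apply(counts, 2, function(x) quantile(x / sum(x), 0.75))
  ref <- which.min(abs(f75 - mean(f75)))
  factors <- vapply(seq_len(ncol(counts)), function(j) {
    tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref],
             logratio_trim, sum_trim)
  }, numeric(1))
  setNames(factors, colnames(counts))
}

# one sample vs reference; weighted trimmed mean of M on doubly-kept genes
tmm_pair <- function(obs, ref, n_obs, n_ref, logratio_trim, sum_trim) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (!length(obs)) return(1)
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(m) & is.finite(a)
  m <- m[fin]; a <- a[fin]; w <- w[fin]
  n <- length(m)
  if (n == 0) return(1)
  if (max(abs(m)) < 1e-6) return(1)
  lo_m <- floor(n * logratio_trim) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * sum_trim) + 1; hi_a <- n + 1 - lo_a
  rm_ <- rank(m, ties.method = "first"); ra <- rank(a, ties.method = "first")
  keep2 <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  if (!any(keep2)) return(1)
  # precision weighting: w holds the asymptotic variance of each M value
  f <- 2^(sum(m[keep2] / w[keep2]) / sum(1 / w[keep2]))
  if (!is.finite(f) || f <= 0) 1 else f
}

#' Expressed-gene filter
#'
#' A gene counts as expressed when its CPM exceeds `threshold` in at least
#' `min_reps` replicates of at least one stage (default: CPM > 1 in >= 2 of 3
#' replicates). By default CPM is computed on raw library sizes; pass
#' TMM-scaled CPM to change that.
#'
#' @param cpm gene x sample CPM matrix
#' @param design a `stage_design`
#' @param threshold CPM threshold (strictly greater than)
#' @param min_reps minimum qualifying replicates within a stage
#' @return list with `expressed` (gene ids) and `per_stage` (named list of
#'   per-stage expressed gene sets)
#' @export
filter_expressed <- function(cpm, design, threshold = 1, min_reps = 2) {
  per_stage <- lapply(design$stages, function(s) {
    reps <- intersect(design$replicates[[s]], colnames(cpm))
    hits <- rowSums(cpm[, reps, drop = FALSE] > threshold)
    rownames(cpm)[hits >= min_reps]
  })
  names(per_stage) <- design$stages
  list(expressed = sort(unique(unlist(per_stage))), per_stage = per_stage)
}

#' log2 TMM-normalized expression
#'
#' Convenience basis for relative expression: `log2(CPM_TMM + 1)` (the
#' pseudo-count avoids minus infinity for zero counts).
#'
#' @param counts count matrix
#' @param tmm_factors factors from [tmm_normalize()] (computed when NULL)
#' @return log2 matrix
#' @export
log2_tmm <- function(counts, tmm_factors = NULL) {
  if (is.null(tmm_factors)) tmm_factors <- tmm_normalize(counts)
  log2(cpm_matrix(counts, tmm_factors) + 1)
}

#' Relative expression (per-gene min-max scaling)
#'
#' \eqn{RE_{i,k} = (x_{i,k} - min_i) / (max_i - min_i)} per gene; a constant
#' gene maps to all zeros by convention. The transform is invariant under
#' per-gene affine rescaling of its input.
#'
#' @param x gene x sample matrix (typically [log2_tmm()] output)
#' @return matrix of the same shape with rows in [0, 1]
#' @export
relative_expression <- function(x) {
  mins <- apply(x, 1, min)
  maxs <- apply(x, 1, max)
  rng <- maxs - mins
  out <- (x - mins) / ifelse(rng == 0, 1, rng)
  out[rng == 0, ] <- 0
  out
}

#' Differential expression between two stages
#'
#' Negative-binomial exact test conditional on per-group sums, with a single
#' common dispersion estimated by method of moments on TMM-normalized
#' pseudo-counts (counts scaled to a common effective library size). Genes
#' with zero counts in both groups are excluded from testing. P-values are
#' Benjamini-Hochberg adjusted; a gene is flagged DEG iff |log2FC| > 2 and
#' adjusted p < 0.05.
#'
#' @param counts gene x sample count matrix
#' @param design a `stage_design`
#' @param stageA,stageB stage labels (log2FC is stageB relative to stageA)
#' @param tmm_factors optional precomputed TMM factors for the used samples
#' @param lfc_min,padj_max DEG thresholds (defaults 2 and 0.05)
#' @return data.frame: gene, log2fc, pvalue, adj_pvalue, is_deg
#' @export
differential_expression <- function(counts, design, stageA, stageB,
                                    tmm_factors = NULL, lfc_min = 2,
                                    padj_max = 0.05) {
  if (!all(c(stageA, stageB) %in% design$stages))
    stop_fdrm("fdrm_design_error", "stage not in design")
  sa <- intersect(design$replicates[[stageA]], colnames(counts))
  sb <- intersect(design$replicates[[stageB]], colnames(counts))
  if (length(sa) < 2 || length(sb) < 2)
    stop_fdrm("fdrm_design_error", "need >= 2 replicates per stage")
  y <- counts[, c(sa, sb), drop = FALSE]
  if (is.null(tmm_factors)) tmm_factors <- tmm_normalize(y)
  eff <- colSums(y) * tmm_factors[colnames(y)]
  scale_to <- exp(mean(log(eff)))
  pseudo <- t(t(y) * (scale_to / eff))
  ga <- seq_along(sa); gb <- length(sa) + seq_along(sb)
  tested <- rowSums(y) > 0
  phi <- common_dispersion_mom(pseudo[tested, , drop = FALSE], ga, gb)
  ids <- rownames(y)
  res <- data.frame(gene = ids, log2fc = NA_real_, pvalue = NA_real_,
                    adj_pvalue = NA_real_, is_deg = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  mA <- rowMeans(pseudo[, ga, drop = FALSE])
  mB <- rowMeans(pseudo[, gb, drop = FALSE])
  res$log2fc <- log2((mB + 0.5) / (mA + 0.5))
  for (i in which(tested)) {
    res$pvalue[i] <- nb_exact_p(round(sum(pseudo[i, ga])),
                                round(sum(pseudo[i, gb])),
                                length(ga), length(gb), phi)
  }
  res$adj_pvalue[tested] <- bh_adjust(res$pvalue[tested])
  res$is_deg <- tested & abs(res$log2fc) > lfc_min &
    !is.na(res$adj_pvalue) & res$adj_pvalue < padj_max
  attr(res, "common_dispersion") <- phi
  res
}

# method-of-moments common dispersion on pseudo-counts:
# per gene, pooled within-group mean/variance give phi = (v - m)/m^2;
# the common value is the median over informative genes, floored at 0
common_dispersion_mom <- function(pseudo, ga, gb) {
  est <- apply(pseudo, 1, function(x) {
    m <- (mean(x[ga]) + mean(x[gb])) / 2
    v <- (var(x[ga]) + var(x[gb])) / 2
    if (!is.finite(m) || m < 1) return(NA_real_)
    (v - m) / m^2
  })
  est <- est[is.finite(est)]
  if (!length(est)) return(0)
  max(0, median(est))
}

# exact conditional NB test: P-value of observing a group-A sum as or less
# likely than sA given total s, groups of nA/nB libraries at common mean
nb_exact_p <- function(sA, sB, nA, nB, phi) {
  s <- sA + sB
  if (s == 0) return(1)
  muA <- nA * s / (nA + nB)
  muB <- nB * s / (nA + nB)
  big <- s > 200000
  if (big) {
    # negligible-mass tails are dropped; window covers > 1 - 1e-25 of mass
    sdA <- sqrt(muA + if (phi > 0) phi * muA^2 / nA else 0)
    lo <- max(0, floor(muA - 45 * sdA)); hi <- min(s, ceiling(muA + 45 * sdA))
    if (sA < lo || sA > hi) return(0)
  } else {
    lo <- 0; hi <- s
  }
  x <- lo:hi
  lp <- if (phi > 0) {
    dnbinom(x, size = nA / phi, mu = muA, log = TRUE) +
      dnbinom(s - x, size = nB / phi, mu = muB, log = TRUE)
  } else {
    dbinom(x, s, nA / (nA + nB), log = TRUE)
  }
  lmax <- max(lp)
  pr <- exp(lp - lmax)
  tot <- sum(pr)
  p_obs <- pr[sA - lo + 1]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-10)]) / tot)
}

#' Cluster relative-expression profiles of DEGs
#'
#' Agglomerative hierarchical clustering (Euclidean distance, Ward linkage)
#' of per-stage mean relative expression, cut at `k` clusters. Rows are
#' ordered lexicographically by gene id beforehand so that ties resolve
#' deterministically regardless of input order.
#'
#' @param re gene x sample relative-expression matrix (restricted to the DEG
#'   union)
#' @param design a `stage_design`
#' @param k number of clusters (default 6, the archetypal developmental
#'   profiles)
#' @return named integer vector gene -> cluster
#' @export
cluster_profiles <- function(re, design, k = 6) {
  if (k > nrow(re)) stop_fdrm("fdrm_data_error", "k exceeds number of genes")
  re <- re[order(rownames(re)), , drop = FALSE]
  stage_mean <- vapply(design$stages, function(s) {
    reps <- intersect(design$replicates[[s]], colnames(re))
    rowMeans(re[, reps, drop = FALSE])
  }, numeric(nrow(re)))
  hc <- hclust(dist(stage_mean), method = "ward.D2")
  cutree(hc, k = k)
}
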