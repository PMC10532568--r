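#' Six archetypal stage-profile templates
#'
#' Relative (0-1) mean-expression profiles over the default nine stages,
#' mirroring the six recurring developmental expression clusters:
#' fruiting-body-high, mycelial, early-germination, mycelial but
#' developmentally regulated, spore/sporulation-high, and
#' germination-transition.
#'
#' @param stages stage labels (profiles are interpolated for non-default
#'   designs)
#' @return 6 x length(stages) matrix
#' @export
profile_templates <- function(stages = stage_design()$stages) {
  tmpl <- rbind(
    fruiting     = c(0.20, 0.10, 0.10, 0.20, 0.20, 0.20, 0.50, 1.00, 1.00),
    mycelial     = c(0.10, 0.20, 0.40, 1.00, 1.00, 0.90, 0.90, 0.30, 0.20),
    germination  = c(0.60, 1.00, 0.90, 0.30, 0.30, 0.40, 0.20, 0.10, 0.20),
    myc_dev      = c(0.10, 0.20, 0.30, 0.80, 0.70, 0.80, 1.00, 0.60, 0.30),
    spore        = c(1.00, 0.60, 0.20, 0.10, 0.10, 0.20, 0.10, 0.30, 0.90),
    germ_trans   = c(0.30, 0.80, 1.00, 0.40, 0.30, 0.30, 0.20, 0.10, 0.10))
  if (length(stages) == 9) {
    colnames(tmpl) <- stages
    return(tmpl)
  }
  idx <- seq(1, 9, length.out = length(stages))
  out <- t(apply(tmpl, 1, function(r) approx(1:9, r, xout = idx)$y))
  colnames(out) <- stages
  out
}

#' Simulate a developmental count matrix with planted DEGs
#'
#' Negative-binomial counts (gene-specific log-normal baseline abundances)
#' over the full stage x replicate design. A fraction of genes follows one
#' of the six archetypal stage templates; `n_deg` genes are planted as
#' differentially expressed with |log2FC| >= `lfc` (default 4) between a
#' designated stage pair. `dispersion = 0` gives Poisson counts.
#'
#' @param design a `stage_design`
#' @param n_genes total genes
#' @param n_deg planted differentially expressed genes
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2)
#' @param lib_size target library size per sample
#' @param lfc planted absolute log2 fold change (>= 2)
#' @param deg_pair optional c(stageA, stageB); default the first/last stage
#' @param template_frac fraction of non-DEG genes following a template
#' @param seed RNG seed
#' @return list: `counts` (gene x sample integer matrix), `truth`
#'   (data.frame gene/stageA/stageB/log2fc), `templates` (named gene ->
#'   template assignment)
#' @export
simulate_expression <- function(design, n_genes = 2000, n_deg = 100,
                                dispersion = 0.05, lib_size = 2e6, lfc = 4,
                                deg_pair = NULL, template_frac = 0.3,
                                seed = 1) {
  set.seed(seed)
  stages <- design$stages
  if (is.null(deg_pair)) deg_pair <- c(stages[1], stages[length(stages)])
  genes <- sprintf("g%05d", seq_len(n_genes))
  base <- 2^rnorm(n_genes, mean = 5, sd = 1.5)
  tmpl <- profile_templates(stages)
  assign <- rep(NA_character_, n_genes)
  mu <- matrix(rep(base, length(stages)), n_genes, length(stages),
               dimnames = list(genes, stages))
  is_tmpl <- runif(n_genes) < template_frac
  assign[is_tmpl] <- rownames(tmpl)[sample.int(nrow(tmpl), sum(is_tmpl),
                                               replace = TRUE)]
  for (i in which(is_tmpl)) {
    mu[i, ] <- base[i] * 2^(3 * (tmpl[assign[i], ] - 0.5))
  }
  deg_idx <- sample(which(!is_tmpl), n_deg)
  sgn <- sample(c(-1, 1), n_deg, replace = TRUE)
  mu[deg_idx, deg_pair[2]] <- mu[deg_idx, deg_pair[2]] * 2^(sgn * lfc)
  truth <- data.frame(gene = genes[deg_idx],
                      stageA = rep(deg_pair[1], n_deg),
                      stageB = rep(deg_pair[2], n_deg),
                      log2fc = sgn * lfc, stringsAsFactors = FALSE)
  counts <- matrix(0L, n_genes, length(design$samples),
                   dimnames = list(genes, design$samples))
  for (s in stages) {
    prop <- mu[, s] / sum(mu[, s])
    m <- prop * lib_size
    for (rep_id in design$replicates[[s]]) {
      counts[, rep_id] <- if (dispersion > 0)
        rnbinom(n_genes, mu = m, size = 1 / dispersion)
      else rpois(n_genes, m)
    }
  }
  fdrm_log("simulate_expression: %d genes, %d planted DEGs", n_genes, n_deg)
  list(counts = counts, truth = truth,
       templates = setNames(assign, genes))
}
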