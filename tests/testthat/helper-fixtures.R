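# shared fixtures and independent oracles (kept deliberately naive)

# a hand-specified 3-exon plus-strand gene and its mini-genome
toy_gene_plus <- function() {
  # codons: M V Y L K stop  (CDS = 18 nt) split over 3 exons
  build_coding_gene(cds = "ATGGTTTACCTTAAATAA",
                    introns = c(paste0("GT", strrep("C", 46), "AG"),
                                paste0("GT", strrep("T", 46), "AG")),
                    cut_sites = c(12, 24),
                    utr5 = strrep("G", 10), utr3 = strrep("T", 8),
                    strand = "+", pad = 50)
}

toy_gene_minus <- function() {
  build_coding_gene(cds = "ATGGTTTACCTTAAATAA",
                    introns = c(paste0("GT", strrep("C", 46), "AG"),
                                paste0("GT", strrep("T", 46), "AG")),
                    cut_sites = c(12, 24),
                    utr5 = strrep("G", 10), utr3 = strrep("T", 8),
                    strand = "-", pad = 50)
}

# minimal junction-evidence rows spread over all samples of a design
jrow <- function(contig, d, a, sample, reads, clean = TRUE) {
  data.frame(contig = contig, donor0 = d, acceptor0 = a, sample = sample,
             reads = reads, clean_overhang = clean, stringsAsFactors = FALSE)
}

# brute-force BH oracle: literal definition with explicit monotonization
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  if (n > 1) for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(1, adj)[order(o)]
}

# exhaustive Fisher oracle: enumerate every table with the observed margins
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  xs <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- vapply(xs, function(x) {
    choose(r1, x) * choose(n - r1, c1 - x) / choose(n, c1)
  }, numeric(1))
  p_obs <- probs[xs == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# step-by-step TMM oracle following the published recipe literally
tmm_oracle <- function(counts, ref, j, logratio_trim = 0.3, sum_trim = 0.05) {
  obs <- counts[, j]; refc <- counts[, ref]
  n_obs <- sum(counts[, j]); n_ref <- sum(counts[, ref])
  keep <- obs > 0 & refc > 0
  obs <- obs[keep]; refc <- refc[keep]
  m <- log2((obs / n_obs) / (refc / n_ref))
  a <- 0.5 * log2((obs / n_obs) * (refc / n_ref))
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - refc) / (n_ref * refc)
  n <- length(m)
  lo_m <- floor(n * logratio_trim) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * sum_trim) + 1; hi_a <- n + 1 - lo_a
  rm_ <- rank(m, ties.method = "first"); ra <- rank(a, ties.method = "first")
  sel <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  2^(sum(m[sel] / v[sel]) / sum(1 / v[sel]))
}

# pileup row in the TSV dialect
prow <- function(contig, pos0, ref, sample, A = 0, C = 0, G = 0, T = 0, N = 0) {
  data.frame(contig = contig, pos0 = pos0, ref = ref, sample = sample,
             A = A, C = C, G = G, T = T, N = N, stringsAsFactors = FALSE)
}

# small two-stage design for focused editing tests
mini_design <- function() stage_design(stages = c("S1", "S2"), n_reps = 3)

# build matched DNA + RNA pileups at one position across a design
ed_fixture <- function(design, pos0 = 500, ref = "T", alt = "C",
                       rna = NULL, dna_depth = 40, dna_alt = 0) {
  rna <- rna %||% lapply(design$samples, function(sm) c(depth = 30, ed = 3))
  names(rna) <- design$samples
  rna_df <- do.call(rbind, lapply(design$samples, function(sm) {
    r <- prow("c1", pos0, ref, sm)
    r[[ref]] <- rna[[sm]]["depth"] - rna[[sm]]["ed"]
    r[[alt]] <- rna[[sm]]["ed"]
    r
  }))
  dna_df <- prow("c1", pos0, ref, "DNA")
  dna_df[[ref]] <- dna_depth - dna_alt
  if (dna_alt > 0) dna_df[[alt]] <- dna_alt
  list(rna = rna_df, dna = dna_df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

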