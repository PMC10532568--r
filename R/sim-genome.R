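#' Simulate a toy genome with intron-containing coding genes
#'
#' Generates random nucleotide contigs carrying `n_genes` protein-coding
#' genes, each with 2-6 exons (configurable), a complete CDS (ATG .. stop,
#' length divisible by 3, no internal stop codon), 5'/3' UTRs, GT..AG
#' introns of short fungal-like length (48-90 nt by default), random strand,
#' and phylostratum (1-12, old-biased by default) plus divergence-stratum
#' labels. Genes are laid out sequentially with intergenic gaps wide enough
#' (> 2x the junction-assignment flank) that evidence near one gene can
#' never be attributed to its neighbour. Fully deterministic under `seed`.
#'
#' @param n_genes number of genes (>= 1)
#' @param exons_per_gene_range inclusive range of exon counts
#' @param seed RNG seed
#' @param n_contigs number of contigs genes are distributed over
#' @param protein_len,utr5_len,utr3_len,intron_len,intergenic inclusive
#'   ranges (nt or aa) for the corresponding lengths
#' @param ps_weights sampling weights for phylostrata 1..12
#' @param div_weights sampling weights for divergence strata 1..10
#' @return list with `genome` (a `genome_ref`) and `models` (named list of
#'   `gene_model`)
#' @export
simulate_genome <- function(n_genes = 50, exons_per_gene_range = c(2, 6),
                            seed = 1, n_contigs = 2,
                            protein_len = c(120, 400), utr5_len = c(30, 80),
                            utr3_len = c(40, 100), intron_len = c(48, 90),
                            intergenic = c(1100, 1500),
                            ps_weights = c(30, 15, 10, 8, 7, 6, 5, 5, 4, 4, 3, 3),
                            div_weights = 10:1) {
  stopifnot(n_genes >= 1, exons_per_gene_range[1] >= 1)
  set.seed(seed)
  codons <- apply(expand.grid(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                              c("T", "C", "A", "G")), 1, paste, collapse = "")
  stops <- c("TAA", "TAG", "TGA")
  sense_codons <- setdiff(codons, stops)
  rseq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                            collapse = "")
  rint <- function(rng) if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1)

  contig_seqs <- setNames(vector("list", n_contigs),
                          paste0("contig_", seq_len(n_contigs)))
  for (nm in names(contig_seqs)) contig_seqs[[nm]] <- character(0)
  contig_len <- setNames(rep(0, n_contigs), names(contig_seqs))
  models <- list()

  for (g in seq_len(n_genes)) {
    gid <- sprintf("gene_%03d", g)
    built <- NULL
    for (try in 1:20) {
      n_ex <- rint(exons_per_gene_range)
      plen <- rint(protein_len)
      u5 <- rint(utr5_len); u3 <- rint(utr3_len)
      cds_nt <- 3 * (plen + 1)
      tx_len <- u5 + cds_nt + u3
      n_int <- n_ex - 1
      if (n_int > 0 && tx_len - 20 < n_int * 25) next
      cutpoints <- if (n_int > 0) {
        cand <- sort(sample(seq(10, tx_len - 10), n_int))
        if (n_int > 1 && min(diff(cand)) < 25) next
        cand
      } else numeric(0)
      built <- list(n_ex = n_ex, plen = plen, u5 = u5, u3 = u3,
                    cds_nt = cds_nt, tx_len = tx_len, cuts = cutpoints)
      break
    }
    if (is.null(built))
      stop_fdrm("fdrm_sim_error", "gene %s: infeasible exon packing", gid)
    cds <- paste0("ATG",
                  paste(sample(sense_codons, built$plen - 1, replace = TRUE),
                        collapse = ""),
                  sample(stops, 1))
    tx <- paste0(rseq(built$u5), cds, rseq(built$u3))
    introns <- vapply(seq_along(built$cuts), function(i)
      paste0("GT", rseq(rint(intron_len) - 4), "AG"), character(1))

    # sense-strand genomic layout: exon/intron interleave
    cuts <- c(0, built$cuts, built$tx_len)
    exon_tx <- cbind(start = cuts[-length(cuts)], end = cuts[-1])
    ilen <- c(0, cumsum(nchar(introns)))
    exon_loc <- cbind(start = exon_tx[, 1] + ilen[seq_len(nrow(exon_tx))],
                      end = exon_tx[, 2] + ilen[seq_len(nrow(exon_tx))])
    gseq <- paste0(vapply(seq_len(nrow(exon_tx)), function(i) {
      e <- substr(tx, exon_tx[i, 1] + 1, exon_tx[i, 2])
      if (i < nrow(exon_tx)) paste0(e, introns[i]) else e
    }, character(1)), collapse = "")
    glen <- nchar(gseq)
    # map a tx interval to local sense genomic intervals
    map_tx <- function(a, b) {
      res <- list()
      for (i in seq_len(nrow(exon_tx))) {
        s <- max(a, exon_tx[i, 1]); e <- min(b, exon_tx[i, 2])
        if (s < e) res[[length(res) + 1]] <-
            c(s + ilen[i], e + ilen[i])
      }
      do.call(rbind, res)
    }
    loc <- list(exons = exon_loc,
                utr5 = map_tx(0, built$u5),
                cds = map_tx(built$u5, built$u5 + built$cds_nt),
                utr3 = map_tx(built$u5 + built$cds_nt, built$tx_len))
    strand <- sample(c("+", "-"), 1)
    if (strand == "-") {
      gseq <- revcomp(gseq)
      flip <- function(iv) if (is.null(iv)) NULL else
        cbind(start = glen - iv[, 2], end = glen - iv[, 1])
      loc <- lapply(loc, flip)
    }
    ct <- names(contig_seqs)[(g - 1) %% n_contigs + 1]
    gap <- rint(intergenic)
    offset <- contig_len[ct] + gap
    contig_seqs[[ct]] <- c(contig_seqs[[ct]], rseq(gap), gseq)
    contig_len[ct] <- offset + glen
    shift <- function(iv) if (is.null(iv)) NULL else iv + offset
    models[[gid]] <- gene_model(
      gene_id = gid, contig = ct, strand = strand,
      exons = shift(loc$exons), cds = shift(loc$cds),
      utr5 = shift(loc$utr5), utr3 = shift(loc$utr3),
      phylostratum = sample(1:12, 1, prob = ps_weights),
      divergence_stratum = sample(seq_along(div_weights), 1, prob = div_weights))
  }
  # trailing intergenic tail so no gene touches a contig end
  genome <- genome_ref(vapply(names(contig_seqs), function(nm)
    paste0(paste(contig_seqs[[nm]], collapse = ""), rseq(500)), character(1)))
  fdrm_log("simulate_genome: %d genes on %d contigs", n_genes, n_contigs)
  list(genome = genome, models = models)
}
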