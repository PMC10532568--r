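#' Construct a coding gene (and its mini-genome) from explicit parts
#'
#' Deterministic builder for worked examples and tests: assembles a
#' single-isoform gene from a transcript-sense CDS, UTRs and intron
#' sequences inserted at given transcript positions, places it on one padded
#' contig, and returns both the `genome_ref` and the `gene_model`. Intron
#' cut positions are 0-based offsets into the (intron-free) transcript
#' `utr5 + cds + utr3`; exon/CDS/UTR coordinates come out in genomic
#' ascending order for either strand.
#'
#' @param cds transcript-sense CDS (ATG..stop, length divisible by 3)
#' @param introns character vector of intron sequences (sense strand)
#' @param cut_sites integer vector, same length as `introns`: transcript
#'   offsets at which each intron is inserted (strictly increasing)
#' @param utr5,utr3 UTR sequences (sense strand)
#' @param strand "+" or "-"
#' @param gene_id,contig identifiers
#' @param pad flanking sequence length added on both sides of the gene
#' @param seed seed for the random padding sequence
#' @return list with `genome` (a `genome_ref`) and `model` (a `gene_model`)
#' @export
build_coding_gene <- function(cds, introns = character(0),
                              cut_sites = integer(0),
                              utr5 = strrep("C", 30), utr3 = strrep("A", 30),
                              strand = "+", gene_id = "gene_1",
                              contig = "chr1", pad = 100, seed = 1) {
  stopifnot(length(introns) == length(cut_sites),
            nchar(cds) %% 3 == 0)
  if (length(cut_sites) > 1 && is.unsorted(cut_sites, strictly = TRUE))
    stop_fdrm("fdrm_model_error", "cut_sites must be strictly increasing")
  tx <- paste0(utr5, cds, utr3)
  tx_len <- nchar(tx)
  if (length(cut_sites) && (min(cut_sites) <= 0 || max(cut_sites) >= tx_len))
    stop_fdrm("fdrm_model_error", "cut_sites outside transcript")
  cuts <- c(0, cut_sites, tx_len)
  exon_tx <- cbind(start = cuts[-length(cuts)], end = cuts[-1])
  ilen <- c(0, cumsum(nchar(introns)))
  gseq <- paste0(vapply(seq_len(nrow(exon_tx)), function(i) {
    e <- substr(tx, exon_tx[i, 1] + 1, exon_tx[i, 2])
    if (i < nrow(exon_tx)) paste0(e, introns[i]) else e
  }, character(1)), collapse = "")
  glen <- nchar(gseq)
  map_tx <- function(a, b) {
    res <- list()
    for (i in seq_len(nrow(exon_tx))) {
      s <- max(a, exon_tx[i, 1]); e <- min(b, exon_tx[i, 2])
      if (s < e) res[[length(res) + 1]] <- c(s + ilen[i], e + ilen[i])
    }
    do.call(rbind, res)
  }
  u5 <- nchar(utr5)
  loc <- list(exons = cbind(start = exon_tx[, 1] + ilen[seq_len(nrow(exon_tx))],
                            end = exon_tx[, 2] + ilen[seq_len(nrow(exon_tx))]),
              utr5 = map_tx(0, u5),
              cds = map_tx(u5, u5 + nchar(cds)),
              utr3 = map_tx(u5 + nchar(cds), tx_len))
  if (strand == "-") {
    gseq <- revcomp(gseq)
    loc <- lapply(loc, function(iv) if (is.null(iv)) NULL else
      cbind(start = glen - iv[, 2], end = glen - iv[, 1]))
  }
  set.seed(seed)
  padseq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")
  genome <- genome_ref(setNames(paste0(padseq(pad), gseq, padseq(pad)), contig))
  shift <- function(iv) if (is.null(iv)) NULL else iv + pad
  model <- gene_model(gene_id = gene_id, contig = contig, strand = strand,
                      exons = shift(loc$exons), cds = shift(loc$cds),
                      utr5 = shift(loc$utr5), utr3 = shift(loc$utr3))
  list(genome = genome, model = model)
}
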