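#' Pileup table dialect
#'
#' Pileups are exchanged as plain TSVs with one row per (position, sample):
#' columns `contig`, `pos0` (0-based), `ref`, `sample`, `A`, `C`, `G`, `T`,
#' `N`. Tallies are quality-filtered base counts; depth is the sum of the
#' A/C/G/T tallies (N is tracked but never counted as coverage or variant
#' support).
#'
#' @param path TSV file
#' @return data.frame in the pileup dialect
#' @export
read_pileup_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("contig", "pos0", "ref", "sample", "A", "C", "G", "T", "N")
  if (!all(need %in% names(df)))
    stop_fdrm("fdrm_format_error", "pileup TSV %s missing columns: %s", path,
              paste(setdiff(need, names(df)), collapse = ","))
  if (any(df[c("A", "C", "G", "T", "N")] < 0))
    stop_fdrm("fdrm_format_error", "negative tally in %s", path)
  fdrm_log("read_pileup_tsv: %d rows from %s", nrow(df), path)
  df[need]
}

#' @rdname read_pileup_tsv
#' @param pileup data.frame in the pileup dialect
#' @export
write_pileup_tsv <- function(pileup, path) {
  utils::write.table(pileup, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pileup depth (A+C+G+T)
#' @param pileup pileup data.frame
#' @return numeric vector of per-row depths
#' @export
pileup_depth <- function(pileup) {
  unname(rowSums(pileup[, c("A", "C", "G", "T"), drop = FALSE]))
}

#' Build a pileup from a SAM/BAM alignment file
#'
#' Tallies only bases with base quality >= `min_base_q` from reads with
#' mapping quality >= `min_map_q` (default 25 for both, matching the editing
#' caller's quality rule). Multi-hit reads (secondary/supplementary
#' alignments, plus anything below the mapping-quality floor) and
#' duplicate-flagged reads are excluded when the corresponding flags are set.
#' SAM input is converted, sorted and indexed into a temporary BAM.
#'
#' @param path SAM or BAM file (BAM is indexed on the fly if needed)
#' @param genome optional `genome_ref` used to fill the `ref` column
#' @param sample sample id recorded in the output rows
#' @param region optional "contig:start1-end1" (1-based, inclusive) restriction
#' @param min_base_q,min_map_q quality floors (default 25)
#' @param drop_multihit exclude secondary/supplementary alignments
#' @param drop_duplicates exclude duplicate-flagged reads
#' @return data.frame in the pileup dialect
#' @export
read_alignments_to_pileup <- function(path, genome = NULL, sample = "S1",
                                      region = NULL, min_base_q = 25,
                                      min_map_q = 25, drop_multihit = TRUE,
                                      drop_duplicates = TRUE) {
  bam <- ensure_bam(path)
  flag <- Rsamtools::scanBamFlag(
    isSecondaryAlignment = if (drop_multihit) FALSE else NA,
    isSupplementaryAlignment = if (drop_multihit) FALSE else NA,
    isDuplicate = if (drop_duplicates) FALSE else NA,
    isUnmappedQuery = FALSE)
  which <- if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+):(\\d+)-(\\d+)$", region))[[1]]
    if (length(m) != 4) stop_fdrm("fdrm_format_error", "bad region '%s'", region)
    GenomicRanges::GRanges(m[2], IRanges::IRanges(as.integer(m[3]), as.integer(m[4])))
  } else NULL
  sb <- if (is.null(which)) Rsamtools::ScanBamParam(flag = flag)
        else Rsamtools::ScanBamParam(flag = flag, which = which)
  pp <- Rsamtools::PileupParam(max_depth = 1000000L,
                               min_base_quality = as.integer(min_base_q),
                               min_mapq = as.integer(min_map_q),
                               min_nucleotide_depth = 1L,
                               distinguish_strands = FALSE,
                               distinguish_nucleotides = TRUE,
                               include_deletions = FALSE,
                               include_insertions = FALSE)
  res <- Rsamtools::pileup(bam, scanBamParam = sb, pileupParam = pp)
  if (nrow(res) == 0) {
    return(data.frame(contig = character(0), pos0 = numeric(0), ref = character(0),
                      sample = character(0), A = integer(0), C = integer(0),
                      G = integer(0), T = integer(0), N = integer(0)))
  }
  res$nucleotide <- as.character(res$nucleotide)
  res <- res[res$nucleotide %in% c("A", "C", "G", "T", "N"), , drop = FALSE]
  key <- paste(res$seqnames, res$pos)
  tal <- matrix(0L, nrow = length(unique(key)), ncol = 5,
                dimnames = list(unique(key), c("A", "C", "G", "T", "N")))
  for (nt in colnames(tal)) {
    sel <- res$nucleotide == nt
    if (any(sel)) {
      agg <- tapply(res$count[sel], key[sel], sum)
      tal[names(agg), nt] <- as.integer(agg)
    }
  }
  first <- !duplicated(key)
  contig <- as.character(res$seqnames)[first]
  pos0 <- res$pos[first] - 1L
  ref <- if (!is.null(genome)) {
    mapply(function(ct, p) genome_seq(genome, ct, p, p + 1), contig, pos0)
  } else rep("N", length(pos0))
  out <- data.frame(contig = contig, pos0 = pos0, ref = unname(ref),
                    sample = sample, tal[key[first], , drop = FALSE],
                    row.names = NULL, stringsAsFactors = FALSE)
  fdrm_log("read_alignments_to_pileup: %d columns from %s", nrow(out), path)
  out[order(out$contig, out$pos0), , drop = FALSE]
}

# convert/sort/index SAM or BAM as needed; returns path to an indexed BAM
ensure_bam <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = TRUE)
    return(bam)
  }
  if (!file.exists(paste0(path, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", path))) {
    ok <- tryCatch({ Rsamtools::indexBam(path); TRUE }, error = function(e) FALSE)
    if (!ok) stop_fdrm("fdrm_io_error", "BAM %s is not indexed and could not be indexed (sorted?)", path)
  }
  path
}
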