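#' Reference genome container
#'
#' A `genome_ref` is an ordered, named set of uppercase nucleotide sequences
#' (alphabet A/C/G/T/N). Internally sequences are stored as a named character
#' vector; all package coordinates are 0-based half-open.
#'
#' @param contigs named character vector of sequences
#' @return object of class `genome_ref`
#' @export
genome_ref <- function(contigs) {
  if (is.null(names(contigs)) || any(names(contigs) == ""))
    stop_fdrm("fdrm_format_error", "contigs must be named")
  if (anyDuplicated(names(contigs)))
    stop_fdrm("fdrm_format_error", "duplicate contig name")
  contigs <- setNames(toupper(as.character(contigs)), names(contigs))
  if (any(nchar(contigs) == 0L))
    stop_fdrm("fdrm_format_error", "empty contig sequence")
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad))
    stop_fdrm("fdrm_format_error", "contig %s contains non-ACGTN characters",
              names(contigs)[bad][1])
  structure(as.list(contigs), class = "genome_ref")
}

#' @export
print.genome_ref <- function(x, ...) {
  cat(sprintf("genome_ref: %d contig(s), %d bp total\n",
              length(x), sum(contig_lengths(x))))
  invisible(x)
}

#' Contig lengths of a genome
#' @param genome a `genome_ref`
#' @return named integer vector
#' @export
contig_lengths <- function(genome) {
  vapply(genome, nchar, integer(1))
}

#' Fetch genome sequence for a 0-based half-open interval
#' @param genome a `genome_ref`
#' @param contig contig name
#' @param start0,end0 0-based half-open bounds
#' @return character scalar
#' @export
genome_seq <- function(genome, contig, start0, end0) {
  if (!contig %in% names(genome))
    stop_fdrm("fdrm_consistency_error", "unknown contig %s", contig)
  len <- nchar(genome[[contig]])
  if (start0 < 0 || end0 > len || start0 > end0)
    stop_fdrm("fdrm_consistency_error", "interval [%d,%d) outside contig %s",
              start0, end0, contig)
  substr(genome[[contig]], start0 + 1L, end0)
}

#' Read a reference genome from FASTA
#'
#' Sequences are uppercased; duplicate headers and empty records are format
#' errors.
#'
#' @param path FASTA file
#' @return a `genome_ref`
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop_fdrm("fdrm_format_error", "no FASTA records in %s", path)
  nm <- sub("\\s.*$", "", names(ss))
  seqs <- as.character(ss)
  names(seqs) <- nm
  if (anyDuplicated(nm))
    stop_fdrm("fdrm_format_error", "duplicate FASTA header in %s", path)
  fdrm_log("read_genome: %d contigs from %s", length(seqs), path)
  genome_ref(seqs)
}

#' Write a genome to FASTA (70-column wrap)
#' @param genome a `genome_ref`
#' @param path output file
#' @export
write_genome <- function(genome, path) {
  stopifnot(inherits(genome, "genome_ref"))
  ss <- Biostrings::DNAStringSet(unlist(unclass(genome)))
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

comp_base <- function(b) {
  unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[b])
}
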