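#' Read a reference genome from FASTA
#'
#' Sequences are uppercased and normalized to the DNA alphabet (`U -> T`);
#' IUPAC ambiguity codes other than `N` are mapped to `N` with a warning.
#' The chromosome name is the FASTA header up to the first whitespace.
#'
#' @param path Path to a FASTA file.
#' @return A `Biostrings::DNAStringSet` named by chromosome.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgu"), fa)
#' as.character(read_genome(fa))  # chr1 = "ACGT"
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  raw <- Biostrings::readBStringSet(path)
  if (!length(raw)) stop("empty FASTA file: ", path, call. = FALSE)
  nms <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(nms)) {
    stop("duplicate sequence name in FASTA: ",
         nms[duplicated(nms)][1], call. = FALSE)
  }
  seqs <- toupper(as.character(raw))
  seqs <- chartr("U", "T", seqs)
  if (any(grepl("[^ACGTN]", seqs))) {
    warning("non-ACGTN characters in genome mapped to N", call. = FALSE)
    seqs <- gsub("[^ACGTN]", "N", seqs)
  }
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- nms
  genome
}

#' Chromosome lengths of a genome
#' @param genome A `DNAStringSet` as returned by [read_genome()].
#' @return Named integer vector of sequence lengths.
#' @export
genome_lengths <- function(genome) {
  setNames(Biostrings::width(genome), names(genome))
}

#' Fetch a stranded genomic subsequence
#'
#' Coordinates are 0-based half-open. On the minus strand the reverse
#' complement is returned, so the result always reads 5' to 3' on the
#' requested strand (as a precursor would be transcribed).
#'
#' @param genome A `DNAStringSet` from [read_genome()].
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval.
#' @param strand `"+"` or `"-"`.
#' @return A character string of length `end - start`.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "AACCC"))
#' fetch_sequence(g, "chr1", 0, 5, "-")  # "GGGTT"
#' @export
fetch_sequence <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) {
    stop("unknown chromosome: ", chrom, call. = FALSE)
  }
  len <- length(genome[[chrom]])
  if (start < 0 || end > len || start >= end) {
    stop(sprintf("interval [%d,%d) out of bounds for %s (length %d)",
                 start, end, chrom, len), call. = FALSE)
  }
  s <- Biostrings::subseq(genome[[chrom]], start + 1L, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}
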