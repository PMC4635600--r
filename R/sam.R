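#' Read strand-specific small RNA alignments from SAM
#'
#' Parses a plain-text SAM file (header optional) into the collapsed read
#' model used by all downstream stages. Unmapped records (flag `0x4`) are
#' skipped; strand comes from flag `0x10`; the aligned reference span is the
#' sum of the reference-consuming CIGAR operations (`M/D/N/=/X`, computed
#' with `GenomicAlignments::cigarWidthAlongReferenceSpace()`); SAM's 1-based
#' `POS` is converted to 0-based half-open coordinates. Identical
#' `(chrom, start, end, strand)` alignments are collapsed into one row with
#' summed `mult`. Secondary and supplementary alignments (flags
#' `0x100`/`0x800`) are included by default because small RNA reads are
#' frequently multi-mapping; set `primary_only = TRUE` to restrict.
#'
#' @param path Path to a SAM file.
#' @param genome `DNAStringSet` from [read_genome()]; records referencing
#'   chromosomes absent from it are an error.
#' @param primary_only Drop secondary/supplementary alignments.
#' @return A tibble with columns `chrom`, `start`, `end` (0-based half-open),
#'   `strand` (`"+"`/`"-"`) and `mult` (collapsed multiplicity), sorted by
#'   position.
#' @export
read_alignments <- function(path, genome, primary_only = FALSE) {
  if (!file.exists(path)) stop("SAM file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "@")]
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), mult = integer()))
  }
  fields <- stringr::str_split_fixed(lines, "\t", 7L)
  if (any(!nzchar(fields[, 6]))) {
    stop("malformed SAM record (fewer than 6 fields)", call. = FALSE)
  }
  flag <- as.integer(fields[, 2])
  rname <- fields[, 3]
  pos <- as.integer(fields[, 4])
  cigar <- fields[, 6]

  mapped <- bitwAnd(flag, 0x4L) == 0L
  flag <- flag[mapped]; rname <- rname[mapped]
  pos <- pos[mapped]; cigar <- cigar[mapped]

  star_cigar <- cigar == "*"
  if (any(star_cigar)) {
    warning(sum(star_cigar),
            " mapped record(s) with CIGAR '*' skipped", call. = FALSE)
    flag <- flag[!star_cigar]; rname <- rname[!star_cigar]
    pos <- pos[!star_cigar]; cigar <- cigar[!star_cigar]
  }
  if (primary_only) {
    keep <- bitwAnd(flag, 0x100L) == 0L & bitwAnd(flag, 0x800L) == 0L
    flag <- flag[keep]; rname <- rname[keep]
    pos <- pos[keep]; cigar <- cigar[keep]
  }
  if (!length(flag)) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), mult = integer()))
  }
  unknown <- setdiff(unique(rname), names(genome))
  if (length(unknown)) {
    stop("alignment references unknown chromosome: ", unknown[1],
         call. = FALSE)
  }

  width <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
  tibble(
    chrom = rname,
    start = pos - 1L,
    end = pos - 1L + width,
    strand = ifelse(bitwAnd(flag, 0x10L) != 0L, "-", "+")
  ) |>
    group_by(.data$chrom, .data$start, .data$end, .data$strand) |>
    summarise(mult = dplyr::n(), .groups = "drop") |>
    arrange(.data$chrom, .data$strand, .data$start, .data$end)
}
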