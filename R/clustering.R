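#' Find expression contigs from collapsed reads
#'
#' A contig is a maximal genomic interval with nonzero read coverage on one
#' strand. Contigs with summed overlapping read multiplicity below
#' `min_reads` are dropped (inclusive threshold: a contig with exactly
#' `min_reads` reads is kept). All `(chrom, strand)` combinations present in
#' `reads` are processed independently.
#'
#' @param reads Tibble from [read_alignments()].
#' @param min_reads Minimum summed multiplicity (default 1 = keep all
#'   coverage islands; the pipeline applies its read threshold after gap
#'   merging).
#' @return Tibble with `chrom`, `strand`, `start`, `end` (0-based half-open)
#'   and `read_count`, sorted by position within each chrom/strand.
#' @export
find_contigs <- function(reads, min_reads = 1L) {
  empty <- tibble(chrom = character(), strand = character(),
                  start = integer(), end = integer(), read_count = integer())
  if (!nrow(reads)) return(empty)
  reads |>
    group_by(.data$chrom, .data$strand) |>
    dplyr::group_modify(function(df, key) {
      ir <- IRanges::IRanges(start = df$start + 1L, end = df$end)
      islands <- IRanges::reduce(ir)
      hits <- IRanges::findOverlaps(ir, islands)
      counts <- tapply(df$mult[S4Vectors::queryHits(hits)],
                       S4Vectors::subjectHits(hits), sum)
      tibble(
        start = IRanges::start(islands) - 1L,
        end = IRanges::end(islands),
        read_count = as.integer(counts[as.character(seq_along(islands))])
      )
    }) |>
    ungroup() |>
    filter(.data$read_count >= min_reads) |>
    arrange(.data$chrom, .data$strand, .data$start)
}

#' Merge neighbouring contigs separated by small gaps
#'
#' Adjacent contigs on the same chromosome and strand whose gap
#' (`next start - previous end`) is strictly smaller than `gap_size` are
#' merged transitively; the merged contig spans the union hull and sums the
#' read counts. `gap_size = 0` disables merging.
#'
#' @param contigs Sorted, non-overlapping tibble from [find_contigs()].
#' @param gap_size Gap threshold in nt (strict `<`).
#' @return Tibble with the same columns as the input.
#' @export
merge_contigs <- function(contigs, gap_size) {
  if (!nrow(contigs)) return(contigs)
  contigs |>
    group_by(.data$chrom, .data$strand) |>
    dplyr::group_modify(function(df, key) {
      if (is.unsorted(df$start) ||
          any(df$start[-1] < head(df$end, -1))) {
        stop("contigs must be sorted and non-overlapping within a ",
             "chromosome/strand", call. = FALSE)
      }
      gap <- df$start - lag(df$end)
      grp <- cumsum(is.na(gap) | gap >= gap_size)
      df |>
        mutate(.grp = grp) |>
        group_by(.data$.grp) |>
        summarise(start = min(.data$start), end = max(.data$end),
                  read_count = sum(.data$read_count), .groups = "drop") |>
        select(-dplyr::any_of(".grp")) |>
        select("start", "end", "read_count")
    }) |>
    ungroup() |>
    arrange(.data$chrom, .data$strand, .data$start)
}

#' Drop over-long contigs
#'
#' Contigs whose length exceeds `max_length` (strict `>`, so a contig of
#' exactly `max_length` nt is kept) are removed. Applied after gap merging
#' and before flank extension.
#'
#' @param contigs Tibble of (merged) contigs.
#' @param max_length Maximum contig length in nt.
#' @return Filtered tibble.
#' @export
filter_contigs <- function(contigs, max_length) {
  filter(contigs, .data$end - .data$start <= max_length)
}

#' Extend contigs by flanking regions into candidate clusters
#'
#' Each contig is extended by `flank_size` nt on both sides (clamped to the
#' chromosome), forming the candidate cluster within which precursor windows
#' are enumerated. Cluster ids are `"chrom:strand:start-end"` of the contig.
#'
#' @param contigs Tibble of contigs surviving [filter_contigs()].
#' @param flank_size Flank F in nt.
#' @param genome `DNAStringSet` (for chromosome lengths).
#' @return Tibble with `id`, `chrom`, `strand`, contig `start`/`end`, and
#'   `flank_start`/`flank_end` (0-based half-open, clamped).
#' @export
extend_clusters <- function(contigs, flank_size, genome) {
  lens <- genome_lengths(genome)
  if (nrow(contigs) && any(!contigs$chrom %in% names(lens))) {
    stop("contig references unknown chromosome", call. = FALSE)
  }
  contigs |>
    mutate(
      flank_start = pmax(0L, .data$start - as.integer(flank_size)),
      flank_end = pmin(unname(lens[.data$chrom]),
                       .data$end + as.integer(flank_size)),
      id = sprintf("%s:%s:%d-%d", .data$chrom, .data$strand,
                   .data$start, .data$end)
    ) |>
    select("id", "chrom", "strand", "start", "end",
           "flank_start", "flank_end", "read_count")
}

#' Stage 1: reads to candidate clusters
#'
#' Runs the full cluster-definition stage: coverage islands, gap merging,
#' read-count threshold (applied after merging), length filter, flank
#' extension.
#'
#' @param reads Tibble from [read_alignments()].
#' @param genome `DNAStringSet` from [read_genome()].
#' @param config `hairpin_config` from [load_config()].
#' @return Cluster tibble as from [extend_clusters()].
#' @export
define_clusters <- function(reads, genome, config) {
  find_contigs(reads, min_reads = 1L) |>
    merge_contigs(config$cluster_gap_size) |>
    filter(.data$read_count >= config$cluster_min_reads) |>
    filter_contigs(config$cluster_max_length) |>
    extend_clusters(config$cluster_flank_size, genome)
}
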