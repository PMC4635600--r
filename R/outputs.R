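#' Write precursor calls as BED6
#'
#' One line per precursor plus one per mature and one per star locus, with
#' name suffixes `.pre`, `.mature`, `.star`. Coordinates are 0-based
#' half-open (native BED). The score column is `-mfe_per_nt * 1000` rounded
#' and clamped to `[0, 1000]`. A `track` header line is always written, so
#' an empty call table yields a file with just the header.
#'
#' @param calls Call tibble from [verify_candidates()] / [run_pipeline()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(calls, path) {
  lines <- "track name=hairpinr description=\"miRNA precursor calls\""
  if (nrow(calls)) {
    score <- pmin(1000L, pmax(0L, as.integer(round(-calls$mfe_per_nt * 1000))))
    pre <- calls |>
      dplyr::distinct(.data$id, .keep_all = TRUE)
    pre_score <- pmin(1000L, pmax(0L, as.integer(round(-pre$mfe_per_nt * 1000))))
    lines <- c(
      lines,
      sprintf("%s\t%d\t%d\t%s.pre\t%d\t%s", pre$chrom, pre$pre_start,
              pre$pre_end, pre$id, pre_score, pre$strand),
      sprintf("%s\t%d\t%d\t%s.mature\t%d\t%s", calls$chrom,
              calls$mature_start, calls$mature_end, calls$id, score,
              calls$strand),
      sprintf("%s\t%d\t%d\t%s.star\t%d\t%s", calls$chrom, calls$star_start,
              calls$star_end, calls$id, score, calls$strand)
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write precursor calls as GTF2.2
#'
#' Feature types `precursor`, `mature` and `star`; coordinates 1-based
#' inclusive (`GTF start = BED start + 1`, `GTF end = BED end`). Attributes
#' carry the call id, p-value (6 decimals), MFE/nt and read support.
#'
#' @inheritParams write_bed
#' @return `path`, invisibly.
#' @export
write_gtf <- function(calls, path) {
  gtf_line <- function(chrom, type, start0, end0, strand, id, p, mfe_nt,
                       support) {
    sprintf(paste0(
      "%s\thairpinr\t%s\t%d\t%d\t.\t%s\t.\t",
      "gene_id \"%s\"; transcript_id \"%s\"; p_value \"%.6f\"; ",
      "mfe_per_nt \"%.4f\"; read_support \"%d\";"),
      chrom, type, start0 + 1L, end0, strand, id, id, p, mfe_nt, support)
  }
  lines <- character(0)
  if (nrow(calls)) {
    pre <- dplyr::distinct(calls, .data$id, .keep_all = TRUE)
    pre_support <- calls |>
      group_by(.data$id) |>
      summarise(total = sum(.data$read_support), .groups = "drop")
    pre <- left_join(pre, pre_support, by = "id")
    lines <- c(
      gtf_line(pre$chrom, "precursor", pre$pre_start, pre$pre_end,
               pre$strand, pre$id, pre$p_value, pre$mfe_per_nt, pre$total),
      gtf_line(calls$chrom, "mature", calls$mature_start, calls$mature_end,
               calls$strand, calls$id, calls$p_value, calls$mfe_per_nt,
               calls$read_support),
      gtf_line(calls$chrom, "star", calls$star_start, calls$star_end,
               calls$strand, calls$id, calls$p_value, calls$mfe_per_nt,
               calls$read_support)
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write the tabular and JSON reports
#'
#' The CSV holds one row per mature/star duplex with every computed
#' statistic (RFC 4180, via `readr::write_csv()`). The JSON mirrors the
#' call table losslessly — including dot-bracket structures — plus a
#' rejection summary (count per failing criterion).
#'
#' @inheritParams write_bed
#' @param rejections Rejection tibble (`cluster_id`, `reason`).
#' @param csv_path,json_path Output files.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_report <- function(calls, rejections, csv_path, json_path) {
  readr::write_csv(calls, csv_path)
  rejection_summary <- rejections |>
    dplyr::count(.data$reason, name = "n") |>
    arrange(desc(.data$n))
  payload <- list(calls = calls, rejection_summary = rejection_summary)
  jsonlite::write_json(payload, json_path, digits = NA, dataframe = "rows",
                       na = "null", pretty = TRUE)
  invisible(c(csv = csv_path, json = json_path))
}

write_outputs <- function(calls, rejections, out_dir) {
  paths <- c(
    calls = file.path(out_dir, "calls.csv"),
    json = file.path(out_dir, "report.json"),
    bed = file.path(out_dir, "calls.bed"),
    gtf = file.path(out_dir, "calls.gtf"),
    rejections = file.path(out_dir, "rejections.csv")
  )
  write_report(calls, rejections, paths["calls"], paths["json"])
  write_bed(calls, paths["bed"])
  write_gtf(calls, paths["gtf"])
  readr::write_csv(rejections, paths["rejections"])
  paths
}
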