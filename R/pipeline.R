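#' Stage 2: fold clusters and score structures
#'
#' For every cluster, searches the window grid for the MFE/nt-optimal
#' precursor window ([select_precursor_window()]), applies the
#' secondary-structure filters, and — for candidates passing all of them —
#' computes the empirical shuffle-test p-value. The configured seed is set
#' once at stage entry, so identical inputs give identical output
#' regardless of `worker_count` (shuffles are drawn serially; folding is
#' deterministic).
#'
#' @param clusters Cluster tibble from [define_clusters()].
#' @param genome `DNAStringSet`.
#' @param config `hairpin_config`.
#' @param engine [fold_engine()]; defaults to `config$fold_backend`.
#' @return Candidate tibble, one row per cluster that yielded a candidate:
#'   window coordinates, sequence, structure, energies, structure stats and
#'   verdicts, `p_value` (`NA` for candidates failing the structure
#'   filters), `null_mean`, `null_sd`, `sig_pass`.
#' @export
fold_clusters <- function(clusters, genome, config,
                          engine = fold_engine(config$fold_backend)) {
  set.seed(config$seed)
  rows <- vector("list", nrow(clusters))
  for (i in seq_len(nrow(clusters))) {
    cl <- clusters[i, ]
    best <- select_precursor_window(cl, genome, config, engine)
    if (!nrow(best)) next
    cand <- apply_structure_filters(
      mutate(best, chrom = cl$chrom), config
    )
    if (cand$structure_pass) {
      null <- null_distribution(cand$sequence, config$permutation_count,
                                engine, method = config$shuffle_method,
                                workers = config$worker_count)
      sig <- empirical_p(cand$mfe_per_nt, null)
      cand <- mutate(cand,
                     p_value = sig$p_value,
                     null_mean = sig$null_mean,
                     null_sd = sig$null_sd,
                     sig_pass = sig$p_value <= config$max_pvalue)
    } else {
      cand <- mutate(cand, p_value = NA_real_, null_mean = NA_real_,
                     null_sd = NA_real_, sig_pass = FALSE)
    }
    rows[[i]] <- cand
  }
  out <- bind_rows(rows)
  if (!nrow(out)) {
    return(tibble(cluster_id = character(), start = integer(),
                  end = integer(), strand = character(), length = integer(),
                  sequence = character(), structure = character(),
                  mfe = numeric(), mfe_per_nt = numeric(),
                  unique_optimum = logical(), chrom = character(),
                  n_term = integer(), l_ds_max = integer(),
                  paired_fraction = numeric(), structure_pass = logical(),
                  filter_reasons = character(), p_value = numeric(),
                  null_mean = numeric(), null_sd = numeric(),
                  sig_pass = logical()))
  }
  arrange(out, .data$chrom, .data$strand, .data$start)
}

#' Stage 3: verify candidates against read coverage
#'
#' Runs the mature/star duplex verification for every candidate passing the
#' structure filters and the significance cut. `reads` may come from an
#' alignment file different from the one used for clustering
#' (cross-verification).
#'
#' @param candidates Candidate tibble from [fold_clusters()].
#' @param reads Read tibble from [read_alignments()] (verification data).
#' @param config `hairpin_config`.
#' @return List: `calls` (tibble, one row per accepted duplex, with stable
#'   ids sorted by chrom/start) and `rejections` (tibble of clusters or
#'   mature loci with the first failing criterion).
#' @export
verify_candidates <- function(candidates, reads, config) {
  eligible <- filter(candidates, .data$structure_pass,
                     !is.na(.data$p_value), .data$sig_pass)
  rej <- candidates |>
    filter(!.data$structure_pass | is.na(.data$p_value) | !.data$sig_pass) |>
    mutate(reason = dplyr::if_else(
      !.data$structure_pass,
      paste0("structure: ", .data$filter_reasons),
      "significance")) |>
    select("cluster_id", "reason")

  calls <- list()
  for (i in seq_len(nrow(eligible))) {
    cand <- eligible[i, ]
    ver <- verify_precursor(cand, reads, config)
    if (ver$called) {
      d <- ver$duplexes
      # precursor-relative -> genomic
      if (cand$strand == "+") {
        d <- mutate(d,
          mature_start = cand$start + .data$mature_rel_start,
          mature_end = cand$start + .data$mature_rel_end,
          star_start = cand$start + .data$star_rel_start,
          star_end = cand$start + .data$star_rel_end)
      } else {
        d <- mutate(d,
          mature_start = cand$end - .data$mature_rel_end,
          mature_end = cand$end - .data$mature_rel_start,
          star_start = cand$end - .data$star_rel_end,
          star_end = cand$end - .data$star_rel_start)
      }
      calls[[length(calls) + 1L]] <- bind_cols(
        tibble(cluster_id = cand$cluster_id, chrom = cand$chrom,
               strand = cand$strand, pre_start = cand$start,
               pre_end = cand$end, structure = cand$structure,
               mfe = cand$mfe, mfe_per_nt = cand$mfe_per_nt,
               p_value = cand$p_value, n_term = cand$n_term,
               l_ds_max = cand$l_ds_max,
               unique_optimum = cand$unique_optimum),
        d
      )
    } else {
      first_reason <- ver$rejections$reason[1] %||% "no passing duplex"
      rej <- bind_rows(rej, tibble(cluster_id = cand$cluster_id,
                                   reason = first_reason))
    }
  }
  calls <- if (length(calls)) bind_rows(calls) else empty_calls()
  calls <- dedupe_calls(calls)
  calls <- calls |>
    arrange(.data$chrom, .data$pre_start, .data$strand,
            .data$mature_start) |>
    group_by(.data$chrom) |>
    mutate(.pre_key = paste(.data$pre_start, .data$pre_end, .data$strand)) |>
    mutate(id = sprintf("mirp-%s-%d", .data$chrom,
                        match(.data$.pre_key, unique(.data$.pre_key)))) |>
    ungroup() |>
    select(-".pre_key") |>
    select("id", dplyr::everything())
  list(calls = calls, rejections = rej)
}

# Overlapping clusters (e.g. the mature-stack and star-stack clusters of
# one hairpin) select near-identical precursor windows and would each emit
# a call; collapse overlapping same-strand precursors to one representative
# (most duplexes, then lowest p-value, then lowest MFE/nt, then 5'-most).
dedupe_calls <- function(calls) {
  if (!nrow(calls)) return(calls)
  pre <- calls |>
    group_by(.data$cluster_id, .data$chrom, .data$strand, .data$pre_start,
             .data$pre_end) |>
    summarise(n_duplex = dplyr::n(), p_value = first(.data$p_value),
              mfe_per_nt = first(.data$mfe_per_nt), .groups = "drop") |>
    arrange(.data$chrom, .data$strand, .data$pre_start, .data$pre_end)
  pre <- pre |>
    group_by(.data$chrom, .data$strand) |>
    mutate(.ovl = cumsum(is.na(lag(.data$pre_end)) |
                           .data$pre_start >=
                             cummax(dplyr::coalesce(lag(.data$pre_end),
                                                    0L)))) |>
    ungroup()
  keep <- pre |>
    group_by(.data$chrom, .data$strand, .data$.ovl) |>
    arrange(desc(.data$n_duplex), .data$p_value, .data$mfe_per_nt,
            .data$pre_start, .data$pre_end, .data$cluster_id,
            .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup()
  dplyr::semi_join(calls, keep,
                   by = c("cluster_id", "chrom", "strand", "pre_start",
                          "pre_end"))
}

empty_calls <- function() {
  bind_cols(
    tibble(cluster_id = character(), chrom = character(),
           strand = character(), pre_start = integer(), pre_end = integer(),
           structure = character(), mfe = numeric(), mfe_per_nt = numeric(),
           p_value = numeric(), n_term = integer(), l_ds_max = integer(),
           unique_optimum = logical()),
    empty_duplexes(),
    tibble(mature_start = integer(), mature_end = integer(),
           star_start = integer(), star_end = integer())
  )
}

#' Run the full precursor-calling pipeline in memory
#'
#' Chains cluster definition, structure analysis with significance testing,
#' and coverage-based verification. Equivalent to [run_stage()] `"full"`
#' without file intermediates.
#'
#' @param genome `DNAStringSet` from [read_genome()].
#' @param reads Read tibble from [read_alignments()].
#' @param config `hairpin_config`.
#' @param verify_reads Reads used for the verification stage; defaults to
#'   `reads`, but an independent alignment may be supplied.
#' @param engine [fold_engine()].
#' @return A `hairpin_result` object: list with `clusters`, `candidates`,
#'   `calls`, `rejections`, `config`.
#' @export
run_pipeline <- function(genome, reads, config, verify_reads = reads,
                         engine = fold_engine(config$fold_backend)) {
  clusters <- define_clusters(reads, genome, config)
  candidates <- fold_clusters(clusters, genome, config, engine)
  ver <- verify_candidates(candidates, verify_reads, config)
  structure(
    list(clusters = clusters, candidates = candidates, calls = ver$calls,
         rejections = ver$rejections, config = config),
    class = "hairpin_result"
  )
}

#' @export
print.hairpin_result <- function(x, ...) {
  cat("<hairpin_result>\n")
  cat("  clusters:   ", nrow(x$clusters), "\n")
  cat("  candidates: ", nrow(x$candidates),
      sprintf("(%d pass structure, %d significant)",
              sum(x$candidates$structure_pass),
              sum(x$candidates$sig_pass, na.rm = TRUE)), "\n")
  cat("  precursors: ", length(unique(x$calls$id)), "called;",
      nrow(x$calls), "mature/star duplexes\n")
  invisible(x)
}

#' Run one pipeline stage with file intermediates
#'
#' Each stage serializes its result to a plain-text file in `out_dir`, so
#' any later stage can restart from it: `cluster` writes `clusters.tsv`,
#' `fold` writes `candidates.tsv`, `coverage` writes `calls.csv`,
#' `rejections.csv`, `calls.bed`, `calls.gtf` and `report.json`. `full`
#' chains all three. The verification stage accepts its own SAM file
#' (`verify_sam`), which may differ from the clustering alignment.
#'
#' @param stage One of `"cluster"`, `"fold"`, `"coverage"`, `"full"`.
#' @param config `hairpin_config`.
#' @param genome_path FASTA reference.
#' @param sam_path SAM alignments (clustering).
#' @param out_dir Output/intermediate directory (created if needed).
#' @param verify_sam Optional independent SAM for verification; defaults to
#'   `sam_path`.
#' @return Invisibly, the paths written by the stage (named character
#'   vector); `"coverage"` and `"full"` also attach the `hairpin_result`-like
#'   call table as attribute `"calls"`.
#' @export
run_stage <- function(stage = c("full", "cluster", "fold", "coverage"),
                      config, genome_path, sam_path, out_dir,
                      verify_sam = sam_path) {
  stage <- match.arg(stage)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- read_genome(genome_path)
  engine <- fold_engine(config$fold_backend)

  cluster_file <- file.path(out_dir, .stage_files$cluster)
  cand_file <- file.path(out_dir, .stage_files$fold)

  written <- character(0)
  if (stage %in% c("cluster", "full")) {
    reads <- read_alignments(sam_path, genome)
    clusters <- define_clusters(reads, genome, config)
    readr::write_tsv(clusters, cluster_file)
    written["clusters"] <- cluster_file
  }
  if (stage %in% c("fold", "full")) {
    if (!file.exists(cluster_file)) {
      stop("cluster intermediate '", cluster_file,
           "' not found: run the 'cluster' stage first", call. = FALSE)
    }
    clusters <- readr::read_tsv(cluster_file, show_col_types = FALSE,
                                col_types = readr::cols(
                                  chrom = "c", strand = "c", id = "c"))
    candidates <- fold_clusters(clusters, genome, config, engine)
    readr::write_tsv(candidates, cand_file)
    written["candidates"] <- cand_file
  }
  if (stage %in% c("coverage", "full")) {
    if (!file.exists(cand_file)) {
      stop("fold intermediate '", cand_file,
           "' not found: run the 'fold' stage first", call. = FALSE)
    }
    candidates <- readr::read_tsv(cand_file, show_col_types = FALSE,
                                  col_types = readr::cols(
                                    chrom = "c", strand = "c",
                                    cluster_id = "c", sequence = "c",
                                    structure = "c", filter_reasons = "c"))
    vreads <- read_alignments(verify_sam, genome)
    ver <- verify_candidates(candidates, vreads, config)
    paths <- write_outputs(ver$calls, ver$rejections, out_dir)
    written <- c(written, paths)
    attr(written, "calls") <- ver$calls
  }
  invisible(written)
}
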