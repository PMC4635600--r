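#' Pair table of a dot-bracket structure
#'
#' @param structure Dot-bracket string over `"()."`.
#' @return Integer vector `p` with `p[i]` the 1-based partner of position
#'   `i`, or `NA` if unpaired. Involution holds: `p[p[i]] == i`.
#' @export
pair_table <- function(structure) {
  chars <- strsplit(structure, "")[[1]]
  if (any(!chars %in% c("(", ")", "."))) {
    stop("structure must use the '(', ')', '.' alphabet", call. = FALSE)
  }
  n <- length(chars)
  partner <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (!length(stack)) stop("unbalanced structure", call. = FALSE)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced structure", call. = FALSE)
  partner
}

#' Count terminal (hairpin) loops
#'
#' N_term is the number of hairpin loops: occurrences of an opening bracket
#' followed, ignoring dots, immediately by a closing bracket. For nested
#' structures this equals the number of leaves of the structure tree.
#'
#' @param structure Dot-bracket string (balanced).
#' @return Integer count.
#' @examples
#' count_terminal_loops("((((...))))")      # 1
#' count_terminal_loops("((..))..((...))")  # 2
#' @export
count_terminal_loops <- function(structure) {
  pair_table(structure)  # validates balance/alphabet
  stringr::str_count(structure, "\\(\\.*\\)")
}

#' Longest double-stranded segment allowing interruptions
#'
#' L_ds,max is the maximum length, in nucleotides and counting
#' interruptions, of a contiguous run of positions on either strand of a
#' helix such that (i) the first and last run positions are paired, (ii) the
#' partners of the paired positions are strictly progressing (one helix, no
#' crossing), all on the same side of the run, and (iii) at most
#' `max_interruptions` defects occur, where each unpaired position and each
#' partner-strand discontinuity between consecutive paired positions counts
#' as one defect.
#'
#' @param structure Dot-bracket string (balanced).
#' @param max_interruptions Maximum number of defects (default 2, the
#'   "two mismatches" convention).
#' @return Integer length in nt (0 for a structure without pairs).
#' @examples
#' longest_duplex("((((.((((....))))))))")  # 9
#' @export
longest_duplex <- function(structure, max_interruptions = 2L) {
  partner <- pair_table(structure)
  n <- length(partner)
  best <- 0L
  for (side in c("5p", "3p")) {
    for (i in seq_len(n)) {
      if (is.na(partner[i])) next
      if (side == "5p" && partner[i] < i) next
      if (side == "3p" && partner[i] > i) next
      defects <- 0L
      last_partner <- partner[i]
      j <- i
      while (j <= n) {
        if (is.na(partner[j])) {
          if (j > i) defects <- defects + 1L
        } else {
          ok_side <- if (side == "5p") partner[j] > j else partner[j] < j
          if (j > i) {
            if (!ok_side || partner[j] >= last_partner) break
            if (last_partner - partner[j] > 1L) defects <- defects + 1L
            last_partner <- partner[j]
          }
          if (defects > max_interruptions) break
          best <- max(best, j - i + 1L)
        }
        if (defects > max_interruptions) break
        j <- j + 1L
      }
    }
  }
  as.integer(best)
}

#' Structure statistics of a folded candidate
#'
#' @param structure Dot-bracket string.
#' @return One-row tibble: `n_term`, `l_ds_max`, `paired_fraction`, `length`.
#' @export
structure_stats <- function(structure) {
  partner <- pair_table(structure)
  tibble(
    n_term = count_terminal_loops(structure),
    l_ds_max = longest_duplex(structure),
    paired_fraction = if (length(partner)) mean(!is.na(partner)) else 0,
    length = length(partner)
  )
}

#' Enumerate candidate precursor windows of a cluster
#'
#' Window start positions run over the 5' flank (`[flank_start,
#' contig start]`) and end positions over the 3' flank (`[contig end,
#' flank_end]`), each stepped by `step`; the grid always includes both
#' anchor coordinates. Windows shorter than `2 * min_duplex_length` are
#' skipped. Coordinates are genomic; for minus-strand clusters the folded
#' sequence is the reverse complement, so flank roles follow the precursor's
#' own 5'/3' orientation in sequence space while the grid stays in genomic
#' coordinates.
#'
#' @param cluster One-row tibble from [define_clusters()].
#' @param step Grid step in nt (>= 1).
#' @param min_duplex_length Lower bound used for the minimum window length.
#' @return Tibble of windows: `start`, `end` (0-based half-open, genomic).
#' @export
enumerate_windows <- function(cluster, step, min_duplex_length = 20L) {
  stopifnot(nrow(cluster) == 1, step >= 1)
  starts <- sort(unique(c(seq(cluster$flank_start, cluster$start, by = step),
                          cluster$start)))
  ends <- sort(unique(c(seq(cluster$end, cluster$flank_end, by = step),
                        cluster$flank_end)))
  grid <- tidyr::expand_grid(start = as.integer(starts),
                             end = as.integer(ends))
  filter(grid, .data$end - .data$start >= 2L * min_duplex_length)
}

#' Fold all candidate windows of a cluster
#'
#' Enumerates the window grid of [enumerate_windows()] at `config$window_step`
#' and folds every window. Clusters whose flank span exceeds 3000 nt are
#' skipped with a warning (cost guard).
#'
#' @param cluster One-row cluster tibble.
#' @param genome `DNAStringSet`.
#' @param config `hairpin_config`.
#' @param engine [fold_engine()].
#' @param step Grid step; defaults to `config$window_step`.
#' @return Tibble of fold candidates: `cluster_id`, `start`, `end`,
#'   `strand`, `length`, `sequence`, `structure`, `mfe`, `mfe_per_nt`.
#' @export
enumerate_candidates <- function(cluster, genome, config,
                                 engine = fold_engine(config$fold_backend),
                                 step = config$window_step) {
  empty <- tibble(cluster_id = character(), start = integer(),
                  end = integer(), strand = character(), length = integer(),
                  sequence = character(), structure = character(),
                  mfe = numeric(), mfe_per_nt = numeric())
  if (cluster$flank_end - cluster$flank_start > 3000L) {
    warning("cluster ", cluster$id, " flank span exceeds 3000 nt; skipped",
            call. = FALSE)
    return(empty)
  }
  windows <- enumerate_windows(cluster, step, config$min_duplex_length)
  fold_windows(windows, cluster, genome, config, engine)
}

fold_windows <- function(windows, cluster, genome, config, engine) {
  if (!nrow(windows)) {
    return(tibble(cluster_id = character(), start = integer(),
                  end = integer(), strand = character(), length = integer(),
                  sequence = character(), structure = character(),
                  mfe = numeric(), mfe_per_nt = numeric()))
  }
  seqs <- purrr::map2_chr(windows$start, windows$end, function(a, b) {
    fetch_sequence(genome, cluster$chrom, a, b, cluster$strand)
  })
  folded <- rna_fold(seqs, engine, workers = config$worker_count)
  tibble(
    cluster_id = cluster$id,
    start = windows$start,
    end = windows$end,
    strand = cluster$strand,
    length = windows$end - windows$start,
    sequence = folded$sequence,
    structure = folded$structure,
    mfe = folded$mfe,
    mfe_per_nt = folded$mfe_per_nt
  )
}

#' Select the optimal fold candidate
#'
#' Picks the candidate minimising MFE/nt. Deterministic tie-break: lower
#' MFE/nt, then longer window, then smaller genomic start. If any other
#' candidate covering a different genomic interval lies within
#' `tolerance` kcal/mol/nt of the minimum, the winner is flagged
#' `unique_optimum = FALSE` (recorded, not rejected).
#'
#' @param candidates Candidate tibble from [enumerate_candidates()].
#' @param tolerance Uniqueness tolerance in kcal/mol/nt.
#' @return One-row tibble (the winner) with an added `unique_optimum`
#'   column, or a zero-row tibble if `candidates` is empty.
#' @export
select_optimal <- function(candidates, tolerance = 0.01) {
  if (!nrow(candidates)) {
    return(mutate(candidates, unique_optimum = logical(0)))
  }
  ordered <- arrange(candidates, .data$mfe_per_nt, desc(.data$length),
                     .data$start)
  winner <- ordered[1, ]
  rivals <- filter(
    candidates,
    .data$mfe_per_nt <= winner$mfe_per_nt + tolerance,
    .data$start != winner$start | .data$end != winner$end
  )
  mutate(winner, unique_optimum = nrow(rivals) == 0L)
}

#' Coarse-to-fine optimal window search for one cluster
#'
#' Folds the coarse window grid (`window_step`), then refines the grid at
#' `window_refine_step` resolution within one coarse step of the winning
#' boundaries, and selects the optimum over everything folded.
#'
#' @inheritParams enumerate_candidates
#' @return As [select_optimal()]; zero-row tibble when the cluster yields
#'   no candidate windows.
#' @export
select_precursor_window <- function(cluster, genome, config,
                                    engine = fold_engine(config$fold_backend)) {
  coarse <- enumerate_candidates(cluster, genome, config, engine)
  if (!nrow(coarse)) return(select_optimal(coarse))
  best <- select_optimal(coarse, config$uniqueness_tolerance)
  fine_step <- config$window_refine_step
  if (fine_step >= 1L && fine_step < config$window_step) {
    lo_s <- max(cluster$flank_start, best$start - config$window_step)
    hi_s <- min(cluster$start, best$start + config$window_step)
    lo_e <- max(cluster$end, best$end - config$window_step)
    hi_e <- min(cluster$flank_end, best$end + config$window_step)
    fine <- tidyr::expand_grid(
      start = as.integer(seq(lo_s, hi_s, by = fine_step)),
      end = as.integer(seq(lo_e, hi_e, by = fine_step))
    ) |>
      filter(.data$end - .data$start >= 2L * config$min_duplex_length) |>
      dplyr::anti_join(coarse, by = c("start", "end"))
    fine_cand <- fold_windows(fine, cluster, genome, config, engine)
    coarse <- bind_rows(coarse, fine_cand)
  }
  select_optimal(coarse, config$uniqueness_tolerance)
}

#' Apply secondary-structure filters to a selected candidate
#'
#' A candidate passes when `mfe_per_nt <= min_mfe_per_nt`, the number of
#' terminal loops satisfies `n_term < max_hairpin_count`, and the longest
#' double-stranded segment satisfies `l_ds_max >= min_double_strand_length`.
#' Statistics are returned for reporting whether or not the candidate
#' passes; failure reasons are enumerated in `filter_reasons`.
#'
#' @param candidate One-row candidate tibble (needs `structure` and
#'   `mfe_per_nt`).
#' @param config `hairpin_config`.
#' @return The input row with `n_term`, `l_ds_max`, `paired_fraction`,
#'   `structure_pass` (logical) and `filter_reasons` (string, `""` on pass)
#'   appended.
#' @export
apply_structure_filters <- function(candidate, config) {
  stopifnot(nrow(candidate) == 1)
  stats <- structure_stats(candidate$structure)
  reasons <- character(0)
  if (!(candidate$mfe_per_nt <= config$min_mfe_per_nt)) {
    reasons <- c(reasons, "mfe_per_nt")
  }
  if (!(stats$n_term < config$max_hairpin_count)) {
    reasons <- c(reasons, "hairpin count")
  }
  if (!(stats$l_ds_max >= config$min_double_strand_length)) {
    reasons <- c(reasons, "double-strand length")
  }
  mutate(candidate,
         n_term = stats$n_term,
         l_ds_max = stats$l_ds_max,
         paired_fraction = stats$paired_fraction,
         structure_pass = length(reasons) == 0L,
         filter_reasons = paste(reasons, collapse = ";"))
}

#' Profile precursor sequences (feature distributions)
#'
#' Folds each sequence of a FASTA file (for example a miRBase precursor
#' export) and reports the per-precursor features used to calibrate the
#' structure filters: MFE/nt, longest double-stranded segment and length.
#' Sequences failing the folding preconditions (shorter than 10 nt or with
#' characters outside ACGTU/N) are skipped with a message.
#'
#' @param path FASTA file of precursor sequences.
#' @param engine [fold_engine()].
#' @param workers Parallel workers for folding.
#' @return Tibble: `name`, `length`, `mfe`, `mfe_per_nt`, `l_ds_max`,
#'   `n_term`, `paired_fraction`; one row per folded sequence.
#' @export
profile_precursors <- function(path, engine = fold_engine(), workers = 1L) {
  raw <- Biostrings::readBStringSet(path)
  nms <- sub("\\s.*$", "", names(raw))
  seqs <- chartr("U", "T", toupper(as.character(raw)))
  ok <- nchar(seqs) >= 10L & !grepl("[^ACGTN]", seqs)
  if (any(!ok)) {
    message(sum(!ok), " sequence(s) skipped (too short or bad alphabet)")
  }
  seqs <- seqs[ok]
  nms <- nms[ok]
  if (!length(seqs)) {
    return(tibble(name = character(), length = integer(), mfe = numeric(),
                  mfe_per_nt = numeric(), l_ds_max = integer(),
                  n_term = integer(), paired_fraction = numeric()))
  }
  folded <- rna_fold(seqs, engine, workers = workers)
  stats <- purrr::map(folded$structure, structure_stats) |> bind_rows()
  tibble(
    name = nms,
    length = unname(nchar(seqs)),
    mfe = folded$mfe,
    mfe_per_nt = folded$mfe_per_nt,
    l_ds_max = stats$l_ds_max,
    n_term = stats$n_term,
    paired_fraction = stats$paired_fraction
  )
}
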