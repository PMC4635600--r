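#' Detect candidate mature miRNA loci from read stacks
#'
#' Dicer-like processing produces reads with homogeneous ends, so mature
#' loci appear as sharp stacks: reads sharing exact genomic start and end.
#' Reads intersecting the precursor are grouped into stacks (optionally
#' merging stacks whose ends differ by at most `config$edge_tolerance` nt
#' into the strongest stack); a stack is a candidate mature locus iff its
#' share of all precursor-mapped read multiplicity is strictly greater than
#' `min_coverage` and its length satisfies
#' `min_duplex_length <= L < max_duplex_length`. Overlapping lower-support
#' stacks are suppressed greedily (by support, ties to the 5'-most on the
#' precursor); multiple disjoint accepted stacks yield a multi-mature
#' precursor.
#'
#' @param reads Read tibble (same strand as the precursor).
#' @param precursor One-row tibble with `chrom`, `strand`, `start`, `end`
#'   (genomic, 0-based half-open).
#' @param config `hairpin_config`.
#' @return Tibble of mature loci, precursor-relative 0-based half-open
#'   coordinates on the precursor's own strand: `rel_start`, `rel_end`,
#'   `length`, `read_support`, `support_fraction`, `accepted`,
#'   `reject_reason` (empty for accepted loci), sorted by decreasing
#'   support. Zero rows when no reads intersect the precursor.
#' @export
detect_mature_loci <- function(reads, precursor, config) {
  stopifnot(nrow(precursor) == 1)
  empty <- tibble(rel_start = integer(), rel_end = integer(),
                  length = integer(), read_support = integer(),
                  support_fraction = numeric(), accepted = logical(),
                  reject_reason = character())
  hits <- filter(reads,
                 .data$chrom == precursor$chrom,
                 .data$strand == precursor$strand,
                 .data$start < precursor$end,
                 .data$end > precursor$start)
  if (!nrow(hits)) return(empty)
  total <- sum(hits$mult)

  stacks <- hits |>
    group_by(.data$start, .data$end) |>
    summarise(read_support = sum(.data$mult), .groups = "drop")

  if (config$edge_tolerance > 0L && nrow(stacks) > 1L) {
    stacks <- merge_near_stacks(stacks, config$edge_tolerance)
  }

  # precursor-relative, 5'->3' on the precursor strand
  if (precursor$strand == "+") {
    stacks <- mutate(stacks,
                     rel_start = .data$start - precursor$start,
                     rel_end = .data$end - precursor$start)
  } else {
    stacks <- mutate(stacks,
                     rel_start = precursor$end - .data$end,
                     rel_end = precursor$end - .data$start)
  }

  loci <- stacks |>
    mutate(length = .data$rel_end - .data$rel_start,
           support_fraction = .data$read_support / total) |>
    arrange(desc(.data$read_support), .data$rel_start) |>
    mutate(reject_reason = dplyr::case_when(
      support_fraction <= config$min_coverage ~ "coverage fraction",
      length < config$min_duplex_length |
        length >= config$max_duplex_length ~ "mature length",
      rel_start < 0 | rel_end > precursor$end - precursor$start ~
        "outside precursor",
      TRUE ~ ""
    ))

  # greedy suppression of overlapping lower-support stacks
  accepted <- logical(nrow(loci))
  taken <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(loci))) {
    if (nzchar(loci$reject_reason[i])) next
    overlaps <- nrow(taken) > 0 &&
      any(loci$rel_start[i] < taken[, 2] & loci$rel_end[i] > taken[, 1])
    if (overlaps) {
      loci$reject_reason[i] <- "overlaps stronger locus"
    } else {
      accepted[i] <- TRUE
      taken <- rbind(taken, c(loci$rel_start[i], loci$rel_end[i]))
    }
  }
  mutate(loci, accepted = accepted) |>
    select("rel_start", "rel_end", "length", "read_support",
           "support_fraction", "accepted", "reject_reason")
}

merge_near_stacks <- function(stacks, tol) {
  stacks <- arrange(stacks, desc(.data$read_support), .data$start)
  out <- stacks[0, ]
  for (i in seq_len(nrow(stacks))) {
    j <- which(abs(out$start - stacks$start[i]) <= tol &
                 abs(out$end - stacks$end[i]) <= tol)
    if (length(j)) {
      out$read_support[j[1]] <- out$read_support[j[1]] +
        stacks$read_support[i]
    } else {
      out <- bind_rows(out, stacks[i, ])
    }
  }
  arrange(out, desc(.data$read_support), .data$start)
}

#' Compute the star segment of a mature locus
#'
#' Dicer-like cleavage leaves 2-nt 3' overhangs on both strands of the
#' mature/star duplex. With the mature locus at inclusive precursor-relative
#' positions `(m5, m3)`, the star 5' end is the partner of `m3 - 2` and the
#' star 3' end is `partner(m5) + 2`. When an anchor position is unpaired,
#' the nearest paired position up to 3 nt inward substitutes; anchors
#' unpaired beyond that (for example a mature locus spanning the terminal
#' loop) yield a `"no star"` failure.
#'
#' @param mature One-row tibble with `rel_start`, `rel_end` (0-based
#'   half-open, precursor-relative).
#' @param partner Pair table of the precursor structure ([pair_table()]).
#' @param config `hairpin_config` (star length bounds).
#' @return List: `ok` (logical), `reason` (failure name or `""`),
#'   `star_start`, `star_end` (0-based half-open) and `length` when `ok`.
#' @export
compute_star <- function(mature, partner, config) {
  n <- length(partner)
  m5 <- mature$rel_start + 1L            # 1-based inclusive
  m3 <- mature$rel_end                   # 1-based inclusive
  fail <- function(reason) list(ok = FALSE, reason = reason,
                                star_start = NA_integer_,
                                star_end = NA_integer_,
                                length = NA_integer_)
  if (m5 < 1L || m3 > n) return(fail("mature outside precursor"))

  anchor_in <- function(pos, dir) {
    # nearest paired position within 3 nt inward (dir +1 from the 5' end,
    # -1 from the 3' end of the mature locus)
    for (k in 0:3) {
      q <- pos + dir * k
      if (q >= 1L && q <= n && !is.na(partner[q])) return(q)
    }
    NA_integer_
  }
  a3 <- anchor_in(m3 - 2L, -1L)
  a5 <- anchor_in(m5, 1L)
  if (is.na(a3) || is.na(a5)) return(fail("no star"))

  star5 <- partner[a3]                   # 1-based inclusive
  star3 <- partner[a5] + 2L              # 1-based inclusive
  if (star5 > star3) return(fail("no star"))
  if (star5 < 1L || star3 > n) return(fail("star outside precursor"))
  star_start <- star5 - 1L               # 0-based half-open
  star_end <- star3
  if (star_start < mature$rel_end && star_end > mature$rel_start) {
    return(fail("star overlaps mature"))
  }
  len <- star_end - star_start
  if (len < config$min_duplex_length || len >= config$max_duplex_length) {
    return(fail("star length"))
  }
  list(ok = TRUE, reason = "", star_start = star_start,
       star_end = star_end, length = len)
}

#' Validate a mature/star duplex against processing-accuracy rules
#'
#' Checks, each recorded by name:
#' \describe{
#'   \item{paired_fraction}{fraction of paired nucleotides over the mature
#'     positions `>= min_paired_fraction`.}
#'   \item{fold_back}{no mature position pairs with another position inside
#'     the mature locus.}
#'   \item{interior_mismatches}{if `allow_three_mismatches`: every maximal
#'     run of adjacent unpaired mature positions lying fully inside 1-based
#'     positions `3 .. L-3` is shorter than 4 nt.}
#'   \item{terminal_mismatches}{if `allow_two_terminal_mismatches`: maximal
#'     unpaired runs touching the first two or last three duplex positions
#'     (1-based `1..2` and `L-2..L`) are shorter than 3 nt.}
#'   \item{mature_length, star_length}{half-open duplex length bounds on
#'     both arms.}
#' }
#'
#' @param mature One-row mature-locus tibble.
#' @param star Result of [compute_star()].
#' @param partner Pair table of the precursor structure.
#' @param config `hairpin_config`.
#' @return One-row tibble of named logical verdicts plus `duplex_pass`.
#' @export
validate_duplex <- function(mature, star, partner, config) {
  m_idx <- (mature$rel_start + 1L):mature$rel_end    # 1-based inclusive
  L <- length(m_idx)
  p <- partner[m_idx]
  paired <- !is.na(p)

  chk_paired <- mean(paired) >= config$min_paired_fraction
  chk_foldback <- !any(paired & p >= m_idx[1] & p <= m_idx[L])

  runs <- rle(!paired)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L           # mature-relative 1-based
  unpaired_runs <- which(runs$values)

  chk_interior <- TRUE
  chk_terminal <- TRUE
  for (r in unpaired_runs) {
    s <- run_start[r]; e <- run_end[r]; len <- runs$lengths[r]
    touches_terminal <- s <= 2L || e >= L - 2L
    if (touches_terminal) {
      if (config$allow_two_terminal_mismatches && len >= 3L) {
        chk_terminal <- FALSE
      }
    } else if (s >= 3L && e <= L - 3L) {
      if (config$allow_three_mismatches && len >= 4L) {
        chk_interior <- FALSE
      }
    }
  }

  chk_mlen <- mature$length >= config$min_duplex_length &&
    mature$length < config$max_duplex_length
  chk_slen <- isTRUE(star$ok)

  tibble(
    paired_fraction_ok = chk_paired,
    no_fold_back = chk_foldback,
    interior_mismatches_ok = chk_interior,
    terminal_mismatches_ok = chk_terminal,
    mature_length_ok = chk_mlen,
    star_ok = chk_slen,
    duplex_pass = chk_paired && chk_foldback && chk_interior &&
      chk_terminal && chk_mlen && chk_slen
  )
}

#' Verify a candidate precursor from read coverage
#'
#' Runs mature-locus detection, star computation and duplex validation for
#' a candidate that already passed the structure filters and the
#' significance test. The reads may come from an alignment independent of
#' the one used for clustering (cross-verification). A precursor call is
#' emitted iff at least one duplex passes every enabled check; no minimum
#' expression is imposed on the star segment. Accepted duplexes may not
#' overlap each other (greedy acceptance by mature support).
#'
#' @param candidate One-row candidate tibble (columns `cluster_id`,
#'   `chrom`, `start`, `end`, `strand`, `structure`, ...).
#' @param reads Read tibble used for verification.
#' @param config `hairpin_config`.
#' @return List with `called` (logical), `duplexes` (tibble of passing
#'   duplexes: mature/star precursor-relative and genomic coordinates,
#'   support, arm, verdicts) and `rejections` (tibble naming the first
#'   failed criterion per rejected mature locus).
#' @export
verify_precursor <- function(candidate, reads, config) {
  stopifnot(nrow(candidate) == 1)
  partner <- pair_table(candidate$structure)
  precursor <- tibble(chrom = candidate$chrom, strand = candidate$strand,
                      start = candidate$start, end = candidate$end)
  loci <- detect_mature_loci(reads, precursor, config)

  rejections <- tibble(rel_start = integer(), rel_end = integer(),
                       reason = character())
  duplexes <- list()
  taken <- matrix(numeric(0), ncol = 2)

  reject <- function(locus, reason) {
    bind_rows(rejections, tibble(rel_start = locus$rel_start,
                                 rel_end = locus$rel_end, reason = reason))
  }

  if (!nrow(loci)) {
    return(list(called = FALSE, duplexes = empty_duplexes(),
                rejections = tibble(rel_start = NA_integer_,
                                    rel_end = NA_integer_,
                                    reason = "no reads in precursor")))
  }

  for (i in seq_len(nrow(loci))) {
    locus <- loci[i, ]
    if (!locus$accepted) {
      rejections <- reject(locus, locus$reject_reason)
      next
    }
    star <- compute_star(locus, partner, config)
    if (!star$ok) {
      rejections <- reject(locus, star$reason)
      next
    }
    checks <- validate_duplex(locus, star, partner, config)
    if (!checks$duplex_pass) {
      failed <- names(checks)[!unlist(checks)][1]
      rejections <- reject(locus, failed)
      next
    }
    # neither arm of the duplex may overlap an already-accepted duplex
    arms <- rbind(c(locus$rel_start, locus$rel_end),
                  c(star$star_start, star$star_end))
    if (nrow(taken) > 0 &&
        any(outer(arms[, 1], taken[, 2], `<`) &
              outer(arms[, 2], taken[, 1], `>`))) {
      rejections <- reject(locus, "overlaps accepted duplex")
      next
    }
    taken <- rbind(taken, arms)
    duplexes[[length(duplexes) + 1L]] <- bind_cols(
      tibble(
        mature_rel_start = locus$rel_start, mature_rel_end = locus$rel_end,
        mature_length = locus$length, read_support = locus$read_support,
        support_fraction = locus$support_fraction,
        star_rel_start = star$star_start, star_rel_end = star$star_end,
        star_length = star$length,
        arm = assign_arm(locus, candidate$structure)
      ),
      checks
    )
  }

  duplexes <- if (length(duplexes)) bind_rows(duplexes) else empty_duplexes()
  list(called = nrow(duplexes) > 0, duplexes = duplexes,
       rejections = rejections)
}

empty_duplexes <- function() {
  tibble(mature_rel_start = integer(), mature_rel_end = integer(),
         mature_length = integer(), read_support = integer(),
         support_fraction = numeric(), star_rel_start = integer(),
         star_rel_end = integer(), star_length = integer(),
         arm = character(), paired_fraction_ok = logical(),
         no_fold_back = logical(), interior_mismatches_ok = logical(),
         terminal_mismatches_ok = logical(), mature_length_ok = logical(),
         star_ok = logical(), duplex_pass = logical())
}

# 5p if the mature midpoint precedes the midpoint of the first hairpin loop
assign_arm <- function(locus, structure) {
  loop <- stringr::str_locate(structure, "\\(\\.*\\)")
  if (anyNA(loop)) return("5p")
  loop_mid <- (loop[1, "start"] + loop[1, "end"]) / 2
  mature_mid <- (locus$rel_start + locus$rel_end + 1) / 2
  if (mature_mid < loop_mid) "5p" else "3p"
}
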