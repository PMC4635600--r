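#' Construct a synthetic hairpin precursor with known geometry
#'
#' Builds a GC-biased random 5' arm, a loop, and the reverse complement of
#' the arm with `n_defects` random point substitutions as the 3' arm. The
#' mature locus sits on the 5' arm at `mature_offset`; the star locus is
#' derived from the perfect-pairing geometry with the 2-nt 3' overhang rule,
#' so [compute_star()] applied to the constructed pair table returns it
#' exactly. The by-construction dot-bracket pairs position `i` with
#' `L - 1 - i` across the arms (defect positions unpaired).
#'
#' @param arm_length Arm length in nt (>= mature_offset + mature_length + 2).
#' @param loop_length Loop length in nt (>= 3).
#' @param n_defects Point substitutions in the 3' arm; at most
#'   `arm_length %/% 4` (beyond that the duplex geometry is infeasible).
#' @param mature_length Mature locus length (default 21 nt).
#' @param mature_offset 0-based offset of the mature locus on the 5' arm
#'   (default 5; must be >= 2 so the star 3' overhang stays inside).
#' @param gc GC fraction of the arm (default 0.6, miRNA stems are GC-richer
#'   than bulk genome).
#' @return List: `sequence`, `length`, `mature` (c(start, end), 0-based
#'   half-open, precursor-relative), `star` (likewise), `structure`
#'   (by-construction dot-bracket), `defect_positions` (3' arm, 0-based).
#' @export
make_precursor <- function(arm_length, loop_length, n_defects = 0L,
                           mature_length = 21L, mature_offset = 5L,
                           gc = 0.6) {
  if (loop_length < 3L) stop("loop_length must be >= 3", call. = FALSE)
  if (mature_offset < 2L) stop("mature_offset must be >= 2", call. = FALSE)
  if (arm_length < mature_offset + mature_length + 2L) {
    stop("infeasible geometry: arm too short for the mature locus",
         call. = FALSE)
  }
  if (n_defects > arm_length %/% 4L) {
    stop("infeasible geometry: defects exceed the pairing budget",
         call. = FALSE)
  }
  base_probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  arm <- sample(names(base_probs), arm_length, replace = TRUE,
                prob = base_probs)
  loop <- sample(c("A", "C", "G", "T"), loop_length, replace = TRUE)
  arm3 <- rev(vapply(arm, function(b) chartr("ACGT", "TGCA", b),
                     character(1)))
  total <- 2L * arm_length + loop_length

  # protect the mature-partner/star span from defects so the constructed
  # duplex always satisfies the processing-accuracy checks
  mature <- c(mature_offset, mature_offset + mature_length)
  star_start <- total - mature[2] + 2L               # partner(m3-2)
  star_end <- total - mature[1] + 2L                 # partner(m5)+2, half-open
  prot_lo <- min(total - mature[2], star_start)
  prot_hi <- max(total - mature[1], star_end)
  # positions on the 3' arm, 0-based within the arm
  arm3_pos <- seq_len(arm_length) - 1L
  arm3_genomic <- arm_length + loop_length + arm3_pos
  allowed <- arm3_pos[arm3_genomic < prot_lo | arm3_genomic >= prot_hi]
  defect_positions <- integer(0)
  if (n_defects > 0L) {
    if (length(allowed) < n_defects) {
      stop("infeasible geometry: defects exceed the pairing budget",
           call. = FALSE)
    }
    defect_positions <- sort(sample(allowed, n_defects))
    for (p in defect_positions) {
      cur <- arm3[p + 1L]
      arm3[p + 1L] <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
    }
  }
  seq <- paste(c(arm, loop, arm3), collapse = "")

  db <- rep(".", total)
  arm5_pair <- seq_len(arm_length)
  partner_pos <- total + 1L - arm5_pair
  defect_genomic <- arm_length + loop_length + defect_positions + 1L
  keep <- !(partner_pos %in% defect_genomic)
  db[arm5_pair[keep]] <- "("
  db[partner_pos[keep]] <- ")"

  list(sequence = seq, length = total,
       mature = c(mature[1], mature[2]),
       star = c(star_start, star_end),
       structure = paste(db, collapse = ""),
       defect_positions = defect_positions)
}

#' Build a synthetic genome with implanted precursors
#'
#' Generates a random background genome and implants `n_precursors`
#' hairpins at random, pairwise-disjoint positions separated by at least
#' `spacing` nt (default twice the flank size, so clustering recovers one
#' cluster per expressed locus), on random strands. Minus-strand implants
#' insert the reverse complement, so the precursor reads 5' to 3' on its
#' own strand.
#'
#' @param length Genome length in nt.
#' @param n_precursors Number of implanted hairpins.
#' @param gc Background GC fraction.
#' @param seed Optional seed (`set.seed()` before generation).
#' @param arm_length,loop_length,n_defects,mature_length Passed to
#'   [make_precursor()].
#' @param spacing Minimum distance between implants (default 400 nt).
#' @param chrom Chromosome name (default `"chrS"`).
#' @return A `synthetic_truth` object: list with `genome` (`DNAStringSet`)
#'   and `precursors` (tibble of genomic truth: precursor, mature and star
#'   intervals, strand, sequence, by-construction structure).
#' @export
build_genome <- function(length = 1e5, n_precursors = 20L, gc = 0.5,
                         seed = NULL, arm_length = 60L, loop_length = 8L,
                         n_defects = 1L, mature_length = 21L,
                         spacing = 400L, chrom = "chrS") {
  if (!is.null(seed)) set.seed(seed)
  pre_len <- 2L * arm_length + loop_length
  slot <- pre_len + spacing
  if (n_precursors * slot > length - 2L * spacing) {
    stop("genome too short for ", n_precursors,
         " disjoint implants with the requested spacing", call. = FALSE)
  }
  bases <- c("A", "C", "G", "T")
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  background <- sample(bases, length, replace = TRUE, prob = probs)

  # draw disjoint implant starts: n ordered draws in the shrunken space
  usable <- length - 2L * spacing - n_precursors * slot
  offsets <- if (n_precursors > 0) {
    sort(sample.int(usable + 1L, n_precursors, replace = TRUE) - 1L)
  } else integer(0)
  starts <- spacing + offsets + (seq_len(n_precursors) - 1L) * slot

  rows <- vector("list", n_precursors)
  for (i in seq_len(n_precursors)) {
    p <- make_precursor(arm_length, loop_length, n_defects, mature_length)
    strand <- sample(c("+", "-"), 1L)
    g0 <- starts[i]
    g1 <- g0 + p$length
    ins <- if (strand == "+") p$sequence else revcomp(p$sequence)
    background[(g0 + 1L):g1] <- strsplit(ins, "")[[1]]
    rel2gen <- function(rel) {
      if (strand == "+") g0 + rel else c(g1 - rel[2], g1 - rel[1])
    }
    m <- rel2gen(p$mature); s <- rel2gen(p$star)
    rows[[i]] <- tibble(
      chrom = chrom, strand = strand, start = g0, end = g1,
      mature_start = m[1], mature_end = m[2],
      star_start = s[1], star_end = s[2],
      sequence = p$sequence, structure = p$structure
    )
  }
  precursors <- if (length(rows)) bind_rows(rows) else
    tibble(chrom = character(), strand = character(), start = integer(),
           end = integer(), mature_start = integer(),
           mature_end = integer(), star_start = integer(),
           star_end = integer(), sequence = character(),
           structure = character())
  genome <- Biostrings::DNAStringSet(setNames(paste(background,
                                                    collapse = ""), chrom))
  structure(list(genome = genome, precursors = precursors),
            class = "synthetic_truth")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth>", nrow(x$precursors), "precursors in a",
      sum(Biostrings::width(x$genome)), "nt genome\n")
  invisible(x)
}

#' Simulate small RNA-seq reads from a synthetic truth
#'
#' Mature and star loci produce exact-coordinate read stacks
#' (`mature_depth` and `star_depth` reads each; up to 10% of stack reads
#' are shifted by up to `jitter` nt to mimic imprecise processing).
#' Background degradation is modelled as `background_reads` uniformly
#' placed 18-26 nt reads on random strands outside the implanted loci.
#' Writes a valid SAM file with header, flags, and match-only CIGARs.
#'
#' @param truth `synthetic_truth` from [build_genome()].
#' @param path Output SAM path.
#' @param mature_depth,star_depth Reads per mature / star stack.
#' @param background_reads Total background reads.
#' @param jitter Maximum shift (nt) applied to at most 10% of stack reads;
#'   0 disables jitter.
#' @param seed Optional seed.
#' @return `path`, invisibly; attribute `"n_records"` holds the record
#'   count (`n_precursors * (mature_depth + star_depth) +
#'   background_reads`).
#' @export
simulate_reads <- function(truth, path, mature_depth = 100L,
                           star_depth = 10L, background_reads = 2000L,
                           jitter = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(mature_depth >= 0, star_depth >= 0, background_reads >= 0)
  genome <- truth$genome
  chrom <- names(genome)[1]
  glen <- Biostrings::width(genome)[1]
  pre <- truth$precursors

  stack_reads <- function(s0, s1, strand, depth) {
    if (depth == 0L) return(NULL)
    starts <- rep(s0, depth)
    ends <- rep(s1, depth)
    if (jitter > 0L && depth > 0L) {
      n_jit <- floor(0.10 * depth)
      if (n_jit > 0L) {
        idx <- seq_len(n_jit)  # deterministic subset; shifts are random
        shift <- sample(c(-seq_len(jitter), seq_len(jitter)), n_jit,
                        replace = TRUE)
        starts[idx] <- pmax(0L, pmin(glen - (ends[idx] - starts[idx]),
                                     starts[idx] + shift))
        ends[idx] <- starts[idx] + (s1 - s0)
      }
    }
    tibble(start = starts, end = ends, strand = strand)
  }

  stacks <- list()
  for (i in seq_len(nrow(pre))) {
    stacks[[length(stacks) + 1L]] <-
      stack_reads(pre$mature_start[i], pre$mature_end[i], pre$strand[i],
                  mature_depth)
    stacks[[length(stacks) + 1L]] <-
      stack_reads(pre$star_start[i], pre$star_end[i], pre$strand[i],
                  star_depth)
  }

  if (background_reads > 0L) {
    lens <- sample(18:26, background_reads, replace = TRUE)
    starts <- integer(background_reads)
    implant <- if (nrow(pre)) IRanges::IRanges(pre$start + 1L, pre$end)
      else IRanges::IRanges()
    for (j in seq_len(background_reads)) {
      repeat {
        s <- sample.int(glen - lens[j], 1L) - 1L
        hit <- IRanges::countOverlaps(
          IRanges::IRanges(s + 1L, s + lens[j]), implant)
        if (hit == 0L) break
      }
      starts[j] <- s
    }
    stacks[[length(stacks) + 1L]] <- tibble(
      start = starts, end = starts + lens,
      strand = sample(c("+", "-"), background_reads, replace = TRUE)
    )
  }

  reads <- bind_rows(stacks)
  n_records <- nrow(reads)

  seqs <- substring(as.character(genome[[1]]), reads$start + 1L, reads$end)
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", chrom, glen))
  records <- sprintf("r%d\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
                     seq_len(n_records),
                     ifelse(reads$strand == "-", 16L, 0L),
                     chrom, reads$start + 1L, reads$end - reads$start, seqs)
  writeLines(c(header, records), path)
  invisible(structure(path, n_records = n_records))
}

#' Write a complete synthetic dataset to disk
#'
#' Convenience wrapper producing `genome.fa`, `reads.sam` and `truth.json`
#' in `out_dir` (used by the `simulate` command-line subcommand).
#'
#' @param out_dir Output directory.
#' @param seed Seed for both genome and reads.
#' @param ... Passed to [build_genome()] and [simulate_reads()] (matched by
#'   name).
#' @return Named character vector of the three paths, invisibly.
#' @export
simulate_dataset <- function(out_dir, seed = 42L, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dots <- list(...)
  gb_args <- dots[names(dots) %in% names(formals(build_genome))]
  sr_args <- dots[names(dots) %in% names(formals(simulate_reads))]
  truth <- do.call(build_genome, c(list(seed = seed), gb_args))
  paths <- c(fasta = file.path(out_dir, "genome.fa"),
             sam = file.path(out_dir, "reads.sam"),
             truth = file.path(out_dir, "truth.json"))
  Biostrings::writeXStringSet(truth$genome, paths["fasta"])
  do.call(simulate_reads, c(list(truth = truth, path = paths["sam"]),
                            sr_args))
  jsonlite::write_json(truth$precursors, paths["truth"], digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(paths)
}
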