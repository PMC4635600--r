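# Shared fixtures and independent brute-force oracles.

pairmax <- fold_engine("pairmax")

tiny_config <- function(preset = "plants", ...) {
  load_config(preset = preset, overrides = list(...))
}

write_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  path
}

# Minimal SAM writer: records as list of c(flag, chrom, pos1, cigar)
write_sam <- function(records, path = tempfile(fileext = ".sam"),
                      sq = NULL) {
  header <- character(0)
  if (!is.null(sq)) {
    header <- c("@HD\tVN:1.6",
                sprintf("@SQ\tSN:%s\tLN:%d", names(sq), unname(sq)))
  }
  body <- vapply(seq_along(records), function(i) {
    r <- records[[i]]
    sprintf("r%d\t%s\t%s\t%s\t255\t%s\t*\t0\t0\t*\t*",
            i, r[1], r[2], r[3], r[4])
  }, character(1))
  writeLines(c(header, body), path)
  path
}

# read tibble shortcut
reads_tbl <- function(start, end, strand = "+", mult = 1L,
                      chrom = "chr1") {
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), strand = strand,
                 mult = as.integer(mult))
}

# random balanced dot-bracket via recursive Dyck-with-dots generation;
# independent of any folding engine
random_db <- function(n) {
  if (n == 0L) return("")
  if (n == 1L) return(".")
  if (runif(1) < 0.4) {
    k <- sample.int(n - 1L, 1L) - 1L  # inner size 0..n-2
    paste0("(", random_db(k), ")", random_db(n - 2L - k))
  } else {
    paste0(".", random_db(n - 1L))
  }
}

# oracle: terminal loops = pairs with no paired position strictly inside
bf_terminal_loops <- function(db) {
  p <- pair_table(db)
  n <- length(p)
  leaves <- 0L
  for (i in seq_len(n)) {
    j <- p[i]
    if (is.na(j) || j < i) next
    inner <- if (j - i > 1L) (i + 1L):(j - 1L) else integer(0)
    if (!any(!is.na(p[inner]))) leaves <- leaves + 1L
  }
  leaves
}

# oracle: longest duplex by exhaustive run enumeration with a standalone
# validity predicate (definition-level, no incremental state)
bf_valid_run <- function(p, i, j, max_int) {
  idx <- i:j
  if (is.na(p[i]) || is.na(p[j])) return(FALSE)
  paired <- idx[!is.na(p[idx])]
  partners <- p[paired]
  side <- partners > paired
  if (length(unique(side)) > 1L) return(FALSE)
  if (any(diff(partners) >= 0)) return(FALSE)  # strictly decreasing
  defects <- sum(is.na(p[idx])) +
    sum((partners[-length(partners)] - partners[-1]) > 1L)
  defects <= max_int
}

bf_longest_duplex <- function(db, max_int = 2L) {
  p <- pair_table(db)
  n <- length(p)
  best <- 0L
  for (i in seq_len(n)) {
    if (is.na(p[i])) next
    defects <- 0L
    for (j in i:n) {
      if (is.na(p[j])) defects <- defects + 1L
      if (defects > max_int + 1L) break   # cannot recover; prune only
      if (!is.na(p[j]) && bf_valid_run(p, i, j, max_int)) {
        best <- max(best, j - i + 1L)
      }
    }
  }
  best
}

# oracle: contigs by per-base coverage scan
bf_contigs <- function(reads, min_reads) {
  out <- list()
  for (key in split(seq_len(nrow(reads)),
                    paste(reads$chrom, reads$strand))) {
    df <- reads[key, ]
    maxpos <- max(df$end)
    cov <- integer(maxpos)
    for (r in seq_len(nrow(df))) {
      idx <- (df$start[r] + 1L):df$end[r]
      cov[idx] <- cov[idx] + df$mult[r]
    }
    runs <- rle(cov > 0L)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in which(runs$values)) {
      s0 <- starts[k] - 1L; e0 <- ends[k]
      cnt <- sum(df$mult[df$start < e0 & df$end > s0])
      if (cnt >= min_reads) {
        out[[length(out) + 1L]] <- tibble::tibble(
          chrom = df$chrom[1], strand = df$strand[1],
          start = s0, end = e0, read_count = cnt)
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(chrom = character(), strand = character(),
                          start = integer(), end = integer(),
                          read_count = integer()))
  }
  dplyr::arrange(dplyr::bind_rows(out), chrom, strand, start)
}

# perfect hairpin structure string
perfect_hairpin_db <- function(arm, loop = 4L) {
  paste0(strrep("(", arm), strrep(".", loop), strrep(")", arm))
}

# small synthetic dataset for pipeline-level tests
small_sim <- function(dir, seed = 7L, n = 3L, genome_len = 2e4,
                      background = 150L, ...) {
  simulate_dataset(dir, seed = seed, length = genome_len,
                   n_precursors = n, background_reads = background, ...)
}
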