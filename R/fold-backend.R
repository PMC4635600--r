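#' Choose a secondary-structure folding engine
#'
#' The default engine is ViennaRNA's `RNAfold` command-line program
#' (thermodynamic nearest-neighbour model, energies in kcal/mol), invoked in
#' batch over a temporary FASTA file. A bundled fallback engine
#' (`"pairmax"`, weighted base-pair maximization with per-pair
#' pseudo-energies, implemented in C++) exists so that the package remains
#' fully functional and testable without any external program; its energies
#' are NOT thermodynamic and published thresholds do not apply to them.
#' `"auto"` picks `RNAfold` when it is on the `PATH` and the fallback
#' otherwise.
#'
#' @param backend `"auto"`, `"vienna"` or `"pairmax"`.
#' @return A `fold_engine` object.
#' @export
fold_engine <- function(backend = c("auto", "vienna", "pairmax")) {
  backend <- match.arg(backend)
  if (backend == "auto") {
    backend <- if (nzchar(Sys.which("RNAfold"))) "vienna" else "pairmax"
  }
  if (backend == "vienna" && !nzchar(Sys.which("RNAfold"))) {
    stop("RNAfold not found on PATH; use backend = 'pairmax'", call. = FALSE)
  }
  structure(list(backend = backend), class = "fold_engine")
}

#' @export
print.fold_engine <- function(x, ...) {
  cat("<fold_engine>", x$backend,
      if (x$backend == "pairmax") "(non-thermodynamic fallback)" else "",
      "\n")
  invisible(x)
}

#' Fold RNA sequences to minimum-free-energy structures
#'
#' @param sequences Character vector of sequences (ACGT/U alphabet, at
#'   least 10 nt each; `N` is tolerated and never pairs).
#' @param engine A [fold_engine()]; default `"auto"`.
#' @param workers Number of parallel workers for the folding workload; the
#'   result is identical for any value (sequences are chunked
#'   deterministically and reassembled in input order).
#' @return Tibble with one row per input: `sequence`, `structure`
#'   (dot-bracket, same length as the sequence), `mfe` (kcal/mol; pseudo
#'   units under the fallback engine) and `mfe_per_nt = mfe / nchar`.
#' @examples
#' rna_fold("GGGGCCCCGGGAAAACCCGGGGCCCC", fold_engine("pairmax"))
#' @export
rna_fold <- function(sequences, engine = fold_engine(), workers = 1L) {
  stopifnot(inherits(engine, "fold_engine"))
  if (!length(sequences)) {
    return(tibble(sequence = character(), structure = character(),
                  mfe = numeric(), mfe_per_nt = numeric()))
  }
  seqs <- chartr("u", "U", toupper(sequences))
  seqs <- chartr("U", "T", seqs)
  if (any(nchar(seqs) < 10L)) {
    stop("sequences must be at least 10 nt long", call. = FALSE)
  }
  if (any(grepl("[^ACGTN]", seqs))) {
    stop("sequences must use the ACGT/U (+N) alphabet", call. = FALSE)
  }

  workers <- max(1L, as.integer(workers))
  n <- length(seqs)
  if (workers > 1L && n > 1L && .Platform$OS.type == "unix") {
    chunks <- split(seq_len(n), cut(seq_len(n), min(workers, n),
                                    labels = FALSE))
    parts <- parallel::mclapply(chunks, function(idx) {
      fold_chunk(seqs[idx], engine$backend)
    }, mc.cores = workers)
    out <- bind_rows(parts)
  } else {
    out <- fold_chunk(seqs, engine$backend)
  }
  out$sequence <- unname(seqs)
  out$mfe_per_nt <- out$mfe / unname(nchar(seqs))
  out[, c("sequence", "structure", "mfe", "mfe_per_nt")]
}

fold_chunk <- function(seqs, backend) {
  if (backend == "pairmax") {
    res <- fold_pairmax_cpp(seqs)
    return(tibble(structure = as.character(res$structure),
                  mfe = as.numeric(res$mfe)))
  }
  fold_vienna(seqs)
}

fold_vienna <- function(seqs) {
  fa <- tempfile(fileext = ".fa")
  on.exit(unlink(fa), add = TRUE)
  writeLines(paste0(">s", seq_along(seqs), "\n", seqs), fa)
  out <- suppressWarnings(
    system2("RNAfold", c("--noPS", "-i", shQuote(fa)), stdout = TRUE)
  )
  status <- attr(out, "status") %||% 0L
  if (status != 0L) stop("RNAfold failed (exit ", status, ")", call. = FALSE)
  headers <- grep("^>", out)
  if (length(headers) != length(seqs)) {
    stop("RNAfold returned ", length(headers), " records for ",
         length(seqs), " sequences", call. = FALSE)
  }
  struct_lines <- out[headers + 2L]
  m <- regmatches(struct_lines,
                  regexpr("^[^ ]+", struct_lines))
  energy <- stringr::str_match(struct_lines,
                               "\\(\\s*(-?\\d+\\.?\\d*)\\s*\\)\\s*$")[, 2]
  if (anyNA(energy) || any(!nzchar(m))) {
    stop("could not parse RNAfold output", call. = FALSE)
  }
  if (any(grepl("[^().]", m))) {
    stop("folding backend emitted non-nested (pseudoknot) annotation",
         call. = FALSE)
  }
  if (any(nchar(m) != nchar(seqs))) {
    stop("RNAfold structure length differs from sequence length",
         call. = FALSE)
  }
  tibble(structure = m, mfe = as.numeric(energy))
}

#' Fold a single sequence
#'
#' Convenience wrapper around [rna_fold()] for one sequence.
#'
#' @inheritParams rna_fold
#' @param sequence A single sequence.
#' @return List with `structure` (dot-bracket) and `mfe` (kcal/mol).
#' @export
fold <- function(sequence, engine = fold_engine()) {
  res <- rna_fold(sequence, engine)
  list(structure = res$structure[1], mfe = res$mfe[1])
}
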