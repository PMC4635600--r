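#' Mono-nucleotide shuffle of a sequence
#'
#' Uniform random permutation of the characters (Fisher-Yates), preserving
#' the nucleotide composition exactly. Uses the current RNG state; seed it
#' (or set `config$seed` in the pipeline) for reproducibility.
#'
#' @param sequence A nucleotide string.
#' @return A shuffled string of the same composition.
#' @export
shuffle_sequence <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  if (!length(chars)) stop("empty sequence", call. = FALSE)
  paste(sample(chars), collapse = "")
}

#' Di-nucleotide shuffle (Altschul-Erickson)
#'
#' Random sequence with exactly the same di-nucleotide counts as the input,
#' generated via a random Eulerian path on the di-nucleotide multigraph.
#' Offered because mono- and di-nucleotide shuffling give the same MFE/nt
#' null for sequences longer than about 100 nt; mono-nucleotide shuffling is
#' the default.
#'
#' @inheritParams shuffle_sequence
#' @return A shuffled string with identical di-nucleotide composition.
#' @export
shuffle_dinucleotide <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  if (!n) stop("empty sequence", call. = FALSE)
  if (n <= 3L) return(sequence)
  succ <- split(chars[-1], chars[-n])  # successor multiset per symbol
  first <- chars[1]
  last <- chars[n]
  vertices <- names(succ)
  # Altschul-Erickson: for every vertex with out-edges except `last`, pick a
  # random out-edge reserved as that vertex's final edge, such that the
  # reserved edges form a functional graph in which every vertex reaches
  # `last`. Then shuffle the remaining edges freely; the greedy walk from
  # the first symbol is then guaranteed to be an Eulerian path.
  for (attempt in seq_len(500L)) {
    final_edge <- vapply(vertices, function(v) {
      if (v == last) NA_character_ else sample(succ[[v]], 1L)
    }, character(1))
    reaches <- vapply(vertices, function(v) {
      seen <- character(0)
      while (v != last && !v %in% seen && v %in% vertices) {
        seen <- c(seen, v)
        v <- final_edge[[v]]
        if (is.na(v)) break
      }
      identical(v, last)
    }, logical(1))
    if (all(reaches)) {
      bags <- lapply(vertices, function(v) {
        bag <- succ[[v]]
        if (v == last) return(sample(bag))
        fe <- final_edge[[v]]
        bag <- bag[-match(fe, bag)]
        c(if (length(bag)) sample(bag), fe)
      })
      names(bags) <- vertices
      walk <- character(n)
      walk[1] <- first
      ptr <- setNames(rep(1L, length(vertices)), vertices)
      for (i in 2:n) {
        cur <- walk[i - 1L]
        walk[i] <- bags[[cur]][ptr[[cur]]]
        ptr[[cur]] <- ptr[[cur]] + 1L
      }
      return(paste(walk, collapse = ""))
    }
  }
  stop("di-nucleotide shuffle failed to draw an Eulerian path",
       call. = FALSE)
}

#' Null distribution of MFE/nt under sequence shuffling
#'
#' Shuffles the sequence `n` times, folds every shuffle, and records the
#' per-nucleotide minimum free energies. Each sequence gets its own null so
#' that sequence-specific nucleotide abundances are accounted for. Folding
#' errors in individual shuffles are tolerated up to 10% of `n`.
#'
#' @param sequence The observed (candidate) sequence.
#' @param n Number of shuffles (`permutation_count`).
#' @param engine [fold_engine()].
#' @param method `"mono"` (default) or `"dinucleotide"`.
#' @param workers Parallel workers for the folding batch.
#' @return An `mfe_null` object: list with `values` (MFE/nt, length `n`
#'   minus tolerated failures), `n`, `source_length`, `source_composition`.
#' @export
null_distribution <- function(sequence, n, engine = fold_engine(),
                              method = c("mono", "dinucleotide"),
                              workers = 1L) {
  stopifnot(n >= 1)
  method <- match.arg(method)
  shuf_fun <- if (method == "mono") shuffle_sequence else shuffle_dinucleotide
  shuffles <- vapply(seq_len(n), function(i) shuf_fun(sequence),
                     character(1))
  folded <- tryCatch(rna_fold(shuffles, engine, workers = workers),
                     error = function(e) NULL)
  if (is.null(folded)) {
    # fold shuffles one by one, tolerating individual failures
    vals <- purrr::map_dbl(shuffles, function(s) {
      tryCatch(rna_fold(s, engine)$mfe_per_nt, error = function(e) NA_real_)
    })
    n_fail <- sum(is.na(vals))
    if (n_fail > 0.1 * n) {
      stop("more than 10% of shuffles failed to fold", call. = FALSE)
    }
    values <- vals[!is.na(vals)]
  } else {
    values <- folded$mfe_per_nt
  }
  comp <- table(factor(strsplit(chartr("U", "T", toupper(sequence)),
                                "")[[1]],
                       levels = c("A", "C", "G", "T", "N")))
  structure(
    list(values = values, n = length(values),
         source_length = nchar(sequence),
         source_composition = as.integer(comp)[1:4] |>
           setNames(c("A", "C", "G", "T"))),
    class = "mfe_null"
  )
}

#' Empirical structure-significance p-value
#'
#' The p-value is the probability mass of the null at or below the observed
#' MFE/nt, estimated with the add-one (pseudocount) permutation estimator
#' `p = (1 + #[null <= observed]) / (n + 1)`, which can never be zero. Null
#' values exactly equal to the observation count against it (conservative).
#'
#' @param observed Observed MFE/nt of the candidate structure.
#' @param null An `mfe_null` from [null_distribution()], or a numeric vector
#'   of null MFE/nt values.
#' @return One-row tibble: `p_value`, `observed_mfe_per_nt`, `null_mean`,
#'   `null_sd`, `null_n`.
#' @examples
#' empirical_p(-0.26, c(-0.30, -0.25, -0.20, -0.15))  # p = 0.4
#' @export
empirical_p <- function(observed, null) {
  values <- if (inherits(null, "mfe_null")) null$values else as.numeric(null)
  if (!length(values)) stop("empty null distribution", call. = FALSE)
  n <- length(values)
  tibble(
    p_value = (1 + sum(values <= observed)) / (n + 1),
    observed_mfe_per_nt = observed,
    null_mean = mean(values),
    null_sd = stats::sd(values),
    null_n = n
  )
}

#' @export
print.mfe_null <- function(x, ...) {
  cat("<mfe_null> n =", x$n, " length =", x$source_length,
      " mean =", signif(mean(x$values), 4),
      " sd =", signif(stats::sd(x$values), 4), "\n")
  invisible(x)
}
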