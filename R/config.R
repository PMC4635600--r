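#' Pipeline configuration
#'
#' All tunable thresholds of the precursor-calling pipeline live in a single
#' flat configuration object. Defaults come from an organism preset
#' (`"plants"` or `"algae"`), can be overridden by a plain-text
#' `key = value` file, and finally by in-call overrides, in that order of
#' increasing precedence.
#'
#' The two presets differ only in the structure thresholds: algal precursors
#' have longer double-stranded segments and lower per-nucleotide minimum free
#' energies than land-plant precursors, so the algae preset uses
#' `min_mfe_per_nt = -0.4` kcal/mol/nt and `min_double_strand_length = 24` nt
#' versus `-0.2` and `18` for plants.
#'
#' @param path Optional path to a configuration file: one `key = value` per
#'   line, `#` starts a comment, blank lines ignored.
#' @param preset Organism preset supplying defaults: `"plants"` or `"algae"`.
#' @param overrides Named list of final overrides (highest precedence).
#'
#' @return A `hairpin_config` object (named list) with fields:
#' \describe{
#'   \item{cluster_min_reads}{minimum summed read multiplicity for a contig
#'     to seed a cluster (default 10).}
#'   \item{cluster_gap_size}{contigs closer than this many nt are merged
#'     (strict `<`; default 10).}
#'   \item{cluster_flank_size}{flank F added to both contig ends (default 200 nt).}
#'   \item{cluster_max_length}{contigs longer than this are discarded
#'     (strict `>`; default 2000 nt).}
#'   \item{min_mfe_per_nt}{structure passes if MFE/nt is at or below this
#'     threshold (kcal/mol/nt).}
#'   \item{max_hairpin_count}{structure passes if the number of terminal
#'     loops N_term is strictly below this (default 4).}
#'   \item{min_double_strand_length}{minimum length of the longest
#'     double-stranded segment L_ds,max (nt).}
#'   \item{permutation_count}{shuffles per null distribution (default 100).}
#'   \item{max_pvalue}{empirical p-value cutoff (default 0.05).}
#'   \item{min_coverage}{minimum fraction of precursor-mapped reads a mature
#'     locus must carry (strict `>`; default 0.10).}
#'   \item{min_duplex_length,max_duplex_length}{half-open bounds on mature
#'     and star lengths, `min <= L < max` (defaults 20, 25).}
#'   \item{min_paired_fraction}{minimum fraction of paired nucleotides in the
#'     mature locus (default 0.67).}
#'   \item{allow_three_mismatches}{enforce `< 4` adjacent unpaired
#'     nucleotides in the mature interior (default TRUE).}
#'   \item{allow_two_terminal_mismatches}{enforce `< 3` adjacent unpaired
#'     nucleotides at the duplex ends (default TRUE).}
#'   \item{worker_count}{parallel workers for the folding workload; results
#'     are independent of this value.}
#'   \item{window_step}{coarse grid step for precursor window enumeration (nt).}
#'   \item{window_refine_step}{fine grid step for local refinement around the
#'     coarse optimum; 0 disables refinement.}
#'   \item{uniqueness_tolerance}{two optima within this MFE/nt distance are
#'     flagged non-unique (kcal/mol/nt).}
#'   \item{fold_backend}{`"auto"`, `"vienna"` (RNAfold CLI) or `"pairmax"`
#'     (bundled non-thermodynamic fallback).}
#'   \item{shuffle_method}{`"mono"` (default) or `"dinucleotide"`.}
#'   \item{edge_tolerance}{merge read stacks whose ends differ by at most
#'     this many nt (default 0, maximum 2).}
#'   \item{seed}{random seed used for shuffling.}
#' }
#'
#' @examples
#' load_config(preset = "plants")$cluster_flank_size      # 200
#' load_config(preset = "algae")$min_double_strand_length # 24
#' load_config(overrides = list(cluster_gap_size = 0))$cluster_gap_size
#' @export
load_config <- function(path = NULL, preset = c("plants", "algae"),
                        overrides = list()) {
  preset <- match.arg(preset)
  cfg <- config_defaults(preset)

  if (!is.null(path)) {
    if (!file.exists(path)) {
      stop("configuration file not found: ", path, call. = FALSE)
    }
    file_vals <- parse_config_file(path)
    cfg <- apply_config_values(cfg, file_vals, origin = path)
  }
  if (length(overrides)) {
    cfg <- apply_config_values(cfg, overrides, origin = "overrides")
  }
  validate_config(cfg)
}

config_defaults <- function(preset) {
  cfg <- list(
    cluster_min_reads = 10L,
    cluster_gap_size = 10L,
    cluster_flank_size = 200L,
    cluster_max_length = 2000L,
    min_mfe_per_nt = -0.2,
    max_hairpin_count = 4L,
    min_double_strand_length = 18L,
    permutation_count = 100L,
    max_pvalue = 0.05,
    min_coverage = 0.10,
    min_duplex_length = 20L,
    max_duplex_length = 25L,
    min_paired_fraction = 0.67,
    allow_three_mismatches = TRUE,
    allow_two_terminal_mismatches = TRUE,
    worker_count = 1L,
    window_step = 20L,
    window_refine_step = 5L,
    uniqueness_tolerance = 0.01,
    fold_backend = "auto",
    shuffle_method = "mono",
    edge_tolerance = 0L,
    seed = 42L
  )
  if (preset == "algae") {
    cfg$min_mfe_per_nt <- -0.4
    cfg$min_double_strand_length <- 24L
  }
  cfg$preset <- preset
  structure(cfg, class = "hairpin_config")
}

parse_config_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(list())
  bad <- !grepl("=", lines, fixed = TRUE)
  if (any(bad)) {
    stop("malformed configuration line (expected 'key = value'): ",
         lines[bad][1], call. = FALSE)
  }
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  setNames(as.list(vals), keys)
}

.config_field_types <- c(
  cluster_min_reads = "int", cluster_gap_size = "int",
  cluster_flank_size = "int", cluster_max_length = "int",
  min_mfe_per_nt = "num", max_hairpin_count = "int",
  min_double_strand_length = "int", permutation_count = "int",
  max_pvalue = "num", min_coverage = "num",
  min_duplex_length = "int", max_duplex_length = "int",
  min_paired_fraction = "num", allow_three_mismatches = "bool",
  allow_two_terminal_mismatches = "bool", worker_count = "int",
  window_step = "int", window_refine_step = "int",
  uniqueness_tolerance = "num", fold_backend = "chr",
  shuffle_method = "chr", edge_tolerance = "int", seed = "int",
  preset = "chr"
)

apply_config_values <- function(cfg, values, origin = "input") {
  if (!length(values)) return(cfg)
  if (is.null(names(values)) || any(!nzchar(names(values)))) {
    stop("configuration values must be named (", origin, ")", call. = FALSE)
  }
  for (key in names(values)) {
    if (!key %in% names(.config_field_types)) {
      stop("unknown configuration key '", key, "' (", origin, ")",
           call. = FALSE)
    }
    cfg[[key]] <- coerce_config_value(key, values[[key]])
  }
  cfg
}

coerce_config_value <- function(key, value) {
  type <- .config_field_types[[key]]
  if (type == "chr") return(as.character(value)[1])
  if (type == "bool") {
    if (is.logical(value)) return(value[1])
    v <- toupper(trimws(as.character(value)[1]))
    if (v %in% c("TRUE", "T", "1", "YES")) return(TRUE)
    if (v %in% c("FALSE", "F", "0", "NO")) return(FALSE)
    stop("configuration key '", key, "' expects a logical, got '", value,
         "'", call. = FALSE)
  }
  num <- suppressWarnings(as.numeric(value))
  if (is.na(num)) {
    stop("configuration key '", key, "' expects a number, got '", value,
         "'", call. = FALSE)
  }
  if (type == "int") {
    if (abs(num - round(num)) > 1e-8) {
      stop("configuration key '", key, "' expects an integer, got '", value,
           "'", call. = FALSE)
    }
    return(as.integer(round(num)))
  }
  num
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  chk(cfg$cluster_min_reads >= 1, "cluster_min_reads >= 1 violated")
  chk(cfg$cluster_gap_size >= 0, "cluster_gap_size >= 0 violated")
  chk(cfg$cluster_flank_size >= 0, "cluster_flank_size >= 0 violated")
  chk(cfg$cluster_max_length > 0, "cluster_max_length > 0 violated")
  chk(cfg$min_duplex_length < cfg$max_duplex_length,
      "min_duplex_length < max_duplex_length violated")
  chk(cfg$min_duplex_length >= 1, "min_duplex_length >= 1 violated")
  chk(cfg$max_pvalue >= 0 && cfg$max_pvalue <= 1,
      "0 <= max_pvalue <= 1 violated")
  chk(cfg$min_coverage > 0 && cfg$min_coverage <= 1,
      "0 < min_coverage <= 1 violated")
  chk(cfg$min_paired_fraction >= 0 && cfg$min_paired_fraction <= 1,
      "0 <= min_paired_fraction <= 1 violated")
  chk(cfg$max_hairpin_count >= 1, "max_hairpin_count >= 1 violated")
  chk(cfg$permutation_count >= 1, "permutation_count >= 1 violated")
  chk(cfg$worker_count >= 1, "worker_count >= 1 violated")
  chk(cfg$window_step >= 1, "window_step >= 1 violated")
  chk(cfg$window_refine_step >= 0, "window_refine_step >= 0 violated")
  chk(cfg$uniqueness_tolerance >= 0, "uniqueness_tolerance >= 0 violated")
  chk(cfg$edge_tolerance >= 0 && cfg$edge_tolerance <= 2,
      "0 <= edge_tolerance <= 2 violated")
  chk(cfg$fold_backend %in% c("auto", "vienna", "pairmax"),
      "fold_backend must be one of 'auto', 'vienna', 'pairmax'")
  chk(cfg$shuffle_method %in% c("mono", "dinucleotide"),
      "shuffle_method must be 'mono' or 'dinucleotide'")
  cfg
}

#' @export
print.hairpin_config <- function(x, ...) {
  cat("<hairpin_config> preset:", x$preset, "\n")
  flds <- setdiff(names(x), "preset")
  for (f in flds) cat(sprintf("  %-30s %s\n", f, format(x[[f]])))
  invisible(x)
}
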