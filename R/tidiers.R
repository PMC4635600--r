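#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a pipeline result into a per-duplex tibble
#'
#' @param x A `hairpin_result` from [run_pipeline()].
#' @param ... Unused.
#' @return The call table: one row per accepted mature/star duplex.
#' @method tidy hairpin_result
#' @export
tidy.hairpin_result <- function(x, ...) {
  x$calls
}

#' One-row summary of a pipeline result
#'
#' @param x A `hairpin_result`.
#' @param ... Unused.
#' @return Tibble with cluster, candidate, filter, significance and call
#'   counts.
#' @method glance hairpin_result
#' @export
glance.hairpin_result <- function(x, ...) {
  tibble(
    n_clusters = nrow(x$clusters),
    n_candidates = nrow(x$candidates),
    n_structure_pass = sum(x$candidates$structure_pass),
    n_significant = sum(x$candidates$sig_pass, na.rm = TRUE),
    n_precursors = length(unique(x$calls$id)),
    n_duplexes = nrow(x$calls),
    median_mfe_per_nt = stats::median(x$calls$mfe_per_nt),
    median_precursor_length = stats::median(x$calls$pre_end -
                                              x$calls$pre_start)
  )
}

#' Feature distributions of called precursors
#'
#' Histograms of MFE/nt, longest double-stranded segment, mature length and
#' precursor length over the calls — the panel layout used to calibrate
#' organism presets from known precursor sets.
#'
#' @param object A `hairpin_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hairpin_result
#' @export
autoplot.hairpin_result <- function(object, ...) {
  calls <- dplyr::distinct(object$calls, .data$id, .keep_all = TRUE)
  primary <- object$calls |>
    group_by(.data$id) |>
    dplyr::slice_max(.data$read_support, n = 1, with_ties = FALSE) |>
    ungroup()
  df <- bind_rows(
    tibble(feature = "MFE/nt [kcal/mol]", value = calls$mfe_per_nt),
    tibble(feature = "L(ds,max) [nt]", value = as.numeric(calls$l_ds_max)),
    tibble(feature = "L(mature) [nt]",
           value = as.numeric(primary$mature_length)),
    tibble(feature = "L(precursor) [nt]",
           value = as.numeric(calls$pre_end - calls$pre_start))
  )
  plot_precursor_features(df)
}

#' Feature distributions of profiled precursor sequences
#'
#' Companion plot for [profile_precursors()] output.
#'
#' @param profile Tibble from [profile_precursors()].
#' @return A ggplot object.
#' @export
plot_profile <- function(profile) {
  df <- bind_rows(
    tibble(feature = "MFE/nt [kcal/mol]", value = profile$mfe_per_nt),
    tibble(feature = "L(ds,max) [nt]", value = as.numeric(profile$l_ds_max)),
    tibble(feature = "L(precursor) [nt]", value = as.numeric(profile$length))
  )
  plot_precursor_features(df)
}

plot_precursor_features <- function(df) {
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey35", colour = "white") +
    ggplot2::facet_wrap(~feature, scales = "free") +
    ggplot2::labs(x = NULL, y = "precursors") +
    ggplot2::theme_minimal()
}
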