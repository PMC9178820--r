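#' Plot a metagene profile
#'
#' Line plot of mean normalized coverage against distance from the TSS, one
#' line per group.
#'
#' @param object A `metagene_profile` from [metagene()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot metagene_profile
#' @export
autoplot.metagene_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$bin_center, y = .data$mean_coverage, colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance from TSS (bp)",
                  y = "mean normalized coverage", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Violin plot of an age-group comparison
#'
#' @param object An `age_comparison` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot age_comparison
#' @export
autoplot.age_comparison <- function(object, ...) {
  v <- object$values
  ggplot2::ggplot(v, ggplot2::aes(
    x = .data$age_group, y = .data$value, fill = .data$age_group)) +
    ggplot2::geom_violin(trim = FALSE, show.legend = FALSE) +
    ggplot2::geom_boxplot(width = 0.15, fill = "white",
                          outlier.shape = NA, show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = object$comparison,
                  subtitle = sprintf("Mann-Whitney p = %.3g",
                                     object$test$p.value)) +
    ggplot2::theme_minimal()
}

#' Bar plot of region-class enrichment over the background
#'
#' @param enrichment Output of [enrichment_by_age()].
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment) {
  long <- enrichment |>
    tidyr::pivot_longer(c("observed_pct", "expected_pct"),
                        names_to = "kind", values_to = "pct") |>
    dplyr::mutate(kind = sub("_pct$", "", .data$kind))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$region, y = .data$pct, fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~.data$age_group) +
    ggplot2::labs(x = NULL, y = "% of genes", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Bar plot of NMD-feature frequencies by age group
#'
#' @param freq Output of [nmd_frequency_by_age()].
#' @return A ggplot object.
#' @export
plot_nmd_frequency <- function(freq) {
  ggplot2::ggplot(freq, ggplot2::aes(
    x = .data$age_group, y = .data$fraction, fill = .data$age_group)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "fraction of genes with an NMD feature") +
    ggplot2::theme_minimal()
}

#' Box plot of nearest-gene age by enhancer region class
#'
#' @param age_by_class Output of [nearest_gene_age_by_class()].
#' @return A ggplot object.
#' @export
plot_age_by_class <- function(age_by_class) {
  long <- age_by_class |>
    dplyr::select("region_class", "ages") |>
    tidyr::unnest("ages")
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$region_class, y = .data$ages)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "phylostratum of nearest gene") +
    ggplot2::theme_minimal()
}

#' Replicate-concordance scatter plot
#'
#' Scatter of log10(RPM + pseudocount) between the first two replicates.
#'
#' @inheritParams replicate_concordance
#' @return A ggplot object.
#' @export
plot_concordance <- function(peaks, library_sizes, pseudocount = 0.01) {
  check_library_sizes(peaks, library_sizes)
  lg <- log10(rpm_matrix(tibble::as_tibble(peaks), library_sizes) + pseudocount)
  df <- tibble::tibble(x = lg[, 1], y = lg[, 2])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = paste0("log10 RPM, ", names(library_sizes)[1]),
                  y = paste0("log10 RPM, ", names(library_sizes)[2])) +
    ggplot2::theme_minimal()
}
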