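# ggplot2 views of the main result types.

#' @rdname mhg_delineate
#' @param object An `mhg_partition`.
#' @method autoplot mhg_partition
#' @export
autoplot.mhg_partition <- function(object, ...) {
  d <- tidy(object)
  d$mhg <- factor(d$mhg_id)
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start, xend = .data$end,
                                       y = .data$genome, yend = .data$genome,
                                       colour = .data$mhg),
                          linewidth = 4, show.legend = FALSE) +
    ggplot2::labs(x = "position (bp)", y = NULL,
                  title = "Maximal homologous groups along genomes") +
    ggplot2::theme_minimal()
}

#' Heatmap of group occurrence by taxon pair
#'
#' @param occurrence Output of [mhg_occurrence()].
#' @return A ggplot object.
#' @export
plot_occurrence <- function(occurrence) {
  ggplot2::ggplot(occurrence,
                  ggplot2::aes(x = .data$taxon_a, y = .data$taxon_b,
                               fill = .data$n_mhgs)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_mhgs), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = NULL, y = NULL, fill = "groups") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Coverage curves across the minimum-taxa threshold
#'
#' @param coverage Output of [mhg_base_coverage()] (possibly several
#'   `min_taxa` values).
#' @return A ggplot object.
#' @export
plot_coverage <- function(coverage) {
  ggplot2::ggplot(coverage,
                  ggplot2::aes(x = .data$min_taxa, y = .data$coverage,
                               colour = .data$genome)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "minimum distinct genomes per group",
                  y = "base-pair coverage") +
    ggplot2::theme_minimal()
}

#' @rdname marker_conflict_experiment
#' @param object A `marker_conflict` report.
#' @method autoplot marker_conflict
#' @export
autoplot.marker_conflict <- function(object, ...) {
  s <- object$support
  if (nrow(s) == 0L) abort("report has no support data (B = 0)")
  s$class <- ifelse(s$source == "marker", "marker",
                    ifelse(s$correct, "component (true)", "component (incorrect)"))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$class, y = .data$support)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "bootstrap support",
                  title = "Branch support: recombinant markers vs components") +
    ggplot2::theme_minimal()
}
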