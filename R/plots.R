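#' Plot the distribution of alignments per fusion molecule
#'
#' Two alignments is a simple head-to-head fusion; three or more indicate
#' inserted DNA between the sub-telomeres.
#'
#' @param events Per-read event table ([event_table()]).
#' @return A ggplot.
#' @export
plot_alignment_counts <- function(events) {
  dat <- dplyr::filter(events, .data$is_fusion)
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$n_alignments))) +
    ggplot2::geom_bar(fill = "grey30") +
    ggplot2::labs(x = "alignments per molecule", y = "reads") +
    ggplot2::theme_minimal()
}

#' Plot junction-type proportions
#'
#' @param annotated Annotated segment tibble ([annotate_events()]).
#' @return A ggplot.
#' @export
plot_junction_spectrum <- function(annotated) {
  dat <- annotated %>%
    dplyr::filter(!is.na(.data$junction_kind)) %>%
    dplyr::count(.data$junction_kind) %>%
    dplyr::mutate(proportion = .data$n / sum(.data$n))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$junction_kind,
                                    y = .data$proportion)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "junction type", y = "proportion") +
    ggplot2::theme_minimal()
}

#' Plot insertion and flank size distributions
#'
#' Reference-interval sizes on a log10 axis, split by segment role.
#'
#' @param annotated Annotated segment tibble.
#' @return A ggplot.
#' @export
plot_segment_sizes <- function(annotated) {
  dat <- annotated %>%
    dplyr::filter(.data$role %in% c("flank", "insertion")) %>%
    dplyr::mutate(size = .data$ref_end - .data$ref_start)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$role, y = .data$size)) +
    ggplot2::geom_jitter(width = 0.2, alpha = 0.3, size = 0.6) +
    ggplot2::stat_summary(fun = median, geom = "crossbar", width = 0.5,
                          colour = "red") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "size (bp)") +
    ggplot2::theme_minimal()
}

#' Plot cluster size distribution
#'
#' @param clusters Cluster table ([cluster_events()]).
#' @return A ggplot.
#' @export
plot_cluster_sizes <- function(clusters) {
  dat <- dplyr::distinct(clusters, .data$cluster_id, .data$n_members)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$n_members)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey30") +
    ggplot2::labs(x = "reads per cluster", y = "clusters") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.fusion_benchmark <- function(object, ...) {
  dat <- tidyr::pivot_longer(object$summary, c("precision", "recall", "f1"),
                             names_to = "metric", values_to = "value")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$metric, y = .data$value,
                                    fill = .data$scope)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
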