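#' Heatmap of an FNC matrix
#'
#' Weighted connectivity heatmap over the 10 RSNs; unretained edges are
#' shown hollow (weight displayed but marked), non-neuronal rows/columns
#' are zero by construction.
#'
#' @param object An [build_fnc()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fnc_matrix <- function(object, ...) {
  df <- tidy(object, upper_only = FALSE)
  df$rsn_i <- factor(df$rsn_i, levels = object$labels)
  df$rsn_j <- factor(df$rsn_j, levels = rev(object$labels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rsn_i, y = .data$rsn_j,
                                   fill = .data$dcor)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = df[df$retained, ], size = 0.8,
                        colour = "white") +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "dCor") +
    ggplot2::labs(x = NULL, y = NULL,
                  caption = "dots mark retained edges") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Time-course traces of a subject
#'
#' @param object A [timecourse_set()].
#' @param ... Unused.
#' @return A ggplot object (one facet per RSN).
#' @export
autoplot.timecourse_set <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~rsn, ncol = 2) +
    ggplot2::labs(x = "time (s)", y = "standardised amplitude") +
    ggplot2::theme_minimal()
}

#' Group profiles of a nodal measure
#'
#' Mean +/- one standard deviation of a nodal network measure per RSN and
#' group, the per-network "fingerprint" view used to compare populations.
#'
#' @param metrics Long tibble from [cohort_metrics()].
#' @param measure One of `"degree"`, `"strength"`, `"clustering"`,
#'   `"betweenness"`, `"eigencentrality"`.
#' @return A ggplot object.
#' @export
plot_nodal_profiles <- function(metrics, measure = "degree") {
  df <- metrics |>
    dplyr::filter(.data$measure == !!measure, .data$rsn != "average") |>
    dplyr::group_by(.data$group, .data$rsn) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rsn, y = .data$mean,
                                   colour = .data$group,
                                   group = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd),
                             fatten = 1.5,
                             position = ggplot2::position_dodge(0.3)) +
    ggplot2::labs(x = NULL, y = measure) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Violin plot of network-average measures by group
#'
#' @param metrics Long tibble from [cohort_metrics()].
#' @param measure Measure to display.
#' @return A ggplot object.
#' @export
plot_average_distribution <- function(metrics, measure = "degree") {
  df <- metrics |>
    dplyr::filter(.data$measure == !!measure, .data$rsn == "average")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$value,
                                   fill = .data$group)) +
    ggplot2::geom_violin(alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.08, size = 0.8) +
    ggplot2::labs(x = NULL, y = paste("average", measure)) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
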