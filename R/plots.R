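#' Plot per-group feature distributions
#'
#' Boxplots of each morphometry feature by group, colored by arm, faceted
#' per feature with free scales — the standard view for eyeballing
#' whether the TR arm tracks the GT arm per pathology group.
#'
#' @param object An `octa_features` table from [quantify_cohort()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.octa_features <- function(object, ...) {
  feature_cols <- intersect(c("bvd", "bvc", "bvt", "vpi"), names(object))
  long <- tidyr::pivot_longer(
    dplyr::select(object, dplyr::all_of(c("group", "arm", "fov", feature_cols))),
    cols = dplyr::all_of(feature_cols),
    names_to = "feature", values_to = "value")
  long <- dplyr::filter(long, is.finite(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$value,
                                     fill = .data$arm)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, linewidth = 0.3) +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, fill = "arm") +
    ggplot2::theme_minimal()
}

#' Plot group means with SD error bars from a cohort report
#'
#' @param object An `octa_report` from [build_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.octa_report <- function(object, ...) {
  m <- dplyr::filter(object$means, is.finite(.data$mean))
  ggplot2::ggplot(m, ggplot2::aes(x = .data$group, y = .data$mean,
                                  color = .data$arm)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean - dplyr::coalesce(.data$sd, 0),
      ymax = .data$mean + dplyr::coalesce(.data$sd, 0)),
      position = ggplot2::position_dodge(width = 0.4), fatten = 1.5) +
    ggplot2::facet_grid(.data$feature ~ .data$fov, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mean ± SD", color = "arm") +
    ggplot2::theme_minimal()
}

#' Display a projection map
#'
#' @param map Numeric matrix in `[0, 1]`.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_map <- function(map, title = NULL) {
  df <- tidyr::expand_grid(row = seq_len(nrow(map)), col = seq_len(ncol(map)))
  df$value <- as.vector(t(map))[(df$row - 1L) * ncol(map) + df$col]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_void()
}
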