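#' Group comparison boxplots of crypt morphometry
#'
#' Volume, prolate ellipticity and tortuosity per crypt, split by clinical
#' group — the standard cohort overview panel.
#'
#' @param cohort Cohort tibble from [sample_crypts()] (or any per-crypt
#'   tibble with `group` and the morphometric columns).
#' @param variables Columns to facet over.
#' @return A ggplot object.
#' @export
plot_group_morphometry <- function(cohort,
                                   variables = c("volume_um3",
                                                 "ellipticity_prolate",
                                                 "tortuosity")) {
  long <- tidyr::pivot_longer(
    cohort, dplyr::all_of(variables),
    names_to = "variable", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.3, size = 0.5) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Per-crypt 3D morphometry by group") +
    ggplot2::theme_minimal()
}

#' Plot a crypt centerline in 2D projections
#'
#' x-z and y-z projections of one centerline, the quickest way to see
#' tortuosity and twist by eye.
#'
#' @param cl Centerline tibble (`x_um`, `y_um`, `z_um`).
#' @return A ggplot object.
#' @export
plot_centerline <- function(cl) {
  long <- dplyr::bind_rows(
    tibble::tibble(axis = "x", pos = cl$x_um - cl$x_um[1], z = cl$z_um),
    tibble::tibble(axis = "y", pos = cl$y_um - cl$y_um[1], z = cl$z_um)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pos, y = -.data$z)) +
    ggplot2::geom_path() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~axis) +
    ggplot2::labs(x = "lateral offset (um)", y = "depth below surface (um)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.metrics_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$per_class,
    c("accuracy", "sensitivity", "specificity", "precision", "f1"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$class, y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL, title = "Per-class classification metrics") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
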