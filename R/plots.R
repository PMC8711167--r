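#' Eigenspace scatter with KDE contours
#'
#' Plots plaque scores in the retained 2-D eigenspace (PC2 vs PC3 by
#' default), colored by cohort, optionally with quantile-calibrated density
#' contours of a reference region at the requested coverages (30/60/90% by
#' default; plotting only, no classification role).
#'
#' @param scores A 2-D score set from [project_scores()].
#' @param region Optional [fit_density_region()] to draw contours for.
#' @param contours Coverage levels for the contour lines.
#' @param grid_n Contour mesh resolution.
#' @return A ggplot object.
#' @export
plot_eigenspace <- function(scores, region = NULL,
                            contours = c(0.3, 0.6, 0.9), grid_n = 80) {
  cols <- pc_columns(scores)
  if (length(cols) != 2) {
    abort_ss("plot_eigenspace needs a 2-D score set",
             "strainscope_invalid_argument")
  }
  p <- ggplot2::ggplot(scores, ggplot2::aes(
    x = .data[[cols[1]]], y = .data[[cols[2]]], colour = .data$cohort
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::labs(x = toupper(cols[1]), y = toupper(cols[2])) +
    ggplot2::theme_minimal()
  if (!is.null(region)) {
    x <- region$reference
    pad <- 3 * sqrt(diag(region$H))
    gx <- seq(min(x[, 1]) - pad[1], max(x[, 1]) + pad[1], length.out = grid_n)
    gy <- seq(min(x[, 2]) - pad[2], max(x[, 2]) + pad[2], length.out = grid_n)
    mesh <- as.matrix(expand.grid(gx, gy))
    dens <- kde_eval(mesh, x, region$H)
    self <- kde_eval(x, x, region$H)
    breaks <- vapply(contours, function(cv) {
      sort(self, decreasing = TRUE)[ceiling(cv * nrow(x))]
    }, numeric(1))
    dd <- data.frame(x = mesh[, 1], y = mesh[, 2], z = dens)
    p <- p + ggplot2::geom_contour(
      data = dd, ggplot2::aes(x = .data$x, y = .data$y, z = .data$z),
      breaks = breaks, colour = "grey40", inherit.aes = FALSE
    )
  }
  p
}

#' Scree plot of a fitted strain space
#'
#' @param object A `strain_space`.
#' @param n_components Number of leading components to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.strain_space <- function(object, n_components = 10, ...) {
  td <- tidy.strain_space(object)
  td <- td[seq_len(min(n_components, nrow(td))), ]
  ggplot2::ggplot(td, ggplot2::aes(x = .data$component,
                                   y = .data$variance_ratio)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Principal component",
                  y = "Proportion of variance") +
    ggplot2::theme_minimal()
}

#' Per-patient heterogeneity distributions by group
#'
#' Kernel-density view of per-patient weighted RMSD values stratified by a
#' grouping column (cohort, pathology grade, ...).
#'
#' @param per_patient Tibble from [per_patient_heterogeneity()], optionally
#'   with extra grouping columns joined on.
#' @param by Grouping column name (default `"cohort"`).
#' @return A ggplot object.
#' @export
plot_heterogeneity <- function(per_patient, by = "cohort") {
  assert_columns(per_patient, c("rmsd", by), "heterogeneity table")
  dat <- per_patient[!is.na(per_patient$rmsd), ]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$rmsd,
                                    fill = factor(.data[[by]]))) +
    ggplot2::geom_density(alpha = 0.4) +
    ggplot2::labs(x = "Weighted RMSD", fill = by) +
    ggplot2::theme_minimal()
}
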