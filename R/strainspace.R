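#' Fit the PCA strain space
#'
#' Performs mean-centered (unscaled) principal component analysis on the
#' composite spectral vectors: each plaque is a point in the 120-dimensional
#' concatenated-spectrum space, and the fitted eigenbasis defines the strain
#' space in which all downstream comparisons are made. Component signs are
#' fixed so that each component's largest-magnitude loading is positive,
#' making the fit deterministic across platforms.
#'
#' @param data Wide composite tibble from [build_composite()], with
#'   `plaque_id`, `patient_id`, `cohort` and `v...` value columns.
#' @return An object of class `strain_space`: a list with `mean_vector`,
#'   `components` (columns = orthonormal loadings), `sdev`,
#'   `explained_variance_ratio`, `scores` (full-score matrix), and `meta`
#'   (the row metadata tibble).
#' @export
fit_strain_space <- function(data) {
  x <- composite_matrix(data)
  if (nrow(x) < 2) {
    abort_ss("at least 2 composite vectors are required to fit a strain space",
             "strainscope_insufficient_data")
  }
  fit <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  # sign convention: largest-|loading| entry of each component positive
  flip <- apply(fit$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  rotation <- sweep(fit$rotation, 2, flip, `*`)
  scores <- sweep(fit$x, 2, flip, `*`)
  var_comp <- fit$sdev^2
  evr <- var_comp / sum(var_comp)
  structure(
    list(
      mean_vector = fit$center,
      components = rotation,
      sdev = fit$sdev,
      explained_variance_ratio = evr,
      scores = scores,
      meta = tibble::as_tibble(data[c("plaque_id", "patient_id", "cohort")])
    ),
    class = "strain_space"
  )
}

#' @export
print.strain_space <- function(x, ...) {
  k <- min(4, length(x$explained_variance_ratio))
  cat(sprintf("<strain_space> %d plaques x %d features\n",
              nrow(x$scores), length(x$mean_vector)))
  cat("  explained variance:",
      paste(sprintf("PC%d %.1f%%", seq_len(k),
                    100 * x$explained_variance_ratio[seq_len(k)]),
            collapse = ", "), "...\n")
  invisible(x)
}

#' @describeIn fit_strain_space One row per component: standard deviation,
#'   proportion of variance, cumulative proportion.
#' @param x A `strain_space` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.strain_space <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$sdev),
    std_dev = x$sdev,
    variance_ratio = x$explained_variance_ratio,
    cumulative = cumsum(x$explained_variance_ratio)
  )
}

#' @describeIn fit_strain_space One-row model summary.
#' @exportS3Method generics::glance
glance.strain_space <- function(x, ...) {
  tibble::tibble(
    n_plaques = nrow(x$scores),
    n_features = length(x$mean_vector),
    n_components = length(x$sdev),
    pc1_variance_ratio = x$explained_variance_ratio[1]
  )
}

#' Project composite vectors into a fitted strain space
#'
#' Centers the rows on the fitted reference mean and projects them onto the
#' retained components. The retained set defaults to PCs 2--3 (the
#' eigenspace used for plots, centroids and MANOVA); PCs 2--4 are used for
#' the heterogeneity statistic. PC1 is excluded by default downstream
#' because it is dominated by an instrument calibration (batch) artifact.
#'
#' @param data Wide composite tibble (same value columns as the fit).
#' @param space A fitted [fit_strain_space()] object.
#' @param retained Integer component indices to keep (default `c(2, 3)`).
#' @return A score set: tibble with `plaque_id`, `patient_id`, `cohort` and
#'   one `pc<k>` column per retained component; attributes `retained` and
#'   `weights` (the explained-variance proportions of the retained
#'   components, used by the weighted RMSD).
#' @export
project_scores <- function(data, space, retained = c(2, 3)) {
  stopifnot(inherits(space, "strain_space"))
  if (any(retained < 1) || any(retained > ncol(space$components))) {
    abort_ss("retained component indices out of range",
             "strainscope_invalid_argument")
  }
  x <- composite_matrix(data)
  centered <- sweep(x, 2, space$mean_vector)
  proj <- centered %*% space$components[, retained, drop = FALSE]
  colnames(proj) <- sprintf("pc%d", retained)
  out <- dplyr::bind_cols(
    tibble::as_tibble(data[c("plaque_id", "patient_id", "cohort")]),
    tibble::as_tibble(proj)
  )
  attr(out, "retained") <- as.integer(retained)
  attr(out, "weights") <- space$explained_variance_ratio[retained]
  out
}

#' Patient centroids in the strain space
#'
#' The per-patient mean coordinate of all of that patient's plaque scores in
#' the retained components; the unit of cohort-level inference (MANOVA,
#' regression) and of the per-cohort heterogeneity statistic.
#'
#' @param scores A score set from [project_scores()].
#' @return Tibble with `patient_id`, `cohort`, `n_plaques` and the mean
#'   `pc<k>` coordinates; `weights`/`retained` attributes carried over.
#' @export
patient_centroids <- function(scores) {
  assert_columns(scores, c("patient_id", "cohort"), "score set")
  cols <- pc_columns(scores)
  out <- scores %>%
    dplyr::group_by(.data$patient_id, .data$cohort) %>%
    dplyr::summarise(
      n_plaques = dplyr::n(),
      dplyr::across(dplyr::all_of(cols), mean),
      .groups = "drop"
    )
  attr(out, "retained") <- attr(scores, "retained")
  attr(out, "weights") <- attr(scores, "weights")
  out
}
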