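#' Variance-weighted distance to a centroid
#'
#' The per-plaque term of the heterogeneity statistic:
#' \deqn{d_i = \sqrt{(x_i-\bar x)^2 w_x^2 + (y_i-\bar y)^2 w_y^2 +
#'   (z_i-\bar z)^2 w_z^2}}
#' where the weights are the proportions of overall variance explained by
#' the retained principal components and enter squared, exactly as in the
#' defining equation (so each weight acts linearly on its coordinate's
#' contribution to `d_i`).
#'
#' @param point,center Numeric vectors of equal length (coordinates in the
#'   retained components).
#' @param weights Nonnegative weights, one per coordinate.
#' @return The weighted distance (scalar).
#' @export
weighted_distance <- function(point, center, weights) {
  if (length(point) != length(center) || length(point) != length(weights)) {
    abort_ss("point, center and weights must have equal dimensionality",
             "strainscope_invalid_argument")
  }
  sqrt(sum((point - center)^2 * weights^2))
}

#' Variance-weighted RMSD about a centroid
#'
#' The heterogeneity statistic:
#' \deqn{\mathrm{RMSD} = \sqrt{\sum_{i=1}^{N} d_i^2 / (N - 1)}}
#' with \eqn{d_i} as in [weighted_distance()]. Applied to one patient's
#' plaque scores about the patient centroid (per-patient heterogeneity) or
#' to one cohort's patient centroids about the cohort centroid (per-cohort
#' heterogeneity). Undefined (`NA`) for fewer than 2 points.
#'
#' @param points Numeric matrix (rows = points) or data frame of
#'   coordinates.
#' @param center Numeric centroid vector.
#' @param weights Nonnegative weights, one per coordinate.
#' @return The weighted RMSD, or `NA_real_` when `N < 2`.
#' @export
weighted_rmsd <- function(points, center, weights) {
  pts <- as.matrix(points)
  storage.mode(pts) <- "double"
  n <- nrow(pts)
  if (n < 2) {
    return(NA_real_)
  }
  if (ncol(pts) != length(center) || ncol(pts) != length(weights)) {
    abort_ss("points, center and weights must have equal dimensionality",
             "strainscope_invalid_argument")
  }
  diffs <- sweep(pts, 2, center)
  d2 <- as.vector(diffs^2 %*% weights^2)
  sqrt(sum(d2) / (n - 1))
}

resolve_weights <- function(scores, weights) {
  if (!is.null(weights)) {
    return(weights)
  }
  w <- attr(scores, "weights")
  if (is.null(w)) {
    abort_ss(
      "weights not supplied and score set carries no 'weights' attribute; project scores from a fitted strain space or pass weights explicitly",
      "strainscope_invalid_argument"
    )
  }
  w
}

#' Per-patient strain heterogeneity
#'
#' Weighted RMSD of each patient's plaque scores about that patient's
#' centroid, with N the patient's number of spectral vectors. Patients with
#' a single vector are reported with `rmsd = NA` (undefined).
#'
#' @param scores A score set from [project_scores()] (typically retained
#'   components 2--4).
#' @param weights Per-component variance-proportion weights; defaults to the
#'   `weights` attribute frozen onto the score set at projection time.
#' @return Tibble `patient_id`, `cohort`, `n_vectors`, `rmsd`.
#' @export
per_patient_heterogeneity <- function(scores, weights = NULL) {
  assert_columns(scores, c("patient_id", "cohort"), "score set")
  w <- resolve_weights(scores, weights)
  cols <- pc_columns(scores)
  scores %>%
    dplyr::group_by(.data$patient_id, .data$cohort) %>%
    dplyr::group_modify(function(g, key) {
      m <- as.matrix(g[cols])
      tibble::tibble(
        n_vectors = nrow(m),
        rmsd = weighted_rmsd(m, colMeans(m), w)
      )
    }) %>%
    dplyr::ungroup()
}

#' Per-cohort strain heterogeneity
#'
#' Weighted RMSD of each cohort's patient centroids about the cohort
#' centroid (the mean of patient centroids), with N the number of patients.
#' Cohorts with a single patient are reported with `rmsd = NA`.
#'
#' @param centroids Patient centroids from [patient_centroids()].
#' @param weights As in [per_patient_heterogeneity()].
#' @return Tibble `cohort`, `n_patients`, `rmsd`.
#' @export
per_cohort_heterogeneity <- function(centroids, weights = NULL) {
  assert_columns(centroids, "cohort", "centroid table")
  w <- resolve_weights(centroids, weights)
  cols <- pc_columns(centroids)
  centroids %>%
    dplyr::group_by(.data$cohort) %>%
    dplyr::group_modify(function(g, key) {
      m <- as.matrix(g[cols])
      tibble::tibble(
        n_patients = nrow(m),
        rmsd = weighted_rmsd(m, colMeans(m), w)
      )
    }) %>%
    dplyr::ungroup()
}

#' Full heterogeneity report
#'
#' Convenience wrapper computing both levels of the statistic with the
#' weights frozen from the strain-space fit.
#'
#' @param scores Score set in the RMSD components (default PCs 2--4).
#' @param weights Optional explicit weights.
#' @return A list of class `heterogeneity_report` with `per_patient`,
#'   `per_cohort`, `weights`, `retained`.
#' @export
strain_heterogeneity <- function(scores, weights = NULL) {
  w <- resolve_weights(scores, weights)
  pp <- per_patient_heterogeneity(scores, w)
  cc <- per_cohort_heterogeneity(patient_centroids(scores), w)
  structure(
    list(per_patient = pp, per_cohort = cc, weights = w,
         retained = attr(scores, "retained")),
    class = "heterogeneity_report"
  )
}

#' @export
print.heterogeneity_report <- function(x, ...) {
  cat("<heterogeneity_report>\n  per-cohort weighted RMSD:\n")
  print(x$per_cohort)
  invisible(x)
}

#' Stratify per-patient heterogeneity by a patient attribute
#'
#' Groups per-patient RMSD values by a stratum label (for example the tau
#' pathology grade) and attaches a kernel-density summary per stratum for
#' plotting. Strata with fewer than 2 defined values get no density curve.
#'
#' @param per_patient Tibble from [per_patient_heterogeneity()].
#' @param strata Tibble with `patient_id` and `stratum` columns (or a named
#'   vector patient_id -> stratum).
#' @return Tibble `stratum`, `n`, `rmsd_values` (list column),
#'   `median_rmsd`, `density` (list column of `stats::density` objects or
#'   `NULL`).
#' @export
stratified_heterogeneity <- function(per_patient, strata) {
  if (!is.data.frame(strata)) {
    strata <- tibble::tibble(patient_id = names(strata),
                             stratum = unname(strata))
  }
  assert_columns(strata, c("patient_id", "stratum"), "strata table")
  joined <- dplyr::left_join(per_patient, strata, by = "patient_id")
  if (any(is.na(joined$stratum))) {
    abort_ss("every patient must be assigned a stratum",
             "strainscope_invalid_argument")
  }
  joined %>%
    dplyr::group_by(.data$stratum, .drop = FALSE) %>%
    dplyr::summarise(
      n = dplyr::n(),
      rmsd_values = list(.data$rmsd[!is.na(.data$rmsd)]),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      median_rmsd = purrr::map_dbl(
        .data$rmsd_values,
        function(v) if (length(v) > 0) stats::median(v) else NA_real_
      ),
      density = purrr::map(
        .data$rmsd_values,
        function(v) if (length(v) >= 2) stats::density(v) else NULL
      )
    )
}
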