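#' Wilks' lambda one-way MANOVA on patient centroids
#'
#' Tests whether cohorts separate in the retained eigenspace by one-way
#' multivariate analysis of variance on the patient centroid coordinates.
#' Wilks' lambda is \eqn{\Lambda = \det(E) / \det(E + H)} with E and H the
#' within- and between-group cross-product matrices; values near 1 mean no
#' separation, near 0 strong separation. The p-value uses Rao's F
#' approximation (exact for 2 groups or 2 response dimensions), as
#' implemented by [stats::manova()].
#'
#' @param centroids Tibble from [patient_centroids()] (or any tibble with
#'   `pc<k>` coordinate columns).
#' @param groups Name of the grouping column (default `"cohort"`), or a
#'   vector of group labels aligned to the rows.
#' @return An object of class `manova_result`: list with `wilks_lambda`,
#'   `approx_f`, `df_num`, `df_den`, `p_value`, `groups`, `n_per_group`,
#'   `dimensions`.
#' @export
wilks_lambda_manova <- function(centroids, groups = "cohort") {
  y <- score_matrix(centroids)
  g <- if (is.character(groups) && length(groups) == 1) {
    assert_columns(centroids, groups, "centroid table")
    centroids[[groups]]
  } else {
    groups
  }
  g <- factor(g)
  tab <- table(g)
  if (length(tab) < 2) {
    abort_ss("at least 2 groups are required", "strainscope_invalid_argument")
  }
  if (any(tab < 2)) {
    abort_ss("every group needs at least 2 centroids",
             "strainscope_invalid_argument")
  }
  if (nrow(y) <= ncol(y) + length(tab)) {
    abort_ss("total n must exceed dimensionality + number of groups",
             "strainscope_insufficient_data")
  }
  # explicit scatter matrices to diagnose degenerate cases:
  # E = within-group, H = between-group cross-products
  gmeans <- rowsum(y, g) / as.vector(tab)
  resid_w <- y - gmeans[as.integer(g), , drop = FALSE]
  E <- crossprod(resid_w)
  grand <- colMeans(y)
  H <- crossprod(sweep(gmeans, 2, grand) * sqrt(as.vector(tab)))
  if (det(E + H) <= 0) {
    abort_ss(
      "total scatter matrix is singular; reduce the retained dimensionality",
      "strainscope_singular_matrix"
    )
  }
  if (det(E) <= 0) {
    # perfect separation: no within-group variance in some direction
    rlang::warn("within-group scatter is singular; Wilks' lambda = 0, p-value degenerate")
    return(structure(
      list(wilks_lambda = 0, approx_f = Inf,
           df_num = ncol(y) * (length(tab) - 1), df_den = NA_real_,
           p_value = 0, groups = levels(g), n_per_group = as.integer(tab),
           dimensions = ncol(y)),
      class = "manova_result"
    ))
  }
  fit <- stats::manova(y ~ g)
  smry <- tryCatch(
    summary(fit, test = "Wilks")$stats,
    error = function(e) {
      abort_ss(
        paste0("MANOVA failed (singular within-group scatter?): ", conditionMessage(e),
               "; consider reducing the retained dimensionality"),
        "strainscope_singular_matrix"
      )
    }
  )
  structure(
    list(
      wilks_lambda = unname(smry["g", "Wilks"]),
      approx_f = unname(smry["g", "approx F"]),
      df_num = unname(smry["g", "num Df"]),
      df_den = unname(smry["g", "den Df"]),
      p_value = unname(smry["g", "Pr(>F)"]),
      groups = levels(g),
      n_per_group = as.integer(tab),
      dimensions = ncol(y)
    ),
    class = "manova_result"
  )
}

#' @export
print.manova_result <- function(x, ...) {
  cat(sprintf(
    "<manova_result> Wilks' lambda = %.3f, F(%g, %g) = %.2f, p = %.3g\n",
    x$wilks_lambda, x$df_num, x$df_den, x$approx_f, x$p_value
  ))
  cat("  groups:", paste(sprintf("%s (n=%d)", x$groups, x$n_per_group),
                         collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn wilks_lambda_manova One-row tidy summary.
#' @param x A `manova_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.manova_result <- function(x, ...) {
  tibble::tibble(
    statistic = x$wilks_lambda,
    approx_f = x$approx_f,
    df_num = x$df_num,
    df_den = x$df_den,
    p_value = x$p_value
  )
}

#' @describeIn wilks_lambda_manova Model-level summary.
#' @exportS3Method generics::glance
glance.manova_result <- function(x, ...) {
  tibble::tibble(
    n = sum(x$n_per_group),
    n_groups = length(x$groups),
    dimensions = x$dimensions,
    wilks_lambda = x$wilks_lambda,
    p_value = x$p_value
  )
}

#' Regress a centroid coordinate on a patient covariate
#'
#' Ordinary least squares of one retained-component centroid coordinate on
#' a numeric patient attribute (e.g. a measured peptide concentration),
#' reporting the Pearson correlation, slope, intercept and two-sided
#' p-value. Patients with a missing covariate are dropped pairwise and
#' counted.
#'
#' @param centroids Tibble from [patient_centroids()].
#' @param component Coordinate column to model, e.g. `"pc2"`.
#' @param covariate Tibble with `patient_id` and `value` columns, or a named
#'   numeric vector keyed by patient id.
#' @return One-row tibble: `component`, `r`, `slope`, `intercept`,
#'   `p_value`, `n`, `n_dropped`.
#' @export
centroid_covariate_regression <- function(centroids, component, covariate) {
  assert_columns(centroids, c("patient_id", component), "centroid table")
  if (!is.data.frame(covariate)) {
    covariate <- tibble::tibble(patient_id = names(covariate),
                                value = unname(covariate))
  }
  assert_columns(covariate, c("patient_id", "value"), "covariate table")
  joined <- dplyr::inner_join(
    centroids[c("patient_id", component)], covariate, by = "patient_id"
  )
  ok <- !is.na(joined$value) & !is.na(joined[[component]])
  n_dropped <- sum(!ok)
  joined <- joined[ok, ]
  if (nrow(joined) < 3) {
    abort_ss("need at least 3 patients with non-missing covariate",
             "strainscope_insufficient_data")
  }
  if (stats::sd(joined$value) == 0) {
    abort_ss("covariate has zero variance; correlation undefined",
             "strainscope_undefined_result")
  }
  y <- joined[[component]]
  x <- joined$value
  fit <- stats::lm(y ~ x)
  ct <- stats::cor.test(x, y)
  tibble::tibble(
    component = component,
    r = unname(ct$estimate),
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    p_value = ct$p.value,
    n = nrow(joined),
    n_dropped = n_dropped
  )
}

#' Rank-based association between patient values and a categorical label
#'
#' Distribution-free test of whether a per-patient quantity (e.g. a centroid
#' coordinate or RMSD) differs between categories: Mann-Whitney/Wilcoxon
#' rank-sum for 2 categories, Kruskal-Wallis for more. When every value is
#' identical there is nothing to discriminate and `p_value = 1` is returned
#' by policy.
#'
#' @param values Tibble with `patient_id` and `value`, or a named vector.
#' @param category Tibble with `patient_id` and `category`, or a named
#'   vector.
#' @return One-row tibble: `test`, `statistic`, `p_value`, `n`,
#'   `n_categories`.
#' @export
categorical_association <- function(values, category) {
  if (!is.data.frame(values)) {
    values <- tibble::tibble(patient_id = names(values),
                             value = unname(values))
  }
  if (!is.data.frame(category)) {
    category <- tibble::tibble(patient_id = names(category),
                               category = unname(category))
  }
  assert_columns(values, c("patient_id", "value"), "values table")
  assert_columns(category, c("patient_id", "category"), "category table")
  joined <- dplyr::inner_join(values, category, by = "patient_id")
  joined <- joined[!is.na(joined$value) & !is.na(joined$category), ]
  tab <- table(joined$category)
  tab <- tab[tab > 0]
  if (length(tab) < 2 || any(tab < 2)) {
    abort_ss("need at least 2 categories with at least 2 patients each",
             "strainscope_invalid_argument")
  }
  if (stats::sd(joined$value) == 0) {
    return(tibble::tibble(
      test = "degenerate", statistic = NA_real_, p_value = 1,
      n = nrow(joined), n_categories = length(tab)
    ))
  }
  if (length(tab) == 2) {
    lv <- names(tab)
    res <- suppressWarnings(stats::wilcox.test(
      joined$value[joined$category == lv[1]],
      joined$value[joined$category == lv[2]]
    ))
    test <- "wilcoxon_rank_sum"
  } else {
    res <- stats::kruskal.test(joined$value, factor(joined$category))
    test <- "kruskal_wallis"
  }
  tibble::tibble(
    test = test,
    statistic = unname(res$statistic),
    p_value = res$p.value,
    n = nrow(joined),
    n_categories = length(tab)
  )
}

#' Run a grid of centroid-covariate regressions
#'
#' Applies [centroid_covariate_regression()] over every combination of
#' retained coordinate column and covariate column, optionally adding
#' Benjamini-Hochberg adjusted p-values (nominal p-values are the default
#' report).
#'
#' @param centroids Tibble from [patient_centroids()].
#' @param covariates Tibble with `patient_id` and one numeric column per
#'   covariate.
#' @param adjust Add a BH-adjusted `p_adj` column (default FALSE).
#' @return Tidy tibble, one row per component x covariate.
#' @export
regression_grid <- function(centroids, covariates, adjust = FALSE) {
  assert_columns(covariates, "patient_id", "covariates table")
  comp_cols <- pc_columns(centroids)
  cov_cols <- setdiff(names(covariates), "patient_id")
  cov_cols <- cov_cols[vapply(covariates[cov_cols], is.numeric, logical(1))]
  out <- purrr::map_dfr(comp_cols, function(comp) {
    purrr::map_dfr(cov_cols, function(cv) {
      res <- centroid_covariate_regression(
        centroids, comp,
        tibble::tibble(patient_id = covariates$patient_id,
                       value = covariates[[cv]])
      )
      dplyr::mutate(res, covariate = cv, .after = "component")
    })
  })
  if (adjust) {
    out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  }
  out
}
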