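# Multivariate Gaussian KDE with full data covariance, evaluated exactly at
# arbitrary query points. Bandwidth matrix H = cov(X) * factor^2 with the
# Scott (n^(-1/(d+4))) or Silverman ((n(d+2)/4)^(-1/(d+4))) factor, or a
# user-fixed factor. Densities are computed in a whitened coordinate system
# (Cholesky of H), chunked over queries to bound memory.

kde_bandwidth_factor <- function(n, d, rule, fixed = NULL) {
  switch(rule,
    scott = n^(-1 / (d + 4)),
    silverman = (n * (d + 2) / 4)^(-1 / (d + 4)),
    fixed = {
      if (is.null(fixed) || fixed <= 0) {
        abort_ss("bandwidth_rule = 'fixed' requires a positive fixed_bandwidth",
                 "strainscope_invalid_argument")
      }
      fixed
    },
    abort_ss("unknown bandwidth rule", "strainscope_invalid_argument")
  )
}

kde_eval <- function(query, ref, H) {
  d <- ncol(ref)
  L <- t(chol(H)) # lower triangular, H = L L'
  uref <- t(forwardsolve(L, t(ref)))
  uq <- t(forwardsolve(L, t(query)))
  norm_const <- (2 * pi)^(-d / 2) / prod(diag(L)) / nrow(ref)
  out <- numeric(nrow(uq))
  chunk <- max(1L, as.integer(2e6 / nrow(ref)))
  refsq <- rowSums(uref^2)
  for (start in seq(1, nrow(uq), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(uq))
    qi <- uq[idx, , drop = FALSE]
    # squared pairwise distances ||q - r||^2 via the cross-product identity
    d2 <- outer(rowSums(qi^2), refsq, `+`) - 2 * tcrossprod(qi, uref)
    d2[d2 < 0] <- 0
    out[idx] <- rowSums(exp(-0.5 * d2)) * norm_const
  }
  out
}

#' Fit a KDE coverage region from reference scores
#'
#' Fits a Gaussian kernel density estimate on a reference cohort's plaque
#' scores and calibrates a density threshold so that a stated fraction of
#' the reference points lie inside the super-level set
#' \{density >= threshold\}. With the default quantile calibration the
#' threshold is the value t such that `ceiling(coverage * N)` reference
#' points have estimated density >= t. An alternative `"mass"` calibration
#' chooses t so the integrated probability mass above t equals `coverage`
#' (evaluated on a mesh grid).
#'
#' @param reference A score set ([project_scores()]) or any tibble with
#'   `pc<k>` columns; typically all plaques of one reference cohort.
#' @param coverage Fraction of the reference to enclose (default 0.995).
#' @param bandwidth_rule One of `"scott"` (default), `"silverman"`,
#'   `"fixed"`.
#' @param fixed_bandwidth Bandwidth factor used when
#'   `bandwidth_rule = "fixed"` (multiplies the data covariance Cholesky).
#' @param calibration `"quantile"` (default) or `"mass"`.
#' @param grid_n Mesh resolution per axis for `"mass"` calibration.
#' @return An object of class `density_region` with the reference matrix,
#'   bandwidth matrix `H`, `density_threshold`, `coverage`, and settings.
#' @export
fit_density_region <- function(reference, coverage = 0.995,
                               bandwidth_rule = c("scott", "silverman", "fixed"),
                               fixed_bandwidth = NULL,
                               calibration = c("quantile", "mass"),
                               grid_n = 128) {
  bandwidth_rule <- match.arg(bandwidth_rule)
  calibration <- match.arg(calibration)
  if (coverage <= 0 || coverage >= 1) {
    abort_ss("coverage must lie strictly between 0 and 1",
             "strainscope_invalid_argument")
  }
  x <- score_matrix(reference)
  n <- nrow(x)
  d <- ncol(x)
  if (n < d + 1) {
    abort_ss("reference must have at least dimensionality + 1 points",
             "strainscope_insufficient_data")
  }
  S <- stats::cov(x)
  if (any(diag(S) <= 0) || det(S) <= 0) {
    abort_ss("reference scores are degenerate (singular covariance); cannot fit KDE",
             "strainscope_singular_kde")
  }
  f <- kde_bandwidth_factor(n, d, bandwidth_rule, fixed_bandwidth)
  H <- S * f^2

  self_density <- kde_eval(x, x, H)
  threshold <- if (calibration == "quantile") {
    k <- ceiling(coverage * n)
    sort(self_density, decreasing = TRUE)[k]
  } else {
    mass_threshold(x, H, coverage, grid_n)
  }
  structure(
    list(
      reference = x,
      n = n, d = d,
      H = H,
      bandwidth_rule = bandwidth_rule,
      bandwidth_factor = f,
      coverage = coverage,
      calibration = calibration,
      density_threshold = threshold
    ),
    class = "density_region"
  )
}

# threshold such that the KDE probability mass above it equals `coverage`,
# approximated on an axis-aligned mesh extending 4 kernel sds past the data
mass_threshold <- function(x, H, coverage, grid_n) {
  pad <- 4 * sqrt(diag(H))
  axes <- lapply(seq_len(ncol(x)), function(j) {
    seq(min(x[, j]) - pad[j], max(x[, j]) + pad[j], length.out = grid_n)
  })
  mesh <- as.matrix(expand.grid(axes))
  dens <- kde_eval(mesh, x, H)
  cell <- prod(vapply(axes, function(a) a[2] - a[1], numeric(1)))
  ord <- order(dens, decreasing = TRUE)
  cum_mass <- cumsum(dens[ord]) * cell
  dens[ord][which(cum_mass >= coverage)[1]]
}

#' @export
print.density_region <- function(x, ...) {
  cat(sprintf(
    "<density_region> %d reference points, %d-D, coverage %.3f (%s calibration, %s bandwidth)\n",
    x$n, x$d, x$coverage, x$calibration, x$bandwidth_rule
  ))
  cat(sprintf("  density threshold: %.4g\n", x$density_threshold))
  invisible(x)
}

#' Evaluate region density / membership at query scores
#'
#' @param region A [fit_density_region()] object.
#' @param scores A score set with the same `pc<k>` columns as the reference.
#' @return `region_density()`: numeric KDE density per query row;
#'   `in_region()`: logical, density >= threshold.
#' @export
region_density <- function(region, scores) {
  stopifnot(inherits(region, "density_region"))
  q <- score_matrix(scores)
  if (ncol(q) != region$d) {
    abort_ss("query dimensionality does not match the fitted region",
             "strainscope_invalid_argument")
  }
  kde_eval(q, region$reference, region$H)
}

#' @rdname region_density
#' @export
in_region <- function(region, scores) {
  region_density(region, scores) >= region$density_threshold
}

#' Classify plaques against shared strain-space regions
#'
#' Evaluates each query plaque against the ADNC and AD coverage regions and
#' assigns one of four mutually exclusive labels. Plaques outside both
#' regions carry spectral signatures not represented in either reference
#' cohort — the operational definition of cohort-unique strains.
#'
#' @param query A score set ([project_scores()]).
#' @param adnc_region,ad_region [fit_density_region()] objects fitted in the
#'   same retained-component space as `query`.
#' @return The query tibble with a `membership` factor with levels
#'   `in_both`, `in_ADNC_region`, `in_AD_region`, `outside_both`.
#' @export
classify_membership <- function(query, adnc_region, ad_region) {
  if (nrow(query) == 0) {
    query$membership <- factor(character(),
                               levels = membership_levels())
    return(query)
  }
  in_adnc <- in_region(adnc_region, query)
  in_ad <- in_region(ad_region, query)
  lab <- dplyr::case_when(
    in_adnc & in_ad ~ "in_both",
    in_adnc ~ "in_ADNC_region",
    in_ad ~ "in_AD_region",
    TRUE ~ "outside_both"
  )
  query$membership <- factor(lab, levels = membership_levels())
  query
}

membership_levels <- function() {
  c("in_both", "in_ADNC_region", "in_AD_region", "outside_both")
}

#' Tabulate membership labels by a grouping column
#'
#' @param labels Output of [classify_membership()].
#' @param by Column to stratify on (default `cohort`); e.g. a patient-level
#'   pathology grade joined onto the labels.
#' @return Tibble of counts and within-group fractions per label.
#' @export
membership_summary <- function(labels, by = "cohort") {
  assert_columns(labels, c("membership", by), "membership table")
  labels %>%
    dplyr::count(.data[[by]], .data$membership, .drop = FALSE) %>%
    dplyr::group_by(.data[[by]]) %>%
    dplyr::mutate(fraction = if (sum(.data$n) > 0) {
      .data$n / sum(.data$n)
    } else {
      0
    }) %>%
    dplyr::ungroup()
}
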