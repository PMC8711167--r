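# Independent brute-force oracles used across tests. These deliberately
# avoid the package's own code paths (explicit loops, direct formula
# evaluation, base eigendecompositions).

# weighted distance, term-by-term from the defining equation
oracle_weighted_distance <- function(point, center, weights) {
  acc <- 0
  for (j in seq_along(point)) {
    acc <- acc + (point[j] - center[j])^2 * weights[j]^2
  }
  sqrt(acc)
}

# weighted RMSD via an explicit loop over the two equations
oracle_weighted_rmsd <- function(points, center, weights) {
  n <- nrow(points)
  total <- 0
  for (i in seq_len(n)) {
    di <- oracle_weighted_distance(points[i, ], center, weights)
    total <- total + di^2
  }
  sqrt(total / (n - 1))
}

# PCA scores via direct eigendecomposition of the sample covariance
oracle_pca_scores <- function(x) {
  xc <- sweep(x, 2, colMeans(x))
  eg <- eigen(stats::cov(x), symmetric = TRUE)
  list(scores = xc %*% eg$vectors, values = eg$values)
}

# align the sign of each column of a to the matching column of b
align_signs <- function(a, b) {
  for (j in seq_len(ncol(a))) {
    s <- sum(a[, j] * b[, j])
    if (s < 0) a[, j] <- -a[, j]
  }
  a
}

# Gaussian KDE self-densities by an O(N^2) pairwise kernel sum with the
# multivariate normal density written out explicitly per pair
oracle_kde_self_densities <- function(x, H) {
  n <- nrow(x)
  d <- ncol(x)
  Hinv <- solve(H)
  norm_const <- 1 / sqrt((2 * pi)^d * det(H))
  dens <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(n)) {
      diff <- x[i, ] - x[j, ]
      s <- s + exp(-0.5 * as.numeric(t(diff) %*% Hinv %*% diff))
    }
    dens[i] <- s * norm_const / n
  }
  dens
}

# piecewise-linear interpolation at a point by explicit interval search
oracle_linear_interp <- function(xs, ys, x0) {
  if (x0 <= xs[1]) return(ys[1])
  if (x0 >= xs[length(xs)]) return(ys[length(ys)])
  i <- max(which(xs <= x0))
  if (xs[i] == x0) return(ys[i])
  ys[i] + (ys[i + 1] - ys[i]) * (x0 - xs[i]) / (xs[i + 1] - xs[i])
}

# small long-format spectra table with known structure: one patient per
# cohort unless stated, deterministic intensities
make_long_spectra <- function(n_plaques = 4, grid = wavelength_grid(),
                              dyes = c("curcumin", "FSB", "BF-188"),
                              cohort = "DS", patient_id = "p01") {
  purrr::map_dfr(seq_len(n_plaques), function(q) {
    purrr::map_dfr(seq_along(dyes), function(di) {
      tibble::tibble(
        plaque_id = sprintf("%s_q%03d", patient_id, q),
        patient_id = patient_id,
        cohort = cohort,
        dye = dyes[di],
        wavelength_nm = grid$channels,
        intensity = 1 + abs(sin(grid$channels / (40 + 7 * q + 3 * di)))
      )
    })
  })
}

# score-set tibble from a coordinate matrix, with weights attribute
make_score_set <- function(coords, patient_id, cohort,
                           retained = seq_len(ncol(coords)) + 1,
                           weights = rep(1, ncol(coords))) {
  colnames(coords) <- sprintf("pc%d", retained)
  out <- dplyr::bind_cols(
    tibble::tibble(
      plaque_id = sprintf("q%04d", seq_len(nrow(coords))),
      patient_id = patient_id,
      cohort = cohort
    ),
    tibble::as_tibble(coords)
  )
  attr(out, "retained") <- as.integer(retained)
  attr(out, "weights") <- weights
  out
}

# IoU-based matching of predicted labels against a truth label image
match_labels_iou <- function(pred, truth, min_iou = 0.5) {
  truth_ids <- setdiff(unique(as.vector(truth)), 0)
  pred_ids <- setdiff(unique(as.vector(pred)), 0)
  matched_truth <- logical(length(truth_ids))
  matched_pred <- logical(length(pred_ids))
  for (ti in seq_along(truth_ids)) {
    tm <- truth == truth_ids[ti]
    for (pi in seq_along(pred_ids)) {
      if (matched_pred[pi]) next
      pm <- pred == pred_ids[pi]
      iou <- sum(tm & pm) / sum(tm | pm)
      if (iou >= min_iou) {
        matched_truth[ti] <- TRUE
        matched_pred[pi] <- TRUE
        break
      }
    }
  }
  list(
    recall = if (length(truth_ids)) mean(matched_truth) else 1,
    precision = if (length(pred_ids)) mean(matched_pred) else 1
  )
}
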