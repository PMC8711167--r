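make_centroids <- function(coords, groups) {
  make_score_set(coords, patient_id = sprintf("p%03d", seq_len(nrow(coords))),
                 cohort = groups, weights = rep(1, ncol(coords)))
}

test_that("Wilks' lambda equals the explicit scatter-matrix ratio on a fixed fixture", {
  coords <- rbind(
    c(0.0, 0.1), c(0.2, -0.1), c(-0.1, 0.0), c(0.1, 0.2),
    c(0.0, -0.2), c(-0.2, 0.1),
    c(1.0, 1.1), c(1.2, 0.9), c(0.9, 1.0), c(1.1, 1.2),
    c(1.0, 0.8), c(0.8, 1.1)
  )
  g <- rep(c("a", "b"), each = 6)
  res <- wilks_lambda_manova(make_centroids(coords, g))

  # independent scatter-matrix computation
  E <- matrix(0, 2, 2)
  for (grp in unique(g)) {
    xg <- coords[g == grp, ]
    cg <- colMeans(xg)
    for (i in seq_len(nrow(xg))) {
      v <- xg[i, ] - cg
      E <- E + tcrossprod(v)
    }
  }
  grand <- colMeans(coords)
  H <- matrix(0, 2, 2)
  for (grp in unique(g)) {
    xg <- coords[g == grp, ]
    v <- colMeans(xg) - grand
    H <- H + nrow(xg) * tcrossprod(v)
  }
  lambda_oracle <- det(E) / det(E + H)
  expect_equal(res$wilks_lambda, lambda_oracle, tolerance = 1e-10)
  expect_true(res$p_value >= 0 && res$p_value <= 1)
  expect_true(res$wilks_lambda > 0 && res$wilks_lambda <= 1)
})

test_that("zero within-group variance with distinct means gives lambda = 0", {
  coords <- rbind(matrix(rep(c(0, 0), 4), ncol = 2, byrow = TRUE),
                  matrix(rep(c(1, 2), 4), ncol = 2, byrow = TRUE),
                  matrix(rep(c(2, 1), 4), ncol = 2, byrow = TRUE))
  g <- rep(c("a", "b", "c"), each = 4)
  expect_warning(res <- wilks_lambda_manova(make_centroids(coords, g)),
                 "singular")
  expect_equal(res$wilks_lambda, 0)
  expect_equal(res$p_value, 0)
})

test_that("Wilks' lambda is invariant under invertible affine maps of the centroids", {
  set.seed(41)
  coords <- rbind(matrix(rnorm(24), 12, 2),
                  matrix(rnorm(24, mean = 1), 12, 2))
  g <- rep(c("a", "b"), each = 12)
  base <- wilks_lambda_manova(make_centroids(coords, g))$wilks_lambda
  for (i in 1:5) {
    A <- matrix(rnorm(4), 2, 2)
    while (abs(det(A)) < 0.1) A <- matrix(rnorm(4), 2, 2)
    b <- rnorm(2)
    mapped <- sweep(coords %*% t(A), 2, b, `+`)
    lam <- wilks_lambda_manova(make_centroids(mapped, g))$wilks_lambda
    expect_equal(lam, base, tolerance = 1e-8)
  }
})

test_that("MANOVA input validation catches degenerate designs", {
  set.seed(1)
  coords <- matrix(rnorm(20), 10, 2)
  expect_error(wilks_lambda_manova(make_centroids(coords, rep("a", 10))),
               class = "strainscope_invalid_argument")
  expect_error(
    wilks_lambda_manova(make_centroids(coords, c("a", rep("b", 9)))),
    class = "strainscope_invalid_argument"
  )
})

test_that("MANOVA null type-I error is near nominal", {
  set.seed(52)
  alpha <- 0.05
  n_rep <- 400
  rejections <- 0
  g <- rep(c("a", "b"), each = 15)
  for (i in seq_len(n_rep)) {
    coords <- matrix(rnorm(60), 30, 2)
    p <- wilks_lambda_manova(make_centroids(coords, g))$p_value
    if (p < alpha) rejections <- rejections + 1
  }
  expect_gt(rejections / n_rep, 0.01)
  expect_lt(rejections / n_rep, 0.10)
})

test_that("centroid-covariate regression recovers exact and simulated relationships", {
  set.seed(61)
  coords <- matrix(rnorm(40), 20, 2)
  cen <- make_centroids(coords, rep("DS", 20))

  # covariate identical to the coordinate: r = 1, slope = 1
  cov_tbl <- tibble::tibble(patient_id = cen$patient_id, value = cen$pc2)
  res <- centroid_covariate_regression(cen, "pc2", cov_tbl)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_equal(res$slope, 1, tolerance = 1e-12)

  # r matches a brute-force covariance/variance computation
  cov2 <- tibble::tibble(patient_id = cen$patient_id, value = rnorm(20))
  res2 <- centroid_covariate_regression(cen, "pc3", cov2)
  x <- cov2$value; y <- cen$pc3
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res2$r, r_manual, tolerance = 1e-12)

  # missing covariates dropped pairwise and counted
  cov3 <- cov2
  cov3$value[1:4] <- NA
  res3 <- centroid_covariate_regression(cen, "pc2", cov3)
  expect_equal(res3$n, 16)
  expect_equal(res3$n_dropped, 4)

  expect_error(
    centroid_covariate_regression(
      cen, "pc2", tibble::tibble(patient_id = cen$patient_id, value = 1)
    ),
    class = "strainscope_undefined_result"
  )
})

test_that("regression slope recovery is calibrated to its standard error", {
  true_slope <- 0.8
  hits <- 0
  for (s in 1:100) {
    set.seed(7000 + s)
    x <- rnorm(30)
    y <- 0.2 + true_slope * x + rnorm(30, sd = 0.5)
    cen <- make_centroids(cbind(y, rnorm(30)), rep("DS", 30))
    res <- centroid_covariate_regression(
      cen, "pc2", tibble::tibble(patient_id = cen$patient_id, value = x)
    )
    se <- summary(stats::lm(y ~ x))$coefficients[2, 2]
    if (abs(res$slope - true_slope) <= 2 * se) hits <- hits + 1
  }
  # +/- 2 SE is a ~94.5% interval under t(28); 90/100 is a 3-sigma lower bound
  expect_gte(hits, 90)
})

test_that("rank tests behave at the null, at complete separation, and under ties", {
  # permuted labels: near-nominal type-I error
  set.seed(71)
  alpha <- 0.05
  rej <- 0
  for (i in 1:300) {
    vals <- tibble::tibble(patient_id = sprintf("p%d", 1:20),
                           value = rnorm(20))
    cats <- tibble::tibble(patient_id = vals$patient_id,
                           category = sample(rep(c("x", "y"), each = 10)))
    if (categorical_association(vals, cats)$p_value < alpha) rej <- rej + 1
  }
  expect_gt(rej / 300, 0.005)
  expect_lt(rej / 300, 0.12)

  # complete separation of two groups of 10: the exact minimal p-value
  vals <- tibble::tibble(patient_id = sprintf("p%d", 1:20),
                         value = c(1:10, 101:110))
  cats <- tibble::tibble(patient_id = vals$patient_id,
                         category = rep(c("lo", "hi"), each = 10))
  res <- categorical_association(vals, cats)
  expect_equal(res$test, "wilcoxon_rank_sum")
  expect_equal(res$p_value, 2 / choose(20, 10), tolerance = 1e-12)

  # all values identical: p = 1 by policy
  vals$value <- 5
  expect_equal(categorical_association(vals, cats)$p_value, 1)

  # three groups dispatch to Kruskal-Wallis
  cats3 <- tibble::tibble(patient_id = sprintf("p%d", 1:20),
                          category = rep(c("a", "b", "c"),
                                         length.out = 20))
  vals3 <- tibble::tibble(patient_id = cats3$patient_id, value = rnorm(20))
  expect_equal(categorical_association(vals3, cats3)$test, "kruskal_wallis")
})

test_that("the regression grid runs every component x covariate pair", {
  set.seed(81)
  cen <- make_centroids(matrix(rnorm(40), 20, 2), rep("DS", 20))
  covs <- tibble::tibble(patient_id = cen$patient_id,
                         abeta40 = rnorm(20), abeta42 = rnorm(20))
  grid <- regression_grid(cen, covs, adjust = TRUE)
  expect_equal(nrow(grid), 4)
  expect_true(all(c("component", "covariate", "r", "p_value", "p_adj") %in%
                    names(grid)))
})
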