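test_that("weighted distance follows the defining equation", {
  expect_equal(weighted_distance(c(1, 2, 3), c(1, 2, 3), c(0.5, 0.3, 0.1)), 0)
  # hand evaluation: sqrt((2-0)^2 * 0.5^2) = 1
  expect_equal(weighted_distance(c(2, 0, 0), c(0, 0, 0), c(0.5, 1, 1)), 1.0)
  expect_error(weighted_distance(c(1, 2), c(1, 2, 3), c(1, 1, 1)),
               class = "strainscope_invalid_argument")

  set.seed(10)
  for (i in 1:50) {
    p <- rnorm(3); cen <- rnorm(3); w <- runif(3)
    expect_equal(weighted_distance(p, cen, w),
                 oracle_weighted_distance(p, cen, w), tolerance = 1e-12)
  }
})

test_that("weighted RMSD follows the defining equation and handles N < 2", {
  pts <- matrix(c(0, 2), ncol = 1)
  # d_i = 0.5 each; rmsd = sqrt((0.25 + 0.25) / 1) = sqrt(0.5)
  expect_equal(weighted_rmsd(pts, 1, 0.5), sqrt(0.5))

  same <- matrix(rep(c(1, 2, 3), 5), 5, 3, byrow = TRUE)
  expect_equal(weighted_rmsd(same, c(1, 2, 3), c(0.2, 0.3, 0.5)), 0)

  expect_true(is.na(weighted_rmsd(matrix(1:3, 1), c(1, 2, 3), c(1, 1, 1))))

  set.seed(11)
  for (i in 1:50) {
    n <- sample(2:12, 1)
    pts <- matrix(rnorm(n * 3), n, 3)
    cen <- rnorm(3); w <- runif(3)
    expect_equal(weighted_rmsd(pts, cen, w),
                 oracle_weighted_rmsd(pts, cen, w), tolerance = 1e-12)
  }
})

test_that("RMSD scales with the coordinates and ignores zero-weight components", {
  set.seed(12)
  pts <- matrix(rnorm(30), 10, 3)
  cen <- colMeans(pts)
  w <- c(0.5, 0.3, 0.2)
  base <- weighted_rmsd(pts, cen, w)
  expect_equal(weighted_rmsd(pts * 4, cen * 4, w), 4 * base,
               tolerance = 1e-12)
  # zero weight on the 3rd axis == dropping the 3rd axis
  expect_equal(weighted_rmsd(pts, cen, c(w[1:2], 0)),
               weighted_rmsd(pts[, 1:2], cen[1:2], w[1:2]),
               tolerance = 1e-12)
})

test_that("per-patient heterogeneity is zero for coincident plaques, symmetric, and monotone in dispersion", {
  coords <- rbind(matrix(1, 4, 2), matrix(1, 4, 2))
  sc <- make_score_set(coords, patient_id = rep(c("a", "b"), each = 4),
                       cohort = "DS", weights = c(0.6, 0.4))
  pp <- per_patient_heterogeneity(sc)
  expect_equal(pp$rmsd, c(0, 0))
  expect_equal(pp$n_vectors, c(4L, 4L))

  # two patients with identical (shifted) clouds get identical rmsd
  set.seed(13)
  cloud <- matrix(rnorm(60), 30, 2)
  sc <- make_score_set(rbind(cloud, cloud + 5),
                       patient_id = rep(c("a", "b"), each = 30),
                       cohort = "DS", weights = c(0.6, 0.4))
  pp <- per_patient_heterogeneity(sc)
  expect_equal(pp$rmsd[1], pp$rmsd[2], tolerance = 1e-12)

  # single-vector patient: undefined
  solo <- make_score_set(matrix(c(1, 1), 1), "solo", "AD",
                         weights = c(1, 1))
  expect_true(is.na(per_patient_heterogeneity(solo)$rmsd))

  # sigma_A > sigma_B recovered in >= 95% of 100 seeded draws at n = 30
  wins <- 0
  for (s in 1:100) {
    set.seed(1000 + s)
    a <- matrix(rnorm(60, sd = 0.10), 30, 2)
    b <- matrix(rnorm(60, sd = 0.05), 30, 2)
    sc <- make_score_set(rbind(a, b),
                         patient_id = rep(c("a", "b"), each = 30),
                         cohort = "DS", weights = c(0.5, 0.5))
    pp <- per_patient_heterogeneity(sc)
    if (pp$rmsd[pp$patient_id == "a"] > pp$rmsd[pp$patient_id == "b"]) {
      wins <- wins + 1
    }
  }
  expect_gte(wins, 95)
})

test_that("per-cohort heterogeneity is zero for identical centroids and label-invariant", {
  cen <- make_score_set(matrix(1, 5, 2), patient_id = sprintf("p%d", 1:5),
                        cohort = "DS", weights = c(0.5, 0.5))
  cen <- dplyr::rename(cen, n_plaques = plaque_id) # centroid-shaped table
  cc <- per_cohort_heterogeneity(cen, weights = c(0.5, 0.5))
  expect_equal(cc$rmsd, 0)

  set.seed(14)
  coords <- matrix(rnorm(20), 10, 2)
  c1 <- make_score_set(coords, patient_id = sprintf("p%d", 1:10),
                       cohort = "AD", weights = c(0.5, 0.5))
  c2 <- make_score_set(coords[sample(10), ], patient_id = sprintf("r%d", 1:10),
                       cohort = "AD", weights = c(0.5, 0.5))
  expect_equal(per_cohort_heterogeneity(c1)$rmsd,
               per_cohort_heterogeneity(c2)$rmsd, tolerance = 1e-12)

  solo <- make_score_set(matrix(c(1, 2), 1), "p1", "ADNC",
                         weights = c(1, 1))
  expect_true(is.na(per_cohort_heterogeneity(solo)$rmsd))
})

test_that("stratified heterogeneity partitions patients and reflects generated mixing", {
  pp <- tibble::tibble(
    patient_id = sprintf("p%d", 1:6), cohort = "DS",
    n_vectors = 10L, rmsd = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  )
  one <- stratified_heterogeneity(
    pp, tibble::tibble(patient_id = pp$patient_id, stratum = "all")
  )
  expect_equal(one$n, 6)
  expect_equal(sort(one$rmsd_values[[1]]), pp$rmsd)

  # empty stratum (unused factor level) yields an empty list, no error
  strata <- tibble::tibble(
    patient_id = pp$patient_id,
    stratum = factor(rep("low", 6), levels = c("low", "high"))
  )
  two <- stratified_heterogeneity(pp, strata)
  expect_equal(nrow(two), 2)
  expect_equal(two$n[two$stratum == "high"], 0L)
  expect_length(two$rmsd_values[[which(two$stratum == "high")]], 0)

  expect_error(
    stratified_heterogeneity(pp, strata[1:3, ]),
    class = "strainscope_invalid_argument"
  )

  # patients generated with more archetype mixing carry higher RMSD
  arch <- generate_archetypes(4, seed = 18)
  cfg <- cohort_config(
    patients_per_cohort = c(DS = 14, AD = 2, ADNC = 2),
    plaques_per_patient = c(15, 25),
    patient_diversity = c(0, 1),
    seed = 19
  )
  ds <- generate_cohort_dataset(cfg, arch)
  comp <- build_composite(ds$spectra, seed = 3)
  space <- fit_strain_space(comp)
  sc <- project_scores(comp, space, retained = 2:4)
  pp <- per_patient_heterogeneity(sc)
  strata <- tibble::tibble(
    patient_id = ds$patients$patient_id,
    stratum = ifelse(ds$patients$x_tau_sim >= 3, "high", "low")
  )
  res <- stratified_heterogeneity(pp, strata)
  med <- setNames(res$median_rmsd, as.character(res$stratum))
  expect_gt(med[["high"]], med[["low"]])
})
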