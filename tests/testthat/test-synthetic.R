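test_that("archetype generation is deterministic, distinct, and non-collinear", {
  a1 <- generate_archetypes(1, seed = 7)
  a2 <- generate_archetypes(1, seed = 7)
  expect_identical(a1$intensity, a2$intensity)

  expect_error(generate_archetypes(0), class = "strainscope_invalid_argument")

  # pairwise peak-channel signatures differ in at least one dye
  a3 <- generate_archetypes(3, seed = 1)
  peaks <- a3 %>%
    dplyr::group_by(archetype_id, dye) %>%
    dplyr::summarise(peak = which.max(intensity), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = dye, values_from = peak)
  sig <- apply(peaks[-1], 1, paste, collapse = "-")
  expect_equal(length(unique(sig)), 3)

  # cosine similarity of max-normalized concatenated profiles < 1
  a4 <- generate_archetypes(2, seed = 5)
  profs <- lapply(split(a4, a4$archetype_id), function(a) {
    v <- unlist(lapply(split(a, a$dye), function(d) {
      d$intensity / max(d$intensity)
    }))
    unname(v)
  })
  cosine <- sum(profs[[1]] * profs[[2]]) /
    sqrt(sum(profs[[1]]^2) * sum(profs[[2]]^2))
  expect_lt(cosine, 1 - 1e-6)
})

test_that("cohort dataset generation respects structure, determinism and the empty case", {
  arch <- generate_archetypes(4, seed = 2)
  cfg <- cohort_config(patients_per_cohort = c(DS = 2, AD = 2, ADNC = 2),
                       plaques_per_patient = c(3, 6), seed = 11)
  ds <- generate_cohort_dataset(cfg, arch)

  # every plaque: exactly 3 dyes x 40 channels; one truth label per plaque
  per_plaque <- ds$spectra %>%
    dplyr::count(plaque_id, dye)
  expect_true(all(per_plaque$n == 40))
  n_dyes <- ds$spectra %>%
    dplyr::distinct(plaque_id, dye) %>%
    dplyr::count(plaque_id)
  expect_true(all(n_dyes$n == 3))
  expect_setequal(unique(ds$spectra$plaque_id), ds$truth$plaque_id)
  expect_equal(anyDuplicated(ds$truth$plaque_id), 0)

  # determinism
  ds2 <- generate_cohort_dataset(cfg, arch)
  expect_identical(ds$spectra$intensity, ds2$spectra$intensity)
  expect_identical(ds$patients$abeta42, ds2$patients$abeta42)

  # empty cohorts
  cfg0 <- cohort_config(patients_per_cohort = c(DS = 0, AD = 0, ADNC = 0))
  ds0 <- generate_cohort_dataset(cfg0, arch)
  expect_equal(nrow(ds0$spectra), 0)
  expect_equal(nrow(ds0$patients), 0)
})

test_that("a noise-free single-archetype dataset yields identical composite vectors", {
  arch <- generate_archetypes(1, seed = 3)
  cfg <- cohort_config(
    patients_per_cohort = c(DS = 2, AD = 2, ADNC = 2),
    archetype_mixture = list(DS = 1, AD = 1, ADNC = 1),
    plaques_per_patient = c(2, 4),
    noise_sd = 0, batch_shift_magnitude = 0, seed = 4
  )
  ds <- generate_cohort_dataset(cfg, arch)
  comp <- build_composite(ds$spectra, seed = 1)
  vals <- as.matrix(comp[grep("^v", names(comp))])
  expect_true(all(abs(sweep(vals, 2, vals[1, ])) < 1e-12))
})

test_that("cohort-unique archetype frequency matches its mixture weight", {
  arch <- generate_archetypes(4, seed = 6)
  cfg <- cohort_config(
    patients_per_cohort = c(DS = 20, AD = 5, ADNC = 5),
    plaques_per_patient = c(20, 30),
    patient_diversity = c(1, 1), # iid draws from the cohort mixture
    seed = 8
  )
  ds <- generate_cohort_dataset(cfg, arch)
  ds_truth <- ds$truth[ds$truth$cohort == "DS", ]
  n <- nrow(ds_truth)
  frac <- mean(ds_truth$archetype_id == "arch04")
  ci <- 3 * sqrt(0.3 * 0.7 / n)
  expect_lt(abs(frac - 0.3), ci)
  # the unique archetype never occurs outside DS
  expect_false(any(ds$truth$archetype_id[ds$truth$cohort != "DS"] == "arch04"))
})

test_that("lambda-stack scenes honor truth masks, determinism and the closed-form mean spectrum", {
  arch <- generate_archetypes(2, seed = 5)

  empty <- generate_lambda_stack(
    scene_config(n_plaques = 0, pixel_noise_sd = 0, seed = 1), arch
  )
  expect_true(all(empty$truth_mask == 0))

  sc <- scene_config(n_plaques = 1, background = 0, pixel_noise_sd = 0,
                     archetype_ids = "arch01", seed = 2)
  st <- generate_lambda_stack(sc, arch)
  st2 <- generate_lambda_stack(sc, arch)
  expect_identical(st$volumes, st2$volumes)

  # noiseless disk: mean in-mask spectrum = archetype profile x mean falloff
  mask <- st$truth_mask == 1
  mean_falloff <- st$plaques$mean_falloff[1]
  prof <- arch$intensity[arch$archetype_id == "arch01" &
                           arch$dye == "curcumin"]
  extracted <- vapply(seq_along(st$wavelengths), function(k) {
    mean(st$volumes[["curcumin"]][, , k][mask])
  }, numeric(1))
  expect_equal(extracted, prof * mean_falloff, tolerance = 1e-12)
})

test_that("lambda stacks round-trip through TIFF + sidecar files", {
  arch <- generate_archetypes(2, seed = 5)
  st <- generate_lambda_stack(
    scene_config(width = 48, height = 40, n_plaques = 2, radius_range = c(5, 8),
                 pixel_noise_sd = 0, seed = 3), arch
  )
  dir <- withr::local_tempdir()
  write_lambda_stack(st, dir)
  rt <- read_lambda_stack(dir)
  expect_equal(rt$wavelengths, st$wavelengths)
  expect_equal(rt$truth_mask, st$truth_mask)
  for (d in st$dyes) {
    expect_equal(rt$volumes[[d]], st$volumes[[d]], tolerance = 1e-6)
  }
})

test_that("generated pathology counts round-trip through scoring for every grade pair", {
  for (ta in 0:4) {
    for (tt in 0:4) {
      counts <- generate_pathology_counts(ta, tt, seed = 100 + 5 * ta + tt)
      scored <- score_pathology(counts)
      expect_equal(scored$x_abeta, ta, info = sprintf("abeta target %d", ta))
      expect_equal(scored$x_tau, tt, info = sprintf("tau target %d", tt))
    }
  }
  # interval endpoints the construction promises
  expect_lt(generate_pathology_counts(0, 0, seed = 1)$mature_nfts, 1)
  expect_gte(generate_pathology_counts(4, 4, seed = 1)$neuritic_plaques, 15)
})
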