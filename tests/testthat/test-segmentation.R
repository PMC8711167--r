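make_stack <- function(volumes, wavelengths = NULL) {
  d3 <- dim(volumes[[1]])[3]
  structure(
    list(volumes = volumes,
         wavelengths = wavelengths %||% seq(385, 780, length.out = d3),
         dyes = names(volumes), truth_mask = NULL),
    class = "lambda_stack"
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("total-intensity projection equals an explicit per-pixel sum", {
  zero <- make_stack(list(a = array(0, c(4, 5, 3))))
  expect_true(all(project_total_intensity(zero) == 0))

  one <- array(runif(20), c(4, 5, 1))
  expect_equal(project_total_intensity(make_stack(list(a = one))), one[, , 1])

  set.seed(12)
  vols <- list(a = array(runif(60), c(4, 5, 3)), b = array(runif(60), c(4, 5, 3)))
  proj <- project_total_intensity(make_stack(vols))
  expected <- matrix(0, 4, 5)
  for (r in 1:4) {
    for (c in 1:5) {
      for (v in vols) for (k in 1:3) expected[r, c] <- expected[r, c] + v[r, c, k]
    }
  }
  expect_equal(proj, expected, tolerance = 1e-12)

  bad <- list(a = array(0, c(4, 5, 3)), b = array(0, c(5, 4, 3)))
  expect_error(project_total_intensity(make_stack(bad)),
               class = "strainscope_invalid_input")
})

test_that("segmentation thresholds, filters by area, and labels deterministically", {
  # uniform image below a fixed threshold: no labels
  img <- matrix(0.1, 32, 32)
  masks <- segment_plaques(img, segmentation_params(
    threshold_method = "fixed", fixed_threshold = 0.5, min_area_px = 1
  ))
  expect_equal(nrow(masks$objects), 0)

  # single bright 10x10 square
  img[11:20, 6:15] <- 5
  masks <- segment_plaques(img, segmentation_params(
    min_area_px = 4, max_area_px = 400
  ))
  expect_equal(nrow(masks$objects), 1)
  expect_equal(masks$objects$area, 100)

  # area filter removes a too-small object
  img[2, 2] <- 5
  masks <- segment_plaques(img, segmentation_params(
    min_area_px = 4, max_area_px = 400
  ))
  expect_equal(nrow(masks$objects), 1)

  # n non-overlapping disks -> n labels, deterministic
  arch <- generate_archetypes(2, seed = 4)
  st <- generate_lambda_stack(
    scene_config(n_plaques = 4, allow_overlap = FALSE, pixel_noise_sd = 0.005,
                 seed = 21), arch
  )
  proj <- project_total_intensity(st)
  m1 <- segment_plaques(proj, segmentation_params(min_area_px = 20))
  m2 <- segment_plaques(proj, segmentation_params(min_area_px = 20))
  expect_equal(nrow(m1$objects), 4)
  expect_identical(m1$label_image, m2$label_image)
})

test_that("8-connected labeling agrees with the 4-connected reference on convex shapes and differs on diagonals", {
  img <- matrix(0, 20, 20)
  img[3:6, 3:6] <- 1
  img[10:14, 12:16] <- 1
  m4 <- segment_plaques(img, segmentation_params(min_area_px = 1,
                                                 connectivity = 4))
  m8 <- segment_plaques(img, segmentation_params(min_area_px = 1,
                                                 connectivity = 8))
  expect_identical(m4$label_image, m8$label_image)

  # two squares touching only at a corner
  diag_img <- matrix(0, 10, 10)
  diag_img[2:4, 2:4] <- 1
  diag_img[5:7, 5:7] <- 1
  m4 <- segment_plaques(diag_img, segmentation_params(min_area_px = 1,
                                                      connectivity = 4))
  m8 <- segment_plaques(diag_img, segmentation_params(min_area_px = 1,
                                                      connectivity = 8))
  expect_equal(nrow(m4$objects), 2)
  expect_equal(nrow(m8$objects), 1)
})

test_that("exclusions remove listed labels and ROI-majority overlaps, renumbering stably", {
  img <- matrix(0, 30, 30)
  img[2:6, 2:6] <- 1     # label 1, 25 px
  img[2:6, 20:24] <- 1   # label 2
  img[20:24, 2:6] <- 1   # label 3
  masks <- segment_plaques(img, segmentation_params(
    threshold_method = "fixed", fixed_threshold = 0.5, min_area_px = 1
  ))
  expect_equal(nrow(masks$objects), 3)

  # empty exclusion set is the identity
  same <- apply_exclusions(masks)
  expect_identical(same$label_image, masks$label_image)

  # exclude everything
  none <- apply_exclusions(masks, exclude_labels = 1:3)
  expect_equal(nrow(none$objects), 0)

  # ROI covering 60% of label 2 (rows 2-6, cols 20-24; cover cols 20-22 = 15/25)
  roi <- tibble::tibble(
    roi_id = 1,
    row = c(1.5, 1.5, 6.5, 6.5),
    col = c(19.5, 22.5, 22.5, 19.5)
  )
  left <- apply_exclusions(masks, roi = roi)
  expect_equal(nrow(left$objects), 2)
  # stable renumbering: remaining labels are 1..K in original raster order
  expect_equal(sort(unique(as.vector(left$label_image[left$label_image > 0]))),
               c(1L, 2L))

  expect_warning(apply_exclusions(masks, exclude_labels = 99), "unknown label")
})

test_that("extracted spectra are in-mask channel means, linear in intensity, and archetype-faithful", {
  arch <- generate_archetypes(2, seed = 9)
  st <- generate_lambda_stack(
    scene_config(n_plaques = 2, allow_overlap = FALSE, background = 0,
                 pixel_noise_sd = 0, archetype_ids = c("arch01", "arch02"),
                 seed = 5),
    arch
  )
  masks <- list(label_image = st$truth_mask,
                objects = NULL, threshold = 0, params = NULL)
  class(masks) <- "plaque_masks"
  spectra <- extract_plaque_spectra(st, masks, patient_id = "pat", cohort = "DS")

  # uniform-intensity region: extracted equals the pixel spectrum
  flat <- make_stack(list(a = array(rep(c(1, 2, 3), each = 25), c(5, 5, 3))))
  fmask <- structure(list(label_image = matrix(1L, 5, 5)),
                     class = "plaque_masks")
  fs <- extract_plaque_spectra(flat, fmask)
  expect_equal(fs$intensity, c(1, 2, 3))

  # linearity: scaling the stack scales the spectra
  st2 <- st
  st2$volumes <- lapply(st$volumes, function(v) v * 2.5)
  spectra2 <- extract_plaque_spectra(st2, masks, patient_id = "pat",
                                     cohort = "DS")
  expect_equal(spectra2$intensity, spectra$intensity * 2.5, tolerance = 1e-12)

  # each plaque's per-dye peak channel matches its own archetype's
  for (q in 1:2) {
    aid <- st$plaques$archetype_id[q]
    for (d in st$dyes) {
      got <- spectra %>%
        dplyr::filter(plaque_id == sprintf("pat_q%03d", q), dye == d) %>%
        dplyr::arrange(wavelength_nm)
      prof <- arch %>%
        dplyr::filter(archetype_id == aid, dye == d) %>%
        dplyr::arrange(wavelength_nm)
      expect_equal(which.max(got$intensity), which.max(prof$intensity))
    }
  }
})
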