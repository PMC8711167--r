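#' @keywords internal
#' Resample one spectrum onto grid channel centers by linear interpolation.
resample_spectrum <- function(wavelengths, intensities, grid) {
  if (length(wavelengths) != length(intensities)) {
    abort_ss("wavelengths and intensities must have equal length",
             "strainscope_invalid_input")
  }
  if (is.unsorted(wavelengths, strictly = TRUE)) {
    abort_ss("wavelengths must be strictly increasing",
             "strainscope_invalid_input")
  }
  ch <- grid$channels
  if (length(wavelengths) == length(ch) &&
      isTRUE(all.equal(as.numeric(wavelengths), ch, tolerance = 1e-9))) {
    return(as.numeric(intensities))
  }
  if (min(wavelengths) > min(ch) + 1e-9 || max(wavelengths) < max(ch) - 1e-9) {
    abort_ss(
      sprintf("spectrum span [%.1f, %.1f] does not cover grid span [%.1f, %.1f]",
              min(wavelengths), max(wavelengths), min(ch), max(ch)),
      "strainscope_missing_coverage"
    )
  }
  stats::approx(wavelengths, intensities, xout = ch, method = "linear",
                rule = 1)$y
}

#' Resample spectra onto a wavelength grid
#'
#' Aligns every (plaque, dye) emission spectrum in a long-format table onto
#' the channel centers of `grid` by piecewise-linear interpolation. Spectra
#' already on the grid are passed through unchanged. A spectrum whose span
#' does not cover the grid raises a missing-coverage error.
#'
#' @param data Long-format tibble with columns `plaque_id`, `dye`,
#'   `wavelength_nm`, `intensity` (extra columns such as `patient_id`,
#'   `cohort` are carried through).
#' @param grid A [wavelength_grid()].
#'
#' @return A tibble in the same long format with one row per grid channel
#'   per (plaque, dye).
#' @export
resample_to_grid <- function(data, grid = wavelength_grid()) {
  assert_columns(data, c("plaque_id", "dye", "wavelength_nm", "intensity"),
                 "spectra table")
  meta_cols <- setdiff(names(data),
                       c("wavelength_nm", "intensity"))
  data %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(meta_cols))) %>%
    dplyr::arrange(.data$wavelength_nm, .by_group = TRUE) %>%
    dplyr::reframe(
      intensity = resample_spectrum(.data$wavelength_nm, .data$intensity, grid),
      wavelength_nm = grid$channels
    ) %>%
    dplyr::relocate("intensity", .after = "wavelength_nm")
}

#' @keywords internal
normalize_max_vec <- function(x) {
  if (any(x < 0)) {
    abort_ss("intensities must be nonnegative", "strainscope_invalid_input")
  }
  m <- max(x)
  if (m == 0) {
    return(x)
  }
  x / m
}

#' Max-normalize emission spectra
#'
#' Divides each (plaque, dye) spectrum by its maximum intensity, so every
#' non-degenerate per-dye block has maximum exactly 1. All-zero spectra are
#' retained unchanged and flagged in the `zero_block` column (a dye can
#' genuinely fail to bind a plaque; exclusion is a pipeline decision, not a
#' normalization error).
#'
#' @param data Long-format spectra tibble (see [resample_to_grid()]).
#' @return The same tibble with `intensity` rescaled and a logical
#'   `zero_block` column. A warning is emitted when any all-zero spectrum is
#'   present.
#' @export
normalize_max <- function(data) {
  assert_columns(data, c("plaque_id", "dye", "intensity"), "spectra table")
  if (any(data$intensity < 0)) {
    abort_ss("intensities must be nonnegative", "strainscope_invalid_input")
  }
  out <- data %>%
    dplyr::group_by(.data$plaque_id, .data$dye) %>%
    dplyr::mutate(
      zero_block = max(.data$intensity) == 0,
      intensity = normalize_max_vec(.data$intensity)
    ) %>%
    dplyr::ungroup()
  if (any(out$zero_block)) {
    n_zero <- out %>%
      dplyr::filter(.data$zero_block) %>%
      dplyr::distinct(.data$plaque_id, .data$dye) %>%
      nrow()
    rlang::warn(sprintf("%d all-zero dye spectrum(s) retained and flagged",
                        n_zero))
  }
  out
}

#' Draw the dye concatenation order for an analysis run
#'
#' The three per-dye blocks are concatenated in one random order drawn once
#' per analysis run and then applied uniformly to every plaque, so the
#' composite vectors share a common coordinate system (a per-plaque random
#' order would destroy the vector space; any fixed order is an isometry).
#'
#' @param dyes Character vector of dye names.
#' @param seed Integer seed making the draw reproducible.
#' @return A permutation of `dyes`.
#' @export
draw_dye_order <- function(dyes = c("curcumin", "FSB", "BF-188"), seed = 1L) {
  with_seed(seed, sample(dyes))
}

#' Build composite spectral vectors
#'
#' Turns a long-format spectra table into the per-plaque composite vectors
#' used as PCA rows: each dye's spectrum is aligned to the grid,
#' max-normalized, and the three blocks are concatenated in `dye_order`
#' (length 3 x `n_channels`, 120 by default). Plaques missing any dye are
#' excluded with a warning.
#'
#' @param data Long-format spectra tibble with columns `plaque_id`,
#'   `patient_id`, `cohort`, `dye`, `wavelength_nm`, `intensity`.
#' @param dye_order Character vector giving the block order; defaults to a
#'   seeded random permutation of the dyes present (see [draw_dye_order()]).
#' @param grid A [wavelength_grid()].
#' @param seed Seed used only when `dye_order` is `NULL`.
#'
#' @return A wide tibble with columns `plaque_id`, `patient_id`, `cohort`
#'   and `v001`...`v120`, with attributes `dye_order` and `grid`.
#' @export
build_composite <- function(data, dye_order = NULL, grid = wavelength_grid(),
                            seed = 1L) {
  assert_columns(
    data,
    c("plaque_id", "patient_id", "cohort", "dye", "wavelength_nm", "intensity"),
    "spectra table"
  )
  dyes_present <- sort(unique(data$dye))
  if (is.null(dye_order)) {
    dye_order <- draw_dye_order(dyes_present, seed = seed)
  }
  if (!setequal(dye_order, dyes_present)) {
    abort_ss("dye_order must be a permutation of the dyes present in the data",
             "strainscope_invalid_argument")
  }

  aligned <- resample_to_grid(data, grid) %>% normalize_max()

  # drop plaques missing any dye (incomplete staining), with a warning
  dye_counts <- aligned %>%
    dplyr::distinct(.data$plaque_id, .data$dye) %>%
    dplyr::count(.data$plaque_id)
  incomplete <- dye_counts$plaque_id[dye_counts$n < length(dye_order)]
  if (length(incomplete) > 0) {
    rlang::warn(sprintf(
      "excluding %d plaque(s) with missing dye spectra: %s",
      length(incomplete), paste(utils::head(incomplete, 5), collapse = ", ")
    ))
    aligned <- dplyr::filter(aligned, !.data$plaque_id %in% incomplete)
  }
  if (nrow(aligned) == 0) {
    out <- tibble::tibble(plaque_id = character(), patient_id = character(),
                          cohort = character())
    attr(out, "dye_order") <- dye_order
    attr(out, "grid") <- grid
    return(out)
  }

  nch <- grid$n_channels
  wide <- aligned %>%
    dplyr::mutate(dye = factor(.data$dye, levels = dye_order)) %>%
    dplyr::group_by(.data$plaque_id, .data$patient_id, .data$cohort,
                    .data$dye) %>%
    dplyr::arrange(.data$wavelength_nm, .by_group = TRUE) %>%
    dplyr::summarise(values = list(.data$intensity), .groups = "drop") %>%
    dplyr::arrange(.data$plaque_id, .data$dye) %>%
    dplyr::group_by(.data$plaque_id, .data$patient_id, .data$cohort) %>%
    dplyr::summarise(values = list(unlist(.data$values)), .groups = "drop")

  vals <- do.call(rbind, wide$values)
  colnames(vals) <- sprintf("v%03d", seq_len(3 * nch))
  out <- dplyr::bind_cols(
    wide[c("plaque_id", "patient_id", "cohort")],
    tibble::as_tibble(vals)
  )
  attr(out, "dye_order") <- dye_order
  attr(out, "grid") <- grid
  out
}

#' Cap the number of composite vectors per patient
#'
#' To avoid biasing the eigenspace toward heavily sampled patients, keeps at
#' most `cap` randomly selected composite vectors per patient (patients with
#' `cap` or fewer keep all of theirs). Selection is uniform without
#' replacement and reproducible under `seed`.
#'
#' @param data Wide composite tibble from [build_composite()] (any tibble
#'   with `plaque_id` and `patient_id` columns works).
#' @param cap Maximum vectors per patient (default 30).
#' @param seed Integer seed.
#' @return The input tibble with at most `cap` rows per patient, original
#'   attributes preserved.
#' @export
cap_vectors_per_patient <- function(data, cap = 30, seed = 1L) {
  assert_columns(data, c("plaque_id", "patient_id"), "composite table")
  if (cap < 1) {
    abort_ss("cap must be >= 1", "strainscope_invalid_argument")
  }
  keep <- with_seed(seed, data %>%
    dplyr::mutate(.row = dplyr::row_number()) %>%
    dplyr::group_by(.data$patient_id) %>%
    dplyr::group_map(function(g, key) {
      if (nrow(g) <= cap) g$.row else sort(sample(g$.row, cap))
    }) %>%
    unlist() %>%
    sort())
  out <- data[keep, , drop = FALSE]
  attr(out, "dye_order") <- attr(data, "dye_order")
  attr(out, "grid") <- attr(data, "grid")
  out
}

#' @keywords internal
#' Extract the numeric value matrix (rows = plaques) from a wide composite
#' or score tibble.
composite_matrix <- function(data) {
  cols <- grep("^v[0-9]+$", names(data), value = TRUE)
  if (length(cols) == 0) {
    abort_ss("no v<k> value columns found", "strainscope_invalid_input")
  }
  m <- as.matrix(data[cols])
  storage.mode(m) <- "double"
  rownames(m) <- data$plaque_id
  m
}
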