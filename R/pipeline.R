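#' Pipeline run configuration
#'
#' Collects every tunable of an end-to-end analysis run. One global seed is
#' expanded into per-stage seeds by a fixed counter scheme so stages are
#' individually reproducible without seed collisions.
#'
#' @param out_dir Output directory for stage CSV/JSON files.
#' @param spectra Optional long spectra tibble (or path to its CSV); when
#'   `NULL` the synthetic generator supplies the data.
#' @param synthetic A [cohort_config()] used when `spectra` is `NULL`
#'   (its own seed is overridden by the derived stage seed).
#' @param n_archetypes Number of latent archetypes to simulate.
#' @param grid A [wavelength_grid()].
#' @param cap Per-patient vector cap (default 30); `Inf` disables it.
#' @param retained_eigenspace Components for plots/centroids/MANOVA
#'   (default `c(2, 3)`).
#' @param retained_rmsd Components for the heterogeneity statistic
#'   (default `c(2, 3, 4)`).
#' @param kde_coverage Coverage of the reference density regions
#'   (default 0.995).
#' @param bandwidth_rule KDE bandwidth rule (default `"scott"`).
#' @param reference_cohorts Length-2 character: the cohorts whose coverage
#'   regions define shared strain space (default ADNC then AD).
#' @param seed Global integer seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("strainscope_run_"),
                            spectra = NULL,
                            synthetic = cohort_config(),
                            n_archetypes = 4,
                            grid = wavelength_grid(),
                            cap = 30,
                            retained_eigenspace = c(2, 3),
                            retained_rmsd = c(2, 3, 4),
                            kde_coverage = 0.995,
                            bandwidth_rule = "scott",
                            reference_cohorts = c("ADNC", "AD"),
                            seed = 1L) {
  structure(
    list(out_dir = out_dir, spectra = spectra, synthetic = synthetic,
         n_archetypes = n_archetypes, grid = grid, cap = cap,
         retained_eigenspace = retained_eigenspace,
         retained_rmsd = retained_rmsd,
         kde_coverage = kde_coverage, bandwidth_rule = bandwidth_rule,
         reference_cohorts = reference_cohorts,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Validate a long-format spectra table
#'
#' Schema and consistency checks for the pipeline input: required columns,
#' nonnegative intensities, a consistent channel count for every
#' (plaque, dye), all dyes present for every plaque, and a unique patient
#' per plaque. Report-only: returns a machine-readable error table rather
#' than raising.
#'
#' @param data Long spectra tibble or path to its CSV.
#' @return Tibble with columns `code`, `message`, `plaque_id` (empty when
#'   the table is well-formed).
#' @export
validate_spectra_table <- function(data) {
  if (is.character(data)) {
    data <- readr::read_csv(data, show_col_types = FALSE)
  }
  errs <- list()
  add <- function(code, message, plaque_id = NA_character_) {
    errs[[length(errs) + 1]] <<- tibble::tibble(
      code = code, message = message, plaque_id = plaque_id
    )
  }
  required <- c("plaque_id", "patient_id", "cohort", "dye",
                "wavelength_nm", "intensity")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    add("missing_columns",
        paste("missing column(s):", paste(missing, collapse = ", ")))
    return(dplyr::bind_rows(errs))
  }
  if (any(data$intensity < 0, na.rm = TRUE)) {
    bad <- unique(data$plaque_id[data$intensity < 0])
    for (b in bad) add("negative_intensity", "negative intensity values", b)
  }
  dup <- data %>%
    dplyr::count(.data$plaque_id, .data$dye, .data$wavelength_nm) %>%
    dplyr::filter(.data$n > 1)
  for (b in unique(dup$plaque_id)) {
    add("duplicate_channel", "duplicated (dye, wavelength) rows", b)
  }
  n_dyes <- dplyr::n_distinct(data$dye)
  chan <- data %>%
    dplyr::distinct(.data$plaque_id, .data$dye, .data$wavelength_nm) %>%
    dplyr::count(.data$plaque_id, .data$dye)
  mode_count <- as.integer(names(sort(table(chan$n), decreasing = TRUE))[1])
  bad_chan <- chan %>% dplyr::filter(.data$n != mode_count)
  for (i in seq_len(nrow(bad_chan))) {
    add("channel_count",
        sprintf("dye %s has %d channels (expected %d)",
                bad_chan$dye[i], bad_chan$n[i], mode_count),
        bad_chan$plaque_id[i])
  }
  dye_per_plaque <- data %>%
    dplyr::distinct(.data$plaque_id, .data$dye) %>%
    dplyr::count(.data$plaque_id) %>%
    dplyr::filter(.data$n < n_dyes)
  for (i in seq_len(nrow(dye_per_plaque))) {
    add("missing_dye", "plaque lacks spectra for some dye(s)",
        dye_per_plaque$plaque_id[i])
  }
  multi_pat <- data %>%
    dplyr::distinct(.data$plaque_id, .data$patient_id) %>%
    dplyr::count(.data$plaque_id) %>%
    dplyr::filter(.data$n > 1)
  for (i in seq_len(nrow(multi_pat))) {
    add("ambiguous_patient", "plaque maps to more than one patient",
        multi_pat$plaque_id[i])
  }
  if (length(errs) == 0) {
    tibble::tibble(code = character(), message = character(),
                   plaque_id = character())
  } else {
    dplyr::bind_rows(errs)
  }
}

#' Run the full strain analysis pipeline
#'
#' Orchestrates simulate (or ingest) -> composite vectors -> cap -> strain
#' space -> KDE membership -> heterogeneity -> cohort statistics ->
#' pathology scoring, writing each stage's output as CSV/JSON under
#' `config$out_dir` and returning a manifest with the configuration
#' snapshot, per-file checksums, timestamps and accumulated warnings.
#' Identical configuration (including seed) yields byte-identical numeric
#' outputs.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `run_manifest`; its `results` element holds the
#'   in-memory stage outputs.
#' @export
run_strain_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character(0)
  note <- function(...) {
    warnings_log <<- c(warnings_log, sprintf(...))
  }
  started <- Sys.time()

  # stage seeds from the global seed by a fixed counter scheme
  seeds <- vapply(1:6, function(i) derive_seed(config$seed, i), integer(1))

  # -- stage 1: data ---------------------------------------------------------
  truth <- NULL
  patients <- NULL
  if (is.null(config$spectra)) {
    arch <- generate_archetypes(config$n_archetypes, seed = seeds[1],
                                grid = config$grid)
    synth <- config$synthetic
    synth$seed <- seeds[2]
    ds <- generate_cohort_dataset(synth, arch)
    spectra <- ds$spectra
    truth <- ds$truth
    patients <- ds$patients
  } else if (is.character(config$spectra)) {
    spectra <- readr::read_csv(config$spectra, show_col_types = FALSE)
  } else {
    spectra <- config$spectra
  }
  issues <- validate_spectra_table(spectra)
  if (nrow(issues) > 0) {
    abort_ss(sprintf(
      "input validation failed at stage 'data': %s (plaques: %s)",
      paste(unique(issues$code), collapse = ", "),
      paste(utils::head(stats::na.omit(unique(issues$plaque_id)), 5),
            collapse = ", ")),
      "strainscope_stage_failure")
  }

  # -- stage 2: composite vectors + cap -------------------------------------
  composite <- build_composite(spectra, grid = config$grid, seed = seeds[3])
  capped <- if (is.finite(config$cap)) {
    cap_vectors_per_patient(composite, cap = config$cap, seed = seeds[4])
  } else {
    composite
  }
  if (nrow(capped) < nrow(composite)) {
    note("cap retained %d of %d vectors", nrow(capped), nrow(composite))
  }

  # -- stage 3: strain space -------------------------------------------------
  space <- fit_strain_space(capped)
  scores_eig <- project_scores(capped, space, config$retained_eigenspace)
  scores_rmsd <- project_scores(capped, space, config$retained_rmsd)
  centroids <- patient_centroids(scores_eig)

  # -- stage 4: membership ---------------------------------------------------
  refs <- config$reference_cohorts
  membership <- NULL
  regions <- NULL
  have_refs <- all(refs %in% scores_eig$cohort)
  if (have_refs) {
    regions <- lapply(refs, function(co) {
      fit_density_region(
        dplyr::filter(scores_eig, .data$cohort == co),
        coverage = config$kde_coverage,
        bandwidth_rule = config$bandwidth_rule
      )
    })
    names(regions) <- refs
    membership <- classify_membership(scores_eig, regions[[1]], regions[[2]])
  } else {
    note("reference cohort(s) missing; membership stage skipped")
  }

  # -- stage 5: heterogeneity ------------------------------------------------
  het <- strain_heterogeneity(scores_rmsd)
  if (any(is.na(het$per_patient$rmsd))) {
    note("%d patient(s) with a single vector have undefined RMSD",
         sum(is.na(het$per_patient$rmsd)))
  }

  # -- stage 6: cohort statistics -------------------------------------------
  man <- tryCatch(wilks_lambda_manova(centroids),
                  error = function(e) {
                    note("MANOVA skipped: %s", conditionMessage(e))
                    NULL
                  })
  regressions <- NULL
  if (!is.null(patients)) {
    covs <- patients[c("patient_id", "abeta40", "abeta42", "ptau")]
    regressions <- regression_grid(centroids, covs)
  }

  # -- stage 7: pathology scores (synthetic counts from simulated grades) ---
  scores_path <- NULL
  if (!is.null(patients) && nrow(patients) > 0) {
    counts <- purrr::map_dfr(seq_len(nrow(patients)), function(i) {
      generate_pathology_counts(
        target_abeta = patients$x_tau_sim[i], # amyloid tracks tau grade here
        target_tau = patients$x_tau_sim[i],
        seed = derive_seed(seeds[6], i),
        case_id = patients$patient_id[i]
      )
    })
    scores_path <- score_pathology(counts)
  }

  # -- write outputs ---------------------------------------------------------
  out <- list(
    composite = capped, space = space, scores_eigenspace = scores_eig,
    scores_rmsd = scores_rmsd, centroids = centroids,
    membership = membership, regions = regions, heterogeneity = het,
    manova = man, regressions = regressions, pathology = scores_path,
    truth = truth, patients = patients
  )
  files <- character(0)
  wr <- function(df, name) {
    if (is.null(df)) return()
    f <- file.path(config$out_dir, name)
    readr::write_csv(df, f)
    files <<- c(files, f)
  }
  wr(capped, "composite_vectors.csv")
  wr(scores_eig, "scores_eigenspace.csv")
  wr(scores_rmsd, "scores_rmsd.csv")
  wr(centroids, "patient_centroids.csv")
  if (!is.null(membership)) wr(membership, "membership.csv")
  wr(het$per_patient, "heterogeneity_per_patient.csv")
  wr(het$per_cohort, "heterogeneity_per_cohort.csv")
  if (!is.null(regressions)) wr(regressions, "regressions.csv")
  if (!is.null(scores_path)) wr(scores_path, "pathology_scores.csv")
  if (!is.null(truth)) wr(truth, "truth_labels.csv")
  if (!is.null(patients)) wr(patients, "patient_covariates.csv")
  f <- file.path(config$out_dir, "explained_variance.json")
  jsonlite::write_json(
    list(explained_variance_ratio = space$explained_variance_ratio,
         retained_eigenspace = config$retained_eigenspace,
         retained_rmsd = config$retained_rmsd,
         manova = if (!is.null(man)) unclass(man) else NULL),
    f, auto_unbox = TRUE, digits = NA
  )
  files <- c(files, f)

  manifest <- structure(
    list(
      config = config[setdiff(names(config), "spectra")],
      dye_order = attr(composite, "dye_order"),
      stage_seeds = seeds,
      version = as.character(utils::packageVersion("strainscope")),
      files = tibble::tibble(
        path = files,
        checksum = unname(tools::md5sum(files))
      ),
      started = started,
      finished = Sys.time(),
      warnings = warnings_log,
      results = out
    ),
    class = "run_manifest"
  )
  jsonlite::write_json(
    list(config = rapply(manifest$config, unclass, how = "replace"),
         dye_order = manifest$dye_order,
         stage_seeds = manifest$stage_seeds,
         version = manifest$version,
         files = manifest$files,
         warnings = manifest$warnings),
    file.path(config$out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, force = TRUE
  )
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> %d output file(s) in %s\n",
              nrow(x$files), dirname(x$files$path[1])))
  if (length(x$warnings)) {
    cat("  warnings:\n")
    for (w in x$warnings) cat("   -", w, "\n")
  }
  invisible(x)
}
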