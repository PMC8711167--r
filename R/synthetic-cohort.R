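#' Configuration of a synthetic patient cohort dataset
#'
#' Describes the study structure the generator emulates: plaques nested in
#' patients nested in cohorts (DS / AD / ADNC), latent strain archetypes
#' shared or cohort-unique, per-plaque spectral noise, a smooth
#' wavelength-dependent batch gain affecting half the patients (the
#' microscope-recalibration artifact that dominates PC1), and patient-level
#' peptide concentrations linearly coupled to the latent strain loading.
#'
#' The defaults assume four archetypes: three shared by all cohorts and a
#' fourth found only in DS at mixture weight 0.3.
#'
#' @param patients_per_cohort Named integer vector, cohort -> patient count.
#' @param plaques_per_patient Length-2 range; each patient's plaque count is
#'   drawn uniformly from it (spans the 30-vector analysis cap).
#' @param archetype_mixture Named list, cohort -> mixture weights over
#'   archetypes (nonnegative, summing to 1).
#' @param noise_sd Additive Gaussian noise sd, as a fraction of each
#'   profile's peak intensity (default 0.02).
#' @param batch_shift_magnitude Amplitude of the multiplicative batch gain,
#'   a linear tilt in wavelength of relative size `m` (gain spans
#'   `1 - m` to `1 + m` across the spectrum) applied to batch-B patients. A
#'   constant gain would be erased by per-dye max-normalization; the tilt
#'   survives it.
#' @param patient_diversity Length-2 range for the per-patient mixing
#'   parameter d: each plaque draws its archetype from the cohort mixture
#'   with probability d and from the patient's dominant archetype otherwise.
#'   High-d patients mix more archetypes (more heterogeneous); the simulated
#'   tau grade is derived from d. Set to `c(1, 1)` for iid mixture sampling.
#' @param covariate_coupling Named numeric: linear coefficients tying the
#'   patient's loading on the marker archetype to simulated Abeta40, Abeta42
#'   and pTau concentrations.
#' @param covariate_noise_sd Gaussian noise sd on the simulated covariates.
#' @param marker_archetype Index of the archetype driving the covariates
#'   (default: the last one, the DS-unique archetype under the default
#'   mixtures).
#' @param brightness_sdlog Log-sd of the lognormal per-patient brightness
#'   factor.
#' @param seed Integer seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(
    patients_per_cohort = c(DS = 15, AD = 10, ADNC = 8),
    plaques_per_patient = c(10, 40),
    archetype_mixture = list(
      DS = c(0.25, 0.25, 0.2, 0.3),
      AD = c(0.4, 0.4, 0.2, 0),
      ADNC = c(0.4, 0.4, 0.2, 0)
    ),
    noise_sd = 0.02,
    batch_shift_magnitude = 0.3,
    patient_diversity = c(0.2, 1),
    covariate_coupling = c(abeta40 = -60, abeta42 = 45, ptau = 35),
    covariate_noise_sd = 10,
    marker_archetype = NULL,
    brightness_sdlog = 0.3,
    seed = 1L) {
  if (any(patients_per_cohort < 0)) {
    abort_ss("patients_per_cohort must be nonnegative",
             "strainscope_invalid_argument")
  }
  if (noise_sd < 0 || batch_shift_magnitude < 0) {
    abort_ss("noise_sd and batch_shift_magnitude must be nonnegative",
             "strainscope_invalid_argument")
  }
  for (co in names(archetype_mixture)) {
    w <- archetype_mixture[[co]]
    if (any(w < 0) || abs(sum(w) - 1) > 1e-8) {
      abort_ss(sprintf(
        "archetype mixture for cohort %s must be nonnegative and sum to 1", co),
        "strainscope_invalid_argument")
    }
  }
  if (!setequal(names(patients_per_cohort), names(archetype_mixture))) {
    abort_ss("patients_per_cohort and archetype_mixture must name the same cohorts",
             "strainscope_invalid_argument")
  }
  structure(
    list(
      patients_per_cohort = patients_per_cohort,
      plaques_per_patient = plaques_per_patient,
      archetype_mixture = archetype_mixture,
      noise_sd = noise_sd,
      batch_shift_magnitude = batch_shift_magnitude,
      patient_diversity = patient_diversity,
      covariate_coupling = covariate_coupling,
      covariate_noise_sd = covariate_noise_sd,
      marker_archetype = marker_archetype,
      brightness_sdlog = brightness_sdlog,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

# smooth multiplicative gain for batch B: linear tilt across the spectrum
batch_gain <- function(wavelengths, magnitude) {
  span <- range(wavelengths)
  1 + magnitude * (2 * (wavelengths - span[1]) / diff(span) - 1)
}

#' Generate a synthetic cohort dataset with known ground truth
#'
#' Simulates the full study structure: per cohort, patients with a dominant
#' archetype and a mixing parameter; per patient, plaques whose spectra are
#' the assigned archetype's three-dye profiles scaled by a patient
#' brightness factor, multiplied by the batch gain for batch-B patients,
#' plus additive Gaussian noise clipped at zero. Patient covariates (Abeta40,
#' Abeta42, pTau) are linear in the patient's marker-archetype loading plus
#' noise, and a simulated tau grade is derived from the mixing parameter.
#'
#' @param config A [cohort_config()].
#' @param archetypes An [generate_archetypes()] set; every cohort's mixture
#'   length must equal the number of archetypes.
#' @return A list of class `synthetic_dataset`:
#'   \describe{
#'     \item{spectra}{long tibble `plaque_id`, `patient_id`, `cohort`,
#'       `dye`, `wavelength_nm`, `intensity` (3 dyes x 40 channels per
#'       plaque)}
#'     \item{truth}{tibble `plaque_id`, `patient_id`, `cohort`,
#'       `archetype_id`}
#'     \item{patients}{tibble of patient covariates: `patient_id`, `cohort`,
#'       `batch`, `abeta40`, `abeta42`, `ptau`, `x_tau_sim`, `diversity`,
#'       `brightness`, `n_plaques`}
#'   }
#' @export
generate_cohort_dataset <- function(config, archetypes) {
  stopifnot(inherits(config, "cohort_config"))
  profs <- archetype_profiles(archetypes)
  arch_ids <- names(profs)
  k <- length(arch_ids)
  if (k == 0) {
    abort_ss("archetype list is empty", "strainscope_invalid_argument")
  }
  for (co in names(config$archetype_mixture)) {
    if (length(config$archetype_mixture[[co]]) != k) {
      abort_ss(sprintf("mixture for cohort %s has %d weights but there are %d archetypes",
                       co, length(config$archetype_mixture[[co]]), k),
               "strainscope_invalid_argument")
    }
  }
  grid <- attr(archetypes, "grid")
  dyes <- attr(archetypes, "dyes")
  ch <- grid$channels
  gain <- batch_gain(ch, config$batch_shift_magnitude)
  marker <- config$marker_archetype %||% k

  with_seed(config$seed, {
    spectra <- list()
    truth <- list()
    patients <- list()
    for (co in names(config$patients_per_cohort)) {
      n_pat <- config$patients_per_cohort[[co]]
      mix <- config$archetype_mixture[[co]]
      if (n_pat == 0) next
      for (p in seq_len(n_pat)) {
        patient_id <- sprintf("%s_p%02d", co, p)
        batch <- if (p %% 2 == 0) "B" else "A"
        d_p <- stats::runif(1, config$patient_diversity[1],
                            config$patient_diversity[2])
        dominant <- sample.int(k, 1, prob = mix)
        brightness <- stats::rlnorm(1, 0, config$brightness_sdlog)
        n_plq <- sample(seq(config$plaques_per_patient[1],
                            config$plaques_per_patient[2]), 1)
        from_mix <- stats::runif(n_plq) < d_p
        arch_idx <- ifelse(from_mix,
                           sample.int(k, n_plq, replace = TRUE, prob = mix),
                           dominant)
        plaque_ids <- sprintf("%s_q%03d", patient_id, seq_len(n_plq))
        for (q in seq_len(n_plq)) {
          aid <- arch_ids[arch_idx[q]]
          for (d in dyes) {
            prof <- profs[[aid]][[d]] * brightness
            if (batch == "B") prof <- prof * gain
            noise <- stats::rnorm(length(ch),
                                  sd = config$noise_sd * max(prof))
            spectra[[length(spectra) + 1]] <- tibble::tibble(
              plaque_id = plaque_ids[q],
              patient_id = patient_id,
              cohort = co,
              dye = d,
              wavelength_nm = ch,
              intensity = pmax(prof + noise, 0)
            )
          }
        }
        truth[[length(truth) + 1]] <- tibble::tibble(
          plaque_id = plaque_ids,
          patient_id = patient_id,
          cohort = co,
          archetype_id = arch_ids[arch_idx]
        )
        loading <- mean(arch_idx == marker)
        cc <- config$covariate_coupling
        cn <- config$covariate_noise_sd
        patients[[length(patients) + 1]] <- tibble::tibble(
          patient_id = patient_id,
          cohort = co,
          batch = batch,
          abeta40 = 100 + cc[["abeta40"]] * loading + stats::rnorm(1, 0, cn),
          abeta42 = 60 + cc[["abeta42"]] * loading + stats::rnorm(1, 0, cn),
          ptau = 40 + cc[["ptau"]] * loading + stats::rnorm(1, 0, cn),
          x_tau_sim = pmin(4L, pmax(0L, as.integer(round(4 * d_p)))),
          diversity = d_p,
          brightness = brightness,
          n_plaques = n_plq
        )
      }
    }
    empty_spectra <- tibble::tibble(
      plaque_id = character(), patient_id = character(), cohort = character(),
      dye = character(), wavelength_nm = numeric(), intensity = numeric()
    )
    empty_truth <- tibble::tibble(
      plaque_id = character(), patient_id = character(), cohort = character(),
      archetype_id = character()
    )
    out <- list(
      spectra = if (length(spectra)) dplyr::bind_rows(spectra) else empty_spectra,
      truth = if (length(truth)) dplyr::bind_rows(truth) else empty_truth,
      patients = if (length(patients)) dplyr::bind_rows(patients) else
        tibble::tibble(patient_id = character(), cohort = character()),
      grid = grid,
      dyes = dyes,
      config = config
    )
    class(out) <- "synthetic_dataset"
    out
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> %d plaques, %d patients, cohorts: %s\n",
    dplyr::n_distinct(x$truth$plaque_id), nrow(x$patients),
    paste(unique(x$patients$cohort), collapse = ", ")
  ))
  invisible(x)
}
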