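#' Validate the eigenspace against sampling choices
#'
#' Refits the strain space under alternative sampling regimes — (a) no
#' per-patient cap, (b) the cap with different random seeds, (c)
#' oversampling of minority cohorts with replacement to the majority's row
#' count — and checks that the retained-component geometry and the
#' qualitative cohort-separation conclusion survive. For each pair of runs,
#' the common plaques are projected into both fitted spaces and the
#' absolute Pearson correlation of matched component scores (after sign
#' alignment; the fit's own sign convention already fixes most flips) is
#' reported, together with each run's centroid MANOVA p-value.
#'
#' @param composite Wide composite tibble from [build_composite()] (uncapped).
#' @param cap Per-patient cap applied in the capped runs (default 30).
#' @param cap_seeds Two or more seeds for independent capped subsamples.
#' @param retained Component indices compared (default `c(2, 3)`).
#' @param alpha Significance level for the MANOVA-agreement column.
#' @return A list of class `robustness_report`: `pairs` (tibble run_a,
#'   run_b, component, abs_r, manova agreement) and `runs` (per-run MANOVA
#'   p-values and row counts).
#' @export
subsample_robustness_check <- function(composite, cap = 30,
                                       cap_seeds = c(11L, 12L),
                                       retained = c(2, 3),
                                       alpha = 0.05) {
  if (dplyr::n_distinct(composite$cohort) < 2) {
    abort_ss("at least 2 cohorts are required", "strainscope_invalid_argument")
  }
  runs <- list(nocap = composite)
  for (s in cap_seeds) {
    runs[[sprintf("cap_seed%d", s)]] <-
      cap_vectors_per_patient(composite, cap = cap, seed = s)
  }
  runs[["oversampled"]] <- oversample_cohorts(composite,
                                              seed = cap_seeds[1])

  fits <- lapply(runs, fit_strain_space)
  # project the full common row set into every fitted space
  common <- composite
  projections <- lapply(fits, function(sp) {
    project_scores(common, sp, retained = retained)
  })
  run_summary <- purrr::imap_dfr(runs, function(r, nm) {
    sc <- project_scores(r[!duplicated(r$plaque_id), ], fits[[nm]],
                         retained = retained)
    p <- tryCatch(
      wilks_lambda_manova(patient_centroids(sc))$p_value,
      error = function(e) NA_real_
    )
    tibble::tibble(run = nm, n_rows = nrow(r), manova_p = p)
  })

  run_names <- names(runs)
  pair_idx <- utils::combn(length(run_names), 2)
  pairs <- purrr::map_dfr(seq_len(ncol(pair_idx)), function(j) {
    a <- run_names[pair_idx[1, j]]
    b <- run_names[pair_idx[2, j]]
    purrr::map_dfr(seq_along(retained), function(ci) {
      col <- sprintf("pc%d", retained[ci])
      r <- stats::cor(projections[[a]][[col]], projections[[b]][[col]])
      tibble::tibble(run_a = a, run_b = b, component = retained[ci],
                     abs_r = abs(r))
    })
  }) %>%
    dplyr::left_join(run_summary[c("run", "manova_p")],
                     by = c(run_a = "run")) %>%
    dplyr::rename(manova_p_a = "manova_p") %>%
    dplyr::left_join(run_summary[c("run", "manova_p")],
                     by = c(run_b = "run")) %>%
    dplyr::rename(manova_p_b = "manova_p") %>%
    dplyr::mutate(
      manova_agree = (.data$manova_p_a < alpha) == (.data$manova_p_b < alpha)
    )
  structure(list(pairs = pairs, runs = run_summary),
            class = "robustness_report")
}

# oversample minority cohorts with replacement to the majority row count
oversample_cohorts <- function(composite, seed = 1L) {
  counts <- table(composite$cohort)
  target <- max(counts)
  with_seed(seed, {
    extra <- purrr::map_dfr(names(counts), function(co) {
      rows <- which(composite$cohort == co)
      need <- target - length(rows)
      if (need <= 0) return(composite[integer(0), ])
      composite[sample(rows, need, replace = TRUE), ]
    })
    out <- dplyr::bind_rows(composite, extra)
    attr(out, "dye_order") <- attr(composite, "dye_order")
    attr(out, "grid") <- attr(composite, "grid")
    out
  })
}

#' @export
print.robustness_report <- function(x, ...) {
  cat("<robustness_report>\n")
  cat(sprintf("  min matched-score |r| across run pairs: %.3f\n",
              min(x$pairs$abs_r)))
  cat(sprintf("  MANOVA conclusion agreement: %d/%d pairs\n",
              sum(x$pairs$manova_agree), nrow(x$pairs)))
  invisible(x)
}
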