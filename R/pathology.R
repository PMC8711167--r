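#' Construct a table of per-field pathology counts
#'
#' @param total_plaques,dense_cored_plaques,neuritic_plaques,mature_nfts
#'   Nonnegative densities per square millimeter of grey matter (fractional
#'   values allowed after field averaging).
#' @param case_id Optional case identifiers.
#' @return A `field_counts` tibble.
#' @export
field_counts <- function(total_plaques, dense_cored_plaques = 0,
                         neuritic_plaques = 0, mature_nfts = 0,
                         case_id = NULL) {
  out <- tibble::tibble(
    total_plaques = as.numeric(total_plaques),
    dense_cored_plaques = as.numeric(dense_cored_plaques),
    neuritic_plaques = as.numeric(neuritic_plaques),
    mature_nfts = as.numeric(mature_nfts)
  )
  if (!is.null(case_id)) {
    out <- dplyr::mutate(out, case_id = case_id, .before = 1)
  }
  validate_field_counts(out)
  out
}

validate_field_counts <- function(counts) {
  assert_columns(counts,
                 c("total_plaques", "dense_cored_plaques",
                   "neuritic_plaques", "mature_nfts"),
                 "field counts")
  num <- counts[c("total_plaques", "dense_cored_plaques",
                  "neuritic_plaques", "mature_nfts")]
  if (any(unlist(num) < 0, na.rm = TRUE)) {
    abort_ss("pathology counts must be nonnegative",
             "strainscope_invalid_input")
  }
  if (any(counts$dense_cored_plaques > counts$total_plaques + 1e-9) ||
      any(counts$neuritic_plaques > counts$total_plaques + 1e-9)) {
    abort_ss("dense-cored and neuritic counts cannot exceed total plaques",
             "strainscope_invalid_input")
  }
  invisible(counts)
}

#' Average pathology counts over fields
#'
#' Per-case arithmetic mean of the counts over the scored 1-mm^2 fields
#' (three random grey-matter fields in the standard protocol).
#'
#' @param counts A `field_counts` tibble, one row per field; averaged within
#'   `case_id` when present, otherwise over all rows.
#' @return One averaged row per case (or a single row).
#' @export
average_fields <- function(counts) {
  if (nrow(counts) == 0) {
    abort_ss("at least one field is required", "strainscope_invalid_argument")
  }
  validate_field_counts(counts)
  count_cols <- c("total_plaques", "dense_cored_plaques",
                  "neuritic_plaques", "mature_nfts")
  if ("case_id" %in% names(counts)) {
    counts %>%
      dplyr::group_by(.data$case_id) %>%
      dplyr::summarise(dplyr::across(dplyr::all_of(count_cols), mean),
                       .groups = "drop")
  } else {
    dplyr::summarise(counts,
                     dplyr::across(dplyr::all_of(count_cols), mean))
  }
}

# Amyloid score rules, as lower-bound conditions evaluated highest-first:
#   4: >= 15 neuritic plaques
#   3: >= 5 dense-cored and >= 2 neuritic plaques
#   2: >= 1 dense-cored plaque
#   1: < 1 dense-cored plaque but >= 2 total plaques
#   0: < 1 plaque
# Upper bounds printed in adjacent rows (e.g. "2-15 neuritic") are
# descriptive: the rules are not exhaustive as printed, and the highest
# satisfied lower bound is the only monotone total extension. Counts
# matching no rule verbatim (e.g. exactly 1 plaque, none dense-cored) score
# 0 and are flagged `gap`.
score_abeta_one <- function(total, dense, neuritic) {
  if (neuritic >= 15) {
    list(score = 4L, rule = "neuritic >= 15", gap = FALSE)
  } else if (dense >= 5 && neuritic >= 2) {
    list(score = 3L, rule = "dense-cored >= 5 and neuritic >= 2", gap = FALSE)
  } else if (dense >= 1) {
    list(score = 2L, rule = "dense-cored >= 1", gap = FALSE)
  } else if (total >= 2) {
    list(score = 1L, rule = "total >= 2, dense-cored < 1", gap = FALSE)
  } else if (total < 1) {
    list(score = 0L, rule = "total < 1", gap = FALSE)
  } else {
    list(score = 0L, rule = "boundary gap (1 <= total < 2, no dense-cored)",
         gap = TRUE)
  }
}

#' Semiquantitative amyloid pathology score
#'
#' Assigns the 0--4 amyloid grade from averaged per-mm^2 plaque densities.
#' Interval boundaries shared between adjacent grades belong to the higher
#' grade (half-open intervals), preserving monotonicity in every count.
#'
#' @param counts A `field_counts` tibble (typically from
#'   [average_fields()]).
#' @return The input with `x_abeta` (integer 0--4), `abeta_rule` (the rule
#'   that fired) and `abeta_gap` (TRUE when no printed rule matched
#'   verbatim) columns.
#' @export
score_abeta <- function(counts) {
  validate_field_counts(counts)
  res <- purrr::pmap(
    counts[c("total_plaques", "dense_cored_plaques", "neuritic_plaques")],
    function(total_plaques, dense_cored_plaques, neuritic_plaques) {
      score_abeta_one(total_plaques, dense_cored_plaques, neuritic_plaques)
    }
  )
  counts %>%
    dplyr::mutate(
      x_abeta = purrr::map_int(res, "score"),
      abeta_rule = purrr::map_chr(res, "rule"),
      abeta_gap = purrr::map_lgl(res, "gap")
    )
}

#' Semiquantitative tau pathology score
#'
#' Assigns the 0--4 tau grade from the averaged mature-NFT density per
#' mm^2: `< 1` scores 0, `[1, 5)` scores 1, `[5, 12)` scores 2, `[12, 25)`
#' scores 3 and `>= 25` scores 4 (shared boundaries belong to the higher
#' grade).
#'
#' @param counts A `field_counts` tibble.
#' @return The input with `x_tau` (integer 0--4) and `tau_rule` columns.
#' @export
score_tau <- function(counts) {
  validate_field_counts(counts)
  breaks <- c(-Inf, 1, 5, 12, 25, Inf)
  labels <- c("< 1 NFT", "1-5 NFTs", "5-12 NFTs", "12-25 NFTs", ">= 25 NFTs")
  bin <- cut(counts$mature_nfts, breaks = breaks, right = FALSE,
             labels = FALSE)
  counts %>%
    dplyr::mutate(
      x_tau = as.integer(bin - 1L),
      tau_rule = labels[bin]
    )
}

#' Score a counts table for both pathologies
#'
#' @param counts A `field_counts` tibble, one row per field; fields are
#'   averaged per case first.
#' @return Averaged counts with `x_abeta`, `x_tau` and rule-trace columns.
#' @export
score_pathology <- function(counts) {
  counts %>%
    average_fields() %>%
    score_abeta() %>%
    score_tau()
}
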