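#' @importFrom rlang abort warn .data
#' @importFrom dplyr %>%
NULL

# stop with a classed condition so callers can test on error class
abort_ss <- function(message, class) {
  rlang::abort(message, class = c(class, "strainscope_error"))
}

assert_columns <- function(data, cols, what = "input") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort_ss(
      sprintf("%s is missing required column(s): %s", what,
              paste(missing, collapse = ", ")),
      "strainscope_missing_columns"
    )
  }
  invisible(data)
}

# score-set coordinate columns are named pc<k>; pull them in stored order
pc_columns <- function(data) {
  grep("^pc[0-9]+$", names(data), value = TRUE)
}

score_matrix <- function(scores) {
  cols <- pc_columns(scores)
  if (length(cols) == 0) {
    abort_ss("no pc<k> coordinate columns found", "strainscope_no_coordinates")
  }
  m <- as.matrix(scores[cols])
  storage.mode(m) <- "double"
  m
}

# derive a stage seed from a global seed; keeps results < 2^31 and stage-local
derive_seed <- function(seed, stage_offset) {
  (as.integer(seed) + 1009L * as.integer(stage_offset)) %% 2147483647L
}

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
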