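#' Generate field counts that score to requested pathology grades
#'
#' Inverse of the scoring rules: draws per-mm^2 plaque and tangle densities
#' from the interior of the rule interval for each requested grade, so that
#' scoring the generated counts always round-trips to the targets. Used to
#' give the scoring stage ground truth without real histology.
#'
#' @param target_abeta,target_tau Integer grades in 0..4.
#' @param seed Integer seed (interior points are jittered reproducibly).
#' @param case_id Optional case identifier.
#' @return A `field_counts` tibble with attributes `target_abeta`,
#'   `target_tau`.
#' @export
generate_pathology_counts <- function(target_abeta, target_tau, seed = 1L,
                                      case_id = NULL) {
  if (!target_abeta %in% 0:4 || !target_tau %in% 0:4) {
    abort_ss("targets must be integers in 0..4",
             "strainscope_invalid_argument")
  }
  with_seed(seed, {
    jit <- function(lo, hi) stats::runif(1, lo, hi)
    # interior points of the amyloid rule intervals
    ab <- switch(as.character(target_abeta),
      "0" = list(total = jit(0, 0.9), dense = 0, neuritic = 0),
      "1" = list(total = jit(2.2, 6), dense = jit(0, 0.8), neuritic = 0),
      "2" = list(total = jit(6, 12), dense = jit(1.2, 4.5),
                 neuritic = jit(0, 1.5)),
      "3" = list(total = jit(15, 25), dense = jit(5.5, 12),
                 neuritic = jit(2.5, 13)),
      "4" = list(total = jit(25, 40), dense = jit(6, 15),
                 neuritic = jit(16, 24))
    )
    # interior points of the tau intervals [0,1) [1,5) [5,12) [12,25) [25,..)
    nft <- switch(as.character(target_tau),
      "0" = jit(0, 0.8),
      "1" = jit(1.3, 4.5),
      "2" = jit(5.5, 11.5),
      "3" = jit(12.5, 24),
      "4" = jit(25.5, 45)
    )
    out <- field_counts(
      total_plaques = ab$total,
      dense_cored_plaques = ab$dense,
      neuritic_plaques = ab$neuritic,
      mature_nfts = nft,
      case_id = case_id
    )
    attr(out, "target_abeta") <- as.integer(target_abeta)
    attr(out, "target_tau") <- as.integer(target_tau)
    out
  })
}
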