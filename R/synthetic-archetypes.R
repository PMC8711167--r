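#' Generate latent strain archetypes
#'
#' Each archetype is a joint three-dye spectral signature: per dye, a smooth
#' nonnegative emission profile built as the sum of 1--2 Gaussian-shaped
#' peaks with archetype-specific centers on the wavelength grid. Strain
#' identity is deliberately a joint property of all three dyes (no single
#' dye need separate two archetypes), mirroring the three-dye
#' discrimination design. Distinct archetypes are guaranteed to differ in
#' the peak-channel index of at least one dye.
#'
#' @param k Number of archetypes (>= 1).
#' @param seed Integer seed; generation is bit-reproducible.
#' @param grid A [wavelength_grid()].
#' @param dyes Dye names (default the three conformation-sensitive dyes).
#' @param blend Similarity control in `[0, 1)`: each profile is shrunk
#'   toward the across-archetype mean profile by this fraction. 0 (default)
#'   keeps the drawn profiles; values near 1 make archetypes nearly
#'   identical, which is how scenarios where an instrument batch shift
#'   dominates the biological signal are constructed. The peak-channel
#'   distinctness invariant is enforced on the blended profiles.
#' @return A long tibble with columns `archetype_id`, `dye`,
#'   `wavelength_nm`, `intensity`, of class `archetype_set`.
#' @export
generate_archetypes <- function(k, seed = 1L, grid = wavelength_grid(),
                                dyes = c("curcumin", "FSB", "BF-188"),
                                blend = 0) {
  if (k < 1) {
    abort_ss("k must be >= 1", "strainscope_invalid_argument")
  }
  if (blend < 0 || blend >= 1) {
    abort_ss("blend must lie in [0, 1)", "strainscope_invalid_argument")
  }
  ch <- grid$channels
  lo <- ch[2]
  hi <- ch[length(ch) - 1]
  with_seed(seed, {
    draw_profile <- function() {
      n_peaks <- sample(1:2, 1)
      centers <- stats::runif(n_peaks, lo, hi)
      widths <- stats::runif(n_peaks, 25, 60)
      amps <- c(stats::runif(1, 0.6, 1),
                if (n_peaks == 2) stats::runif(1, 0.3, 0.8))
      prof <- rep(0, length(ch))
      for (p in seq_len(n_peaks)) {
        prof <- prof + amps[p] * exp(-0.5 * ((ch - centers[p]) / widths[p])^2)
      }
      prof
    }
    peak_key <- function(profiles) {
      paste(vapply(profiles, which.max, integer(1)), collapse = "-")
    }
    tries <- 0
    repeat {
      tries <- tries + 1
      seen <- character(0)
      sets <- vector("list", k)
      for (a in seq_len(k)) {
        repeat {
          profiles <- lapply(dyes, function(d) draw_profile())
          key <- peak_key(profiles)
          if (!key %in% seen) break
        }
        seen <- c(seen, key)
        sets[[a]] <- profiles
      }
      if (blend > 0 && k > 1) {
        common <- lapply(seq_along(dyes), function(di) {
          Reduce(`+`, lapply(sets, `[[`, di)) / k
        })
        sets <- lapply(sets, function(profiles) {
          lapply(seq_along(dyes), function(di) {
            (1 - blend) * profiles[[di]] + blend * common[[di]]
          })
        })
        keys <- vapply(sets, peak_key, character(1))
        if (anyDuplicated(keys) > 0) {
          if (tries > 100) {
            abort_ss("could not draw distinct archetypes at this blend level",
                     "strainscope_invalid_argument")
          }
          next
        }
      }
      break
    }
    rows <- purrr::imap(sets, function(profiles, a) {
      purrr::map2_dfr(dyes, profiles, function(d, p) {
        tibble::tibble(
          archetype_id = sprintf("arch%02d", a),
          dye = d,
          wavelength_nm = ch,
          intensity = p
        )
      })
    })
    out <- dplyr::bind_rows(rows)
    class(out) <- c("archetype_set", class(out))
    attr(out, "grid") <- grid
    attr(out, "dyes") <- dyes
    out
  })
}

#' @keywords internal
#' Archetype profiles as a named list: archetype_id -> dye -> intensity
#' vector on the grid.
archetype_profiles <- function(archetypes) {
  split(archetypes, archetypes$archetype_id) %>%
    lapply(function(a) {
      split(a, a$dye) %>%
        lapply(function(d) d$intensity[order(d$wavelength_nm)])
    })
}
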