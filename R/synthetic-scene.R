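#' Configuration for a synthetic spectral image scene
#'
#' @param width,height Image size in pixels.
#' @param n_plaques Number of plaque disks to place.
#' @param radius_range Length-2 range of disk radii (pixels).
#' @param archetype_ids Archetype assigned to each plaque (recycled);
#'   defaults to cycling through all archetypes.
#' @param background Background autofluorescence level (peak of a broad
#'   low-level emission curve added everywhere).
#' @param pixel_noise_sd Additive Gaussian pixel noise sd.
#' @param allow_overlap When `FALSE`, disk centers are drawn by rejection
#'   sampling so no two disks overlap (default `TRUE`: overlaps permitted
#'   and flagged).
#' @param seed Integer seed.
#' @return A `scene_config` list.
#' @export
scene_config <- function(width = 128, height = 128, n_plaques = 6,
                         radius_range = c(6, 14), archetype_ids = NULL,
                         background = 0.02, pixel_noise_sd = 0.01,
                         allow_overlap = TRUE, seed = 1L) {
  if (any(radius_range <= 0)) {
    abort_ss("radii must be positive", "strainscope_invalid_argument")
  }
  if (max(radius_range) * 2 + 2 > min(width, height)) {
    abort_ss("radius range too large for the image size",
             "strainscope_invalid_argument")
  }
  structure(
    list(width = as.integer(width), height = as.integer(height),
         n_plaques = as.integer(n_plaques),
         radius_range = radius_range, archetype_ids = archetype_ids,
         background = background, pixel_noise_sd = pixel_noise_sd,
         allow_overlap = isTRUE(allow_overlap),
         seed = as.integer(seed)),
    class = "scene_config"
  )
}

#' Generate a synthetic three-dye lambda stack
#'
#' Renders plaques as disks whose pixels carry their archetype's per-dye
#' emission spectrum scaled by a parabolic radial falloff
#' `1 - (r/R)^2`, over a broad low-level background autofluorescence
#' curve, with optional per-pixel Gaussian noise. Centers are drawn so
#' every disk lies fully inside the image; overlapping disks are permitted
#' and flagged in the metadata. Truth masks label each plaque's pixels with
#' its index (ties at overlaps go to the plaque with the larger falloff).
#'
#' @param scene A [scene_config()].
#' @param archetypes An [generate_archetypes()] set.
#' @return A list of class `lambda_stack` with elements `volumes` (named
#'   list dye -> array `height x width x n_channels`), `wavelengths`,
#'   `dyes`, `truth_mask` (integer matrix, 0 = background), `plaques`
#'   (tibble: plaque index, archetype, center, radius, mean falloff over
#'   the mask), and `overlaps` (tibble of overlapping pairs).
#' @export
generate_lambda_stack <- function(scene, archetypes) {
  stopifnot(inherits(scene, "scene_config"))
  grid <- attr(archetypes, "grid")
  dyes <- attr(archetypes, "dyes")
  ch <- grid$channels
  profs <- archetype_profiles(archetypes)
  arch_ids <- names(profs)
  n <- scene$n_plaques
  ids <- scene$archetype_ids %||% rep(arch_ids, length.out = max(n, 1))
  ids <- rep(ids, length.out = max(n, 1))

  with_seed(scene$seed, {
    h <- scene$height
    w <- scene$width
    radii <- if (n > 0) {
      stats::runif(n, scene$radius_range[1], scene$radius_range[2])
    } else numeric(0)
    rows <- numeric(n)
    cols <- numeric(n)
    for (i in seq_len(n)) {
      attempt <- 0
      repeat {
        ri <- stats::runif(1, radii[i] + 1, h - radii[i])
        ci <- stats::runif(1, radii[i] + 1, w - radii[i])
        if (scene$allow_overlap || i == 1) break
        prev <- seq_len(i - 1)
        if (all(sqrt((rows[prev] - ri)^2 + (cols[prev] - ci)^2) >
                  radii[prev] + radii[i] + 2)) break
        attempt <- attempt + 1
        if (attempt > 500) {
          abort_ss("could not place non-overlapping disks; reduce n_plaques or radii",
                   "strainscope_invalid_argument")
        }
      }
      rows[i] <- ri
      cols[i] <- ci
    }

    # per-pixel falloff per plaque; label = argmax falloff
    rr <- matrix(rep(seq_len(h), w), nrow = h)
    cc <- matrix(rep(seq_len(w), each = h), nrow = h)
    falloff_max <- matrix(0, h, w)
    truth <- matrix(0L, h, w)
    falloffs <- vector("list", max(n, 0))
    for (i in seq_len(n)) {
      d2 <- (rr - rows[i])^2 + (cc - cols[i])^2
      f <- pmax(1 - d2 / radii[i]^2, 0)
      falloffs[[i]] <- f
      take <- f > falloff_max
      truth[take] <- i
      falloff_max <- pmax(falloff_max, f)
    }

    # broad background autofluorescence curve, shared by all dyes
    bg_curve <- scene$background *
      exp(-0.5 * ((ch - 550) / 150)^2)

    volumes <- lapply(dyes, function(d) {
      vol <- array(0, dim = c(h, w, length(ch)))
      for (k in seq_along(ch)) {
        plane <- matrix(bg_curve[k], h, w)
        for (i in seq_len(n)) {
          plane <- plane + falloffs[[i]] * profs[[ids[i]]][[d]][k]
        }
        if (scene$pixel_noise_sd > 0) {
          plane <- plane + matrix(stats::rnorm(h * w,
                                               sd = scene$pixel_noise_sd),
                                  h, w)
        }
        vol[, , k] <- pmax(plane, 0)
      }
      vol
    })
    names(volumes) <- dyes

    plaques <- tibble::tibble(
      plaque = seq_len(n),
      archetype_id = ids[seq_len(n)],
      center_row = rows, center_col = cols, radius = radii,
      mean_falloff = vapply(seq_len(n), function(i) {
        m <- truth == i
        if (any(m)) mean(falloffs[[i]][m]) else NA_real_
      }, numeric(1))
    )
    overlaps <- if (n >= 2) {
      pairs <- utils::combn(n, 2)
      sel <- sqrt((rows[pairs[1, ]] - rows[pairs[2, ]])^2 +
                    (cols[pairs[1, ]] - cols[pairs[2, ]])^2) <
        (radii[pairs[1, ]] + radii[pairs[2, ]])
      tibble::tibble(a = pairs[1, sel], b = pairs[2, sel])
    } else {
      tibble::tibble(a = integer(), b = integer())
    }

    structure(
      list(volumes = volumes, wavelengths = ch, dyes = dyes,
           truth_mask = truth, plaques = plaques, overlaps = overlaps),
      class = "lambda_stack"
    )
  })
}

#' Write / read a lambda stack as multi-page TIFF plus JSON sidecar
#'
#' One 32-bit float multi-page TIFF per dye (one page per channel), a JSON
#' sidecar mapping page index to channel-center wavelength, and, when
#' present, the truth mask as a single-page 16-bit label TIFF.
#'
#' @param stack A `lambda_stack`.
#' @param dir Output directory (created if needed).
#' @return `write_lambda_stack()`: invisibly, the written file paths.
#'   `read_lambda_stack()`: a `lambda_stack` (without plaque metadata).
#' @export
write_lambda_stack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (d in stack$dyes) {
    vol <- stack$volumes[[d]]
    pages <- lapply(seq_len(dim(vol)[3]), function(k) vol[, , k])
    f <- file.path(dir, paste0("stack_", gsub("[^A-Za-z0-9]", "_", d), ".tif"))
    tiff::writeTIFF(pages, f, bits.per.sample = 32, reduce = FALSE)
    paths <- c(paths, f)
  }
  sidecar <- file.path(dir, "channels.json")
  jsonlite::write_json(
    list(dyes = stack$dyes,
         files = paste0("stack_", gsub("[^A-Za-z0-9]", "_", stack$dyes), ".tif"),
         wavelength_nm = stack$wavelengths),
    sidecar, auto_unbox = FALSE, digits = NA
  )
  paths <- c(paths, sidecar)
  if (!is.null(stack$truth_mask)) {
    f <- file.path(dir, "truth_mask.tif")
    tiff::writeTIFF(stack$truth_mask / 65535, f, bits.per.sample = 16)
    paths <- c(paths, f)
  }
  invisible(paths)
}

#' @rdname write_lambda_stack
#' @export
read_lambda_stack <- function(dir) {
  sidecar <- jsonlite::read_json(file.path(dir, "channels.json"),
                                 simplifyVector = TRUE)
  volumes <- lapply(seq_along(sidecar$dyes), function(i) {
    pages <- tiff::readTIFF(file.path(dir, sidecar$files[i]), all = TRUE)
    array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  })
  names(volumes) <- sidecar$dyes
  mask_file <- file.path(dir, "truth_mask.tif")
  truth <- if (file.exists(mask_file)) {
    m <- tiff::readTIFF(mask_file)
    matrix(as.integer(round(m * 65535)), nrow = nrow(m))
  } else NULL
  structure(
    list(volumes = volumes, wavelengths = sidecar$wavelength_nm,
         dyes = sidecar$dyes, truth_mask = truth,
         plaques = NULL, overlaps = NULL),
    class = "lambda_stack"
  )
}
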