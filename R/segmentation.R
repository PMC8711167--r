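#' Segmentation parameters
#'
#' @param threshold_method `"otsu"` (parameter-free, computed on the
#'   total-intensity projection) or `"fixed"`.
#' @param fixed_threshold Intensity threshold, used iff
#'   `threshold_method = "fixed"`.
#' @param min_area_px,max_area_px Connected components outside this pixel
#'   area band are discarded (defaults 50 and 50000, sized for 512x512
#'   fields).
#' @param connectivity Pixel connectivity for component labeling, 4 or 8.
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(threshold_method = c("otsu", "fixed"),
                                fixed_threshold = NULL,
                                min_area_px = 50, max_area_px = 50000,
                                connectivity = 4) {
  threshold_method <- match.arg(threshold_method)
  if (threshold_method == "fixed" &&
      (is.null(fixed_threshold) || fixed_threshold < 0)) {
    abort_ss("fixed threshold_method requires a nonnegative fixed_threshold",
             "strainscope_invalid_argument")
  }
  if (min_area_px <= 0 || min_area_px > max_area_px) {
    abort_ss("need 0 < min_area_px <= max_area_px",
             "strainscope_invalid_argument")
  }
  if (!connectivity %in% c(4, 8)) {
    abort_ss("connectivity must be 4 or 8", "strainscope_invalid_argument")
  }
  structure(
    list(threshold_method = threshold_method,
         fixed_threshold = fixed_threshold,
         min_area_px = min_area_px, max_area_px = max_area_px,
         connectivity = as.integer(connectivity)),
    class = "segmentation_params"
  )
}

#' Total-intensity projection of a lambda stack
#'
#' Pixel-wise sum over all channels of all dyes; the default image on which
#' plaques are thresholded and segmented.
#'
#' @param stack A `lambda_stack`.
#' @return A numeric matrix (height x width).
#' @export
project_total_intensity <- function(stack) {
  dims <- lapply(stack$volumes, dim)
  if (length(unique(lapply(dims, function(d) d[1:2]))) != 1) {
    abort_ss("all dye volumes must share height and width",
             "strainscope_invalid_input")
  }
  Reduce(`+`, lapply(stack$volumes, function(v) {
    apply(v, c(1, 2), sum)
  }))
}

# 8-connected component labeling by row-run union-find (EBImage::bwlabel is
# 4-connected; runs overlapping or diagonally adjacent between consecutive
# rows are merged here)
label_components8 <- function(mask) {
  h <- nrow(mask)
  w <- ncol(mask)
  runs <- list() # each: (row, col_start, col_end)
  for (r in seq_len(h)) {
    v <- mask[r, ]
    if (!any(v)) next
    d <- diff(c(0L, as.integer(v), 0L))
    starts <- which(d == 1)
    ends <- which(d == -1) - 1L
    for (i in seq_along(starts)) {
      runs[[length(runs) + 1]] <- c(r, starts[i], ends[i])
    }
  }
  nr <- length(runs)
  if (nr == 0) return(matrix(0L, h, w))
  parent <- seq_len(nr)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  rmat <- do.call(rbind, runs)
  for (i in seq_len(nr)) {
    prev <- which(rmat[, 1] == rmat[i, 1] - 1L)
    for (j in prev) {
      # 8-connectivity: runs touch if column ranges overlap +/- 1
      if (rmat[j, 2] <= rmat[i, 3] + 1L && rmat[j, 3] >= rmat[i, 2] - 1L) {
        union(i, j)
      }
    }
  }
  roots <- vapply(seq_len(nr), find, integer(1))
  labels <- match(roots, unique(roots))
  out <- matrix(0L, h, w)
  for (i in seq_len(nr)) {
    out[rmat[i, 1], rmat[i, 2]:rmat[i, 3]] <- labels[i]
  }
  out
}

# relabel 1..K in order of each component's first pixel in reading
# (row-major) order
relabel_raster <- function(lab) {
  if (max(lab) == 0) return(lab)
  tr <- t(lab) # column-major over t = row-major over original
  first_idx <- vapply(seq_len(max(lab)), function(k) {
    idx <- which(tr == k)
    if (length(idx) == 0) NA_integer_ else min(idx)
  }, integer(1))
  present <- which(!is.na(first_idx))
  ord <- present[order(first_idx[present])]
  map <- integer(max(lab))
  map[ord] <- seq_along(ord)
  out <- lab
  out[lab > 0] <- map[lab[lab > 0]]
  out
}

#' Segment plaques in an intensity image
#'
#' Thresholds the image (Otsu by default), labels connected components at
#' the configured connectivity, removes components outside the area band,
#' and relabels survivors 1..K in raster order of their first pixel.
#'
#' @param image Numeric matrix, finite and nonnegative (typically
#'   [project_total_intensity()]).
#' @param params A [segmentation_params()].
#' @return A list of class `plaque_masks`: `label_image` (integer matrix)
#'   and `objects` (tibble: `label`, `area`, `centroid_row`,
#'   `centroid_col`), plus the `threshold` used.
#' @export
segment_plaques <- function(image, params = segmentation_params()) {
  if (!all(is.finite(image)) || any(image < 0)) {
    abort_ss("image must be finite and nonnegative",
             "strainscope_invalid_input")
  }
  mx <- max(image)
  threshold <- if (params$threshold_method == "fixed") {
    params$fixed_threshold
  } else if (mx == 0) {
    0
  } else {
    # EBImage's Otsu operates on [0,1]; rescale and map back
    EBImage::otsu(EBImage::Image(image / mx), range = c(0, 1)) * mx
  }
  mask <- image > threshold
  lab <- if (!any(mask)) {
    matrix(0L, nrow(image), ncol(image))
  } else if (params$connectivity == 4) {
    m <- EBImage::bwlabel(EBImage::Image(mask * 1))
    matrix(as.integer(EBImage::imageData(m)), nrow = nrow(image))
  } else {
    label_components8(mask)
  }
  # area filter
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0], nbins = max(lab))
    bad <- which(areas < params$min_area_px | areas > params$max_area_px)
    lab[lab %in% bad] <- 0L
  }
  lab <- relabel_raster(lab)
  structure(
    list(label_image = lab, objects = mask_objects(lab),
         threshold = threshold, params = params),
    class = "plaque_masks"
  )
}

mask_objects <- function(lab) {
  k <- max(lab)
  if (k == 0) {
    return(tibble::tibble(label = integer(), area = integer(),
                          centroid_row = numeric(), centroid_col = numeric()))
  }
  idx <- which(lab > 0, arr.ind = TRUE)
  lv <- lab[lab > 0]
  tibble::tibble(label = lv,
                 row = idx[, 1], col = idx[, 2]) %>%
    dplyr::group_by(.data$label) %>%
    dplyr::summarise(area = dplyr::n(),
                     centroid_row = mean(.data$row),
                     centroid_col = mean(.data$col),
                     .groups = "drop")
}

#' @export
print.plaque_masks <- function(x, ...) {
  cat(sprintf("<plaque_masks> %d object(s), threshold %.4g\n",
              nrow(x$objects), x$threshold))
  invisible(x)
}

# even-odd ray-casting point-in-polygon test; polygon as (row, col) matrix
point_in_polygon <- function(pr, pc, poly_r, poly_c) {
  n <- length(poly_r)
  inside <- rep(FALSE, length(pr))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((poly_r[i] > pr) != (poly_r[j] > pr)) &
      (pc < (poly_c[j] - poly_c[i]) * (pr - poly_r[i]) /
         (poly_r[j] - poly_r[i]) + poly_c[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Remove false-positive objects from a segmentation
#'
#' Reproducible, file-drivable replacement for the manual exclusion step:
#' removes explicitly listed labels, and any label more than half of whose
#' area falls inside an exclusion ROI polygon. Remaining labels are
#' renumbered stably (by original order).
#'
#' @param masks A `plaque_masks` object.
#' @param exclude_labels Integer vector of label ids to drop (unknown ids
#'   warn and are ignored).
#' @param roi Optional tibble of polygons with columns `roi_id`, `row`,
#'   `col` (vertices in order).
#' @param min_overlap Fraction of a label's area inside an ROI required for
#'   removal (default 0.5, exclusive).
#' @return A new `plaque_masks`.
#' @export
apply_exclusions <- function(masks, exclude_labels = NULL, roi = NULL,
                             min_overlap = 0.5) {
  lab <- masks$label_image
  present <- sort(unique(lab[lab > 0]))
  drop <- integer(0)
  if (!is.null(exclude_labels)) {
    unknown <- setdiff(exclude_labels, present)
    if (length(unknown) > 0) {
      rlang::warn(sprintf("ignoring unknown label id(s): %s",
                          paste(unknown, collapse = ", ")))
    }
    drop <- intersect(exclude_labels, present)
  }
  if (!is.null(roi) && nrow(roi) > 0) {
    assert_columns(roi, c("roi_id", "row", "col"), "ROI table")
    idx <- which(lab > 0, arr.ind = TRUE)
    lv <- lab[lab > 0]
    in_any <- rep(FALSE, nrow(idx))
    for (id in unique(roi$roi_id)) {
      poly <- roi[roi$roi_id == id, ]
      in_any <- in_any | point_in_polygon(idx[, 1], idx[, 2],
                                          poly$row, poly$col)
    }
    frac <- tapply(in_any, lv, mean)
    drop <- union(drop, as.integer(names(frac))[frac > min_overlap])
  }
  lab[lab %in% drop] <- 0L
  lab <- relabel_raster(lab)
  structure(
    list(label_image = lab, objects = mask_objects(lab),
         threshold = masks$threshold, params = masks$params),
    class = "plaque_masks"
  )
}

#' Extract per-plaque mean spectra from a lambda stack
#'
#' For every label and dye, the channel-wise mean intensity over the
#' label's pixels; the bridge from segmented images to the long spectra
#' table consumed by the composite-vector stage.
#'
#' @param stack A `lambda_stack`.
#' @param masks A `plaque_masks` (same height/width as the stack).
#' @param patient_id,cohort Metadata stamped onto the output rows.
#' @return Long tibble `plaque_id`, `patient_id`, `cohort`, `dye`,
#'   `wavelength_nm`, `intensity`.
#' @export
extract_plaque_spectra <- function(stack, masks, patient_id = "patient",
                                   cohort = "unknown") {
  lab <- masks$label_image
  dims <- dim(stack$volumes[[1]])
  if (!all(dim(lab) == dims[1:2])) {
    abort_ss("mask dimensions do not match the stack",
             "strainscope_invalid_input")
  }
  labels <- sort(unique(lab[lab > 0]))
  out <- list()
  for (k in labels) {
    sel <- lab == k
    if (!any(sel)) {
      rlang::warn(sprintf("label %d has zero area; skipped", k))
      next
    }
    for (d in stack$dyes) {
      vol <- stack$volumes[[d]]
      spec <- vapply(seq_len(dims[3]), function(ci) {
        mean(vol[, , ci][sel])
      }, numeric(1))
      out[[length(out) + 1]] <- tibble::tibble(
        plaque_id = sprintf("%s_q%03d", patient_id, k),
        patient_id = patient_id,
        cohort = cohort,
        dye = d,
        wavelength_nm = stack$wavelengths,
        intensity = spec
      )
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(
      plaque_id = character(), patient_id = character(), cohort = character(),
      dye = character(), wavelength_nm = numeric(), intensity = numeric()
    ))
  }
  dplyr::bind_rows(out)
}
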