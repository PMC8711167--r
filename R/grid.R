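#' Wavelength grid for spectral channels
#'
#' Defines the emission-channel grid on which all spectra are aligned. The
#' default matches a confocal lambda scan acquiring 40 image steps spanning
#' 385--780 nm with a sliding 15-nm-wide detection window: 40 channel
#' centers evenly spaced on the closed interval, step ~10.1 nm.
#'
#' @param n_channels Number of spectral channels (default 40).
#' @param span Length-2 numeric, lower and upper wavelength in nm.
#' @param window_width Detector window width in nm (metadata only; channel
#'   spacing is derived from `n_channels` and `span`).
#'
#' @return An object of class `wavelength_grid` with elements `channels`
#'   (channel-center wavelengths in nm), `n_channels`, `span`,
#'   `window_width`.
#' @examples
#' g <- wavelength_grid()
#' head(g$channels)
#' @export
wavelength_grid <- function(n_channels = 40, span = c(385, 780),
                            window_width = 15) {
  if (n_channels < 2) {
    abort_ss("n_channels must be >= 2", "strainscope_invalid_argument")
  }
  if (length(span) != 2 || span[1] >= span[2]) {
    abort_ss("span must be (lower, upper) with lower < upper",
             "strainscope_invalid_argument")
  }
  structure(
    list(
      channels = seq(span[1], span[2], length.out = n_channels),
      n_channels = as.integer(n_channels),
      span = as.numeric(span),
      window_width = as.numeric(window_width)
    ),
    class = "wavelength_grid"
  )
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf(
    "<wavelength_grid> %d channels, %.0f-%.0f nm (step %.2f nm, window %.0f nm)\n",
    x$n_channels, x$span[1], x$span[2],
    diff(x$span) / (x$n_channels - 1), x$window_width
  ))
  invisible(x)
}
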