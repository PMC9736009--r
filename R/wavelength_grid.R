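#' Wavelength grid for a spectral sweep
#'
#' The acquisition sweeps a tunable bandpass filter across the visible range;
#' the default grid is 311 equally spaced samples from 420 to 730 nm
#' (1 nm step), the band layout every cube and curve in the package assumes.
#' All band arithmetic downstream uses nm values, never band indices.
#'
#' @param from First wavelength in nm.
#' @param to Last wavelength in nm.
#' @param n_bands Number of bands.
#' @return Numeric vector of strictly increasing wavelengths in nm.
#' @examples
#' grid <- wavelength_grid()
#' length(grid) # 311
#' @export
wavelength_grid <- function(from = 420, to = 730, n_bands = 311) {
  assert_scalar_number(from, "from", min = 0)
  assert_scalar_number(to, "to", min = 0)
  assert_scalar_number(n_bands, "n_bands", min = 2)
  if (to <= from) stop("`to` must exceed `from`", call. = FALSE)
  seq(from, to, length.out = as.integer(n_bands))
}

validate_grid <- function(grid) {
  if (!is.numeric(grid) || length(grid) < 2L || any(!is.finite(grid)) ||
      any(diff(grid) <= 0)) {
    stop("wavelength grid must be a strictly increasing finite numeric vector",
         call. = FALSE)
  }
  invisible(grid)
}
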