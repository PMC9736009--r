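#' Construct a hypercube
#'
#' A hypercube is a bands x rows x cols array of nonnegative intensities with
#' its wavelength grid and acquisition kind (`sample` or `white_reference`)
#' attached, the raw object a spectral sweep produces.
#'
#' @param data Numeric array, dims `c(n_bands, n_rows, n_cols)`, all values
#'   `>= 0`.
#' @param grid Wavelength grid, length `n_bands`.
#' @param kind `"sample"` or `"white_reference"`.
#' @param meta Named list of provenance (seed, material, mixture row, ...).
#' @return Object of class `hypercube`.
#' @export
hypercube <- function(data, grid, kind = c("sample", "white_reference"),
                      meta = list()) {
  kind <- match.arg(kind)
  validate_grid(grid)
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3-D array (bands x rows x cols)", call. = FALSE)
  }
  if (dim(data)[1] != length(grid)) {
    stop("first dimension of `data` must equal the grid length", call. = FALSE)
  }
  if (any(data < 0)) stop("hypercube intensities must be >= 0", call. = FALSE)
  structure(list(data = data, grid = grid, kind = kind, meta = meta),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Hypercube (%s): %d bands x %d x %d pixels, %g-%g nm\n",
              x$kind, d[1], d[2], d[3], min(x$grid), max(x$grid)))
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$data)

# Smooth multiplicative illumination profile over the sensor: a gentle radial
# vignette around a configurable center. strength = 0 gives a flat field;
# strength must stay below 1 so the field is positive everywhere.
illumination_field <- function(n_rows, n_cols, strength = 0.1,
                               center_rel = c(0.5, 0.5)) {
  assert_scalar_number(strength, "illumination strength", min = 0)
  if (strength >= 1) {
    stop("illumination `strength` must be < 1 (field must stay positive)",
         call. = FALSE)
  }
  r0 <- 1 + center_rel[1] * (n_rows - 1)
  c0 <- 1 + center_rel[2] * (n_cols - 1)
  r <- matrix(seq_len(n_rows), n_rows, n_cols)
  cc <- matrix(seq_len(n_cols), n_rows, n_cols, byrow = TRUE)
  d2 <- (r - r0)^2 + (cc - c0)^2
  d2max <- max((c(1, n_rows) - r0)^2) + max((c(1, n_cols) - c0)^2)
  1 - strength * d2 / max(d2max, 1)
}

# Smooth lamp emission spectrum: a broad visible hump, positive everywhere.
lamp_spectrum <- function(grid, peak_nm = 560, width_nm = 180, floor = 0.6) {
  floor + (1 - floor) * exp(-((grid - peak_nm) / width_nm)^2)
}

#' Simulate a matched sample / white-reference cube pair
#'
#' Emulates one acquisition: the white-reference cube is a smooth
#' multiplicative illumination field times a smooth lamp spectrum, plus
#' additive white readout noise, independent across pixels and bands; the
#' sample cube is the same noiseless illumination multiplied by the mixture
#' transmittance `tau(lambda)` before its own noise draw. Dividing the
#' noiseless sample by the noiseless white therefore recovers `tau` exactly,
#' which is what the transmittance calibration downstream relies on.
#'
#' @param tau Mixture transmittance curve over `grid` (see
#'   [mixture_spectrum()]).
#' @param grid Wavelength grid.
#' @param dims `c(n_rows, n_cols)`, each at least 4.
#' @param illumination List: `strength` in `[0, 1)` and `center_rel`
#'   (relative row/col of the vignette center).
#' @param lamp Either a positive numeric vector over `grid`, a single
#'   positive number, or a list with `peak_nm`, `width_nm`, `floor` for the
#'   built-in smooth lamp.
#' @param sigma_read Additive white-noise standard deviation per pixel and
#'   band (readout electronics); `>= 0`.
#' @param seed Integer seed; the pair is a pure function of
#'   (arguments, seed).
#' @param meta Extra provenance stored on both cubes.
#' @return List with elements `sample` and `white`, both `hypercube`s.
#' @export
simulate_cube_pair <- function(tau, grid = wavelength_grid(),
                               dims = c(64, 64),
                               illumination = list(strength = 0.1,
                                                   center_rel = c(0.5, 0.5)),
                               lamp = list(peak_nm = 560, width_nm = 180,
                                           floor = 0.6),
                               sigma_read = 0.002,
                               seed = 0,
                               meta = list()) {
  validate_grid(grid)
  if (length(tau) != length(grid) || any(!is.finite(tau)) || any(tau < 0)) {
    stop("`tau` must be a nonnegative curve over `grid`", call. = FALSE)
  }
  if (length(dims) != 2L || any(dims < 4)) {
    stop("`dims` must be c(rows, cols) with each >= 4", call. = FALSE)
  }
  assert_scalar_number(sigma_read, "sigma_read", min = 0)

  n_bands <- length(grid)
  field <- illumination_field(dims[1], dims[2],
                              strength = illumination$strength %||% 0.1,
                              center_rel = illumination$center_rel %||% c(0.5, 0.5))
  lamp_curve <- if (is.list(lamp)) {
    lamp_spectrum(grid, peak_nm = lamp$peak_nm %||% 560,
                  width_nm = lamp$width_nm %||% 180,
                  floor = lamp$floor %||% 0.6)
  } else if (length(lamp) == 1L) {
    rep(as.numeric(lamp), n_bands)
  } else {
    as.numeric(lamp)
  }
  if (length(lamp_curve) != n_bands || any(lamp_curve <= 0)) {
    stop("lamp spectrum must be positive over every band", call. = FALSE)
  }

  # noiseless cubes: outer product lamp (x) field, sample scaled by tau
  white0 <- array(outer(lamp_curve, field), dim = c(n_bands, dims))
  sample0 <- array(outer(lamp_curve * tau, field), dim = c(n_bands, dims))

  n_vals <- length(white0)
  noisy <- with_rng_seed(seed, {
    list(white = white0 + stats::rnorm(n_vals, 0, sigma_read),
         sample = sample0 + stats::rnorm(n_vals, 0, sigma_read))
  })

  meta <- c(meta, list(seed = seed, sigma_read = sigma_read))
  list(
    sample = hypercube(pmax(noisy$sample, 0), grid, "sample", meta),
    white = hypercube(pmax(noisy$white, 0), grid, "white_reference", meta)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
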