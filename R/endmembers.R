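#' Generate a seeded endmember transmittance library
#'
#' Pure-material (honey or syrup) transmittance spectra are drawn as smooth
#' curves: each material gets a baseline absorbance plus 3-6 broad Gaussian
#' absorbance bands with random centers, widths and strengths, mapped through
#' `exp(-absorbance)` so every curve lies in (0, 1]. Broad widths (>= 30 nm)
#' keep the curves band-limited, like real visible-range transmittance of
#' honeys and syrups. The library is rejected and redrawn until every pair of
#' materials differs by at least `separation` somewhere on the grid, so each
#' material keeps a recognizable spectral identity.
#'
#' @param material_names Character vector of at least two material names,
#'   e.g. `c("Q", "GS", "F", "G", "M")`.
#' @param grid Wavelength grid in nm (see [wavelength_grid()]).
#' @param seed Integer seed; the library is a pure function of
#'   (arguments, seed).
#' @param separation Minimum required `max_lambda |tau_i - tau_j|` between
#'   every pair of materials (default 0.1 transmittance units).
#' @param n_bumps_range Integer range for the number of absorbance bands per
#'   material.
#' @param max_retries Redraw attempts before giving up on `separation`.
#' @return An object of class `endmember_library`: a named list of numeric
#'   transmittance vectors over `grid`, with the grid and generation
#'   parameters attached.
#' @examples
#' lib <- generate_endmembers(c("GS", "F"), wavelength_grid(), seed = 0)
#' range(lib$curves$GS)
#' @export
generate_endmembers <- function(material_names,
                                grid = wavelength_grid(),
                                seed = 0,
                                separation = 0.1,
                                n_bumps_range = c(3L, 6L),
                                max_retries = 50L) {
  validate_grid(grid)
  if (!is.character(material_names) || length(material_names) < 2L ||
      anyDuplicated(material_names)) {
    stop("`material_names` must be >= 2 distinct names", call. = FALSE)
  }
  assert_scalar_number(separation, "separation", min = 0, max = 1)

  draw_library <- function() {
    curves <- lapply(material_names, function(nm) {
      n_bumps <- sample(seq(n_bumps_range[1], n_bumps_range[2]), 1L)
      baseline <- stats::runif(1, 0.05, 0.4)
      centers <- stats::runif(n_bumps, min(grid) + 10, max(grid) - 10)
      widths <- stats::runif(n_bumps, 30, 120)
      strengths <- stats::runif(n_bumps, 0.2, 1.5)
      absorbance <- rep(baseline, length(grid))
      for (i in seq_len(n_bumps)) {
        absorbance <- absorbance +
          strengths[i] * exp(-(grid - centers[i])^2 / (2 * widths[i]^2))
      }
      exp(-absorbance)
    })
    names(curves) <- material_names
    curves
  }

  separated <- function(curves) {
    pairs <- utils::combn(length(curves), 2)
    all(apply(pairs, 2, function(ij) {
      max(abs(curves[[ij[1]]] - curves[[ij[2]]])) >= separation
    }))
  }

  curves <- with_rng_seed(seed, {
    for (attempt in seq_len(max_retries)) {
      cand <- draw_library()
      if (separated(cand)) break
      cand <- NULL
    }
    cand
  })
  if (is.null(curves)) {
    stop(sprintf(
      "could not draw endmembers separated by %.3g in %d attempts; lower `separation`",
      separation, max_retries), call. = FALSE)
  }
  structure(
    list(curves = curves, grid = grid, materials = material_names),
    class = "endmember_library",
    seed = seed, separation = separation
  )
}

#' @export
print.endmember_library <- function(x, ...) {
  cat(sprintf("Endmember library: %d materials (%s), %d bands %g-%g nm\n",
              length(x$materials), paste(x$materials, collapse = ", "),
              length(x$grid), min(x$grid), max(x$grid)))
  invisible(x)
}

#' Mix two endmember spectra at a honey mass fraction
#'
#' Composes the transmittance of a honey/syrup mixture from the two pure
#' spectra. `linear` mixes transmittances by mass fraction,
#' `tau = w tau_h + (1 - w) tau_s`; `beer_lambert` mixes absorbances,
#' `tau = tau_h^w * tau_s^(1-w)`, the physically motivated alternative.
#' Either way the mixture lies pointwise between the endmembers, so curve
#' families are ordered by purity at every band.
#'
#' @param library An `endmember_library`.
#' @param honey,syrup Material names present in the library.
#' @param honey_fraction Honey mass fraction in percent, in `[0, 100]`.
#' @param mode `"linear"` (default) or `"beer_lambert"`.
#' @return Numeric transmittance curve over the library grid.
#' @export
mixture_spectrum <- function(library, honey, syrup, honey_fraction,
                             mode = c("linear", "beer_lambert")) {
  stopifnot(inherits(library, "endmember_library"))
  mode <- match.arg(mode)
  assert_scalar_number(honey_fraction, "honey_fraction", min = 0, max = 100)
  for (nm in c(honey, syrup)) {
    if (!nm %in% library$materials) {
      stop(sprintf("material '%s' not in library (%s)", nm,
                   paste(library$materials, collapse = ", ")), call. = FALSE)
    }
  }
  w <- honey_fraction / 100
  th <- library$curves[[honey]]
  ts <- library$curves[[syrup]]
  switch(mode,
         linear = w * th + (1 - w) * ts,
         beer_lambert = th^w * ts^(1 - w))
}
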