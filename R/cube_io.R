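#' Write / read a hypercube as multi-page TIFF with a JSON sidecar
#'
#' One 32-bit float page per band; the wavelength grid, acquisition kind,
#' scale factor and metadata go to `<path>.json`. Intensities are divided by
#' a common scale factor before writing (float TIFF stores `[0, 1]`), and
#' rescaled on read; round trips are exact to single-float precision
#' (relative error ~1e-7).
#'
#' @param cube A `hypercube`.
#' @param path Path to the `.tif` file; the sidecar is written next to it.
#' @return `write_hypercube` returns `path` invisibly; `read_hypercube`
#'   returns a `hypercube`.
#' @export
write_hypercube <- function(cube, path) {
  stopifnot(inherits(cube, "hypercube"))
  scale <- max(cube$data, 1e-12) * (1 + 1e-6)
  pages <- lapply(seq_len(dim(cube$data)[1]),
                  function(b) cube$data[b, , , drop = TRUE] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  sidecar <- list(
    wavelengths_nm = cube$grid,
    kind = cube$kind,
    scale = scale,
    meta = cube$meta
  )
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_hypercube
#' @export
read_hypercube <- function(path) {
  sidecar <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  data <- array(0, dim = c(length(pages), dim(pages[[1]])))
  for (b in seq_along(pages)) data[b, , ] <- pages[[b]] * sidecar$scale
  hypercube(data, as.numeric(sidecar$wavelengths_nm), sidecar$kind,
            as.list(sidecar$meta))
}

sidecar_path <- function(path) paste0(path, ".json")
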