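#' Construct a spectral curve set
#'
#' A curve set holds one spectral curve per 4x4 (in general k x k) pixel
#' neighborhood: a curves x bands matrix plus the grid, a class label per
#' curve, and per-curve provenance (tile coordinates, cube id). Transmittance
#' values may slightly exceed 1 under noise; they are flagged in provenance,
#' never clipped, so the noise statistics stay unbiased.
#'
#' @param curves Numeric matrix, `n_curves x n_bands`, all values `>= 0`.
#' @param grid Wavelength grid, length `n_bands`.
#' @param labels Class label per curve (recycled if length 1).
#' @param provenance `data.frame` with one row per curve (tile coordinates
#'   etc.); created empty if missing.
#' @param meta Named list carried along (seeds, cube ids, ...).
#' @return Object of class `spectral_curve_set`.
#' @export
spectral_curve_set <- function(curves, grid, labels = NA_character_,
                               provenance = NULL, meta = list()) {
  validate_grid(grid)
  curves <- as.matrix(curves)
  if (ncol(curves) != length(grid)) {
    stop("`curves` must have one column per band", call. = FALSE)
  }
  if (any(!is.finite(curves)) || any(curves < 0)) {
    stop("curve values must be finite and >= 0", call. = FALSE)
  }
  n <- nrow(curves)
  labels <- rep_len(as.character(labels), n)
  if (is.null(provenance)) {
    provenance <- data.frame(tile_row = rep(NA_integer_, n),
                             tile_col = rep(NA_integer_, n))
  }
  if (nrow(provenance) != n) {
    stop("`provenance` must have one row per curve", call. = FALSE)
  }
  structure(list(curves = curves, grid = grid, labels = labels,
                 provenance = provenance, meta = meta),
            class = "spectral_curve_set")
}

#' @export
print.spectral_curve_set <- function(x, ...) {
  cat(sprintf("Spectral curve set: %d curves x %d bands; classes: %s\n",
              nrow(x$curves), ncol(x$curves),
              paste(names(table(x$labels)), collapse = ", ")))
  invisible(x)
}

#' Select a region of interest from a hypercube
#'
#' Spatial crop preserving all bands. Either explicit 0-based half-open
#' bounds or `"center"` with a window size. The ROI extent must be a
#' positive multiple of the neighborhood side `k` in both directions, so
#' the subsequent tiling is exact: remainders are an error, never silently
#' cropped.
#'
#' @param cube A `hypercube`.
#' @param roi `"center"`, or integer vector
#'   `c(row_start, row_stop, col_start, col_stop)` (0-based, half-open).
#' @param size For `"center"`: window side, or `c(height, width)`.
#' @param k Neighborhood side the extent must divide by (default 4).
#' @return A `hypercube` with the requested spatial extent.
#' @export
select_roi <- function(cube, roi = "center", size = NULL, k = 4L) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$data)
  if (identical(roi, "center")) {
    if (is.null(size)) stop("`size` is required for roi = \"center\"", call. = FALSE)
    size <- rep_len(as.integer(size), 2L)
    r0 <- (d[2] - size[1]) %/% 2L
    c0 <- (d[3] - size[2]) %/% 2L
    roi <- c(r0, r0 + size[1], c0, c0 + size[2])
  }
  roi <- as.integer(roi)
  if (length(roi) != 4L) {
    stop("`roi` must be c(row_start, row_stop, col_start, col_stop)", call. = FALSE)
  }
  h <- roi[2] - roi[1]
  w <- roi[4] - roi[3]
  if (roi[1] < 0 || roi[3] < 0 || roi[2] > d[2] || roi[4] > d[3] ||
      h <= 0 || w <= 0) {
    stop(sprintf("ROI [%d,%d) x [%d,%d) outside cube extent %d x %d",
                 roi[1], roi[2], roi[3], roi[4], d[2], d[3]), call. = FALSE)
  }
  if (h %% k != 0 || w %% k != 0) {
    stop(sprintf("ROI extent %d x %d must be a multiple of the neighborhood side %d",
                 h, w, k), call. = FALSE)
  }
  hypercube(cube$data[, (roi[1] + 1):roi[2], (roi[3] + 1):roi[4], drop = FALSE],
            cube$grid, cube$kind,
            c(cube$meta, list(roi = roi)))
}

#' Average non-overlapping k x k neighborhoods into spectral curves
#'
#' Subdivides the cube's spatial extent into non-overlapping `k x k` tiles
#' and averages the `k^2` pixels of each tile at every band, yielding
#' `(H/k) * (W/k)` curves. Tile coordinates (0-based) are recorded as
#' provenance.
#'
#' @param cube A `hypercube` whose extent is divisible by `k`.
#' @param k Neighborhood side (default 4, the acquisition's convention).
#' @param label Class label to attach to every curve.
#' @return A `spectral_curve_set` with one curve per tile, ordered by
#'   tile column then tile row (column-major).
#' @export
average_neighborhoods <- function(cube, k = 4L, label = NA_character_) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$data)
  if (d[2] %% k != 0 || d[3] %% k != 0) {
    stop(sprintf("cube extent %d x %d is not divisible by k = %d", d[2], d[3], k),
         call. = FALSE)
  }
  nt_r <- d[2] %/% k
  nt_c <- d[3] %/% k
  # tile id per pixel (column-major over the spatial plane)
  tile_r <- (seq_len(d[2]) - 1L) %/% k
  tile_c <- (seq_len(d[3]) - 1L) %/% k
  tile_id <- outer(tile_r, tile_c * nt_r, `+`) # rows x cols
  flat <- matrix(cube$data, nrow = d[1]) # bands x pixels
  sums <- rowsum(t(flat), group = as.vector(tile_id)) # tiles x bands
  curves <- sums[order(as.integer(rownames(sums))), , drop = FALSE] / k^2
  ids <- sort(unique(as.vector(tile_id)))
  provenance <- data.frame(tile_row = ids %% nt_r,
                           tile_col = ids %/% nt_r)
  spectral_curve_set(pmax(curves, 0), cube$grid, label, provenance,
                     meta = c(cube$meta, list(k = k)))
}

#' Transmittance calibration of sample curves against a white reference
#'
#' Divides each sample curve by the matching white-reference curve band by
#' band: `tau(lambda) = P(lambda) / W(lambda)`, where `P` is the averaged
#' transmitted intensity and `W` the incident illumination measured the same
#' way. Curves where noise pushes `tau` above 1 are flagged in provenance
#' (`over_one`), not clipped.
#'
#' @param sample_curves,white_curves `spectral_curve_set`s from the same ROI
#'   and tiling (matching grid and tile provenance).
#' @return A `spectral_curve_set` of transmittance curves.
#' @export
compute_transmittance <- function(sample_curves, white_curves) {
  stopifnot(inherits(sample_curves, "spectral_curve_set"),
            inherits(white_curves, "spectral_curve_set"))
  if (!isTRUE(all.equal(sample_curves$grid, white_curves$grid))) {
    stop("sample and white curve sets must share one wavelength grid", call. = FALSE)
  }
  if (nrow(sample_curves$curves) != nrow(white_curves$curves) ||
      !identical(sample_curves$provenance$tile_row, white_curves$provenance$tile_row) ||
      !identical(sample_curves$provenance$tile_col, white_curves$provenance$tile_col)) {
    stop("sample and white curve sets must come from the same tiling", call. = FALSE)
  }
  W <- white_curves$curves
  bad <- which(W <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "white reference is <= 0 at band %g nm, tile (%d, %d): cannot divide",
      sample_curves$grid[bad[1, 2]],
      sample_curves$provenance$tile_row[bad[1, 1]],
      sample_curves$provenance$tile_col[bad[1, 1]]), call. = FALSE)
  }
  tau <- sample_curves$curves / W
  provenance <- sample_curves$provenance
  provenance$over_one <- apply(tau > 1, 1, any)
  spectral_curve_set(tau, sample_curves$grid, sample_curves$labels,
                     provenance, meta = sample_curves$meta)
}

#' Randomly subsample curves per class
#'
#' Draws exactly `n_per_class` curves from every class without replacement,
#' deterministically for a given seed — the step that cuts the full tile
#' population down to the working set (e.g. 100 curves per class).
#'
#' @param curve_set A `spectral_curve_set`.
#' @param n_per_class Curves to keep per class (default 100).
#' @param seed Integer seed.
#' @return A `spectral_curve_set` with `n_per_class` curves per class,
#'   provenance retained.
#' @export
subsample_curves <- function(curve_set, n_per_class = 100, seed = 0) {
  stopifnot(inherits(curve_set, "spectral_curve_set"))
  classes <- unique(curve_set$labels)
  keep <- with_rng_seed(seed, {
    unlist(lapply(classes, function(cl) {
      idx <- which(curve_set$labels == cl)
      if (length(idx) < n_per_class) {
        stop(sprintf("class '%s' has only %d curves, need %d", cl,
                     length(idx), n_per_class), call. = FALSE)
      }
      sort(sample(idx, n_per_class))
    }))
  })
  spectral_curve_set(curve_set$curves[keep, , drop = FALSE], curve_set$grid,
                     curve_set$labels[keep],
                     curve_set$provenance[keep, , drop = FALSE],
                     meta = c(curve_set$meta, list(subsample_seed = seed)))
}

#' Write / read a spectral curve set as wide CSV
#'
#' Columns: `label`, `tile_row`, `tile_col`, then one column per band named
#' by its wavelength in nm.
#'
#' @param curve_set A `spectral_curve_set`.
#' @param path File path.
#' @return `write_curve_set` returns `path` invisibly; `read_curve_set`
#'   returns a `spectral_curve_set`.
#' @export
write_curve_set <- function(curve_set, path) {
  stopifnot(inherits(curve_set, "spectral_curve_set"))
  df <- data.frame(label = curve_set$labels,
                   tile_row = curve_set$provenance$tile_row,
                   tile_col = curve_set$provenance$tile_col,
                   check.names = FALSE)
  mat <- as.data.frame(curve_set$curves)
  names(mat) <- formatC(curve_set$grid, format = "fg", digits = 10)
  utils::write.csv(cbind(df, mat), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_curve_set
#' @export
read_curve_set <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(label = "character"))
  band_cols <- setdiff(names(df), c("label", "tile_row", "tile_col"))
  spectral_curve_set(as.matrix(df[, band_cols]),
                     as.numeric(band_cols),
                     df$label,
                     df[, c("tile_row", "tile_col"), drop = FALSE])
}
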