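test_that("center ROI selection is exact and remainders are errors", {
  grid <- test_grid(8)
  cube <- hypercube(array(1, c(8, 64, 64)), grid)
  roi <- select_roi(cube, "center", size = 16)
  expect_equal(dim(roi$data), c(8, 16, 16))
  expect_equal(roi$meta$roi, c(24L, 40L, 24L, 40L))
  # explicit 0-based half-open bounds pick exactly those pixels
  cube2 <- hypercube(array(seq_len(2 * 6 * 6), c(2, 6, 6)), test_grid(2))
  crop <- select_roi(cube2, c(1, 5, 2, 6), k = 4)
  expect_equal(crop$data, cube2$data[, 2:5, 3:6, drop = FALSE])
  expect_error(select_roi(cube, "center", size = 18, k = 4), "multiple")
  expect_error(select_roi(cube, c(0, 4, 60, 68)), "outside")
  expect_error(select_roi(cube, c(4, 4, 0, 4)), "outside")
  expect_error(select_roi(cube, "center"), "size")
})

test_that("neighborhood averaging matches a brute-force per-tile loop", {
  grid <- test_grid(3)
  set.seed(42)
  dat <- array(abs(rnorm(3 * 8 * 12)), c(3, 8, 12))
  cube <- hypercube(dat, grid)
  cs <- average_neighborhoods(cube, k = 4, label = "x")
  expect_equal(nrow(cs$curves), (8 / 4) * (12 / 4))
  expect_identical(cs$labels, rep("x", 6))
  for (i in seq_len(nrow(cs$curves))) {
    tr <- cs$provenance$tile_row[i]
    tc <- cs$provenance$tile_col[i]
    manual <- apply(dat[, tr * 4 + 1:4, tc * 4 + 1:4, drop = FALSE], 1, mean)
    expect_equal(unname(cs$curves[i, ]), manual, tolerance = 1e-12)
  }
  # every tile appears exactly once
  expect_equal(nrow(unique(cs$provenance[, c("tile_row", "tile_col")])), 6)

  cube2 <- hypercube(array(2.5, c(3, 8, 8)), grid)
  cs2 <- average_neighborhoods(cube2, 4)
  expect_lt(max(abs(cs2$curves - 2.5)), 1e-12)
  expect_error(average_neighborhoods(hypercube(array(1, c(3, 7, 8)), grid), 4),
               "divisible")
})

test_that("transmittance calibration divides band by band and flags tau > 1", {
  grid <- test_grid(4)
  W <- matrix(c(2, 2, 2, 2, 4, 4, 4, 4), 2, 4, byrow = TRUE)
  P <- matrix(c(1, 2, 3, 2.2, 1, 2, 3, 4), 2, 4, byrow = TRUE)
  prov <- data.frame(tile_row = 0:1, tile_col = c(0L, 0L))
  sw <- spectral_curve_set(W, grid, "w", prov)
  sp <- spectral_curve_set(P, grid, "s", prov)
  tau <- compute_transmittance(sp, sw)
  expect_equal(unname(tau$curves[1, ]), c(0.5, 1, 1.5, 1.1))
  expect_equal(unname(tau$curves[2, ]), c(0.25, 0.5, 0.75, 1))
  expect_identical(tau$provenance$over_one, c(TRUE, FALSE))
  expect_identical(tau$labels, sp$labels)

  # a zero in the white reference is an error naming the offending band
  W0 <- W
  W0[2, 3] <- 0
  sw0 <- spectral_curve_set(W0, grid, "w", prov)
  expect_error(compute_transmittance(sp, sw0), "422")
  # mismatched tilings are refused
  prov2 <- data.frame(tile_row = c(0L, 2L), tile_col = c(0L, 0L))
  expect_error(compute_transmittance(sp, spectral_curve_set(W, grid, "w", prov2)),
               "tiling")
  expect_error(
    compute_transmittance(sp, spectral_curve_set(W, test_grid(4) + 1, "w", prov)),
    "grid")
})

test_that("per-class subsampling is exact, seeded and conserves labels", {
  grid <- test_grid(4)
  set.seed(8)
  curves <- matrix(runif(40 * 4), 40, 4)
  labels <- rep(c("A", "B"), each = 20)
  cs <- spectral_curve_set(curves, grid, labels)
  s1 <- subsample_curves(cs, 15, seed = 5)
  s2 <- subsample_curves(cs, 15, seed = 5)
  s3 <- subsample_curves(cs, 15, seed = 6)
  expect_equal(unname(c(table(s1$labels))), c(15, 15))
  expect_identical(s1$curves, s2$curves)
  expect_false(identical(s1$curves, s3$curves))
  expect_true(all(s1$curves %in% curves))
  expect_error(subsample_curves(cs, 21, seed = 1), "only")
})

test_that("the noiseless pipeline recovers the mixture transmittance to 1e-10", {
  grid <- wavelength_grid()
  lib <- generate_endmembers(c("H", "S"), grid, seed = 2)
  tau <- mixture_spectrum(lib, "H", "S", 70)
  pair <- simulate_cube_pair(tau, grid, dims = c(8, 8), sigma_read = 0,
                             seed = 0)
  s <- average_neighborhoods(pair$sample, 4, "70")
  w <- average_neighborhoods(pair$white, 4)
  out <- compute_transmittance(s, w)
  expect_equal(nrow(out$curves), 4)
  expect_lt(max(abs(sweep(out$curves, 2, tau))), 1e-10)
})

test_that("calibration averages each neighborhood before dividing", {
  grid <- test_grid(8)
  tau <- seq(0.3, 0.8, length.out = 8)
  pair <- simulate_cube_pair(tau, grid, dims = c(8, 8), sigma_read = 0.05,
                             seed = 11)
  s <- average_neighborhoods(pair$sample, 4, "x")
  w <- average_neighborhoods(pair$white, 4)
  out <- compute_transmittance(s, w)
  avg_then_divide <- t(vapply(seq_len(nrow(out$curves)), function(i) {
    rows <- out$provenance$tile_row[i] * 4 + 1:4
    cols <- out$provenance$tile_col[i] * 4 + 1:4
    apply(pair$sample$data[, rows, cols], 1, mean) /
      apply(pair$white$data[, rows, cols], 1, mean)
  }, numeric(8)))
  expect_equal(unname(out$curves), unname(avg_then_divide), tolerance = 1e-12)
  # the reversed order (per-pixel ratio, then average) is a different number
  # under noise, so the test pins the implemented order
  divide_then_avg <- t(vapply(seq_len(nrow(out$curves)), function(i) {
    rows <- out$provenance$tile_row[i] * 4 + 1:4
    cols <- out$provenance$tile_col[i] * 4 + 1:4
    apply(pair$sample$data[, rows, cols] / pair$white$data[, rows, cols],
          1, mean)
  }, numeric(8)))
  expect_gt(max(abs(avg_then_divide - divide_then_avg)), 1e-6)
})
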