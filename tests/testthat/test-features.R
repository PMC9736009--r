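test_that("canonicalization collapses sine symmetries without changing the curve", {
  grid <- wavelength_grid()
  terms <- data.frame(a = c(-0.5, 0.3, 0.2),
                      b = c(0.03, -0.011, 0.07),
                      c = c(4.0, -7.0, 0.2))
  canon <- canonicalize_terms(terms)
  expect_true(all(canon$a >= 0))
  expect_true(all(canon$b >= 0))
  expect_true(all(canon$c > -pi & canon$c <= pi + 1e-12))
  expect_equal(canon$b, sort(canon$b))
  expect_equal(canonicalize_terms(canon), canon)
  expect_equal(eval_terms(canon, grid), eval_terms(terms, grid),
               tolerance = 1e-12)
  # zero-amplitude terms get a fixed phase so equal fits are equal tables
  z <- canonicalize_terms(data.frame(a = c(0, 1), b = c(0.5, 0.2),
                                     c = c(2.2, 0.1)))
  expect_equal(z$c[z$a == 0], 0)
})

test_that("FFT initialization lands on the true frequency bins", {
  grid <- wavelength_grid() # 311 bands, 1 nm step
  b1 <- 2 * pi * 10 / 311 # exactly bin 10
  y <- 0.6 * sin(b1 * grid + 0.4)
  init <- initialize_sine_parameters(y, grid, 1)
  expect_equal(init$b, b1, tolerance = 1e-9)
  expect_equal(init$a, 0.6, tolerance = 1e-6)
  expect_gt(cor(eval_terms(init, grid), y), 0.999)

  b2 <- 2 * pi * 25 / 311
  y2 <- 0.5 * sin(b1 * grid + 1) + 0.3 * sin(b2 * grid - 0.5)
  init2 <- initialize_sine_parameters(y2, grid, 2)
  expect_equal(sort(init2$b), sort(c(b1, b2)), tolerance = 1e-9)

  expect_warning(initialize_sine_parameters(rep(1, 311), grid, 2), "padding")
  expect_error(initialize_sine_parameters(rep(1, 10), test_grid(10), 2),
               "too short")
  expect_error(initialize_sine_parameters(rep(1, 10), grid, 1), "differ")
})

test_that("an exact one-term model is fitted to machine precision", {
  grid <- wavelength_grid()
  y <- 0.7 * sin(0.02 * grid + 1.0)
  fit <- fit_sum_of_sines(y, grid, n_terms = 1)
  expect_true(fit$converged)
  expect_lt(fit$rmse, 1e-8)
  expect_equal(fit$terms$a, 0.7, tolerance = 1e-6)
  expect_equal(fit$terms$b, 0.02, tolerance = 1e-6)
  recon <- reconstruct_spectrum(fit, grid)
  expect_lt(sqrt(mean((recon - y)^2)), 1e-6)
  # the reported rmse is the rmse of the canonical reconstruction
  expect_equal(sqrt(mean((recon - y)^2)), fit$rmse, tolerance = 1e-9)
})

test_that("a known 8-term expansion is fitted below the fit-quality floor", {
  grid <- wavelength_grid()
  set.seed(3)
  true_terms <- data.frame(a = runif(8, 0.1, 0.5),
                           b = sort(runif(8, 0.005, 0.15)),
                           c = runif(8, -3, 3))
  y <- eval_terms(true_terms, grid)
  fit <- fit_sum_of_sines(y, grid, n_terms = 8)
  expect_true(fit$converged)
  expect_lt(fit$rmse, 2e-3)
  expect_equal(nrow(fit$terms), 8)
  expect_identical(names(fit$terms), c("a", "b", "c"))
  # invalid inputs
  expect_error(fit_sum_of_sines(c(y[-1], NA), grid), "finite")
  expect_error(fit_sum_of_sines(y, grid, n_terms = 0), "n_terms")
})

test_that("more terms never fit worse when seeded with the smaller fit", {
  grid <- wavelength_grid()
  lib <- generate_endmembers(c("H", "S"), grid, seed = 21)
  for (fr in c(60, 75, 90)) {
    tau <- mixture_spectrum(lib, "H", "S", fr)
    fit5 <- fit_sum_of_sines(tau, grid, n_terms = 5)
    pad <- data.frame(a = rep(0, 3), b = c(0.5, 0.6, 0.7), c = 0)
    fit8 <- fit_sum_of_sines(tau, grid, n_terms = 8,
                             init = rbind(fit5$terms, pad))
    expect_lte(fit8$rmse, fit5$rmse + 1e-12)
  }
})

test_that("fingerprints are stable across noise realizations of one sample", {
  grid <- wavelength_grid()
  lib <- generate_endmembers(c("H", "S"), grid, seed = 31)
  tau <- mixture_spectrum(lib, "H", "S", 80)
  sigma <- 0.002
  one_curve <- function(seed) {
    pair <- simulate_cube_pair(tau, grid, dims = c(4, 4), sigma_read = sigma,
                               seed = seed)
    t <- compute_transmittance(average_neighborhoods(pair$sample, 4, "80"),
                               average_neighborhoods(pair$white, 4))
    t$curves[1, ]
  }
  f1 <- fit_sum_of_sines(one_curve(101), grid)
  f2 <- fit_sum_of_sines(one_curve(202), grid)
  d <- reconstruct_spectrum(f1, grid) - reconstruct_spectrum(f2, grid)
  expect_lt(sqrt(mean(d^2)), 3 * sigma)
})

test_that("the feature matrix is n_curves x 24 in interleaved canonical order", {
  grid <- wavelength_grid()
  lib <- generate_endmembers(c("H", "S"), grid, seed = 12)
  tau90 <- mixture_spectrum(lib, "H", "S", 90)
  tau60 <- mixture_spectrum(lib, "H", "S", 60)
  cs <- spectral_curve_set(rbind(tau90, tau60, tau90), grid,
                           c("90", "60", "90"))
  fm <- build_feature_matrix(cs, n_terms = 8, seed = 1)
  expect_equal(dim(fm$values), c(3L, 24L))
  expect_identical(colnames(fm$values),
                   as.vector(outer(c("a", "b", "c"), 1:8, paste0)))
  expect_identical(fm$labels, cs$labels)
  expect_lt(max(fm$rmse), 0.01) # the 1% fit-quality requirement
  # identical curves map to identical fingerprints
  expect_equal(unname(fm$values[1, ]), unname(fm$values[3, ]))
  # row layout: (a1, b1, c1, ..., a8, b8, c8) reconstructs its own curve
  v <- fm$values[1, ]
  tm <- data.frame(a = v[seq(1, 24, 3)], b = v[seq(2, 24, 3)],
                   c = v[seq(3, 24, 3)])
  expect_equal(sqrt(mean((eval_terms(tm, grid) - tau90)^2)), fm$rmse[1],
               tolerance = 1e-9)
})
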