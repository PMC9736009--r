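# shared helpers for the test suite

# short uniform grid starting at 420 nm with 1 nm steps
test_grid <- function(n = 64) wavelength_grid(420, 420 + n - 1, n)

# hand-built endmember library with known curves (bypasses the generator)
fake_library <- function(curves, grid) {
  structure(list(curves = curves, grid = grid, materials = names(curves)),
            class = "endmember_library")
}

# evaluate a sum-of-sines term table independently of the package internals
eval_terms <- function(terms, grid) {
  rowSums(vapply(seq_len(nrow(terms)), function(i) {
    terms$a[i] * sin(terms$b[i] * grid + terms$c[i])
  }, numeric(length(grid))))
}
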