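#' Run code with a temporary RNG seed
#'
#' Evaluates `code` with the global random number generator seeded to `seed`,
#' then restores the previous RNG state, so seeded generators are pure
#' functions of their arguments and never perturb the caller's stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_rng_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old_seed <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old_seed, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a stage seed from a master seed
#'
#' Deterministically maps a master seed and a stage tag to an integer seed
#' below 2^31, so every pipeline stage gets an independent, reproducible
#' stream from one master seed.
#'
#' @param master Integer master seed.
#' @param tag Character stage tag, e.g. `"simulate/Q+F/90"`.
#' @return A single integer in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(master, tag) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(tag))
  m <- 2147483647 # 2^31 - 1, prime
  h <- (as.double(master) %% m + 1) * 48271 %% m
  for (ch in utf8ToInt(paste(tag, collapse = "/"))) {
    h <- (h * 131 + ch) %% m
  }
  as.integer(h)
}

#' Round half away from zero
#'
#' Report-level rounding convention: 84.25 rounds to 84.3 and -84.25 to
#' -84.3, unlike [base::round()]'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# shared argument checks ------------------------------------------------------

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max) {
    stop(sprintf("`%s` must be a single finite number in [%s, %s]", name, min, max),
         call. = FALSE)
  }
  invisible(x)
}
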