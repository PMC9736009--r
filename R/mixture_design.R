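#' Build a honey/syrup mixture design
#'
#' Each row prescribes one adulteration level: the honey mass fraction (in
#' percent of the total), the honey and syrup masses in grams, and a class
#' label. Masses are stored exactly; display rounding to 0.1 g is left to
#' print/CSV formatting.
#'
#' @param total_mass Total mass of one mixture in grams (default 23 g).
#' @param honey_fractions Honey mass fractions in percent, each in
#'   `[0, 100]` (default `c(100, 90, 80, 70, 60)`, pure honey plus four
#'   adulteration levels).
#' @param labels Optional class labels, one per fraction; default is the
#'   fraction printed as an integer percent.
#' @return A `data.frame` with columns `fraction_pct`, `honey_g`, `syrup_g`,
#'   `label`, of class `mixture_design`.
#' @examples
#' make_mixture_design(23, c(90, 60))
#' @export
make_mixture_design <- function(total_mass = 23,
                                honey_fractions = c(100, 90, 80, 70, 60),
                                labels = NULL) {
  assert_scalar_number(total_mass, "total_mass")
  if (total_mass <= 0) stop("`total_mass` must be positive", call. = FALSE)
  if (!is.numeric(honey_fractions) || length(honey_fractions) < 1L ||
      any(!is.finite(honey_fractions))) {
    stop("`honey_fractions` must be finite numeric percentages", call. = FALSE)
  }
  if (any(honey_fractions < 0 | honey_fractions > 100)) {
    stop("honey fractions must lie in [0, 100] percent", call. = FALSE)
  }
  if (is.null(labels)) labels <- formatC(honey_fractions, format = "fg")
  if (length(labels) != length(honey_fractions)) {
    stop("`labels` must match `honey_fractions` in length", call. = FALSE)
  }
  honey_g <- honey_fractions / 100 * total_mass
  design <- data.frame(
    fraction_pct = honey_fractions,
    honey_g = honey_g,
    syrup_g = total_mass - honey_g,
    label = as.character(labels),
    stringsAsFactors = FALSE
  )
  class(design) <- c("mixture_design", "data.frame")
  attr(design, "total_mass") <- total_mass
  design
}

#' @export
print.mixture_design <- function(x, ...) {
  cat(sprintf("Mixture design: total mass %s g\n", attr(x, "total_mass")))
  shown <- data.frame(
    fraction_pct = x$fraction_pct,
    honey_g = round_half_away(x$honey_g, 1),
    syrup_g = round_half_away(x$syrup_g, 1),
    label = x$label
  )
  print.data.frame(shown, row.names = FALSE)
  invisible(x)
}

#' Write / read a mixture design as CSV
#'
#' Plain CSV with header `fraction_pct,honey_g,syrup_g,label`.
#'
#' @param design A `mixture_design`.
#' @param path File path.
#' @return `write_mixture_design` returns `path` invisibly;
#'   `read_mixture_design` returns a `mixture_design`.
#' @export
write_mixture_design <- function(design, path) {
  stopifnot(inherits(design, "mixture_design"))
  utils::write.csv(as.data.frame(design)[, c("fraction_pct", "honey_g",
                                             "syrup_g", "label")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mixture_design
#' @export
read_mixture_design <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(label = "character"))
  out <- make_mixture_design(
    total_mass = d$honey_g[1] + d$syrup_g[1],
    honey_fractions = d$fraction_pct,
    labels = d$label
  )
  out
}
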