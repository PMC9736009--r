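#' Configure the end-to-end adulteration-detection pipeline
#'
#' Bundles every knob of the simulate -> preprocess -> features -> classify
#' -> metrics chain with a single master seed; every stage derives its own
#' seed deterministically from it, so a config fully determines all outputs.
#'
#' @param honeys,syrups Material names; every honey x syrup combination is
#'   simulated and classified separately (the default reporting layout).
#' @param class_fractions Honey mass-percent levels that form the classes
#'   (default `c(90, 80, 70, 60)`; the pure level is optional).
#' @param include_pure Also simulate and classify the 100% class.
#' @param total_mass Mixture total mass in grams (design bookkeeping).
#' @param grid Wavelength grid (default 311 bands, 420-730 nm).
#' @param dims Cube spatial extent `c(rows, cols)` (default 64 x 64; the
#'   sensor-scale maximum is 1200 x 1920).
#' @param sigma_read Additive readout-noise standard deviation
#'   (default 0.002, the low-noise regime).
#' @param illumination,lamp Passed to [simulate_cube_pair()].
#' @param separation Minimum pairwise endmember separation (default 0.1).
#' @param mixing `"linear"` or `"beer_lambert"` (see [mixture_spectrum()]).
#' @param n_per_class Curves kept per class after random subsampling
#'   (default 100).
#' @param k_neighborhood Averaging-neighborhood side (default 4).
#' @param n_terms Sine terms per curve (default 8, i.e. 24 coefficients).
#' @param restarts Fit restarts (default 5).
#' @param models Classifier families to run; `"svm"` is accepted as an
#'   alias for `"svm_quadratic"`.
#' @param k_folds Cross-validation folds (default 10).
#' @param joint Pool all combinations into one classification task instead
#'   of one per combination.
#' @param seed Master seed.
#' @return Object of class `pipeline_config` (a validated named list).
#' @export
pipeline_config <- function(honeys = c("Q", "GS"),
                            syrups = c("F", "G", "M"),
                            class_fractions = c(90, 80, 70, 60),
                            include_pure = FALSE,
                            total_mass = 23,
                            grid = wavelength_grid(),
                            dims = c(64, 64),
                            sigma_read = 0.002,
                            illumination = list(strength = 0.1,
                                                center_rel = c(0.5, 0.5)),
                            lamp = list(peak_nm = 560, width_nm = 180,
                                        floor = 0.6),
                            separation = 0.1,
                            mixing = c("linear", "beer_lambert"),
                            n_per_class = 100,
                            k_neighborhood = 4L,
                            n_terms = 8L,
                            restarts = 5L,
                            models = c("lda", "svm_quadratic", "nn"),
                            k_folds = 10L,
                            joint = FALSE,
                            seed = 0L) {
  mixing <- match.arg(mixing)
  models <- vapply(models, function(m) {
    if (m == "svm") "svm_quadratic" else m
  }, character(1), USE.NAMES = FALSE)
  bad <- setdiff(models, c("lda", "svm_quadratic", "nn"))
  if (length(bad)) stop(sprintf("unknown model family: %s", bad[1]), call. = FALSE)
  validate_grid(grid)
  if (any(dims %% k_neighborhood != 0)) {
    stop("cube dims must be multiples of the neighborhood side", call. = FALSE)
  }
  n_tiles <- prod(dims %/% k_neighborhood)
  if (n_tiles < n_per_class) {
    stop(sprintf("%d tiles per cube < n_per_class = %d; enlarge dims",
                 n_tiles, n_per_class), call. = FALSE)
  }
  cfg <- list(honeys = honeys, syrups = syrups,
              class_fractions = class_fractions, include_pure = include_pure,
              total_mass = total_mass, grid = grid, dims = as.integer(dims),
              sigma_read = sigma_read, illumination = illumination,
              lamp = lamp, separation = separation, mixing = mixing,
              n_per_class = as.integer(n_per_class),
              k_neighborhood = as.integer(k_neighborhood),
              n_terms = as.integer(n_terms), restarts = as.integer(restarts),
              models = models, k_folds = as.integer(k_folds),
              joint = isTRUE(joint), seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline config as YAML
#'
#' The YAML stores the grid as `grid_from` / `grid_to` / `grid_bands`;
#' every other field maps one-to-one to [pipeline_config()] arguments.
#'
#' @param path YAML file path.
#' @param config A `pipeline_config`.
#' @param seed Optional master-seed override applied after reading.
#' @return `read_pipeline_config` returns a `pipeline_config`;
#'   `write_pipeline_config` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  grid <- wavelength_grid(y$grid_from %||% 420, y$grid_to %||% 730,
                          y$grid_bands %||% 311)
  y$grid_from <- NULL; y$grid_to <- NULL; y$grid_bands <- NULL
  if (!is.null(seed)) y$seed <- seed
  args <- c(list(grid = grid), y)
  do.call(pipeline_config, args)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  y <- unclass(config)
  y$grid_from <- min(config$grid)
  y$grid_to <- max(config$grid)
  y$grid_bands <- length(config$grid)
  y$grid <- NULL
  yaml::write_yaml(y, path)
  invisible(path)
}

combination_label <- function(honey, syrup) paste0(honey, "+", syrup)

combine_curve_sets <- function(sets) {
  spectral_curve_set(
    do.call(rbind, lapply(sets, `[[`, "curves")),
    sets[[1]]$grid,
    unlist(lapply(sets, `[[`, "labels")),
    do.call(rbind, lapply(sets, function(s) {
      s$provenance[, c("tile_row", "tile_col"), drop = FALSE]
    })),
    meta = sets[[1]]$meta
  )
}

#' Simulate and preprocess the curves of one honey x syrup combination
#'
#' For every class fraction: composes the mixture transmittance from the
#' endmember library, simulates a sample/white cube pair, averages 4 x 4
#' neighborhoods in both, divides sample by white, and labels the curves
#' `<honey><fraction>` (e.g. `Q90`). The pooled set is then randomly
#' subsampled to `n_per_class` curves per class.
#'
#' @param config A [pipeline_config()].
#' @param library An [generate_endmembers()] library covering the materials.
#' @param honey,syrup Material names from the config.
#' @return A `spectral_curve_set`.
#' @export
simulate_combination_curves <- function(config, library, honey, syrup) {
  stopifnot(inherits(config, "pipeline_config"))
  fractions <- config$class_fractions
  if (config$include_pure) fractions <- c(100, fractions)
  combo <- combination_label(honey, syrup)
  sets <- lapply(fractions, function(fr) {
    tau <- mixture_spectrum(library, honey, syrup, fr, mode = config$mixing)
    pair <- simulate_cube_pair(
      tau, config$grid, dims = config$dims,
      illumination = config$illumination, lamp = config$lamp,
      sigma_read = config$sigma_read,
      seed = derive_seed(config$seed, sprintf("simulate/%s/%g", combo, fr)),
      meta = list(honey = honey, syrup = syrup, fraction = fr))
    sample_curves <- average_neighborhoods(pair$sample, config$k_neighborhood,
                                           label = paste0(honey, fr))
    white_curves <- average_neighborhoods(pair$white, config$k_neighborhood,
                                          label = paste0(honey, fr))
    compute_transmittance(sample_curves, white_curves)
  })
  subsample_curves(combine_curve_sets(sets), config$n_per_class,
                   seed = derive_seed(config$seed, sprintf("subsample/%s", combo)))
}

model_spec_from_config <- function(config, family, combo) {
  model_spec(family,
             seed = derive_seed(config$seed, sprintf("model/%s/%s", family, combo)))
}

#' Run the full adulteration-detection pipeline
#'
#' Simulates every honey x syrup combination, extracts 24-coefficient
#' sum-of-sines features, cross-validates each configured classifier, and
#' writes per-combination artifacts to `outdir`: curves, features and
#' prediction CSVs, metric tables (CSV + JSON) with confusion matrices, the
#' mixture design, and a run log (`run.json`) holding the resolved config
#' and all derived seeds. Two identical invocations produce byte-identical
#' CSVs.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if missing); `NULL` skips all
#'   file output.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a named list per combination with elements `curves`,
#'   `features`, `predictions` (per model) and `metrics` (per model), plus
#'   `design` and `config` at the top level.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  out_path <- function(...) file.path(outdir, sprintf(...))

  design_fracs <- if (config$include_pure) c(100, config$class_fractions)
                  else config$class_fractions
  design <- make_mixture_design(config$total_mass, design_fracs)
  library <- generate_endmembers(
    c(config$honeys, config$syrups), config$grid,
    seed = derive_seed(config$seed, "endmembers"),
    separation = config$separation)

  combos <- expand.grid(honey = config$honeys, syrup = config$syrups,
                        stringsAsFactors = FALSE)
  results <- list(design = design, config = config, combinations = list())

  for (i in seq_len(nrow(combos))) {
    honey <- combos$honey[i]; syrup <- combos$syrup[i]
    combo <- combination_label(honey, syrup)
    say("[%s] simulating %d levels (%d x %d cubes, sigma = %g)", combo,
        length(design_fracs), config$dims[1], config$dims[2], config$sigma_read)
    curves <- simulate_combination_curves(config, library, honey, syrup)
    say("[%s] fitting %d curves with %d-term sum of sines", combo,
        nrow(curves$curves), config$n_terms)
    features <- build_feature_matrix(
      curves, n_terms = config$n_terms, restarts = config$restarts,
      seed = derive_seed(config$seed, sprintf("features/%s", combo)))
    results$combinations[[combo]] <-
      list(curves = curves, features = features,
           predictions = list(), metrics = list())
    if (!is.null(outdir)) {
      write_curve_set(curves, out_path("curves_%s_%s.csv", honey, syrup))
      write_feature_matrix(features, out_path("features_%s_%s.csv", honey, syrup))
    }
  }

  classify_one <- function(features, combo) {
    folds <- stratified_folds(features$labels, config$k_folds,
                              seed = derive_seed(config$seed,
                                                 sprintf("folds/%s", combo)))
    out <- list(predictions = list(), metrics = list())
    for (family in config$models) {
      spec <- model_spec_from_config(config, family, combo)
      preds <- cross_validate(spec, features, folds)
      tab <- metrics_table(preds)
      say("[%s] %s: accuracy %.1f%%", combo, family, attr(tab, "accuracy"))
      out$predictions[[family]] <- preds
      out$metrics[[family]] <- tab
    }
    out
  }

  if (config$joint) {
    pooled <- list(
      values = do.call(rbind, lapply(results$combinations,
                                     function(r) r$features$values)),
      labels = unlist(lapply(names(results$combinations), function(cb) {
        paste0(gsub("\\+", "", cb), "-", results$combinations[[cb]]$features$labels)
      })),
      meta = list(n_terms = config$n_terms))
    class(pooled) <- "feature_matrix"
    res <- classify_one(pooled, "joint")
    results$joint <- res
    if (!is.null(outdir)) {
      for (family in names(res$predictions)) {
        write_predictions(res$predictions[[family]],
                          out_path("predictions_joint_%s.csv", family))
        write_metrics_table(res$metrics[[family]],
                            out_path("metrics_joint_%s.csv", family))
      }
    }
  } else {
    for (combo in names(results$combinations)) {
      res <- classify_one(results$combinations[[combo]]$features, combo)
      results$combinations[[combo]]$predictions <- res$predictions
      results$combinations[[combo]]$metrics <- res$metrics
      if (!is.null(outdir)) {
        hs <- strsplit(combo, "+", fixed = TRUE)[[1]]
        for (family in names(res$predictions)) {
          write_predictions(res$predictions[[family]],
                            out_path("predictions_%s_%s_%s.csv", hs[1], hs[2], family))
          write_metrics_table(res$metrics[[family]],
                              out_path("metrics_%s_%s_%s.csv", hs[1], hs[2], family))
        }
      }
    }
  }

  if (!is.null(outdir)) {
    write_mixture_design(design, out_path("mixture_design.csv"))
    log <- list(
      config = unclass(write_config_for_log(config)),
      derived_seeds = list(endmembers = derive_seed(config$seed, "endmembers")),
      r_version = as.character(getRversion()),
      package_version = as.character(utils::packageVersion("honeyspec"))
    )
    jsonlite::write_json(log, out_path("run.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(results)
}

write_config_for_log <- function(config) {
  y <- unclass(config)
  y$grid <- list(from = min(config$grid), to = max(config$grid),
                 n_bands = length(config$grid))
  y
}

#' Summarize pipeline accuracies across combinations
#'
#' @param results The list returned by [run_pipeline()].
#' @return `data.frame` with columns `combination`, `model`, `accuracy`.
#' @export
pipeline_accuracies <- function(results) {
  rows <- list()
  for (combo in names(results$combinations)) {
    for (family in names(results$combinations[[combo]]$metrics)) {
      rows[[length(rows) + 1L]] <- data.frame(
        combination = combo, model = family,
        accuracy = attr(results$combinations[[combo]]$metrics[[family]],
                        "accuracy"))
    }
  }
  do.call(rbind, rows)
}
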