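#' Read a two-column trace CSV
#'
#' Comma-separated, header row, '.' decimal. Errors name the file and the
#' missing column.
#'
#' @param path CSV file path.
#' @param columns required column names (e.g. `c("time_s", "absorbance")`).
#' @return A tibble.
#' @export
read_trace_csv <- function(path, columns) {
  if (!file.exists(path)) stopf("input file not found: %s", path)
  df <- tryCatch(read.csv(path, check.names = FALSE),
                 error = function(e) stopf("cannot parse CSV %s: %s", path,
                                           conditionMessage(e)))
  missing <- setdiff(columns, names(df))
  if (length(missing))
    stopf("%s: missing column(s) %s", path, paste(missing, collapse = ", "))
  as_tibble(df)
}

#' Read a grayscale TIFF image or stack
#'
#' @param path TIFF path.
#' @return A matrix (single page) or y-by-x-by-frame array (stack; page
#'   order is time order).
#' @export
read_image_tiff <- function(path) {
  if (!file.exists(path)) stopf("input file not found: %s", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stopf("cannot parse TIFF %s: %s", path,
                                              conditionMessage(e)))
  pages <- map(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  if (length(pages) == 1) return(pages[[1]])
  arr <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]]
  arr
}

#' Write a grayscale TIFF image or stack
#'
#' Intensities are linearly rescaled to \[0, 1\] for storage; the scale and
#' offset are returned (and recorded in stage sidecar files) so absolute
#' units can be recovered. All analyses in this package are invariant to
#' such affine intensity rescaling.
#'
#' @param x matrix or 3-D array (third dimension = time).
#' @param path output TIFF path.
#' @return Invisibly, `list(offset, scale)` of the applied rescaling.
#' @export
write_image_tiff <- function(x, path) {
  x <- unclass(x)
  rng <- range(x)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  xs <- (x - rng[1]) / scale
  pages <- if (length(dim(x)) == 3) {
    map(seq_len(dim(x)[3]), ~ xs[, , .x])
  } else list(as.matrix(xs))
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(list(offset = rng[1], scale = scale))
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  path
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Serialize an empirical model to JSON
#'
#' Writes the coefficient set, retained terms, factors, units and fit R^2;
#' the underlying `lm` objects are not serialized, so a reloaded model
#' predicts identically but offers no prediction intervals.
#'
#' @param model a `hydrogel_model`.
#' @param path output JSON path.
#' @return The path, invisibly.
#' @export
write_model_json <- function(model, path) {
  write_json_out(list(
    property = model$property, units = model$units,
    coefficients = as.list(model$coefficients), terms = model$terms,
    factors = model$factors, r_squared = model$r_squared,
    source = model$source
  ), path)
  invisible(path)
}

#' Load an empirical model from JSON
#'
#' @param path JSON file written by [write_model_json()].
#' @return A `hydrogel_model`.
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) stopf("input file not found: %s", path)
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_hydrogel_model(
    property = m$property, units = m$units,
    coefficients = unlist(m$coefficients), terms = as.character(m$terms),
    factors = as.character(m$factors), r_squared = m$r_squared,
    source = m$source %||% "serialized"
  )
}

#' Run one analysis or simulation stage with file I/O
#'
#' Config-driven entry point shared with the `gelchar` command-line script
#' (`system.file("scripts", "gelchar", package = "gelchar")`). Each run
#' writes its artifacts plus a provenance sidecar (`provenance.json`:
#' package version, stage, config hash, seed), and is deterministic given
#' identical config, inputs and seed.
#'
#' Stages: `simulate_turbidity`, `simulate_compression`, `simulate_fiber`,
#' `simulate_frap`, `simulate_dataset` (generator parameters in `params`;
#' CSV/TIFF output plus a ground-truth JSON sidecar); `kinetics`,
#' `compression`, `fiber`, `frap` (analysis of a CSV/TIFF input); `fit`,
#' `predict`, `sensitivity`, `design` (empirical-model operations;
#' `params$model` is `"published"` or a model-JSON path).
#'
#' @param stage stage name (see Details).
#' @param output_dir directory for artifacts (created if needed).
#' @param input input file path (stages that read data).
#' @param params named list of stage parameters; unknown keys are rejected.
#' @param seed integer seed for stages with randomness.
#' @return Invisibly, a list with `artifacts` (paths) and `result`.
#' @export
run_stage <- function(stage, output_dir, input = NULL, params = list(),
                      seed = NULL) {
  stages <- c("simulate_turbidity", "simulate_compression", "simulate_fiber",
              "simulate_frap", "simulate_dataset", "kinetics", "compression",
              "fiber", "frap", "fit", "predict", "sensitivity", "design")
  stage <- match.arg(stage, stages)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  art <- function(name) file.path(output_dir, name)
  artifacts <- character()
  take <- function(allowed) {
    unknown <- setdiff(names(params), allowed)
    if (length(unknown))
      stopf("unknown parameter(s) for stage `%s`: %s", stage,
            paste(unknown, collapse = ", "))
    params
  }
  get_models <- function(spec) {
    if (is.null(spec) || identical(spec, "published")) published_models()
    else {
      m <- read_model_json(spec)
      setNames(list(m), m$property)
    }
  }

  result <- switch(stage,
    simulate_turbidity = {
      p <- take(names(formals(sim_turbidity_trace)))
      p$seed <- p$seed %||% seed
      tr <- do.call(sim_turbidity_trace, p)
      write.csv(tr, art("turbidity.csv"), row.names = FALSE)
      write_json_out(c(attr(tr, "truth"), list(seed = seed)), art("turbidity_truth.json"))
      artifacts <- c(art("turbidity.csv"), art("turbidity_truth.json"))
      tr
    },
    simulate_compression = {
      p <- take(names(formals(sim_compression_trace)))
      p$seed <- p$seed %||% seed
      tr <- do.call(sim_compression_trace, p)
      write.csv(tr, art("compression.csv"), row.names = FALSE)
      write_json_out(c(attr(tr, "truth"), attr(tr, "meta")),
                     art("compression_truth.json"))
      artifacts <- c(art("compression.csv"), art("compression_truth.json"))
      tr
    },
    simulate_fiber = {
      p <- take(names(formals(sim_fiber_image)))
      p$seed <- p$seed %||% seed
      img <- do.call(sim_fiber_image, p)
      sc <- write_image_tiff(img, art("fiber.tif"))
      tr <- attr(img, "truth")
      write_json_out(list(fiber_diameter_um = tr$fiber_diameter_um,
                          n_fibers = tr$n_fibers, seed = seed,
                          pixel_size_um = attr(img, "pixel_size_um"),
                          intensity_offset = sc$offset,
                          intensity_scale = sc$scale),
                     art("fiber_truth.json"))
      artifacts <- c(art("fiber.tif"), art("fiber_truth.json"))
      img
    },
    simulate_frap = {
      p <- take(names(formals(sim_frap_sequence)))
      p$seed <- p$seed %||% seed
      sq <- do.call(sim_frap_sequence, p)
      sc <- write_image_tiff(sq$frames, art("frap.tif"))
      write_json_out(list(true_D_um2_s = sq$truth$true_D_um2_s,
                          frame_dt_s = sq$frame_dt_s, n_pre = sq$n_pre,
                          pixel_size_um = sq$pixel_size_um, seed = seed,
                          intensity_offset = sc$offset,
                          intensity_scale = sc$scale),
                     art("frap_truth.json"))
      artifacts <- c(art("frap.tif"), art("frap_truth.json"))
      sq
    },
    simulate_dataset = {
      p <- take(names(formals(sim_property_table)))
      p$seed <- p$seed %||% seed
      tab <- do.call(sim_property_table, p)
      write.csv(tab, art("properties.csv"), row.names = FALSE)
      artifacts <- art("properties.csv")
      tab
    },
    kinetics = {
      p <- take(c("smoothing_window"))
      tr <- read_trace_csv(input, c("time_s", "absorbance"))
      res <- do.call(extract_kinetics, c(list(tr), p))
      artifacts <- write_json_out(
        c(as.list(res), list(units = list(delta_abs = "AU", t_half_s = "s",
                                          rate_au_per_s = "AU/s",
                                          lag_time_s = "s"))),
        art("kinetics.json"))
      res
    },
    compression = {
      p <- take(c("nominal_thickness_mm", "plug_area_mm2",
                  "platen_start_height_mm", "noise_rms_N"))
      tr <- read_trace_csv(input, c("position_mm", "force_N"))
      res <- do.call(analyze_compression, c(list(tr), p))
      artifacts <- write_json_out(
        c(as.list(res), list(units = list(modulus_Pa = "Pa",
                                          measured_thickness_mm = "mm"))),
        art("compression.json"))
      res
    },
    fiber = {
      p <- take(c("pixel_size_um", "expected_diameter_um", "scale_convention"))
      img <- read_image_tiff(input)
      cfg_args <- p[intersect(names(p), c("expected_diameter_um", "scale_convention"))]
      cfg <- do.call(fiber_config, cfg_args)
      ps <- p$pixel_size_um %||% 0.0549
      res <- analyze_fiber_image(img, cfg, pixel_size_um = ps)
      dists <- attr(res, "distributions")
      write.csv(bind_rows(mutate(dists$fiber, which = "fiber"),
                          mutate(dists$pore, which = "pore")),
                art("fiber_distributions.csv"), row.names = FALSE)
      write_json_out(c(as.list(res), list(units = "um")), art("fiber.json"))
      artifacts <- c(art("fiber.json"), art("fiber_distributions.csv"))
      res
    },
    frap = {
      p <- take(c("frame_dt_s", "n_pre", "pixel_size_um", "meta"))
      meta <- if (!is.null(p$meta)) yaml::read_yaml(p$meta) else list()
      frames <- read_image_tiff(input)
      if (length(dim(frames)) != 3) stopf("%s: FRAP input must be a multi-page stack", input)
      sq <- structure(list(
        frames = frames,
        frame_dt_s = p$frame_dt_s %||% meta$frame_dt_s %||% 1.5,
        n_pre = p$n_pre %||% meta$n_pre %||% 5,
        pixel_size_um = p$pixel_size_um %||% meta$pixel_size_um %||% 0.439,
        bleach_axis = meta$bleach_axis %||% "y"
      ), class = "frap_sequence")
      res <- analyze_frap(sq)
      artifacts <- write_json_out(
        c(as.list(res), list(units = list(D_um2_s = "um^2/s"))), art("frap.json"))
      res
    },
    fit = {
      p <- take(c("property", "primary_alpha", "interaction_alpha"))
      tab <- read_trace_csv(input, c("property", "value"))
      m <- do.call(fit_property_model, c(list(tab), p))
      artifacts <- art("model.json")
      write_model_json(m, art("model.json"))
      m
    },
    predict = {
      p <- take(c("model", "concentration_mg_ml", "temperature_C", "pH",
                  "hydrodynamic_radius_nm", "override"))
      models <- get_models(p$model)
      cond_args <- p[intersect(names(p),
                               c("concentration_mg_ml", "temperature_C", "pH",
                                 "hydrodynamic_radius_nm"))]
      cond <- as_tibble(cond_args)
      preds <- imap(models, function(m, prop) {
        if (all(m$factors %in% names(cond)))
          list(value = predict(m, cond, override = isTRUE(p$override))$.pred,
               units = m$units)
      })
      preds <- preds[!vapply(preds, is.null, logical(1))]
      if (!length(preds)) stopf("condition is missing the factors of every model")
      artifacts <- write_json_out(list(condition = as.list(cond),
                                        predictions = preds),
                                   art("predictions.json"))
      preds
    },
    sensitivity = {
      p <- take(c("model"))
      s <- sensitivity(get_models(p$model))
      write.csv(s, art("sensitivity.csv"), row.names = FALSE)
      artifacts <- art("sensitivity.csv")
      s
    },
    design = {
      p <- take(c("model", "targets", "fixed", "resolution",
                  "temperature_discrete"))
      tg <- do.call(design_targets, p$targets %||% stopf("`targets` required"))
      res <- design_condition(get_models(p$model), tg,
                              fixed = p$fixed %||% list(),
                              resolution = p$resolution %||% 0.01,
                              temperature_discrete = p$temperature_discrete %||% TRUE)
      artifacts <- write_json_out(list(condition = as.list(res$condition),
                                        predictions = res$predictions,
                                        desirability = res$desirability),
                                   art("design.json"))
      res
    }
  )

  prov <- list(package = "gelchar",
               version = as.character(packageVersion("gelchar")),
               stage = stage, input = input %||% NA,
               seed = seed %||% NA,
               config_hash = config_hash(params))
  write_json_out(prov, art("provenance.json"))
  invisible(list(artifacts = c(artifacts, art("provenance.json")),
                 result = result))
}
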