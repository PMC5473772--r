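## Pipeline glue: one-call regime simulation (simulate -> render ->
## ground-truth extraction -> quantification) and the umbrella
## `run_pipeline()` that ties the modules into a reproducible artifact
## directory. All randomness flows from one top-level seed through named
## substreams, so e.g. changing segmentation parameters never changes the
## simulated images.

#' Simulation parameter bundle
#'
#' Collects every knob of the synthetic-data generator with this
#' package's default study conditions.
#'
#' @param occupancy an [occupancy_params()].
#' @param area an [area_distribution()].
#' @param optics an [optics_noise_config()] (its seed is overridden by the
#'   pipeline substreams).
#' @param brightness_per_fluorophore photons per fluorophore per exposure.
#' @param autofluorescence photons/pixel of cellular autofluorescence.
#' @param expression_sdlog lognormal sdlog of per-cell expression noise.
#' @param frame_dim frame size in pixels.
#' @param cells_per_frame maximum cells rendered per frame; larger
#'   populations are split over several frames.
#' @return a `sim_params` list.
#' @export
sim_params <- function(occupancy = occupancy_params(),
                       area = area_distribution(),
                       optics = optics_noise_config(),
                       brightness_per_fluorophore = 50,
                       autofluorescence = 3,
                       expression_sdlog = 0.3,
                       frame_dim = c(512L, 512L),
                       cells_per_frame = 80L) {
  structure(list(occupancy = occupancy, area = area, optics = optics,
                 brightness_per_fluorophore = brightness_per_fluorophore,
                 autofluorescence = autofluorescence,
                 expression_sdlog = expression_sdlog,
                 frame_dim = as.integer(frame_dim),
                 cells_per_frame = as.integer(cells_per_frame)),
            class = "sim_params")
}

#' Simulate one experimental regime end to end
#'
#' Samples a population of the requested construct, renders as many
#' frames as needed, extracts per-cell measurements against the
#' ground-truth label masks, and quantifies them. Cell ids are globally
#' renumbered across frames.
#'
#' @param construct `"FULL_LENGTH"`, `"SPLIT"`, or `"EMPTY"`.
#' @param n_arrays hybrid-array copies per cell (overrides the occupancy
#'   parameter bundle).
#' @param n_cells total cells across frames.
#' @param params a [sim_params()] bundle.
#' @param seed top-level seed for this regime.
#' @param cfg a [quant_config()].
#' @param keep_images if `TRUE`, rendered `synthetic_image`s are returned
#'   too.
#' @return list with `quants` (a `cell_quant` data.frame carrying
#'   `passed_filters`), `measurements` (a `cell_measurements` object) and
#'   optionally `images`.
#' @export
simulate_regime <- function(construct, n_arrays, n_cells,
                            params = sim_params(), seed = 1L,
                            cfg = quant_config(), keep_images = FALSE) {
  stopifnot(n_cells >= 1)
  occ <- params$occupancy
  occ$n_arrays <- n_arrays
  chunks <- split(seq_len(n_cells),
                  ceiling(seq_len(n_cells) / params$cells_per_frame))
  measurements <- list()
  images <- list()
  next_id <- 0L
  for (f in seq_along(chunks)) {
    n_f <- length(chunks[[f]])
    pop <- sample_population(
      n_f, construct = construct, occupancy = occ,
      area_distribution = params$area,
      seed = substream_seed(seed, sprintf("sample/%s/%d", construct, f)),
      frame_dim = params$frame_dim,
      brightness_per_fluorophore = params$brightness_per_fluorophore,
      autofluorescence = params$autofluorescence,
      expression_sdlog = params$expression_sdlog)
    optics <- params$optics
    optics$seed <- substream_seed(seed, sprintf("render/%s/%d", construct, f))
    img <- render_image(pop, optics)
    meas <- extract_measurements(img)
    for (m in meas) {
      m$cell_id <- m$cell_id + next_id
      measurements[[length(measurements) + 1L]] <- m
    }
    next_id <- next_id + n_f
    if (keep_images) images[[f]] <- img
  }
  class(measurements) <- "cell_measurements"
  out <- list(quants = quantify_cells(measurements, cfg),
              measurements = measurements)
  if (keep_images) out$images <- images
  out
}

#' Run configuration for the full pipeline
#'
#' Bundles the top-level seed, population size per regime, and all module
#' configurations. Round-trips losslessly through YAML via
#' [write_run_config()] / [read_run_config()].
#'
#' @param seed top-level integer seed.
#' @param n_cells cells per simulated regime.
#' @param pool_size,affinity,sites_per_array,free_complementation_rate
#'   occupancy model parameters (see [occupancy_params()]).
#' @param psf_sigma,read_noise_sd,gain,offset optics/camera parameters
#'   (see [optics_noise_config()]).
#' @param brightness_per_fluorophore,autofluorescence,expression_sdlog
#'   photon-budget parameters (see [sim_params()]).
#' @param signal_fraction,background_fraction,max_intensity,min_ratio
#'   quantification settings (see [quant_config()]).
#' @param bin_window,bin_min_cells area-binning settings.
#' @param x_cap,y_cap regression axis caps.
#' @param subset_fraction fold-change subsetting (1.0 or 0.5).
#' @return a `run_config` (plain nested list; YAML-serialisable).
#' @export
run_config <- function(seed = 1L, n_cells = 300L,
                       pool_size = 600, affinity = 1, sites_per_array = 64,
                       free_complementation_rate = 0.002,
                       psf_sigma = 1.3, read_noise_sd = 10, gain = 16,
                       offset = 100,
                       brightness_per_fluorophore = 50, autofluorescence = 3,
                       expression_sdlog = 0.3,
                       signal_fraction = 0.10, background_fraction = 0.50,
                       max_intensity = 65000, min_ratio = 5.0,
                       bin_window = 10L, bin_min_cells = 10L,
                       x_cap = 65000, y_cap = 15000,
                       subset_fraction = 1.0) {
  structure(list(
    seed = as.integer(seed), n_cells = as.integer(n_cells),
    pool_size = pool_size, affinity = affinity,
    sites_per_array = sites_per_array,
    free_complementation_rate = free_complementation_rate,
    psf_sigma = psf_sigma, read_noise_sd = read_noise_sd, gain = gain,
    offset = offset,
    brightness_per_fluorophore = brightness_per_fluorophore,
    autofluorescence = autofluorescence,
    expression_sdlog = expression_sdlog,
    signal_fraction = signal_fraction,
    background_fraction = background_fraction,
    max_intensity = max_intensity, min_ratio = min_ratio,
    bin_window = as.integer(bin_window),
    bin_min_cells = as.integer(bin_min_cells),
    x_cap = x_cap, y_cap = y_cap, subset_fraction = subset_fraction
  ), class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

config_to_objects <- function(config) {
  list(
    sim = sim_params(
      occupancy = occupancy_params(
        pool_size = config$pool_size, n_arrays = 1,
        sites_per_array = config$sites_per_array,
        affinity = config$affinity,
        free_complementation_rate = config$free_complementation_rate),
      optics = optics_noise_config(
        psf_sigma = config$psf_sigma, read_noise_sd = config$read_noise_sd,
        gain = config$gain, offset = config$offset),
      brightness_per_fluorophore = config$brightness_per_fluorophore,
      autofluorescence = config$autofluorescence,
      expression_sdlog = config$expression_sdlog),
    quant = quant_config(
      signal_fraction = config$signal_fraction,
      background_fraction = config$background_fraction,
      max_intensity = config$max_intensity, min_ratio = config$min_ratio)
  )
}

#' Run the full simulate-quantify-analyze pipeline
#'
#' Simulates five arms — full-length fusion with and without array, split
#' fusion with and without array (the no-array split arm doubles as the
#' background-control strain), and a two-copy split arm — quantifies
#' every cell against the ground-truth masks, and writes all artifacts:
#' one TIFF image/mask pair and truth CSV per arm's first frame, per-cell
#' quantification CSVs, a pooled pixel histogram CSV for the split+array
#' arm, area-bin CSVs, a regression-comparison JSON, a fold-change JSON
#' (two-copy vs one-copy, control-subtracted), the run configuration as
#' YAML, and a structured provenance log. Reruns with the same
#' configuration are byte-identical for all CSV/JSON artifacts.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing).
#' @return named list of artifact paths, invisibly; the computed
#'   `regression` and `fold_change` objects are attached as attributes.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (config$n_cells < 1) {
    stop("n_cells must be >= 1; nothing was written")
  }
  obj <- config_to_objects(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "provenance.jsonl")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))
  log_line <- function(stage, ...) {
    rec <- c(list(stage = stage, seed = config$seed,
                  config_hash = config_hash(unclass(config))), list(...))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), log_con)
  }

  arms <- list(
    full_no_array = list(construct = "FULL_LENGTH", n_arrays = 0L),
    full_array    = list(construct = "FULL_LENGTH", n_arrays = 1L),
    split_no_array = list(construct = "SPLIT", n_arrays = 0L),
    split_array   = list(construct = "SPLIT", n_arrays = 1L),
    split_array_2copy = list(construct = "SPLIT", n_arrays = 2L)
  )
  paths <- list(config = file.path(out_dir, "config.yaml"))
  write_run_config(config, paths$config)
  results <- list()
  for (arm in names(arms)) {
    res <- simulate_regime(
      arms[[arm]]$construct, arms[[arm]]$n_arrays, config$n_cells,
      params = obj$sim, seed = substream_seed(config$seed, arm),
      cfg = obj$quant, keep_images = TRUE)
    results[[arm]] <- res
    prefix <- file.path(out_dir, arm)
    write_synthetic_image(res$images[[1]], prefix)
    qp <- paste0(prefix, "_cells.csv")
    utils::write.csv(res$quants, qp, row.names = FALSE)
    bp <- paste0(prefix, "_bins.csv")
    utils::write.csv(
      bin_by_area(res$quants, window = config$bin_window,
                  min_cells = config$bin_min_cells), bp, row.names = FALSE)
    paths[[paste0(arm, "_cells")]] <- qp
    paths[[paste0(arm, "_bins")]] <- bp
    log_line("simulate_quantify", arm = arm, n_in = config$n_cells,
             n_out = nrow(res$quants),
             n_retained = sum(res$quants$passed_filters))
  }

  hp <- file.path(out_dir, "split_array_pixel_histogram.csv")
  utils::write.csv(pixel_histogram(results$split_array$measurements,
                                   obj$quant), hp, row.names = FALSE)
  paths$histogram <- hp
  log_line("pixel_histogram", arm = "split_array")

  reg <- list(
    full_array = regress_signal_vs_background(
      results$full_array$quants, config$x_cap, config$y_cap),
    split_array = regress_signal_vs_background(
      results$split_array$quants, config$x_cap, config$y_cap))
  rp <- file.path(out_dir, "regression.json")
  jsonlite::write_json(lapply(reg, unclass), rp, auto_unbox = TRUE,
                       digits = NA)
  paths$regression <- rp
  log_line("regression", slope_full = reg$full_array$slope,
           slope_split = reg$split_array$slope)

  fc <- estimate_fold_change(results$split_array$quants,
                             results$split_array_2copy$quants,
                             subset_fraction = config$subset_fraction,
                             control = results$split_no_array$quants)
  fp <- file.path(out_dir, "fold_change.json")
  jsonlite::write_json(unclass(fc), fp, auto_unbox = TRUE, digits = NA)
  paths$fold_change <- fp
  log_line("fold_change", fold = fc$fold, n_a = fc$n_a, n_b = fc$n_b)

  out <- paths
  attr(out, "regression") <- reg
  attr(out, "fold_change") <- fc
  invisible(out)
}
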