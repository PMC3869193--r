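# End-to-end pipeline driver: simulate (or read) stacks, extract
# transmission series, analyze growth, summarize, plot, and write a
# manifest with checksums so a run is reproducible from its config + seed.

#' Build a pipeline configuration
#'
#' All knobs of a synthetic end-to-end run in one serializable list.
#' Defaults describe the reference experiment: a 4 x 6 array of 1-ul
#' droplets, four loading concentrations (1000, 100, 10, 1 cells/ul) with
#' six droplets each, frames every 0.5 h for 72 h.
#'
#' @param concentrations Loading concentrations in cells/ul.
#' @param droplets_per_concentration Droplets per concentration group.
#' @param volume Droplet volume in ul.
#' @param layout A [moca_layout()].
#' @param growth A [growth_params()].
#' @param times Frame timestamps (hours).
#' @param threshold Normalized-transmission crossing level (default 0.99).
#' @param baseline_frames Frames averaged for normalization (default 1).
#' @param min_final_drop Sustained-drop guard (default 0.05).
#' @param min_rise,min_frames Rebound detection parameters.
#' @param noise_sd,illumination_sd,background_intensity,oil_intensity,colony_absorbance,area_per_biomass
#'   Scene rendering parameters (see [synthetic_scene()]).
#' @param extraction_mode `"grid"` or `"detect"` ROI location.
#' @param shrink_factor Measurement-disk fraction of the spot radius.
#' @param seed Master seed.
#' @param write_stacks If `TRUE`, also write per-droplet TIFF stacks.
#' @param write_plots If `TRUE` (default), write PNG figures.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(concentrations = c(1000, 100, 10, 1),
                            droplets_per_concentration = 6,
                            volume = 1,
                            layout = moca_layout(),
                            growth = growth_params(),
                            times = seq(0, 72, by = 0.5),
                            threshold = 0.99,
                            baseline_frames = 1,
                            min_final_drop = 0.05,
                            min_rise = 0.05, min_frames = 6,
                            noise_sd = 2, illumination_sd = 0.05,
                            background_intensity = 200, oil_intensity = 120,
                            colony_absorbance = 2.3, area_per_biomass = 5e-6,
                            extraction_mode = c("grid", "detect"),
                            shrink_factor = 0.9,
                            seed = 1,
                            write_stacks = FALSE,
                            write_plots = TRUE) {
  cfg <- list(concentrations = concentrations,
              droplets_per_concentration = droplets_per_concentration,
              volume = volume, layout = layout, growth = growth,
              times = times, threshold = threshold,
              baseline_frames = baseline_frames,
              min_final_drop = min_final_drop,
              min_rise = min_rise, min_frames = min_frames,
              noise_sd = noise_sd, illumination_sd = illumination_sd,
              background_intensity = background_intensity,
              oil_intensity = oil_intensity,
              colony_absorbance = colony_absorbance,
              area_per_biomass = area_per_biomass,
              extraction_mode = match.arg(extraction_mode),
              shrink_factor = shrink_factor,
              seed = as.integer(seed),
              write_stacks = isTRUE(write_stacks),
              write_plots = isTRUE(write_plots))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields override the [pipeline_config()] defaults; `layout` and
#' `growth` may be given as nested maps of their constructor arguments,
#' `times` as a `{start, end, step}` map.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  scalars <- c("concentrations", "droplets_per_concentration", "volume",
               "threshold", "baseline_frames", "min_final_drop", "min_rise",
               "min_frames", "noise_sd", "illumination_sd",
               "background_intensity", "oil_intensity", "colony_absorbance",
               "area_per_biomass", "extraction_mode", "shrink_factor",
               "seed", "write_stacks", "write_plots")
  for (s in intersect(names(y), scalars)) args[[s]] <- y[[s]]
  if (!is.null(y$layout)) args$layout <- do.call(moca_layout, y$layout)
  if (!is.null(y$growth)) args$growth <- do.call(growth_params, y$growth)
  if (!is.null(y$times))
    args$times <- seq(y$times$start, y$times$end, by = y$times$step)
  unknown <- setdiff(names(y), c(scalars, "layout", "growth", "times"))
  if (length(unknown))
    stop_domain("unknown config fields: ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, args)
}

#' Run the full synthetic pipeline
#'
#' Simulate -> extract -> analyze: builds the scene from the config,
#' renders and extracts each droplet, analyzes the growth curves, and
#' writes `series.csv`, `results.csv`, `summary.csv`,
#' `occupancy_table.csv`, `ground_truth.csv`, figures, a run log and a
#' `manifest.json` listing every output with its MD5 checksum. A run is
#' bit-identical for a fixed config + seed.
#'
#' @param config A [pipeline_config()] or path to a YAML config.
#' @param out_dir Output directory.
#' @param quiet Suppress progress messages (default `FALSE`).
#' @return Invisibly, a list with `series`, `results`, `summary`,
#'   `ground_truth`, `scene` and `manifest`.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_file <- file.path(out_dir, "run.log")
  log_con <- file(log_file, open = "wt")
  on.exit(close(log_con), add = TRUE)
  say <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   sprintf(...))
    writeLines(msg, log_con)
    if (!quiet) message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  say("planning: %d groups x %d droplets, seed %d",
      length(config$concentrations), config$droplets_per_concentration,
      config$seed)
  plan <- stage("plan", plan_experiment(
    config$layout, config$concentrations,
    config$droplets_per_concentration, config$volume, seed = config$seed))
  scene <- stage("scene", synthetic_scene(
    plan, growth = config$growth, times = config$times,
    background_intensity = config$background_intensity,
    oil_intensity = config$oil_intensity,
    colony_absorbance = config$colony_absorbance,
    area_per_biomass = config$area_per_biomass,
    noise_sd = config$noise_sd, illumination_sd = config$illumination_sd,
    seed = config$seed))

  say("simulating and extracting %d droplets x %d frames",
      nrow(scene$droplets), length(scene$times))
  clip_warnings <- character(0)
  sim <- stage("simulate/extract", withCallingHandlers(
    simulate_experiment(scene, shrink_factor = config$shrink_factor),
    warning = function(w) {
      clip_warnings <<- c(clip_warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    }))
  for (w in clip_warnings) say("warning: %s", w)

  say("analyzing growth curves (threshold %.2f)", config$threshold)
  groups <- tibble::tibble(droplet_id = scene$droplets$droplet,
                           group = scene$droplets$cells_per_droplet)
  results <- stage("analyze", analyze_droplets(
    sim$series, groups, threshold = config$threshold,
    baseline_frames = config$baseline_frames,
    min_final_drop = config$min_final_drop,
    min_rise = config$min_rise, min_frames = config$min_frames))
  summary_tbl <- stage("summarize", summarize_groups(results))

  norm_series <- normalize_curve(sim$series, config$baseline_frames)
  occ <- do.call(rbind, lapply(unique(config$concentrations), function(cc) {
    tab <- occupancy_table(occupancy_model(concentration = cc,
                                           volume = config$volume),
                           max_k = NULL)
    tab$concentration <- cc
    tab
  }))

  files <- character(0)
  wr <- function(obj, name) {
    fn <- file.path(out_dir, name)
    df <- as.data.frame(obj)
    for (cl in names(df))
      if (is.list(df[[cl]]))
        df[[cl]] <- vapply(df[[cl]], paste, "", collapse = ";")
    write.csv(df, fn, row.names = FALSE)
    files <<- c(files, fn)
  }
  wr(sim$series, "series.csv")
  wr(results, "results.csv")
  wr(summary_tbl, "summary.csv")
  wr(occ, "occupancy_table.csv")
  wr(sim$ground_truth, "ground_truth.csv")

  if (config$write_stacks) {
    say("writing TIFF stacks")
    files <- c(files, stage("write stacks",
                            write_scene(scene, file.path(out_dir, "stacks"))))
  }
  if (config$write_plots && capabilities("png")) {
    say("writing figures")
    p1 <- plot_growth_curves(norm_series, groups, config$threshold)
    p2 <- plot_threshold_boxes(results)
    for (nm in c("curves.png", "boxplot.png")) {
      fn <- file.path(out_dir, nm)
      grDevices::png(fn, width = 1200, height = 800, res = 150)
      print(if (nm == "curves.png") p1 else p2)
      grDevices::dev.off()
      files <- c(files, fn)
    }
  }

  manifest <- list(
    package = "mocar",
    version = as.character(packageVersion("mocar")),
    seed = config$seed, rng = "Mersenne-Twister",
    config = config_to_list(config),
    n_droplets = nrow(scene$droplets),
    n_grew = sum(results$grew),
    warnings = clip_warnings,
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) unname(md5sum(f))))
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  say("done: %d/%d droplets grew; %d files in %s",
      sum(results$grew), nrow(results), length(files) + 1L, out_dir)
  invisible(list(series = sim$series, results = results,
                 summary = summary_tbl, ground_truth = sim$ground_truth,
                 scene = scene, manifest = manifest))
}

config_to_list <- function(config) {
  cfg <- unclass(config)
  cfg$layout <- cfg$layout[c("n_rows", "n_cols", "spot_diameter", "pitch",
                             "pixels_per_mm")]
  cfg$growth <- unclass(cfg$growth)
  cfg$times <- list(start = cfg$times[1],
                    end = cfg$times[length(cfg$times)],
                    step = cfg$times[2] - cfg$times[1])
  cfg
}

#' Write a pipeline configuration to YAML
#'
#' @param config A [pipeline_config()].
#' @param path Output YAML file.
#' @return Invisibly, `path`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(config_to_list(config), path)
  invisible(path)
}
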