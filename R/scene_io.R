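# File plumbing for synthetic scenes: multi-page 8-bit grayscale TIFF per
# droplet, ground-truth CSV, and a JSON scene configuration (including the
# seed and RNG name) sufficient to regenerate the scene bit-identically.

#' Write a rendered scene to disk
#'
#' Writes one multi-page TIFF per droplet (`droplet_NN.tif`), the
#' ground-truth table (`ground_truth.csv`), and the scene configuration
#' with seed (`scene.json`). Stacks are rendered droplet-by-droplet if not
#' supplied.
#'
#' @param scene A [synthetic_scene()].
#' @param path Output directory (created if missing).
#' @param stacks Optional pre-rendered result of [render_stack()].
#' @param noiseless Passed to the renderer when `stacks` is `NULL`.
#' @return Invisibly, a character vector of the files written.
#' @export
write_scene <- function(scene, path, stacks = NULL, noiseless = FALSE) {
  stopifnot(inherits(scene, "synthetic_scene"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  gt <- NULL
  for (d in scene$droplets$droplet) {
    st <- if (!is.null(stacks)) stacks$stacks[[sprintf("droplet_%02d", d)]]
          else render_droplet(scene, d, noiseless = noiseless)
    fn <- file.path(path, sprintf("droplet_%02d.tif", d))
    pages <- lapply(seq_len(dim(st$pixels)[3]),
                    function(j) st$pixels[, , j] / 255)
    tiff::writeTIFF(pages, fn, bits.per.sample = 8L, compression = "none")
    files <- c(files, fn)
    if (is.null(stacks))
      gt <- rbind(gt, ground_truth_row(scene, d, latent = st$latent))
  }
  if (!is.null(stacks)) gt <- stacks$ground_truth
  gt_fn <- file.path(path, "ground_truth.csv")
  write.csv(gt, gt_fn, row.names = FALSE)
  cfg_fn <- file.path(path, "scene.json")
  jsonlite::write_json(scene_config(scene), cfg_fn, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(files, gt_fn, cfg_fn))
}

# serializable scene configuration (ground truth excluded: regenerated
# from the seed)
scene_config <- function(scene) {
  list(
    layout = scene$layout[c("n_rows", "n_cols", "spot_diameter", "pitch",
                            "pixels_per_mm")],
    plan = list(concentrations = unique(scene$droplets$concentration),
                droplets_per_concentration =
                  nrow(scene$droplets) /
                  length(unique(scene$droplets$concentration)),
                volume = scene$plan$volume, seed = scene$plan$seed),
    growth = unclass(scene$growth),
    times = list(start = scene$times[1],
                 end = scene$times[length(scene$times)],
                 step = scene$times[2] - scene$times[1]),
    render = scene[c("background_intensity", "oil_intensity",
                     "colony_absorbance", "area_per_biomass", "noise_sd",
                     "illumination_sd", "colony_margin")],
    seed = scene$seed, rng = scene$rng)
}

#' Read a droplet frame stack from a multi-page TIFF
#'
#' @param path TIFF file written by [write_scene()] (8-bit grayscale).
#' @param times Frame timestamps in hours (default `0, 1, 2, ...`).
#' @param droplet_id Droplet id to attach (default parsed from the file
#'   name if it matches `droplet_NN`, else 1).
#' @return A `droplet_stack` with integer pixels in 0-255.
#' @export
read_stack <- function(path, times = NULL, droplet_id = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  pix <- array(NA_integer_, dim = c(H, W, length(pages)))
  for (j in seq_along(pages))
    pix[, , j] <- as.integer(round(pages[[j]] * 255))
  if (is.null(droplet_id)) {
    m <- regmatches(basename(path),
                    regexpr("droplet_([0-9]+)", basename(path)))
    droplet_id <- if (length(m)) as.integer(sub("droplet_", "", m)) else 1L
  }
  if (is.null(times)) times <- seq_along(pages) - 1
  structure(list(pixels = pix, times = times, latent = NULL,
                 droplet_id = droplet_id, layout = NULL, noiseless = NA),
            class = "droplet_stack")
}
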