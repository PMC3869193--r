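# Bright-field rendering of synthetic droplets.
#
# Optical model: the spot (droplet) is drawn at background_intensity times
# the droplet's illumination multiplier; pixels outside the spot show the
# darker oil background. Each colony is a filled disk whose area is
# proportional to its biomass; interior transmission is multiplied by
# exp(-colony_absorbance), so frames darken monotonically as biomass
# accumulates (Beer-Lambert-style attenuation). Colony disks are
# anti-aliased: fractional edge-pixel coverage is rescaled so the summed
# pixel coverage equals the exact disk area, which keeps the mean
# transmission smooth in time even for sub-pixel colonies. Under
# sporulation the colony areas freeze at the population plateau and the
# absorbance ramps down, brightening the droplet again. Gaussian noise is
# added and frames are quantized to 8 bits.

#' Render one droplet's frame stack
#'
#' @param scene A [synthetic_scene()].
#' @param droplet Droplet id (row-major index in the array).
#' @param frames Optional integer indices into `scene$times` to render a
#'   subset of frames (default all).
#' @param noiseless If `TRUE`, omit the additive Gaussian noise (frames
#'   are still quantized to 8 bits).
#' @return A `droplet_stack`: list with `pixels` (integer array
#'   height x width x frames, gray levels 0-255), `times` (hours),
#'   `latent` (the unquantized noise-free mean intensity over the
#'   measurement disk per frame, the generator's ground-truth signal),
#'   `droplet_id`, and `layout`.
#' @export
render_droplet <- function(scene, droplet, frames = NULL, noiseless = FALSE) {
  stopifnot(inherits(scene, "synthetic_scene"))
  n <- nrow(scene$droplets)
  check_number(droplet, "droplet", lower = 1, upper = n, integerish = TRUE)
  if (is.null(frames)) frames <- seq_along(scene$times)
  if (any(frames < 1) || any(frames > length(scene$times)))
    stop_domain("`frames` out of range")
  layout <- scene$layout
  H <- layout$frame_shape[1]; W <- layout$frame_shape[2]
  ctr <- layout$frame_center
  ppmm <- layout$pixels_per_mm
  Rpx <- layout$spot_radius_px

  d2 <- frame_dist2(layout$frame_shape, ctr, ctr)
  in_spot <- d2 <= Rpx^2
  measure_idx <- which(d2 <= (0.9 * Rpx)^2)

  row_d <- scene$droplets[scene$droplets$droplet == droplet, ]
  ill <- row_d$illumination
  base <- matrix(scene$oil_intensity, H, W)
  base[in_spot] <- scene$background_intensity * ill

  sim <- simulate_biomass(row_d$cell_count, row_d$lags[[1]], scene$growth,
                          scene$times)
  times <- scene$times[frames]
  nt <- length(frames)
  centers <- row_d$centers[[1]]
  ncol_d <- row_d$cell_count
  spor <- scene$growth$sporulation
  t_p <- sim$plateau_time
  rf <- scene$growth$rebound_fraction
  delay <- scene$growth$rebound_onset_delay

  # biomass at the plateau (for frozen areas), by linear interpolation
  b_frozen <- NULL
  if (spor && !is.na(t_p) && ncol_d > 0) {
    b_frozen <- apply(sim$biomass, 1, function(bi)
      stats::approx(scene$times, bi, xout = t_p, rule = 2)$y)
  }

  stack <- array(NA_integer_, dim = c(H, W, nt))
  latent <- numeric(nt)
  n_clipped <- 0L
  if (!noiseless) {
    old <- local_rng(derive_seed(scene$seed, "noise", droplet))
    on.exit(restore_rng(old))
  }

  for (j in seq_len(nt)) {
    t <- times[j]
    frame <- base
    if (ncol_d > 0) {
      # sporulation relaxes the attenuation term (1 - transmission) of
      # every colony pixel linearly to (1 - rebound_fraction) of its peak:
      # cells shrink, so their scattering cross-section drops
      s_t <- 1
      if (spor && !is.na(t_p) && t > t_p)
        s_t <- 1 - rf * min(1, (t - t_p) / delay)
      f_t <- exp(-scene$colony_absorbance)
      b_t <- sim$biomass[, frames[j]]
      if (!is.null(b_frozen) && t > t_p) b_t <- b_frozen
      r_px <- sqrt(scene$area_per_biomass * b_t / pi) * ppmm
      for (i in seq_len(ncol_d)) {
        r <- r_px[i]
        if (r <= 0) next
        cr <- ctr + centers[i, 2] * ppmm   # y offset -> row
        cc <- ctr + centers[i, 1] * ppmm   # x offset -> col
        r0 <- floor(cr - r - 1); r1 <- ceiling(cr + r + 1)
        c0 <- floor(cc - r - 1); c1 <- ceiling(cc + r + 1)
        clip_frame <- r0 < 0 || c0 < 0 || r1 > H - 1 || c1 > W - 1
        clip_spot <- sqrt((cr - ctr)^2 + (cc - ctr)^2) + r > Rpx
        if (clip_frame || clip_spot) n_clipped <- n_clipped + 1L
        rr <- max(0, r0):min(H - 1, r1)
        cols <- max(0, c0):min(W - 1, c1)
        dd <- sqrt(outer((rr - cr)^2, (cols - cc)^2, "+"))
        raw <- pmin(1, pmax(0, r - dd + 0.71))
        sr <- sum(raw)
        if (sr <= 0) next
        w <- pmin(1, raw * (pi * r^2 / sr))
        w[!in_spot[rr + 1, cols + 1, drop = FALSE]] <- 0  # confine to droplet
        frame[rr + 1, cols + 1] <- frame[rr + 1, cols + 1] *
          (1 - w * s_t * (1 - f_t))
      }
    }
    latent[j] <- mean(frame[measure_idx])
    if (!noiseless) frame <- frame + rnorm(H * W, 0, scene$noise_sd)
    stack[, , j] <- as.integer(pmin(255, pmax(0, round(frame))))
  }
  if (n_clipped > 0L)
    warning(sprintf("droplet %d: %d colony disk(s) clipped at the droplet/frame boundary",
                    droplet, n_clipped), call. = FALSE)
  structure(list(pixels = stack, times = times, latent = latent,
                 droplet_id = droplet, layout = layout,
                 noiseless = noiseless),
            class = "droplet_stack")
}

#' @export
print.droplet_stack <- function(x, ...) {
  cat(sprintf("<droplet_stack> droplet %d: %d x %d px, %d frames (%g..%g h)\n",
              x$droplet_id, dim(x$pixels)[1], dim(x$pixels)[2],
              dim(x$pixels)[3], min(x$times), max(x$times)))
  invisible(x)
}

#' Render a synthetic scene to frame stacks plus ground truth
#'
#' Renders one stack per droplet (one field of view per droplet) and
#' returns them with the generator's ground-truth table. For the default
#' full-size scene the stacks are large; [simulate_experiment()] renders
#' droplet-by-droplet and keeps only the extracted series.
#'
#' @inheritParams render_droplet
#' @param droplets Droplet ids to render (default all).
#' @return A list with `stacks` (list of `droplet_stack`) and
#'   `ground_truth` (tibble, see [simulate_experiment()]).
#' @export
render_stack <- function(scene, droplets = NULL, frames = NULL,
                         noiseless = FALSE) {
  stopifnot(inherits(scene, "synthetic_scene"))
  if (is.null(droplets)) droplets <- scene$droplets$droplet
  stacks <- lapply(droplets, function(d)
    render_droplet(scene, d, frames = frames, noiseless = noiseless))
  names(stacks) <- sprintf("droplet_%02d", droplets)
  all_frames <- is.null(frames) || identical(frames, seq_along(scene$times))
  gt <- do.call(rbind, lapply(seq_along(droplets), function(i)
    ground_truth_row(scene, droplets[i],
                     latent = if (all_frames) stacks[[i]]$latent else NULL)))
  list(stacks = stacks, ground_truth = gt)
}

# one ground-truth row for a droplet; latent (full-length noise-free mean
# series) is needed for the true threshold time, else that column is NA
ground_truth_row <- function(scene, droplet, latent = NULL) {
  row_d <- scene$droplets[scene$droplets$droplet == droplet, ]
  sim <- simulate_biomass(row_d$cell_count, row_d$lags[[1]], scene$growth,
                          scene$times)
  thr <- NA_real_
  if (!is.null(latent))
    thr <- threshold_growth_time(latent / latent[1], scene$times)
  tibble::tibble(
    droplet = row_d$droplet, row = row_d$row, col = row_d$col,
    concentration = row_d$concentration,
    cells_per_droplet = row_d$cells_per_droplet,
    cell_count = row_d$cell_count,
    illumination = row_d$illumination,
    lags = paste(signif(row_d$lags[[1]], 8), collapse = ";"),
    centers = paste(apply(row_d$centers[[1]], 1,
                          function(p) sprintf("%.6f,%.6f", p[1], p[2])),
                    collapse = ";"),
    plateau_time_h = sim$plateau_time,
    merge_time_h = merge_time(scene, row_d, sim),
    true_threshold_time_h = thr)
}

# first frame time at which any two colony disks overlap (NA if never, or
# if the droplet is denser than the distinct-microcolony regime)
merge_time <- function(scene, row_d, sim) {
  n <- row_d$cell_count
  if (n < 2L || n > 50L) return(NA_real_)
  cen <- row_d$centers[[1]]
  D <- as.matrix(stats::dist(cen))
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  a <- scene$area_per_biomass
  for (j in seq_along(scene$times)) {
    r <- sqrt(a * sim$biomass[, j] / pi)
    if (any(r[pairs[, 1]] + r[pairs[, 2]] > D[pairs])) return(scene$times[j])
  }
  NA_real_
}

#' Simulate a full experiment: render, extract, and keep the series
#'
#' Renders each droplet's stack in turn, extracts its transmission time
#' series over the measurement disk, and discards the pixels, so that a
#' full-size scene can be processed in bounded memory.
#'
#' @inheritParams render_droplet
#' @param shrink_factor Fraction of the spot radius used for the
#'   measurement disk (default 0.9, excluding the rim).
#' @return A list with `series` (tibble: `droplet_id`, `time_h`,
#'   `raw_mean_intensity`, `pixel_count`) and `ground_truth` (tibble with
#'   per-droplet cell counts, lags, colony centers, illumination, plateau
#'   and merge times, and the true threshold-crossing time of the
#'   noise-free latent signal).
#' @examples
#' \donttest{
#' pl <- plan_experiment(moca_layout(1, 2), c(10, 1), 1, seed = 1)
#' sim <- simulate_experiment(synthetic_scene(pl, times = seq(0, 4, 0.5)))
#' head(sim$series)
#' }
#' @export
simulate_experiment <- function(scene, noiseless = FALSE,
                                shrink_factor = 0.9) {
  stopifnot(inherits(scene, "synthetic_scene"))
  series <- vector("list", nrow(scene$droplets))
  gt <- vector("list", nrow(scene$droplets))
  for (d in scene$droplets$droplet) {
    st <- render_droplet(scene, d, noiseless = noiseless)
    roi <- locate_droplets(st, scene$layout, mode = "grid",
                           droplet_id = d, shrink_factor = shrink_factor)
    series[[d]] <- extract_transmission(st, roi)
    gt[[d]] <- ground_truth_row(scene, d, latent = st$latent)
  }
  list(series = do.call(rbind, series), ground_truth = do.call(rbind, gt))
}

#' Pre-merge microcolony counting checkpoint
#'
#' Finds the first frame at which every colony in a droplet has reached
#' `factor` times the counting area floor while no two colonies have yet
#' merged — the frame at which distinct microcolonies are best counted
#' (late enough to segment, early enough that the droplet is still mostly
#' bright and colonies are disjoint).
#'
#' @inheritParams render_droplet
#' @param min_area_px Counting area floor in pixels (default 20, matching
#'   [count_microcolonies()]).
#' @param factor Required multiple of the floor (default 10).
#' @return Frame index into `scene$times`, or `NA` if no such frame exists
#'   (empty droplet, colonies merge too early, or they never reach size).
#' @export
microcolony_checkpoint <- function(scene, droplet, min_area_px = 20,
                                   factor = 10) {
  stopifnot(inherits(scene, "synthetic_scene"))
  row_d <- scene$droplets[scene$droplets$droplet == droplet, ]
  n <- row_d$cell_count
  if (n == 0L) return(NA_integer_)
  sim <- simulate_biomass(n, row_d$lags[[1]], scene$growth, scene$times)
  px_area <- scene$area_per_biomass * scene$layout$pixels_per_mm^2  # px^2/biomass
  big_enough <- apply(sim$biomass * px_area >= factor * min_area_px, 2, all)
  mt <- merge_time(scene, row_d, sim)
  ok <- big_enough & (is.na(mt) | scene$times < mt)
  if (!any(ok)) return(NA_integer_)
  min(which(ok))
}
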