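# Experiment planning and fully-specified synthetic scenes.
#
# A plan assigns each droplet of the array a loading-concentration group
# (row-major, consecutive droplets per group) and draws its Poisson cell
# count. A scene adds the latent growth process (per-cell lags, colony
# center positions inside the spot) and the rendering parameters
# (intensities, attenuation, noise, per-droplet illumination).

#' Plan a droplet-array experiment
#'
#' Assigns each droplet a loading concentration (groups fill the array in
#' row-major order) and draws its cell count from the Poisson occupancy
#' model at \eqn{\lambda =} concentration x volume.
#'
#' @param layout A [moca_layout()].
#' @param concentrations Loading concentrations in cells/\eqn{\mu}l, one
#'   per group (e.g. `c(1000, 100, 10, 1)`).
#' @param droplets_per_concentration Droplets per group; the product with
#'   `length(concentrations)` must equal the layout capacity.
#' @param volume Droplet volume in \eqn{\mu}l (default 1).
#' @param seed Integer seed for the Poisson draws.
#' @param cell_counts Optional integer vector overriding the sampled
#'   counts (one per droplet), for ground-truth-controlled scenes.
#' @return An object of class `moca_plan`: layout plus a tibble of
#'   droplets with columns `droplet`, `row`, `col`, `concentration`,
#'   `cells_per_droplet` (the nominal \eqn{\lambda}) and `cell_count`.
#' @examples
#' plan_experiment(moca_layout(), c(1000, 100, 10, 1), 6, seed = 1)
#' @export
plan_experiment <- function(layout, concentrations, droplets_per_concentration,
                            volume = 1, seed = 1, cell_counts = NULL) {
  stopifnot(inherits(layout, "moca_layout"))
  if (!is.numeric(concentrations) || length(concentrations) < 1L ||
      any(concentrations < 0))
    stop_domain("`concentrations` must be non-negative cells/ul values")
  check_number(droplets_per_concentration, "droplets_per_concentration",
               lower = 1, integerish = TRUE)
  check_number(volume, "volume", lower = 0, strict_lower = TRUE)
  check_number(seed, "seed", integerish = TRUE)
  n <- layout$n_droplets
  if (length(concentrations) * droplets_per_concentration != n)
    stop_domain(sprintf(
      "capacity mismatch: %d group(s) x %d droplet(s) != %d array positions",
      length(concentrations), droplets_per_concentration, n))
  pos <- droplet_positions(layout)
  pos$concentration <- rep(concentrations, each = droplets_per_concentration)
  pos$cells_per_droplet <- pos$concentration * volume
  if (is.null(cell_counts)) {
    counts <- integer(0)
    for (g in seq_along(concentrations)) {
      model <- occupancy_model(concentration = concentrations[g],
                               volume = volume)
      counts <- c(counts, sample_counts(model, droplets_per_concentration,
                                        seed = derive_seed(seed, "counts", g)))
    }
  } else {
    if (length(cell_counts) != n || any(cell_counts < 0) ||
        any(abs(cell_counts - round(cell_counts)) > 1e-8))
      stop_domain("`cell_counts` must be one non-negative integer per droplet")
    counts <- as.integer(round(cell_counts))
  }
  pos$cell_count <- as.integer(counts)
  structure(list(layout = layout, volume = volume, seed = as.integer(seed),
                 droplets = pos),
            class = "moca_plan")
}

#' @export
print.moca_plan <- function(x, ...) {
  cat(sprintf("<moca_plan> %d droplets, groups: %s cells/ul, seed %d\n",
              nrow(x$droplets),
              paste(unique(x$droplets$concentration), collapse = ", "),
              x$seed))
  invisible(x)
}

#' Fully-specified synthetic scene
#'
#' Extends a plan with the latent growth process and rendering parameters,
#' drawing per-cell lags and colony center positions for every droplet.
#' Colony centers are placed inside a disk of `colony_margin` times the
#' spot radius; for droplets with at most 50 cells, placement targets a
#' minimum pairwise separation so that colonies remain spatially distinct
#' until the droplet approaches saturation (mirroring the microcolony
#' pattern seen on droplet arrays); denser droplets are placed uniformly.
#'
#' @param plan A [plan_experiment()] result.
#' @param growth A [growth_params()] object shared by all droplets.
#' @param times Frame timestamps in hours, strictly increasing
#'   (default every 0.5 h for 72 h, i.e. 145 frames).
#' @param background_intensity Mean gray level of an empty droplet under
#'   nominal illumination, 8-bit scale (default 200).
#' @param oil_intensity Gray level outside the spot (default 120).
#' @param colony_absorbance Optical absorbance of colony interior; the
#'   transmission factor inside a colony is `exp(-colony_absorbance)`
#'   (default 2.3, i.e. ~10% interior transmission).
#' @param area_per_biomass Colony footprint per biomass unit in
#'   mm\eqn{^2} (default 5e-6, a ~5 um^2 cell footprint; colony area grows
#'   linearly with biomass, a monolayer-like expansion).
#' @param noise_sd Additive Gaussian frame noise sd in gray levels
#'   (default 2).
#' @param illumination_sd Sd of the per-droplet illumination multiplier
#'   around 1 (default 0.05, clipped to \[0.8, 1.2\]).
#' @param colony_margin Colony centers are confined to this fraction of
#'   the spot radius (default 0.8, avoiding rim artifacts).
#' @param seed Integer seed; defaults to the plan's seed.
#' @return An object of class `synthetic_scene`.
#' @examples
#' sc <- synthetic_scene(plan_experiment(moca_layout(1, 2), c(10, 1), 1, seed = 1))
#' sc
#' @export
synthetic_scene <- function(plan,
                            growth = growth_params(),
                            times = seq(0, 72, by = 0.5),
                            background_intensity = 200,
                            oil_intensity = 120,
                            colony_absorbance = 2.3,
                            area_per_biomass = 5e-6,
                            noise_sd = 2,
                            illumination_sd = 0.05,
                            colony_margin = 0.8,
                            seed = NULL) {
  stopifnot(inherits(plan, "moca_plan"), inherits(growth, "growth_params"))
  if (!is.numeric(times) || length(times) < 2L || any(diff(times) <= 0) ||
      times[1] < 0)
    stop_domain("`times` must be a strictly increasing vector of hours")
  check_number(background_intensity, "background_intensity", lower = 1,
               upper = 255)
  check_number(oil_intensity, "oil_intensity", lower = 0, upper = 255)
  check_number(colony_absorbance, "colony_absorbance", lower = 0)
  check_number(area_per_biomass, "area_per_biomass", lower = 0,
               strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(illumination_sd, "illumination_sd", lower = 0)
  check_number(colony_margin, "colony_margin", lower = 0, upper = 1)
  if (is.null(seed)) seed <- plan$seed
  check_number(seed, "seed", integerish = TRUE)

  layout <- plan$layout
  droplets <- plan$droplets
  n <- nrow(droplets)

  # per-droplet illumination multipliers
  old <- local_rng(derive_seed(seed, "illumination"))
  illum <- pmin(1.2, pmax(0.8, 1 + rnorm(n, 0, illumination_sd)))
  restore_rng(old)
  droplets$illumination <- illum

  placement_radius <- colony_margin * layout$spot_radius
  lags <- vector("list", n)
  centers <- vector("list", n)
  for (d in seq_len(n)) {
    k <- droplets$cell_count[d]
    old <- local_rng(derive_seed(seed, "lags", d))
    lags[[d]] <- sample_lags(k, growth$lag_mean, growth$lag_sd)
    restore_rng(old)
    centers[[d]] <- place_colonies(
      k, placement_radius,
      d_min = colony_separation_target(k, growth$carrying_capacity,
                                       area_per_biomass, placement_radius,
                                       lags = lags[[d]],
                                       mu = growth$specific_growth_rate),
      seed = derive_seed(seed, "centers", d))
  }
  droplets$lags <- lags
  droplets$centers <- centers

  structure(
    list(layout = layout, plan = plan, growth = growth, times = times,
         background_intensity = background_intensity,
         oil_intensity = oil_intensity,
         colony_absorbance = colony_absorbance,
         area_per_biomass = area_per_biomass,
         noise_sd = noise_sd, illumination_sd = illumination_sd,
         colony_margin = colony_margin,
         seed = as.integer(seed), rng = "Mersenne-Twister",
         droplets = droplets),
    class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "<synthetic_scene> %d droplets, %d frames (%g..%g h), noise sd %g, seed %d\n",
    nrow(x$droplets), length(x$times), min(x$times), max(x$times),
    x$noise_sd, x$seed))
  invisible(x)
}

# Minimum pairwise colony-center separation (mm) that keeps every colony
# pair disjoint while the droplet total biomass is below half the carrying
# capacity. Once all colonies are active their biomass ratios are fixed at
# exp(-mu * lag) weights (the shared logistic factor cancels), so the
# worst pair at total K/2 has radius sum
#   sqrt(w1 K a / (2 pi)) + sqrt(w2 K a / (2 pi))
# for the two largest shares w1, w2. A 10% safety factor absorbs
# pixelation; the target is capped at 95% of the ring-packing bound for n
# points, and dropped for dense droplets (n > 50) where distinct
# microcolonies are not expected anyway.
colony_separation_target <- function(n, carrying_capacity, area_per_biomass,
                                     placement_radius, lags = rep(0, n),
                                     mu = 1) {
  if (n < 2L || n > 50L || !is.finite(carrying_capacity)) return(0)
  w <- exp(-mu * (lags - min(lags)))
  w <- sort(w / sum(w), decreasing = TRUE)
  half_area <- carrying_capacity * area_per_biomass / 2
  want <- 1.1 * (sqrt(w[1] * half_area / pi) + sqrt(w[2] * half_area / pi))
  cap <- 0.95 * 2 * placement_radius * sin(pi / n)
  min(want, cap)
}

# Colony centers in a disk of the given radius (mm, offsets from the spot
# center), targeting minimum pairwise separation d_min: rejection sampling
# of uniform configurations first, then a greedy best-candidate (maximin)
# fallback. Returns an n x 2 matrix (x, y).
place_colonies <- function(n, radius, d_min = 0, seed = 1) {
  if (n == 0L) return(matrix(numeric(0), 0, 2))
  old <- local_rng(seed)
  on.exit(restore_rng(old))
  runif_disk <- function(m) {
    r <- radius * sqrt(runif(m)); th <- 2 * pi * runif(m)
    cbind(r * cos(th), r * sin(th))
  }
  if (n == 1L || d_min <= 0) return(runif_disk(n))
  min_sep <- function(p) min(stats::dist(p))
  for (try in seq_len(200L)) {
    p <- runif_disk(n)
    if (min_sep(p) >= d_min) return(p)
  }
  # greedy maximin: keep the candidate farthest from the placed points
  p <- runif_disk(1)
  for (i in 2:n) {
    cand <- runif_disk(64L)
    d2 <- apply(cand, 1, function(q) min((p[, 1] - q[1])^2 + (p[, 2] - q[2])^2))
    p <- rbind(p, cand[which.max(d2), ])
  }
  if (min_sep(p) >= d_min) return(p)
  # deterministic fallback: a randomly rotated ring at the smallest radius
  # achieving the separation, with angular jitter inside the spare margin
  rho <- min(0.98 * radius, max(d_min / (2 * sin(pi / n)), 0.85 * radius))
  margin <- max(0, 2 * rho * sin(pi / n) - d_min)
  th <- 2 * pi * runif(1) + 2 * pi * (seq_len(n) - 1) / n +
    runif(n, -1, 1) * margin / (4 * rho)
  cbind(rho * cos(th), rho * sin(th))
}
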