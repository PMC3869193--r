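# Latent per-droplet growth process: each founding cell seeds one
# microcolony; colonies grow logistically against a shared droplet-level
# carrying capacity after a per-cell lag drawn from a lognormal
# distribution. Optional sporulation mode: once the droplet population
# plateaus, colony areas freeze and their optical attenuation relaxes,
# so the droplet brightens again (the post-peak rebound seen for
# spore-forming bacteria such as B. subtilis).

#' Growth-process parameters for synthetic droplets
#'
#' @param specific_growth_rate Exponential-phase specific growth rate
#'   \eqn{\mu} in 1/h (default 0.7, a ~1 h doubling time).
#' @param lag_mean,lag_sd Mean and standard deviation (hours) of the
#'   per-cell lognormal lag before growth starts (defaults 2 and 1).
#'   `lag_mean = 0` means no lag; `lag_sd = 0` a deterministic lag.
#' @param initial_biomass_per_cell Biomass units per founding cell
#'   (default 1; biomass is in arbitrary cell-equivalent units).
#' @param carrying_capacity Total droplet biomass at saturation, shared by
#'   all colonies (default 1e6, i.e. ~1e9 cells/ml at saturation in a 1-ul
#'   droplet; may be `Inf` for pure exponential growth).
#' @param sporulation If `TRUE`, after the total biomass first reaches 99%
#'   of capacity, colony areas are held fixed and the optical attenuation
#'   ramps down, producing a transmission rebound.
#' @param rebound_onset_delay Hours over which the attenuation relaxes to
#'   its final level after the plateau (default 6).
#' @param rebound_fraction Fraction of the peak attenuation lost to
#'   sporulation, in \[0, 1\] (default 0.3).
#' @return An object of class `growth_params`.
#' @examples
#' growth_params()
#' growth_params(sporulation = TRUE, rebound_fraction = 0.3)
#' @export
growth_params <- function(specific_growth_rate = 0.7,
                          lag_mean = 2, lag_sd = 1,
                          initial_biomass_per_cell = 1,
                          carrying_capacity = 1e6,
                          sporulation = FALSE,
                          rebound_onset_delay = 6,
                          rebound_fraction = 0.3) {
  check_number(specific_growth_rate, "specific_growth_rate",
               lower = 0, strict_lower = TRUE)
  check_number(lag_mean, "lag_mean", lower = 0)
  check_number(lag_sd, "lag_sd", lower = 0)
  check_number(initial_biomass_per_cell, "initial_biomass_per_cell",
               lower = 0, strict_lower = TRUE)
  if (!(is.numeric(carrying_capacity) && length(carrying_capacity) == 1L &&
        carrying_capacity > initial_biomass_per_cell))
    stop_domain("`carrying_capacity` must exceed `initial_biomass_per_cell`")
  stopifnot(is.logical(sporulation), length(sporulation) == 1L)
  check_number(rebound_onset_delay, "rebound_onset_delay",
               lower = 0, strict_lower = TRUE)
  check_number(rebound_fraction, "rebound_fraction", lower = 0, upper = 1)
  structure(
    list(specific_growth_rate = specific_growth_rate,
         lag_mean = lag_mean, lag_sd = lag_sd,
         initial_biomass_per_cell = initial_biomass_per_cell,
         carrying_capacity = carrying_capacity,
         sporulation = sporulation,
         rebound_onset_delay = rebound_onset_delay,
         rebound_fraction = rebound_fraction),
    class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat(sprintf(
    "<growth_params> mu = %g /h, lag %g +/- %g h, K = %g, sporulation: %s\n",
    x$specific_growth_rate, x$lag_mean, x$lag_sd, x$carrying_capacity,
    if (x$sporulation) sprintf("rebound %.0f%% over %g h",
                               100 * x$rebound_fraction,
                               x$rebound_onset_delay) else "off"))
  invisible(x)
}

# draw per-cell lags (hours) from the lognormal parametrized by its own
# mean and sd; degenerate cases handled explicitly
sample_lags <- function(n, lag_mean, lag_sd) {
  if (n == 0L) return(numeric(0))
  if (lag_mean == 0) return(rep(0, n))
  if (lag_sd == 0) return(rep(lag_mean, n))
  sdlog <- sqrt(log(1 + (lag_sd / lag_mean)^2))
  meanlog <- log(lag_mean) - sdlog^2 / 2
  rlnorm(n, meanlog, sdlog)
}
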