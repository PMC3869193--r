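# Poisson occupancy statistics for droplet cell loading.
#
# When a cell suspension at concentration C (cells/ul) is dispensed into
# droplets of volume V (ul), the number of cells trapped in a droplet is
# Poisson with mean lambda = C * V. These functions cover the forward
# calculation (occupancy fractions at a given loading), the inverse design
# problem (what lambda yields a desired single-cell fraction), and
# reproducible sampling of per-droplet counts.

#' Poisson occupancy model for droplet loading
#'
#' Constructs the occupancy model describing how many cells land in each
#' droplet. The mean occupancy \eqn{\lambda} (cells per droplet) can be
#' given directly, or derived from a loading concentration and droplet
#' volume via [lambda_from_loading()].
#'
#' @param mean_occupancy Mean number of cells per droplet (\eqn{\lambda});
#'   non-negative. Mutually exclusive with `concentration`/`volume`.
#' @param concentration Loading concentration in cells/\eqn{\mu}l.
#' @param volume Droplet volume in \eqn{\mu}l (default 1).
#' @return An object of class `occupancy_model` with fields
#'   `mean_occupancy`, and, when derived, `concentration` and `volume`.
#' @examples
#' occupancy_model(1)                       # one cell per droplet on average
#' occupancy_model(concentration = 0.25)    # the marine-sample dilution
#' @export
occupancy_model <- function(mean_occupancy = NULL, concentration = NULL,
                            volume = 1) {
  if (is.null(mean_occupancy)) {
    if (is.null(concentration))
      stop_domain("give either `mean_occupancy` or `concentration`")
    mean_occupancy <- lambda_from_loading(concentration, volume)
  } else {
    check_number(mean_occupancy, "mean_occupancy", lower = 0)
    if (!is.null(concentration))
      stop_domain("give `mean_occupancy` or `concentration`, not both")
  }
  structure(
    list(mean_occupancy = as.numeric(mean_occupancy),
         concentration = if (is.null(concentration)) NULL else as.numeric(concentration),
         volume = as.numeric(volume)),
    class = "occupancy_model")
}

#' @export
print.occupancy_model <- function(x, ...) {
  cat(sprintf("<occupancy_model> lambda = %g cells/droplet\n", x$mean_occupancy))
  if (!is.null(x$concentration))
    cat(sprintf("  loading: %g cells/ul x %g ul\n", x$concentration, x$volume))
  invisible(x)
}

as_lambda <- function(model) {
  if (inherits(model, "occupancy_model")) return(model$mean_occupancy)
  check_number(model, "model", lower = 0)
}

#' Mean droplet occupancy from loading concentration and volume
#'
#' The mean number of cells per droplet is the product of the loading
#' concentration and the droplet volume: 1 cell/\eqn{\mu}l loaded into
#' 1-\eqn{\mu}l droplets gives an average occupancy of one cell per droplet.
#'
#' @param concentration Cell concentration in cells/\eqn{\mu}l; >= 0.
#' @param volume Droplet volume in \eqn{\mu}l; > 0.
#' @return Mean occupancy \eqn{\lambda} in cells per droplet.
#' @examples
#' lambda_from_loading(1, 1)     # 1
#' lambda_from_loading(0.25, 1)  # the single-cell-biased marine loading
#' @export
lambda_from_loading <- function(concentration, volume) {
  check_number(concentration, "concentration", lower = 0)
  check_number(volume, "volume", lower = 0, strict_lower = TRUE)
  concentration * volume
}

#' Probability that a droplet holds exactly k cells
#'
#' Poisson probability mass \eqn{e^{-\lambda}\lambda^k/k!}, evaluated in
#' log space so that extreme loadings (e.g. \eqn{\lambda = 1000}) do not
#' overflow. At \eqn{\lambda = 1} about 37% of droplets are empty and 37%,
#' 18%, 6% and 1.5% hold one to four cells.
#'
#' @param k Non-negative integer cell count (vectorized).
#' @param model An [occupancy_model()] or a bare \eqn{\lambda}.
#' @return Probability (vector along `k`).
#' @examples
#' occupancy_pmf(0:4, occupancy_model(1))
#' occupancy_pmf(1, 0.25)  # single-cell fraction at the marine dilution
#' @export
occupancy_pmf <- function(k, model) {
  lambda <- as_lambda(model)
  if (length(k) == 0L || !is.numeric(k) || anyNA(k))
    stop_domain("`k` must be numeric and non-missing")
  if (any(k < 0) || any(abs(k - round(k)) > 1e-8))
    stop_domain("`k` must consist of non-negative integers")
  dpois(round(k), lambda)
}

#' Probability that a droplet holds two or more cells
#'
#' The multicell tail \eqn{P(K \ge 2) = 1 - e^{-\lambda}(1 + \lambda)},
#' the quantity a dilution design seeks to keep small so that grown
#' colonies are clonal. At \eqn{\lambda = 0.25} it is 2.65% (with
#' \eqn{P(K = 2)} alone 2.43%); both are loosely "around 2%".
#'
#' @inheritParams occupancy_pmf
#' @return Probability of multicell occupancy.
#' @examples
#' multicell_probability(0.25)
#' @export
multicell_probability <- function(model) {
  lambda <- as_lambda(model)
  ppois(1, lambda, lower.tail = FALSE)
}

#' Probability that a droplet holds exactly one cell
#'
#' Convenience wrapper for `occupancy_pmf(1, model)`:
#' \eqn{P(K = 1) = \lambda e^{-\lambda}}, maximized (at about 36.8%) by
#' \eqn{\lambda = 1}.
#'
#' @inheritParams occupancy_pmf
#' @return Probability of single-cell occupancy.
#' @export
single_cell_probability <- function(model) {
  occupancy_pmf(1, model)
}

#' Solve for the mean occupancy giving a target single-cell fraction
#'
#' Inverts \eqn{\lambda e^{-\lambda} = p}. The map is unimodal with
#' maximum \eqn{e^{-1}} at \eqn{\lambda = 1}, so any attainable fraction
#' below the maximum has two roots: a dilute one (`branch = "low"`,
#' \eqn{\lambda < 1}, fewer multicell droplets, more empties) and a
#' concentrated one (`branch = "high"`). Designing a dilution for a 20%
#' single-cell fraction on the low branch gives \eqn{\lambda \approx 0.25}.
#'
#' Bracketed bisection to an interval width of 1e-12, giving
#' \eqn{|\lambda e^{-\lambda} - p| \le 10^{-10}}.
#'
#' @param target Desired \eqn{P(K = 1)}, in \eqn{(0, e^{-1}]}.
#' @param branch `"low"` for the root in \eqn{(0, 1]}, `"high"` for the
#'   root in \eqn{[1, \infty)}.
#' @return Mean occupancy \eqn{\lambda} (cells per droplet).
#' @examples
#' solve_lambda_for_single_fraction(0.20)           # ~0.25 cells/droplet
#' solve_lambda_for_single_fraction(exp(-1))        # 1, the maximizer
#' @export
solve_lambda_for_single_fraction <- function(target, branch = c("low", "high")) {
  branch <- match.arg(branch)
  check_number(target, "target", lower = 0, strict_lower = TRUE)
  pmax1 <- exp(-1)
  if (target > pmax1 + 1e-15)
    stop_domain(sprintf(
      "single-cell fraction %.6g is infeasible: maximum is e^-1 = %.6g at lambda = 1",
      target, pmax1))
  if (target >= pmax1) return(1)
  f <- function(lambda) lambda * exp(-lambda) - target
  if (branch == "low") {
    lo <- 0; hi <- 1
  } else {
    lo <- 1; hi <- 2
    while (f(hi) > 0) hi <- hi * 2   # f -> -target < 0 as lambda -> Inf
  }
  # plain bisection: f(lo) <= 0 <= f(hi) on low branch (f(0) = -target),
  # f(lo) >= 0 >= f(hi) on high branch
  for (i in seq_len(200L)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    rising <- branch == "low"
    if ((fm < 0) == rising) lo <- mid else hi <- mid
    if (hi - lo < 1e-12) break
  }
  (lo + hi) / 2
}

#' Sample per-droplet cell counts
#'
#' Independent Poisson draws of the number of cells encapsulated in each
#' droplet, reproducible for a fixed seed (Mersenne-Twister; the generator
#' name is recorded in pipeline manifests).
#'
#' @inheritParams occupancy_pmf
#' @param n_droplets Number of droplets to draw; >= 1.
#' @param seed Integer seed.
#' @return Integer vector of length `n_droplets`.
#' @examples
#' sample_counts(occupancy_model(0.25), 36, seed = 1)
#' @export
sample_counts <- function(model, n_droplets, seed) {
  lambda <- as_lambda(model)
  check_number(n_droplets, "n_droplets", lower = 1, integerish = TRUE)
  check_number(seed, "seed", integerish = TRUE)
  old <- local_rng(seed)
  on.exit(restore_rng(old))
  rpois(n_droplets, lambda)
}

# save/seed/restore the global RNG state
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Tabulate the occupancy distribution
#'
#' @inheritParams occupancy_pmf
#' @param max_k Largest count to tabulate; if `NULL`, chosen adaptively so
#'   the omitted tail mass is below 1e-9.
#' @return A tibble with columns `k`, `probability`, `percent`.
#' @examples
#' occupancy_table(occupancy_model(1), max_k = 4)
#' @export
occupancy_table <- function(model, max_k = NULL) {
  lambda <- as_lambda(model)
  if (is.null(max_k)) {
    max_k <- if (lambda == 0) 0L else
      as.integer(stats::qpois(1e-9, lambda, lower.tail = FALSE)) + 1L
  }
  check_number(max_k, "max_k", lower = 0, integerish = TRUE)
  k <- 0:max_k
  p <- occupancy_pmf(k, lambda)
  tibble::tibble(k = k, probability = p, percent = 100 * p)
}
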