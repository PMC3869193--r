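# Shared fixtures, built in code. Small-scale layouts keep unit tests
# fast; the full-resolution reference scene used by the acceptance tests
# is simulated once and memoized.

# a coarse layout: same spot geometry, fewer pixels
small_layout <- function(n_rows = 1, n_cols = 2, pixels_per_mm = 40) {
  moca_layout(n_rows, n_cols, pixels_per_mm = pixels_per_mm)
}

# single-droplet scene with fixed count and deterministic-ish growth
quick_scene <- function(cell_counts, concentrations = NULL,
                        layout = small_layout(1, length(cell_counts)),
                        growth = growth_params(),
                        times = seq(0, 24, 0.5), noise_sd = 2, seed = 1, ...) {
  if (is.null(concentrations)) concentrations <- cell_counts
  pl <- plan_experiment(layout, concentrations, 1, seed = seed,
                        cell_counts = cell_counts)
  synthetic_scene(pl, growth = growth, times = times, noise_sd = noise_sd,
                  seed = seed, ...)
}

# the reference experiment: default 4 x 6 array, four concentrations,
# six droplets each, full resolution and horizon; simulated once
.default_sim_cache <- new.env(parent = emptyenv())
default_scene <- function(seed = 101) {
  pl <- plan_experiment(moca_layout(), c(1000, 100, 10, 1), 6, seed = seed)
  synthetic_scene(pl)
}
default_sim <- function(seed = 101) {
  key <- as.character(seed)
  if (is.null(.default_sim_cache[[key]])) {
    sim <- suppressWarnings(simulate_experiment(default_scene(seed)))
    .default_sim_cache[[key]] <- sim
  }
  .default_sim_cache[[key]]
}

# independent flood-fill component counter (8-connectivity), used as an
# oracle against label_components
count_components_bfs <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  n <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (!mask[i, j] || seen[i, j]) next
    n <- n + 1L
    queue <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        a <- p[1] + di; b <- p[2] + dj
        if (a >= 1 && a <= H && b >= 1 && b <= W &&
            mask[a, b] && !seen[a, b]) {
          seen[a, b] <- TRUE
          queue[[length(queue) + 1L]] <- c(a, b)
        }
      }
    }
  }
  n
}
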