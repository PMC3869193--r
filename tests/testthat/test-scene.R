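# Experiment planning and scene construction: group assignment, capacity
# checks, occupancy statistics of plans, colony placement.

test_that("plans assign groups row-major and draw Poisson counts", {
  pl <- plan_experiment(moca_layout(), c(1000, 100, 10, 1), 6, seed = 1)
  expect_equal(nrow(pl$droplets), 24L)
  expect_equal(pl$droplets$concentration, rep(c(1000, 100, 10, 1), each = 6))
  # groups fill consecutive row-major positions: first six droplets = row 1
  expect_equal(pl$droplets$row[pl$droplets$concentration == 1000],
               rep(1L, 6))
  # counts delegate to sample_counts with a derived per-group seed
  expect_equal(pl$droplets$cell_count[1:6],
               sample_counts(occupancy_model(1000), 6,
                             seed = mocar:::derive_seed(1, "counts", 1)))
})

test_that("capacity mismatches and bad counts are configuration errors", {
  expect_error(plan_experiment(moca_layout(), c(10, 1), 6, seed = 1),
               "capacity mismatch")
  expect_error(plan_experiment(moca_layout(1, 2), c(10, 1), 1, seed = 1,
                               cell_counts = c(1, -2)),
               "non-negative")
})

test_that("zero concentration loads nothing", {
  pl <- plan_experiment(moca_layout(), 0, 24, seed = 5)
  expect_true(all(pl$droplets$cell_count == 0L))
})

test_that("plans at the marine dilution average ~7 single-cell droplets of 36", {
  # E[singles] = 36 * P(K = 1) at lambda = 0.25, i.e. 36 * 0.1947 = 7.01
  model <- occupancy_model(0.25)
  singles <- vapply(seq_len(1e4), function(r)
    sum(sample_counts(model, 36, seed = r) == 1L), 0)
  p1 <- occupancy_pmf(1, model)
  se <- sqrt(36 * p1 * (1 - p1) / 1e4)
  expect_lt(abs(mean(singles) - 36 * p1), 3 * se)
})

test_that("scenes are deterministic given plan and seed", {
  sc1 <- quick_scene(c(3, 2), seed = 9)
  sc2 <- quick_scene(c(3, 2), seed = 9)
  expect_identical(sc1$droplets$lags, sc2$droplets$lags)
  expect_identical(sc1$droplets$centers, sc2$droplets$centers)
  expect_identical(sc1$droplets$illumination, sc2$droplets$illumination)
})

test_that("colony centers stay inside the placement disk", {
  for (seed in 1:5) {
    sc <- quick_scene(c(6, 12), seed = seed)
    r_place <- sc$colony_margin * sc$layout$spot_radius
    for (cen in sc$droplets$centers) {
      if (nrow(cen) == 0) next
      expect_true(all(sqrt(rowSums(cen^2)) <= r_place + 1e-9))
    }
  }
})

test_that("colonies stay disjoint until the droplet nears saturation", {
  # the microcolony regime: single-digit founders, default parameters;
  # disjointness must hold while total biomass <= K/2
  for (seed in 1:6) {
    for (n_cells in 2:6) {
      sc <- quick_scene(n_cells, layout = small_layout(1, 1), seed = seed,
                        times = seq(0, 48, 1))
      row_d <- sc$droplets[1, ]
      sim <- simulate_biomass(n_cells, row_d$lags[[1]], sc$growth, sc$times)
      cen <- row_d$centers[[1]]
      D <- as.matrix(stats::dist(cen))
      K <- sc$growth$carrying_capacity
      pre <- which(sim$total <= K / 2)
      for (j in pre) {
        r <- sqrt(sc$area_per_biomass * sim$biomass[, j] / pi)
        overlap <- outer(r, r, "+") - D
        diag(overlap) <- -1
        expect_lt(max(overlap), 0)
      }
    }
  }
})
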