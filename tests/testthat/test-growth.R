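# Growth-curve analytics: normalization, threshold crossing, growth
# classification, rebound detection.

test_that("normalization divides by the baseline and is idempotent", {
  expect_equal(normalize_curve(c(200, 200, 200)), c(1, 1, 1))
  expect_equal(normalize_curve(c(200, 100, 50)), c(1, 0.5, 0.25))
  v <- c(180, 150, 90, 60)
  expect_identical(normalize_curve(normalize_curve(v)), normalize_curve(v))
  # multi-frame baseline averages the leading frames
  expect_equal(normalize_curve(c(2, 4, 3), baseline_frames = 2),
               c(2, 4, 3) / 3)
  expect_error(normalize_curve(c(0, 1)), "zero or negative")
  expect_error(normalize_curve(numeric(0)), "non-empty")
})

test_that("normalization applies per droplet on series tables", {
  ser <- tibble::tibble(droplet_id = rep(1:2, each = 3),
                        time_h = rep(0:2, 2),
                        raw_mean_intensity = c(200, 100, 50, 80, 40, 20))
  out <- normalize_curve(ser)
  expect_equal(out$normalized, c(1, 0.5, 0.25, 1, 0.5, 0.25))
})

test_that("threshold crossing interpolates linearly between frames", {
  expect_equal(threshold_growth_time(c(1, 0.98), c(0, 1)), 0.5)
  expect_equal(threshold_growth_time(c(1, 1, 0.97), c(0, 1, 2), 0.99),
               1 + 1 / 3)
  expect_true(is.na(threshold_growth_time(rep(1, 145), seq(0, 72, 0.5))))
  expect_error(threshold_growth_time(c(0.9, 0.5), c(0, 1)),
               "not normalized")
})

test_that("lowering the threshold never gives an earlier crossing", {
  set.seed(5)
  for (i in 1:20) {
    v <- c(1, 1 - cumsum(runif(30, 0, 0.03)))
    t <- seq(0, 15, 0.5)
    crossings <- vapply(c(0.995, 0.99, 0.9, 0.7, 0.5),
                        function(th) threshold_growth_time(v, t, th), 0)
    expect_true(all(diff(crossings) >= -1e-12, na.rm = TRUE))
  }
})

test_that("growth classification requires a sustained drop", {
  t <- seq(0, 10, 0.5)
  plateau <- c(rep(1, 5), seq(1, 0.3, length.out = 8), rep(0.3, 8))
  expect_true(classify_growth(plateau, t))
  # single-frame dip that recovers is not growth
  dip <- rep(1, 21); dip[8] <- 0.95
  expect_false(classify_growth(dip, t))
  # flat noise never classifies as growth
  set.seed(8)
  noisy <- c(1, 1 + rnorm(20, 0, 0.002))
  expect_false(classify_growth(noisy, t))
})

test_that("rebound needs both rise and persistence", {
  t <- seq(0, 20, 0.5)
  sink <- c(seq(1, 0.4, length.out = 21), rep(0.4, 20))
  expect_false(detect_rebound(sink, t)$rebound)
  bounce <- c(seq(1, 0.4, length.out = 21), seq(0.42, 0.6, length.out = 20))
  rb <- detect_rebound(bounce, t)
  expect_true(rb$rebound)
  expect_equal(rb$onset_h, 10)
  # a rise below min_rise is ignored
  shallow <- c(seq(1, 0.4, length.out = 21),
               seq(0.405, 0.44, length.out = 20))
  expect_false(detect_rebound(shallow, t)$rebound)
  # a brief spike lacks persistence
  spike <- c(seq(1, 0.4, length.out = 21), rep(0.4, 20))
  spike[30] <- 0.5
  expect_false(detect_rebound(spike, t)$rebound)
})

test_that("analyze_droplets ties grew to threshold presence", {
  sc <- quick_scene(c(4, 0), concentrations = c(4, 0),
                    times = seq(0, 30, 0.5), seed = 6)
  sim <- suppressWarnings(simulate_experiment(sc))
  res <- analyze_droplets(sim$series,
                          tibble::tibble(droplet_id = 1:2, group = c(4, 0)))
  expect_equal(res$grew, c(TRUE, FALSE))
  expect_equal(is.na(res$threshold_time_h), !res$grew)
  expect_false(any(res$rebound))
})

test_that("interpolated crossings agree with a dense re-rendering oracle", {
  # coarse 0.5 h cadence vs a 0.05 h re-render of the same latent scene
  gp <- growth_params(lag_mean = 1, lag_sd = 0)
  coarse <- quick_scene(2, layout = small_layout(1, 1), growth = gp,
                        times = seq(0, 16, 0.5), noise_sd = 0, seed = 17)
  dense <- quick_scene(2, layout = small_layout(1, 1), growth = gp,
                       times = seq(0, 16, 0.05), noise_sd = 0, seed = 17)
  expect_identical(coarse$droplets$centers, dense$droplets$centers)
  t_coarse <- render_droplet(coarse, 1, noiseless = TRUE)
  t_dense <- render_droplet(dense, 1, noiseless = TRUE)
  x1 <- threshold_growth_time(t_coarse$latent / t_coarse$latent[1],
                              coarse$times)
  x2 <- threshold_growth_time(t_dense$latent / t_dense$latent[1],
                              dense$times)
  expect_lt(abs(x1 - x2), 0.1)
})
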