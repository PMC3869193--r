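# Rendering contract: darker with biomass, blank droplets at background x
# illumination, sporulation brightening, bit-identical determinism.

test_that("blank droplets render at background times illumination", {
  sc <- quick_scene(c(0, 0), concentrations = c(0, 0), noise_sd = 0)
  st <- render_droplet(sc, 1, noiseless = TRUE)
  expected <- sc$background_intensity * sc$droplets$illumination[1]
  expect_equal(st$latent, rep(expected, length(sc$times)))
  # quantized pixels constant within rounding of the expected value
  ctr <- sc$layout$frame_center
  d2 <- mocar:::frame_dist2(sc$layout$frame_shape, ctr, ctr)
  in_disk <- d2 <= (0.9 * sc$layout$spot_radius_px)^2
  vals <- unique(as.vector(st$pixels[, , 1][in_disk]))
  expect_length(vals, 1L)
  expect_lt(abs(vals - expected), 0.5 + 1e-9)
})

test_that("noisy blank droplets average to background within noise", {
  sc <- quick_scene(c(0, 0), concentrations = c(0, 0), noise_sd = 2)
  st <- render_droplet(sc, 2)
  roi <- locate_droplets(st, sc$layout, mode = "grid", droplet_id = 2)
  ser <- extract_transmission(st, roi)
  expected <- sc$background_intensity * sc$droplets$illumination[2]
  npx <- ser$pixel_count[1]
  expect_true(all(abs(ser$raw_mean_intensity - expected) <
                    5 * 2 / sqrt(npx) + 0.5))
})

test_that("noiseless mean intensity is non-increasing before any rebound", {
  for (seed in 1:4) {
    sc <- quick_scene(sample(1:8, 1), layout = small_layout(1, 1),
                      seed = seed, times = seq(0, 36, 0.5))
    st <- suppressWarnings(render_droplet(sc, 1, noiseless = TRUE))
    expect_true(all(diff(st$latent) <= 1e-6 * st$latent[1]))
  }
})

test_that("sporulation scenes brighten after the plateau", {
  sc <- quick_scene(3, layout = small_layout(1, 1),
                    growth = growth_params(sporulation = TRUE,
                                           rebound_fraction = 0.3),
                    times = seq(0, 48, 0.5), seed = 7)
  st <- suppressWarnings(render_droplet(sc, 1, noiseless = TRUE))
  gt <- mocar:::ground_truth_row(sc, 1, latent = st$latent)
  plateau_frame <- which.min(abs(sc$times - gt$plateau_time_h))
  expect_gt(st$latent[length(sc$times)], st$latent[plateau_frame])
})

test_that("rendering is bit-identical for identical scene and seed", {
  sc1 <- quick_scene(c(4, 1), seed = 13, times = seq(0, 12, 0.5))
  sc2 <- quick_scene(c(4, 1), seed = 13, times = seq(0, 12, 0.5))
  st1 <- render_droplet(sc1, 1)
  st2 <- render_droplet(sc2, 1)
  expect_identical(st1$pixels, st2$pixels)
  expect_identical(st1$latent, st2$latent)
})

test_that("oversized colonies are clipped with a warning", {
  # a single colony grows past the droplet boundary late in the run
  sc <- quick_scene(1, layout = small_layout(1, 1), times = seq(0, 48, 2),
                    seed = 3)
  expect_warning(render_droplet(sc, 1, noiseless = TRUE), "clipped")
})

test_that("tenfold inoculum advances the threshold crossing by ln(10)/mu", {
  gp <- growth_params(lag_mean = 0)
  sc <- quick_scene(c(10, 100), layout = small_layout(1, 2, 100),
                    growth = gp, times = seq(0, 16, 0.5), noise_sd = 0)
  sim <- suppressWarnings(simulate_experiment(sc, noiseless = TRUE))
  tt <- sim$ground_truth$true_threshold_time_h
  expect_equal(tt[1] - tt[2], log(10) / gp$specific_growth_rate,
               tolerance = 0.02)
})
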