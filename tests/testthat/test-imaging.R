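# ROI location, transmission extraction, and microcolony counting.

test_that("grid ROIs hit the true spot center and radius", {
  sc <- quick_scene(c(0, 0), concentrations = c(0, 0))
  st <- render_droplet(sc, 1, noiseless = TRUE)
  roi <- locate_droplets(st, sc$layout, mode = "grid", droplet_id = 1)
  expect_equal(roi$center_row, sc$layout$frame_center)
  expect_equal(roi$center_col, sc$layout$frame_center)
  expect_equal(roi$radius, sc$layout$spot_radius_px)
})

test_that("detect mode recovers the spot on a noiseless blank frame", {
  sc <- quick_scene(c(0, 0), concentrations = c(0, 0), noise_sd = 0)
  st <- render_droplet(sc, 1, noiseless = TRUE)
  roi <- locate_droplets(st, mode = "detect")
  grid <- locate_droplets(st, sc$layout, mode = "grid", droplet_id = 1)
  expect_lt(abs(roi$radius - grid$radius) / grid$radius, 0.02)
  expect_lt(abs(roi$center_row - grid$center_row), 2)
  expect_lt(abs(roi$center_col - grid$center_col), 2)
})

test_that("detect mode fails cleanly without contrast", {
  expect_error(locate_droplets(matrix(128, 64, 64), mode = "detect"),
               "no contrast")
})

test_that("extraction returns the plain mean for uniform frames", {
  f <- matrix(177, 64, 64)
  roi <- droplet_roi(1, 31.5, 31.5, 30)
  ser <- extract_transmission(f, roi)
  expect_equal(ser$raw_mean_intensity, 177)
  expect_equal(ser$time_h, 0)
})

test_that("pixels outside the measurement disk never affect the series", {
  sc <- quick_scene(3, layout = small_layout(1, 1), times = seq(0, 8, 0.5),
                    seed = 2)
  st <- render_droplet(sc, 1)
  roi <- locate_droplets(st, sc$layout, mode = "grid", droplet_id = 1)
  ser1 <- extract_transmission(st, roi)
  # corrupt everything outside the measurement disk
  d2 <- mocar:::frame_dist2(dim(st$pixels)[1:2], roi$center_row,
                            roi$center_col)
  outside <- d2 > (roi$shrink_factor * roi$radius)^2
  pix <- st$pixels
  for (j in seq_len(dim(pix)[3])) {
    fr <- pix[, , j]; fr[outside] <- 0L; pix[, , j] <- fr
  }
  ser2 <- extract_transmission(pix, roi, times = st$times)
  expect_identical(ser1$raw_mean_intensity, ser2$raw_mean_intensity)
})

test_that("extracted noiseless growth series are non-increasing pre-rebound", {
  sc <- quick_scene(4, layout = small_layout(1, 1), times = seq(0, 30, 0.5),
                    noise_sd = 0, seed = 5)
  st <- suppressWarnings(render_droplet(sc, 1, noiseless = TRUE))
  ser <- extract_transmission(st, locate_droplets(st, sc$layout, "grid",
                                                  droplet_id = 1))
  expect_true(all(diff(ser$raw_mean_intensity) <= 0.05))
})

test_that("component labeling is 8-connected and matches a BFS oracle", {
  m <- matrix(FALSE, 5, 5)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE  # diagonal touch: one component
  expect_equal(max(label_components(m)), 1L)
  set.seed(31)
  for (i in 1:12) {
    mask <- matrix(runif(400) < 0.35, 20, 20)
    lab <- label_components(mask)
    expect_equal(max(lab), count_components_bfs(mask))
    expect_identical(lab > 0L, mask)       # labels cover exactly the mask
  }
})

test_that("microcolony counting finds seeded colonies and their merges", {
  # constructed frame: three dark disks inside the disk, one dust speck
  f <- matrix(200, 161, 161)
  roi <- droplet_roi(1, 80, 80, 75)
  put_disk <- function(f, r0, c0, rad, val) {
    d2 <- mocar:::frame_dist2(dim(f), r0, c0)
    f[d2 <= rad^2] <- val
    f
  }
  f <- put_disk(f, 50, 50, 6, 30)
  f <- put_disk(f, 100, 60, 8, 40)
  f <- put_disk(f, 70, 110, 5, 25)
  f <- put_disk(f, 110, 110, 1.5, 30)  # below min_area
  out <- count_microcolonies(f, roi)
  expect_equal(out$count, 3L)
  expect_equal(nrow(out$centroids), 3L)
  # merge the two nearest disks with a bridge: count drops
  f2 <- put_disk(f, 60, 80, 40, 35)
  expect_lte(count_microcolonies(f2, roi)$count, 3L)
  # blank droplet
  expect_equal(count_microcolonies(matrix(200, 161, 161), roi)$count, 0L)
})

test_that("scene-based counting matches the seeded cell count pre-merge", {
  sc <- quick_scene(3, layout = small_layout(1, 1, 100), seed = 21,
                    times = seq(0, 24, 0.5))
  cp <- microcolony_checkpoint(sc, 1)
  expect_false(is.na(cp))
  st <- render_droplet(sc, 1, frames = cp)
  roi <- locate_droplets(st, sc$layout, mode = "grid", droplet_id = 1)
  out <- count_microcolonies(st$pixels[, , 1], roi)
  expect_equal(out$count, 3L)
})
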