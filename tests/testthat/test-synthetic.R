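test_that("identical parameters give a bit-identical raster", {
  a <- generate_scene(scene_params(seed = 13))
  b <- generate_scene(scene_params(seed = 13))
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth$laser_points_px, b$truth$laser_points_px)
  d <- generate_scene(scene_params(seed = 14))
  expect_false(identical(a$image$pixels, d$image$pixels))
})

test_that("vignette strength controls the corner/center falloff", {
  flat <- generate_scene(scene_params(seed = 2, vignette_strength = 0,
                                      color_cast = c(1, 1, 1), noise_sd = 0,
                                      texture_amplitude = 0,
                                      nodule_density_per_m2 = 0))
  expect_equal(corner_center_ratio(flat$image$pixels), 1, tolerance = 1e-6)

  dark <- generate_scene(scene_params(seed = 2, vignette_strength = 0.8,
                                      noise_sd = 0))
  expect_lt(corner_center_ratio(dark$image$pixels), 0.6)
})

test_that("expected intensity is non-increasing with radius", {
  sc <- generate_scene(scene_params(seed = 6, noise_sd = 0,
                                    texture_amplitude = 0,
                                    nodule_density_per_m2 = 0))
  px <- sc$image$pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  r <- sqrt((row(px[, , 1]) - cy)^2 + (col(px[, , 1]) - cx)^2)
  # exclude the stamped laser dots
  red <- px[, , 1] - pmax(px[, , 2], px[, , 3]) >= 80
  g <- px[, , 2]
  band <- cut(r[!red], breaks = 12)
  means <- tapply(g[!red], band, mean)
  expect_true(all(diff(means) <= 0.5))  # monotone up to quantization
})

test_that("altitude scales the image: px/cm and laser separation halve at 2x altitude", {
  p1 <- scene_params(seed = 3, altitude_m = 1, laser_separation_cm = 3)
  p2 <- scene_params(seed = 3, altitude_m = 2, laser_separation_cm = 3)
  s1 <- generate_scene(p1); s2 <- generate_scene(p2)
  expect_equal(s1$truth$true_scale_px_per_cm / 2, s2$truth$true_scale_px_per_cm)
  d1 <- mean(stats::dist(s1$truth$laser_points_px))
  d2 <- mean(stats::dist(s2$truth$laser_points_px))
  expect_equal(d1 / 2, d2, tolerance = 1 / d2)  # within 1 px
})

test_that("ground-truth laser geometry is consistent with the scale", {
  for (alt in c(1, 1.7, 2.8)) {
    sc <- generate_scene(scene_params(seed = 21, altitude_m = alt))
    d <- as.numeric(stats::dist(sc$truth$laser_points_px))
    expect_equal(d / sc$truth$params$laser_separation_cm,
                 rep(sc$truth$true_scale_px_per_cm, 3), tolerance = 1e-9)
  }
})

test_that("out-of-frame laser dots are rejected with advice", {
  expect_error(generate_scene(scene_params(seed = 1, altitude_m = 0.3,
                                           laser_separation_cm = 20)),
               regexp = "laser_separation_cm",
               class = "benthicready_synthetic_error")
})

test_that("transects are deterministic, time-ordered and span the scale range", {
  tr1 <- generate_transect(n = 12, seed = 77)
  tr2 <- generate_transect(n = 12, seed = 77)
  expect_identical(lapply(tr1$images, `[[`, "pixels"),
                   lapply(tr2$images, `[[`, "pixels"))
  times <- vapply(tr1$images, function(im) as.numeric(im$acquisition_time),
                  numeric(1))
  expect_equal(diff(times), rep(10, 11))  # 0.1 Hz capture
  for (im in tr1$images)
    expect_no_error(parse_image_filename(im$filename))
  # n=1 degenerate transect
  t1 <- generate_transect(n = 1, seed = 3)
  alt <- t1$truths[[1]]$params$altitude_m
  expect_true(alt >= 1 && alt <= 3)

  # altitude range (1,3): scale ratio across a long transect reaches >= 2
  tr3 <- generate_transect(n = 40, seed = 11, altitude_range = c(1, 3))
  sc <- vapply(tr3$truths, function(t) t$true_scale_px_per_cm, numeric(1))
  expect_gte(max(sc) / min(sc), 2)
})

test_that("transect metadata matches the schema and the ground truth", {
  tr <- generate_transect(n = 5, seed = 9)
  rec <- tr$metadata$records
  expect_identical(rec$image_name,
                   vapply(tr$images, `[[`, character(1), "filename"))
  expect_true(all(rec$seafloor_class %in% c("A", "B", "C", "D")))
  expect_equal(rec$original_scale_cm_per_px,
               1 / vapply(tr$truths, function(t) t$true_scale_px_per_cm,
                          numeric(1)))
})
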