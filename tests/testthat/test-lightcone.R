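test_that("batches are consecutive with the remainder rule", {
  expect_equal(lengths(partition_batches(100, 50)), c(50, 50))
  expect_equal(lengths(partition_batches(103, 50)), c(50, 53))
  expect_equal(lengths(partition_batches(60, 50)), c(50, 10))
  expect_equal(lengths(partition_batches(51, 50)), 51)
  expect_equal(lengths(partition_batches(5, 50)), 5)
  b <- partition_batches(103, 50)
  expect_identical(unlist(b), 1:103)  # consecutive, non-overlapping
  expect_error(partition_batches(1, 50), class = "benthicready_batch_error")
  expect_error(partition_batches(0, 50), class = "benthicready_batch_error")
})

test_that("z-score matches the closed form on a two-image batch", {
  a <- array(0, dim = c(2, 2, 3))
  b <- array(2, dim = c(2, 2, 3))
  zs <- zscore_batch(list(a, b))
  expect_equal(zs$standardized[[1]], array(-1, dim = c(2, 2, 3)))
  expect_equal(zs$standardized[[2]], array(1, dim = c(2, 2, 3)))
  expect_equal(zs$stats$mean, array(1, dim = c(2, 2, 3)))
  expect_equal(zs$stats$sd, array(1, dim = c(2, 2, 3)))
})

test_that("identical images map to all zeros (static-pixel branch)", {
  a <- random_rgb(6, 7, seed = 1)
  zs <- zscore_batch(list(a, a, a))
  for (z in zs$standardized)
    expect_equal(z, array(0, dim = dim(a)))
})

test_that("z-scored batches have per-position mean 0 and unit variance", {
  arrs <- lapply(1:6, function(s) random_rgb(9, 11, seed = s))
  zs <- zscore_batch(arrs)
  Z <- array(unlist(zs$standardized), dim = c(9, 11, 3, 6))
  m <- rowMeans(Z, dims = 3)
  v <- rowMeans(Z^2, dims = 3)
  expect_lt(max(abs(m)), 1e-6)
  expect_true(all(v >= 1 - 1e-4 & v <= 1 + 1e-4))
})

test_that("z-score agrees with the direct per-position oracle", {
  for (n in c(2, 3, 5)) {
    arrs <- lapply(seq_len(n), function(s) random_rgb(4, 5, seed = 100 + s))
    got <- zscore_batch(arrs)$standardized
    want <- oracle_zscore(arrs)
    for (k in seq_len(n)) expect_equal(got[[k]], want[[k]], tolerance = 1e-12)
  }
})

test_that("shape mismatches name the offending image", {
  imgs <- list(image_record(random_rgb(4, 4, 1), filename = "ok.JPG"),
               image_record(random_rgb(4, 5, 2), filename = "bad_shape.JPG"))
  expect_error(zscore_batch(imgs), regexp = "bad_shape",
               class = "benthicready_batch_error")
  expect_error(zscore_batch(list(random_rgb(4, 4, 1))),
               class = "benthicready_batch_error")
})

test_that("display remap is the clipped linear map with half-up rounding", {
  z <- array(c(0, 3, -3, 4.2, -7, 1.5), dim = c(1, 2, 3))
  out <- remap_to_display(z)
  expect_identical(as.vector(out), c(128L, 255L, 0L, 255L, 0L, 191L))
  # monotone over random inputs (vs brute-force sort)
  set.seed(42)
  zr <- sort(stats::rnorm(500, sd = 2))
  o <- as.vector(remap_to_display(matrix(zr)))
  expect_true(!is.unsorted(o))
})

test_that("correction flattens a shared vignette (corner/center recovery)", {
  tr <- generate_transect(n = 10, seed = 31,
                          params = scene_params(vignette_strength = 0.8))
  ratios_in <- vapply(tr$images, function(im) corner_center_ratio(im$pixels),
                      numeric(1))
  expect_lt(mean(ratios_in), 0.7)
  corrected <- correct_light_cone(tr$images, batch_size = 10)
  ratios_out <- vapply(corrected, function(im) corner_center_ratio(im$pixels),
                       numeric(1))
  expect_gt(mean(ratios_out), 0.9)
})

test_that("permuting a batch permutes outputs identically", {
  arrs <- lapply(1:4, function(s) random_rgb(6, 6, seed = 200 + s))
  z1 <- zscore_batch(arrs)$standardized
  perm <- c(3, 1, 4, 2)
  z2 <- zscore_batch(arrs[perm])$standardized
  for (k in seq_along(perm)) expect_equal(z2[[k]], z1[[perm[k]]])
})
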