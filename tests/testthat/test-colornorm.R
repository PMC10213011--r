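test_that("reference selection takes the largest px/cm with time tie-break", {
  expect_equal(select_reference(c(18.2, 21.5, 25.0)), 3)
  expect_equal(select_reference(25.0), 1)
  t0 <- as.POSIXct("2019-03-04 09:35:10", tz = "UTC")
  expect_equal(select_reference(c(25.0, 18, 25.0),
                                acquired_at = t0 + c(30, 0, 10)), 3)
  expect_error(select_reference(numeric(0)),
               class = "benthicready_colornorm_error")
})

test_that("matching an image to itself is the identity (<= 1 level)", {
  img <- random_rgb(16, 16, seed = 7)
  out <- match_histograms(img, img)
  expect_lte(max(abs(out - img)), 1)
})

test_that("point-mass histograms transport exactly", {
  a <- array(64L, dim = c(8, 8, 3))
  b <- array(200L, dim = c(8, 8, 3))
  expect_equal(match_histograms(a, b), array(200L, dim = c(8, 8, 3)))
})

test_that("matching agrees with the brute-force CDF-inverse oracle", {
  for (s in 1:4) {
    img <- random_rgb(16, 16, seed = 300 + s)
    ref <- random_rgb(16, 16, seed = 400 + s)
    expect_identical(match_histograms(img, ref),
                     oracle_match_histograms(img, ref))
  }
  # and for differently sized images
  img <- random_rgb(12, 20, seed = 777)
  ref <- random_rgb(30, 10, seed = 778)
  expect_identical(match_histograms(img, ref),
                   oracle_match_histograms(img, ref))
})

test_that("matched output lands within 2/256 of the reference CDF", {
  # Atom-free inputs (every level has mass 1/256): the transport bound
  # guarantees KS < 2/256 against ANY reference. Inputs with repeated
  # values can only be matched to within their largest point mass, which
  # the transect-scale checks assert separately.
  for (s in 1:4) {
    set.seed(500 + s)
    img <- array(c(sample(0:255), sample(0:255), sample(0:255)),
                 dim = c(16, 16, 3))
    storage.mode(img) <- "integer"
    ref <- random_rgb(16, 16, seed = 600 + s)
    out <- match_histograms(img, ref)
    for (ch in 1:3)
      expect_lt(ks_distance_256(out[, , ch], ref[, , ch]), 2 / 256)
  }
})

test_that("matching error never exceeds the largest input point mass", {
  for (s in 1:4) {
    img <- random_rgb(16, 16, seed = 700 + s)
    ref <- random_rgb(16, 16, seed = 800 + s)
    out <- match_histograms(img, ref)
    for (ch in 1:3) {
      atom <- max(tabulate(as.vector(img[, , ch]) + 1L, 256L)) / 256
      expect_lte(ks_distance_256(out[, , ch], ref[, , ch]), atom + 1e-12)
    }
  }
})

test_that("matching preserves rank order within each channel", {
  img <- random_rgb(20, 20, seed = 9)
  ref <- random_rgb(20, 20, seed = 10)
  out <- match_histograms(img, ref)
  for (ch in 1:3) {
    x <- as.vector(img[, , ch]); y <- as.vector(out[, , ch])
    ord <- order(x)
    expect_true(!is.unsorted(y[ord]))
  }
})

test_that("normalization harmonizes brightness across heterogeneous casts", {
  tr <- generate_transect(n = 8, seed = 55)
  scales <- vapply(tr$truths, function(t) t$true_scale_px_per_cm, numeric(1))
  ref <- tr$images[[select_reference(scales)]]
  normed <- lapply(tr$images, match_histograms, reference = ref)
  v_before <- apply(t(vapply(tr$images, median_intensity, numeric(3))), 2,
                    pop_var_)
  v_after <- apply(t(vapply(normed, median_intensity, numeric(3))), 2,
                   pop_var_)
  expect_true(all(v_after < 0.05 * v_before))
})
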