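test_that("filename convention parses and round-trips", {
  p <- parse_image_filename("SO268_100-1_OFOS_20190304_093510.JPG")
  expect_equal(p$cruise, "SO268")
  expect_equal(p$station, "100-1")
  expect_equal(p$platform, "OFOS")
  expect_equal(p$date, as.Date("2019-03-04"))
  expect_equal(p$time, "09:35:10")
  expect_equal(p$acquisition_time,
               as.POSIXct("2019-03-04 09:35:10", tz = "UTC"))
  expect_equal(build_image_filename(p), "SO268_100-1_OFOS_20190304_093510.JPG")
})

test_that("malformed names give structured parse errors naming the token", {
  expect_error(parse_image_filename("badname.JPG"),
               class = "benthicready_parse_error")
  expect_error(parse_image_filename("SO268_100-1_OFOS_20190304_093510"),
               class = "benthicready_parse_error")
  expect_error(parse_image_filename("A_B_C_2019XX04_093510.JPG"),
               regexp = "2019XX04", class = "benthicready_parse_error")
  expect_error(parse_image_filename("A_B_C_20190304_25int0.JPG"),
               regexp = "25int0", class = "benthicready_parse_error")
  # invalid calendar date / clock time
  expect_error(parse_image_filename("A_B_C_20190231_093510.JPG"),
               class = "benthicready_parse_error")
  expect_error(parse_image_filename("A_B_C_20190304_256100.JPG"),
               class = "benthicready_parse_error")
})

test_that("parse/assemble is a bijection on generated well-formed names", {
  set.seed(99)
  rand_tok <- function() paste(sample(c(LETTERS, 0:9, "-"), sample(2:6, 1),
                                      replace = TRUE), collapse = "")
  for (i in 1:25) {
    ts <- as.POSIXct("2019-03-04 00:00:00", tz = "UTC") +
      sample(0:5e6, 1)
    nm <- build_image_filename(cruise = rand_tok(), station = rand_tok(),
                               platform = rand_tok(), acquisition_time = ts)
    p <- parse_image_filename(nm)
    expect_identical(build_image_filename(p), nm)
    expect_equal(p$acquisition_time, ts)
  }
})

test_that("metadata CSV reads, validates, sorts and round-trips", {
  tr <- generate_transect(n = 6, seed = 5)
  csv <- file.path(tempdir(), "meta.csv")
  # shuffle rows before writing: reading must restore time order
  shuffled <- tr$metadata
  shuffled$records <- shuffled$records[c(4, 1, 6, 3, 2, 5), ]
  write_metadata_table(shuffled, csv)
  idx <- read_metadata_table(csv)
  expect_equal(nrow(idx$records), 6)
  expect_identical(idx$records$image_name, tr$metadata$records$image_name)
  expect_true(!is.unsorted(idx$records$acquired_at))
  expect_equal(idx$records$latitude, tr$metadata$records$latitude,
               tolerance = 1e-9)
  expect_equal(idx$records$original_scale_cm_per_px,
               tr$metadata$records$original_scale_cm_per_px, tolerance = 1e-9)
  expect_identical(idx$records$seafloor_class,
                   tr$metadata$records$seafloor_class)
  expect_equal(idx$records$acquired_at, tr$metadata$records$acquired_at)
})

test_that("schema violations are reported with row context", {
  tr <- generate_transect(n = 3, seed = 8)
  rec <- tr$metadata$records
  rec$seafloor_class[2] <- "E"
  csv <- file.path(tempdir(), "meta_bad.csv")
  write_metadata_table(structure(list(records = rec,
                                      col_map = metadata_columns()),
                                 class = "dataset_index"), csv)
  expect_error(read_metadata_table(csv), regexp = "row 2.*A, B, C, D",
               class = "benthicready_schema_error")
  expect_warning(idx <- read_metadata_table(csv, skip_bad = TRUE),
                 regexp = "dropping 1")
  expect_equal(nrow(idx$records), 2)

  # missing required column
  df <- utils::read.csv(csv, check.names = FALSE)
  df$latitude <- NULL
  utils::write.csv(df, csv, row.names = FALSE)
  expect_error(read_metadata_table(csv), regexp = "latitude",
               class = "benthicready_schema_error")
})

test_that("header-only CSV yields an empty index with a warning", {
  csv <- file.path(tempdir(), "meta_empty.csv")
  writeLines(paste(metadata_columns(), collapse = ","), csv)
  expect_warning(idx <- read_metadata_table(csv), regexp = "no rows")
  expect_equal(nrow(idx$records), 0)
  expect_error(summarize_coverage(idx), class = "benthicready_schema_error")
})

test_that("coverage summary computes medians, bounds and span", {
  rec <- data.frame(
    latitude = c(1, 2, 3), longitude = c(10, 30, 20),
    acquired_at = as.POSIXct("2019-03-04 09:35:10", tz = "UTC") + c(20, 0, 10)
  )
  cov <- summarize_coverage(rec)
  expect_equal(cov$median_lat, 2)
  expect_equal(cov$median_lon, 20)
  expect_equal(cov$bounds$south, 1)
  expect_equal(cov$bounds$north, 3)
  expect_equal(cov$bounds$west, 10)
  expect_equal(cov$bounds$east, 30)
  expect_equal(as.numeric(diff(cov$time_span)), 20)

  # single record: degenerate bounds
  cov1 <- summarize_coverage(rec[1, ])
  expect_equal(cov1$median_lat, cov1$bounds$south)
  expect_equal(cov1$bounds$south, cov1$bounds$north)

  # even count: mean of the two central values
  expect_equal(summarize_coverage(rec[c(1, 2), ])$median_lat, 1.5)

  # invariant under permutation
  for (perm in list(c(3, 1, 2), c(2, 3, 1))) {
    expect_equal(summarize_coverage(rec[perm, ])$median_lat, cov$median_lat)
    expect_equal(summarize_coverage(rec[perm, ])$median_lon, cov$median_lon)
  }
})

test_that("image I/O round-trips PNG bit-exactly and rejects alpha", {
  px <- random_rgb(20, 30, seed = 4)
  f <- file.path(tempdir(), "A_B_C_20190304_093510.png")
  write_seafloor_image(px, f)
  back <- read_seafloor_image(f)
  expect_identical(back$pixels, px)
  expect_equal(back$acquisition_time,
               as.POSIXct("2019-03-04 09:35:10", tz = "UTC"))

  fa <- file.path(tempdir(), "alpha.png")
  png::writePNG(array(0.5, dim = c(4, 4, 4)), fa)
  expect_error(read_seafloor_image(fa), regexp = "alpha",
               class = "benthicready_io_error")
})
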