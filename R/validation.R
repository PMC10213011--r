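#' Per-channel RMS contrast of an image
#'
#' RMS contrast is the (population) standard deviation of the pixel
#' intensities, computed separately for the R, G and B channels; higher
#' values indicate higher contrast.
#'
#' @param image an [image_record] or `h x w x 3` array.
#' @return named numeric vector `c(R=, G=, B=)`.
#' @export
rms_contrast <- function(image) {
  # the pipeline hands in already-computed stats to avoid re-decoding images
  if (inherits(image, "precomputed_stats")) return(image$rc)
  px <- as_pixels(image)
  c(R = pop_sd(as.numeric(px[, , 1])),
    G = pop_sd(as.numeric(px[, , 2])),
    B = pop_sd(as.numeric(px[, , 3])))
}

#' Per-channel median intensity of an image
#'
#' The channel-wise median quantifies overall scene brightness; even pixel
#' counts take the mean of the two central values.
#'
#' @inheritParams rms_contrast
#' @return named numeric vector `c(R=, G=, B=)`.
#' @export
median_intensity <- function(image) {
  if (inherits(image, "precomputed_stats")) return(image$mi)
  px <- as_pixels(image)
  c(R = stats::median(as.numeric(px[, , 1])),
    G = stats::median(as.numeric(px[, , 2])),
    B = stats::median(as.numeric(px[, , 3])))
}

channel_stats_table <- function(images, set_name) {
  rc <- t(vapply(images, rms_contrast, numeric(3)))
  mi <- t(vapply(images, median_intensity, numeric(3)))
  nm <- vapply(seq_along(images), function(i) {
    im <- images[[i]]
    if (inherits(im, "image_record") && !is.na(im$filename)) im$filename
    else paste0("image_", i)
  }, character(1))
  rbind(
    data.frame(set = set_name, image = nm, metric = "rms_contrast",
               R = rc[, 1], G = rc[, 2], B = rc[, 3],
               stringsAsFactors = FALSE),
    data.frame(set = set_name, image = nm, metric = "median_intensity",
               R = mi[, 1], G = mi[, 2], B = mi[, 3],
               stringsAsFactors = FALSE)
  )
}

#' Before/after technical-validation report
#'
#' Quantifies what the pipeline achieved, mirroring the dataset's technical
#' validation: per-image, per-channel RMS contrast and median intensity for
#' the raw ("before") and analysis-ready ("after") sets; the across-image
#' population variance of each metric per channel; the after/before variance
#' ratios; and, when footprint areas are supplied, the across-image variance
#' of the spatial footprint in each set. After standardization every output
#' shares the same crop, so the after-footprint variance is exactly 0.
#'
#' @param before,after non-empty lists of images ([image_record]s or arrays).
#' @param before_footprint_m2,after_footprint_m2 optional numeric vectors of
#'   per-image seafloor footprint areas (m^2).
#' @param paired if `TRUE`, require `length(before) == length(after)` (a
#'   per-image before/after pairing).
#' @return object of class `validation_report`: `per_image` (long-format
#'   data.frame of ChannelStats), `variances` (per set x metric x channel),
#'   `ratios` (after/before per metric and channel), `footprint`
#'   (`before_var`, `after_var`, and the per-image areas).
#' @export
dataset_variance_report <- function(before, after,
                                    before_footprint_m2 = NULL,
                                    after_footprint_m2 = NULL,
                                    paired = FALSE) {
  if (length(before) == 0L || length(after) == 0L)
    br_stop("both image sets must be non-empty", "benthicready_validation_error")
  if (paired && length(before) != length(after))
    br_stop(paste0("--paired requested but sets have ", length(before),
                   " and ", length(after), " images"),
            "benthicready_validation_error")
  per_image <- rbind(channel_stats_table(before, "before"),
                     channel_stats_table(after, "after"))
  var_rows <- do.call(rbind, lapply(c("before", "after"), function(s) {
    do.call(rbind, lapply(c("rms_contrast", "median_intensity"), function(m) {
      sub <- per_image[per_image$set == s & per_image$metric == m, ]
      data.frame(set = s, metric = m,
                 R = pop_var(sub$R), G = pop_var(sub$G), B = pop_var(sub$B),
                 stringsAsFactors = FALSE)
    }))
  }))
  ratios <- do.call(rbind, lapply(c("rms_contrast", "median_intensity"),
                                  function(m) {
    b <- var_rows[var_rows$set == "before" & var_rows$metric == m, c("R", "G", "B")]
    a <- var_rows[var_rows$set == "after" & var_rows$metric == m, c("R", "G", "B")]
    out <- a / b
    out[b == 0] <- NA_real_
    cbind(data.frame(metric = m, stringsAsFactors = FALSE), out)
  }))
  footprint <- list(
    before_m2 = before_footprint_m2, after_m2 = after_footprint_m2,
    before_var = if (!is.null(before_footprint_m2)) pop_var(before_footprint_m2) else NA_real_,
    after_var = if (!is.null(after_footprint_m2)) pop_var(after_footprint_m2) else NA_real_
  )
  structure(list(per_image = per_image, variances = var_rows,
                 ratios = ratios, footprint = footprint,
                 n_before = length(before), n_after = length(after)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, digits = 4, ...) {
  cat(sprintf("<validation_report> %d before / %d after image(s)\n",
              x$n_before, x$n_after))
  cat("across-image variances (population):\n")
  print(format(x$variances, digits = digits), row.names = FALSE)
  cat("after/before variance ratios:\n")
  print(format(x$ratios, digits = digits), row.names = FALSE)
  if (!is.na(x$footprint$before_var) || !is.na(x$footprint$after_var))
    cat(sprintf("footprint variance (m^4): before %.4g, after %.4g\n",
                x$footprint$before_var, x$footprint$after_var))
  invisible(x)
}

#' Serialize a validation report
#'
#' Writes `report.csv` (the per-image long table) and `summary.json`
#' (variances, ratios, footprint variances) into `dir`.
#'
#' @param report a [dataset_variance_report()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_validation_report <- function(report, dir) {
  stopifnot(inherits(report, "validation_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$per_image, file.path(dir, "report.csv"),
                   row.names = FALSE)
  summ <- list(variances = report$variances, ratios = report$ratios,
               footprint_variance_before_m4 = report$footprint$before_var,
               footprint_variance_after_m4 = report$footprint$after_var,
               n_before = report$n_before, n_after = report$n_after)
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       na = "null")
  invisible(dir)
}
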