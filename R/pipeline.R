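#' Pipeline configuration
#'
#' Collects all stage parameters. The stage order is fixed: light-cone
#' correction, contrast enhancement, color normalization, footprint
#' standardization — scale estimation runs first on the raw images since the
#' later stages alter colors and geometry. Configurations serialize losslessly
#' to YAML via [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param input_dir directory of raw images (JPG/PNG) named by the
#'   `<cruise_station_platform_date_time>` convention.
#' @param output_dir destination; per-stage subdirectories are created under
#'   it, so an aborted run can be inspected and resumed.
#' @param laser_separation_cm calibrated separation of the laser beams (cm);
#'   required unless every image's scale comes from `metadata_csv`.
#' @param metadata_csv optional metadata table; supplies acquisition times
#'   (matched by image name) and the fallback `original_scale_cm_per_px` when
#'   laser detection finds fewer than 2 points.
#' @param batch_size light-cone batch size (default 50).
#' @param clip_sigma display remap clipping (default 3).
#' @param tile_grid,clip_limit CLAHE parameters (defaults 8 x 8 tiles, 2.0).
#' @param reference optional image file name to force as the color reference
#'   (default: automatic, largest px/cm).
#' @param redness_threshold,min_area,max_area laser detector parameters.
#' @param target_scale optional px/cm override of the median target scale.
#' @param target_size optional `c(height, width)` override of the per-axis
#'   minimum crop target.
#' @param export_format `"png"` (lossless, default) or `"jpg"` for the final
#'   stage; intermediates are always PNG.
#' @param jpeg_quality quality for JPG export.
#' @param verbose log one line per image per stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, output_dir,
                            laser_separation_cm = NULL,
                            metadata_csv = NULL,
                            batch_size = 50L, clip_sigma = 3,
                            tile_grid = c(8L, 8L), clip_limit = 2.0,
                            reference = NULL,
                            redness_threshold = 80, min_area = 4,
                            max_area = 500,
                            target_scale = NULL, target_size = NULL,
                            export_format = c("png", "jpg"),
                            jpeg_quality = 95,
                            verbose = TRUE) {
  export_format <- match.arg(export_format)
  structure(list(
    input_dir = input_dir, output_dir = output_dir,
    laser_separation_cm = laser_separation_cm, metadata_csv = metadata_csv,
    batch_size = as.integer(batch_size), clip_sigma = clip_sigma,
    tile_grid = as.integer(tile_grid), clip_limit = clip_limit,
    reference = reference,
    redness_threshold = redness_threshold,
    min_area = min_area, max_area = max_area,
    target_scale = target_scale, target_size = target_size,
    export_format = export_format, jpeg_quality = jpeg_quality,
    verbose = isTRUE(verbose)
  ), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(pipeline_config, x)
}

plog <- function(verbose, stage, image, detail = "") {
  if (verbose)
    message(sprintf("[%s] %s%s", stage, image,
                    if (nzchar(detail)) paste0("  ", detail) else ""))
}

# List input images sorted by acquisition time (metadata acquired_at when a
# table is given, else the filename convention), ties by name.
index_input_images <- function(input_dir, metadata = NULL) {
  files <- list.files(input_dir, pattern = "\\.(jpe?g|png)$",
                      ignore.case = TRUE)
  if (length(files) == 0L)
    br_stop(paste0("no JPG/PNG images found in ", input_dir),
            "benthicready_pipeline_error")
  times <- as.POSIXct(rep(NA_real_, length(files)), origin = "1970-01-01",
                      tz = "UTC")
  if (!is.null(metadata)) {
    m <- match(files, metadata$records$image_name)
    times[!is.na(m)] <- metadata$records$acquired_at[m[!is.na(m)]]
  }
  need <- is.na(times)
  if (any(need)) {
    times[need] <- as.POSIXct(vapply(files[need], function(f) {
      p <- tryCatch(parse_image_filename(f), error = function(e) NULL)
      if (is.null(p)) NA_real_ else as.numeric(p$acquisition_time)
    }, numeric(1)), origin = "1970-01-01", tz = "UTC")
  }
  if (anyNA(times))
    br_stop(paste0("cannot determine acquisition time for: ",
                   paste(files[is.na(times)], collapse = ", "),
                   " (name does not follow the convention and no metadata row matches)"),
            "benthicready_pipeline_error")
  ord <- order(times, files)
  data.frame(file = files[ord], acquired_at = times[ord],
             stringsAsFactors = FALSE)
}

#' Run the full raw-to-analysis-ready pipeline on a directory of images
#'
#' Executes, in order: per-image laser scale estimation (on the raw images),
#' batch z-score light-cone correction, contrast-limited adaptive histogram
#' equalization, histogram matching to the automatically selected reference,
#' and rescaling + center-cropping to the common footprint. Intermediates are
#' written losslessly (PNG) into stage subdirectories of `output_dir`; the
#' final images go to `output_dir/analysis_ready`. Validation metrics are
#' computed on in-memory pixel buffers before any lossy export. Re-running
#' with identical inputs and config reproduces all outputs bit-exactly. At
#' most one light-cone batch of images is held decoded in memory at a time.
#'
#' @param config a [pipeline_config()].
#' @return object of class `pipeline_result`: `manifest` (per-image
#'   provenance: input name, batch id, scale and its method, reference flag,
#'   rescale ratio, crop offsets, output name), `footprint_spec`,
#'   `report` (a `validation_report`), `reference` (file name), `scales`,
#'   and `output_dir`. The manifest, footprint spec JSON, scale CSV and
#'   validation report are also written under `output_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  metadata <- if (!is.null(cfg$metadata_csv))
    read_metadata_table(cfg$metadata_csv) else NULL
  idx <- index_input_images(cfg$input_dir, metadata)
  n <- nrow(idx)
  dirs <- list(
    lightcone = file.path(cfg$output_dir, "01_lightcone"),
    contrast = file.path(cfg$output_dir, "02_contrast"),
    colornorm = file.path(cfg$output_dir, "03_colornorm"),
    final = file.path(cfg$output_dir, "analysis_ready")
  )
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  stem <- sub("\\.(jpe?g|png)$", "", idx$file, ignore.case = TRUE)
  png_name <- paste0(stem, ".png")

  ## Stage 0: scale estimation + before-metrics on the raw images
  scales <- numeric(n)
  scale_method <- character(n)
  before_rc <- matrix(0, n, 3)
  before_mi <- matrix(0, n, 3)
  dims_in <- matrix(0L, n, 2)
  for (i in seq_len(n)) {
    img <- read_seafloor_image(file.path(cfg$input_dir, idx$file[i]))
    dims_in[i, ] <- c(img$height_px, img$width_px)
    metadata_fallback <- function(why) {
      m <- if (!is.null(metadata))
        match(idx$file[i], metadata$records$image_name) else NA_integer_
      if (is.na(m))
        br_stop(paste0("stage scale, image ", idx$file[i], ": ", why,
                       "; no metadata row to fall back to"),
                "benthicready_pipeline_error")
      plog(cfg$verbose, "scale", idx$file[i],
           paste0(why, "; using metadata scale"))
      scale_from_metadata(metadata$records$original_scale_cm_per_px[m])
    }
    est <- if (is.null(cfg$laser_separation_cm)) {
      metadata_fallback("no laser_separation_cm configured")
    } else {
      det <- detect_laser_points(img, cfg$redness_threshold,
                                 cfg$min_area, cfg$max_area)
      tryCatch(estimate_scale(det, cfg$laser_separation_cm),
               benthicready_scale_error = function(e)
                 metadata_fallback(conditionMessage(e)))
    }
    scales[i] <- est$px_per_cm
    scale_method[i] <- est$method
    before_rc[i, ] <- rms_contrast(img)
    before_mi[i, ] <- median_intensity(img)
    plog(cfg$verbose, "scale", idx$file[i],
         sprintf("%.3f px/cm (%s)", est$px_per_cm, est$method))
  }
  before_fp <- (dims_in[, 1] / scales) * (dims_in[, 2] / scales) / 1e4
  utils::write.csv(
    data.frame(image = idx$file, px_per_cm = scales, method = scale_method),
    file.path(cfg$output_dir, "scales.csv"), row.names = FALSE)

  ## Stage 1: light-cone correction, one batch in memory at a time
  batches <- partition_batches(n, cfg$batch_size)
  batch_id <- integer(n)
  for (b in seq_along(batches)) {
    sel <- batches[[b]]
    batch <- lapply(sel, function(i)
      read_seafloor_image(file.path(cfg$input_dir, idx$file[i])))
    zs <- zscore_batch(batch)
    for (j in seq_along(sel)) {
      i <- sel[j]
      out <- remap_to_display(zs$standardized[[j]], cfg$clip_sigma)
      write_seafloor_image(out, file.path(dirs$lightcone, png_name[i]))
      plog(cfg$verbose, "lightcone", idx$file[i], sprintf("batch %d", b))
    }
    batch_id[sel] <- b
  }

  ## Stage 2: contrast enhancement
  for (i in seq_len(n)) {
    img <- read_seafloor_image(file.path(dirs$lightcone, png_name[i]))
    eq <- equalize_adaptive(img, cfg$tile_grid, cfg$clip_limit)
    write_seafloor_image(eq, file.path(dirs$contrast, png_name[i]))
    plog(cfg$verbose, "contrast", idx$file[i])
  }

  ## Stage 3: color normalization against the reference
  ref_i <- if (!is.null(cfg$reference)) {
    m <- match(cfg$reference, idx$file)
    if (is.na(m))
      br_stop(paste0("stage colornorm: requested reference '", cfg$reference,
                     "' is not among the inputs"), "benthicready_pipeline_error")
    m
  } else select_reference(scales, idx$acquired_at)
  ref_img <- read_seafloor_image(file.path(dirs$contrast, png_name[ref_i]))
  for (i in seq_len(n)) {
    img <- read_seafloor_image(file.path(dirs$contrast, png_name[i]))
    out <- match_histograms(img, ref_img)
    write_seafloor_image(out, file.path(dirs$colornorm, png_name[i]))
    plog(cfg$verbose, "colornorm", idx$file[i],
         if (i == ref_i) "(reference)" else "")
  }

  ## Stage 4: footprint standardization
  target_scale <- cfg$target_scale %||% compute_target_scale(scales)
  ratio <- target_scale / scales
  dims_rescaled <- cbind(as.integer(round_half_up(dims_in[, 1] * ratio)),
                         as.integer(round_half_up(dims_in[, 2] * ratio)))
  spec <- if (!is.null(cfg$target_size))
    footprint_spec(target_scale, cfg$target_size[1], cfg$target_size[2])
  else compute_footprint_spec(dims_rescaled, target_scale)
  after_rc <- matrix(0, n, 3)
  after_mi <- matrix(0, n, 3)
  offsets <- matrix(0L, n, 2)
  out_ext <- if (cfg$export_format == "jpg") ".jpg" else ".png"
  out_name <- paste0(stem, out_ext)
  for (i in seq_len(n)) {
    img <- read_seafloor_image(file.path(dirs$colornorm, png_name[i]))
    res <- rescale_to_scale(img, scales[i], target_scale)
    crop <- center_crop(res, spec$target_height_px, spec$target_width_px)
    offsets[i, ] <- attr(crop, "crop_offsets")
    after_rc[i, ] <- rms_contrast(crop)
    after_mi[i, ] <- median_intensity(crop)
    write_seafloor_image(crop, file.path(dirs$final, out_name[i]),
                         quality = cfg$jpeg_quality)
    plog(cfg$verbose, "footprint", idx$file[i],
         sprintf("ratio %.3f, crop offsets (%d, %d)",
                 ratio[i], offsets[i, 1], offsets[i, 2]))
  }

  ## Validation report: raw vs analysis-ready (metrics from decoded buffers)
  report <- dataset_variance_report(
    before = lapply(seq_len(n), function(i) {
      structure(list(rc = before_rc[i, ], mi = before_mi[i, ]),
                class = "precomputed_stats")
    }),
    after = lapply(seq_len(n), function(i) {
      structure(list(rc = after_rc[i, ], mi = after_mi[i, ]),
                class = "precomputed_stats")
    }),
    before_footprint_m2 = before_fp,
    after_footprint_m2 = rep(spec$footprint_m2, n),
    paired = TRUE)
  write_validation_report(report, file.path(cfg$output_dir, "validation"))

  manifest <- data.frame(
    input = idx$file,
    acquired_at = format(idx$acquired_at, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    batch_id = batch_id,
    px_per_cm = scales,
    scale_method = scale_method,
    is_reference = seq_len(n) == ref_i,
    rescale_ratio = ratio,
    crop_offset_row = offsets[, 1],
    crop_offset_col = offsets[, 2],
    output = out_name,
    stringsAsFactors = FALSE
  )
  utils::write.csv(manifest, file.path(cfg$output_dir, "manifest.csv"),
                   row.names = FALSE)
  jsonlite::write_json(unclass(spec),
                       file.path(cfg$output_dir, "footprint_spec.json"),
                       auto_unbox = TRUE, digits = NA)
  structure(list(manifest = manifest, footprint_spec = spec, report = report,
                 reference = idx$file[ref_i], scales = scales,
                 output_dir = cfg$output_dir, config = cfg),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d image(s) -> %s\n",
              nrow(x$manifest), x$output_dir))
  print(x$footprint_spec)
  cat("reference image:", x$reference, "\n")
  invisible(x)
}
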