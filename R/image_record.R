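#' An 8-bit RGB seafloor image with its identity
#'
#' The container that flows through every pipeline stage: a `height x width x 3`
#' integer array of intensities in \[0, 255\] (channels R, G, B), plus the image
#' filename and its acquisition time (UTC, second resolution). Acquisition time
#' is parsed from the filename convention when possible (see
#' [parse_image_filename()]); it is never read from EXIF.
#'
#' @param pixels numeric or integer array of dimension `c(height, width, 3)`
#'   with all values in \[0, 255\]. Values are rounded to integers.
#' @param filename optional image file name (basename), used for identity and
#'   for parsing the acquisition time.
#' @param acquisition_time optional `POSIXct` (UTC). When `NULL` and `filename`
#'   follows the `<cruise_station_platform_date_time.JPG>` convention, the time
#'   is taken from the name.
#' @return an object of class `image_record` with elements `pixels`,
#'   `filename`, `acquisition_time`, `height_px`, `width_px`.
#' @examples
#' img <- image_record(array(128, dim = c(4, 6, 3)))
#' dim(img$pixels)
#' @export
image_record <- function(pixels, filename = NA_character_, acquisition_time = NULL) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    br_stop("'pixels' must be a height x width x 3 array (R, G, B channels)",
            "benthicready_image_error")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    br_stop("pixel intensities must be finite and in [0, 255]",
            "benthicready_image_error")
  px <- round_half_up(pixels)
  storage.mode(px) <- "integer"
  if (is.null(acquisition_time) && !is.na(filename)) {
    parsed <- tryCatch(parse_image_filename(filename), error = function(e) NULL)
    if (!is.null(parsed)) acquisition_time <- parsed$acquisition_time
  }
  if (is.null(acquisition_time)) acquisition_time <- as.POSIXct(NA)
  structure(
    list(pixels = px, filename = filename,
         acquisition_time = acquisition_time,
         height_px = dim(px)[1], width_px = dim(px)[2]),
    class = "image_record"
  )
}

#' @export
print.image_record <- function(x, ...) {
  cat(sprintf("<image_record> %s  %d x %d px, RGB 8-bit\n",
              ifelse(is.na(x$filename), "(unnamed)", x$filename),
              x$height_px, x$width_px))
  if (!is.na(x$acquisition_time))
    cat("  acquired:", format(x$acquisition_time, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
        "UTC\n")
  invisible(x)
}

#' @export
dim.image_record <- function(x) dim(x$pixels)

# Accept either an image_record or a bare h x w x 3 array.
as_pixels <- function(image) {
  if (inherits(image, "image_record")) return(image$pixels)
  if (is.array(image) && length(dim(image)) == 3L && dim(image)[3] == 3L)
    return(image)
  br_stop("expected an image_record or a height x width x 3 array",
          "benthicready_image_error")
}

# Rebuild an object of the same kind as `template` from new pixel values.
rewrap <- function(pixels, template) {
  if (inherits(template, "image_record"))
    image_record(pixels, filename = template$filename,
                 acquisition_time = template$acquisition_time)
  else pixels
}

# benthicready stores pixels row-major (h, w, 3) in 0..255; EBImage stores
# (x = col, y = row, channel) in [0, 1]. Converters used at package edges.
to_ebimage <- function(pixels) {
  EBImage::Image(aperm(pixels, c(2L, 1L, 3L)) / 255, colormode = "Color")
}

from_ebimage <- function(img) {
  a <- aperm(EBImage::imageData(img), c(2L, 1L, 3L)) * 255
  a <- round_half_up(pmin(pmax(a, 0), 255))
  storage.mode(a) <- "integer"
  a
}

#' Read a seafloor photograph (JPG or PNG, 8-bit RGB)
#'
#' @param path path to a `.jpg`/`.jpeg`/`.png` file. Images with an alpha
#'   channel or a single (gray) channel are rejected: the pipeline is defined
#'   on 3-channel RGB rasters only.
#' @return an [image_record] whose acquisition time is parsed from the file
#'   name when it follows the naming convention.
#' @export
read_seafloor_image <- function(path) {
  if (!file.exists(path))
    br_stop(paste0("file not found: ", path), "benthicready_io_error")
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) != 3L)
      br_stop(paste0(path, ": grayscale PNG; 8-bit RGB required"),
              "benthicready_io_error")
    if (dim(a)[3] == 4L)
      br_stop(paste0(path, ": PNG has an alpha channel; 8-bit RGB required"),
              "benthicready_io_error")
    px <- round_half_up(a[, , 1:3, drop = FALSE] * 255)
  } else if (ext %in% c("jpg", "jpeg")) {
    img <- EBImage::readImage(path)
    if (length(dim(img)) != 3L || dim(img)[3] < 3L)
      br_stop(paste0(path, ": expected a 3-channel JPG"), "benthicready_io_error")
    px <- from_ebimage(img[, , 1:3])
  } else {
    br_stop(paste0("unsupported image format '.", ext, "' (JPG and PNG only)"),
            "benthicready_io_error")
  }
  image_record(px, filename = basename(path))
}

#' Write a seafloor image to disk
#'
#' PNG output is lossless and byte-reproducible; all intermediate pipeline
#' stages use it. JPG is offered for final export only.
#'
#' @param image an [image_record] or `h x w x 3` array in \[0, 255\].
#' @param path destination; format chosen by extension (`.png`, `.jpg`).
#' @param quality JPG quality (ignored for PNG).
#' @return `path`, invisibly.
#' @export
write_seafloor_image <- function(image, path, quality = 95) {
  px <- as_pixels(image)
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "png") {
    png::writePNG(px / 255, target = path)
  } else if (ext %in% c("jpg", "jpeg")) {
    EBImage::writeImage(to_ebimage(px), path, quality = quality)
  } else {
    br_stop(paste0("unsupported output format '.", ext, "'"),
            "benthicready_io_error")
  }
  invisible(path)
}
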