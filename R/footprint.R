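#' Target scale for footprint standardization
#'
#' The dataset-level target is the median of the per-image scales (even
#' counts: mean of the two central values). Rescaling to the median, rather
#' than the mean, bounds the worst-case resampling factor and is robust to
#' occasional failed scale estimates.
#'
#' @param scales numeric vector of px/cm values, non-empty and positive.
#' @return the median scale, px/cm.
#' @export
compute_target_scale <- function(scales) {
  if (length(scales) == 0L)
    br_stop("cannot compute a target scale from an empty list",
            "benthicready_footprint_error")
  stopifnot(is.numeric(scales), all(is.finite(scales)), all(scales > 0))
  stats::median(scales)
}

#' Rescale an image from its native scale to a target scale
#'
#' Output dimensions are `round(dim * to_scale / from_scale)` (half-up);
#' resampling is bilinear, with anti-aliasing when downscaling. The physical
#' extent of the image in centimeters is preserved to within one output pixel
#' per axis.
#'
#' @param image an [image_record] or array.
#' @param from_scale native scale, px/cm.
#' @param to_scale target scale, px/cm.
#' @return the rescaled image (same type as input).
#' @export
rescale_to_scale <- function(image, from_scale, to_scale) {
  stopifnot(from_scale > 0, to_scale > 0)
  px <- as_pixels(image)
  ratio <- to_scale / from_scale
  nh <- as.integer(round_half_up(dim(px)[1] * ratio))
  nw <- as.integer(round_half_up(dim(px)[2] * ratio))
  if (nh < 8L || nw < 8L)
    br_stop(paste0("rescaling by ", signif(ratio, 4), " would produce a ",
                   nh, "x", nw, " image (< 8 px per axis)"),
            "benthicready_footprint_error")
  if (nh == dim(px)[1] && nw == dim(px)[2]) return(rewrap(px, image))
  eb <- EBImage::resize(to_ebimage(px), w = nw, h = nh,
                        filter = "bilinear", antialias = ratio < 1)
  rewrap(from_ebimage(eb), image)
}

#' Construct a footprint specification
#'
#' @param target_scale_px_per_cm the common scale of the standardized set.
#' @param target_height_px,target_width_px the common pixel dimensions.
#' @return object of class `footprint_spec` whose `footprint_m2` equals
#'   `(h / s) * (w / s) / 1e4` — the physical seafloor area of one image.
#' @examples
#' # the published output geometry: 2240 x 3360 px at 21.5 px/cm ~ 1.6 m^2
#' footprint_spec(21.5, 2240, 3360)$footprint_m2
#' @export
footprint_spec <- function(target_scale_px_per_cm, target_height_px,
                           target_width_px) {
  stopifnot(target_scale_px_per_cm > 0,
            is_count(target_height_px), target_height_px > 0,
            is_count(target_width_px), target_width_px > 0)
  structure(
    list(target_scale_px_per_cm = target_scale_px_per_cm,
         target_height_px = as.integer(target_height_px),
         target_width_px = as.integer(target_width_px),
         footprint_m2 = (target_height_px / target_scale_px_per_cm) *
           (target_width_px / target_scale_px_per_cm) / 1e4),
    class = "footprint_spec")
}

#' @export
print.footprint_spec <- function(x, ...) {
  cat(sprintf("<footprint_spec> %d x %d px at %.4g px/cm = %.3f m^2 on the seafloor\n",
              x$target_height_px, x$target_width_px,
              x$target_scale_px_per_cm, x$footprint_m2))
  invisible(x)
}

#' Derive the common footprint from the rescaled image dimensions
#'
#' The crop target is the elementwise per-axis minimum over all rescaled
#' images — the largest rectangle croppable from every image. (A minimum
#' *area* alone does not determine a rectangle; per-axis minima do, and they
#' preserve the native aspect ratio when all inputs share it.)
#'
#' @param dims a list of `c(height, width)` pairs or a 2-column matrix of
#'   rescaled pixel dimensions.
#' @param target_scale the common scale, px/cm.
#' @return a [footprint_spec()].
#' @export
compute_footprint_spec <- function(dims, target_scale) {
  if (is.list(dims)) dims <- do.call(rbind, dims)
  if (is.null(dims) || nrow(dims) == 0L)
    br_stop("cannot compute a footprint from an empty dimension list",
            "benthicready_footprint_error")
  footprint_spec(target_scale, min(dims[, 1]), min(dims[, 2]))
}

#' Center-crop an image to target dimensions
#'
#' The crop window is centered with floor offsets (`floor((dim - target)/2)`),
#' so for odd margins the top/left side gets the smaller margin. Padding is
#' never performed: a target exceeding the image is an error.
#'
#' @param image an [image_record] or array.
#' @param target_height,target_width output dimensions in pixels.
#' @return the cropped image (same type as input) with an integer attribute
#'   `crop_offsets = c(row, col)` giving the 0-based window origin.
#' @export
center_crop <- function(image, target_height, target_width) {
  px <- as_pixels(image)
  h <- dim(px)[1]; w <- dim(px)[2]
  stopifnot(is_count(target_height), target_height > 0,
            is_count(target_width), target_width > 0)
  if (target_height > h || target_width > w)
    br_stop(paste0("crop target ", target_height, "x", target_width,
                   " exceeds image ", h, "x", w, " (padding is never done)"),
            "benthicready_footprint_error")
  off_r <- floor((h - target_height) / 2)
  off_c <- floor((w - target_width) / 2)
  out <- px[off_r + seq_len(target_height), off_c + seq_len(target_width), ,
            drop = FALSE]
  res <- rewrap(out, image)
  attr(res, "crop_offsets") <- c(row = off_r, col = off_c)
  res
}
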