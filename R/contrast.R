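#' Contrast-limited adaptive histogram equalization
#'
#' Maximizes local contrast by equalizing the intensity histogram within tiles
#' of the image and interpolating between tiles (CLAHE, applied per channel in
#' RGB space). The clip limit bounds how much any histogram bin can be
#' amplified, preventing noise blow-up in flat regions. After equalization,
#' intensities occupy the available 0-255 range far more uniformly, which is
#' what makes low-contrast seafloor images comparable.
#'
#' @param image an [image_record] or `h x w x 3` array in \[0, 255\].
#' @param tile_grid integer `(rows, cols)` of contextual tiles; at least 2 x 2
#'   (default 8 x 8).
#' @param clip_limit contrast-limiting factor (default 2.0); larger values
#'   approach unlimited adaptive equalization.
#' @return the equalized image, same type and shape as the input.
#' @details Dimensions that are not multiples of the tile grid are handled by
#'   edge-replication padding to the next multiple, equalizing, and cropping
#'   back, so any image at least as large as the grid is accepted.
#' @export
equalize_adaptive <- function(image, tile_grid = c(8L, 8L), clip_limit = 2.0) {
  px <- as_pixels(image)
  stopifnot(length(tile_grid) == 2L, all(tile_grid >= 1), clip_limit > 0)
  ty <- as.integer(tile_grid[1])  # tile rows
  tx <- as.integer(tile_grid[2])  # tile cols
  h <- dim(px)[1]; w <- dim(px)[2]
  if (h < ty || w < tx)
    br_stop(paste0("image (", h, "x", w, ") is smaller than the tile grid (",
                   ty, "x", tx, "); use a smaller --tiles grid"),
            "benthicready_contrast_error")
  if (ty < 2L || tx < 2L)
    br_stop("tile_grid must be at least 2x2 (>= 4 contextual regions)",
            "benthicready_contrast_error")
  ph <- ceiling(h / ty) * ty
  pw <- ceiling(w / tx) * tx
  padded <- px[c(seq_len(h), rep(h, ph - h)),
               c(seq_len(w), rep(w, pw - w)), , drop = FALSE]
  eq <- EBImage::clahe(to_ebimage(padded), nx = tx, ny = ty,
                       limit = clip_limit)
  out <- from_ebimage(eq)[seq_len(h), seq_len(w), , drop = FALSE]
  rewrap(out, image)
}
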