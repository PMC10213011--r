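#' Choose the color-normalization reference image
#'
#' The reference is the image with the maximum ground resolution — i.e. the
#' one taken closest to the seafloor, operationalized as the largest
#' pixels-per-centimeter scale. Ties are broken by earliest acquisition time,
#' then by position in the input.
#'
#' @param scales numeric vector of px/cm scale estimates, one per candidate.
#' @param acquired_at optional `POSIXct` vector of acquisition times for
#'   tie-breaking.
#' @return integer index of the selected reference.
#' @export
select_reference <- function(scales, acquired_at = NULL) {
  if (length(scales) == 0L)
    br_stop("cannot select a reference from an empty candidate set",
            "benthicready_colornorm_error")
  stopifnot(is.numeric(scales), all(is.finite(scales)), all(scales > 0))
  best <- which(scales == max(scales))
  if (length(best) > 1L && !is.null(acquired_at))
    best <- best[order(acquired_at[best])]
  best[1L]
}

# Monotone 256-bin CDF-inverse mapping of one channel's histogram onto the
# reference's: level l maps to the lowest reference level whose CDF reaches
# cdf_in(l). findInterval(..., left.open = TRUE) counts reference CDF values
# strictly below cdf_in, which is exactly that level (0-based).
match_channel <- function(ch, ref_ch) {
  cdf_in <- cumsum(tabulate(ch + 1L, 256L)) / length(ch)
  cdf_ref <- cumsum(tabulate(ref_ch + 1L, 256L)) / length(ref_ch)
  map <- findInterval(cdf_in, cdf_ref, left.open = TRUE)
  map <- pmin(map, 255L)
  out <- map[ch + 1L]
  storage.mode(out) <- "integer"
  out
}

#' Match an image's per-channel histograms to a reference image
#'
#' Channel-wise histogram specification: each channel's intensity
#' distribution is transported onto the reference's by the standard monotone
#' CDF-inverse mapping on exact 256-bin histograms. Ties in the reference CDF
#' resolve to the lowest intensity attaining the CDF value. Rank order within
#' a channel is preserved (`in(p) < in(q)` implies `out(p) <= out(q)`), and an
#' image matched to itself is returned unchanged.
#'
#' @param image image to normalize ([image_record] or array).
#' @param reference reference image (8-bit RGB, any size).
#' @return the color-normalized image, same type and shape as `image`.
#' @seealso [select_reference()]
#' @export
match_histograms <- function(image, reference) {
  px <- as_pixels(image)
  ref <- as_pixels(reference)
  out <- px
  for (ch in 1:3) {
    plane <- px[, , ch]
    mapped <- match_channel(as.vector(plane), as.vector(ref[, , ch]))
    out[, , ch] <- array(mapped, dim = dim(plane))
  }
  rewrap(out, image)
}
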