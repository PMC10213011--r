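#' Partition a time-sorted image sequence into batches
#'
#' The light-cone correction z-scores pixel positions *across* images, so the
#' sequence (already sorted by acquisition time) is split into consecutive,
#' non-overlapping batches — 50 images each by default. A small trailing
#' remainder (fewer than `max(2, batch_size / 5)` images) is merged into the
#' previous batch so every batch supports a meaningful per-position standard
#' deviation; larger remainders stay as their own batch.
#'
#' @param images either an integer count or a list/vector whose length is the
#'   number of images, in acquisition-time order.
#' @param batch_size images per batch (>= 2; default 50).
#' @return list of integer index vectors, one per batch, covering
#'   `1:n` consecutively.
#' @examples
#' lengths(partition_batches(103))  # 50, 53
#' @export
partition_batches <- function(images, batch_size = 50L) {
  n <- if (is.numeric(images) && length(images) == 1L) as.integer(images)
       else length(images)
  stopifnot(is_count(batch_size), batch_size >= 2)
  if (n < 2L)
    br_stop("need at least 2 images: the per-position z-score is undefined for a single image",
            "benthicready_batch_error")
  k <- n %/% batch_size
  rem <- n %% batch_size
  if (k == 0L) return(list(seq_len(n)))
  sizes <- rep(batch_size, k)
  if (rem > 0L) {
    if (rem < max(2, batch_size / 5))
      sizes[k] <- sizes[k] + rem
    else
      sizes <- c(sizes, rem)
  }
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-length(ends)] + 1L)
  Map(seq, starts, ends)
}

#' Per-pixel-position z-score over a batch of images
#'
#' The light-cone (vignetting) pattern is a property of the lighting geometry,
#' not the scene, so it is nearly constant across consecutive frames. For
#' every pixel position and channel independently, the batch mean is
#' subtracted and the result scaled to unit population variance; the static
#' illumination pattern cancels while scene content (which varies across
#' frames) is retained. Positions whose standard deviation is below `eps`
#' (static pixels) map to 0.
#'
#' @param batch list of [image_record]s (or `h x w x 3` arrays) with identical
#'   dimensions, length >= 2.
#' @param eps standard-deviation floor on the 0-255 intensity scale below
#'   which a position is treated as constant.
#' @return list with `standardized` (list of real-valued `h x w x 3` arrays,
#'   per-position mean 0 and population variance 1 across the batch wherever
#'   `sd > eps`) and `stats` (class `batch_statistics`: per-position `mean`
#'   and `sd` rasters and `batch_size`).
#' @seealso [remap_to_display()], [correct_light_cone()]
#' @export
zscore_batch <- function(batch, eps = 1e-6) {
  n <- length(batch)
  if (n < 2L)
    br_stop("a batch must contain at least 2 images", "benthicready_batch_error")
  px <- lapply(batch, as_pixels)
  d1 <- dim(px[[1]])
  for (i in seq_along(px)) {
    if (!identical(dim(px[[i]]), d1)) {
      nm <- if (inherits(batch[[i]], "image_record") &&
                !is.na(batch[[i]]$filename)) batch[[i]]$filename
            else paste0("image #", i)
      br_stop(paste0("shape mismatch within batch: ", nm, " is ",
                     paste(dim(px[[i]])[1:2], collapse = "x"),
                     " but the batch is ", paste(d1[1:2], collapse = "x")),
              "benthicready_batch_error")
    }
  }
  X <- array(unlist(px, use.names = FALSE), dim = c(d1, n))
  m <- rowMeans(X, dims = 3L)
  v <- rowMeans((X - c(m))^2, dims = 3L)
  s <- sqrt(pmax(v, 0))
  static <- s <= eps
  denom <- s
  denom[static] <- 1
  standardized <- lapply(seq_len(n), function(i) {
    z <- (px[[i]] - m) / denom
    z[static] <- 0
    z
  })
  list(standardized = standardized,
       stats = structure(list(mean = m, sd = s, batch_size = n),
                         class = "batch_statistics"))
}

#' @export
print.batch_statistics <- function(x, ...) {
  cat(sprintf("<batch_statistics> %d images, %d x %d px; per-position sd in [%.3g, %.3g]\n",
              x$batch_size, dim(x$mean)[1], dim(x$mean)[2],
              min(x$sd), max(x$sd)))
  invisible(x)
}

#' Remap a standardized raster to displayable 8-bit intensities
#'
#' Z-scored values are clipped symmetrically to `[-clip_sigma, +clip_sigma]`
#' and mapped linearly onto \[0, 255\] (rounded half-up), so 0 maps to
#' mid-gray (128) and the map is monotone. `clip_sigma = 3` keeps ~99.7% of a
#' Gaussian-distributed signal inside the linear range.
#'
#' @param z real-valued array from [zscore_batch()].
#' @param clip_sigma symmetric clipping bound in standard-deviation units.
#' @return integer array of the same shape with values in \[0, 255\].
#' @export
remap_to_display <- function(z, clip_sigma = 3) {
  stopifnot(clip_sigma > 0)
  zc <- pmin(pmax(z, -clip_sigma), clip_sigma)
  out <- round_half_up((zc + clip_sigma) / (2 * clip_sigma) * 255)
  storage.mode(out) <- "integer"
  out
}

#' Light-cone correction for a time-sorted image sequence
#'
#' Convenience wrapper over [partition_batches()], [zscore_batch()] and
#' [remap_to_display()]: splits the sequence into batches, z-scores each
#' batch per pixel position and channel, and remaps to 8-bit images.
#'
#' @param images list of [image_record]s sorted by acquisition time.
#' @param batch_size images per batch (default 50).
#' @param clip_sigma display clipping bound (default 3).
#' @inheritParams zscore_batch
#' @return list of corrected [image_record]s in the input order, with a
#'   `batch_id` integer attribute on the list recording each image's batch.
#' @export
correct_light_cone <- function(images, batch_size = 50L, clip_sigma = 3,
                               eps = 1e-6) {
  batches <- partition_batches(images, batch_size)
  out <- vector("list", length(images))
  batch_id <- integer(length(images))
  for (b in seq_along(batches)) {
    idx <- batches[[b]]
    zs <- zscore_batch(images[idx], eps = eps)
    for (j in seq_along(idx)) {
      out[[idx[j]]] <- rewrap(remap_to_display(zs$standardized[[j]],
                                               clip_sigma),
                              images[[idx[j]]])
    }
    batch_id[idx] <- b
  }
  attr(out, "batch_id") <- batch_id
  out
}
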