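#' Detect red laser points in a seafloor image
#'
#' Three downward-pointing red lasers at a calibrated separation are the
#' scale reference in towed-camera imagery. Candidate pixels are those whose
#' redness score `R - max(G, B)` reaches `redness_threshold` — this rejects
#' bright white sediment, which is high in all channels. Candidates are
#' grouped into 8-connected components; components with area in
#' `[min_area, max_area]` pixels become detections. Centroids are returned
#' sorted by area (largest first), truncated to `max_points`.
#'
#' @param image an [image_record] or `h x w x 3` array.
#' @param redness_threshold minimum `R - max(G, B)` (default 80).
#' @param min_area,max_area blob area bounds in pixels (defaults 4 and 500);
#'   the upper bound filters large red objects that cannot be laser dots.
#' @param max_points maximum detections returned (default 3, one per laser).
#' @return object of class `laser_detection`: `points_px` (k x 2 matrix of
#'   (row, col) centroids, possibly 0 rows — an empty detection is a valid
#'   result) and `blob_areas_px`.
#' @seealso [estimate_scale()]
#' @export
detect_laser_points <- function(image, redness_threshold = 80,
                                min_area = 4, max_area = 500,
                                max_points = 3L) {
  px <- as_pixels(image)
  redness <- px[, , 1] - pmax(px[, , 2], px[, , 3])
  mask <- redness >= redness_threshold
  empty <- structure(list(points_px = matrix(numeric(0), 0L, 2L,
                                             dimnames = list(NULL, c("row", "col"))),
                          blob_areas_px = integer(0)),
                     class = "laser_detection")
  if (!any(mask)) return(empty)

  lab <- label_components_8(mask)
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= min_area & areas <= max_area)
  if (length(keep) == 0L) return(empty)

  idx <- which(lab > 0L & matrix(lab %in% keep, nrow(lab)))
  labs <- lab[idx]
  rows <- ((idx - 1L) %% nrow(lab)) + 1L
  cols <- ((idx - 1L) %/% nrow(lab)) + 1L
  cen_r <- tapply(rows, labs, mean)
  cen_c <- tapply(cols, labs, mean)
  a <- areas[as.integer(names(cen_r))]
  ord <- order(a, decreasing = TRUE)
  ord <- ord[seq_len(min(length(ord), max_points))]
  structure(list(points_px = cbind(row = unname(cen_r[ord]),
                                   col = unname(cen_c[ord])),
                 blob_areas_px = as.integer(a[ord])),
            class = "laser_detection")
}

# 8-connected labeling: EBImage's bwlabel is 4-connected, so labels touching
# only diagonally are merged afterwards with a union-find pass.
label_components_8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab4 <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(mask * 1)))))
  storage.mode(lab4) <- "integer"
  nlab <- max(lab4)
  if (nlab <= 1L) return(lab4)
  parent <- seq_len(nlab)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  union2 <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  if (h > 1L && w > 1L) {
    pairs <- rbind(
      cbind(as.vector(lab4[-h, -w]), as.vector(lab4[-1, -1])),  # \ diagonal
      cbind(as.vector(lab4[-1, -w]), as.vector(lab4[-h, -1]))   # / diagonal
    )
    pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
    if (nrow(pairs) > 0L) {
      pairs <- unique(pairs)
      for (i in seq_len(nrow(pairs))) union2(pairs[i, 1], pairs[i, 2])
    }
  }
  roots <- vapply(seq_len(nlab), find, integer(1))
  relabel <- match(roots, sort(unique(roots)))
  out <- lab4
  out[lab4 > 0L] <- relabel[lab4[lab4 > 0L]]
  out
}

#' @export
print.laser_detection <- function(x, ...) {
  cat(sprintf("<laser_detection> %d point(s)\n", nrow(x$points_px)))
  if (nrow(x$points_px) > 0L)
    print(round(cbind(x$points_px, area_px = x$blob_areas_px), 2))
  invisible(x)
}

#' Estimate image scale from detected laser points
#'
#' The scale in pixels/centimeter is the ratio of the photographed laser
#' separation (pixels) to the calibrated physical separation (centimeters),
#' averaged over all point pairs. No layout is assumed: with the standard
#' equilateral three-laser rig all pairs agree, but the pairwise mean is
#' equally valid for two points or an irregular rig.
#'
#' @param detection a `laser_detection` with at least 2 points.
#' @param calibrated_separation_cm physical distance between laser beams on
#'   the seafloor, centimeters (a property of the camera rig).
#' @return object of class `scale_estimate`: `px_per_cm`, `n_points_used`,
#'   `method = "laser"`.
#' @seealso [scale_from_metadata()] for the fallback when detection fails.
#' @export
estimate_scale <- function(detection, calibrated_separation_cm) {
  stopifnot(inherits(detection, "laser_detection"),
            calibrated_separation_cm > 0)
  k <- nrow(detection$points_px)
  if (k < 2L)
    br_stop(paste0("scale unavailable: ", k, " laser point(s) detected, ",
                   "need >= 2 (fall back to the metadata scale)"),
            "benthicready_scale_error")
  d <- stats::dist(detection$points_px)
  structure(list(px_per_cm = mean(d) / calibrated_separation_cm,
                 n_points_used = k,
                 method = "laser"),
            class = "scale_estimate")
}

#' Scale estimate from the metadata's cm/pixel field
#'
#' @param cm_per_px the metadata table's `original_scale_cm_per_px` value.
#' @return a `scale_estimate` with `method = "metadata"`.
#' @export
scale_from_metadata <- function(cm_per_px) {
  stopifnot(is.numeric(cm_per_px), length(cm_per_px) == 1L, cm_per_px > 0)
  structure(list(px_per_cm = 1 / cm_per_px,
                 n_points_used = 0L,
                 method = "metadata"),
            class = "scale_estimate")
}

#' @export
print.scale_estimate <- function(x, ...) {
  cat(sprintf("<scale_estimate> %.4g px/cm (%s, %d point(s))\n",
              x$px_per_cm, x$method, x$n_points_used))
  invisible(x)
}
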