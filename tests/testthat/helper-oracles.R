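# Independent brute-force oracles and small fixture builders. The oracles
# deliberately avoid the package's code paths (explicit loops, no
# findInterval / no vectorized recycling) so they can arbitrate.

# Random 8-bit RGB image as a plain array.
random_rgb <- function(h, w, seed) {
  set.seed(seed)
  a <- array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3))
  storage.mode(a) <- "integer"
  a
}

# Brute-force histogram specification: for every input level, scan the
# reference CDF for the lowest level attaining it.
oracle_match_histograms <- function(img, ref) {
  out <- img
  for (ch in 1:3) {
    x <- as.vector(img[, , ch]); r <- as.vector(ref[, , ch])
    cdf_in <- numeric(256); cdf_ref <- numeric(256)
    for (l in 0:255) {
      cdf_in[l + 1] <- sum(x <= l) / length(x)
      cdf_ref[l + 1] <- sum(r <= l) / length(r)
    }
    map <- integer(256)
    for (l in 0:255) {
      hit <- NA_integer_
      for (r2 in 0:255) {
        if (cdf_ref[r2 + 1] >= cdf_in[l + 1]) { hit <- r2; break }
      }
      map[l + 1] <- if (is.na(hit)) 255L else hit
    }
    plane <- img[, , ch]
    for (i in seq_along(plane)) plane[i] <- map[plane[i] + 1]
    out[, , ch] <- plane
  }
  out
}

# Direct per-position z-score: triple loop over (row, col, channel).
oracle_zscore <- function(arrs, eps = 1e-6) {
  d <- dim(arrs[[1]])
  n <- length(arrs)
  out <- lapply(arrs, function(a) array(0, dim = d))
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (c in seq_len(d[3])) {
    v <- vapply(arrs, function(a) a[i, j, c], numeric(1))
    m <- mean(v)
    s <- sqrt(mean((v - m)^2))
    for (k in seq_len(n))
      out[[k]][i, j, c] <- if (s > eps) (v[k] - m) / s else 0
  }
  out
}

# Empirical sup-distance between the 256-bin CDFs of two channels.
ks_distance_256 <- function(x, y) {
  cx <- cumsum(tabulate(as.vector(x) + 1L, 256L)) / length(x)
  cy <- cumsum(tabulate(as.vector(y) + 1L, 256L)) / length(y)
  max(abs(cx - cy))
}

# Mean intensity of the four 5% corner patches vs the central 5% patch.
corner_center_ratio <- function(px) {
  h <- dim(px)[1]; w <- dim(px)[2]
  ph <- max(1, round(0.05 * h)); pw <- max(1, round(0.05 * w))
  corners <- c(mean(px[1:ph, 1:pw, ]),
               mean(px[1:ph, (w - pw + 1):w, ]),
               mean(px[(h - ph + 1):h, 1:pw, ]),
               mean(px[(h - ph + 1):h, (w - pw + 1):w, ]))
  cy <- (h %/% 2); cx <- (w %/% 2)
  center <- mean(px[(cy - ph %/% 2):(cy + ph %/% 2),
                    (cx - pw %/% 2):(cx + pw %/% 2), ])
  mean(corners) / center
}

pop_var_ <- function(x) mean((x - mean(x))^2)

# Write a transect's scenes as PNGs into a directory; returns the dir.
write_transect_pngs <- function(tr, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (im in tr$images)
    write_seafloor_image(im, file.path(dir, sub("\\.JPG$", ".png", im$filename)))
  dir
}
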