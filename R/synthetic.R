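#' Parameters for a synthetic seafloor scene
#'
#' Describes one simulated photograph of nodule-covered abyssal sediment taken
#' by a towed camera with artificial lighting. The simulated degradations are
#' exactly the ones the pipeline corrects: radial illumination falloff
#' (light cone), a blue-green color cast, low local contrast, and an
#' altitude-dependent scale. Three red laser dots at a known separation are
#' stamped for scale estimation. Identical parameters (including `seed`)
#' produce a bit-identical raster.
#'
#' The scale model is pinhole proportionality:
#' `true_scale_px_per_cm = base_scale_px_per_cm_at_1m / altitude_m`.
#' The vignette is a multiplicative radial Gaussian falloff
#' `1 - strength * (1 - exp(-(r/R)^2))` with `r` the distance from the image
#' center and `R = vignette_radius_frac * half_diagonal`.
#'
#' @param seed integer seed driving all randomness in the scene.
#' @param width_px,height_px frame size in pixels (3:2 default mirrors a
#'   full-frame DSLR aspect).
#' @param altitude_m camera altitude above the seafloor, meters.
#' @param base_scale_px_per_cm_at_1m scale the camera would deliver at 1 m.
#' @param vignette_strength fraction of brightness lost far from the center,
#'   in \[0, 1\]; 0 disables the light cone.
#' @param vignette_radius_frac falloff radius as a fraction of the
#'   half-diagonal.
#' @param color_cast per-channel multipliers (r, g, b) in (0, 1\]; the default
#'   attenuates red most, as seawater does.
#' @param nodule_density_per_m2 expected manganese-nodule count per square
#'   meter of imaged seafloor.
#' @param nodule_radius_cm length-2 range of nodule radii, cm.
#' @param laser_separation_cm side length of the equilateral laser triangle on
#'   the seafloor, cm.
#' @param laser_dot_radius_px radius of each stamped laser dot, pixels.
#' @param noise_sd per-pixel Gaussian sensor noise, intensity units.
#' @param texture_amplitude amplitude (sd, intensity units) of the smooth
#'   sediment texture field; 0 gives a flat background.
#' @param background_mean mean sediment intensity before cast/vignette,
#'   in \[0, 255\].
#' @return a list of class `scene_params`.
#' @seealso [generate_scene()], [generate_transect()]
#' @export
scene_params <- function(seed = 1L,
                         width_px = 360L, height_px = 240L,
                         altitude_m = 1.6,
                         base_scale_px_per_cm_at_1m = 30,
                         vignette_strength = 0.6,
                         vignette_radius_frac = 0.7,
                         color_cast = c(r = 0.55, g = 0.90, b = 1.00),
                         nodule_density_per_m2 = 150,
                         nodule_radius_cm = c(0.8, 2.5),
                         laser_separation_cm = 5,
                         laser_dot_radius_px = 3L,
                         noise_sd = 3,
                         texture_amplitude = 12,
                         background_mean = 150) {
  stopifnot(is_count(seed),
            is_count(width_px), width_px > 0,
            is_count(height_px), height_px > 0,
            altitude_m > 0, base_scale_px_per_cm_at_1m > 0,
            vignette_strength >= 0, vignette_strength <= 1,
            vignette_radius_frac > 0,
            length(color_cast) == 3L, all(color_cast > 0), all(color_cast <= 1),
            nodule_density_per_m2 >= 0,
            length(nodule_radius_cm) == 2L, all(nodule_radius_cm > 0),
            laser_separation_cm > 0,
            is_count(laser_dot_radius_px), laser_dot_radius_px > 0,
            noise_sd >= 0, texture_amplitude >= 0,
            background_mean >= 0, background_mean <= 255)
  structure(as.list(environment()), class = "scene_params")
}

# Smooth sediment texture: coarse white-noise grid upsampled bilinearly.
sediment_texture <- function(h, w, amplitude) {
  if (amplitude == 0) return(matrix(0, h, w))
  ch <- max(2L, round(h / 30)); cw <- max(2L, round(w / 30))
  coarse <- matrix(stats::rnorm(ch * cw, sd = amplitude), ch, cw)
  fine <- EBImage::resize(EBImage::Image(t(coarse)), w = w, h = h,
                          filter = "bilinear")
  t(EBImage::imageData(fine))
}

#' Generate one ground-truthed synthetic seafloor photograph
#'
#' Builds the raster as
#' `clip([textured sediment + dark elliptical nodules] * vignette * cast
#'  + noise, 0..255)`, then stamps three pure-red laser dots (R = 255,
#' G = B = 0) at an equilateral triangle centered mid-image, with side length
#' `laser_separation_cm * true_scale_px_per_cm`.
#'
#' @param params a [scene_params()] object.
#' @return list with `image` (an [image_record]) and `truth` (class
#'   `ground_truth`): `true_scale_px_per_cm`, the exact (sub-pixel) laser dot
#'   centers `laser_points_px` as a 3 x 2 (row, col) matrix, the vignette and
#'   cast parameters, and `nodule_centers_px`.
#' @examples
#' sc <- generate_scene(scene_params(seed = 7))
#' sc$truth$true_scale_px_per_cm
#' @export
generate_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  p <- params
  h <- p$height_px; w <- p$width_px
  scale <- p$base_scale_px_per_cm_at_1m / p$altitude_m

  # Laser geometry first: fail before any work if the dots cannot fit.
  side_px <- p$laser_separation_cm * scale
  circum <- side_px / sqrt(3)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  ang <- c(-pi / 2, pi / 6, 5 * pi / 6)  # one vertex pointing up
  pts <- cbind(row = cy + circum * sin(ang), col = cx + circum * cos(ang))
  pad <- p$laser_dot_radius_px
  if (any(pts[, 1] < 1 + pad | pts[, 1] > h - pad |
          pts[, 2] < 1 + pad | pts[, 2] > w - pad))
    br_stop(paste0("laser dots fall outside the ", h, "x", w, " raster at ",
                   signif(scale, 4), " px/cm; reduce laser_separation_cm or ",
                   "use a lower scale (higher altitude)"),
            "benthicready_synthetic_error")

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(p$seed)

  base <- p$background_mean + sediment_texture(h, w, p$texture_amplitude)

  # Nodules: dark ellipses, count ~ Poisson(density * imaged area).
  area_m2 <- (h / scale) * (w / scale) / 1e4
  n_nod <- stats::rpois(1L, p$nodule_density_per_m2 * area_m2)
  centers <- NULL
  if (n_nod > 0L) {
    rr_px <- stats::runif(n_nod, p$nodule_radius_cm[1], p$nodule_radius_cm[2]) * scale
    ctr_r <- stats::runif(n_nod, 1, h)
    ctr_c <- stats::runif(n_nod, 1, w)
    aspect <- stats::runif(n_nod, 0.65, 1)
    theta <- stats::runif(n_nod, 0, pi)
    dark <- stats::runif(n_nod, 25, 55)
    rows <- row(base); cols <- col(base)
    for (k in seq_len(n_nod)) {
      dr <- rows - ctr_r[k]; dc <- cols - ctr_c[k]
      u <- dr * cos(theta[k]) + dc * sin(theta[k])
      v <- -dr * sin(theta[k]) + dc * cos(theta[k])
      inside <- (u / rr_px[k])^2 + (v / (rr_px[k] * aspect[k]))^2 <= 1
      base[inside] <- dark[k]
    }
    centers <- cbind(row = ctr_r, col = ctr_c)
  }

  # Vignette (shared by all channels) and sediment tint.
  half_diag <- sqrt(((h - 1) / 2)^2 + ((w - 1) / 2)^2)
  R <- p$vignette_radius_frac * half_diag
  r2 <- (row(base) - cy)^2 + (col(base) - cx)^2
  vignette <- 1 - p$vignette_strength * (1 - exp(-r2 / R^2))
  tint <- c(1, 0.96, 0.88)  # slightly brownish sediment before the water cast

  arr <- array(0, dim = c(h, w, 3L))
  for (ch in 1:3)
    arr[, , ch] <- base * tint[ch] * vignette * p$color_cast[ch]
  if (p$noise_sd > 0)
    arr <- arr + array(stats::rnorm(h * w * 3L, sd = p$noise_sd),
                       dim = c(h, w, 3L))
  arr <- round_half_up(pmin(pmax(arr, 0), 255))

  # Stamp the laser dots last so they are unobstructed and saturated red.
  rows <- row(arr[, , 1]); cols <- col(arr[, , 1])
  for (k in 1:3) {
    disk <- (rows - pts[k, 1])^2 + (cols - pts[k, 2])^2 <= pad^2
    for (ch in 1:3) {
      plane <- arr[, , ch]
      plane[disk] <- if (ch == 1L) 255 else 0
      arr[, , ch] <- plane
    }
  }

  truth <- structure(
    list(true_scale_px_per_cm = scale,
         laser_points_px = pts,
         vignette = list(strength = p$vignette_strength,
                         radius_frac = p$vignette_radius_frac),
         color_cast = p$color_cast,
         nodule_centers_px = centers,
         params = p),
    class = "ground_truth")
  list(image = image_record(arr), truth = truth)
}

#' Generate a synthetic photo transect
#'
#' Simulates a towed-camera deployment: `n` scenes with altitude drawn
#' uniformly from `altitude_range` (so the scale varies as `1/altitude`),
#' per-image brightness and color-cast jitter (the heterogeneous scene
#' brightness that color normalization removes), timestamps 10 s apart (the
#' camera's 0.1 Hz capture frequency), and file names following the
#' `<cruise_station_platform_date_time.JPG>` convention. A metadata table in
#' the standard schema is built alongside.
#'
#' @param n number of images (>= 1).
#' @param seed integer; all randomness (altitudes, jitters, per-scene seeds)
#'   derives from it.
#' @param altitude_range length-2 range of altitudes, meters.
#' @param params base [scene_params()]; per-scene altitude, seed,
#'   `background_mean` and `color_cast` are overridden by the transect drift.
#' @param brightness_jitter half-width of the uniform per-image
#'   `background_mean` drift (intensity units).
#' @param cast_jitter half-width of the uniform per-image cast drift applied
#'   to each channel multiplier.
#' @param cruise,station,platform tokens for the file names.
#' @param start_time `POSIXct` UTC time of the first frame.
#' @return list of class `synthetic_transect`: `images` (list of
#'   [image_record]), `truths` (list of `ground_truth`), and `metadata`
#'   (a `dataset_index`).
#' @export
generate_transect <- function(n, seed = 1L,
                              altitude_range = c(1, 3),
                              params = scene_params(),
                              brightness_jitter = 25,
                              cast_jitter = 0.12,
                              cruise = "SYN268", station = "100-1",
                              platform = "OFOS",
                              start_time = as.POSIXct("2019-03-04 09:35:10",
                                                      tz = "UTC")) {
  stopifnot(is_count(n), n >= 1, is_count(seed),
            length(altitude_range) == 2L, all(altitude_range > 0),
            inherits(params, "scene_params"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  altitudes <- stats::runif(n, altitude_range[1], altitude_range[2])
  bg <- pmin(pmax(params$background_mean +
                    stats::runif(n, -brightness_jitter, brightness_jitter),
                  30), 240)
  cast <- matrix(stats::runif(3L * n, -cast_jitter, cast_jitter), n, 3L)
  cast <- sweep(cast, 2L, as.numeric(params$color_cast), `+`)
  cast <- pmin(pmax(cast, 0.05), 1)
  # Per-scene seeds spread out deterministically; kept far below 2^31.
  scene_seeds <- (as.integer(seed) %% 1000000L) * 1000L + seq_len(n)

  images <- vector("list", n)
  truths <- vector("list", n)
  times <- start_time + 10 * (seq_len(n) - 1L)
  lat0 <- 12.6; lon0 <- -119.98  # CCZ working area
  classes <- sample(SEAFLOOR_CLASSES, n, replace = TRUE,
                    prob = c(0.05, 0.50, 0.30, 0.15))
  scores <- stats::runif(n, 0.6, 1)
  for (i in seq_len(n)) {
    p <- params
    p$seed <- scene_seeds[i]
    p$altitude_m <- altitudes[i]
    p$background_mean <- bg[i]
    p$color_cast <- cast[i, ]
    sc <- generate_scene(p)
    fname <- build_image_filename(cruise = cruise, station = station,
                                  platform = platform,
                                  acquisition_time = times[i])
    sc$image$filename <- fname
    sc$image$acquisition_time <- times[i]
    images[[i]] <- sc$image
    truths[[i]] <- sc$truth
  }
  rec <- data.frame(
    image_name = vapply(images, function(im) im$filename, character(1)),
    contract_area = "German",
    depth_m = 4250,
    latitude = lat0 + (seq_len(n) - 1L) * 2e-5,
    longitude = lon0 + (seq_len(n) - 1L) * 1e-5,
    acquired_at = times,
    original_scale_cm_per_px =
      1 / vapply(truths, function(tr) tr$true_scale_px_per_cm, numeric(1)),
    seafloor_class = classes,
    class_score = scores,
    stringsAsFactors = FALSE
  )
  structure(list(images = images, truths = truths,
                 metadata = structure(list(records = rec,
                                           col_map = metadata_columns()),
                                      class = "dataset_index")),
            class = "synthetic_transect")
}

#' @export
print.synthetic_transect <- function(x, ...) {
  n <- length(x$images)
  sc <- vapply(x$truths, function(tr) tr$true_scale_px_per_cm, numeric(1))
  cat(sprintf("<synthetic_transect> %d scene(s), %d x %d px, scale %.1f-%.1f px/cm\n",
              n, x$images[[1]]$height_px, x$images[[1]]$width_px,
              min(sc), max(sc)))
  invisible(x)
}
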