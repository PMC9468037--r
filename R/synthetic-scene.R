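#' Class presets for the synthetic nodule seafloor
#'
#' Densities (nodules per m2 of seabed) and physical radii (lognormal, cm)
#' for the four substrate classes: A sediment with no or few nodules, B
#' nodule patches partly covering the seabed, C densely distributed nodules,
#' D qualitatively large nodules. Densities are strictly ordered A < B < C
#' and D has the largest radius.
#'
#' @return named list of per-class `list(density, radius_cm = c(meanlog-scale
#'   mean in cm, sdlog))`.
#' @export
seafloor_class_presets <- function() {
  list(
    A = list(density = 3,   radius_cm = c(2.0, 0.30)),
    B = list(density = 30,  radius_cm = c(2.5, 0.35)),
    C = list(density = 120, radius_cm = c(2.5, 0.35)),
    D = list(density = 25,  radius_cm = c(6.0, 0.30))
  )
}

#' Parameters of a synthetic seafloor scene
#'
#' The generator states a simple physical world: a pinhole camera at
#' `altitude_m` above a sediment plain scattered with dark elliptical
#' nodules, lit by a centered source (radial vignette plus exponential
#' attenuation with altitude), with three red laser dots projected in an
#' equilateral triangle of real-world side `laser_spacing_cm`. The image
#' scale follows `scale = focal_scale / altitude_m` (px/cm); the default
#' `focal_scale` reproduces the survey working resolution of 43.2 px/cm at
#' 1 m and 21.6 px/cm at 2 m on a full 4480 x 6720 frame. The default frame
#' here is a quarter of that (1120 x 1680) with `focal_scale` scaled to
#' match, so renders stay fast; pass `width = 4480, height = 6720,
#' focal_scale = 43.2` for full size.
#'
#' @param width,height frame size in px (width = columns).
#' @param altitude_m camera altitude above the seafloor, > 0.
#' @param laser_spacing_cm real-world laser separation (default 40).
#' @param focal_scale px.m/cm constant: scale = focal_scale / altitude_m.
#' @param seafloor_class one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param nodule_density nodules per m2; default from the class preset.
#' @param nodule_radius_cm length-2 `c(mean_cm, sdlog)` of the lognormal
#'   nodule radius; default from the class preset.
#' @param vignette_strength radial darkening factor in `[0, 1]`.
#' @param brightness_jitter multiplicative global brightness factor.
#' @param attenuation_per_m light loss per meter of altitude (exponential).
#' @param laser_dot_radius_px rendered laser dot radius in px.
#' @param noise_sd additive Gaussian sensor/texture noise (intensity levels).
#' @param rng_seed integer seed; fixed seed gives bit-identical renders.
#' @return object of class `scene_params`.
#' @export
scene_params <- function(width = 1120, height = 1680, altitude_m = 2,
                         laser_spacing_cm = 40, focal_scale = 10.8,
                         seafloor_class = "B",
                         nodule_density = NULL, nodule_radius_cm = NULL,
                         vignette_strength = 0.5, brightness_jitter = 1,
                         attenuation_per_m = 0.15, laser_dot_radius_px = 5,
                         noise_sd = 6, rng_seed = 1L) {
  seafloor_class <- match.arg(seafloor_class, c("A", "B", "C", "D"))
  preset <- seafloor_class_presets()[[seafloor_class]]
  if (is.null(nodule_density)) nodule_density <- preset$density
  if (is.null(nodule_radius_cm)) nodule_radius_cm <- preset$radius_cm
  stopifnot(altitude_m > 0, width >= 16, height >= 16,
            laser_spacing_cm > 0, focal_scale > 0,
            vignette_strength >= 0, vignette_strength <= 1,
            nodule_density >= 0, length(nodule_radius_cm) == 2L,
            all(nodule_radius_cm > 0), brightness_jitter > 0)
  structure(list(
    width = as.integer(width), height = as.integer(height),
    altitude_m = altitude_m, laser_spacing_cm = laser_spacing_cm,
    focal_scale = focal_scale, seafloor_class = seafloor_class,
    nodule_density = nodule_density, nodule_radius_cm = nodule_radius_cm,
    vignette_strength = vignette_strength,
    brightness_jitter = brightness_jitter,
    attenuation_per_m = attenuation_per_m,
    laser_dot_radius_px = laser_dot_radius_px,
    noise_sd = noise_sd, rng_seed = as.integer(rng_seed)
  ), class = "scene_params")
}

# anti-aliased coverage of an (possibly rotated, elliptical) disc: 1 inside,
# linear falloff across one pixel at the boundary
.disc_coverage <- function(nr, nc, cy, cx, ry, rx = ry, theta = 0) {
  r0 <- max(1L, floor(cy - max(ry, rx) - 2)); r1 <- min(nr, ceiling(cy + max(ry, rx) + 2))
  c0 <- max(1L, floor(cx - max(ry, rx) - 2)); c1 <- min(nc, ceiling(cx + max(ry, rx) + 2))
  if (r0 > r1 || c0 > c1) return(NULL)
  yy <- (r0:r1) - cy
  xx <- (c0:c1) - cx
  ct <- cos(theta); st <- sin(theta)
  # rotated coordinates (rows = y down, cols = x right)
  u <- outer(yy * st, rep(1, length(xx))) + outer(rep(1, length(yy)), xx * ct)
  v <- outer(yy * ct, rep(1, length(xx))) + outer(rep(1, length(yy)), xx * -st)
  d <- sqrt((u / rx)^2 + (v / ry)^2)
  # signed distance approx in px units at the boundary
  alpha <- clamp((1 - d) * min(rx, ry) + 0.5, 0, 1)
  list(rows = r0:r1, cols = c0:c1, alpha = alpha)
}

#' Render one synthetic seafloor photograph with ground truth
#'
#' @param params a [scene_params()] object.
#' @return list with `image` (height x width x 3 array, integer-valued 0..255)
#'   and `truth`: `true_scale_px_per_cm`, `true_laser_points` (3 x 2 matrix,
#'   columns x = column, y = row, 1-based pixel coordinates),
#'   `true_class`, `illumination_field` (per-pixel multiplier),
#'   `altitude_m`, `n_nodules`.
#' @details The laser triangle is equilateral with pixel side
#'   `laser_spacing_cm * scale`, centered in the frame; an altitude putting
#'   any dot outside the frame raises the error "lasers out of frame".
#' @export
render_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  p <- params
  set.seed(p$rng_seed)
  nr <- p$height; nc <- p$width
  s <- p$focal_scale / p$altitude_m  # px/cm

  # laser geometry first so impossible altitudes fail before any work
  side <- p$laser_spacing_cm * s
  circum <- side / sqrt(3)
  cx <- (nc + 1) / 2; cy <- (nr + 1) / 2
  ang <- c(-pi / 2, -pi / 2 + 2 * pi / 3, -pi / 2 + 4 * pi / 3)
  lp <- cbind(x = cx + circum * cos(ang), y = cy + circum * sin(ang))
  pad <- p$laser_dot_radius_px + 1
  if (any(lp[, 1] < pad) || any(lp[, 1] > nc - pad + 1) ||
      any(lp[, 2] < pad) || any(lp[, 2] > nr - pad + 1)) {
    stop("lasers out of frame")
  }

  # sediment base with sensor/texture noise
  base_col <- c(160, 150, 135)
  img <- array(0, c(nr, nc, 3))
  for (ch in 1:3) {
    img[, , ch] <- base_col[ch] + matrix(rnorm(nr * nc, 0, p$noise_sd), nr, nc)
  }

  # nodules: physical density per m2, physical lognormal radius in cm
  area_m2 <- (nc / s) * (nr / s) / 1e4
  n_nod <- if (p$nodule_density > 0) rpois(1, p$nodule_density * area_m2) else 0L
  if (n_nod > 0) {
    ys <- runif(n_nod, 1, nr); xs <- runif(n_nod, 1, nc)
    rad_px <- rlnorm(n_nod, log(p$nodule_radius_cm[1]), p$nodule_radius_cm[2]) * s
    aspect <- runif(n_nod, 0.6, 1)
    theta <- runif(n_nod, 0, pi)
    shade <- runif(n_nod, 0.8, 1.2)
    for (i in seq_len(n_nod)) {
      d <- .disc_coverage(nr, nc, ys[i], xs[i], rad_px[i],
                          rad_px[i] * aspect[i], theta[i])
      if (is.null(d)) next
      nod_col <- c(46, 42, 38) * shade[i]
      for (ch in 1:3) {
        blk <- img[d$rows, d$cols, ch]
        img[d$rows, d$cols, ch] <- blk * (1 - d$alpha) + nod_col[ch] * d$alpha
      }
    }
  }

  # illumination: radial vignette x exponential altitude attenuation x jitter
  rr <- ((seq_len(nr) - cy) / (nr / 2))^2
  cc2 <- ((seq_len(nc) - cx) / (nc / 2))^2
  # normalized squared radius, 1 at the frame corners; the light pool
  # saturates to full darkening at ~70% of the corner distance, as on a
  # centered-light deep-sea frame
  rad2 <- outer(rr, cc2, `+`) / 2
  vig <- 1 - p$vignette_strength * clamp(rad2 / 0.7, 0, 1)
  glob <- exp(-p$attenuation_per_m * p$altitude_m) * p$brightness_jitter
  illum <- vig * glob
  for (ch in 1:3) img[, , ch] <- img[, , ch] * illum

  # laser dots: saturated red, drawn on top of the illuminated scene
  laser_col <- c(255, 40, 40)
  for (i in 1:3) {
    d <- .disc_coverage(nr, nc, lp[i, "y"], lp[i, "x"], p$laser_dot_radius_px)
    for (ch in 1:3) {
      blk <- img[d$rows, d$cols, ch]
      img[d$rows, d$cols, ch] <- blk * (1 - d$alpha) + laser_col[ch] * d$alpha
    }
  }

  img <- quantize8(img)
  truth <- list(
    true_scale_px_per_cm = s,
    true_laser_points = lp,
    true_class = p$seafloor_class,
    illumination_field = illum,
    altitude_m = p$altitude_m,
    n_nodules = n_nod
  )
  list(image = img, truth = truth)
}

#' Generate a synthetic towed-camera survey on disk
#'
#' Renders `n_images` scenes along a straight tow track, writes one PNG per
#' image plus a navigation table and a ground-truth table, and echoes all
#' generation parameters to a YAML sidecar. Acquisition emulates a towed
#' platform photographing every `interval_s` seconds at altitudes drawn
#' uniformly from `altitude_range` (default 1-4 m).
#'
#' @param out_dir output directory (created if needed).
#' @param class_sequence character vector of per-image classes (A-D); its
#'   length sets the number of images.
#' @param start_lonlat,end_lonlat numeric `c(lon, lat)` of the track ends.
#' @param interval_s seconds between consecutive images (default 10); must
#'   be positive so timestamps are strictly increasing.
#' @param start_time POSIXct UTC of the first image.
#' @param altitude_range length-2 range of camera altitudes in meters.
#' @param jitter_range range of the per-image global brightness factor.
#' @param base_params [scene_params()] supplying frame size, optics and
#'   rendering parameters shared by all images.
#' @param seed integer; all per-image seeds derive from it.
#' @return (invisibly) list with `images` (paths), `nav`, `truth`
#'   data frames and the files written (`nav_csv`, `truth_csv`, `sidecar`).
#' @export
generate_survey <- function(out_dir, class_sequence,
                            start_lonlat = c(-125.00, 14.00),
                            end_lonlat = c(-125.02, 14.02),
                            interval_s = 10,
                            start_time = as.POSIXct("2019-04-01 00:00:00",
                                                    tz = "UTC"),
                            altitude_range = c(1, 4),
                            jitter_range = c(0.75, 1.25),
                            base_params = scene_params(),
                            seed = 1L) {
  n <- length(class_sequence)
  stopifnot(n >= 1, all(class_sequence %in% c("A", "B", "C", "D")))
  if (interval_s <= 0) stop("non-monotone timestamps: interval_s must be > 0")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  altitudes <- runif(n, altitude_range[1], altitude_range[2])
  jitters <- runif(n, jitter_range[1], jitter_range[2])
  img_seeds <- (as.integer(seed) %% 100000L) * 10000L + seq_len(n)

  ids <- sprintf("img_%04d", seq_len(n))
  ts <- start_time + (seq_len(n) - 1) * interval_s
  frac <- if (n == 1) 0 else (seq_len(n) - 1) / (n - 1)
  nav <- data.frame(
    timestamp_utc = format(ts, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    latitude = start_lonlat[2] + frac * (end_lonlat[2] - start_lonlat[2]),
    longitude = start_lonlat[1] + frac * (end_lonlat[1] - start_lonlat[1])
  )

  paths <- character(n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    p <- base_params
    p$altitude_m <- altitudes[i]
    p$seafloor_class <- class_sequence[i]
    preset <- seafloor_class_presets()[[class_sequence[i]]]
    p$nodule_density <- preset$density
    p$nodule_radius_cm <- preset$radius_cm
    p$brightness_jitter <- jitters[i]
    p$rng_seed <- img_seeds[i]
    sc <- render_scene(p)
    paths[i] <- file.path(out_dir, paste0(ids[i], ".png"))
    write_image(sc$image, paths[i])
    truth[[i]] <- data.frame(
      image_id = ids[i], class = class_sequence[i],
      altitude_m = altitudes[i],
      scale_px_per_cm = sc$truth$true_scale_px_per_cm,
      lp1_x = sc$truth$true_laser_points[1, 1],
      lp1_y = sc$truth$true_laser_points[1, 2],
      lp2_x = sc$truth$true_laser_points[2, 1],
      lp2_y = sc$truth$true_laser_points[2, 2],
      lp3_x = sc$truth$true_laser_points[3, 1],
      lp3_y = sc$truth$true_laser_points[3, 2]
    )
  }
  truth <- do.call(rbind, truth)
  nav_csv <- file.path(out_dir, "nav.csv")
  truth_csv <- file.path(out_dir, "truth.csv")
  write.csv(nav, nav_csv, row.names = FALSE)
  write.csv(truth, truth_csv, row.names = FALSE)
  sidecar <- file.path(out_dir, "survey_params.yaml")
  yaml::write_yaml(list(
    n_images = n, seed = as.integer(seed), interval_s = interval_s,
    altitude_range = altitude_range, jitter_range = jitter_range,
    start_lonlat = start_lonlat, end_lonlat = end_lonlat,
    classes = as.list(table(class_sequence)),
    base_params = unclass(base_params)
  ), sidecar)
  invisible(list(images = paths, ids = ids, nav = nav, truth = truth,
                 nav_csv = nav_csv, truth_csv = truth_csv, sidecar = sidecar))
}
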