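#' Laser template from one hand-annotated image
#'
#' One image with well visible laser points is annotated once per
#' deployment; the three annotated points define the expected laser
#' geometry: a triangular search mask (dilated by `buffer_px`) and the
#' expected mean pairwise pixel distance `expected_pairwise_px`, which sets
#' the minimum peak separation during detection.
#'
#' Pixel coordinate convention: `x` = column, `y` = row, 1-based (R array
#' indexing), used consistently for annotations, detections and truth.
#'
#' @param points 3 x 2 numeric matrix (columns x, y) of annotated laser
#'   points; must be three distinct points.
#' @param buffer_px mask dilation radius in px (default 250, chosen for the
#'   full-resolution 4480 x 6720 frame; scale down with the frame).
#' @param known_spacing_cm real-world laser separation (default 40).
#' @return object of class `laser_template`.
#' @export
laser_template <- function(points, buffer_px = 250, known_spacing_cm = 40) {
  points <- as.matrix(points)
  stopifnot(nrow(points) == 3L, ncol(points) == 2L, buffer_px >= 0,
            known_spacing_cm > 0)
  colnames(points) <- c("x", "y")
  d <- as.numeric(stats::dist(points))
  if (any(d == 0)) stop("annotated points must be distinct")
  structure(list(
    annotated_points = points,
    buffer_px = buffer_px,
    known_spacing_cm = known_spacing_cm,
    expected_pairwise_px = mean(d)
  ), class = "laser_template")
}

#' Laser signal image
#'
#' Per-pixel `R - coeff * (B + G)` in signed arithmetic: red laser dots give
#' strongly positive values, blue/green-dominated pixels go negative and are
#' retained (no unsigned wraparound). A coefficient of 0.2 is the default
#' working value; 0 returns the red channel unchanged.
#'
#' @param image RGB array (0..255).
#' @param coeff scalar in `[0, 1]`.
#' @return numeric matrix (signed).
#' @export
laser_signal <- function(image, coeff = 0.2) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("three channels required")
  stopifnot(coeff >= 0, coeff <= 1)
  image[, , 1] - coeff * (image[, , 3] + image[, , 2])
}

#' Triangular laser search mask
#'
#' Filled triangle through the template's annotated points, dilated by the
#' template buffer (Euclidean), clipped to the frame. The same mask is
#' reused for every image of a deployment.
#'
#' @param template a [laser_template()].
#' @param image_shape `c(height, width)`.
#' @return logical matrix of that shape.
#' @export
build_mask <- function(template, image_shape) {
  stopifnot(inherits(template, "laser_template"), length(image_shape) >= 2L)
  nr <- image_shape[1]; nc <- image_shape[2]
  p <- template$annotated_points
  if (any(p[, "x"] < 1 | p[, "x"] > nc | p[, "y"] < 1 | p[, "y"] > nr))
    stop("annotated points outside image")
  # twice the signed triangle area; ~0 means collinear annotations
  area2 <- (p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
           (p[3, 1] - p[1, 1]) * (p[2, 2] - p[1, 2])
  if (abs(area2) < 1e-9) stop("degenerate triangle")

  xs <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  ys <- matrix(rep(seq_len(nr), nc), nr, nc)
  # signed edge distances; inside when all have the sign of the area
  sgn <- sign(area2)
  edge <- function(a, b) {
    sgn * ((b[1] - a[1]) * (ys - a[2]) - (b[2] - a[2]) * (xs - a[1]))
  }
  e1 <- edge(p[1, ], p[2, ]); e2 <- edge(p[2, ], p[3, ]); e3 <- edge(p[3, ], p[1, ])
  inside <- e1 >= 0 & e2 >= 0 & e3 >= 0
  if (template$buffer_px == 0) return(inside)

  # Euclidean distance to the nearest triangle edge segment, vectorized
  seg_d2 <- function(a, b) {
    vx <- b[1] - a[1]; vy <- b[2] - a[2]
    tt <- clamp(((xs - a[1]) * vx + (ys - a[2]) * vy) / (vx^2 + vy^2), 0, 1)
    (xs - a[1] - tt * vx)^2 + (ys - a[2] - tt * vy)^2
  }
  d2 <- pmin(seg_d2(p[1, ], p[2, ]), seg_d2(p[2, ], p[3, ]),
             seg_d2(p[3, ], p[1, ]))
  inside | d2 <= template$buffer_px^2
}

#' Detect the three laser points in one image
#'
#' Runs on the original (not contrast-enhanced) image: local maxima of the
#' [laser_signal()] are thinned to a minimum mutual separation of
#' `min_sep_fraction * expected_pairwise_px`, must exceed a robust signal
#' floor (`median + floor_factor * MAD` of the signal, and be positive),
#' and are filtered to the buffered triangular mask; the top three surviving
#' peaks (by signal value) are refined to sub-pixel precision by a local
#' signal-weighted centroid. Zero detected points is a valid outcome
#' (lasers off, flag `"unscaled"`), never an error.
#'
#' @param image RGB array (0..255).
#' @param template a [laser_template()].
#' @param coeff laser-signal coefficient (default 0.2).
#' @param min_sep_fraction fraction of the template pairwise distance used
#'   as minimum peak separation (default 0.4; laser spacing shrinks with
#'   altitude, so requiring the full template distance rejects valid
#'   high-altitude detections).
#' @param floor_factor MAD multiplier of the signal floor (default 5).
#' @param refine logical; sub-pixel centroid refinement (default TRUE).
#' @param refine_radius half-width of the refinement window in px.
#' @param mask optional precomputed mask from [build_mask()] (the mask is
#'   constant per deployment, so precomputing it once is the fast path).
#' @return object of class `laser_detection`: `points` (n x 2, columns x,
#'   y), `pairwise_distances` (choose(n, 2) values), `n_found`,
#'   `scale_px_per_cm` (NA when fewer than two points), `flag` (`"ok"` or
#'   `"unscaled"`).
#' @export
detect_laser_points <- function(image, template, coeff = 0.2,
                                min_sep_fraction = 0.4, floor_factor = 5,
                                refine = TRUE, refine_radius = 6,
                                mask = NULL) {
  stopifnot(inherits(template, "laser_template"))
  sig <- laser_signal(image, coeff)
  if (is.null(mask)) mask <- build_mask(template, dim(sig))
  med <- median(sig)
  floor_value <- max(med + floor_factor * stats::mad(sig), 0)
  min_dist <- min_sep_fraction * template$expected_pairwise_px
  peaks <- cpp_peak_local_max(sig, min_dist, floor_value)
  keep <- peaks[mask[cbind(peaks[, "row"], peaks[, "col"])], , drop = FALSE]
  keep <- utils::head(keep, 3L)
  n <- nrow(keep)
  pts <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y")))
  if (n > 0) {
    pts <- cbind(x = keep[, "col"], y = keep[, "row"])
    if (refine) {
      nr <- nrow(sig); nc <- ncol(sig)
      for (i in seq_len(n)) {
        r0 <- max(1, keep[i, "row"] - refine_radius)
        r1 <- min(nr, keep[i, "row"] + refine_radius)
        c0 <- max(1, keep[i, "col"] - refine_radius)
        c1 <- min(nc, keep[i, "col"] + refine_radius)
        w <- pmax(sig[r0:r1, c0:c1] - floor_value, 0)
        if (sum(w) > 0) {
          pts[i, "y"] <- sum((r0:r1) * rowSums(w)) / sum(w)
          pts[i, "x"] <- sum((c0:c1) * colSums(w)) / sum(w)
        }
      }
    }
  }
  dists <- if (n >= 2) as.numeric(stats::dist(pts)) else numeric(0)
  s <- if (n >= 2) mean(dists) / template$known_spacing_cm else NA_real_
  structure(list(
    points = pts, pairwise_distances = dists, n_found = n,
    scale_px_per_cm = s, flag = if (n >= 2) "ok" else "unscaled"
  ), class = "laser_detection")
}

#' Image scale from detected laser points
#'
#' `s = mean(pairwise distances) / known_spacing_cm` in px/cm: the mean is
#' over the set of pairwise distances (3 points give 3 pairs, 2 points give
#' the single distance). Fewer than two points leave the image unscaled
#' (NA).
#'
#' @param detection a [detect_laser_points()] result, or a numeric vector of
#'   pairwise pixel distances.
#' @param known_spacing_cm real-world spacing (default 40).
#' @return scale in px/cm, or NA.
#' @export
compute_scale <- function(detection, known_spacing_cm = 40) {
  d <- if (inherits(detection, "laser_detection"))
    detection$pairwise_distances else as.numeric(detection)
  if (length(d) < 1) return(NA_real_)
  mean(d) / known_spacing_cm
}

#' Batch laser detection over a survey
#'
#' Builds the deployment mask once and detects laser points in every image,
#' producing the per-image scale table consumed by the normalization stage.
#' Results are per-image independent (order does not matter).
#'
#' @param image_paths character vector of image files.
#' @param template a [laser_template()].
#' @param ... passed to [detect_laser_points()].
#' @return data frame `image_id, n_found, scale_px_per_cm, flag`.
#' @export
detect_scales <- function(image_paths, template, ...) {
  stopifnot(length(image_paths) >= 1)
  mask <- NULL
  out <- vector("list", length(image_paths))
  for (i in seq_along(image_paths)) {
    img <- read_image(image_paths[i])
    if (is.null(mask)) mask <- build_mask(template, dim(img))
    det <- detect_laser_points(img, template, mask = mask, ...)
    out[[i]] <- data.frame(
      image_id = sub("\\.[^.]+$", "", basename(image_paths[i])),
      n_found = det$n_found,
      scale_px_per_cm = det$scale_px_per_cm,
      flag = det$flag
    )
  }
  do.call(rbind, out)
}
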