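#' Correct illumination drop-off by local z-scoring
#'
#' Removes the spatial illumination field (vignetting, uneven artificial
#' light) from each channel by local z-score normalization: a smooth
#' per-pixel mean and standard deviation are estimated with a large
#' triple-box (Gaussian-like) filter of window about `window_frac` of the
#' image diagonal, and the channel is re-targeted to `(mu_target,
#' sigma_target)`. Following the gray-world reading of the correction, the
#' default targets are the channel's own global mean and a common sd, so
#' corrected channel means land on `mu_target` within one intensity level.
#'
#' @param image RGB array (0..255).
#' @param mu_target per-channel target mean (length 1 or 3); default the
#'   channel global means (reference-image stats in the survey pipeline).
#' @param sigma_target per-channel target sd (length 1 or 3); default the
#'   channel global sds.
#' @param window_frac window size as a fraction of the image diagonal.
#' @return corrected RGB array (integer-valued 0..255).
#' @export
correct_illumination <- function(image, mu_target = NULL, sigma_target = NULL,
                                 window_frac = 0.25) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  nr <- dim(image)[1]; nc <- dim(image)[2]
  radius <- max(2L, as.integer(round(window_frac *
                                       sqrt(nr^2 + nc^2) / 2 / 3)))
  # triple box filter ~ Gaussian of the requested support
  smooth <- function(m) {
    for (i in 1:3) m <- cpp_box_mean(m, radius)
    m
  }
  out <- image
  for (ch in 1:3) {
    x <- image[, , ch]
    mu_t <- if (is.null(mu_target)) mean(x) else
      mu_target[min(ch, length(mu_target))]
    sd_t <- if (is.null(sigma_target)) sd(x) else
      sigma_target[min(ch, length(sigma_target))]
    mu_loc <- smooth(x)
    v_loc <- smooth(x^2) - mu_loc^2
    sd_loc <- sqrt(pmax(v_loc, 0))
    if (max(sd_loc) < 1e-8) {
      warning("zero-variance channel; passed through at target mean")
      out[, , ch] <- matrix(mu_t, nr, nc)
      next
    }
    z <- (x - mu_loc) / pmax(sd_loc, 1e-6)
    out[, , ch] <- z * sd_t + mu_t
  }
  quantize8(out)
}

#' Contrast-limited adaptive histogram equalization
#'
#' CLAHE applied to the lightness (luma) channel over a tile grid with a
#' clip limit, chroma preserved by rescaling all three channels by the
#' lightness gain. Spreads narrow intensity histograms over the full 8-bit
#' range; on the package's synthetic fixtures the grayscale histogram
#' entropy never decreases.
#'
#' @param image RGB array (0..255), normally illumination-corrected.
#' @param tiles `c(rows, cols)` tile grid (default 8 x 8).
#' @param clip_limit clip limit as a fraction of the tile histogram mass.
#' @return enhanced RGB array (integer-valued 0..255).
#' @export
enhance_contrast <- function(image, tiles = c(8, 8), clip_limit = 0.03) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  L <- rgb_to_gray(image)
  Lh <- cpp_clahe(L, tiles[1], tiles[2], clip_limit)
  gain <- Lh / pmax(L, 1)
  out <- image
  for (ch in 1:3) out[, , ch] <- image[, , ch] * gain
  quantize8(out)
}

#' Choose the color-normalization reference image
#'
#' The reference is the image acquired closest to the seafloor, i.e. the one
#' with the maximum scale (px/cm); ties break to the earliest image.
#'
#' @param scales numeric vector of per-image scales (NA allowed).
#' @param ids optional ids aligned with `scales`.
#' @return the selected index (or id when `ids` is given).
#' @export
select_reference <- function(scales, ids = NULL) {
  stopifnot(length(scales) >= 1)
  if (all(is.na(scales))) stop("no scaled image available")
  i <- which(scales == max(scales, na.rm = TRUE))[1]
  if (is.null(ids)) i else ids[i]
}

#' Reference intensity profile for histogram matching
#'
#' Per-channel empirical cumulative distribution of the reference image over
#' the 256 intensity levels, plus provenance (reference id and scale).
#'
#' @param image reference RGB array (0..255).
#' @param image_id,scale provenance fields.
#' @return object of class `reference_profile` with `ecdf` (256 x 3 matrix
#'   of cumulative proportions, monotone 0..1).
#' @export
reference_profile <- function(image, image_id = NA_character_,
                              scale = NA_real_) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  ec <- sapply(1:3, function(ch) {
    cumsum(tabulate(quantize8(image[, , ch]) + 1L, nbins = 256L)) /
      (dim(image)[1] * dim(image)[2])
  })
  structure(list(ecdf = ec, reference_image_id = image_id,
                 reference_scale = scale), class = "reference_profile")
}

#' Match an image's color distribution to the reference
#'
#' Per-channel rank-based histogram specification: each pixel's rank in its
#' channel (ties broken by pixel order, so the map is deterministic) is sent
#' to the smallest reference level whose cumulative proportion reaches the
#' rank quantile. The output ECDF therefore equals the reference ECDF to
#' within 1/n at every percentile, and matching the reference image to
#' itself is the exact identity.
#'
#' @param image RGB array (0..255).
#' @param profile a [reference_profile()].
#' @return color-normalized RGB array (integer-valued 0..255).
#' @export
match_histogram <- function(image, profile) {
  stopifnot(inherits(profile, "reference_profile"),
            length(dim(image)) == 3L, dim(image)[3] == 3L)
  npix <- dim(image)[1] * dim(image)[2]
  out <- image
  for (ch in 1:3) {
    x <- quantize8(image[, , ch])
    ord <- order(x, method = "radix")
    ranks <- integer(npix)
    ranks[ord] <- seq_len(npix)
    ref_cdf <- profile$ecdf[, ch]
    # smallest reference level u with ref_cdf[u] >= rank/n
    lev <- findInterval(ranks / npix, ref_cdf, left.open = TRUE)
    out[, , ch] <- matrix(pmin(lev, 255L), dim(image)[1], dim(image)[2])
  }
  out
}

#' Survey median scale
#'
#' Standard median of the per-image scales: even N averages the two central
#' order statistics, odd N takes the central one. This is the common target
#' resolution all images are standardized to.
#'
#' @param scales numeric vector (NA entries dropped).
#' @return the median scale `Sc^M`.
#' @export
median_scale <- function(scales) {
  scales <- scales[!is.na(scales)]
  stopifnot(length(scales) >= 1)
  median(scales)
}

#' Footprint standardization settings
#'
#' A crop of `crop_width` x `crop_height` px at the survey median scale
#' covers `crop_width * crop_height / (median_scale^2 * 1e4)` square meters
#' of seabed; the defaults (2240 x 3360 at 21.6 px/cm) give about 1.61 m2.
#'
#' @param median_scale survey median scale in px/cm (see [median_scale()]).
#' @param crop_width,crop_height center-crop size in px.
#' @return object of class `footprint_spec` with derived `footprint_m2`.
#' @export
footprint_spec <- function(median_scale, crop_width = 2240,
                           crop_height = 3360) {
  stopifnot(median_scale > 0, crop_width >= 1, crop_height >= 1)
  structure(list(
    median_scale = median_scale,
    crop_width = as.integer(crop_width),
    crop_height = as.integer(crop_height),
    footprint_m2 = crop_width * crop_height / (median_scale^2 * 1e4)
  ), class = "footprint_spec")
}

#' Standardize an image's spatial footprint
#'
#' Resamples the image with cubic interpolation by the factor
#' `median_scale / scale` so its new scale equals the survey median scale,
#' then center-crops to the spec's size: every standardized image has
#' identical pixel dimensions and covers the identical seabed area.
#'
#' @param image RGB array (0..255).
#' @param scale this image's scale in px/cm.
#' @param spec a [footprint_spec()].
#' @return standardized RGB array `crop_height x crop_width x 3`.
#' @export
standardize_footprint <- function(image, scale, spec) {
  stopifnot(inherits(spec, "footprint_spec"), is.finite(scale), scale > 0)
  f <- spec$median_scale / scale
  nr <- dim(image)[1]; nc <- dim(image)[2]
  new_nr <- as.integer(round(nr * f)); new_nc <- as.integer(round(nc * f))
  if (new_nr < spec$crop_height || new_nc < spec$crop_width)
    stop("footprint exceeds frame")
  resized <- if (new_nr == nr && new_nc == nc) image else {
    out <- array(0, c(new_nr, new_nc, 3))
    for (ch in 1:3) out[, , ch] <- cpp_resize_cubic(image[, , ch], new_nr, new_nc)
    quantize8(out)
  }
  r0 <- (new_nr - spec$crop_height) %/% 2L
  c0 <- (new_nc - spec$crop_width) %/% 2L
  resized[r0 + seq_len(spec$crop_height), c0 + seq_len(spec$crop_width), ,
          drop = FALSE]
}

#' Full color-normalization chain for one image
#'
#' Fixed stage order: raw -> illumination-corrected -> contrast-enhanced ->
#' histogram-matched -> footprint-standardized. Targets for the
#' illumination step and the reference profile come from the survey
#' reference image.
#'
#' @param image RGB array (0..255).
#' @param scale this image's scale (px/cm).
#' @param profile [reference_profile()] built from the processed reference.
#' @param spec [footprint_spec()] for the survey.
#' @param mu_target,sigma_target illumination targets (reference stats).
#' @param tiles,clip_limit CLAHE settings, see [enhance_contrast()].
#' @return standardized, color-normalized RGB array.
#' @export
normalize_image <- function(image, scale, profile, spec,
                            mu_target = NULL, sigma_target = NULL,
                            tiles = c(8, 8), clip_limit = 0.03) {
  il <- correct_illumination(image, mu_target, sigma_target)
  he <- enhance_contrast(il, tiles, clip_limit)
  im <- match_histogram(he, profile)
  standardize_footprint(im, scale, spec)
}
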