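#' Otsu threshold of a grayscale image
#'
#' Maximizes the between-class variance of the 256-bin histogram; the
#' returned value is the bin boundary, pixels strictly below it form the
#' dark class.
#'
#' @param gray matrix in 0..255.
#' @return threshold in 1..255 (intensity units).
#' @export
otsu_threshold <- function(gray) {
  h <- tabulate(quantize8(gray) + 1L, nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  which.max(sigma_b[-256])  # boundary after bin k-1: dark class is < k
}

#' Dark-blob threshold from a reference image
#'
#' For a survey whose images are histogram-matched to one reference, a
#' single binarization threshold is appropriate for all images. The
#' midpoint between the reference's dark-class mean and its Otsu threshold
#' (both on the lightly smoothed grayscale) sits below the sediment noise
#' tail but above the nodule interiors, so images without any true dark
#' blobs yield a near-empty mask instead of an arbitrary Otsu split of
#' their unimodal histogram.
#'
#' @param gray grayscale matrix (or RGB array) of the processed reference.
#' @param smooth_radius pre-smoothing box radius in px (default 1).
#' @return threshold in intensity units.
#' @export
nodule_threshold <- function(gray, smooth_radius = 1) {
  gray <- rgb_to_gray(gray)
  if (smooth_radius >= 1) gray <- cpp_box_mean(gray, as.integer(smooth_radius))
  thr <- otsu_threshold(gray)
  dark <- gray[gray < thr]
  if (length(dark) == 0) return(thr)
  (mean(dark) + thr) / 2
}

#' Segment dark nodule blobs
#'
#' Manganese nodules appear as irregular blobs of dark pixels: the
#' grayscale is lightly smoothed (single-pixel sensor noise collapses
#' toward the sediment mean while contiguous dark blob interiors survive),
#' the below-threshold set is kept (Otsu by default, or a survey-constant
#' threshold from [nodule_threshold()]), components are labelled with
#' 8-connectivity, and components smaller than `min_area` px are removed.
#'
#' @param gray grayscale matrix (or RGB array) in 0..255 of a normalized
#'   image.
#' @param min_area minimum component area in px (default 20 at the
#'   package's quarter-scale working resolution; scale with resolution).
#' @param smooth_radius pre-smoothing box radius in px (0 disables).
#' @param threshold fixed threshold; default NULL uses this image's Otsu
#'   threshold (appropriate when the image has a genuine dark mode).
#' @return logical mask with attribute `labels` (integer component matrix,
#'   relabelled compactly) and `n_components`.
#' @export
binarize_nodules <- function(gray, min_area = 20, smooth_radius = 1,
                             threshold = NULL) {
  gray <- rgb_to_gray(gray)
  if (stats::sd(gray) == 0 && is.null(threshold)) {
    mask <- matrix(FALSE, nrow(gray), ncol(gray))
    attr(mask, "labels") <- matrix(0L, nrow(gray), ncol(gray))
    attr(mask, "n_components") <- 0L
    return(mask)
  }
  if (smooth_radius >= 1) gray <- cpp_box_mean(gray, as.integer(smooth_radius))
  thr <- if (is.null(threshold)) otsu_threshold(gray) else threshold
  mask <- quantize8(gray) < thr
  lab <- cpp_label_components(mask)
  n <- attr(lab, "n_components")
  if (n > 0 && min_area > 1) {
    sizes <- tabulate(lab[lab > 0L], nbins = n)
    keep <- which(sizes >= min_area)
    relab <- integer(n)
    relab[keep] <- seq_along(keep)
    lab[lab > 0L] <- relab[lab[lab > 0L]]
    mask <- lab > 0L
    n <- length(keep)
  }
  attr(mask, "labels") <- lab
  attr(mask, "n_components") <- as.integer(n)
  mask
}

# convex-hull area of one component's pixel set, measured over the pixel
# squares (a filled w x h rectangle of pixels has hull area w*h)
.hull_area <- function(rows, cols) {
  x <- c(cols - 0.5, cols + 0.5, cols - 0.5, cols + 0.5)
  y <- c(rows - 0.5, rows - 0.5, rows + 0.5, rows + 0.5)
  h <- grDevices::chull(x, y)
  if (length(h) < 3) return(0)
  xx <- x[h]; yy <- y[h]
  abs(sum(xx * c(yy[-1], yy[1]) - c(xx[-1], xx[1]) * yy)) / 2
}

#' Texture properties of the nodule components
#'
#' The five component-based texture features: median convex-hull area over
#' components, 75th-percentile component area, total component area,
#' density (total area / image area), and component count. An empty mask
#' yields all zeros.
#'
#' @param mask logical matrix from [binarize_nodules()] (its `labels`
#'   attribute is used when present).
#' @return named numeric vector `median_hull_area, q75_area, total_area,
#'   density, component_count`.
#' @export
component_properties <- function(mask) {
  lab <- attr(mask, "labels")
  if (is.null(lab)) {
    lab <- cpp_label_components(mask)
  }
  n <- max(lab)
  if (n == 0) {
    return(c(median_hull_area = 0, q75_area = 0, total_area = 0,
             density = 0, component_count = 0))
  }
  areas <- tabulate(lab[lab > 0L], nbins = n)
  idx <- which(lab > 0L)
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  comp <- lab[idx]
  hulls <- vapply(split(seq_along(idx), comp), function(j) {
    .hull_area(rows[j], cols[j])
  }, numeric(1))
  c(median_hull_area = median(hulls),
    q75_area = unname(quantile(areas, 0.75)),
    total_area = sum(areas),
    density = sum(areas) / length(lab),
    component_count = n)
}

#' Total local entropy of an image
#'
#' Per-pixel Shannon entropy (base 2) of the intensity histogram over a
#' disc neighbourhood of `radius` px (window clipped at the border),
#' summed over all pixels. Reveals subtle intensity variation: a constant
#' image scores 0, a two-valued texture at most 1 bit per pixel.
#'
#' @param gray grayscale matrix (or RGB array) in 0..255.
#' @param radius disc radius in px, >= 1 (default 5 at the quarter-scale
#'   working resolution).
#' @param nbins number of intensity bins (default 256).
#' @return total entropy (bits).
#' @export
extract_entropy <- function(gray, radius = 5, nbins = 256) {
  gray <- rgb_to_gray(gray)
  stopifnot(radius >= 1)
  q <- matrix(as.integer(pmin((quantize8(gray) * nbins) %/% 256L, nbins - 1L)),
              nrow(gray), ncol(gray))
  sum(cpp_local_entropy(q, as.integer(radius), as.integer(nbins)))
}

#' 6-dimensional texture/entropy feature vector of one image
#'
#' Concatenates the five component texture properties of
#' [component_properties()] with the [extract_entropy()] total.
#'
#' @param image RGB array or grayscale matrix (0..255), normally a
#'   footprint-standardized normalized image.
#' @param entropy_radius disc radius for the local entropy.
#' @param min_area minimum nodule component area in px.
#' @param smooth_radius,threshold binarization controls, see
#'   [binarize_nodules()].
#' @return named numeric vector of length 6.
#' @export
extract_features <- function(image, entropy_radius = 5, min_area = 20,
                             smooth_radius = 1, threshold = NULL) {
  gray <- rgb_to_gray(image)
  mask <- binarize_nodules(gray, min_area = min_area,
                           smooth_radius = smooth_radius,
                           threshold = threshold)
  c(component_properties(mask),
    total_entropy = extract_entropy(gray, radius = entropy_radius))
}

#' Stack and standardize per-image feature vectors
#'
#' Rows are images, columns the six features; each column is standardized
#' to mean 0 and unit variance. A constant column gets scale 1 (with a
#' warning) instead of dividing by zero.
#'
#' @param features matrix or list of feature vectors (rows = images).
#' @param ids image ids (default from row names or sequence).
#' @return object of class `feature_matrix`: standardized `X`, `raw`,
#'   `center`, `scale`, `ids`.
#' @export
build_matrix <- function(features, ids = NULL) {
  raw <- if (is.list(features)) do.call(rbind, features) else as.matrix(features)
  stopifnot(nrow(raw) >= 3)
  if (is.null(ids)) ids <- rownames(raw)
  if (is.null(ids)) ids <- sprintf("img_%04d", seq_len(nrow(raw)))
  ctr <- colMeans(raw)
  scl <- apply(raw, 2, sd)
  if (any(scl == 0)) {
    warning("constant feature column(s); scale set to 1")
    scl[scl == 0] <- 1
  }
  X <- sweep(sweep(raw, 2, ctr), 2, scl, "/")
  rownames(X) <- ids
  structure(list(X = X, raw = raw, center = ctr, scale = scl, ids = ids),
            class = "feature_matrix")
}

#' 2-D principal-component embedding of the feature matrix
#'
#' Projects the standardized features onto their top two principal
#' components (for centered data, linear-kernel PCA scores coincide with
#' classical PCA scores). Axis signs are fixed by forcing each component's
#' largest-magnitude loading positive, so embeddings are reproducible.
#'
#' @param fm a [build_matrix()] result.
#' @return object of class `embedding_2d`: `coords` (N x 2), `var_share`
#'   (explained-variance shares, decreasing), `loadings`, `ids`.
#' @export
project_2d <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  X <- scale(fm$X, center = TRUE, scale = FALSE)  # guard: already centered
  e <- eigen(stats::cov(X), symmetric = TRUE)
  V <- e$vectors[, 1:2, drop = FALSE]
  for (j in 1:2) if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  coords <- X %*% V
  colnames(coords) <- c("PC1", "PC2")
  rownames(coords) <- fm$ids
  structure(list(coords = coords,
                 var_share = e$values[1:2] / sum(pmax(e$values, 0)),
                 loadings = V, ids = fm$ids), class = "embedding_2d")
}
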