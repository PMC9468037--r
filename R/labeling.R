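#' Propose seed images for hand labeling
#'
#' Approximates an analyst's uniform coverage of the 2-D embedding by
#' greedy farthest-point selection: the start point is drawn with the given
#' seed, then each further seed maximizes the minimum distance to those
#' already selected (ties to the lowest index). Uniformly spread seeds
#' reduce class imbalance in the labeled set.
#'
#' @param embedding a [project_2d()] result (or an N x 2 matrix).
#' @param n_seeds number of seeds, `<= N`.
#' @param seed RNG seed for the start point.
#' @return character vector of selected image ids (indices when the
#'   embedding has no ids).
#' @export
propose_seeds <- function(embedding, n_seeds, seed = 1L) {
  coords <- if (inherits(embedding, "embedding_2d")) embedding$coords
            else as.matrix(embedding)
  ids <- if (inherits(embedding, "embedding_2d")) embedding$ids
         else rownames(coords)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(coords)))
  n <- nrow(coords)
  if (n_seeds > n) stop("n_seeds exceeds number of images")
  if (n_seeds == n) return(ids)
  set.seed(seed)
  sel <- integer(n_seeds)
  sel[1] <- sample.int(n, 1)
  mind <- colSums((t(coords) - coords[sel[1], ])^2)
  if (n_seeds > 1) {
    for (k in 2:n_seeds) {
      sel[k] <- which.max(mind)
      mind <- pmin(mind, colSums((t(coords) - coords[sel[k], ])^2))
    }
  }
  ids[sel]
}

#' Expand seed labels by nearest-neighbor sampling
#'
#' Each seed's label is propagated to its `k_nn` nearest non-seed images in
#' the standardized 6-D feature space. Expansion is disjoint: every image is
#' claimed at most once, and a contested image goes to the closer seed
#' (Euclidean; exact ties to the seed listed first by image id). With
#' enough images this yields exactly `n_seeds * k_nn` expanded labels on
#' top of the seeds.
#'
#' @param seeds data frame `image_id, label`.
#' @param features a [build_matrix()] result (expansion runs in the 6-D
#'   standardized feature space, not the 2-D embedding).
#' @param k_nn neighbors per seed (default 100).
#' @return data frame `image_id, label, source` (`source` is `"seed"` or
#'   `"expanded"`), with attributes `n_seeds` and `k_nn`.
#' @export
expand_labels <- function(seeds, features, k_nn = 100) {
  stopifnot(inherits(features, "feature_matrix"), k_nn >= 0,
            all(c("image_id", "label") %in% names(seeds)))
  if (anyDuplicated(seeds$image_id)) stop("duplicate seed image_id")
  seeds <- seeds[order(seeds$image_id), , drop = FALSE]
  X <- features$X
  si <- match(seeds$image_id, features$ids)
  if (anyNA(si)) stop("seed image_id not present in feature matrix")
  ns <- nrow(seeds)
  pool <- setdiff(seq_len(nrow(X)), si)
  out_seed <- data.frame(image_id = seeds$image_id, label = seeds$label,
                         source = "seed")
  if (k_nn == 0 || length(pool) == 0) {
    res <- out_seed
  } else {
    if (length(pool) < ns * k_nn)
      warning("population too small; expansion truncated")
    # squared distances pool x seeds
    d2 <- outer(rowSums(X[pool, , drop = FALSE]^2), rep(1, ns)) +
      outer(rep(1, length(pool)), rowSums(X[si, , drop = FALSE]^2)) -
      2 * X[pool, , drop = FALSE] %*% t(X[si, , drop = FALSE])
    # greedy globally-nearest assignment: order all (image, seed) pairs by
    # distance (ties by seed order = sorted seed id), fill each seed's quota
    ord <- order(as.numeric(d2))
    quota <- integer(ns)
    assigned <- integer(length(pool))
    n_left <- min(length(pool), ns * k_nn)
    for (o in ord) {
      if (n_left == 0) break
      i <- (o - 1L) %% length(pool) + 1L
      j <- (o - 1L) %/% length(pool) + 1L
      if (assigned[i] == 0L && quota[j] < k_nn) {
        assigned[i] <- j
        quota[j] <- quota[j] + 1L
        n_left <- n_left - 1L
      }
    }
    hit <- which(assigned > 0L)
    res <- rbind(out_seed, data.frame(
      image_id = features$ids[pool[hit]],
      label = seeds$label[assigned[hit]],
      source = "expanded"
    ))
  }
  res <- res[order(res$image_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_seeds") <- ns
  attr(res, "k_nn") <- k_nn
  res
}

#' Stratified train/validation/test split of a labeled set
#'
#' Random split stratified by class: within each class, items are shuffled
#' and apportioned to the three partitions by largest remainder, so split
#' sizes match the fractions exactly (up to integer rounding per class) and
#' per-class proportions are preserved. Partitions are disjoint and
#' exhaustive.
#'
#' @param labeled data frame with `image_id` and `label` (e.g. from
#'   [expand_labels()]).
#' @param fractions length-3 numeric `c(train, val, test)` summing to ~1
#'   (default `c(0.80, 0.07, 0.13)`).
#' @param seed RNG seed.
#' @return list of data frames `train`, `val`, `test`.
#' @export
split_labeled <- function(labeled, fractions = c(0.80, 0.07, 0.13),
                          seed = 1L) {
  stopifnot(length(fractions) == 3L, all(fractions >= 0),
            abs(sum(fractions) - 1) < 0.02)
  set.seed(seed)
  part <- integer(nrow(labeled))
  for (cl in unique(labeled$label)) {
    idx <- sample(which(labeled$label == cl))
    m <- length(idx)
    base <- floor(fractions * m)
    rem <- fractions * m - base
    short <- m - sum(base)
    if (short > 0) base <- base + (rank(-rem, ties.method = "first") <= short)
    part[idx] <- rep.int(1:3, times = base)
  }
  list(train = labeled[part == 1, , drop = FALSE],
       val = labeled[part == 2, , drop = FALSE],
       test = labeled[part == 3, , drop = FALSE])
}
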