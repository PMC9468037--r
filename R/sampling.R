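#' Random training-set sampling
#'
#' Uniform sampling without replacement: every image has equal inclusion
#' likelihood.
#'
#' @param ids vector of image ids.
#' @param n sample size, `<= length(ids)`.
#' @param seed RNG seed.
#' @return `n` unique ids.
#' @export
sample_random <- function(ids, n, seed = 1L) {
  stopifnot(n >= 0, n <= length(ids))
  set.seed(seed)
  ids[sample.int(length(ids), n)]
}

#' Spatially uniform training-set sampling
#'
#' Orders images along the tow track by cumulative along-track distance
#' (the transect is one-dimensional in nature), splits them into `n`
#' equal-count contiguous bins, and draws one image at random from each
#' non-empty bin, spreading the sample uniformly over the surveyed line.
#'
#' @param ids image ids.
#' @param coords data frame or matrix with `longitude`, `latitude` per
#'   image, aligned with `ids` and given in track order.
#' @param n number of bins / target sample size.
#' @param seed RNG seed.
#' @return up to `n` unique ids (fewer, with a warning, when bins collapse).
#' @export
sample_spatial <- function(ids, coords, n, seed = 1L) {
  stopifnot(n >= 1, n <= length(ids), nrow(coords) == length(ids))
  coords <- as.data.frame(coords)
  lon <- coords$longitude; lat <- coords$latitude
  stopifnot(!is.null(lon), !is.null(lat))
  set.seed(seed)
  # equirectangular along-track step lengths (adequate at survey extent)
  if (length(ids) > 1) {
    dlat <- diff(lat); dlon <- diff(lon) * cos(mean(lat) * pi / 180)
    along <- c(0, cumsum(sqrt(dlat^2 + dlon^2)))
  } else along <- 0
  ord <- order(along, seq_along(along))
  # integer arithmetic: equal-count contiguous bins, exact for n = N
  bin <- ((seq_along(ord) - 1L) * n) %/% length(ord) + 1L
  pick <- vapply(split(ord, bin), function(ix) {
    ix[sample.int(length(ix), 1)]
  }, integer(1))
  if (length(pick) < n) warning("fewer non-empty bins than requested draws")
  ids[sort(pick)]
}

#' Stratified cluster-based training-set sampling
#'
#' Over-clusters the 1-D entropy feature with k-means into `n_strata`
#' strata, then samples each stratum uniformly (quota `n / n_strata`,
#' small strata exhausted and their deficit redistributed over the
#' remaining strata). Drawing uniformly across all regions of the
#' entropy-defined feature space naturally reduces class imbalance.
#'
#' @param entropy numeric vector (one value per image, e.g. the
#'   `total_entropy` feature).
#' @param ids image ids aligned with `entropy`.
#' @param n sample size.
#' @param n_strata number of strata (default 20).
#' @param seed RNG seed.
#' @return `n` unique ids (when the population permits).
#' @export
sample_stratified <- function(entropy, ids, n, n_strata = 20, seed = 1L) {
  stopifnot(length(entropy) == length(ids), n >= 0, n <= length(ids),
            n_strata >= 1)
  if (n == 0) return(ids[0])
  set.seed(seed)
  k <- min(n_strata, length(unique(entropy)))
  strata <- if (k == 1) rep(1L, length(ids)) else
    kmeans(matrix(entropy, ncol = 1), centers = k, nstart = 5)$cluster
  groups <- split(seq_along(ids), strata)
  take <- integer(length(groups))
  remaining <- n
  open <- rep(TRUE, length(groups))
  sizes <- lengths(groups)
  # uniform quota; exhaust small strata and redistribute the deficit
  while (remaining > 0 && any(open)) {
    quota <- ceiling(remaining / sum(open))
    for (g in which(open)) {
      if (remaining == 0) break
      add <- min(quota, sizes[g] - take[g], remaining)
      take[g] <- take[g] + add
      remaining <- remaining - add
      if (take[g] == sizes[g]) open[g] <- FALSE
    }
  }
  picked <- unlist(lapply(seq_along(groups), function(g) {
    if (take[g] == 0) return(integer(0))
    ix <- groups[[g]]
    ix[sample.int(length(ix), take[g])]
  }))
  ids[sort(picked)]
}

#' Probabilistic weighted re-sampling
#'
#' Fits a one-dimensional Gaussian mixture (default 20 components) to the
#' entropy values, then samples without replacement with weights
#' proportional to the inverted density `1 / max(pdf, eps)`, oversampling
#' the under-represented regions of the entropy distribution. The floor
#' `eps = eps_frac * max(pdf)` keeps weights finite where the density
#' vanishes.
#'
#' @param entropy numeric vector per image.
#' @param ids image ids aligned with `entropy`.
#' @param n sample size.
#' @param n_components mixture size (default 20).
#' @param seed RNG seed.
#' @param eps_frac density floor as a fraction of the density maximum.
#' @return `n` unique ids.
#' @export
sample_probabilistic <- function(entropy, ids, n, n_components = 20,
                                 seed = 1L, eps_frac = 1e-6) {
  stopifnot(length(entropy) == length(ids), n >= 0, n <= length(ids))
  if (n == 0) return(ids[0])
  set.seed(seed)
  fit <- fit_gmm1d(entropy, k = n_components)
  dens <- gmm1d_density(fit, entropy)
  w <- 1 / pmax(dens, eps_frac * max(dens))
  ids[sort(sample.int(length(ids), n, prob = w))]
}

#' Fit a one-dimensional Gaussian mixture by EM
#'
#' Plain EM with quantile-spread initialization; component standard
#' deviations are floored at 1e-3 of the data range to avoid degenerate
#' spikes. `k` is reduced to the number of distinct values when necessary.
#'
#' @param x numeric data.
#' @param k number of components (default 20).
#' @param max_iter,tol EM stopping rule (log-likelihood change).
#' @return list `weights, means, sds, loglik, k`.
#' @export
fit_gmm1d <- function(x, k = 20, max_iter = 200, tol = 1e-6) {
  stopifnot(length(x) >= 2)
  k <- max(1L, min(as.integer(k), length(unique(x))))
  rng <- diff(range(x))
  if (rng == 0) {
    return(list(weights = 1, means = x[1], sds = 1, loglik = NA_real_, k = 1L))
  }
  floor_sd <- 1e-3 * rng
  mu <- as.numeric(quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE))
  sdv <- rep(max(rng / (2 * k), floor_sd), k)
  w <- rep(1 / k, k)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j) w[j] * dnorm(x, mu[j], sdv[j]),
                   numeric(length(x)))
    tot <- rowSums(dens)
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    resp <- dens / tot
    nk <- colSums(resp)
    nk[nk == 0] <- .Machine$double.eps
    w <- nk / length(x)
    mu <- colSums(resp * x) / nk
    sdv <- sqrt(colSums(resp * (outer(x, mu, `-`))^2) / nk)
    sdv <- pmax(sdv, floor_sd)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll_old)) break
    ll_old <- ll
  }
  list(weights = w, means = mu, sds = sdv, loglik = ll, k = k)
}

#' Mixture density of a fitted 1-D GMM
#'
#' @param fit a [fit_gmm1d()] result.
#' @param x evaluation points.
#' @return density values.
#' @export
gmm1d_density <- function(fit, x) {
  rowSums(vapply(seq_len(fit$k), function(j) {
    fit$weights[j] * dnorm(x, fit$means[j], fit$sds[j])
  }, numeric(length(x))))
}

#' Time and score one sampling strategy
#'
#' Runs a sampling strategy, fits a k-means classifier on the sampled
#' feature vectors with silhouette-based selection of k, and reports the
#' wall-clock time from sampling start to fit convergence together with the
#' training silhouette and chosen k.
#'
#' @param fm a [build_matrix()] result.
#' @param strategy one of `"random"`, `"spatial"`, `"stratified"`,
#'   `"probabilistic"`.
#' @param n training-set size (default 5000).
#' @param seed RNG seed.
#' @param coords nav coordinates (required for `"spatial"`).
#' @param k_range candidate cluster counts (default 2:20).
#' @param n_strata,n_components strategy parameters.
#' @return object of class `strategy_report`: `strategy, time_to_fit_s,
#'   silhouette, chosen_k, n, ids, model`.
#' @export
evaluate_strategy <- function(fm, strategy = c("random", "spatial",
                                               "stratified", "probabilistic"),
                              n = 5000, seed = 1L, coords = NULL,
                              k_range = 2:20, n_strata = 20,
                              n_components = 20) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(fm, "feature_matrix"))
  ecol <- if ("total_entropy" %in% colnames(fm$X)) "total_entropy"
          else ncol(fm$X)
  entropy <- fm$X[, ecol]
  t0 <- proc.time()["elapsed"]
  ids <- switch(strategy,
    random = sample_random(fm$ids, n, seed),
    spatial = {
      if (is.null(coords)) stop("spatial strategy needs coords")
      sample_spatial(fm$ids, coords, n, seed)
    },
    stratified = sample_stratified(entropy, fm$ids, n, n_strata, seed),
    probabilistic = sample_probabilistic(entropy, fm$ids, n, n_components,
                                         seed)
  )
  Xs <- fm$X[match(ids, fm$ids), , drop = FALSE]
  k <- select_k(Xs, k_min = min(k_range), k_max = max(k_range), seed = seed)
  model <- fit_kmeans(Xs, k, seed = seed)
  elapsed <- unname(proc.time()["elapsed"] - t0)
  structure(list(strategy = strategy, time_to_fit_s = elapsed,
                 silhouette = model$silhouette, chosen_k = k, n = length(ids),
                 ids = ids, model = model), class = "strategy_report")
}
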