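#' Mean silhouette width of a clustering
#'
#' For each point, `a` is its mean distance to its own cluster (excluding
#' itself) and `b` the smallest mean distance to any other cluster; the
#' silhouette is `(b - a) / max(a, b)`, 0 for singleton clusters. Computed
#' from the full Euclidean distance matrix, so intended for training-sample
#' sizes (quadratic memory).
#'
#' @param X numeric matrix (rows = points).
#' @param labels cluster assignment per row.
#' @return mean silhouette in `[-1, 1]`; NA when fewer than 2 clusters.
#' @export
silhouette_score <- function(X, labels) {
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2) return(NA_real_)
  d <- as.matrix(stats::dist(X))
  n <- nrow(d)
  sizes <- tabulate(labels, k)
  # mean distance of every point to every cluster
  md <- sapply(seq_len(k), function(j) rowSums(d[, labels == j, drop = FALSE]))
  own <- md[cbind(seq_len(n), labels)]
  a <- own / pmax(sizes[labels] - 1, 1)
  md_other <- sweep(md, 2, sizes, "/")
  md_other[cbind(seq_len(n), labels)] <- Inf
  b <- apply(md_other, 1, min)
  s <- ifelse(sizes[labels] == 1, 0, (b - a) / pmax(a, b))
  mean(s)
}

#' Fit a k-means cluster model
#'
#' Multiple random restarts of k-means with a fixed seed; the training
#' silhouette is stored with the model. Prediction assigns new points to
#' the nearest centroid.
#'
#' @param X training feature matrix (standardized).
#' @param k number of clusters.
#' @param seed RNG seed.
#' @param nstart restarts (default 10).
#' @param iter_max iteration cap (default 300).
#' @return object of class `cluster_model`: `centroids`, `chosen_k`,
#'   `silhouette`, `cluster` (training assignment).
#' @export
fit_kmeans <- function(X, k, seed = 1L, nstart = 10, iter_max = 300) {
  X <- as.matrix(X)
  stopifnot(k >= 1, k <= nrow(X))
  set.seed(seed)
  km <- kmeans(X, centers = k, nstart = nstart, iter.max = iter_max)
  sil <- if (k >= 2) silhouette_score(X, km$cluster) else NA_real_
  structure(list(centroids = km$centers, chosen_k = k, silhouette = sil,
                 cluster = km$cluster, tot_withinss = km$tot.withinss),
            class = "cluster_model")
}

#' Assign points to the nearest centroid
#'
#' @param model a [fit_kmeans()] result.
#' @param X feature matrix (same columns as training).
#' @return integer cluster labels.
#' @export
predict_clusters <- function(model, X) {
  stopifnot(inherits(model, "cluster_model"))
  X <- as.matrix(X)
  ctr <- model$centroids
  d2 <- outer(rowSums(X^2), rep(1, nrow(ctr))) +
    outer(rep(1, nrow(X)), rowSums(ctr^2)) - 2 * X %*% t(ctr)
  max.col(-d2, ties.method = "first")
}

#' Select the number of clusters by silhouette sweep
#'
#' Fits k-means for every k in `k_min:k_max` and returns the k with the
#' highest mean silhouette (ties to the smaller k). When the data cannot
#' support the sweep (fewer distinct points than `k_min + 1`), `k_min` is
#' returned with a warning.
#'
#' @param X feature matrix.
#' @param k_min,k_max sweep range (defaults 2 and 20).
#' @param seed RNG seed.
#' @param nstart restarts per k.
#' @return chosen k, with attribute `silhouettes` (the sweep profile).
#' @export
select_k <- function(X, k_min = 2, k_max = 20, seed = 1L, nstart = 10) {
  X <- as.matrix(X)
  n_distinct <- nrow(unique(X))
  if (n_distinct <= k_min) {
    warning("too few distinct points; returning k_min")
    return(k_min)
  }
  ks <- k_min:min(k_max, n_distinct - 1, nrow(X) - 1)
  sil <- vapply(ks, function(k) {
    fit_kmeans(X, k, seed = seed, nstart = nstart)$silhouette
  }, numeric(1))
  k <- ks[which.max(sil)]
  attr(k, "silhouettes") <- stats::setNames(sil, ks)
  k
}

#' Train the supervised seafloor classifier
#'
#' Pluggable-backend contract: a backend must fit on labeled training data
#' and expose class probabilities summing to one per image (see
#' [predict_proba()]). The default `"softmax"` desk-scale backend trains
#' multinomial logistic regression on the 6-D texture/entropy features by
#' full-batch gradient descent with Armijo backtracking (so the
#' cross-entropy loss is non-increasing), mirroring the fine-tuning recipe
#' shape: a frozen feature extractor with a trainable classification head,
#' run for `iterations` steps (default 200) with loss and accuracy curves
#' logged. A GPU CNN fine-tune can be slotted in as another backend; it is
#' not required by the desk-scale workflow.
#'
#' @param X training feature matrix (standardized), rows = images.
#' @param labels class label per row; every class level must be present.
#' @param iterations gradient steps (default 200).
#' @param l2 ridge penalty on the weights.
#' @param backend backend name; only `"softmax"` ships with the package.
#' @return object of class `benthoscan_classifier` with weights, class
#'   levels, the training `loss_curve` and `accuracy_curve`, and the
#'   recorded backend config.
#' @export
train_supervised <- function(X, labels, iterations = 200, l2 = 1e-4,
                             backend = "softmax") {
  X <- as.matrix(X)
  labels <- factor(labels)
  if (nlevels(labels) < 2 || any(table(labels) == 0))
    stop("degenerate class set")
  if (backend != "softmax") stop("unknown backend: ", backend)
  n <- nrow(X); k <- nlevels(labels); p <- ncol(X)
  Y <- matrix(0, n, k); Y[cbind(seq_len(n), as.integer(labels))] <- 1
  Xb <- cbind(1, X)
  W <- matrix(0, p + 1, k)
  softmax <- function(Z) {
    Z <- Z - apply(Z, 1, max)
    E <- exp(Z)
    E / rowSums(E)
  }
  loss_fn <- function(W) {
    P <- softmax(Xb %*% W)
    -sum(Y * log(pmax(P, 1e-12))) / n + l2 * sum(W[-1, ]^2) / 2
  }
  loss_curve <- numeric(iterations)
  acc_curve <- numeric(iterations)
  step <- 1
  cur <- loss_fn(W)
  for (it in seq_len(iterations)) {
    P <- softmax(Xb %*% W)
    G <- t(Xb) %*% (P - Y) / n
    G[-1, ] <- G[-1, ] + l2 * W[-1, ]
    # Armijo backtracking keeps the loss monotone non-increasing
    repeat {
      W_new <- W - step * G
      new <- loss_fn(W_new)
      if (new <= cur - 1e-4 * step * sum(G^2) || step < 1e-10) break
      step <- step / 2
    }
    if (new <= cur) { W <- W_new; cur <- new; step <- min(step * 2, 64) }
    loss_curve[it] <- cur
    acc_curve[it] <- mean(max.col(Xb %*% W) == as.integer(labels))
  }
  structure(list(
    W = W, classes = levels(labels), backend = backend,
    config = list(iterations = iterations, l2 = l2, frozen_base = TRUE,
                  head = c(ncol(X), k)),
    loss_curve = loss_curve, accuracy_curve = acc_curve
  ), class = "benthoscan_classifier")
}

#' Class probabilities from a trained classifier
#'
#' @param classifier a [train_supervised()] result.
#' @param X feature matrix (same columns as training).
#' @return N x K matrix of probabilities; each row sums to 1.
#' @export
predict_proba <- function(classifier, X) {
  stopifnot(inherits(classifier, "benthoscan_classifier"))
  Z <- cbind(1, as.matrix(X)) %*% classifier$W
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  P <- E / rowSums(E)
  colnames(P) <- classifier$classes
  P
}

#' Predicted class and confidence
#'
#' @param classifier a [train_supervised()] result.
#' @param X feature matrix.
#' @return data frame `pred_class, confidence` (max probability).
#' @export
predict_class <- function(classifier, X) {
  P <- predict_proba(classifier, X)
  j <- max.col(P, ties.method = "first")
  data.frame(pred_class = classifier$classes[j],
             confidence = P[cbind(seq_len(nrow(P)), j)])
}
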