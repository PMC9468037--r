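test_that("silhouette k-selection recovers the generative k", {
  for (k_true in 2:5) {
    set.seed(100 + k_true)
    # centers on a circle: separation guaranteed by construction
    ang <- 2 * pi * seq_len(k_true) / k_true
    centers <- 10 * cbind(cos(ang), sin(ang))
    X <- do.call(rbind, lapply(seq_len(k_true), function(j) {
      sweep(matrix(rnorm(25 * 2), 25, 2), 2, centers[j, ], "+")
    }))
    expect_identical(as.integer(select_k(X, 2, 8, seed = 1)), k_true)
  }
  same <- matrix(rep(c(0, 5), each = 12), ncol = 1)
  expect_warning(k <- select_k(same[c(1, 13), , drop = FALSE], 2, 5),
                 "too few distinct")
  expect_identical(k, 2)
})

test_that("k-means model assigns centroids to themselves and ignores row
          order", {
  bl <- blob_features(n_per_class = 20, sep = 8, seed = 50)
  model <- fit_kmeans(bl$X, 4, seed = 2)
  self <- predict_clusters(model, model$centroids)
  expect_identical(self, seq_len(4L))
  perm <- sample(nrow(bl$X))
  l1 <- predict_clusters(model, bl$X)
  l2 <- predict_clusters(model, bl$X[perm, ])
  expect_identical(l1[perm], l2)
})

test_that("supervised backend: monotone loss, calibrated probabilities,
          strong held-out F1", {
  bl <- blob_features(n_per_class = 50, sep = 8, seed = 60)
  fm <- build_matrix(bl$X, ids = as.character(seq_along(bl$labels)))
  lab <- data.frame(image_id = fm$ids, label = bl$labels)
  sp <- split_labeled(lab, c(0.8, 0.07, 0.13), seed = 3)
  tr_idx <- match(sp$train$image_id, fm$ids)
  clf <- train_supervised(fm$X[tr_idx, ], sp$train$label)
  expect_true(all(diff(clf$loss_curve) <= 1e-9))
  expect_equal(clf$accuracy_curve[length(clf$accuracy_curve)], 1)
  P <- predict_proba(clf, fm$X)
  expect_true(all(abs(rowSums(P) - 1) < 1e-6))
  te_idx <- match(sp$test$image_id, fm$ids)
  pred <- predict_class(clf, fm$X[te_idx, ])
  cm <- confusion(sp$test$label, pred$pred_class)
  expect_gte(f1_macro(cm), 0.9)
  expect_error(train_supervised(fm$X[1:5, ], rep("A", 5)),
               "degenerate class set")
})

test_that("agreement metrics hit their closed forms", {
  a <- rep(c("A", "B", "C"), times = c(5, 3, 2))
  expect_equal(cohens_kappa(a, a), 1)
  expect_equal(fowlkes_mallows(a, a), 1)
  expect_equal(f1_macro(confusion(a, a)), 1)

  # agreement exactly at chance level
  x <- rep(c("x", "y"), each = 50)
  y <- rep(c("x", "y"), 50)
  expect_equal(cohens_kappa(x, y), 0)

  # hand-computed confusion matrix: cm = [[8,2],[1,9]]
  true <- rep(c("a", "b"), each = 10)
  pred <- c(rep("a", 8), rep("b", 2), rep("a", 1), rep("b", 9))
  cm <- confusion(true, pred)
  expect_identical(unname(cm), matrix(c(8L, 1L, 2L, 9L), 2))
  f1a <- 2 * (8 / 9) * (8 / 10) / ((8 / 9) + (8 / 10))
  f1b <- 2 * (9 / 11) * (9 / 10) / ((9 / 11) + (9 / 10))
  expect_equal(f1_macro(cm), (f1a + f1b) / 2)
  expect_equal(f1_weighted(cm), (f1a + f1b) / 2)  # equal support

  # kappa symmetry and bounds on random labelings
  set.seed(9)
  for (i in 1:20) {
    u <- sample(letters[1:3], 30, replace = TRUE)
    v <- sample(letters[1:3], 30, replace = TRUE)
    expect_equal(cohens_kappa(u, v), cohens_kappa(v, u))
    expect_true(cohens_kappa(u, v) >= -1 && cohens_kappa(u, v) <= 1)
  }
})

test_that("FMI equals brute-force pair counting", {
  fmi_oracle <- function(a, b) {
    pr <- combn(length(a), 2)
    same_a <- a[pr[1, ]] == a[pr[2, ]]
    same_b <- b[pr[1, ]] == b[pr[2, ]]
    tp <- sum(same_a & same_b)
    fp <- sum(!same_a & same_b)
    fn <- sum(same_a & !same_b)
    if ((tp + fp) == 0 || (tp + fn) == 0) return(0)
    tp / sqrt((tp + fp) * (tp + fn))
  }
  expect_equal(fowlkes_mallows(c(1, 1, 2, 2), c(1, 2, 1, 2)),
               fmi_oracle(c(1, 1, 2, 2), c(1, 2, 1, 2)))
  set.seed(23)
  for (n in 4:6) {
    for (rep_i in 1:30) {
      a <- sample(1:3, n, replace = TRUE)
      b <- sample(1:3, n, replace = TRUE)
      expect_equal(fowlkes_mallows(a, b), fmi_oracle(a, b))
    }
  }
})

test_that("confidence distributions and cluster-class agreement", {
  one_hot <- data.frame(pred_class = rep(c("A", "B"), 5),
                        confidence = rep(1, 10))
  cd <- confidence_distribution(one_hot)
  expect_true(all(cd$frac_above == 1))
  expect_true(all(cd[["50%"]] == 1))
  uni <- data.frame(pred_class = rep("A", 8), confidence = rep(0.25, 8))
  cdu <- confidence_distribution(uni)
  expect_true(all(cdu$frac_above == 0))

  # unsupervised vs supervised agreement on a separable survey
  bl <- blob_features(n_per_class = 40, sep = 8, seed = 70)
  fm <- build_matrix(bl$X, ids = as.character(1:160))
  clf <- train_supervised(fm$X, bl$labels)
  sup <- predict_class(clf, fm$X)$pred_class
  km <- fit_kmeans(fm$X, 4, seed = 5)
  clusters <- predict_clusters(km, fm$X)
  mapped <- map_clusters_to_classes(clusters, sup)$mapped
  expect_gte(cohens_kappa(mapped, sup), 0.8)
})
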