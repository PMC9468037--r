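test_that("binarization keeps dark blobs and drops noise", {
  white <- matrix(255, 40, 40)
  m <- binarize_nodules(white)
  expect_identical(attr(m, "n_components"), 0L)
  expect_false(any(m))

  sq <- matrix(255, 60, 60)
  sq[20:29, 30:39] <- 0
  m2 <- binarize_nodules(sq, min_area = 1, smooth_radius = 0)
  expect_identical(attr(m2, "n_components"), 1L)
  expect_identical(sum(m2), 100L)

  # denser class => more components, same seed family, fixed threshold
  count_for <- function(cl) {
    sc <- render_scene(small_params(altitude_m = 2, seafloor_class = cl,
                                    rng_seed = 13))
    m <- binarize_nodules(rgb_to_gray(sc$image), min_area = 8, threshold = 60)
    attr(m, "n_components")
  }
  expect_gt(count_for("C"), count_for("A"))
})

test_that("component properties match a per-component geometry oracle", {
  empty <- matrix(FALSE, 30, 30)
  expect_equal(unname(component_properties(empty)), rep(0, 5))

  one <- matrix(FALSE, 100, 100)
  one[11:20, 31:40] <- TRUE
  p1 <- component_properties(one)
  expect_equal(unname(p1), c(100, 100, 100, 0.01, 1))

  two <- matrix(FALSE, 100, 100)
  two[5:14, 5:14] <- TRUE        # 10 x 10
  two[40:59, 40:59] <- TRUE      # 20 x 20
  p2 <- component_properties(two)
  # oracle: axis-aligned squares have hull area side^2; areas 100 and 400
  expect_equal(unname(p2["component_count"]), 2)
  expect_equal(unname(p2["total_area"]), 500)
  expect_equal(unname(p2["q75_area"]), unname(quantile(c(100, 400), 0.75)))
  expect_equal(unname(p2["median_hull_area"]), median(c(100, 400)))
  expect_equal(unname(p2["density"]), 500 / 1e4)
})

test_that("local entropy behaves like a two-symbol information measure", {
  expect_equal(extract_entropy(matrix(80, 30, 30)), 0)
  checker <- 255 * outer(1:40, 1:40, function(r, c) (r + c) %% 2)
  tot <- extract_entropy(checker, radius = 2)
  expect_lte(tot, 40 * 40)            # <= 1 bit per pixel
  expect_gt(tot, 0.85 * 40 * 40)      # near-balanced mix, border-clipped
  set.seed(4)
  noise <- matrix(runif(900, 0, 255), 30, 30)
  expect_gt(extract_entropy(noise), extract_entropy(matrix(80, 30, 30)))
})

test_that("feature matrix standardization and the embedding contract", {
  set.seed(10)
  raw <- matrix(rexp(60), 10, 6,
                dimnames = list(NULL, c("median_hull_area", "q75_area",
                                        "total_area", "density",
                                        "component_count", "total_entropy")))
  fm <- build_matrix(raw)
  expect_true(all(abs(colMeans(fm$X)) < 1e-9))
  expect_true(all(abs(apply(fm$X, 2, sd) - 1) < 1e-9))
  raw2 <- raw; raw2[, 3] <- 7
  expect_warning(fm2 <- build_matrix(raw2), "constant")
  expect_true(all(is.finite(fm2$X)))

  # linear-kernel PCA equals covariance PCA: kernel-matrix oracle
  set.seed(11)
  M <- matrix(rnorm(120), 20, 6)
  fmm <- build_matrix(M)
  emb <- project_2d(fmm)
  K <- fmm$X %*% t(fmm$X)                  # linear kernel, centered data
  ek <- eigen(K, symmetric = TRUE)
  oracle <- ek$vectors[, 1:2] %*% diag(sqrt(ek$values[1:2]))
  for (j in 1:2) {
    s <- sign(sum(oracle[, j] * emb$coords[, j]))
    expect_lt(max(abs(oracle[, j] * s - emb$coords[, j])), 1e-8)
  }
  expect_true(emb$var_share[1] >= emb$var_share[2])

  # data lying in a 2-D plane: projection preserves pairwise distances
  set.seed(12)
  basis <- qr.Q(qr(matrix(rnorm(12), 6, 2)))
  planar <- matrix(rnorm(40), 20, 2) %*% t(basis)
  fp <- list(X = scale(planar, scale = FALSE), ids = as.character(1:20))
  class(fp) <- "feature_matrix"
  ep <- project_2d(fp)
  expect_equal(as.numeric(dist(ep$coords)), as.numeric(dist(planar)),
               tolerance = 1e-8)
})

test_that("feature extraction is deterministic and classes separate in the
          embedding", {
  sc <- render_scene(small_params(altitude_m = 2, rng_seed = 17))
  f1 <- extract_features(sc$image, min_area = 8)
  f2 <- extract_features(sc$image, min_area = 8)
  expect_identical(f1, f2)

  run <- small_run()
  sv <- small_survey()
  emb <- run$embedding
  cls <- sv$truth$class[match(emb$ids, sv$truth$image_id)]
  co <- emb$coords
  between <- mean(dist(rbind(colMeans(co[cls == "A", , drop = FALSE]),
                             colMeans(co[cls == "C", , drop = FALSE]))))
  within <- mean(c(dist(co[cls == "A", , drop = FALSE]),
                   dist(co[cls == "C", , drop = FALSE])))
  expect_gt(between, within)
})
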