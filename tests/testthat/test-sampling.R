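test_that("random sampling is uniform without replacement", {
  ids <- sprintf("r%02d", 1:20)
  expect_setequal(sample_random(ids, 20, 1), ids)
  expect_length(sample_random(ids, 0, 1), 0)
  s <- sample_random(ids, 7, 5)
  expect_false(anyDuplicated(s) > 0)
  # inclusion frequency ~ n/N within 3 binomial sigmas
  hits <- rowSums(vapply(1:1000, function(r) ids %in% sample_random(ids, 5, r),
                         logical(20)))
  p <- hits / 1000
  sigma <- sqrt(0.25 * 0.75 / 1000)
  expect_true(all(abs(p - 0.25) < 3.5 * sigma + 0.02))
})

test_that("spatial sampling spreads draws along the track", {
  n <- 60
  ids <- sprintf("s%02d", 1:n)
  coords <- data.frame(longitude = seq(0, 0.01, length.out = n),
                       latitude = rep(10, n))
  expect_setequal(sample_spatial(ids, coords, n, 1), ids)
  # co-located fixes still yield the requested count
  co <- data.frame(longitude = rep(1, n), latitude = rep(2, n))
  expect_length(sample_spatial(ids, co, 10, 1), 10)
  # uniform track: spacing more even than random sampling (Monte-Carlo)
  cv <- function(idx) {
    gaps <- diff(sort(idx))
    sd(gaps) / mean(gaps)
  }
  cv_sp <- mean(vapply(1:50, function(r) {
    cv(match(sample_spatial(ids, coords, 12, r), ids))
  }, numeric(1)))
  cv_rn <- mean(vapply(1:50, function(r) {
    cv(match(sample_random(ids, 12, r), ids))
  }, numeric(1)))
  expect_lt(cv_sp, cv_rn)
})

test_that("stratified sampling balances strata", {
  # two tight entropy blobs, 900/100 items, n = 100 from 2 strata -> 50/50
  set.seed(9)
  entropy <- c(rnorm(900, 0, 0.05), rnorm(100, 10, 0.05))
  ids <- sprintf("t%04d", 1:1000)
  s <- sample_stratified(entropy, ids, 100, n_strata = 2, seed = 3)
  expect_length(s, 100)
  taken <- as.integer(substring(s, 2))
  expect_identical(sum(taken > 900), 50L)
  # single stratum degenerates to simple random sampling size
  s1 <- sample_stratified(entropy, ids, 50, n_strata = 1, seed = 4)
  expect_length(unique(s1), 50)
})

test_that("probabilistic resampling oversamples rare entropy modes", {
  set.seed(31)
  n <- 1000
  entropy <- c(rnorm(950, 0, 0.5), rnorm(50, 6, 0.3))
  ids <- sprintf("p%04d", 1:n)
  minority <- ids[951:1000]
  rate <- mean(vapply(1:30, function(r) {
    s <- sample_probabilistic(entropy, ids, 100, n_components = 5, seed = r)
    mean(s %in% minority)
  }, numeric(1)))
  expect_gt(rate, 0.05)  # population share is 5%
  s <- sample_probabilistic(entropy, ids, 200, seed = 1)
  expect_length(unique(s), 200)
})

test_that("the 1-D GMM recovers well-separated modes with finite weights", {
  set.seed(14)
  x <- c(rnorm(300, -4, 0.3), rnorm(300, 4, 0.3))
  fit <- fit_gmm1d(x, k = 2)
  expect_equal(sort(fit$means), c(-4, 4), tolerance = 0.2)
  d <- gmm1d_density(fit, c(-4, 0, 4))
  expect_true(all(is.finite(1 / pmax(d, 1e-6 * max(d)))))
  expect_lt(d[2], d[1])
})

test_that("strategy evaluation reports silhouette, k and timing", {
  bl <- blob_features(n_per_class = 40, sep = 8, seed = 44)
  fm <- build_matrix(bl$X, ids = sprintf("e%03d", 1:160))
  rep_r <- evaluate_strategy(fm, "random", n = 120, seed = 2,
                             k_range = 2:6)
  expect_s3_class(rep_r, "strategy_report")
  expect_gt(rep_r$silhouette, 0.7)
  expect_identical(rep_r$n, 120L)
  expect_true(rep_r$time_to_fit_s >= 0)
  expect_true(rep_r$silhouette >= -1 && rep_r$silhouette <= 1)
  rep_s <- evaluate_strategy(fm, "stratified", n = 120, seed = 2,
                             k_range = 2:6)
  expect_gt(rep_s$silhouette, 0.7)
})

test_that("stratified sampling reduces class imbalance versus random", {
  # 80/10/5/5 class mix expressed through class-dependent entropy modes
  set.seed(77)
  n <- 800
  cls <- sample(c("A", "B", "C", "D"), n, replace = TRUE,
                prob = c(0.8, 0.1, 0.05, 0.05))
  mode <- c(A = 0, B = 4, C = 8, D = 12)[cls]
  entropy <- rnorm(n, mode, 0.5)
  ids <- sprintf("j%04d", 1:n)
  uni <- rep(0.25, 4)
  js <- vapply(1:100, function(r) {
    take_s <- sample_stratified(entropy, ids, 80, n_strata = 8, seed = r)
    take_r <- sample_random(ids, 80, seed = r)
    p_s <- table(factor(cls[match(take_s, ids)], c("A", "B", "C", "D"))) / 80
    p_r <- table(factor(cls[match(take_r, ids)], c("A", "B", "C", "D"))) / 80
    c(js_distance(as.numeric(p_s), uni), js_distance(as.numeric(p_r), uni))
  }, numeric(2))
  expect_lt(mean(js[1, ]), mean(js[2, ]))
})
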