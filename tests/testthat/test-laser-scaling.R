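test_that("laser signal arithmetic is signed and exact", {
  img <- array(0, c(2, 2, 3))
  img[1, 1, ] <- c(200, 50, 50)
  img[1, 2, ] <- c(0, 255, 255)
  sig <- laser_signal(img, 0.2)
  expect_equal(sig[1, 1], 180)
  expect_equal(sig[1, 2], -102)
  expect_equal(laser_signal(img, 0), img[, , 1])
  expect_error(laser_signal(matrix(0, 4, 4)), "three channels")
})

test_that("mask is the buffered triangle, validated against a brute-force
          membership oracle", {
  pts <- cbind(x = c(10, 40, 25), y = c(12, 15, 42))
  tmpl0 <- laser_template(pts, buffer_px = 0)
  m0 <- build_mask(tmpl0, c(50, 50))

  # oracle: barycentric point-in-triangle test per pixel
  inside <- function(px, py) {
    d <- function(ax, ay, bx, by) (px - bx) * (ay - by) - (ax - bx) * (py - by)
    d1 <- d(pts[1, 1], pts[1, 2], pts[2, 1], pts[2, 2])
    d2 <- d(pts[2, 1], pts[2, 2], pts[3, 1], pts[3, 2])
    d3 <- d(pts[3, 1], pts[3, 2], pts[1, 1], pts[1, 2])
    !((d1 < 0 || d2 < 0 || d3 < 0) && (d1 > 0 || d2 > 0 || d3 > 0))
  }
  oracle <- outer(1:50, 1:50, Vectorize(function(r, c) inside(c, r)))
  expect_identical(unname(m0), unname(oracle))

  tmpl <- laser_template(pts, buffer_px = 6)
  m1 <- build_mask(tmpl, c(50, 50))
  expect_true(all(m1[m0]))          # dilation contains the triangle
  expect_gt(sum(m1), sum(m0))
  # annotated point on the frame edge: clipped, no out-of-range access
  edge <- laser_template(cbind(x = c(1, 50, 25), y = c(1, 3, 50)),
                         buffer_px = 10)
  expect_silent(build_mask(edge, c(50, 50)))
  expect_error(build_mask(laser_template(cbind(x = c(1, 5, 9),
                                               y = c(1, 5, 9))),
                          c(50, 50)), "degenerate triangle")
})

test_that("detection recovers the rendered laser points", {
  tmpl <- small_template()
  sc <- render_scene(small_params(altitude_m = 2, rng_seed = 31))
  det <- detect_laser_points(sc$image, tmpl)
  expect_identical(det$n_found, 3L)
  expect_length(det$pairwise_distances, 3L)
  # each detection within 3 px of a true laser point
  dmat <- as.matrix(dist(rbind(det$points, sc$truth$true_laser_points)))
  nearest <- apply(dmat[1:3, 4:6], 1, min)
  expect_true(all(nearest < 3))

  # lasers off: plain sediment scene, no red discs
  set.seed(8)
  dark <- array(rnorm(60 * 60 * 3, 120, 6), c(60, 60, 3))
  tmpl2 <- laser_template(cbind(x = c(20, 40, 30), y = c(20, 20, 40)),
                          buffer_px = 10)
  det2 <- detect_laser_points(dark, tmpl2)
  expect_identical(det2$n_found, 0L)
  expect_identical(det2$flag, "unscaled")
  expect_true(is.na(det2$scale_px_per_cm))
})

test_that("overlapping peaks are thinned by the minimum separation", {
  img <- array(0, c(40, 40, 3))
  img[, , 2] <- 10; img[, , 3] <- 10
  # two red discs 5 px apart, template expects ~30 px separation
  for (ctr in list(c(20, 18), c(20, 23))) {
    for (dr in -2:2) for (dc in -2:2) {
      if (dr^2 + dc^2 <= 4) img[ctr[1] + dr, ctr[2] + dc, 1] <- 255
    }
  }
  tmpl <- laser_template(cbind(x = c(10, 35, 20), y = c(10, 12, 35)),
                         buffer_px = 15)
  det <- detect_laser_points(img, tmpl, refine = FALSE)
  expect_lte(det$n_found, 2L)
})

test_that("scale follows the pairwise-distance average", {
  side <- function(s) 40 * s
  eq_tri <- function(L) cbind(x = c(0, L, L / 2), y = c(0, 0, L * sqrt(3) / 2))
  expect_equal(compute_scale(as.numeric(dist(eq_tri(400)))), 10)
  expect_equal(compute_scale(as.numeric(dist(eq_tri(864)))), 21.6)
  expect_equal(compute_scale(880), 22)
  expect_true(is.na(compute_scale(numeric(0))))
})

test_that("scale recovery: accurate, brightness-invariant, vignette-proof", {
  tmpl <- small_template()
  set.seed(5)
  alts <- runif(12, 1, 4)
  errs <- vapply(seq_along(alts), function(i) {
    sc <- render_scene(small_params(altitude_m = alts[i],
                                    seafloor_class = c("A", "B", "C", "D")[
                                      (i %% 4) + 1],
                                    rng_seed = 500 + i))
    det <- detect_laser_points(sc$image, tmpl)
    abs(det$scale_px_per_cm - sc$truth$true_scale_px_per_cm) /
      sc$truth$true_scale_px_per_cm
  }, numeric(1))
  expect_true(all(is.finite(errs)))
  expect_lt(median(errs), 0.02)

  # global brightness rescaling preserving channel ratios
  sc <- render_scene(small_params(altitude_m = 2.5, rng_seed = 77))
  s1 <- detect_laser_points(sc$image, tmpl)$scale_px_per_cm
  s2 <- detect_laser_points(sc$image * 0.6, tmpl)$scale_px_per_cm
  expect_lt(abs(s1 - s2) / s1, 0.005)

  # vignetted and unvignetted images both succeed
  for (v in c(0, 0.9)) {
    scv <- render_scene(small_params(altitude_m = 2, vignette_strength = v,
                                     rng_seed = 12))
    expect_identical(detect_laser_points(scv$image, tmpl)$n_found, 3L)
  }
})
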