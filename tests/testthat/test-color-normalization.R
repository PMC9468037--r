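test_that("illumination correction flattens the vignette", {
  sc <- render_scene(small_params(altitude_m = 2.5, vignette_strength = 0.5,
                                  rng_seed = 41, seafloor_class = "A"))
  img <- sc$image
  ratio <- function(x) {
    corner <- mean(x[1:40, 1:40, ])
    center <- mean(x[190:230, 120:160, ])
    corner / center
  }
  expect_lt(ratio(img), 0.6)
  il <- correct_illumination(img)
  expect_gt(ratio(il), 0.9)
  # channel means land on their targets within one level
  for (ch in 1:3) expect_lt(abs(mean(il[, , ch]) - mean(img[, , ch])), 1)
})

test_that("constant channels pass through at the target mean", {
  flat <- array(137, c(64, 48, 3))
  w <- capture_warnings(out <- correct_illumination(flat, mu_target = 120))
  expect_length(w, 3)  # one per channel
  expect_match(w, "zero-variance")
  expect_lte(max(abs(out - 120)), 2)
})

test_that("same scene at different exposure corrects to the same image", {
  p <- small_params(altitude_m = 2, rng_seed = 55, seafloor_class = "B")
  a <- render_scene(p)$image
  p$brightness_jitter <- 0.75
  b <- render_scene(p)$image
  mu <- sapply(1:3, function(ch) mean(a[, , ch]))
  sdv <- sapply(1:3, function(ch) sd(a[, , ch]))
  ca <- correct_illumination(a, mu, sdv)
  cb <- correct_illumination(b, mu, sdv)
  rms <- sqrt(mean((ca - cb)^2))
  expect_lt(rms, 2)
})

test_that("contrast enhancement spreads narrow histograms, never loses
          entropy on the fixtures", {
  set.seed(6)
  low <- array(runif(240 * 240 * 3, 100, 140), c(240, 240, 3))
  he <- enhance_contrast(low)
  expect_gte(diff(range(rgb_to_gray(he))), 0.8 * 255)
  expect_gte(hist_entropy(he), hist_entropy(low))

  for (sd_ in c(61, 62)) {
    sc <- render_scene(small_params(altitude_m = 2, rng_seed = sd_))
    il <- correct_illumination(sc$image)
    expect_gte(hist_entropy(enhance_contrast(il)), hist_entropy(il))
  }

  flat <- array(100, c(64, 64, 3))
  out <- enhance_contrast(flat)
  # unchanged up to the clip-limit mass shift (<= clip_limit * 255 + rounding)
  expect_lte(max(abs(out - flat)), 0.03 * 255 + 2)
})

test_that("reference selection is argmax with earliest-id tie-break", {
  expect_identical(select_reference(c(10, 22, 15)), 2L)
  expect_identical(select_reference(7), 1L)
  expect_identical(select_reference(c(22, 22), ids = c("a", "b")), "a")
  expect_identical(select_reference(c(NA, 3, NA)), 2L)
})

test_that("histogram matching reproduces the reference ECDF", {
  sc <- render_scene(small_params(altitude_m = 1.5, rng_seed = 71))
  ref <- enhance_contrast(correct_illumination(sc$image))
  prof <- reference_profile(ref, "ref", 1.8)
  expect_true(all(diff(prof$ecdf) >= -1e-12))
  expect_equal(max(prof$ecdf), 1)

  # identity on the reference itself
  expect_lte(max(abs(match_histogram(ref, prof) - ref)), 1)

  dark <- render_scene(small_params(altitude_m = 3.8, rng_seed = 72,
                                    brightness_jitter = 0.8))$image
  m <- match_histogram(enhance_contrast(correct_illumination(dark)), prof)
  for (ch in 1:3) {
    expect_lte(abs(median(m[, , ch]) - median(ref[, , ch])), 1)
    ec <- cumsum(tabulate(round(m[, , ch]) + 1L, 256)) / length(m[, , ch])
    expect_lt(max(abs(ec - prof$ecdf[, ch])), 0.02)
  }
})

test_that("median scale follows the order statistics", {
  expect_equal(median_scale(c(20, 21, 23, 25)), 22)
  expect_equal(median_scale(c(20, 22, 30)), 22)
  expect_equal(median_scale(21.6), 21.6)
  expect_equal(median_scale(c(NA, 21.6)), 21.6)
})

test_that("footprint standardization lands every image on the same frame", {
  spec <- footprint_spec(21.6)
  expect_equal(spec$footprint_m2, 2240 * 3360 / (21.6^2 * 1e4))
  expect_lt(abs(spec$footprint_m2 - 1.61), 0.01)

  img <- render_scene(small_params(altitude_m = 2, rng_seed = 81))$image
  sp <- footprint_spec(1.35, crop_width = 100, crop_height = 150)
  # image already at the median scale: crop only
  out <- standardize_footprint(img, 1.35, sp)
  expect_identical(dim(out), c(150L, 100L, 3L))
  r0 <- (420 - 150) %/% 2; c0 <- (280 - 100) %/% 2
  expect_identical(out, img[r0 + 1:150, c0 + 1:100, , drop = FALSE])

  # factor-two downsizing: S_i = 2 Sc^M halves the linear size
  sp2 <- footprint_spec(0.675, crop_width = 100, crop_height = 150)
  out2 <- standardize_footprint(img, 1.35, sp2)
  expect_identical(dim(out2), c(150L, 100L, 3L))
  expect_error(standardize_footprint(img, 1.35,
                                     footprint_spec(0.2, 100, 150)),
               "footprint exceeds frame")
})

test_that("stage idempotence within tolerance", {
  sc <- render_scene(small_params(altitude_m = 2, rng_seed = 91))
  il <- correct_illumination(sc$image)
  mu <- sapply(1:3, function(ch) mean(il[, , ch]))
  sdv <- sapply(1:3, function(ch) sd(il[, , ch]))
  il2 <- correct_illumination(il, mu, sdv)
  # idempotent up to second-order sd re-estimation on texture boundaries
  expect_lt(sqrt(mean((il2 - il)^2)), 4)
  for (ch in 1:3) expect_lt(abs(mean(il2[, , ch]) - mean(il[, , ch])), 1)
  prof <- reference_profile(il)
  expect_lte(max(abs(match_histogram(match_histogram(il, prof), prof) -
                       match_histogram(il, prof))), 2)
})

test_that("normalization synchronizes channel means across a survey", {
  sv <- small_survey()
  run <- small_run()
  raw_means <- t(vapply(sv$images, function(p) {
    img <- read_image(p)
    vapply(1:3, function(ch) mean(img[, , ch]), numeric(1))
  }, numeric(3)))
  norm_dir <- file.path(dirname(sv$images[1]), "run", "normalized")
  norm_files <- list.files(norm_dir, full.names = TRUE)
  norm_means <- t(vapply(norm_files, function(p) {
    img <- read_image(p)
    vapply(1:3, function(ch) mean(img[, , ch]), numeric(1))
  }, numeric(3)))
  drop <- apply(raw_means, 2, sd) / apply(norm_means, 2, sd)
  expect_true(all(drop >= 5))
})
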