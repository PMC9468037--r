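# Shared synthetic fixtures. Everything is generated in code at test time;
# expensive fixtures are built once per test run and cached in an
# environment so several test files can reuse them.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) assign(name, force(expr), envir = .fixtures)
  .fixtures[[name]]
}

# small test frame: 1/16 linear of the full-resolution survey camera, with
# the focal constant scaled to match (43.2 / 16 = 2.7)
small_params <- function(...) {
  scene_params(width = 280, height = 420, focal_scale = 2.7,
               laser_dot_radius_px = 3, ...)
}

# template from an altitude-2 m render, as annotated once per deployment;
# buffer 250 px at full resolution ~ 16x smaller on the test frame
small_template <- function() {
  fixture("small_template", {
    truth <- render_scene(small_params(altitude_m = 2, rng_seed = 3))$truth
    laser_template(truth$true_laser_points, buffer_px = 40)
  })
}

# a 12-image mixed-class survey on disk plus its full pipeline run
small_survey <- function() {
  fixture("small_survey", {
    dir <- file.path(tempdir(), "benthoscan-small-survey")
    cls <- rep(c("A", "B", "C", "D"), each = 3)
    sv <- generate_survey(dir, cls, base_params = small_params(), seed = 11)
    sv
  })
}

small_run <- function() {
  fixture("small_run", {
    sv <- small_survey()
    tmpl <- small_template()
    cfg <- pipeline_config(
      images_dir = dirname(sv$images[1]), nav_csv = sv$nav_csv,
      out_dir = file.path(dirname(sv$images[1]), "run"),
      template_points = tmpl$annotated_points,
      template = list(buffer_px = 40),
      normalize = list(crop_width = 96, crop_height = 144),
      features = list(entropy_radius = 5, min_area = 8),
      classify = list(mode = "unsupervised", strategy = "stratified",
                      n_train = 12, k_min = 2, k_max = 6, n_strata = 6),
      seed = 3)
    run_pipeline(cfg)
  })
}

# the acceptance-scale survey: 200 images, two 100-image halves with an
# injected class shift, run end to end in unsupervised mode
e2e_run <- function() {
  fixture("e2e_run", {
    dir <- file.path(tempdir(), "benthoscan-acceptance-e2e")
    set.seed(442)
    n_half <- 100
    cls_before <- sample(c("A", "B", "C", "D"), n_half, replace = TRUE,
                         prob = c(0.10, 0.40, 0.35, 0.15))
    cls_after <- sample(c("A", "B", "C", "D"), n_half, replace = TRUE,
                        prob = c(0.40, 0.25, 0.22, 0.13))
    sv <- generate_survey(dir, c(cls_before, cls_after),
                          base_params = small_params(), seed = 99)
    tmpl <- small_template()
    cfg <- pipeline_config(
      images_dir = dir, nav_csv = sv$nav_csv,
      out_dir = file.path(dir, "run"),
      template_points = tmpl$annotated_points,
      template = list(buffer_px = 40),
      normalize = list(crop_width = 96, crop_height = 144),
      features = list(entropy_radius = 5, min_area = 8),
      classify = list(mode = "unsupervised", strategy = "stratified",
                      n_train = 5000),
      seed = 5)
    res <- run_pipeline(cfg)
    list(dir = dir, sv = sv, res = res, n_half = n_half,
         cls_before = cls_before, cls_after = cls_after)
  })
}

# well-separated 4-class Gaussian blobs in 6-D, the desk-scale stand-in for
# a separable feature space
blob_features <- function(n_per_class = 30, sep = 6, seed = 42) {
  set.seed(seed)
  k <- 4
  centers <- matrix(rnorm(k * 6), k, 6) * sep
  X <- do.call(rbind, lapply(seq_len(k), function(j) {
    sweep(matrix(rnorm(n_per_class * 6), n_per_class, 6), 2, centers[j, ], "+")
  }))
  list(X = X, labels = rep(LETTERS[1:4], each = n_per_class))
}

# Jensen-Shannon distance between two discrete distributions
js_distance <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) sum(ifelse(a > 0, a * log2(a / b), 0))
  sqrt((kl(p, m) + kl(q, m)) / 2)
}
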