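#' Assemble a pipeline configuration
#'
#' Collects the per-stage parameter blocks with the survey defaults: laser
#' coefficient 0.2, mask buffer 250 px, laser spacing 40 cm, crop
#' 2240 x 3360 px, training-set size 5000, 50 seeds with 100 nearest
#' neighbors, 20 GMM components, cluster sweep 2..20, 200 training
#' iterations, split fractions 0.80/0.07/0.13. Any field can be
#' overridden; all randomness derives from the single `seed`.
#'
#' @param images_dir directory of input PNG images.
#' @param nav_csv navigation CSV (`timestamp_utc,latitude,longitude`).
#' @param out_dir run directory for all stage outputs.
#' @param template_points 3 x 2 matrix of annotated laser points (x, y) for
#'   the deployment template.
#' @param template,laser,normalize,features,classify,map named lists
#'   overriding individual stage parameters.
#' @param seed root RNG seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(images_dir, nav_csv, out_dir, template_points,
                            template = list(), laser = list(),
                            normalize = list(), features = list(),
                            classify = list(), map = list(), seed = 1L) {
  merge_block <- function(defaults, user) {
    defaults[names(user)] <- user
    defaults
  }
  cfg <- list(
    images_dir = images_dir, nav_csv = nav_csv, out_dir = out_dir,
    template = merge_block(list(points = template_points, buffer_px = 250,
                                known_spacing_cm = 40), template),
    laser = merge_block(list(coeff = 0.2, min_sep_fraction = 0.4,
                             floor_factor = 5), laser),
    normalize = merge_block(list(crop_width = 2240, crop_height = 3360,
                                 tiles = c(8, 8), clip_limit = 0.03), normalize),
    features = merge_block(list(entropy_radius = 5, min_area = 20), features),
    classify = merge_block(list(mode = "unsupervised", strategy = "stratified",
                                n_train = 5000, k_min = 2, k_max = 20,
                                n_strata = 20, n_components = 20,
                                seeds_csv = NULL, n_seeds = 50, k_nn = 100,
                                fractions = c(0.80, 0.07, 0.13),
                                iterations = 200), classify),
    map = merge_block(list(max_gap_s = 30), map),
    seed = as.integer(seed)
  )
  structure(cfg, class = "pipeline_config")
}

# cluster-assignment confidence: margin between the two nearest centroids,
# 1 when the point sits on its centroid, 0.5 when equidistant to two
.cluster_confidence <- function(model, X) {
  ctr <- model$centroids
  if (nrow(ctr) < 2) return(rep(1, nrow(X)))
  d2 <- outer(rowSums(X^2), rep(1, nrow(ctr))) +
    outer(rep(1, nrow(X)), rowSums(ctr^2)) - 2 * X %*% t(ctr)
  d2 <- pmax(d2, 0)
  srt <- t(apply(d2, 1, sort))[, 1:2, drop = FALSE]
  ifelse(srt[, 1] + srt[, 2] == 0, 1, srt[, 2] / (srt[, 1] + srt[, 2]))
}

#' Run the full seafloor-classification pipeline
#'
#' Executes the stages in fixed order -- laser detection, normalization,
#' feature extraction, labeling/sampling, classification, mapping -- on the
#' images in `config$images_dir`, writing every stage artifact plus a
#' manifest to `config$out_dir`. Re-running with the same configuration
#' reproduces identical stage outputs. Images whose lasers cannot be
#' detected (unscaled) or whose rescaled frame cannot contain the crop are
#' flagged and excluded downstream; the manifest records the counts.
#'
#' In unsupervised mode a training subset is drawn with the configured
#' sampling strategy, k is chosen by silhouette sweep and a k-means model
#' classifies every image (confidence is the nearest-centroid margin). In
#' supervised mode seed labels are read from `classify$seeds_csv`
#' (`image_id,label`), expanded by nearest neighbors, split, and the
#' supervised backend is trained and applied.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with the per-stage tables (`scales`, `features`,
#'   `predictions`, `track`, `proportions`) and the `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  images <- sort(list.files(config$images_dir, pattern = "\\.png$",
                            full.names = TRUE))
  if (length(images) == 0) stop("stage lasers: no input images found")
  ids <- sub("\\.png$", "", basename(images))

  # --- stage 1: laser detection and scale ---------------------------------
  tmpl <- laser_template(config$template$points,
                         buffer_px = config$template$buffer_px,
                         known_spacing_cm = config$template$known_spacing_cm)
  scales <- detect_scales(images, tmpl, coeff = config$laser$coeff,
                          min_sep_fraction = config$laser$min_sep_fraction,
                          floor_factor = config$laser$floor_factor)
  write.csv(scales, file.path(out, "scales.csv"), row.names = FALSE)
  scaled <- !is.na(scales$scale_px_per_cm)
  if (!any(scaled)) stop("stage normalize: no image could be scaled")

  # --- stage 2: color normalization + footprint ---------------------------
  ref_id <- select_reference(scales$scale_px_per_cm, scales$image_id)
  ref_img <- read_image(images[match(ref_id, scales$image_id)])
  mu_t <- vapply(1:3, function(ch) mean(ref_img[, , ch]), numeric(1))
  sd_t <- vapply(1:3, function(ch) sd(ref_img[, , ch]), numeric(1))
  ref_il <- correct_illumination(ref_img, mu_t, sd_t)
  ref_he <- enhance_contrast(ref_il, config$normalize$tiles,
                             config$normalize$clip_limit)
  profile <- reference_profile(ref_he, ref_id,
                               scales$scale_px_per_cm[scales$image_id == ref_id])
  sc_med <- median_scale(scales$scale_px_per_cm)
  spec <- footprint_spec(sc_med, config$normalize$crop_width,
                         config$normalize$crop_height)
  norm_dir <- file.path(out, "normalized")
  dir.create(norm_dir, showWarnings = FALSE)
  usable <- logical(length(images))
  for (i in seq_along(images)) {
    if (!scaled[i]) next
    img <- read_image(images[i])
    res <- tryCatch(
      normalize_image(img, scales$scale_px_per_cm[i], profile, spec,
                      mu_target = mu_t, sigma_target = sd_t,
                      tiles = config$normalize$tiles,
                      clip_limit = config$normalize$clip_limit),
      error = function(e) NULL)
    if (is.null(res)) next
    write_image(res, file.path(norm_dir, paste0(ids[i], ".png")))
    usable[i] <- TRUE
  }
  if (sum(usable) < 3) stop("stage features: fewer than 3 normalized images")

  # --- stage 3: features + embedding --------------------------------------
  # all feature images share the reference histogram, so one binarization
  # threshold (from the processed reference) serves the whole survey
  thr <- nodule_threshold(ref_he)
  uids <- ids[usable]
  fvecs <- t(vapply(uids, function(id) {
    extract_features(read_image(file.path(norm_dir, paste0(id, ".png"))),
                     entropy_radius = config$features$entropy_radius,
                     min_area = config$features$min_area,
                     threshold = thr)
  }, numeric(6)))
  fm <- build_matrix(fvecs, ids = uids)
  emb <- project_2d(fm)
  feat_df <- data.frame(image_id = uids, fm$raw, emb$coords,
                        check.names = FALSE)
  write.csv(feat_df, file.path(out, "features.csv"), row.names = FALSE)

  # --- stage 4/5: classification ------------------------------------------
  cc <- config$classify
  if (cc$mode == "unsupervised") {
    n_train <- min(cc$n_train, nrow(fm$X))
    nav_coords <- NULL
    if (identical(cc$strategy, "spatial")) {
      nav0 <- read_nav(config$nav_csv)
      nav_coords <- nav0[match(uids, ids), c("longitude", "latitude")]
    }
    report <- evaluate_strategy(fm, strategy = cc$strategy, n = n_train,
                                seed = config$seed, coords = nav_coords,
                                k_range = cc$k_min:cc$k_max,
                                n_strata = cc$n_strata,
                                n_components = cc$n_components)
    cl <- predict_clusters(report$model, fm$X)
    conf <- .cluster_confidence(report$model, fm$X)
    predictions <- data.frame(image_id = uids,
                              pred_class = paste0("cluster_", cl),
                              confidence = conf)
    jsonlite::write_json(
      list(strategy = report$strategy, chosen_k = report$chosen_k,
           silhouette = report$silhouette,
           time_to_fit_s = report$time_to_fit_s, n = report$n),
      file.path(out, "strategy_report.json"), auto_unbox = TRUE, digits = NA)
    model_info <- list(mode = "unsupervised", chosen_k = report$chosen_k,
                       silhouette = report$silhouette)
  } else {
    if (is.null(cc$seeds_csv)) stop("stage label: seeds_csv required")
    seeds <- read.csv(cc$seeds_csv, stringsAsFactors = FALSE)
    labeled <- expand_labels(seeds, fm, k_nn = cc$k_nn)
    write.csv(labeled, file.path(out, "labeled.csv"), row.names = FALSE)
    splits <- split_labeled(labeled, cc$fractions, seed = config$seed)
    tr <- rbind(splits$train, splits$val)
    clf <- train_supervised(fm$X[match(tr$image_id, uids), , drop = FALSE],
                            tr$label, iterations = cc$iterations)
    pred <- predict_class(clf, fm$X)
    predictions <- data.frame(image_id = uids, pred)
    model_info <- list(mode = "supervised",
                       final_loss = clf$loss_curve[length(clf$loss_curve)],
                       test_n = nrow(splits$test))
  }
  write.csv(predictions, file.path(out, "predictions.csv"), row.names = FALSE)

  # --- stage 6: georeference + map ----------------------------------------
  nav <- read_nav(config$nav_csv)
  img_times <- nav$timestamp_utc[match(uids, ids)]
  if (anyNA(img_times)) stop("stage map: nav rows do not cover all images")
  geo <- georeference(img_times, nav, max_gap_s = config$map$max_gap_s)
  track <- data.frame(image_id = uids, timestamp_utc = geo$timestamp_utc,
                      longitude = geo$longitude, latitude = geo$latitude,
                      pred_class = predictions$pred_class,
                      confidence = predictions$confidence,
                      placed = geo$placed)
  export_track(track, file.path(out, "track.geojson"), "geojson")
  props <- class_proportions(track)
  write.csv(props, file.path(out, "class_proportions.csv"), row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("benthoscan")),
    seed = config$seed,
    stages = list(
      lasers = list(n_images = length(images), n_scaled = sum(scaled)),
      normalize = list(reference = ref_id, median_scale = sc_med,
                       footprint_m2 = spec$footprint_m2,
                       n_normalized = sum(usable)),
      features = list(n_rows = nrow(feat_df)),
      classify = model_info,
      map = list(n_placed = sum(track$placed),
                 n_unplaced = sum(!track$placed))
    )
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(scales = scales, features = feat_df,
                 predictions = predictions, track = track,
                 proportions = props, manifest = manifest,
                 feature_matrix = fm, embedding = emb))
}
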