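#' Read a navigation table
#'
#' CSV with header `timestamp_utc,latitude,longitude`; timestamps are
#' parsed as UTC.
#'
#' @param path CSV file.
#' @return data frame with POSIXct `timestamp_utc`.
#' @export
read_nav <- function(path) {
  nav <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("timestamp_utc", "latitude", "longitude") %in% names(nav)))
  nav$timestamp_utc <- as.POSIXct(nav$timestamp_utc,
                                  format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  if (anyNA(nav$timestamp_utc))
    nav$timestamp_utc <- as.POSIXct(read.csv(path)$timestamp_utc, tz = "UTC")
  nav
}

#' Georeference images by acquisition time
#'
#' Matches each image's UTC acquisition time to the nearest navigation fix
#' (ties to the earlier fix). Images farther than `max_gap_s` seconds from
#' any fix are flagged unplaced (NA coordinates). Deterministic and
#' independent of input order.
#'
#' @param image_times POSIXct vector of acquisition times.
#' @param nav navigation data frame (see [read_nav()]).
#' @param max_gap_s maximum tolerated time gap in seconds (default 30).
#' @return data frame `timestamp_utc, longitude, latitude, placed,
#'   nav_index`.
#' @export
georeference <- function(image_times, nav, max_gap_s = 30) {
  stopifnot(nrow(nav) >= 1)
  ord <- order(nav$timestamp_utc)
  nav <- nav[ord, , drop = FALSE]
  tn <- as.numeric(nav$timestamp_utc)
  ti <- as.numeric(image_times)
  lo <- findInterval(ti, tn)
  pick <- integer(length(ti))
  for (i in seq_along(ti)) {
    cand <- unique(pmin(pmax(c(lo[i], lo[i] + 1L), 1L), length(tn)))
    gaps <- abs(tn[cand] - ti[i])
    pick[i] <- cand[which.min(gaps)]  # which.min ties to the earlier fix
  }
  gap <- abs(tn[pick] - ti)
  placed <- gap <= max_gap_s
  data.frame(
    timestamp_utc = image_times,
    longitude = ifelse(placed, nav$longitude[pick], NA_real_),
    latitude = ifelse(placed, nav$latitude[pick], NA_real_),
    placed = placed,
    nav_index = ifelse(placed, pick, NA_integer_)
  )
}

#' Class proportions along a track
#'
#' Fractions of each predicted class over the placed points; fractions sum
#' to one.
#'
#' @param points data frame with `pred_class` and optionally `placed`.
#' @param classes optional class level set.
#' @return object of class `proportion_summary`: data frame
#'   `class, fraction` with attribute `n_points`.
#' @export
class_proportions <- function(points, classes = NULL) {
  if (!is.null(points$placed)) points <- points[points$placed, , drop = FALSE]
  if (nrow(points) == 0) stop("no placed points")
  if (is.null(classes)) classes <- sort(unique(as.character(points$pred_class)))
  counts <- table(factor(as.character(points$pred_class), levels = classes))
  out <- data.frame(class = classes,
                    fraction = as.numeric(counts) / sum(counts))
  attr(out, "n_points") <- sum(counts)
  class(out) <- c("proportion_summary", class(out))
  out
}

#' Change in class proportions between two summaries
#'
#' Per-class change in percentage points (`after - before`); over a common
#' class set the deltas sum to zero.
#'
#' @param before,after [class_proportions()] summaries.
#' @return data frame `class, before, after, delta_pp`.
#' @export
proportion_delta <- function(before, after) {
  classes <- sort(union(before$class, after$class))
  b <- stats::setNames(rep(0, length(classes)), classes)
  a <- b
  b[before$class] <- before$fraction
  a[after$class] <- after$fraction
  data.frame(class = classes, before = unname(b), after = unname(a),
             delta_pp = unname(100 * (a - b)))
}

#' Export classified track points
#'
#' GeoJSON (RFC 7946) FeatureCollection of Point features with properties
#' `image_id, class, confidence, time`, or an equivalent CSV. Unplaced
#' points are dropped.
#'
#' @param points data frame with `image_id, timestamp_utc, longitude,
#'   latitude, pred_class, confidence` (and optionally `placed`).
#' @param path output file.
#' @param format `"geojson"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
export_track <- function(points, path, format = c("geojson", "csv")) {
  format <- match.arg(format)
  if (!is.null(points$placed)) points <- points[points$placed, , drop = FALSE]
  tstr <- if (inherits(points$timestamp_utc, "POSIXct"))
    format(points$timestamp_utc, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  else as.character(points$timestamp_utc)
  if (format == "csv") {
    out <- data.frame(image_id = points$image_id, time = tstr,
                      longitude = points$longitude,
                      latitude = points$latitude,
                      class = points$pred_class,
                      confidence = points$confidence)
    write.csv(out, path, row.names = FALSE)
    return(invisible(path))
  }
  features <- lapply(seq_len(nrow(points)), function(i) {
    list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(points$longitude[i],
                                      points$latitude[i])),
      properties = list(image_id = points$image_id[i],
                        class = as.character(points$pred_class[i]),
                        confidence = points$confidence[i],
                        time = tstr[i])
    )
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read an exported GeoJSON track
#'
#' Round-trips [export_track()] output back into a data frame.
#'
#' @param path GeoJSON file.
#' @return data frame `image_id, timestamp_utc, longitude, latitude,
#'   pred_class, confidence`.
#' @export
read_track <- function(path) {
  fc <- jsonlite::read_json(path)
  stopifnot(identical(fc$type, "FeatureCollection"))
  if (length(fc$features) == 0) {
    return(data.frame(image_id = character(0), timestamp_utc = character(0),
                      longitude = numeric(0), latitude = numeric(0),
                      pred_class = character(0), confidence = numeric(0)))
  }
  do.call(rbind, lapply(fc$features, function(f) {
    data.frame(image_id = f$properties$image_id,
               timestamp_utc = f$properties$time,
               longitude = f$geometry$coordinates[[1]],
               latitude = f$geometry$coordinates[[2]],
               pred_class = f$properties$class,
               confidence = f$properties$confidence)
  }))
}
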