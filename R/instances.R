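# Detection instances: one segmented putative insect in one frame.

#' Create a detection instance
#'
#' The unit record passed between detection, matching, tracking and
#' classification: a closed mask polygon in image pixels plus derived
#' geometry, the segmenter score, and (optionally) the image crop and the
#' exact pixel set from segmentation.
#'
#' @param polygon n x 2 matrix (columns x, y, 0-based image px).
#' @param frame_id integer frame index within the series.
#' @param time POSIXct acquisition time of the frame.
#' @param score segmenter confidence in \[0, 1\].
#' @param crop optional numeric matrix, image region over the bbox.
#' @param pixels optional 2-column integer matrix of mask pixels (exact
#'   rasterization from segmentation; used for Jaccard computations).
#' @param truth_id optional ground-truth track id (synthetic data).
#' @param id optional stable identifier.
#' @return A list of class `"detection_instance"` with fields `polygon`,
#'   `area` (px^2), `centroid` (x, y), `bbox` (half-open), `frame_id`,
#'   `time`, `score` and the optional fields above. `area` is the pixel
#'   count when `pixels` is given, else the polygon shoelace area.
#' @export
new_instance <- function(polygon, frame_id = NA_integer_, time = NA,
                         score = 1, crop = NULL, pixels = NULL,
                         truth_id = NA, id = NA_integer_) {
  stopifnot(is.matrix(polygon), ncol(polygon) == 2, nrow(polygon) >= 3)
  area <- if (!is.null(pixels)) nrow(pixels) else polygon_area(polygon)
  if (area <= 0) stop("instance has non-positive area", call. = FALSE)
  centroid <- if (!is.null(pixels)) {
    c(mean(pixels[, 1]) + 0.5, mean(pixels[, 2]) + 0.5)
  } else polygon_centroid(polygon)
  structure(
    list(id = id, frame_id = as.integer(frame_id), time = time,
         polygon = polygon, area = area, centroid = centroid,
         bbox = polygon_bbox(polygon), score = score, crop = crop,
         pixels = pixels, truth_id = truth_id),
    class = "detection_instance")
}

#' @export
print.detection_instance <- function(x, ...) {
  cat(sprintf(
    "<detection_instance> frame %s  centroid (%.1f, %.1f)  area %.0f px^2\n",
    x$frame_id, x$centroid[1], x$centroid[2], x$area))
  invisible(x)
}

# Longest bounding-box side in px ("length" of the object for size filters
# and the classifier's scale feature).
instance_max_side <- function(inst) {
  max(inst$bbox[3] - inst$bbox[1], inst$bbox[4] - inst$bbox[2])
}

#' Summarise a list of instances as a data frame
#'
#' @param instances list of [new_instance()] records.
#' @return data.frame with one row per instance (id, frame_id, time, x, y,
#'   area, max_side, score, truth_id).
#' @export
instances_df <- function(instances) {
  if (length(instances) == 0L) {
    return(data.frame(id = integer(), frame_id = integer(),
                      time = as.POSIXct(character(), tz = "UTC"),
                      x = numeric(), y = numeric(), area = numeric(),
                      max_side = numeric(), score = numeric(),
                      truth_id = character(), stringsAsFactors = FALSE))
  }
  data.frame(
    id = vapply(instances, function(i) as.integer(i$id), integer(1)),
    frame_id = vapply(instances, function(i) i$frame_id, integer(1)),
    time = as.POSIXct(vapply(instances, function(i) as.numeric(i$time),
                             numeric(1)), origin = "1970-01-01", tz = "UTC"),
    x = vapply(instances, function(i) i$centroid[1], numeric(1)),
    y = vapply(instances, function(i) i$centroid[2], numeric(1)),
    area = vapply(instances, function(i) i$area, numeric(1)),
    max_side = vapply(instances, instance_max_side, numeric(1)),
    score = vapply(instances, function(i) i$score, numeric(1)),
    truth_id = vapply(instances, function(i) as.character(i$truth_id),
                      character(1)),
    stringsAsFactors = FALSE)
}
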