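# Series loading, filename metadata, and JSON artifact persistence.

#' Parse a frame filename
#'
#' Filenames follow `<device_id>.<YYYY-MM-DD_HH-MM-SS>.<ext>`.
#'
#' @param filename file name or path.
#' @return List `device_id`, `time` (POSIXct UTC), or NULL when the name
#'   does not match the pattern.
#' @export
parse_frame_filename <- function(filename) {
  bn <- basename(filename)
  m <- regmatches(bn, regexec(
    "^([A-Za-z0-9_-]+)\\.([0-9]{4}-[0-9]{2}-[0-9]{2}_[0-9]{2}-[0-9]{2}-[0-9]{2})\\.(jpg|jpeg|png)$",
    bn))[[1]]
  if (length(m) == 0) return(NULL)
  tm <- as.POSIXct(m[3], format = "%Y-%m-%d_%H-%M-%S", tz = "UTC")
  if (is.na(tm)) return(NULL)
  list(device_id = m[2], time = tm)
}

#' Format a frame filename
#'
#' @param device_id device label.
#' @param time POSIXct.
#' @param ext file extension.
#' @return Character file name.
#' @export
frame_filename <- function(device_id, time, ext = "png") {
  sprintf("%s.%s.%s", device_id, format(time, "%Y-%m-%d_%H-%M-%S",
                                        tz = "UTC"), ext)
}

#' Load a device image series from a directory
#'
#' Frames are sorted by the timestamp parsed from their filenames; malformed
#' names are skipped with a warning carrying the count. A warning is also
#' raised when a gap exceeds 3x the nominal frame interval.
#'
#' @param directory path containing `<device>.<datetime>.<ext>` images.
#' @param nominal_interval_min expected frame interval (default 20 min).
#' @return Object of class `"device_series"`: `device_id`, `frames`
#'   (data.frame path, time), `n_skipped`.
#' @export
load_series <- function(directory, nominal_interval_min = 20) {
  files <- list.files(directory, full.names = TRUE)
  files <- files[grepl("\\.(jpg|jpeg|png)$", files)]
  if (length(files) == 0)
    stop("no image files in ", directory, call. = FALSE)
  parsed <- lapply(files, parse_frame_filename)
  ok <- !vapply(parsed, is.null, logical(1))
  if (any(!ok))
    warning(sprintf("skipped %d malformed filename(s)", sum(!ok)),
            call. = FALSE)
  if (!any(ok)) stop("no parseable frames in ", directory, call. = FALSE)
  df <- data.frame(
    path = files[ok],
    device_id = vapply(parsed[ok], `[[`, "", "device_id"),
    time = as.POSIXct(vapply(parsed[ok], function(p) as.numeric(p$time),
                             numeric(1)), origin = "1970-01-01", tz = "UTC"),
    stringsAsFactors = FALSE)
  df <- df[order(df$time), , drop = FALSE]
  gaps <- diff(as.numeric(df$time)) / 60
  if (any(gaps > 3 * nominal_interval_min))
    warning(sprintf("%d frame gap(s) exceed 3x the nominal interval",
                    sum(gaps > 3 * nominal_interval_min)), call. = FALSE)
  structure(list(device_id = df$device_id[1],
                 frames = df[, c("path", "time")], n_skipped = sum(!ok)),
            class = "device_series")
}

#' Read an image frame as a grayscale matrix
#'
#' @param path PNG or JPEG file.
#' @return Numeric matrix in \[0, 1\], rows = x.
#' @export
read_frame <- function(path) {
  img <- EBImage::readImage(path)
  d <- EBImage::imageData(img)
  if (length(dim(d)) == 3) d <- apply(d, c(1, 2), mean)
  d
}

#' Write the frames of a synthetic series as image files
#'
#' @param series a `synthetic_series`.
#' @param directory output directory (created if needed).
#' @param ext `"png"` (default) or `"jpg"`.
#' @return Character vector of file paths, invisibly.
#' @export
write_series <- function(series, directory, ext = "png") {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(series$frames))
  for (f in seq_along(series$frames)) {
    paths[f] <- file.path(directory, frame_filename(series$device_id,
                                                    series$times[f], ext))
    EBImage::writeImage(EBImage::Image(series$frames[[f]]), paths[f])
  }
  invisible(paths)
}

# ---- detection JSON --------------------------------------------------------

#' Write detections to JSON
#'
#' One record per instance: frame, time (ISO 8601), polygon, area, bbox,
#' centroid, score, id. Round-trips through [read_detections_json()]
#' without loss of the stored fields.
#'
#' @param frames_dets list (per frame) of instance lists.
#' @param path output file.
#' @export
write_detections_json <- function(frames_dets, path) {
  recs <- list()
  for (dets in frames_dets) for (d in dets) {
    recs[[length(recs) + 1L]] <- list(
      id = d$id, frame = d$frame_id,
      time = format(d$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
      polygon = unname(apply(d$polygon, 1, function(r) c(r[1], r[2]),
                             simplify = FALSE)),
      area = d$area, bbox = as.numeric(d$bbox),
      centroid = as.numeric(d$centroid), score = d$score)
  }
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read detections from JSON
#'
#' @param path file from [write_detections_json()].
#' @return List (per frame) of instance lists; instances carry no crops or
#'   cached pixel sets (these are re-derived from the polygon on demand).
#' @export
read_detections_json <- function(path) {
  recs <- jsonlite::read_json(path)
  if (length(recs) == 0) return(list())
  frames <- sort(unique(vapply(recs, function(r) r$frame, numeric(1))))
  out <- lapply(seq_len(max(frames)), function(f) list())
  for (r in recs) {
    poly <- do.call(rbind, lapply(r$polygon, unlist))
    inst <- new_instance(poly, frame_id = r$frame,
                         time = as.POSIXct(r$time, tz = "UTC",
                                           format = "%Y-%m-%dT%H:%M:%S"),
                         score = r$score, id = r$id)
    out[[r$frame]] <- c(out[[r$frame]], list(inst))
  }
  out
}

#' Export tuboids as a flat CSV table
#'
#' @param tuboids list from [extract_tuboids()].
#' @param path output CSV.
#' @param device_id device label.
#' @return The written data.frame, invisibly.
#' @export
write_tuboids_csv <- function(tuboids, path, device_id = "dev01") {
  df <- data.frame(
    tuboid_id = vapply(tuboids, function(t) t$id, numeric(1)),
    device = device_id,
    start_time = format(as.POSIXct(
      vapply(tuboids, function(t) t$start, numeric(1)),
      origin = "1970-01-01", tz = "UTC"), "%Y-%m-%dT%H:%M:%S"),
    n_frames = vapply(tuboids, function(t) length(t$instances), numeric(1)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
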