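# End-to-end pipeline over a synthetic (or pre-rendered) series:
# detect -> match/track -> classify -> chronoecology, with per-stage
# artifacts and a manifest.

#' Attach ground-truth ids to detections
#'
#' Matches each detection to the visible ground-truth track whose centre is
#' nearest (within `max_dist` px) in the same frame.
#'
#' @param frames_dets list (per frame) of instance lists.
#' @param series the `synthetic_series` the frames came from.
#' @param max_dist assignment radius in px.
#' @return `frames_dets` with `truth_id` (and `truth_taxon`) filled in.
#' @export
assign_truth <- function(frames_dets, series, max_dist = 10) {
  tdf <- truth_df(series)
  for (f in seq_along(frames_dets)) {
    vis <- tdf[tdf$frame == f & tdf$visible, , drop = FALSE]
    for (k in seq_along(frames_dets[[f]])) {
      inst <- frames_dets[[f]][[k]]
      if (nrow(vis)) {
        dd <- sqrt((vis$x - inst$centroid[1])^2 +
                     (vis$y - inst$centroid[2])^2)
        j <- which.min(dd)
        if (dd[j] <= max_dist) {
          inst$truth_id <- vis$track_id[j]
          inst$truth_taxon <- vis$taxon[j]
        }
      }
      frames_dets[[f]][[k]] <- inst
    }
  }
  frames_dets
}

#' Collect labelled matching pairs from a truth-annotated series
#'
#' Builds [assemble_features()] rows for candidate pairs in consecutive
#' frames (within a centroid gate), labelled positive when both detections
#' carry the same ground-truth id. The raw label mix reflects the scene;
#' [fit_matcher()] re-balances batches to 50% negatives.
#'
#' @param frames_dets truth-annotated detections ([assign_truth()]).
#' @param frames list of image matrices.
#' @param backend descriptor backend.
#' @param gate_px candidate gate in px.
#' @param max_gap_frames also sample pairs this many frames apart (> 1
#'   produces gap-like positives and harder negatives).
#' @return List: `features` (n x 5 matrix), `labels` (0/1).
#' @export
collect_match_features <- function(frames_dets, frames,
                                   backend = ncc_backend(), gate_px = 150,
                                   max_gap_frames = 2) {
  feats <- list(); labs <- integer(0)
  for (f in seq_len(length(frames_dets) - 1)) {
    for (g in seq_len(max_gap_frames)) {
      if (f + g > length(frames_dets)) break
      for (m in frames_dets[[f]]) for (n in frames_dets[[f + g]]) {
        if (sqrt(sum((m$centroid - n$centroid)^2)) > gate_px) next
        S <- naive_similarity(m, n, frames[[f]], frames[[f + g]], backend)
        Q <- self_similarity(m, frames[[f]], frames[[f + g]], backend)
        feats[[length(feats) + 1L]] <-
          assemble_features(m, n, S = S, Q = Q)
        labs <- c(labs, as.integer(!is.na(m$truth_id) &&
                                     !is.na(n$truth_id) &&
                                     m$truth_id == n$truth_id))
      }
    }
  }
  list(features = do.call(rbind, feats), labels = labs)
}

pipeline_log <- function(log, stage, message, n = NA, secs = NA) {
  rbind(log, data.frame(stage = stage, message = message, n = n,
                        secs = round(secs, 2), stringsAsFactors = FALSE))
}

#' Run the full pipeline on a synthetic device-week
#'
#' Simulates capture events and a rendered series, detects every frame,
#' trains the matcher on truth-labelled pairs, tracks into tuboids,
#' classifies them (training on a split of the tuboids), and computes the
#' chronoecology outputs. Artifacts (events.csv, detections.json,
#' tuboids.csv, predictions.csv, diel_profile.csv) and a manifest
#' (config hash, seeds, package version, stage log, artifact checksums) are
#' written under `out`.
#'
#' @param taxa list of [taxon_spec()].
#' @param out output directory.
#' @param seed master seed; stage seeds are derived from it.
#' @param start POSIXct start time.
#' @param n_frames number of frames (default 504 = one week at 20 min).
#' @param frame_interval_min frame interval.
#' @param width,height scene size in px.
#' @param behaviour a [scene_behaviour()].
#' @param sun a [wzt_params()].
#' @param cfg a [tracker_config()].
#' @param windows diel windows for [window_fraction()] (NULL to skip).
#' @return List of class `"pipeline_result"`: `events`, `series` (frames
#'   dropped), `detections`, `tuboids`, `tracking` (metrics),
#'   `predictions`, `profiles`, `manifest`, `out`.
#' @export
run_pipeline <- function(taxa, out, seed = 1L,
                         start = as.POSIXct("2020-07-01 00:00:00",
                                            tz = "UTC"),
                         n_frames = 504, frame_interval_min = 20,
                         width = 640, height = 480,
                         behaviour = scene_behaviour(),
                         sun = wzt_params(), cfg = tracker_config(),
                         windows = NULL) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log <- data.frame()
  duration_h <- n_frames * frame_interval_min / 60

  t0 <- proc.time()[3]
  events <- simulate_capture_times(taxa, start, duration_h, sun,
                                   seed = seed)
  series <- render_series(events, taxa, start, n_frames,
                          frame_interval_min, width, height,
                          behaviour = behaviour, seed = seed + 1L)
  write_events_csv(events, file.path(out, "events.csv"), series$device_id)
  log <- pipeline_log(log, "simulate", "events simulated and rendered",
                      nrow(events), proc.time()[3] - t0)

  t0 <- proc.time()[3]
  dets <- detect_series(series)
  dets <- assign_truth(dets, series)
  write_detections_json(dets, file.path(out, "detections.json"))
  log <- pipeline_log(log, "detect", "frames segmented",
                      sum(lengths(dets)), proc.time()[3] - t0)

  t0 <- proc.time()[3]
  backend <- ncc_backend()
  train_frames <- seq_len(min(60L, length(dets)))
  pairs <- collect_match_features(dets[train_frames],
                                  series$frames[train_frames], backend)
  head <- if (length(unique(pairs$labels)) == 2) {
    fit_matcher(pairs$features, pairs$labels, backend, seed = seed + 2L)
  } else match_head() # degenerate scene: untrained head scores 0.5
  scorer <- make_series_scorer(series$frames, head, backend)
  tuboids <- track_series(dets, scorer, cfg)
  tracking <- evaluate_tracking(tuboids)
  write_tuboids_csv(tuboids, file.path(out, "tuboids.csv"),
                    series$device_id)
  log <- pipeline_log(log, "track", "tuboids extracted", length(tuboids),
                      proc.time()[3] - t0)

  t0 <- proc.time()[3]
  predictions <- NULL
  truth_lab <- vapply(tuboids, function(tb) {
    labs <- vapply(tb$instances, function(i)
      if (is.null(i$truth_taxon)) NA_character_ else i$truth_taxon,
      character(1))
    labs <- labs[!is.na(labs)]
    if (length(labs)) names(sort(table(labs), decreasing = TRUE))[1]
    else NA_character_
  }, character(1))
  usable <- which(!is.na(truth_lab))
  if (length(usable) >= 6 && length(unique(truth_lab[usable])) >= 2) {
    feats <- t(vapply(tuboids[usable], function(tb)
      tuboid_features(tb, seed = seed + 3L),
      numeric(attr(radial_embedder(), "embed_dim") + 1L)))
    scheme <- label_scheme(labels = sort(unique(truth_lab[usable])),
                           merges = list())
    set.seed(seed + 4L)
    tr <- sample(seq_along(usable), ceiling(0.7 * length(usable)))
    model <- train_tuboid_classifier(feats[tr, , drop = FALSE],
                                     truth_lab[usable][tr], scheme)
    cls <- classify_tuboid(model, feats)
    predictions <- data.frame(
      tuboid_id = vapply(tuboids[usable], function(t) t$id, numeric(1)),
      label = cls$label, truth = truth_lab[usable],
      held_out = !(seq_along(usable) %in% tr),
      probability = apply(cls$probs, 1, max),
      device = series$device_id,
      start_time = format(as.POSIXct(
        vapply(tuboids[usable], function(t) t$start, numeric(1)),
        origin = "1970-01-01", tz = "UTC"), "%Y-%m-%dT%H:%M:%S"),
      stringsAsFactors = FALSE)
    write.csv(predictions, file.path(out, "predictions.csv"),
              row.names = FALSE, quote = FALSE)
  }
  log <- pipeline_log(log, "classify", "tuboids classified",
                      length(usable), proc.time()[3] - t0)

  t0 <- proc.time()[3]
  tub_times <- as.POSIXct(vapply(tuboids, function(t) t$start, numeric(1)),
                          origin = "1970-01-01", tz = "UTC")
  tub_taxon <- if (!is.null(predictions)) predictions$label else
    rep("all", length(tuboids))
  wzt_h <- wzt_clock(tub_times[seq_along(tub_taxon)], sun) * 24
  profiles <- NULL
  if (length(wzt_h)) {
    profiles <- do.call(rbind, lapply(unique(tub_taxon), function(tx) {
      p <- diel_profile(wzt_h[tub_taxon == tx], rep("w1", sum(tub_taxon == tx)),
                        rep_days = duration_h / 24)
      cbind(taxon = tx, as.data.frame(p))
    }))
    write.csv(profiles, file.path(out, "diel_profile.csv"),
              row.names = FALSE, quote = FALSE)
  }
  wf <- if (!is.null(windows) && length(wzt_h))
    window_fraction(wzt_h, windows, seed = seed + 5L) else NULL
  log <- pipeline_log(log, "chrono", "diel statistics computed",
                      length(wzt_h), proc.time()[3] - t0)

  cfg_tmp <- tempfile()
  saveRDS(list(taxa = taxa, seed = seed, n_frames = n_frames,
               frame_interval_min = frame_interval_min,
               width = width, height = height), cfg_tmp)
  artifacts <- list.files(out, full.names = TRUE)
  manifest <- list(
    package = "chronotrap",
    version = as.character(utils::packageVersion("chronotrap")),
    seed = seed, config_hash = unname(tools::md5sum(cfg_tmp)),
    stages = log,
    artifacts = as.list(setNames(unname(tools::md5sum(artifacts)),
                                 basename(artifacts))))
  unlink(cfg_tmp)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  structure(list(events = events, detections = dets, tuboids = tuboids,
                 tracking = tracking, predictions = predictions,
                 profiles = profiles, window_fraction = wf,
                 manifest = manifest, out = out),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result> %d events -> %d tuboids (purity %.3f) in %s\n",
    nrow(x$events), length(x$tuboids), x$tracking$purity, x$out))
  invisible(x)
}
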