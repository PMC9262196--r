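# Shared fixtures, built in code at test time.

# Axis-aligned square instance with exact pixel set.
inst_square <- function(x0, y0, side, frame_id = 1L,
                        time = as.POSIXct("2020-07-01 00:00:00", tz = "UTC"),
                        score = 1, id = NA_integer_) {
  poly <- cbind(c(x0, x0 + side, x0 + side, x0),
                c(y0, y0, y0 + side, y0 + side))
  pix <- as.matrix(expand.grid(x0:(x0 + side - 1), y0:(y0 + side - 1)))
  colnames(pix) <- NULL
  new_instance(poly, frame_id = frame_id, time = time, score = score,
               pixels = pix, id = id)
}

# Axis-aligned rectangle instance (for size-filter boundary cases).
inst_rect <- function(x0, y0, w, h, frame_id = 1L,
                      time = as.POSIXct("2020-07-01 00:00:00", tz = "UTC")) {
  poly <- cbind(c(x0, x0 + w, x0 + w, x0), c(y0, y0, y0 + h, y0 + h))
  pix <- as.matrix(expand.grid(x0:(x0 + w - 1), y0:(y0 + h - 1)))
  colnames(pix) <- NULL
  new_instance(poly, frame_id = frame_id, time = time, pixels = pix)
}

default_test_taxa <- function() {
  list(taxon_spec("diurnal", 0.3, peaks = 6, peak_sd = 2,
                  size_px = c(50, 5)),
       taxon_spec("nocturnal", 0.3, peaks = 18, peak_sd = 2,
                  size_px = c(70, 6), darkness = 0.55))
}

# One rendered scene with truth-annotated detections, cached per option set
# so several test files can share it.
.scene_cache <- new.env(parent = emptyenv())
test_scene <- function(key = "default", n_frames = 40, width = 450,
                       height = 350, seed = 11,
                       behaviour = scene_behaviour(p_occlude = 0,
                                                   p_escape = 0)) {
  if (!is.null(.scene_cache[[key]])) return(.scene_cache[[key]])
  taxa <- default_test_taxa()
  start <- as.POSIXct("2020-07-01 00:00:00", tz = "UTC")
  ev <- simulate_capture_times(taxa, start, n_frames * 20 / 60, seed = seed)
  series <- render_series(ev, taxa, start, n_frames, width = width,
                          height = height, behaviour = behaviour,
                          seed = seed + 1)
  dets <- assign_truth(detect_series(series), series)
  out <- list(taxa = taxa, events = ev, series = series, dets = dets)
  .scene_cache[[key]] <- out
  out
}

# Linearly separable synthetic matching pairs (feature space only).
synthetic_pairs <- function(n = 200, seed = 42) {
  set.seed(seed)
  np <- n %/% 2; nn <- n - np
  pos <- cbind(runif(np, 0.7, 1), runif(np, 0, 0.4), runif(np, 0, 15),
               runif(np, 0, 0.3), runif(np, 0, 0.4))
  neg <- cbind(runif(nn, 0, 0.35), runif(nn, 0.6, 1), runif(nn, 60, 200),
               runif(nn, 0.8, 2), runif(nn, 0, 0.4))
  f <- rbind(pos, neg)
  colnames(f) <- c("S", "Q", "centroid_dist", "abs_log_area_ratio",
                   "log_dt")
  list(features = f, labels = c(rep(1, np), rep(0, nn)))
}

# A trained head shared across tests (trained on the separable pairs).
.head_cache <- new.env(parent = emptyenv())
trained_test_head <- function() {
  if (is.null(.head_cache$head)) {
    p <- synthetic_pairs(400, seed = 7)
    .head_cache$head <- fit_matcher(p$features, p$labels, seed = 7)
  }
  .head_cache$head
}

# Lookup scorer for hand-built tracking fixtures: scores[[from_id, to_id]].
lookup_scorer <- function(score_matrix) {
  function(m, n) {
    s <- score_matrix[m$id, n$id]
    if (is.na(s)) 0 else s
  }
}

# Frame list of instances at given (id, x, y) coordinates per frame.
frames_fixture <- function(frame_specs, t0 = as.POSIXct("2020-07-01",
                                                        tz = "UTC"),
                           interval_min = 20) {
  lapply(seq_along(frame_specs), function(f) {
    spec <- frame_specs[[f]]
    if (is.null(spec)) return(list())
    lapply(seq_len(nrow(spec)), function(r)
      inst_square(spec[r, "x"], spec[r, "y"], 10, frame_id = f,
                  time = t0 + (f - 1) * interval_min * 60,
                  id = spec[r, "id"]))
  })
}
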