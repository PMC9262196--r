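# Synthetic sticky-trap scenes: diel-modulated arrival processes and
# rendered image series with ground truth, so the whole pipeline can be
# exercised without field data.

#' Specify a synthetic taxon
#'
#' A taxon is an arrival process (expected captures per hour, modulated by a
#' 24 h-periodic diel profile) plus a body-size distribution. The diel
#' profile is a sum of wrapped-Gaussian bumps over one or two peak phases
#' plus a uniform floor, normalised so its mean over 24 h is exactly 1 —
#' `base_rate` is therefore the marginal capture rate.
#'
#' @param name label string.
#' @param base_rate expected captures per hour (>= 0).
#' @param peaks peak phase(s) in Warped Zeitgeber hours (length 0, 1 or 2;
#'   `NULL` for a flat profile).
#' @param peak_sd bump concentration as a circular sd in hours (recycled).
#' @param peak_weight relative mass of each bump (recycled).
#' @param floor weight of the uniform component (0 = fully peaked).
#' @param size_px mean and sd of body length in px; the simulator clamps
#'   drawn sizes to \[30, 600\] px unless `clamp_size = FALSE`.
#' @param darkness mean blob darkness in \[0, 1\] (1 = black on the card).
#' @param clamp_size clamp drawn body lengths to \[30, 600\] px?
#' @return Object of class `"taxon_spec"`.
#' @examples
#' crep <- taxon_spec("crepuscular", 2, peaks = c(0, 12), peak_sd = 1.5)
#' h <- seq(0, 24, by = 0.1)
#' stopifnot(abs(mean(diel_intensity(h[-length(h)], crep)) - 1) < 1e-2)
#' @export
taxon_spec <- function(name, base_rate, peaks = NULL, peak_sd = 2,
                       peak_weight = 1, floor = 0.2,
                       size_px = c(60, 8), darkness = 0.7,
                       clamp_size = TRUE) {
  if (!is.finite(base_rate) || base_rate < 0)
    stop("base_rate must be finite and >= 0", call. = FALSE)
  if (length(peaks) > 0 && (any(peaks < 0) || any(peaks >= 24)))
    stop("peaks must lie in [0, 24)", call. = FALSE)
  if (floor < 0) stop("floor must be >= 0", call. = FALSE)
  if (length(peaks) == 0 && floor == 0)
    stop("flat profile needs floor > 0", call. = FALSE)
  structure(
    list(name = name, base_rate = base_rate, peaks = peaks,
         peak_sd = rep_len(peak_sd, max(1L, length(peaks))),
         peak_weight = rep_len(peak_weight, max(1L, length(peaks))),
         floor = floor, size_px = size_px, darkness = darkness,
         clamp_size = clamp_size),
    class = "taxon_spec")
}

# Wrapped-normal density on a 24 h circle (5 wraps are ample for sd <= 6 h).
wrapped_dnorm24 <- function(h, mu, sd) {
  out <- 0
  for (k in -2:2) out <- out + stats::dnorm(h, mu + 24 * k, sd)
  out
}

#' Diel intensity multiplier of a taxon
#'
#' @param wzt_h time of day in Warped Zeitgeber hours (vectorised).
#' @param spec a [taxon_spec()].
#' @return Non-negative multiplier with mean 1 over the 24 h day.
#' @export
diel_intensity <- function(wzt_h, spec) {
  h <- wzt_h %% 24
  u <- rep(spec$floor / 24, length(h))
  if (length(spec$peaks) > 0) {
    for (p in seq_along(spec$peaks))
      u <- u + spec$peak_weight[p] *
        wrapped_dnorm24(h, spec$peaks[p], spec$peak_sd[p])
  }
  total <- spec$floor + sum(if (length(spec$peaks)) spec$peak_weight else 0)
  24 * u / total
}

#' Simulate capture times from diel-modulated Poisson arrivals
#'
#' Each taxon contributes an independent inhomogeneous Poisson process with
#' intensity `base_rate * diel_intensity(WZT(t))`, simulated by thinning.
#'
#' @param taxa list of [taxon_spec()] objects.
#' @param start POSIXct (UTC) start of the observation window.
#' @param duration_h window length in hours (> 0).
#' @param sun [wzt_params()] giving sunrise and day length used to convert
#'   clock time to Warped Zeitgeber time. The default (sunrise 06:00,
#'   day length 12 h) makes WZT coincide with ordinary Zeitgeber time.
#' @param seed integer seed; fixed seed gives a bit-identical event list.
#' @return data.frame with columns `taxon`, `time` (POSIXct UTC), sorted by
#'   time.
#' @export
simulate_capture_times <- function(taxa, start, duration_h, sun = wzt_params(),
                                   seed = 1L) {
  if (!is.finite(duration_h) || duration_h <= 0)
    stop("duration_h must be > 0", call. = FALSE)
  if (inherits(taxa, "taxon_spec")) taxa <- list(taxa)
  set.seed(seed)
  out <- list()
  for (spec in taxa) {
    if (spec$base_rate == 0) next
    grid <- seq(0, 24, by = 0.05)
    lam_max <- spec$base_rate * max(diel_intensity(grid, spec)) * 1.0001
    n <- rpois(1, lam_max * duration_h)
    if (n == 0) next
    t_h <- sort(runif(n, 0, duration_h))
    abs_t <- start + t_h * 3600
    wzt_h <- wzt_clock(abs_t, sun) * 24
    lam <- spec$base_rate * diel_intensity(wzt_h, spec)
    keep <- runif(n) < lam / lam_max
    if (any(keep))
      out[[length(out) + 1L]] <- data.frame(
        taxon = spec$name, time = abs_t[keep], stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(taxon = character(),
                      time = as.POSIXct(character(), tz = "UTC"),
                      stringsAsFactors = FALSE))
  ev <- do.call(rbind, out)
  ev <- ev[order(ev$time), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Behaviour parameters for rendered scenes
#'
#' @param jitter_sd per-frame positional jitter sd in px (trapped insects
#'   wiggle but do not travel).
#' @param max_jitter hard bound on displacement from the arrival point, px.
#' @param p_occlude per-frame probability of entering a transient occlusion
#'   (two-state Markov chain).
#' @param p_reappear per-frame probability of leaving the occluded state.
#' @param p_escape per-frame probability of permanent escape; once escaped an
#'   insect is never visible again.
#' @return list of class `"scene_behaviour"`.
#' @export
scene_behaviour <- function(jitter_sd = 1, max_jitter = 5,
                            p_occlude = 0.02, p_reappear = 0.5,
                            p_escape = 0.002) {
  structure(list(jitter_sd = jitter_sd, max_jitter = max_jitter,
                 p_occlude = p_occlude, p_reappear = p_reappear,
                 p_escape = p_escape), class = "scene_behaviour")
}

draw_size <- function(spec) {
  len <- rnorm(1, spec$size_px[1], spec$size_px[2])
  if (isTRUE(spec$clamp_size)) len <- min(600, max(30, len))
  max(len, 4)
}

# Per-track speckle texture, fixed for the lifetime of the insect so that
# appearance-based matching has a stable signal.
make_texture <- function(n, darkness) {
  base <- 1 - darkness
  tex <- matrix(base + runif(n * n, -0.12, 0.12), n, n)
  pmin(pmax(tex, 0), 1)
}

#' Render an image series with ground-truth tracks
#'
#' One grayscale frame per interval; every insect captured before a frame's
#' time is rendered (unless occluded or escaped) as a textured ellipse at its
#' arrival point plus bounded per-frame jitter. Pixels and ground truth are
#' generated from the same geometry, so rasterising the truth polygons
#' reproduces the rendered foreground.
#'
#' @param events data.frame from [simulate_capture_times()].
#' @param taxa the list of [taxon_spec()] used to simulate `events` (sizes
#'   and darkness are drawn per insect from its taxon).
#' @param start POSIXct time of the first frame.
#' @param n_frames number of frames.
#' @param frame_interval_min minutes between frames (default 20).
#' @param width,height image size in px.
#' @param background card brightness in \[0, 1\].
#' @param noise_sd per-pixel Gaussian noise sd.
#' @param behaviour a [scene_behaviour()].
#' @param seed integer seed.
#' @param max_tries placement retries before an overcrowding error.
#' @param device_id device label stored with the series.
#' @return List of class `"synthetic_series"` with `frames` (list of
#'   width x height matrices in \[0, 1\]), `times` (POSIXct per frame),
#'   `tracks` (list of ground-truth tracks: `track_id`, `taxon`,
#'   `arrival_time`, `size_len`, `size_wid`, `angle`, and a per-frame
#'   data.frame `frames` with columns frame, time, x, y, visible) and
#'   `device_id`.
#' @export
render_series <- function(events, taxa, start, n_frames,
                          frame_interval_min = 20, width = 640, height = 480,
                          background = 0.85, noise_sd = 0.015,
                          behaviour = scene_behaviour(), seed = 1L,
                          max_tries = 200L, device_id = "dev01") {
  if (frame_interval_min <= 0) stop("frame_interval_min must be > 0")
  set.seed(seed)
  taxa_by_name <- setNames(taxa, vapply(taxa, `[[`, "", "name"))
  times <- start + (seq_len(n_frames) - 1) * frame_interval_min * 60
  events <- events[events$time <= times[n_frames], , drop = FALSE]

  # Assign geometry and behavioural fate per insect up front.
  tracks <- list()
  placed <- matrix(numeric(0), ncol = 3) # x, y, radius
  for (i in seq_len(nrow(events))) {
    spec <- taxa_by_name[[events$taxon[i]]]
    if (is.null(spec)) stop("event taxon not in `taxa`: ", events$taxon[i])
    len <- draw_size(spec)
    wid <- len * runif(1, 0.45, 0.6)
    if (len / 2 + 2 > min(width, height) / 2 - 2)
      stop("image too small to hold a ", round(len), " px insect")
    margin <- len / 2 + 2
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      x <- runif(1, margin, width - margin)
      y <- runif(1, margin, height - margin)
      if (nrow(placed) == 0 ||
          all(sqrt((placed[, 1] - x)^2 + (placed[, 2] - y)^2) >
              (placed[, 3] + len / 2 + behaviour$max_jitter * 2 + 2))) {
        ok <- TRUE; break
      }
    }
    if (!ok)
      stop(sprintf("overcrowding: could not place insect arriving %s",
                   format(events$time[i])), call. = FALSE)
    placed <- rbind(placed, c(x, y, len / 2))
    first_frame <- which(times >= events$time[i])[1]
    if (is.na(first_frame)) next
    nf <- n_frames - first_frame + 1L
    # Escape: geometric lifetime in frames (p_escape per frame after arrival).
    life <- if (behaviour$p_escape > 0) rgeom(1, behaviour$p_escape) + 1L else Inf
    # Occlusion: two-state Markov chain, starts visible.
    occl <- logical(nf)
    st <- FALSE
    for (k in seq_len(nf)) {
      st <- if (st) runif(1) >= behaviour$p_reappear
            else runif(1) < behaviour$p_occlude
      occl[k] <- st
    }
    # Random-walk jitter clamped to max displacement from the arrival point.
    jx <- pmin(pmax(cumsum(rnorm(nf, 0, behaviour$jitter_sd)),
                    -behaviour$max_jitter), behaviour$max_jitter)
    jy <- pmin(pmax(cumsum(rnorm(nf, 0, behaviour$jitter_sd)),
                    -behaviour$max_jitter), behaviour$max_jitter)
    frames_df <- data.frame(
      frame = first_frame:n_frames,
      time = times[first_frame:n_frames],
      x = x + jx, y = y + jy,
      visible = !occl & (seq_len(nf) <= life))
    tracks[[length(tracks) + 1L]] <- list(
      track_id = sprintf("t%03d", length(tracks) + 1L),
      taxon = events$taxon[i], arrival_time = events$time[i],
      size_len = len, size_wid = wid, angle = runif(1, 0, pi),
      texture = make_texture(ceiling(len) + 4, spec$darkness),
      frames = frames_df)
  }

  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    img <- matrix(background, width, height) +
      matrix(rnorm(width * height, 0, noise_sd), width, height)
    for (tr in tracks) {
      row <- tr$frames[tr$frames$frame == f, ]
      if (nrow(row) == 0 || !row$visible) next
      img <- draw_blob(img, row$x, row$y, tr$size_len / 2, tr$size_wid / 2,
                       tr$angle, tr$texture)
    }
    frames[[f]] <- pmin(pmax(img, 0), 1)
  }
  tracks <- lapply(tracks, function(tr) { tr$texture <- NULL; tr })
  structure(list(frames = frames, times = times, tracks = tracks,
                 width = width, height = height, device_id = device_id),
            class = "synthetic_series")
}

# Paint a textured ellipse into an image matrix (rows = x, cols = y).
draw_blob <- function(img, cx, cy, a, b, angle, texture) {
  w <- nrow(img); h <- ncol(img)
  r <- ceiling(max(a, b)) + 1
  xs <- max(1, floor(cx - r)):min(w, ceiling(cx + r))
  ys <- max(1, floor(cy - r)):min(h, ceiling(cy + r))
  gx <- rep(xs - 0.5, times = length(ys)) - cx
  gy <- rep(ys - 0.5, each = length(xs)) - cy
  ca <- cos(angle); sa <- sin(angle)
  u <- gx * ca + gy * sa
  v <- -gx * sa + gy * ca
  inside <- (u / a)^2 + (v / b)^2 <= 1
  if (!any(inside)) return(img)
  nt <- nrow(texture)
  ti <- pmin(nt, pmax(1, round(u + nt / 2)))
  tj <- pmin(nt, pmax(1, round(v + nt / 2)))
  sub <- img[xs, ys, drop = FALSE]
  sub[inside] <- texture[cbind(ti[inside], tj[inside])]
  img[xs, ys] <- sub
  img
}

#' Ground-truth mask polygon of a track at one frame
#'
#' @param track one element of a `synthetic_series$tracks` list.
#' @param frame frame index.
#' @return n x 2 polygon in image px, or NULL if the track is absent or not
#'   visible in that frame.
#' @export
truth_polygon <- function(track, frame) {
  row <- track$frames[track$frames$frame == frame, ]
  if (nrow(row) == 0 || !row$visible) return(NULL)
  # draw_blob tests pixel centres against the same ellipse, so this polygon
  # rasterizes to the rendered foreground (up to the 64-gon approximation)
  ellipse_polygon(row$x, row$y, track$size_len / 2, track$size_wid / 2,
                  track$angle, n = 64)
}

#' Flatten ground-truth tracks to a data frame
#'
#' @param series a `synthetic_series`.
#' @return data.frame: track_id, taxon, frame, time, x, y, visible.
#' @export
truth_df <- function(series) {
  do.call(rbind, lapply(series$tracks, function(tr) {
    cbind(data.frame(track_id = tr$track_id, taxon = tr$taxon,
                     stringsAsFactors = FALSE),
          tr$frames)
  }))
}

#' Write capture events to CSV
#'
#' Columns `taxon`, `arrival_iso8601`, `device_id`.
#' @param events data.frame from [simulate_capture_times()].
#' @param path output file.
#' @param device_id device label stored with every event.
#' @export
write_events_csv <- function(events, path, device_id = "dev01") {
  df <- data.frame(taxon = events$taxon,
                   arrival_iso8601 = format(events$time, "%Y-%m-%dT%H:%M:%S",
                                            tz = "UTC"),
                   device_id = device_id, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a capture-event CSV
#'
#' @param path CSV written by [write_events_csv()] (or any file with columns
#'   taxon, arrival_iso8601, device_id).
#' @return data.frame with `taxon`, `time` (POSIXct UTC), `device_id`.
#' @export
read_events_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  data.frame(taxon = df$taxon,
             time = as.POSIXct(df$arrival_iso8601, tz = "UTC",
                               format = "%Y-%m-%dT%H:%M:%S"),
             device_id = df$device_id, stringsAsFactors = FALSE)
}
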