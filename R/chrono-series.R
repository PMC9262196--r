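# Capture-rate series and rhythmicity statistics. A sticky trap integrates
# arrivals: the per-frame insect count is a cumulative process, and the
# capture rate dN/dt is the observable standing in for flight activity.

#' Build a capture-rate series
#'
#' Either bin event times (tuboid start times) into uniform bins, or wrap a
#' per-frame count series.
#'
#' @param events POSIXct vector of capture times (mutually exclusive with
#'   `counts`).
#' @param counts integer vector of per-frame cumulative insect counts.
#' @param times POSIXct vector: frame times for `counts`, or the series span
#'   for `events` (defaults to the event range).
#' @param bin_min bin width in minutes for event binning (default 60).
#' @return Object of class `"capture_series"`: `time` (bin centres or frame
#'   times), `rate` (captures per hour; NULL for count series until
#'   [lowpass()] is applied), `counts`, `bin_min`, `kind`.
#' @export
rate_series <- function(events = NULL, counts = NULL, times = NULL,
                        bin_min = 60) {
  if (!is.null(events) && !is.null(counts))
    stop("give events or counts, not both", call. = FALSE)
  if (!is.null(counts)) {
    if (is.null(times)) stop("counts need frame times", call. = FALSE)
    if (is.unsorted(as.numeric(times)))
      stop("times must be monotone", call. = FALSE)
    if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
    return(structure(list(time = times, rate = NULL, counts = counts,
                          bin_min = NA_real_, kind = "counts"),
                     class = "capture_series"))
  }
  ev <- as.numeric(events)
  if (is.unsorted(ev)) ev <- sort(ev)
  span <- if (!is.null(times)) as.numeric(range(times)) else
    if (length(ev)) range(ev) else c(0, 3600)
  breaks <- seq(span[1], span[2] + bin_min * 60, by = bin_min * 60)
  cnt <- if (length(ev))
    as.numeric(table(cut(ev, breaks, right = FALSE, include.lowest = TRUE)))
  else rep(0, length(breaks) - 1)
  structure(list(
    time = as.POSIXct(breaks[-length(breaks)] + bin_min * 30,
                      origin = "1970-01-01", tz = "UTC"),
    rate = cnt / (bin_min / 60), counts = cnt, bin_min = bin_min,
    kind = "events"), class = "capture_series")
}

# Moving average with shrinking windows at the edges (length preserved).
running_mean <- function(x, k) {
  h <- (k - 1) %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i)
    mean(x[max(1, i - h):min(n, i + h)]), numeric(1))
}

#' Low-pass filter a cumulative count series
#'
#' The pair of filters applied to per-frame counts: a running median
#' (`k_median`) on the raw counts to kill single-frame detection noise,
#' first differencing to the instantaneous capture rate dN/dt, then a
#' uniform moving average (`k_uniform`) on the rate. Edges are handled by
#' shrinking windows. At a 20-min frame interval the k = 5 filters each span
#' 100 min ([lowpass_span()]).
#'
#' @param series a `"capture_series"` of kind `"counts"` (or a numeric count
#'   vector with `times`).
#' @param k_median,k_uniform filter orders (odd; default 5).
#' @param times frame times when `series` is a bare vector.
#' @return A `"capture_series"` with `counts` (median-filtered), `rate`
#'   (filtered dN/dt in h^-1, one value per frame transition) and `time`
#'   (transition midpoints). If the series is shorter than the filter order
#'   a warning is raised and the attribute `filtered` is FALSE.
#' @export
lowpass <- function(series, k_median = 5, k_uniform = 5, times = NULL) {
  if (is.numeric(series))
    series <- rate_series(counts = series, times = times)
  stopifnot(inherits(series, "capture_series"), series$kind == "counts")
  cnt <- series$counts
  tt <- as.numeric(series$time)
  if (length(cnt) < max(k_median, k_uniform) + 1) {
    warning("series shorter than filter order; filters skipped",
            call. = FALSE)
    dt_h <- diff(tt) / 3600
    out <- structure(list(
      time = as.POSIXct((tt[-1] + tt[-length(tt)]) / 2,
                        origin = "1970-01-01", tz = "UTC"),
      rate = diff(cnt) / dt_h, counts = cnt, bin_min = series$bin_min,
      kind = "counts"), class = "capture_series")
    attr(out, "filtered") <- FALSE
    return(out)
  }
  med <- as.numeric(stats::runmed(cnt, k_median, endrule = "median"))
  dt_h <- diff(tt) / 3600
  rate <- diff(med) / dt_h
  rate_f <- running_mean(rate, k_uniform)
  out <- structure(list(
    time = as.POSIXct((tt[-1] + tt[-length(tt)]) / 2,
                      origin = "1970-01-01", tz = "UTC"),
    rate = rate_f, counts = med, bin_min = series$bin_min, kind = "counts"),
    class = "capture_series")
  attr(out, "filtered") <- TRUE
  out
}

#' Temporal span of the low-pass filters
#'
#' A filter of order k applied to samples `frame_interval_min` apart draws
#' on a window of `k * frame_interval_min` minutes: 100 min for the default
#' k = 5 at 20-min frames.
#'
#' @param k filter order.
#' @param frame_interval_min sampling interval in minutes.
#' @return Span in minutes.
#' @export
lowpass_span <- function(k = 5, frame_interval_min = 20) {
  k * frame_interval_min
}

# Pearson autocorrelation of a series at an integer bin lag.
acf_at_lag <- function(x, lag_bins) {
  n <- length(x)
  if (lag_bins >= n) stop("lag exceeds series span", call. = FALSE)
  a <- x[seq_len(n - lag_bins)]
  b <- x[seq_len(n - lag_bins) + lag_bins]
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)
}

#' Rhythmicity of a group of capture-rate series
#'
#' Per series, the Pearson autocorrelation of the rate at the bin lag
#' closest to `lag_h` (default 24 h); across series, a two-sided one-sample
#' t-test of the autocorrelations against 0. A significantly positive mean
#' indicates a daily rhythm.
#'
#' @param series_group list of `"capture_series"` (or bare rate vectors).
#' @param lag_h target lag in hours.
#' @param bin_h bin width in hours of bare vectors (taken from the series
#'   objects otherwise).
#' @return List: `acf` (per-series values), `mean`, `t`, `p_value`, `n`,
#'   `lag_bins`.
#' @export
rhythmicity <- function(series_group, lag_h = 24, bin_h = 1) {
  rates <- lapply(series_group, function(s)
    if (inherits(s, "capture_series")) s$rate else as.numeric(s))
  bins <- vapply(series_group, function(s)
    if (inherits(s, "capture_series") && is.finite(s$bin_min))
      s$bin_min / 60 else bin_h, numeric(1))
  vals <- mapply(function(r, b) acf_at_lag(r, round(lag_h / b)),
                 rates, bins)
  vals <- vals[!is.na(vals)]
  if (length(vals) < 2)
    stop("need >= 2 series for the group test", call. = FALSE)
  tt <- t.test(vals, mu = 0)
  list(acf = unname(vals), mean = mean(vals),
       t = unname(tt$statistic), p_value = tt$p.value,
       n = length(vals), lag_bins = round(lag_h / bins[1]))
}

#' Diel activity profile across replicates
#'
#' Per Warped Zeitgeber hour bin: the mean capture rate over replicate-level
#' rates (replicate = device x week) and its standard error across
#' replicates.
#'
#' @param wzt_h event times as WZT hours in \[0, 24).
#' @param replicate replicate key per event.
#' @param rep_days observed days per replicate: a single number or a named
#'   vector keyed by replicate (a WZT-hour bin is observed once per day, so
#'   the replicate rate in a bin is count / days).
#' @return Object of class `"diel_profile"`: data.frame with `bin` (0-23),
#'   `mean` (h^-1), `se`, `n_rep`.
#' @export
diel_profile <- function(wzt_h, replicate, rep_days = 7) {
  stopifnot(length(wzt_h) == length(replicate))
  reps <- sort(unique(as.character(replicate)))
  days <- if (length(rep_days) == 1)
    setNames(rep(rep_days, length(reps)), reps) else rep_days
  bins <- 0:23
  per_rep <- sapply(reps, function(r) {
    cnt <- tabulate(floor(wzt_h[replicate == r] %% 24) + 1, 24)
    cnt / days[[r]]
  })
  per_rep <- matrix(per_rep, nrow = 24)
  se <- if (length(reps) > 1)
    apply(per_rep, 1, sd) / sqrt(length(reps)) else rep(0, 24)
  out <- data.frame(
    bin = bins,
    mean = rowMeans(per_rep),
    se = se,
    n_rep = length(reps))
  class(out) <- c("diel_profile", "data.frame")
  out
}

# Merge overlapping/adjacent hour intervals on [0, 24].
merge_windows <- function(windows) {
  if (length(windows) == 0) return(list())
  w <- do.call(rbind, lapply(windows, function(x) sort(x[1:2])))
  w <- w[order(w[, 1]), , drop = FALSE]
  out <- list(w[1, ])
  for (i in seq_len(nrow(w))[-1]) {
    last <- out[[length(out)]]
    if (w[i, 1] <= last[2]) out[[length(out)]] <- c(last[1],
                                                    max(last[2], w[i, 2]))
    else out[[length(out) + 1]] <- w[i, ]
  }
  out
}

#' Fraction of captures inside diel windows
#'
#' Observed share of events falling inside a set of WZT-hour windows,
#' against the time-uniform null (total merged window length / 24) with a
#' percentile bootstrap CI. Wrap-around windows (e.g. "WZT < 2 or WZT > 22")
#' are passed as two intervals.
#'
#' @param wzt_h event times as WZT hours in \[0, 24).
#' @param windows list of `c(lo, hi)` hour intervals within \[0, 24\];
#'   overlapping windows are merged before measuring.
#' @param n_boot bootstrap replicates (default 10,000).
#' @param level CI level.
#' @param seed integer seed for the resampling.
#' @return List: `observed`, `null`, `ci` (length 2), `n_events`,
#'   `windows` (merged).
#' @export
window_fraction <- function(wzt_h, windows, n_boot = 10000, level = 0.95,
                            seed = 1L) {
  win <- merge_windows(windows)
  if (length(win) == 0)
    return(list(observed = 0, null = 0, ci = c(0, 0),
                n_events = length(wzt_h), windows = win))
  if (any(vapply(win, function(w) w[1] < 0 || w[2] > 24, logical(1))))
    stop("windows must lie within [0, 24]", call. = FALSE)
  inside <- function(h) {
    hit <- rep(FALSE, length(h))
    for (w in win) hit <- hit | (h >= w[1] & h < w[2])
    hit
  }
  null <- sum(vapply(win, function(w) w[2] - w[1], numeric(1))) / 24
  if (length(wzt_h) == 0)
    return(list(observed = NA_real_, null = null, ci = c(NA, NA),
                n_events = 0L, windows = win))
  hits <- inside(wzt_h)
  obs <- mean(hits)
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(b)
    mean(hits[sample.int(length(hits), replace = TRUE)]), numeric(1))
  a <- (1 - level) / 2
  list(observed = obs, null = null,
       ci = unname(quantile(boot, c(a, 1 - a))),
       n_events = length(wzt_h), windows = win)
}

#' Trap-saturation linearity test
#'
#' If capture rate is unaffected by the insects already on the card, the
#' count in the first half of a 6-day trial is a binomial half of the total:
#' the per-trap-week response N_first3days / N_first6days has expectation
#' 1/2, independent of trap load. Per taxon, an ordinary least-squares fit
#' of the response on the trap-week's total insect count (all taxa) is
#' reported with t-tests of intercept - 1/2 and slope - 0.
#'
#' @param day event times in days since the start of each trap-week
#'   (\[0, 6) used).
#' @param taxon,replicate labels per event.
#' @param trial_days trial length (default 6; the response splits it in
#'   half).
#' @return List: `per_taxon` data.frame (taxon, n_weeks, intercept,
#'   intercept_se, intercept_p, slope, slope_se, slope_p), `n_excluded`
#'   (trap-weeks with no captures of the taxon).
#' @export
saturation_test <- function(day, taxon, replicate, trial_days = 6) {
  stopifnot(length(day) == length(taxon), length(day) == length(replicate))
  keep <- day >= 0 & day < trial_days
  day <- day[keep]; taxon <- as.character(taxon)[keep]
  replicate <- as.character(replicate)[keep]
  half <- trial_days / 2
  totals <- table(replicate)
  taxa <- sort(unique(taxon))
  excluded <- 0L
  rows <- list()
  for (tx in taxa) {
    sel <- taxon == tx
    reps <- sort(unique(replicate[sel]))
    y <- x <- numeric(0)
    for (r in reps) {
      d <- day[sel & replicate == r]
      n6 <- length(d)
      if (n6 == 0) { excluded <- excluded + 1L; next }
      y <- c(y, sum(d < half) / n6)
      x <- c(x, as.numeric(totals[r]))
    }
    if (length(y) < 3) next
    fit <- lm(y ~ x)
    s <- summary(fit)$coefficients
    b0 <- s[1, 1]; se0 <- s[1, 2]
    b1 <- if (nrow(s) > 1) s[2, 1] else NA_real_
    se1 <- if (nrow(s) > 1) s[2, 2] else NA_real_
    df <- fit$df.residual
    t0 <- (b0 - 0.5) / se0
    p0 <- 2 * pt(abs(t0), df, lower.tail = FALSE)
    p1 <- if (!is.na(b1)) 2 * pt(abs(b1 / se1), df, lower.tail = FALSE)
    else NA_real_
    rows[[tx]] <- data.frame(
      taxon = tx, n_weeks = length(y), intercept = b0, intercept_se = se0,
      intercept_p = p0, slope = b1, slope_se = se1, slope_p = p1,
      stringsAsFactors = FALSE)
  }
  list(per_taxon = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       n_excluded = excluded)
}
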