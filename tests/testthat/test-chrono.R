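t0 <- as.POSIXct("2020-06-01 00:00:00", tz = "UTC")

test_that("the WZT map pins sunrise, sunset, noon and midnight for any day length", {
  for (d in c(0.3, 0.45, 0.5, 0.62, 0.8)) {
    p <- wzt_params(day_length = d)
    expect_equal(wzt(0, p), 0)            # sunrise
    expect_equal(wzt(d, p), 0.5)          # sunset always half a day
    expect_equal(wzt(d / 2, p), 0.25)     # solar noon quarter day
    expect_equal(wzt(d + (1 - d) / 2, p), 0.75) # solar midnight
  }
  # equinox: identity map
  p <- wzt_params(day_length = 0.5)
  z <- seq(0, 0.999, by = 0.001)
  expect_equal(wzt(z, p), z)
  expect_error(wzt_params(day_length = 1.2), "strictly")
})

test_that("the WZT map is continuous, increasing and invertible", {
  p <- wzt_params(day_length = 0.37)
  z <- seq(0, 0.9999, length.out = 5000)
  w <- wzt(z, p)
  expect_true(all(diff(w) > 0))
  expect_lt(max(abs(diff(w))), 0.002) # no jumps
  expect_equal(wzt_inverse(w, p), z, tolerance = 1e-12)
  # clock-time wrapper: sunrise at 06:00 maps to WZT 0
  tt <- as.POSIXct("2020-06-01 06:00:00", tz = "UTC")
  expect_equal(wzt_clock(tt, wzt_params(sunrise = 0.25, day_length = 0.37)),
               0)
})

test_that("the solar calculator gives sensible sunrise/sunset", {
  eq <- sun_times(0, 0, as.Date("2020-03-20")) # equator at equinox
  expect_equal(eq$day_length, 0.5, tolerance = 0.01)
  summer <- sun_times(49.24, -121.76, as.Date("2020-06-21"))
  expect_gt(summer$day_length, 0.6) # long boreal summer day
  winter <- sun_times(49.24, -121.76, as.Date("2020-12-21"))
  expect_lt(winter$day_length, 0.4)
})

test_that("rate series bin events as expected", {
  s <- rate_series(events = as.POSIXct(character(), tz = "UTC"),
                   times = c(t0, t0 + 3 * 3600))
  expect_true(all(s$rate == 0))
  ten <- rep(t0 + 1800, 10)
  s <- rate_series(events = ten, times = c(t0, t0 + 3600))
  expect_equal(s$rate[1], 10) # 10 events in a 1 h bin
  expect_error(rate_series(counts = c(1, 2), times = rev(c(t0, t0 + 60))),
               "monotone")
  expect_error(rate_series(counts = c(1, -1), times = c(t0, t0 + 60)),
               "non-negative")
})

test_that("event binning and count differencing agree on a no-escape series", {
  set.seed(8)
  ev_times <- sort(t0 + runif(60, 0, 48 * 3600))
  frame_times <- t0 + seq(0, 48 * 3600, by = 1200)
  counts <- vapply(frame_times, function(ft) sum(ev_times <= ft),
                   numeric(1))
  # total captures from both routes
  binned <- rate_series(events = ev_times, times = range(frame_times))
  expect_equal(sum(binned$counts), 60)
  expect_equal(max(counts) - counts[1], sum(diff(counts)))
  expect_equal(sum(diff(counts)), 60)
})

test_that("the low-pass pair removes spikes and conserves mass", {
  times <- t0 + (0:39) * 1200
  # constant counts: rate identically 0
  lp <- lowpass(rep(5, 40), times = times)
  expect_true(all(lp$rate == 0))
  # single-frame +1 spike: killed by the k=5 median
  spiky <- rep(5, 40); spiky[20] <- 6
  lp <- lowpass(spiky, times = times)
  expect_true(all(lp$rate == 0))
  # unit step: filtered rate mass is exactly one insect
  step <- c(rep(0, 20), rep(1, 20))
  lp <- lowpass(step, times = times)
  expect_equal(sum(lp$rate * 1200 / 3600), 1)
  expect_true(attr(lp, "filtered"))
  # too-short series: warning and flag
  expect_warning(lp2 <- lowpass(c(0, 1, 1), times = times[1:3]),
                 "skipped")
  expect_false(attr(lp2, "filtered"))
})

test_that("the k = 5 filters at 20-min sampling span 100 minutes", {
  expect_equal(lowpass_span(5, 20), 100)
  # impulse response: a unit step's rate support widens to the filter span
  times <- t0 + (0:39) * 1200
  step <- c(rep(0, 20), rep(1, 20))
  lp <- lowpass(step, times = times)
  support_min <- diff(range(which(lp$rate > 1e-12))) * 20 + 20
  expect_lte(support_min, 100)
})

test_that("rhythmicity detects periodic signals and respects the null", {
  hours <- seq_len(240)
  periodic <- lapply(1:6, function(i)
    pmax(0, cos(2 * pi * hours / 24)) + rnorm(240, 0, 0.05))
  r <- rhythmicity(periodic, lag_h = 24, bin_h = 1)
  expect_gte(r$mean, 0.95)
  expect_lt(r$p_value, 1e-6)
  set.seed(33)
  noise <- lapply(1:6, function(i) rnorm(240))
  rn <- rhythmicity(noise, lag_h = 24, bin_h = 1)
  expect_lt(abs(rn$mean), 0.1)
  expect_gt(rn$p_value, 0.05)
  expect_error(rhythmicity(list(rnorm(20), rnorm(20)), lag_h = 24,
                           bin_h = 1), "lag")
})

test_that("a synthetic crepuscular population is significantly rhythmic", {
  taxon <- list(taxon_spec("crep", 3, peaks = c(0, 12), peak_sd = 1.5))
  accs <- vapply(1:6, function(s) {
    ev <- simulate_capture_times(taxon, t0, 10 * 24, seed = 100 + s)
    rs <- rate_series(events = ev$time, times = c(t0, t0 + 10 * 86400))
    chronotrap:::acf_at_lag(rs$rate, 24)
  }, numeric(1))
  tt <- t.test(accs, mu = 0)
  expect_gt(mean(accs), 0.2)
  expect_lt(tt$p.value, 0.01)
})

test_that("diel profiles average correctly across replicates", {
  # uniform events: flat profile at the overall mean rate
  set.seed(2)
  wz <- runif(48 * 200, 0, 24) # 200 events/day-hour over 2 replicates
  reps <- sample(c("r1", "r2"), length(wz), replace = TRUE)
  pr <- diel_profile(wz, reps, rep_days = c(r1 = 200, r2 = 200))
  expect_equal(nrow(pr), 24)
  expect_lt(diff(range(pr$mean)) / mean(pr$mean), 0.25)
  # all events in one WZT hour: single nonzero bin
  pr1 <- diel_profile(rep(6.5, 30), rep("r1", 30), rep_days = 7)
  expect_equal(which(pr1$mean > 0), 7) # bin 6 is the 7th row
  expect_true(all(pr1$se >= 0))
})

test_that("simulated peak phases are recovered by the profile argmax", {
  taxon <- list(taxon_spec("pk", 10, peaks = 14, peak_sd = 2))
  ev <- simulate_capture_times(taxon, t0, 1000, seed = 6)
  expect_gt(nrow(ev), 5000)
  wz <- wzt_clock(ev$time, wzt_params()) * 24
  pr <- diel_profile(wz, rep("r", length(wz)), rep_days = 1000 / 24)
  expect_lte(abs(pr$bin[which.max(pr$mean)] - 14), 1)
})

test_that("window fractions use the exact uniform null", {
  wz <- c(runif(300, 0, 12), runif(100, 12, 24))
  wf <- window_fraction(wz, list(c(0, 12)), n_boot = 200, seed = 1)
  expect_equal(wf$null, 0.5) # day window: 50% by chance
  expect_equal(wf$observed, 0.75)
  expect_true(wf$ci[1] <= wf$observed && wf$observed <= wf$ci[2])
  # dawn + dusk windows totalling 8 h: null = 1/3
  wf8 <- window_fraction(wz, list(c(9, 13), c(0, 2), c(22, 24)),
                         n_boot = 200, seed = 1)
  expect_equal(wf8$null, 8 / 24)
  # overlapping windows are merged before measuring
  wfo <- window_fraction(wz, list(c(0, 6), c(4, 10)), n_boot = 200,
                         seed = 1)
  expect_equal(wfo$null, 10 / 24)
  # empty window set
  wf0 <- window_fraction(wz, list())
  expect_equal(wf0$observed, 0)
  expect_equal(wf0$null, 0)
})

test_that("saturation test recovers linearity and detects saturation", {
  set.seed(44)
  # linear (homogeneous Poisson) captures: both tests should be
  # non-significant in the vast majority of simulation runs
  linear_run <- function() {
    day <- numeric(0); rep_k <- character(0)
    for (w in 1:15) {
      nw <- rpois(1, 30 + 30 * w)
      day <- c(day, runif(nw, 0, 6))
      rep_k <- c(rep_k, rep(paste0("w", w), nw))
    }
    st <- saturation_test(day, rep("a", length(day)), rep_k)
    c(int = st$per_taxon$intercept, ok = st$per_taxon$intercept_p > 0.05 &&
        st$per_taxon$slope_p > 0.05)
  }
  runs <- t(replicate(100, linear_run()))
  expect_gte(mean(runs[, "ok"]), 0.85) # ~90% expected under the null
  expect_lt(abs(mean(runs[, "int"]) - 0.5), 0.05)
  # all events in days 0-3: response exactly 1
  st1 <- suppressWarnings( # perfect fit: every response is exactly 1
    saturation_test(runif(300, 0, 3), rep("a", 300),
                    sample(paste0("w", 1:5), 300, replace = TRUE)))
  expect_equal(st1$per_taxon$intercept +
                 st1$per_taxon$slope * 0, 1, tolerance = 0.2)
  # saturating capture (rate decays with accumulated load): the response
  # N_[0,3]/N_[0,6] rises to ~0.82 and the intercept test detects it
  lam <- function(d) exp(-d / 2)
  day_s <- numeric(0); rep_s <- character(0)
  for (w in 1:20) {
    n_cand <- rpois(1, 100 + 30 * w)
    cand <- sort(runif(n_cand, 0, 6))
    keep <- runif(n_cand) < lam(cand)
    day_s <- c(day_s, cand[keep])
    rep_s <- c(rep_s, rep(paste0("s", w), sum(keep)))
  }
  sts <- saturation_test(day_s, rep("a", length(day_s)), rep_s)
  expect_gt(sts$per_taxon$intercept, 0.5)
  expect_lt(sts$per_taxon$intercept_p, 0.05)
})
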