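# Warped Zeitgeber time (WZT).
#
# Zeitgeber time (ZT) counts hours since sunrise, so days of different
# lengths are not comparable at their far end. WZT rescales ZT piecewise
# linearly so that sunrise maps to 0 and sunset always maps to half a day:
#   W(z) = a z          for z <= d        (daytime)
#        = a' z + b'    otherwise         (nighttime)
# with a = 1/(2d), a' = 1/(2(1-d)), b' = 1 - a', where d is the day length
# as a fraction of 24 h and z is ZT as a day fraction. Solar noon maps to
# 1/4 day and solar midnight to 3/4 day, for any d.

#' Parameters of the Warped Zeitgeber time map
#'
#' @param sunrise time of sunrise as a fraction of the day since midnight
#'   (e.g. 0.25 for 06:00).
#' @param day_length day length d as a day fraction, 0 < d < 1.
#' @return Object of class `"wzt_params"` with fields `sunrise`, `day_length`
#'   and the derived slopes `a = 1/(2d)`, `a2 = 1/(2(1-d))` and intercept
#'   `b2 = 1 - a2`.
#' @export
wzt_params <- function(sunrise = 0.25, day_length = 0.5) {
  d <- day_length
  if (!is.finite(d) || d <= 0 || d >= 1)
    stop("day_length must lie strictly in (0, 1)", call. = FALSE)
  if (!is.finite(sunrise)) stop("sunrise must be finite", call. = FALSE)
  a2 <- 1 / (2 * (1 - d))
  structure(list(sunrise = sunrise %% 1, day_length = d,
                 a = 1 / (2 * d), a2 = a2, b2 = 1 - a2),
            class = "wzt_params")
}

#' Warped Zeitgeber time of a Zeitgeber time
#'
#' @param z Zeitgeber time as a day fraction in \[0, 1) (0 = sunrise);
#'   vectorised. Values outside the range are wrapped.
#' @param p a [wzt_params()].
#' @return WZT as a day fraction in \[0, 1): 0 at sunrise, 1/2 at sunset.
#' @examples
#' p <- wzt_params(day_length = 0.6)
#' wzt(p$day_length, p)       # sunset -> 0.5
#' wzt(p$day_length / 2, p)   # solar noon -> 0.25
#' @export
wzt <- function(z, p) {
  z <- z %% 1
  ifelse(z <= p$day_length, p$a * z, p$a2 * z + p$b2)
}

#' Inverse of the WZT map
#'
#' @param w WZT day fraction in \[0, 1).
#' @inheritParams wzt
#' @return Zeitgeber time z such that `wzt(z, p) == w`.
#' @export
wzt_inverse <- function(w, p) {
  w <- w %% 1
  ifelse(w <= 0.5, w / p$a, (w - p$b2) / p$a2)
}

#' WZT of absolute clock times
#'
#' Convenience wrapper: converts POSIXct times to time-of-day fractions,
#' subtracts sunrise (z = (t - s) mod 1) and applies [wzt()].
#'
#' @param time POSIXct vector (UTC recommended).
#' @param p a [wzt_params()]; `sunrise` is taken as the local sunrise time in
#'   the same clock as `time`.
#' @return WZT day fractions in \[0, 1).
#' @export
wzt_clock <- function(time, p) {
  tod <- (as.numeric(time) %% 86400) / 86400
  wzt((tod - p$sunrise) %% 1, p)
}

#' Sunrise and sunset from latitude, longitude and date
#'
#' Standard sunrise-equation calculation (NOAA formulation, atmospheric
#' refraction at -0.83 deg solar altitude), accurate to a few minutes —
#' adequate for diel binning. Sunrise and sunset are returned as UTC day
#' fractions; polar day/night yields NA.
#'
#' @param lat,lon degrees north / east.
#' @param date Date (or coercible).
#' @return data.frame with `date`, `sunrise`, `sunset` (UTC day fractions)
#'   and `day_length` (day fraction), one row per date.
#' @export
sun_times <- function(lat, lon, date) {
  date <- as.Date(date)
  n <- as.numeric(date - as.Date("2000-01-01")) + 0.0008
  Jstar <- n - lon / 360
  M <- (357.5291 + 0.98560028 * Jstar) %% 360
  Mr <- M * pi / 180
  C <- 1.9148 * sin(Mr) + 0.02 * sin(2 * Mr) + 0.0003 * sin(3 * Mr)
  lambda <- (M + C + 180 + 102.9372) %% 360
  lr <- lambda * pi / 180
  Jtransit <- 2451545 + Jstar + 0.0053 * sin(Mr) - 0.0069 * sin(2 * lr)
  delta <- asin(sin(lr) * sin(23.4397 * pi / 180))
  latr <- lat * pi / 180
  cosw <- (sin(-0.833 * pi / 180) - sin(latr) * sin(delta)) /
    (cos(latr) * cos(delta))
  w0 <- suppressWarnings(acos(cosw))
  Jrise <- Jtransit - w0 * 180 / pi / 360
  Jset <- Jtransit + w0 * 180 / pi / 360
  frac <- function(J) ((J - 0.5) %% 1) # JD starts at noon; shift to midnight
  data.frame(date = date, sunrise = frac(Jrise), sunset = frac(Jset),
             day_length = (Jset - Jrise))
}
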