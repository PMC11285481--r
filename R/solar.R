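#' Solar elevation angle (NOAA algorithm)
#'
#' Vectorized implementation of the NOAA solar position calculations,
#' accurate to a small fraction of a degree — ample for day/night
#' classification.
#'
#' @param time POSIXct (UTC) or numeric seconds since the Unix epoch.
#' @param lat,lon decimal degrees.
#' @return solar elevation above the horizon, degrees.
#' @export
solar_elevation <- function(time, lat, lon) {
  t_sec <- as.numeric(time)
  jd <- t_sec / 86400 + 2440587.5
  jc <- (jd - 2451545) / 36525
  d2r <- pi / 180

  l0 <- (280.46646 + jc * (36000.76983 + 0.0003032 * jc)) %% 360
  m <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  ecc <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  ceq <- sin(m * d2r) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(2 * m * d2r) * (0.019993 - 0.000101 * jc) +
    sin(3 * m * d2r) * 0.000289
  true_long <- l0 + ceq
  omega <- 125.04 - 1934.136 * jc
  app_long <- true_long - 0.00569 - 0.00478 * sin(omega * d2r)
  eps0 <- 23 + (26 + (21.448 - jc * (46.815 + jc *
    (0.00059 - jc * 0.001813))) / 60) / 60
  eps <- eps0 + 0.00256 * cos(omega * d2r)
  decl <- asin(sin(eps * d2r) * sin(app_long * d2r)) / d2r

  y <- tan(eps / 2 * d2r)^2
  eqtime <- 4 / d2r * (y * sin(2 * l0 * d2r) - 2 * ecc * sin(m * d2r) +
    4 * ecc * y * sin(m * d2r) * cos(2 * l0 * d2r) -
    0.5 * y^2 * sin(4 * l0 * d2r) - 1.25 * ecc^2 * sin(2 * m * d2r))

  minutes_utc <- (t_sec %% 86400) / 60
  tst <- (minutes_utc + eqtime + 4 * lon) %% 1440
  ha <- tst / 4 - 180
  cos_zen <- sin(lat * d2r) * sin(decl * d2r) +
    cos(lat * d2r) * cos(decl * d2r) * cos(ha * d2r)
  90 - acos(pmin(1, pmax(-1, cos_zen))) / d2r
}

#' Label positions as day or night and assign a diel date
#'
#' A record is `day` when the solar elevation at the anchor location exceeds
#' zero at its timestamp. Each record also receives a diel calendar date:
#' daytime records keep their civil (UTC) date; night records in the early
#' morning (before local noon) are attributed to the date the night started.
#'
#' @param times numeric seconds since the study epoch.
#' @param origin `c(lat, lon)` anchor.
#' @param epoch POSIXct of study time 0 (UTC).
#' @return data.frame with `diel` (`"day"`/`"night"`) and `date` (Date).
#' @export
split_diel <- function(times, origin, epoch) {
  abs_t <- as.numeric(epoch) + times
  elev <- solar_elevation(abs_t, origin[1], origin[2])
  diel <- ifelse(elev > 0, "day", "night")
  date <- as.Date(as.POSIXct(abs_t, origin = "1970-01-01", tz = "UTC"))
  frac <- (abs_t %% 86400) / 3600
  before_noon <- frac < 12
  date[diel == "night" & before_noon] <-
    date[diel == "night" & before_noon] - 1
  data.frame(diel = diel, date = date)
}
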