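# Circular and clock-time helpers.  All clock arithmetic is modulo 24 h.

#' Hours since midnight of a POSIXct time
#' @param t POSIXct vector.
#' @return numeric clock hours in [0, 24).
#' @keywords internal
#' @noRd
clockHours <- function(t) {
  s <- as.numeric(t)
  (s %% 86400) / 3600
}

#' Hours since an origin datetime
#' @noRd
hoursSince <- function(t, origin) {
  (as.numeric(t) - as.numeric(origin)) / 3600
}

#' @noRd
hoursToPosix <- function(h, origin) {
  origin + h * 3600
}

#' Signed circular distance between clock hours, in (-12, 12]
#' @noRd
circDiffHours <- function(a, b) {
  d <- (a - b) %% 24
  ifelse(d > 12, d - 24, d)
}

#' Unsigned circular distance between clock hours, in [0, 12]
#' @noRd
circDistHours <- function(a, b) abs(circDiffHours(a, b))

#' Circular mean of clock hours; NA when the resultant length is ~0
#' @noRd
circMeanHours <- function(h) {
  th <- h / 24 * 2 * pi
  s <- mean(sin(th)); c <- mean(cos(th))
  if (sqrt(s^2 + c^2) < 1e-12) return(NA_real_)
  m <- (atan2(s, c) / (2 * pi) * 24) %% 24
  if (24 - m < 1e-9) 0 else m
}

#' Mean resultant length of clock hours
#' @noRd
circResultant <- function(h) {
  th <- h / 24 * 2 * pi
  sqrt(mean(sin(th))^2 + mean(cos(th))^2)
}
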