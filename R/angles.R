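# Angle helpers. All public angles are degrees; arena-frame headings follow
# the usual mathematical convention (counterclockwise positive from +x).

#' Wrap angles in degrees to (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector wrapped to the half-open interval (-180, 180].
#' @examples
#' wrap_deg(c(190, -190, 180, -180, 540))
#' @export
wrap_deg <- function(x) {
  w <- x %% 360
  out <- ifelse(w > 180, w - 360, w)
  # -180 maps to 180 so the range is (-180, 180]
  out[!is.na(out) & out == -180] <- 180
  out
}

#' Circular mean of angles in degrees
#'
#' @param x numeric vector of angles in degrees (NAs dropped).
#' @return circular mean in (-180, 180], or NA if no data or the mean
#'   resultant length is numerically zero (direction undefined).
#' @export
circ_mean_deg <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  s <- mean(sin(x * pi / 180))
  c_ <- mean(cos(x * pi / 180))
  if (sqrt(s^2 + c_^2) < 1e-12) return(NA_real_)
  wrap_deg(atan2(s, c_) * 180 / pi)
}
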