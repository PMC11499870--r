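#' Wrap angles to the orientation interval \[-90, 90)
#'
#' Orientation (as opposed to direction) is 180-degree periodic: a grating at
#' 10 degrees and one at 190 degrees have the same orientation. All orientation
#' values in the package live on \[-90, 90).
#'
#' @param x numeric vector of angles in degrees.
#' @return angles wrapped to \[-90, 90).
#' @export
#' @examples
#' wrap_orientation(c(-95, 90, 170, 185))
wrap_orientation <- function(x) {
  ((x + 90) %% 180) - 90
}

#' Signed circular difference between two orientations
#'
#' Returns `a - b` on the 180-degree-periodic orientation circle, wrapped to
#' \[-90, 90). Positive values mean `a` lies counter-clockwise of `b`.
#'
#' @param a,b orientations in degrees (any range; wrapped mod 180).
#' @return signed differences in degrees in \[-90, 90).
#' @export
orientation_diff <- function(a, b) {
  wrap_orientation(a - b)
}

#' Absolute circular distance between two orientations
#'
#' The minimal distance on the 180-degree-periodic orientation circle, used for
#' drift magnitude |dPO| and distance from an experienced orientation |rPO|.
#'
#' @param a,b orientations in degrees (any range; wrapped mod 180).
#' @return distances in degrees in \[0, 90\].
#' @export
#' @examples
#' orientation_distance(80, -80)  # 20, across the wrap
#' orientation_distance(0, 90)    # 90, the maximum
orientation_distance <- function(a, b) {
  abs(orientation_diff(a, b))
}

#' Circular mean of orientations
#'
#' Angles are doubled (mapping the orientation circle onto the full circle),
#' averaged as unit vectors (optionally weighted), and halved back.
#' Returns `NA` when the resultant vector is numerically zero.
#'
#' @param x orientations in degrees.
#' @param w optional non-negative weights.
#' @return mean orientation in degrees in \[-90, 90), or `NA`.
#' @export
circular_mean_orientation <- function(x, w = NULL) {
  if (length(x) == 0L) return(NA_real_)
  th <- 2 * x * pi / 180
  if (is.null(w)) w <- rep(1, length(x))
  X <- sum(w * cos(th)) / sum(w)
  Y <- sum(w * sin(th)) / sum(w)
  if (abs(X) < 1e-15 && abs(Y) < 1e-15) return(NA_real_)
  wrap_orientation(atan2(Y, X) / 2 * 180 / pi)
}
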