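# Angular width of the eyeshine emission beam, from tank-side triangulation.
#
# The beam's onset and offset points are observed in air from a few metres;
# the triangle between the two observation points and the fish's eye gives
# the in-air apex angle by the law of cosines. Because the beam actually
# travels in water and crosses a flat, parallel-faced tank wall, each in-air
# half-angle is converted to its in-water counterpart by Snell's law (the
# glass layer's index cancels for parallel faces).

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

#' Construct an observation triangle for beam-width measurement
#'
#' @param chord Distance between the beam onset and offset observation
#'   points (m).
#' @param left_arm,right_arm Distances from each observation point to the
#'   eye (m).
#' @return An object of class `beam_triangle`.
#' @export
beam_triangle <- function(chord, left_arm, right_arm) {
  sides <- c(chord = chord, left_arm = left_arm, right_arm = right_arm)
  if (!all(is.finite(sides)) || any(sides <= 0)) {
    stop("all triangle sides must be positive and finite")
  }
  s <- sort(sides)
  if (s[1] + s[2] <= s[3]) {
    stop("triangle inequality violated: ", paste(round(sides, 4), collapse = ", "))
  }
  structure(as.list(sides), class = "beam_triangle")
}

#' Apex angle at the eye from triangle side lengths
#'
#' Law of cosines: the angle opposite the chord,
#' arccos((b^2 + c^2 - a^2) / (2 b c)) with a the chord and b, c the arms.
#'
#' @param t A [beam_triangle()].
#' @return Angle in degrees.
#' @export
angle_from_sides <- function(t) {
  if (!inherits(t, "beam_triangle")) stop("t must be a beam_triangle")
  a <- t$chord; b <- t$left_arm; c <- t$right_arm
  arg <- (b^2 + c^2 - a^2) / (2 * b * c)
  # triangle inequality already guarantees |arg| < 1; clamp rounding slack
  rad2deg(acos(min(1, max(-1, arg))))
}

#' Refract an angle across a flat interface
#'
#' Snell's law: n_in sin(theta_in) = n_out sin(theta_out), angles measured
#' from the interface normal.
#'
#' @param angle_in Incident angle in degrees, in `[0, 90)`.
#' @param n_in,n_out Refractive indices of the incident and transmitting
#'   media.
#' @return Refracted angle in degrees.
#' @export
refract <- function(angle_in, n_in, n_out) {
  if (!is.finite(angle_in) || angle_in < 0 || angle_in >= 90) {
    stop("angle_in must be in [0, 90) degrees, got ", angle_in)
  }
  if (n_in <= 0 || n_out <= 0) stop("refractive indices must be positive")
  arg <- n_in * sin(deg2rad(angle_in)) / n_out
  if (arg > 1) {
    stop("total internal reflection: n_in sin(theta)/n_out = ",
         round(arg, 4), " > 1")
  }
  rad2deg(asin(arg))
}

#' In-water beam width corrected for refraction at the tank wall
#'
#' Decomposes the in-air apex angle into the two half-angles each arm makes
#' with the wall normal (the foot of the altitude from the eye onto the
#' chord), refracts each into the water, and sums them. With
#' `n_water == n_air` this equals [angle_from_sides()]; for a symmetric
#' triangle with in-air width w it equals `2 asin(sin(w/2)/n_water)`.
#' The correction is applied on the water side of the light path; see the
#' package vignette for why this choice is the defensible one for a
#' parallel-faced wall.
#'
#' @param t A [beam_triangle()] measured in air.
#' @param n_water,n_air Refractive indices (defaults 1.333 and 1.000).
#' @return Beam angular width inside the tank, degrees.
#' @export
corrected_beam_width <- function(t, n_water = 1.333, n_air = 1.000) {
  if (!inherits(t, "beam_triangle")) stop("t must be a beam_triangle")
  a <- t$chord; b <- t$left_arm; c <- t$right_arm
  # chord endpoints A=(0,0), B=(a,0); eye at (x0, h)
  x0 <- (b^2 + a^2 - c^2) / (2 * a)
  h2 <- b^2 - x0^2
  if (h2 <= 0) stop("degenerate triangle: eye lies on the chord")
  h <- sqrt(h2)
  # signed half-angles from the altitude (interface normal)
  th1 <- rad2deg(atan2(x0, h))
  th2 <- rad2deg(atan2(a - x0, h))
  refr_signed <- function(th) sign(th) * refract(abs(th), n_air, n_water)
  refr_signed(th1) + refr_signed(th2)
}
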