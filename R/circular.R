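# Length-weighted axial circular statistics for pleated optic-nerve layers.
#
# Layer angles are axial data: a pleat tilted at 10 degrees and one at 190
# degrees describe the same orientation. Before averaging, angles are
# therefore remapped modulo 180 so that the circular range (largest minus
# smallest angle) is minimal; the weighted circular mean and circular
# standard deviation are then computed on the transformed sample.

#' Axial transformation minimising the circular range
#'
#' Each angle may be replaced by itself plus or minus 180 degrees (axial
#' equivalence). This function returns the assignment whose spread
#' (max - min) is minimal, found by reducing angles modulo 180, locating the
#' largest gap on the 180-degree-period circle, and lifting the angles below
#' the cut by +180. Ties between equally large gaps are broken toward the
#' solution with the smallest non-negative mean. Equivalence with brute-force
#' enumeration over all per-angle shifts is established in the test suite.
#'
#' @param angles Numeric vector of angles in degrees.
#' @return Numeric vector, same length; each element is congruent to its
#'   input modulo 180 and lies in `[0, 360)`.
#' @export
axial_transform <- function(angles) {
  if (length(angles) < 1L) stop("angles must be nonempty")
  if (!all(is.finite(angles))) stop("angles must be finite")
  a <- angles %% 180
  u <- sort(unique(a))
  if (length(u) == 1L) return(a)
  gaps <- diff(c(u, u[1L] + 180))
  widest <- which(gaps == max(gaps))
  candidates <- lapply(widest, function(k) {
    # occupied arc starts just above the gap following u[k]
    start <- if (k == length(u)) u[1L] else u[k + 1L]
    out <- a
    out[a < start] <- out[a < start] + 180
    out
  })
  means <- vapply(candidates, mean, 0)
  candidates[[which.min(means)]]
}

#' Length-weighted circular mean of layer angles
#'
#' The mean direction of unit vectors at each angle, weighted by relative
#' layer length l_i / sum(l_i), computed with the quadrant-aware
#' two-argument arctangent and normalised to `[0, 360)`.
#'
#' @param angle Angles in degrees.
#' @param length Positive weights (layer lengths, um); defaults to equal
#'   weights.
#' @return Mean angle in degrees, or `NA` with a warning when the resultant
#'   vector has (numerically) zero length so the mean is undefined.
#' @export
weighted_circular_mean <- function(angle, length = rep(1, base::length(angle))) {
  cm <- circ_moments(angle, length)
  if (cm$R < 1e-12) {
    warning("resultant length ~ 0: circular mean undefined")
    return(NA_real_)
  }
  (rad2deg(atan2(cm$S, cm$C))) %% 360
}

#' Length-weighted circular standard deviation
#'
#' v = sqrt(-2 ln R) where R is the weighted mean resultant length;
#' converted from radians to degrees. R = 0 (e.g. an equal-weight antipodal
#' pair) makes the dispersion undefined and returns `NA` with a warning
#' rather than infinity.
#'
#' @inheritParams weighted_circular_mean
#' @return Circular SD in degrees, or `NA` when undefined.
#' @export
circular_sd <- function(angle, length = rep(1, base::length(angle))) {
  cm <- circ_moments(angle, length)
  if (cm$R < 1e-12) {
    warning("resultant length ~ 0: circular SD undefined")
    return(NA_real_)
  }
  R <- min(cm$R, 1) # guard rounding above 1
  if (1 - R < 1e-12) return(0) # coincident angles up to floating noise
  rad2deg(sqrt(-2 * log(R)))
}

#' Weighted mean resultant length
#'
#' @inheritParams weighted_circular_mean
#' @return R in `[0, 1]`.
#' @export
resultant_length <- function(angle, length = rep(1, base::length(angle))) {
  min(circ_moments(angle, length)$R, 1)
}

circ_moments <- function(angle, length) {
  n <- base::length(angle)
  if (n < 1L) stop("angle must be nonempty")
  if (base::length(length) != n) stop("angle and length must have equal length")
  if (!all(is.finite(angle)) || !all(is.finite(length))) {
    stop("angles and lengths must be finite")
  }
  if (any(length < 0) || sum(length) <= 0) {
    stop("lengths must be >= 0 with positive total")
  }
  w <- length / sum(length)
  r <- deg2rad(angle)
  S <- sum(sin(r) * w)
  C <- sum(cos(r) * w)
  list(S = S, C = C, R = sqrt(S^2 + C^2))
}

#' Per-section summary of layer measurements
#'
#' Applies the axial transformation (optional), then the length-weighted
#' circular mean and SD, to the layers of one transverse section.
#'
#' @param distance Distance of the section from the optic disc, mm.
#' @param angle Layer angles in degrees.
#' @param length Layer lengths in um, positive.
#' @param axial Apply [axial_transform()] before averaging (default `TRUE`).
#' @return An object of class `section_mean`: list with `distance`,
#'   `mean_angle`, `circular_sd`, `resultant_length`, `n_layers`.
#' @export
section_mean <- function(distance, angle, length = rep(1, base::length(angle)),
                         axial = TRUE) {
  if (!is.finite(distance) || distance < 0) {
    stop("distance must be a non-negative number")
  }
  if (any(length <= 0)) stop("layer lengths must be > 0")
  a <- if (axial) axial_transform(angle) else angle
  structure(
    list(distance = distance,
         mean_angle = weighted_circular_mean(a, length),
         circular_sd = circular_sd(a, length),
         resultant_length = resultant_length(a, length),
         n_layers = base::length(angle)),
    class = "section_mean"
  )
}

#' Per-section means for a whole nerve
#'
#' Convenience wrapper applying [section_mean()] to every section of a
#' long-format measurement table.
#'
#' @param sections A data.frame with columns `distance_mm`, `angle_deg`,
#'   `length_um` (one row per layer), e.g. from [read_sections_csv()] or
#'   [gen_nerve_sections()].
#' @param axial Apply the axial transformation per section.
#' @return A data.frame ordered by distance with columns `distance_mm`,
#'   `mean_angle_deg`, `circular_sd_deg`, `resultant_length`, `n_layers`.
#' @export
section_means <- function(sections, axial = TRUE) {
  need <- c("distance_mm", "angle_deg", "length_um")
  if (!all(need %in% names(sections))) {
    stop("sections must have columns ", paste(need, collapse = ", "))
  }
  ds <- sort(unique(sections$distance_mm))
  rows <- lapply(ds, function(d) {
    sub <- sections[sections$distance_mm == d, , drop = FALSE]
    sm <- section_mean(d, sub$angle_deg, sub$length_um, axial = axial)
    data.frame(distance_mm = d, mean_angle_deg = sm$mean_angle,
               circular_sd_deg = sm$circular_sd,
               resultant_length = sm$resultant_length,
               n_layers = sm$n_layers)
  })
  do.call(rbind, rows)
}

#' Unwrap a distance-ordered series of axial mean angles
#'
#' Assuming continuous, roughly constant torsion along the nerve, each
#' successive mean is shifted by an integer multiple of 180 degrees (its
#' axial equivalence class) so that consecutive steps never exceed 90
#' degrees in magnitude; ties are broken toward the smaller shift.
#'
#' @param mean_deg Mean angles in degrees, ordered by strictly increasing
#'   distance.
#' @return Numeric vector of unwrapped angles (may leave `[0, 360)`).
#' @export
unwrap_means <- function(mean_deg) {
  if (length(mean_deg) < 1L) stop("mean_deg must be nonempty")
  out <- mean_deg
  for (i in seq_along(out)[-1L]) {
    delta <- out[i] - out[i - 1L]
    ks <- unique(c(floor(-delta / 180), ceiling(-delta / 180)))
    resid <- delta + 180 * ks
    best <- which(abs(resid) == min(abs(resid)))
    if (length(best) > 1L) best <- best[which.min(abs(ks[best]))]
    out[i] <- out[i] + 180 * ks[best]
  }
  out
}
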