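# Spectral curves and underwater light propagation.

# CODATA constants to 6 significant digits.
PLANCK_H <- 6.62607e-34 # J s
LIGHT_C <- 2.99792e8    # m/s

#' Recognised spectral quantity tags
#'
#' Units are carried explicitly by the quantity tag; conversions between them
#' are explicit operations, never implicit.
#'
#' @format A character vector of tags:
#' \describe{
#'   \item{energy_radiance}{W sr^-1 m^-2 nm^-1}
#'   \item{energy_irradiance}{W m^-2 nm^-1}
#'   \item{photon_radiance}{photons s^-1 sr^-1 mm^-2 nm^-1}
#'   \item{photon_irradiance}{photons s^-1 m^-2 nm^-1}
#'   \item{transmittance}{unitless, >= 0}
#'   \item{sensitivity}{unitless, >= 0}
#' }
#' @export
spectral_quantities <- c(
  "energy_radiance", "energy_irradiance",
  "photon_radiance", "photon_irradiance",
  "transmittance", "sensitivity"
)

#' Construct a spectral curve
#'
#' A wavelength-indexed quantity: an emission or irradiance spectrum, a
#' transmittance, or a receptor sensitivity. Wavelengths must be a strictly
#' increasing grid in nanometres within 300--800 nm (the working range of the
#' instruments and visual systems this package models).
#'
#' @param wavelength Numeric vector of wavelengths in nm, strictly increasing.
#' @param value Numeric vector of per-wavelength magnitudes, same length.
#' @param quantity One of [spectral_quantities].
#' @param label Optional character label carried through for provenance.
#' @return An object of class `spectral_curve`: a list with elements
#'   `wavelength`, `value`, `quantity`, `label`.
#' @examples
#' flat <- spectral_curve(380:780, rep(1, 401), "transmittance")
#' @export
spectral_curve <- function(wavelength, value, quantity, label = NULL) {
  quantity <- match.arg(quantity, spectral_quantities)
  wavelength <- as.numeric(wavelength)
  value <- as.numeric(value)
  if (length(wavelength) != length(value)) {
    stop("wavelength and value must have equal length (", length(wavelength),
         " vs ", length(value), ")")
  }
  if (length(wavelength) < 1L) stop("empty spectral curve")
  if (!all(is.finite(wavelength)) || !all(is.finite(value))) {
    stop("spectral curve contains non-finite entries")
  }
  if (length(wavelength) > 1L && any(diff(wavelength) <= 0)) {
    stop("wavelengths must be strictly increasing")
  }
  if (min(wavelength) < 300 || max(wavelength) > 800) {
    stop("wavelengths outside the supported 300-800 nm range")
  }
  if (quantity %in% c("transmittance", "sensitivity") && any(value < 0)) {
    stop(quantity, " values must be >= 0")
  }
  structure(
    list(wavelength = wavelength, value = value,
         quantity = quantity, label = label),
    class = "spectral_curve"
  )
}

#' @export
print.spectral_curve <- function(x, ...) {
  cat("<spectral_curve>", x$quantity,
      if (!is.null(x$label)) paste0("(", x$label, ")"), "\n")
  cat("  ", length(x$wavelength), " wavelengths, ",
      min(x$wavelength), "-", max(x$wavelength), " nm\n", sep = "")
  cat("  value range: ", format(min(x$value)), " - ",
      format(max(x$value)), "\n", sep = "")
  invisible(x)
}

is_spectral_curve <- function(x) inherits(x, "spectral_curve")

assert_curve <- function(x, arg = deparse(substitute(x))) {
  if (!is_spectral_curve(x)) stop(arg, " must be a spectral_curve")
  invisible(x)
}

#' Resample a spectral curve onto a new wavelength grid
#'
#' Linear interpolation; extrapolation is refused because spectral shapes
#' outside the measured span are unknowable.
#'
#' @param curve A [spectral_curve()].
#' @param grid Numeric vector of target wavelengths (nm), strictly increasing,
#'   within the curve's span.
#' @return A `spectral_curve` on `grid` with the same quantity tag.
#' @export
resample <- function(curve, grid) {
  assert_curve(curve)
  grid <- as.numeric(grid)
  lo <- min(curve$wavelength)
  hi <- max(curve$wavelength)
  bad <- grid[grid < lo | grid > hi]
  if (length(bad)) {
    stop("resample would extrapolate: wavelength ", bad[1],
         " nm outside curve span [", lo, ", ", hi, "] nm")
  }
  v <- stats::approx(curve$wavelength, curve$value, xout = grid,
                     method = "linear", ties = "ordered")$y
  spectral_curve(grid, v, curve$quantity, label = curve$label)
}

# Shared strictly-increasing intersection grid of several curves, at the
# resolution of the first curve clipped to the common span.
common_grid <- function(...) {
  curves <- list(...)
  lo <- max(vapply(curves, function(c) min(c$wavelength), 0))
  hi <- min(vapply(curves, function(c) max(c$wavelength), 0))
  if (lo >= hi) stop("curves share no overlapping wavelength range")
  g <- curves[[1L]]$wavelength
  g[g >= lo & g <= hi]
}

#' Convert an energy spectrum to a photon-flux spectrum
#'
#' Each photon at wavelength lambda carries energy h c / lambda, so the photon
#' flux is N(lambda) = L(lambda) lambda / (h c) with lambda in metres. The
#' quantity tag is relabelled (`energy_radiance` to `photon_radiance`,
#' `energy_irradiance` to `photon_irradiance`); the per-area unit is left as
#' supplied.
#'
#' @param curve A `spectral_curve` with an energy quantity.
#' @return A `spectral_curve` with the corresponding photon quantity.
#' @export
energy_to_photon <- function(curve) {
  assert_curve(curve)
  if (!curve$quantity %in% c("energy_radiance", "energy_irradiance")) {
    stop("energy_to_photon requires an energy flux, got ", curve$quantity)
  }
  if (any(curve$value < 0)) stop("negative energy values cannot be converted")
  lambda_m <- curve$wavelength * 1e-9
  n <- curve$value * lambda_m / (PLANCK_H * LIGHT_C)
  q <- if (curve$quantity == "energy_radiance") "photon_radiance" else "photon_irradiance"
  spectral_curve(curve$wavelength, n, q, label = curve$label)
}

#' Wavelength-specific transmittance of a sample relative to a reference
#'
#' T(lambda) = L_sample(lambda) / L_reference(lambda), the ratio of the
#' radiance measured through a tissue sample to the radiance of the bare
#' light path. Values above 1 are physically impossible but arise from
#' measurement noise; they are kept (clipping would bias band-integrated
#' ratios) and flagged with a warning.
#'
#' @param sample,reference `spectral_curve`s on a common grid (use
#'   [resample()] first if needed).
#' @return A `spectral_curve` with quantity `transmittance`.
#' @export
transmittance <- function(sample, reference) {
  assert_curve(sample); assert_curve(reference)
  if (!identical(sample$wavelength, reference$wavelength)) {
    stop("sample and reference must share a wavelength grid; resample first")
  }
  zero_ref <- reference$value == 0
  if (any(zero_ref & sample$value != 0)) {
    bad <- sample$wavelength[zero_ref & sample$value != 0]
    stop("reference is zero where sample is nonzero at wavelengths: ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ...")
  }
  tr <- ifelse(zero_ref, 0, sample$value / reference$value)
  if (any(tr < 0)) stop("negative transmittance; check input signs")
  if (any(tr > 1)) {
    warning(sum(tr > 1), " transmittance value(s) > 1 kept (measurement noise)")
  }
  spectral_curve(sample$wavelength, tr, "transmittance", label = sample$label)
}

# Trapezoid integral over an irregular grid.
trapz <- function(x, y) {
  if (length(x) < 2L) stop("need at least two points to integrate")
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

#' Band-integrated transmission efficiency
#'
#' Trapezoid-integrates both photon-flux curves over a wavelength band and
#' returns the ratio of integrals. With the sample an eyeshine radiance and
#' the reference a diffuse-white-standard radiance under identical
#' illumination, this is the eyeshine's transmission efficiency.
#'
#' @param sample,reference `spectral_curve`s on a common grid.
#' @param band Length-2 numeric, band limits in nm (default 380--780).
#' @return A single numeric fraction.
#' @export
band_ratio <- function(sample, reference, band = c(380, 780)) {
  assert_curve(sample); assert_curve(reference)
  if (!identical(sample$wavelength, reference$wavelength)) {
    stop("sample and reference must share a wavelength grid; resample first")
  }
  if (length(band) != 2L || band[1] >= band[2]) {
    stop("band must be an increasing pair of wavelengths")
  }
  keep <- sample$wavelength >= band[1] & sample$wavelength <= band[2]
  if (sum(keep) < 2L) {
    stop("band [", band[1], ", ", band[2],
         "] nm has no overlap with the curve grid")
  }
  w <- sample$wavelength[keep]
  trapz(w, sample$value[keep]) / trapz(w, reference$value[keep])
}

#' Construct a depth series of downwelling irradiance spectra
#'
#' @param depths Numeric vector of depths in metres, strictly increasing,
#'   at least two.
#' @param curves List of photon-irradiance `spectral_curve`s, one per depth,
#'   all on a common wavelength grid.
#' @return An object of class `depth_series`.
#' @export
depth_series <- function(depths, curves) {
  depths <- as.numeric(depths)
  if (length(depths) < 2L) stop("a depth series needs at least two depths")
  if (any(diff(depths) <= 0)) stop("depths must be strictly increasing")
  if (length(curves) != length(depths)) {
    stop("one curve required per depth")
  }
  lapply(curves, assert_curve)
  grid <- curves[[1L]]$wavelength
  same <- vapply(curves, function(c) identical(c$wavelength, grid), TRUE)
  if (!all(same)) stop("all curves in a depth series must share one grid")
  structure(list(depths = depths, curves = curves, wavelength = grid),
            class = "depth_series")
}

#' @export
print.depth_series <- function(x, ...) {
  cat("<depth_series> ", length(x$depths), " depths, ",
      min(x$depths), "-", max(x$depths), " m, grid ",
      min(x$wavelength), "-", max(x$wavelength), " nm\n", sep = "")
  invisible(x)
}

#' Construct an attenuation spectrum
#'
#' @param wavelength Wavelengths in nm.
#' @param K Diffuse attenuation coefficient per metre at each wavelength;
#'   `NA` marks wavelengths where K could not be estimated.
#' @return An object of class `attenuation_spectrum`.
#' @export
attenuation_spectrum <- function(wavelength, K) {
  wavelength <- as.numeric(wavelength); K <- as.numeric(K)
  if (length(wavelength) != length(K)) stop("wavelength and K lengths differ")
  if (any(diff(wavelength) <= 0)) stop("wavelengths must be strictly increasing")
  if (any(is.infinite(K), na.rm = TRUE)) stop("K must be finite or NA")
  structure(list(wavelength = wavelength, K = K),
            class = "attenuation_spectrum")
}

#' Estimate attenuation coefficients from a depth series
#'
#' Downwelling irradiance decays approximately exponentially with depth,
#' E(lambda, z) = E(lambda, 0) exp(-K(lambda) z). K(lambda) is recovered per
#' wavelength as minus the ordinary-least-squares slope of ln E on z; with
#' exactly two depths this reduces to ln(E1/E2) / (z2 - z1). Wavelengths with
#' any non-positive irradiance are flagged `NA` rather than fabricated.
#'
#' @param series A [depth_series()].
#' @return An [attenuation_spectrum()] on the series' grid.
#' @export
attenuation_coefficients <- function(series) {
  if (!inherits(series, "depth_series")) stop("series must be a depth_series")
  E <- vapply(series$curves, function(c) c$value, numeric(length(series$wavelength)))
  # E: wavelengths x depths
  z <- series$depths
  zc <- z - mean(z)
  denom <- sum(zc^2)
  K <- apply(E, 1L, function(e) {
    if (any(e <= 0)) return(NA_real_)
    -sum(zc * (log(e) - mean(log(e)))) / denom
  })
  attenuation_spectrum(series$wavelength, K)
}

#' Propagate a surface spectrum to depth
#'
#' E(lambda, z) = E(lambda, 0) exp(-K(lambda) z). The attenuation spectrum is
#' interpolated onto the curve's grid (no extrapolation).
#'
#' @param surface A `spectral_curve` measured just below the surface.
#' @param K An [attenuation_spectrum()] covering the curve's span.
#' @param z Depth in metres, >= 0.
#' @return A `spectral_curve` at depth with the same quantity.
#' @export
propagate <- function(surface, K, z) {
  assert_curve(surface)
  if (!inherits(K, "attenuation_spectrum")) stop("K must be an attenuation_spectrum")
  if (!is.finite(z) || z < 0) stop("depth z must be >= 0, got ", z)
  ok <- !is.na(K$K)
  if (sum(ok) < 2L) stop("attenuation spectrum has too few usable wavelengths")
  lo <- min(K$wavelength[ok]); hi <- max(K$wavelength[ok])
  if (min(surface$wavelength) < lo || max(surface$wavelength) > hi) {
    stop("attenuation spectrum does not cover the curve span [",
         min(surface$wavelength), ", ", max(surface$wavelength), "] nm")
  }
  k <- stats::approx(K$wavelength[ok], K$K[ok], xout = surface$wavelength,
                     method = "linear", ties = "ordered")$y
  spectral_curve(surface$wavelength, surface$value * exp(-k * z),
                 surface$quantity, label = surface$label)
}
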