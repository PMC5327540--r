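# Seeded synthetic-data generators.
#
# Every generator is a pure function of its arguments (same seed, same
# output) and produces data with the statistical structure the analysis
# stages assume: eyeshine radiance spectra whose transmission rises with
# wavelength, exponentially attenuated depth profiles of downwelling
# irradiance, pleated-nerve angle series with constant torsion plus wrapped
# angular noise and axial flips, and specimen morphometry records drawn
# around published species means.

#' Default per-species parameter profiles
#'
#' Means and SDs of the anatomical and spectrometric quantities used to
#' parameterise the generators, keyed by species. These are generator
#' defaults transcribed from published summaries, not data.
#'
#' @return Named list of profiles; each profile is a list of
#'   `c(mean, sd)` pairs plus scalar band efficiencies.
#' @export
species_profiles <- function() {
  list(
    T_delaisi = list(
      total_length_mm = c(53.6, 4.6), head_diameter_mm = c(6.9, 0.4),
      body_volume_mm3 = c(684, 133), skull_thickness_um = c(54.0, 6.9),
      dermis_thickness_um = c(94.2, 8.0), on_depth_mm = c(1.57, 0.04),
      on_layers = c(7.8, 0.8), on_layer_thickness_um = c(54.9, 13.4),
      on_csa_mm2 = c(0.135, 0.040),
      dws_total = 1.51e19, ont_efficiency = 0.0203, pet_efficiency = 0.0047,
      torsion = list(start = 19.3, rate = 93.4, length = 0.81)
    ),
    T_melanurus = list(
      total_length_mm = c(40.5, 5.1), head_diameter_mm = c(4.9, 0.1),
      body_volume_mm3 = c(258, 86), skull_thickness_um = c(38.3, 7.5),
      dermis_thickness_um = c(35.3, 6.2), on_depth_mm = c(1.09, 0.05),
      on_layers = c(6.5, 0.7), on_layer_thickness_um = c(40.1, 11.1),
      on_csa_mm2 = c(0.065, 0.035),
      dws_total = 1.04e19, ont_efficiency = 0.0205, pet_efficiency = 0.0021,
      torsion = list(start = 19.3, rate = 93.4, length = 0.81)
    ),
    P_zvonimiri = list(
      total_length_mm = c(42, 0), head_diameter_mm = c(5.55, 0),
      body_volume_mm3 = c(339, 0), skull_thickness_um = c(84.2, 54.7),
      dermis_thickness_um = c(260.6, 160.4), on_depth_mm = c(1.38, 0.21),
      on_layers = c(4.5, 0), on_layer_thickness_um = c(63.5, 8.4),
      on_csa_mm2 = c(0.124, 0.037),
      dws_total = 1.47e19, ont_efficiency = 0.0108, pet_efficiency = 0.0022,
      torsion = list(start = 12.5, rate = 78.7, length = 0.96)
    ),
    A_ocellaris = list(
      total_length_mm = c(52.9, 5.2), head_diameter_mm = c(10.0, 1.2),
      body_volume_mm3 = c(1419, 503), skull_thickness_um = c(255.5, 39.5),
      dermis_thickness_um = c(275.0, 80.9), on_depth_mm = c(2.16, 0.31),
      on_layers = c(10.2, 0.8), on_layer_thickness_um = c(42.7, 4.3),
      on_csa_mm2 = c(0.096, 0.007),
      dws_total = 1.46e19, ont_efficiency = 0.0112, pet_efficiency = 0.0008,
      torsion = list(start = 11.6, rate = 82.5, length = 1.40)
    )
  )
}

# logistic transmission shape rising with wavelength, in (0, 1)
logistic_shape <- function(grid, midpoint = 560, scale = 60) {
  1 / (1 + exp(-(grid - midpoint) / scale))
}

#' Generate eyeshine and white-standard radiance spectra
#'
#' The diffuse white standard (DWS) is a broad, cyan-weighted illumination
#' spectrum scaled to a stated band-integrated photon radiance. The
#' optic-disc eyeshine is T(lambda) times the DWS with T a logistic rising
#' in wavelength (tissue transmits long wavelengths better), scaled exactly
#' so that its band-integrated efficiency relative to the DWS equals
#' `ont_efficiency` when noise is zero; the retinal background analogously
#' at `pet_efficiency`. Optional multiplicative log-normal measurement
#' noise is applied per wavelength.
#'
#' @param seed Integer RNG seed.
#' @param species Profile key (see [species_profiles()]) supplying defaults.
#' @param grid Wavelength grid in nm.
#' @param ont_efficiency,pet_efficiency Band efficiencies; default from the
#'   species profile.
#' @param dws_total Band-integrated DWS photon radiance
#'   (photons s^-1 sr^-1 mm^-2); default from the species profile.
#' @param noise_sd SD of log-normal multiplicative noise (default 0 =
#'   noiseless construction).
#' @param band Band over which efficiencies are defined.
#' @return List with `spectral_curve`s `dws`, `ont`, `pet` (all
#'   `photon_radiance`).
#' @export
gen_eyeshine_spectra <- function(seed = 1L, species = "T_delaisi",
                                 grid = 380:780,
                                 ont_efficiency = NULL, pet_efficiency = NULL,
                                 dws_total = NULL, noise_sd = 0,
                                 band = c(380, 780)) {
  prof <- species_profiles()[[species]]
  if (is.null(prof)) stop("unknown species profile: ", species)
  if (is.null(ont_efficiency)) ont_efficiency <- prof$ont_efficiency
  if (is.null(pet_efficiency)) pet_efficiency <- prof$pet_efficiency
  if (is.null(dws_total)) dws_total <- prof$dws_total
  withr_seed(seed, {
    shape <- exp(-((grid - 520) / 120)^2)
    dws_v <- shape * dws_total / trapz(grid, shape)
    g <- logistic_shape(grid)
    # scale the logistic so the band-integrated ratio is exact by construction
    keep <- grid >= band[1] & grid <= band[2]
    eff_g <- trapz(grid[keep], (g * dws_v)[keep]) / trapz(grid[keep], dws_v[keep])
    ont_v <- g * (ont_efficiency / eff_g) * dws_v
    pet_v <- g * (pet_efficiency / eff_g) * dws_v
    if (noise_sd > 0) {
      ont_v <- ont_v * exp(stats::rnorm(length(grid), 0, noise_sd))
      pet_v <- pet_v * exp(stats::rnorm(length(grid), 0, noise_sd))
      dws_v <- dws_v * exp(stats::rnorm(length(grid), 0, noise_sd))
    }
    list(
      dws = spectral_curve(grid, dws_v, "photon_radiance", label = "DWS"),
      ont = spectral_curve(grid, ont_v, "photon_radiance", label = "ONT eyeshine"),
      pet = spectral_curve(grid, pet_v, "photon_radiance", label = "PET eyeshine")
    )
  })
}

#' Water-like attenuation coefficient model
#'
#' A smooth K(lambda) with its minimum in the blue-green (clear coastal
#' water transmits 450--550 nm best) rising steeply into the red and gently
#' into the violet.
#'
#' @param grid Wavelength grid (nm).
#' @return An [attenuation_spectrum()].
#' @export
default_attenuation <- function(grid = 380:780) {
  K <- 0.035 +
    ifelse(grid > 490, 1.2e-5 * (grid - 490)^2, 2.0e-6 * (490 - grid)^2)
  attenuation_spectrum(grid, K)
}

#' Generate a depth-stratified downwelling irradiance series
#'
#' E(lambda, z) = E0(lambda) exp(-K(lambda) z) over a set of depths, with
#' optional per-measurement log-normal noise. The default depth grid is
#' 0 to 10 m in 0.5-m intervals, matching a standard irradiance dive
#' profile; the surface spectrum is a broad daylight-like curve.
#'
#' @param seed Integer RNG seed.
#' @param depths Depths in m, strictly increasing, >= 2 values.
#' @param grid Wavelength grid (nm).
#' @param K An [attenuation_spectrum()]; default [default_attenuation()].
#' @param noise_sd SD of log-normal multiplicative noise (0 = noiseless).
#' @return A [depth_series()] with attribute `K_true` holding the generating
#'   attenuation spectrum.
#' @export
gen_depth_profiles <- function(seed = 1L, depths = seq(0, 10, by = 0.5),
                               grid = 380:780, K = default_attenuation(grid),
                               noise_sd = 0) {
  if (length(depths) < 2L) stop("need at least two depths")
  if (!inherits(K, "attenuation_spectrum")) stop("K must be an attenuation_spectrum")
  withr_seed(seed, {
    e0 <- 3.5e18 * exp(-((grid - 550) / 180)^2)
    k <- stats::approx(K$wavelength, K$K, xout = grid, ties = "ordered")$y
    if (anyNA(k)) stop("attenuation model does not cover the grid")
    curves <- lapply(depths, function(z) {
      v <- e0 * exp(-k * z)
      if (noise_sd > 0) v <- v * exp(stats::rnorm(length(grid), 0, noise_sd))
      spectral_curve(grid, v, "photon_irradiance",
                     label = sprintf("E_d at %.1f m", z))
    })
    out <- depth_series(depths, curves)
    attr(out, "K_true") <- attenuation_spectrum(grid, k)
    out
  })
}

#' Generate pleated-nerve section measurements
#'
#' Sections are spaced at uniform-random 40--60 um steps from the optic
#' disc to the nerve's end. Each section has a uniform-random 4--11 layers
#' of uniform-random 30--60 um length. The true axis angle follows
#' start + rate * distance; observed angles add wrapped-normal noise
#' (optionally von Mises) and, when `flips` is on, a random half of layers
#' are reported 180 degrees off (the axial ambiguity of an orientation).
#'
#' @param seed Integer RNG seed.
#' @param start_angle True angle at the optic disc, degrees.
#' @param torsion_rate True torsion, degrees per mm.
#' @param noise_sd Angular noise SD in degrees (wrapped normal).
#' @param nerve_length Nerve length in mm.
#' @param flips Randomly flip layers by 180 degrees (default `TRUE`).
#' @param noise_model `"wrapped_normal"` (default) or `"von_mises"` with
#'   concentration `kappa = (180 / (pi * noise_sd))^2` matched to the same
#'   angular SD.
#' @return A data.frame with columns `distance_mm`, `layer_index`,
#'   `angle_deg` (in `[0, 360)`), `length_um`, plus attribute `truth`
#'   (list of the generating parameters).
#' @export
gen_nerve_sections <- function(seed = 1L, start_angle = 19.3,
                               torsion_rate = 93.4, noise_sd = 10,
                               nerve_length = 0.81, flips = TRUE,
                               noise_model = c("wrapped_normal", "von_mises")) {
  noise_model <- match.arg(noise_model)
  if (!is.finite(torsion_rate)) stop("torsion_rate must be finite")
  if (!is.finite(nerve_length) || nerve_length <= 0) {
    stop("nerve_length must be positive")
  }
  withr_seed(seed, {
    d <- 0
    repeat {
      nxt <- d[length(d)] + stats::runif(1, 0.040, 0.060)
      if (nxt > nerve_length) break
      d <- c(d, nxt)
    }
    rows <- lapply(seq_along(d), function(i) {
      nl <- sample(4:11, 1L)
      truth <- start_angle + torsion_rate * d[i]
      noise <- if (noise_sd == 0) {
        rep(0, nl)
      } else if (noise_model == "wrapped_normal") {
        stats::rnorm(nl, 0, noise_sd)
      } else {
        kappa <- (180 / (pi * noise_sd))^2
        rad2deg(rvonmises(nl, kappa))
      }
      ang <- truth + noise
      if (flips) ang <- ang + 180 * stats::rbinom(nl, 1L, 0.5)
      data.frame(distance_mm = d[i], layer_index = seq_len(nl),
                 angle_deg = ang %% 360,
                 length_um = stats::runif(nl, 30, 60))
    })
    out <- do.call(rbind, rows)
    attr(out, "truth") <- list(start_angle = start_angle,
                               torsion_rate = torsion_rate,
                               noise_sd = noise_sd,
                               nerve_length = nerve_length)
    out
  })
}

# von Mises sampler (Best & Fisher rejection algorithm), centred on 0
rvonmises <- function(n, kappa) {
  if (kappa <= 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c_ <- kappa * (r - f)
      if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
        out[i] <- sign(u[3] - 0.5) * acos(f)
        break
      }
    }
  }
  out
}

#' Generate specimen morphometry records
#'
#' Draws records from normals truncated at zero around a species profile's
#' means and SDs; per-individual head diameter and derived relative values
#' are consistent by construction.
#'
#' @param seed Integer RNG seed.
#' @param species Profile key (see [species_profiles()]).
#' @param n Number of specimens.
#' @return A data.frame with one row per specimen and the numeric columns of
#'   [specimen_fields] (head width/height synthesised so their mean equals
#'   the profile head diameter).
#' @export
gen_morphometry <- function(seed = 1L, species = "T_delaisi", n = 10L) {
  prof <- species_profiles()[[species]]
  if (is.null(prof)) stop("unknown species profile: ", species)
  rtnorm <- function(n, mean, sd) {
    if (sd == 0) return(rep(mean, n))
    x <- stats::rnorm(n, mean, sd)
    while (any(x <= 0)) x[x <= 0] <- stats::rnorm(sum(x <= 0), mean, sd)
    x
  }
  withr_seed(seed, {
    hd <- rtnorm(n, prof$head_diameter_mm[1], prof$head_diameter_mm[2])
    spread <- rtnorm(n, 0.5, 0.15) # width/height asymmetry around the mean
    data.frame(
      species = species,
      total_length_mm = rtnorm(n, prof$total_length_mm[1], prof$total_length_mm[2]),
      head_width_mm = hd * (1 + (spread - 0.5)),
      head_height_mm = hd * (1 - (spread - 0.5)),
      head_diameter_mm = hd,
      body_volume_mm3 = rtnorm(n, prof$body_volume_mm3[1], prof$body_volume_mm3[2]),
      skull_thickness_um = rtnorm(n, prof$skull_thickness_um[1], prof$skull_thickness_um[2]),
      dermis_thickness_um = rtnorm(n, prof$dermis_thickness_um[1], prof$dermis_thickness_um[2]),
      on_depth_mm = rtnorm(n, prof$on_depth_mm[1], prof$on_depth_mm[2]),
      on_layers = pmax(1, round(rtnorm(n, prof$on_layers[1], prof$on_layers[2]))),
      on_layer_thickness_um = rtnorm(n, prof$on_layer_thickness_um[1],
                                     prof$on_layer_thickness_um[2]),
      on_csa_mm2 = rtnorm(n, prof$on_csa_mm2[1], prof$on_csa_mm2[2])
    )
  })
}

# run code under a local RNG seed without disturbing the caller's RNG state
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}
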