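# Receptor-noise-limited model of eyeshine conspicuousness.
#
# Photoreceptor spectral sensitivities are built from the Govardovskii A1
# visual pigment template (alpha plus beta band), filtered by the ocular
# media, and integrated against photon spectra to give quantum catches.
# Chromatic contrast between two stimuli is the Vorobyev-Osorio
# receptor-noise distance on log catches (bright-light form); achromatic
# contrast uses the summed double-cone channel.

#' Govardovskii A1 visual pigment template
#'
#' Alpha band: S(x) = 1 / (exp(A(a - x)) + exp(B(b - x)) + exp(C(c - x)) + D)
#' with x = lambda_max / lambda, A = 69.7, B = 28, C = -14.9, D = 0.674,
#' b = 0.922, c = 1.104 and a = 0.8795 + 0.0459 exp(-(lambda_max - 300)^2 /
#' 11940). Beta band: a Gaussian with amplitude 0.26 centred at
#' 189 + 0.315 lambda_max with width -40.5 + 0.195 lambda_max. The sum is
#' normalised to peak 1.
#'
#' @param lambda_max Wavelength of peak absorbance in nm, in `[330, 650]`
#'   (the template's validated range for A1 pigments).
#' @param grid Wavelength grid in nm (default 1-nm steps over 380--780).
#' @param beta Include the beta band (default `TRUE`).
#' @return A `spectral_curve` with quantity `sensitivity`, peak-normalised.
#' @export
pigment_template <- function(lambda_max, grid = 380:780, beta = TRUE) {
  if (!is.finite(lambda_max) || lambda_max < 330 || lambda_max > 650) {
    stop("lambda_max must be within [330, 650] nm, got ", lambda_max)
  }
  x <- lambda_max / grid
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                exp(-14.9 * (1.104 - x)) + 0.674)
  s <- alpha
  if (beta) {
    lmb <- 189 + 0.315 * lambda_max
    bb <- -40.5 + 0.195 * lambda_max
    s <- s + 0.26 * exp(-((grid - lmb) / bb)^2)
  }
  spectral_curve(grid, s / max(s), "sensitivity",
                 label = paste0("A1 template ", lambda_max, " nm"))
}

#' Construct a visual system
#'
#' A trichromatic receptor set with relative densities, a Weber fraction for
#' the most abundant class, and optional ocular-media transmittance. The
#' double-cone members (used for the achromatic channel) are identified by
#' index.
#'
#' @param lambda_max Numeric length 3: peak sensitivities in nm, listed as
#'   (single cone, double-cone member 1, double-cone member 2) by default.
#' @param density Relative photoreceptor densities, length 3 (default
#'   `c(1, 4, 4)`).
#' @param weber Weber fraction of the most abundant class (default 0.05).
#' @param ocular_media Optional `spectral_curve` of quantity `transmittance`
#'   (e.g. the product of cornea and lens transmittances); `NULL` means
#'   perfectly transparent media.
#' @param double_cone Indices of the double-cone members (default `c(2, 3)`).
#' @param labels Receptor labels.
#' @return An object of class `visual_system`.
#' @export
visual_system <- function(lambda_max = c(468, 516, 530),
                          density = c(1, 4, 4),
                          weber = 0.05,
                          ocular_media = NULL,
                          double_cone = c(2L, 3L),
                          labels = c("single", "double_1", "double_2")) {
  if (length(lambda_max) != 3L || length(density) != 3L) {
    stop("a trichromatic system needs exactly 3 receptor classes")
  }
  if (any(density <= 0)) stop("densities must be positive")
  if (!is.finite(weber) || weber <= 0) stop("weber fraction must be > 0")
  if (!is.null(ocular_media)) {
    assert_curve(ocular_media)
    if (ocular_media$quantity != "transmittance") {
      stop("ocular_media must be a transmittance curve")
    }
  }
  if (length(double_cone) != 2L || !all(double_cone %in% 1:3)) {
    stop("double_cone must name two of the three receptor classes")
  }
  structure(
    list(lambda_max = as.numeric(lambda_max), density = as.numeric(density),
         weber = weber, ocular_media = ocular_media,
         double_cone = as.integer(double_cone), labels = labels),
    class = "visual_system"
  )
}

#' @export
print.visual_system <- function(x, ...) {
  cat("<visual_system> trichromat\n")
  cat("  lambda_max:", paste0(x$lambda_max, " nm", collapse = ", "), "\n")
  cat("  densities :", paste(x$density, collapse = ":"),
      " weber:", x$weber, "\n")
  cat("  ocular media:", if (is.null(x$ocular_media)) "none (T = 1)" else "supplied", "\n")
  invisible(x)
}

#' Effective spectral sensitivity of a receptor behind the ocular media
#'
#' Pigment template times media transmittance, element-wise on a common
#' grid.
#'
#' @param lambda_max Receptor peak wavelength, nm.
#' @param media `spectral_curve` of quantity `transmittance`, or `NULL` for
#'   transparent media.
#' @param grid Wavelength grid (nm).
#' @return A `spectral_curve` of quantity `sensitivity` (not re-normalised:
#'   media filtering legitimately reduces and shifts the peak).
#' @export
effective_sensitivity <- function(lambda_max, media = NULL, grid = 380:780) {
  templ <- pigment_template(lambda_max, grid)
  if (is.null(media)) return(templ)
  m <- resample(media, grid)
  spectral_curve(grid, templ$value * m$value, "sensitivity",
                 label = templ$label)
}

#' Quantum catch of a receptor viewing a stimulus
#'
#' Trapezoid integral of sensitivity times the stimulus photon spectrum over
#' the shared grid. Relative units: any common scale factor cancels in the
#' contrast model.
#'
#' @param sens `spectral_curve` of quantity `sensitivity`.
#' @param stimulus `spectral_curve` of a photon quantity, same grid.
#' @return Numeric catch.
#' @export
quantum_catch <- function(sens, stimulus) {
  assert_curve(sens); assert_curve(stimulus)
  if (!identical(sens$wavelength, stimulus$wavelength)) {
    stop("sensitivity and stimulus must share a wavelength grid; resample first")
  }
  trapz(sens$wavelength, sens$value * stimulus$value)
}

#' Per-class receptor noise
#'
#' omega_i = weber * sqrt(density_max / density_i): the stated Weber
#' fraction applies to the most abundant class, rarer classes are noisier by
#' the square-root law of noise pooling.
#'
#' @param system A [visual_system()].
#' @return Numeric length 3 of noise values, ordered as the receptors.
#' @export
receptor_noise <- function(system) {
  if (!inherits(system, "visual_system")) stop("system must be a visual_system")
  system$weber * sqrt(max(system$density) / system$density)
}

#' Chromatic contrast (receptor-noise model, trichromat)
#'
#' Log receptor signals f_i = ln(Q_i^target / Q_i^background); the
#' just-noticeable-difference distance is
#' sqrt((w1^2 (df3 - df2)^2 + w2^2 (df3 - df1)^2 + w3^2 (df2 - df1)^2) /
#'      ((w1 w2)^2 + (w1 w3)^2 + (w2 w3)^2)).
#'
#' @param catch_target,catch_background Numeric length 3, positive quantum
#'   catches per receptor class.
#' @param noise Numeric length 3 of receptor noise values (see
#'   [receptor_noise()]).
#' @return Chromatic contrast in JND.
#' @export
chromatic_contrast <- function(catch_target, catch_background, noise) {
  if (length(catch_target) != 3L || length(catch_background) != 3L ||
      length(noise) != 3L) {
    stop("trichromatic contrast needs 3 catches per stimulus and 3 noise values")
  }
  if (any(catch_target <= 0) || any(catch_background <= 0)) {
    stop("quantum catches must be positive for the log-linear model")
  }
  df <- log(catch_target / catch_background)
  w <- noise
  num <- w[1]^2 * (df[3] - df[2])^2 +
         w[2]^2 * (df[3] - df[1])^2 +
         w[3]^2 * (df[2] - df[1])^2
  den <- (w[1] * w[2])^2 + (w[1] * w[3])^2 + (w[2] * w[3])^2
  sqrt(num / den)
}

#' Achromatic contrast (double-cone channel)
#'
#' delta L = |ln(Q_target / Q_background)| / omega_D, with catches taken
#' through the summed double-cone sensitivity.
#'
#' @param catch_target,catch_background Positive achromatic catches.
#' @param omega_d Noise of the achromatic channel (default: the double
#'   cones' Weber fraction, 0.05).
#' @return Achromatic contrast in JND.
#' @export
achromatic_contrast <- function(catch_target, catch_background, omega_d = 0.05) {
  if (catch_target <= 0 || catch_background <= 0) {
    stop("quantum catches must be positive")
  }
  abs(log(catch_target / catch_background)) / omega_d
}

#' Perceived contrast of eyeshine against the retinal background at depth
#'
#' Propagates a surface irradiance spectrum to depth, builds the eyeshine
#' stimulus as the nerve-transmitted fraction of that light and the
#' background as the pigment-epithelium-transmitted fraction, and evaluates
#' chromatic and achromatic receptor-noise contrasts. Any common geometric
#' factor between irradiance and pupil radiance cancels in the log ratios.
#'
#' @param surface_irradiance `spectral_curve`, photon irradiance just below
#'   the surface.
#' @param K [attenuation_spectrum()].
#' @param depth Depth in metres, >= 0.
#' @param ont_transmission,pet_transmission `spectral_curve`s of quantity
#'   `transmittance`: the optic-disc and surrounding-retina transmission
#'   spectra.
#' @param system A [visual_system()].
#' @return An object of class `contrast_result`: list with `delta_S`,
#'   `delta_L` (JND), `depth`.
#' @export
eyeshine_contrast_at_depth <- function(surface_irradiance, K, depth,
                                       ont_transmission, pet_transmission,
                                       system) {
  assert_curve(surface_irradiance)
  assert_curve(ont_transmission); assert_curve(pet_transmission)
  if (!inherits(system, "visual_system")) stop("system must be a visual_system")
  grid <- common_grid(surface_irradiance, ont_transmission, pet_transmission)
  if (!is.null(system$ocular_media)) {
    lo <- max(min(grid), min(system$ocular_media$wavelength))
    hi <- min(max(grid), max(system$ocular_media$wavelength))
    grid <- grid[grid >= lo & grid <= hi]
  }
  e0 <- resample(surface_irradiance, grid)
  ed <- propagate(e0, K, depth)
  t_ont <- resample(ont_transmission, grid)
  t_pet <- resample(pet_transmission, grid)
  target <- spectral_curve(grid, t_ont$value * ed$value, ed$quantity)
  backgr <- spectral_curve(grid, t_pet$value * ed$value, ed$quantity)
  sens <- lapply(system$lambda_max, effective_sensitivity,
                 media = system$ocular_media, grid = grid)
  qt <- vapply(sens, quantum_catch, 0, stimulus = target)
  qb <- vapply(sens, quantum_catch, 0, stimulus = backgr)
  dc <- system$double_cone
  dsens <- spectral_curve(grid, sens[[dc[1]]]$value + sens[[dc[2]]]$value,
                          "sensitivity")
  ds <- chromatic_contrast(qt, qb, receptor_noise(system))
  dl <- achromatic_contrast(quantum_catch(dsens, target),
                            quantum_catch(dsens, backgr),
                            omega_d = system$weber)
  structure(list(delta_S = ds, delta_L = dl, depth = depth),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("<contrast_result> depth %.1f m: dS = %.3f JND, dL = %.3f JND\n",
              x$depth, x$delta_S, x$delta_L))
  invisible(x)
}
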