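# spectral curve construction, conversion, ratios, attenuation, propagation

test_that("spectral_curve validates its invariants", {
  expect_s3_class(spectral_curve(380:780, rep(1, 401), "transmittance"),
                  "spectral_curve")
  expect_error(spectral_curve(c(400, 400, 500), c(1, 1, 1), "sensitivity"),
               "strictly increasing")
  expect_error(spectral_curve(400:500, rep(1, 100), "transmittance"),
               "equal length")
  expect_error(spectral_curve(c(400, 500), c(1, NA), "transmittance"),
               "non-finite")
  expect_error(spectral_curve(c(250, 500), c(1, 1), "transmittance"),
               "300-800")
  expect_error(spectral_curve(c(400, 500), c(-1, 1), "sensitivity"), ">= 0")
})

test_that("resample is the identity on the curve's own grid and linear between", {
  cv <- spectral_curve(c(400, 500), c(0, 1), "energy_radiance")
  expect_identical(resample(cv, c(400, 500))$value, c(0, 1))
  expect_equal(resample(cv, 450)$value, 0.5)
  expect_equal(resample(cv, c(410, 425, 490))$value, c(0.1, 0.25, 0.9))
  # quantity travels along
  expect_identical(resample(cv, 450)$quantity, "energy_radiance")
  wide <- spectral_curve(380:780, rnorm(401)^2, "energy_radiance")
  expect_error(resample(wide, 350), "350")
})

test_that("energy_to_photon follows the Planck relation", {
  # oracle: N = L * lambda / (h c); frozen for 1 W sr^-1 m^-2 nm^-1 at 500 nm
  cv <- spectral_curve(c(400, 500, 800), c(1, 1, 1), "energy_radiance")
  ph <- energy_to_photon(cv)
  expect_identical(ph$quantity, "photon_radiance")
  expect_equal(ph$value[2L], 2.51706e18, tolerance = 1e-5)
  # linear in wavelength: equal energy at 400 vs 800 nm -> 1:2 photons
  expect_equal(ph$value[3L] / ph$value[1L], 2)
  # zero light stays zero
  z <- energy_to_photon(spectral_curve(400:410, rep(0, 11), "energy_irradiance"))
  expect_identical(unique(z$value), 0)
  expect_identical(z$quantity, "photon_irradiance")
  expect_error(energy_to_photon(spectral_curve(400:410, rep(1, 11), "transmittance")),
               "energy flux")
  expect_error(energy_to_photon(spectral_curve(c(400, 500), c(-1, 1), "energy_radiance")),
               "negative")
})

test_that("transmittance is an element-wise ratio with guards", {
  ref <- make_flat_curve(2, 400:500)
  expect_identical(transmittance(ref, ref)$value, rep(1, 101))
  half <- spectral_curve(400:500, rep(1, 101), "photon_radiance")
  expect_identical(transmittance(half, ref)$value, rep(0.5, 101))
  # scale invariance
  s <- spectral_curve(400:500, runif(101), "photon_radiance")
  t1 <- transmittance(s, ref)$value
  s2 <- spectral_curve(400:500, s$value * 7, "photon_radiance")
  ref2 <- spectral_curve(400:500, ref$value * 7, "photon_radiance")
  expect_equal(transmittance(s2, ref2)$value, t1)
  # zero reference under nonzero sample errors with wavelengths named
  ref0 <- spectral_curve(400:500, c(0, rep(1, 100)), "photon_radiance")
  expect_error(transmittance(make_flat_curve(1, 400:500), ref0), "400")
  # > 1 kept but warned
  expect_warning(tr <- transmittance(ref, half), "> 1")
  expect_identical(tr$value, rep(2, 101))
  expect_error(transmittance(make_flat_curve(1, 400:500), make_flat_curve(1, 410:510)),
               "grid")
})

test_that("band_ratio equals the flux-weighted mean transmittance", {
  grid <- 380:780
  dws <- spectral_curve(grid, exp(-((grid - 520) / 100)^2) * 1e18,
                        "photon_radiance")
  tr <- 0.02 / (1 + exp(-(grid - 560) / 50))
  ont <- spectral_curve(grid, tr * dws$value, "photon_radiance")
  # independent numeric-integration oracle on the same grid
  expected <- sum(diff(grid) * (head(tr * dws$value, -1) + tail(tr * dws$value, -1)) / 2) /
    sum(diff(grid) * (head(dws$value, -1) + tail(dws$value, -1)) / 2)
  expect_equal(band_ratio(ont, dws), expected)
  # proportional spectra give the constant for any band
  prop <- spectral_curve(grid, 0.5 * dws$value, "photon_radiance")
  expect_equal(band_ratio(prop, dws), 0.5)
  expect_equal(band_ratio(prop, dws, band = c(401, 433)), 0.5)
  # bounded by the min/max per-wavelength ratio over the band
  expect_gt(band_ratio(ont, dws), min(tr))
  expect_lt(band_ratio(ont, dws), max(tr))
  expect_error(band_ratio(ont, dws, band = c(300, 350)), "no overlap")
  expect_error(band_ratio(ont, dws, band = c(500, 400)), "increasing")
})

test_that("attenuation coefficients: closed forms and regression oracle", {
  grid <- seq(400, 700, by = 10)
  e0 <- spectral_curve(grid, rep(100, length(grid)), "photon_irradiance")
  # two-point closed form
  e1 <- spectral_curve(grid, rep(100 * exp(-0.1 * 3), length(grid)),
                       "photon_irradiance")
  K2 <- attenuation_coefficients(depth_series(c(2, 5), list(e0, e1)))
  expect_equal(K2$K, rep(0.1, length(grid)), tolerance = 1e-12)
  # depth-constant profile -> K = 0
  K0 <- attenuation_coefficients(depth_series(c(0, 1, 2), list(e0, e0, e0)))
  expect_equal(K0$K, rep(0, length(grid)), tolerance = 1e-12)
  # noiseless 5-depth synthetic with per-wavelength K: exact recovery,
  # matching the independent per-wavelength lm() oracle
  set.seed(42)
  ktrue <- runif(length(grid), 0.02, 0.8)
  depths <- c(0, 1.5, 3, 4.5, 6)
  curves <- lapply(depths, function(z) {
    spectral_curve(grid, 100 * exp(-ktrue * z), "photon_irradiance")
  })
  series <- depth_series(depths, curves)
  Khat <- attenuation_coefficients(series)
  expect_equal(Khat$K, ktrue, tolerance = 1e-10)
  expect_equal(Khat$K, unname(oracle_attenuation(series)), tolerance = 1e-10)
  # non-positive irradiance flags NA instead of fabricating
  bad <- spectral_curve(grid, c(0, rep(1, length(grid) - 1L)), "photon_irradiance")
  Kna <- attenuation_coefficients(depth_series(c(0, 1), list(e0, bad)))
  expect_true(is.na(Kna$K[1L]))
  expect_false(anyNA(Kna$K[-1L]))
})

test_that("propagate decays exponentially and composes over depth", {
  grid <- 400:700
  K <- attenuation_spectrum(grid, 0.02 + 1e-5 * (grid - 490)^2)
  e0 <- spectral_curve(grid, 1e18 * exp(-((grid - 550) / 150)^2),
                       "photon_irradiance")
  expect_equal(propagate(e0, K, 0)$value, e0$value)
  e5 <- propagate(e0, K, 5)
  expect_true(all(e5$value < e0$value))
  # semigroup property: z1 + z2 == z2 after z1
  expect_equal(propagate(e0, K, 7)$value,
               propagate(propagate(e0, K, 3), K, 4)$value,
               tolerance = 1e-12)
  # round-trip with attenuation_coefficients recovers K
  series <- depth_series(c(0, 5), list(e0, e5))
  expect_equal(attenuation_coefficients(series)$K, K$K, tolerance = 1e-10)
  expect_error(propagate(e0, K, -1), ">= 0")
})
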