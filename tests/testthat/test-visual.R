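# pigment templates, quantum catches, receptor-noise contrasts

test_that("pigment_template peaks at lambda_max and stays in (0, 1]", {
  for (lm in c(468, 516, 530)) {
    tpl <- pigment_template(lm, 380:780)
    expect_equal(max(tpl$value), 1)
    expect_equal(tpl$wavelength[which.max(tpl$value)], lm, tolerance = 2)
    expect_true(all(tpl$value > 0 & tpl$value <= 1))
  }
  # long-wavelength ordering: the 530 template exceeds the 516 one at 600 nm
  at600 <- function(lm) resample(pigment_template(lm), 600)$value
  expect_gt(at600(530), at600(516))
  expect_error(pigment_template(300), "330")
})

test_that("effective_sensitivity filters through the media", {
  grid <- 400:700
  tpl <- pigment_template(516, grid)
  clear <- spectral_curve(grid, rep(1, length(grid)), "transmittance")
  expect_equal(effective_sensitivity(516, clear, grid)$value, tpl$value)
  half <- spectral_curve(grid, rep(0.5, length(grid)), "transmittance")
  expect_equal(effective_sensitivity(516, half, grid)$value, tpl$value / 2)
  # short-pass-blocking media shift the effective peak to longer wavelengths
  block <- spectral_curve(grid, 1 / (1 + exp(-(grid - 540) / 10)), "transmittance")
  eff <- effective_sensitivity(516, block, grid)
  expect_gt(grid[which.max(eff$value)], grid[which.max(tpl$value)])
})

test_that("quantum_catch is a linear trapezoid integral", {
  grid <- 400:700
  flat_s <- spectral_curve(grid, rep(1, length(grid)), "sensitivity")
  flat_q <- spectral_curve(grid, rep(1, length(grid)), "photon_radiance")
  expect_equal(quantum_catch(flat_s, flat_q), 300)
  zero <- spectral_curve(grid, rep(0, length(grid)), "photon_radiance")
  expect_equal(quantum_catch(flat_s, zero), 0)
  stim <- spectral_curve(grid, runif(length(grid)), "photon_radiance")
  k3 <- spectral_curve(grid, 3 * stim$value, "photon_radiance")
  expect_equal(quantum_catch(flat_s, k3), 3 * quantum_catch(flat_s, stim))
  expect_error(quantum_catch(flat_s, spectral_curve(500:700, rep(1, 201), "photon_radiance")),
               "grid")
})

test_that("receptor_noise follows the square-root density law", {
  vs <- visual_system(density = c(1, 4, 4), weber = 0.05)
  expect_equal(receptor_noise(vs), c(0.10, 0.05, 0.05))
  eq <- visual_system(density = c(2, 2, 2), weber = 0.07)
  expect_equal(receptor_noise(eq), rep(0.07, 3))
})

test_that("chromatic_contrast matches a scalar arithmetic oracle", {
  w <- c(0.1, 0.05, 0.05)
  # identical stimuli
  expect_equal(chromatic_contrast(c(1, 2, 3), c(1, 2, 3), w), 0)
  # symmetry under swapping target and background
  qt <- c(1.3, 0.8, 2.0); qb <- c(1.0, 1.1, 1.7)
  expect_equal(chromatic_contrast(qt, qb, w), chromatic_contrast(qb, qt, w))
  # hand-evaluated: df = (0.1, 0, 0)
  qt2 <- c(exp(0.1), 1, 1); qb2 <- c(1, 1, 1)
  num <- w[1]^2 * 0 + w[2]^2 * (-0.1)^2 + w[3]^2 * (-0.1)^2
  den <- (w[1] * w[2])^2 + (w[1] * w[3])^2 + (w[2] * w[3])^2
  expect_equal(chromatic_contrast(qt2, qb2, w), sqrt(num / den))
  # common rescaling of both stimuli cancels
  expect_equal(chromatic_contrast(5 * qt, 5 * qb, w),
               chromatic_contrast(qt, qb, w))
  # doubling the weber fraction halves the contrast
  expect_equal(chromatic_contrast(qt, qb, 2 * w),
               chromatic_contrast(qt, qb, w) / 2)
  expect_error(chromatic_contrast(c(0, 1, 1), qb, w), "positive")
})

test_that("dichromat reduction limit of the trichromat formula", {
  # collapse classes 2 and 3 to identical catches and noise: the formula
  # reduces to |df1 - df2| / sqrt(w1^2 + w2^2)
  w <- c(0.1, 0.05, 0.05)
  qt <- c(2.0, 1.5, 1.5); qb <- c(1.0, 1.2, 1.2)
  df <- log(qt / qb)
  tri <- chromatic_contrast(qt, qb, w)
  # exact algebra when df2 == df3 and w2 == w3: substitute into the formula
  num <- w[1]^2 * 0 + (w[2]^2 + w[3]^2) * (df[2] - df[1])^2
  den <- (w[1] * w[2])^2 + (w[1] * w[3])^2 + (w[2] * w[3])^2
  expect_equal(tri, sqrt(num / den))
  # and with w2 = w3 = w_pooled/sqrt(2) this is |df1 - df2|/sqrt(w1^2 + wp^2)
  wp <- w[2] / sqrt(2)
  expect_equal(tri, abs(df[1] - df[2]) / sqrt(w[1]^2 + wp^2), tolerance = 1e-12)
})

test_that("achromatic_contrast is |log ratio| over the Weber fraction", {
  expect_equal(achromatic_contrast(exp(0.05), 1, 0.05), 1)
  expect_equal(achromatic_contrast(3, 3, 0.05), 0)
  expect_equal(achromatic_contrast(2, 1, 0.05), achromatic_contrast(1, 2, 0.05))
  expect_equal(achromatic_contrast(2, 1, 0.10),
               achromatic_contrast(2, 1, 0.05) / 2)
  expect_error(achromatic_contrast(0, 1), "positive")
})

test_that("eyeshine_contrast_at_depth has the predicted cancellations", {
  grid <- 380:780
  series <- gen_depth_profiles(seed = 2)
  K <- attenuation_coefficients(series)
  e0 <- series$curves[[1L]]
  vs <- visual_system()
  tr <- spectral_curve(grid, 0.02 / (1 + exp(-(grid - 560) / 60)), "transmittance")
  # identical transmissions: zero on both channels
  same <- eyeshine_contrast_at_depth(e0, K, 5, tr, tr, vs)
  expect_equal(same$delta_S, 0, tolerance = 1e-9)
  expect_equal(same$delta_L, 0, tolerance = 1e-9)
  # spectrally flat factor k: dS = 0, dL = |ln k| / omega exactly
  k <- 0.25
  tr_k <- spectral_curve(grid, k * tr$value, "transmittance")
  fl <- eyeshine_contrast_at_depth(e0, K, 5, tr, tr_k, vs)
  expect_equal(fl$delta_S, 0, tolerance = 1e-9)
  expect_equal(fl$delta_L, abs(log(k)) / vs$weber, tolerance = 1e-9)
  # invariance to common rescaling of the illumination
  e0x <- spectral_curve(grid, 10 * e0$value, e0$quantity)
  fl2 <- eyeshine_contrast_at_depth(e0x, K, 5, tr, tr_k, vs)
  expect_equal(fl2$delta_L, fl$delta_L, tolerance = 1e-9)
  expect_equal(fl2$delta_S, fl$delta_S, tolerance = 1e-9)
})
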