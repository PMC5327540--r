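# seeded generators: construction guarantees and determinism

test_that("gen_eyeshine_spectra builds ratios exactly and deterministically", {
  sp <- gen_eyeshine_spectra(seed = 1, noise_sd = 0)
  expect_equal(band_ratio(sp$ont, sp$dws), 0.0203, tolerance = 1e-12)
  expect_equal(band_ratio(sp$pet, sp$dws), 0.0047, tolerance = 1e-12)
  # stated magnitude: band-integrated DWS photon radiance
  grid <- sp$dws$wavelength
  expect_equal(sum(diff(grid) * (head(sp$dws$value, -1) + tail(sp$dws$value, -1)) / 2),
               1.51e19, tolerance = 1e-9)
  # per-wavelength transmission rises with wavelength by construction
  tr <- sp$ont$value / sp$dws$value
  expect_true(all(diff(tr) > 0))
  # explicit efficiency override is honoured exactly
  sp2 <- gen_eyeshine_spectra(seed = 1, ont_efficiency = 0.02, noise_sd = 0)
  expect_equal(band_ratio(sp2$ont, sp2$dws), 0.02, tolerance = 1e-12)
  # determinism (with noise engaged)
  a <- gen_eyeshine_spectra(seed = 4, noise_sd = 0.05)
  b <- gen_eyeshine_spectra(seed = 4, noise_sd = 0.05)
  expect_identical(a$ont$value, b$ont$value)
  c <- gen_eyeshine_spectra(seed = 5, noise_sd = 0.05)
  expect_false(identical(a$ont$value, c$ont$value))
})

test_that("gen_depth_profiles round-trips through attenuation_coefficients", {
  ds <- gen_depth_profiles(seed = 1, noise_sd = 0)
  K <- attenuation_coefficients(ds)
  expect_equal(K$K, attr(ds, "K_true")$K, tolerance = 1e-10)
  expect_error(gen_depth_profiles(seed = 1, depths = 0), "two depths")
  # noisy profile still recovers K within 5% at mid-band
  dsn <- gen_depth_profiles(seed = 8, noise_sd = 0.02)
  Kn <- attenuation_coefficients(dsn)
  mid <- dsn$wavelength >= 450 & dsn$wavelength <= 650
  rel <- abs(Kn$K[mid] - attr(dsn, "K_true")$K[mid]) / attr(dsn, "K_true")$K[mid]
  expect_lt(stats::median(rel), 0.05)
})

test_that("gen_nerve_sections respects its stated world", {
  secs <- gen_nerve_sections(seed = 2)
  steps <- diff(sort(unique(secs$distance_mm)))
  expect_true(all(steps >= 0.040 - 1e-12 & steps <= 0.060 + 1e-12))
  layer_counts <- table(secs$distance_mm)
  expect_true(all(layer_counts >= 4 & layer_counts <= 11))
  expect_true(all(secs$length_um >= 30 & secs$length_um <= 60))
  expect_true(all(secs$angle_deg >= 0 & secs$angle_deg < 360))
  expect_identical(gen_nerve_sections(seed = 2), secs)
  # noiseless without flips: plain OLS on section means recovers the slope
  clean <- gen_nerve_sections(seed = 3, noise_sd = 0, flips = FALSE)
  sm <- section_means(clean, axial = FALSE)
  orc <- oracle_ols(sm$distance_mm, sm$mean_angle_deg)
  expect_equal(unname(orc["slope"]), 93.4, tolerance = 1e-6)
  # noiseless with flips: the axial pipeline still recovers it exactly
  flipped <- gen_nerve_sections(seed = 3, noise_sd = 0, flips = TRUE)
  fit <- analyze_nerve(flipped)
  expect_equal(fit$torsion_rate, 93.4, tolerance = 1e-8)
  # von Mises noise option runs and stays on the circle
  vm <- gen_nerve_sections(seed = 6, noise_model = "von_mises")
  expect_true(all(vm$angle_deg >= 0 & vm$angle_deg < 360))
})

test_that("gen_morphometry draws around its profile", {
  recs <- gen_morphometry(seed = 1, species = "T_delaisi", n = 400)
  prof <- species_profiles()$T_delaisi
  s <- summarize_records(recs)
  hd <- s[s$field == "head_diameter_mm", ]
  # large-n mean within 3 SE of the profile mean
  expect_lt(abs(hd$mean - prof$head_diameter_mm[1]),
            3 * prof$head_diameter_mm[2] / sqrt(400))
  # head diameter is the mean of width and height by construction
  expect_equal(head_diameter(recs$head_width_mm, recs$head_height_mm),
               recs$head_diameter_mm, tolerance = 1e-9)
  # SD-0 profile fields are constant
  pz <- gen_morphometry(seed = 1, species = "P_zvonimiri", n = 5)
  expect_identical(unique(pz$head_diameter_mm), 5.55)
  expect_identical(gen_morphometry(seed = 3, n = 4), gen_morphometry(seed = 3, n = 4))
  expect_error(gen_morphometry(species = "nope"), "unknown species")
})

test_that("generator outputs satisfy downstream type invariants end-to-end", {
  sp <- gen_eyeshine_spectra(seed = 10, noise_sd = 0.05)
  ds <- gen_depth_profiles(seed = 10)
  K <- attenuation_coefficients(ds)
  grid <- sp$dws$wavelength
  t_ont <- transmittance(sp$ont, sp$dws)
  t_pet <- transmittance(sp$pet, sp$dws)
  vs <- visual_system()
  # runs without error, and dL grows with the ONT/PET efficiency ratio
  dl <- vapply(c(2, 4, 8), function(ratio) {
    s <- gen_eyeshine_spectra(seed = 10, ont_efficiency = 0.005 * ratio,
                              pet_efficiency = 0.005, noise_sd = 0)
    eyeshine_contrast_at_depth(ds$curves[[1L]], K, 5,
                               transmittance(s$ont, s$dws),
                               transmittance(s$pet, s$dws), vs)$delta_L
  }, 0)
  expect_true(all(diff(dl) > 0))
})
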