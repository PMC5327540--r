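# Independent oracles, kept deliberately naive.

# minimum achievable circular range over all per-angle +/-180 assignments,
# by exhaustive enumeration (2^n patterns)
brute_axial_min_range <- function(angles) {
  a <- angles %% 180
  n <- length(a)
  patterns <- expand.grid(rep(list(c(0, 180)), n))
  ranges <- apply(as.matrix(patterns), 1L, function(s) diff(range(a + s)))
  min(ranges)
}

# unweighted circular mean by direct vector summation
oracle_circular_mean <- function(angles_deg) {
  r <- angles_deg * pi / 180
  (atan2(mean(sin(r)), mean(cos(r))) * 180 / pi) %% 360
}

# per-wavelength log-linear regression for attenuation, one lm() per
# wavelength (the slow, obvious way)
oracle_attenuation <- function(series) {
  E <- vapply(series$curves, function(c) c$value,
              numeric(length(series$wavelength)))
  apply(E, 1L, function(e) {
    if (any(e <= 0)) return(NA_real_)
    -unname(coef(lm(log(e) ~ series$depths))[2L])
  })
}

# closed-form OLS on two vectors
oracle_ols <- function(x, y) {
  sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(intercept = mean(y) - sl * mean(x), slope = sl)
}

# fine-grid numeric integration of a function of wavelength
oracle_integral <- function(f, lo, hi, n = 20001L) {
  x <- seq(lo, hi, length.out = n)
  y <- f(x)
  sum((y[-1L] + y[-n]) / 2 * diff(x))
}

make_flat_curve <- function(value = 1, grid = 380:780,
                            quantity = "photon_radiance") {
  spectral_curve(grid, rep(value, length(grid)), quantity)
}
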