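# Optic-nerve torsion: linear fit of unwrapped section mean angles on
# distance from the optic disc, with significance-based zeroing, and
# per-individual / per-group summaries.

#' Fit optic-nerve torsion
#'
#' Ordinary least squares of (unwrapped) section mean angle on distance from
#' the optic disc. The intercept is the starting angle at the disc; the
#' slope is the torsion rate in degrees per mm. With three or more sections
#' each coefficient gets a two-sided t-test (df = n - 2); a coefficient not
#' significantly different from zero at level `alpha` is set to zero and
#' flagged. Total torsion is |slope| times the nerve length (the fitted
#' distance span unless supplied), and zero when the slope is zeroed.
#'
#' @param distance_mm Section distances, strictly increasing, length >= 2.
#' @param mean_deg Unwrapped mean angles (see [unwrap_means()]).
#' @param alpha Significance level for the zeroing test (default 0.05).
#' @param nerve_length Optional nerve length in mm; defaults to
#'   `diff(range(distance_mm))`.
#' @return An object of class `torsion_fit`: list with `starting_angle`,
#'   `torsion_rate`, `nerve_length`, `total_torsion`, `intercept_zeroed`,
#'   `slope_zeroed`, `p_intercept`, `p_slope`, `n`.
#' @export
fit_torsion <- function(distance_mm, mean_deg, alpha = 0.05,
                        nerve_length = NULL) {
  n <- length(distance_mm)
  if (n < 2L) stop("torsion fit needs at least 2 sections")
  if (length(mean_deg) != n) stop("distance and mean angle lengths differ")
  if (any(diff(distance_mm) <= 0)) stop("distances must be strictly increasing")
  if (anyNA(mean_deg)) stop("mean angles contain NA (undefined section means)")
  fit <- stats::lm(mean_deg ~ distance_mm)
  coefs <- stats::coef(fit)
  intercept <- unname(coefs[1L]); slope <- unname(coefs[2L])
  p_int <- NA_real_; p_slo <- NA_real_
  int_zeroed <- FALSE; slo_zeroed <- FALSE
  if (n >= 3L) {
    # coefficient t-tests computed directly (summary.lm warns on the
    # noiseless fits the synthetic round-trips produce)
    df <- n - 2L
    sigma2 <- sum(stats::residuals(fit)^2) / df
    sxx <- sum((distance_mm - mean(distance_mm))^2)
    coef_p <- function(est, se) {
      if (sigma2 <= .Machine$double.eps * max(1, mean(mean_deg)^2)) {
        # zero residual variance: any nonzero estimate is unambiguous
        return(if (abs(est) < 1e-10) 1 else 0)
      }
      2 * stats::pt(-abs(est / se), df)
    }
    p_int <- coef_p(intercept,
                    sqrt(sigma2 * (1 / n + mean(distance_mm)^2 / sxx)))
    p_slo <- coef_p(slope, sqrt(sigma2 / sxx))
    if (p_int >= alpha) { intercept <- 0; int_zeroed <- TRUE }
    if (p_slo >= alpha) { slope <- 0; slo_zeroed <- TRUE }
  }
  len <- if (is.null(nerve_length)) diff(range(distance_mm)) else nerve_length
  if (len <= 0) stop("nerve_length must be positive")
  structure(
    list(starting_angle = intercept, torsion_rate = slope,
         nerve_length = len,
         total_torsion = if (slo_zeroed) 0 else abs(slope) * len,
         intercept_zeroed = int_zeroed, slope_zeroed = slo_zeroed,
         p_intercept = p_int, p_slope = p_slo, n = n),
    class = "torsion_fit"
  )
}

#' @export
print.torsion_fit <- function(x, ...) {
  cat("<torsion_fit> n =", x$n, "sections\n")
  cat(sprintf("  starting angle: %.1f deg%s\n", x$starting_angle,
              if (x$intercept_zeroed) " (zeroed, p >= alpha)" else ""))
  cat(sprintf("  torsion rate:   %.1f deg/mm%s\n", x$torsion_rate,
              if (x$slope_zeroed) " (zeroed, p >= alpha)" else ""))
  cat(sprintf("  nerve length:   %.2f mm\n", x$nerve_length))
  cat(sprintf("  total torsion:  %.1f deg\n", x$total_torsion))
  invisible(x)
}

#' Analyse one nerve from raw layer measurements
#'
#' Full per-nerve pipeline: per-section axial means, unwrapping, torsion
#' fit.
#'
#' @inheritParams section_means
#' @inheritParams fit_torsion
#' @return A `torsion_fit`.
#' @export
analyze_nerve <- function(sections, alpha = 0.05, nerve_length = NULL,
                          axial = TRUE) {
  sm <- section_means(sections, axial = axial)
  unwrapped <- unwrap_means(sm$mean_angle_deg)
  fit_torsion(sm$distance_mm, unwrapped, alpha = alpha,
              nerve_length = nerve_length)
}

#' Summarise torsion fits per group
#'
#' Arithmetic mean and sample SD (n - 1 denominator) of nerve length,
#' starting angle, torsion rate and total torsion. When `individual` is
#' given (e.g. two nerves per fish), fits are first averaged per individual,
#' then across individuals. A single contributing unit leaves the SDs `NA`.
#'
#' @param fits A list of `torsion_fit` objects.
#' @param individual Optional vector of individual identifiers, one per fit.
#' @return A one-row data.frame with columns `n`, and `<field>_mean` /
#'   `<field>_sd` for `on_length`, `starting_angle`, `torsion`,
#'   `total_torsion`.
#' @export
summarize_group <- function(fits, individual = NULL) {
  if (!length(fits)) stop("fits must be nonempty")
  ok <- vapply(fits, inherits, TRUE, what = "torsion_fit")
  if (!all(ok)) stop("fits must all be torsion_fit objects")
  m <- data.frame(
    on_length = vapply(fits, `[[`, 0, "nerve_length"),
    starting_angle = vapply(fits, `[[`, 0, "starting_angle"),
    torsion = vapply(fits, function(f) abs(f$torsion_rate), 0),
    total_torsion = vapply(fits, `[[`, 0, "total_torsion")
  )
  if (!is.null(individual)) {
    if (length(individual) != nrow(m)) stop("one individual id per fit required")
    m <- stats::aggregate(m, by = list(individual = individual), FUN = mean)
    m$individual <- NULL
  }
  out <- data.frame(n = nrow(m))
  for (f in names(m)) {
    out[[paste0(f, "_mean")]] <- mean(m[[f]])
    out[[paste0(f, "_sd")]] <- if (nrow(m) > 1L) stats::sd(m[[f]]) else NA_real_
  }
  out
}
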