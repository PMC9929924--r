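#' Apparent Gibbs free energy over temperature from intact-complex intensity
#'
#' Transforms a normalised intact-complex intensity (percent of total ion
#' current, strictly between 0 and 100) into the apparent dissociation free
#' energy divided by the absolute temperature,
#' `dG#/T = -R * ln((100 - I) / I)`. The temperature itself is unknown under
#' gas-phase conditions and never materialises: all quantities are carried
#' as G/T.
#'
#' @param intensity_pct Intensity in percent, strictly inside (0, 100);
#'   vectorised. Callers must clip or exclude boundary points first.
#' @return dG#/T in J mol^-1 K^-1.
#' @export
delta_g_over_t <- function(intensity_pct) {
  if (any(intensity_pct <= 0 | intensity_pct >= 100))
    stop("intensity_pct must lie strictly inside (0, 100)")
  -.RGAS * log((100 - intensity_pct) / intensity_pct)
}

#' Dimensionless apparent gas-phase dissociation constant
#'
#' `K_D^# = exp(-dG0#/T / R)`, the exact inverse of the free-energy
#' transform evaluated at zero collision energy.
#'
#' @param dg0_over_T Intercept of the linear free-energy fit
#'   (J mol^-1 K^-1).
#' @return Dimensionless K_D^#.
#' @export
kd_gasphase <- function(dg0_over_T) {
  if (any(!is.finite(dg0_over_T))) stop("dg0_over_T must be finite")
  exp(-dg0_over_T / .RGAS)
}

#' Linear free-energy fit of dG#/T against collision energy
#'
#' Ordinary least-squares line through (E_com, dG#/T) points under the model
#' `dG#/T = dG0#/T - n * E_com`; the intercept extrapolates the apparent
#' activation free energy to zero external activation and yields the
#' dimensionless apparent dissociation constant `exp(-intercept / R)`. The
#' slope is reported as positive `n_slope` for a curve that loses free
#' energy with increasing collision energy.
#'
#' @param points data.frame with columns `e_com` (eV) and `dg_over_t`
#'   (J mol^-1 K^-1); at least two distinct energies.
#' @return An object of class `lfer_fit` with fields `dg0_over_T`,
#'   `n_slope`, `r_squared`, `points_used`, `kd_gas`.
#' @export
fit_lfer <- function(points) {
  if (length(unique(points$e_com)) < 2)
    stop("at least 2 distinct e_com points are required")
  m <- stats::lm(dg_over_t ~ e_com, data = points)
  co <- stats::coef(m)
  sst <- sum((points$dg_over_t - mean(points$dg_over_t))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(m)^2) / sst
  structure(
    list(dg0_over_T = unname(co[1]), n_slope = unname(-co[2]),
         r_squared = r2, points_used = nrow(points),
         kd_gas = kd_gasphase(unname(co[1]))),
    class = "lfer_fit"
  )
}

#' @export
print.lfer_fit <- function(x, ...) {
  cat(sprintf(
    "<lfer_fit> dG0#/T %.4g J/mol/K, n %.4g J/mol/K/eV, R^2 %.4f, K_D^# %.4g (%d points)\n",
    x$dg0_over_T, x$n_slope, x$r_squared, x$kd_gas, x$points_used))
  invisible(x)
}

#' Estimate the apparent gas-phase dissociation constant from voltage ramps
#'
#' Runs the full pipeline on each replicate ramp: extract the dissociation
#' curve, exclude intensities too close to the plateaus (where the
#' log-transform diverges), transform to dG#/T, fit the linear free-energy
#' relationship, and convert the intercept to K_D^#. Replicates are
#' summarised as mean and standard deviation.
#'
#' @param ramps List of [ramp_experiment()] replicates (or a single one).
#' @param clip_lo Exclusion margin in percent: points with intensity at or
#'   below `clip_lo` or at or above `100 - clip_lo` are dropped, not
#'   clipped.
#' @param pooled Pool all replicate points into one fit instead of fitting
#'   per replicate.
#' @param ... Passed to [extract_dissociation_curve()] (tolerances, peak
#'   sigma, gas mass).
#' @return An object of class `kd_summary` with fields `per_replicate`
#'   (K_D^# per replicate), `fits` (the per-replicate `lfer_fit`s), `mean`,
#'   `sd` (NA for a single replicate), `curves`.
#' @export
estimate_kd_from_ramps <- function(ramps, clip_lo = 0.5, pooled = FALSE, ...) {
  if (inherits(ramps, "ramp_experiment")) ramps <- list(ramps)
  if (!length(ramps)) stop("at least one ramp experiment is required")
  curves <- lapply(ramps, extract_dissociation_curve, ...)
  usable <- lapply(curves, function(cv) {
    keep <- cv$intensity_pct > clip_lo & cv$intensity_pct < 100 - clip_lo
    data.frame(e_com = cv$e_com[keep],
               dg_over_t = if (any(keep)) delta_g_over_t(cv$intensity_pct[keep])
                           else numeric(0))
  })
  if (pooled) {
    pts <- do.call(rbind, usable)
    if (nrow(pts) < 2) stop("no usable points after plateau exclusion")
    fit <- fit_lfer(pts)
    return(structure(
      list(per_replicate = fit$kd_gas, fits = list(fit),
           mean = fit$kd_gas, sd = NA_real_, curves = curves, pooled = TRUE),
      class = "kd_summary"))
  }
  fits <- list()
  for (i in seq_along(usable)) {
    if (nrow(usable[[i]]) < 2 ||
        length(unique(usable[[i]]$e_com)) < 2) {
      warning("replicate ", i, " dropped: fewer than 2 usable points",
              call. = FALSE)
      next
    }
    fits[[length(fits) + 1L]] <- fit_lfer(usable[[i]])
  }
  if (!length(fits))
    stop("no usable points in any replicate after plateau exclusion")
  kds <- vapply(fits, function(f) f$kd_gas, numeric(1))
  structure(
    list(per_replicate = kds, fits = fits, mean = mean(kds),
         sd = if (length(kds) > 1) stats::sd(kds) else NA_real_,
         curves = curves, pooled = FALSE),
    class = "kd_summary"
  )
}

#' @export
print.kd_summary <- function(x, ...) {
  cat(sprintf("<kd_summary> K_D^# = %.3g", x$mean))
  if (!is.na(x$sd)) cat(sprintf(" +/- %.3g", x$sd))
  cat(sprintf(" (n = %d)\n", length(x$per_replicate)))
  invisible(x)
}
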