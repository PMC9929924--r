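#' Abundance-weighted mean charge state
#'
#' @param abundance_by_charge Named numeric vector or mapping of charge ->
#'   area (names are the integer charges).
#' @param charge_subset Optional integer charges to include; empty means all.
#' @return Weighted mean charge (elementary charges).
#' @export
weighted_mean_charge <- function(abundance_by_charge, charge_subset = integer(0)) {
  z <- as.numeric(names(abundance_by_charge))
  a <- as.numeric(abundance_by_charge)
  if (length(charge_subset)) {
    sel <- z %in% charge_subset
    z <- z[sel]; a <- a[sel]
  }
  if (!length(a) || sum(a) <= 0)
    stop("no selected charge state with positive area")
  sum(z * a) / sum(a)
}

#' Centre-of-mass collision energy
#'
#' The fraction of laboratory-frame kinetic energy (charge times
#' acceleration voltage) available for internal activation of an ion
#' colliding with a neutral gas:
#' `E_com = z * V * m_gas / (m_gas + m_ion)` in eV.
#'
#' @param mean_charge Abundance-weighted mean charge (elementary charges).
#' @param accel_voltage Acceleration voltage (V).
#' @param complex_mass Ion mass (Da).
#' @param gas_mass Collision gas mass (Da); argon by default.
#' @return Energy in eV.
#' @export
center_of_mass_energy <- function(mean_charge, accel_voltage, complex_mass,
                                  gas_mass = ms_constants[["argon_mass"]]) {
  if (mean_charge <= 0 || complex_mass <= 0 || gas_mass <= 0)
    stop("mean_charge, complex_mass and gas_mass must be positive")
  if (accel_voltage < 0) stop("accel_voltage must be non-negative")
  mean_charge * accel_voltage * gas_mass / (gas_mass + complex_mass)
}

#' Extract a dissociation curve from a voltage ramp
#'
#' For every spectrum in the ramp, detects peaks, assigns charge series,
#' locates the series whose inferred mass matches the monitored complex
#' within `mass_rel_tol`, and records the complex intensity as percent of
#' total ion current (over `ramp$charge_subset`), the abundance-weighted
#' mean charge, and the centre-of-mass collision energy. Voltages at which
#' the complex series cannot be found are excluded with a warning.
#'
#' @param ramp A [ramp_experiment()].
#' @param mass_rel_tol Relative tolerance for matching the complex mass.
#' @param peak_sigma Expected peak sigma (Thomson); peak areas are
#'   integrated over +/- 6 sigma so that essentially the full Gaussian area
#'   is captured.
#' @param min_snr Peak detection threshold.
#' @param gas_mass Collision gas mass (Da).
#' @param z_range Candidate charges for series assignment.
#' @return An object of class `dissociation_curve` with fields `voltages`,
#'   `e_com`, `intensity_pct`, `mean_charge`, `replicate_id`,
#'   `complex_mass`, `excluded_voltages`.
#' @export
extract_dissociation_curve <- function(ramp, mass_rel_tol = 1e-3,
                                       peak_sigma = 8, min_snr = 3,
                                       gas_mass = ms_constants[["argon_mass"]],
                                       z_range = 2:40) {
  stopifnot(inherits(ramp, "ramp_experiment"))
  voltages <- c(); e_com <- c(); intensity_pct <- c(); mean_charge <- c()
  excluded <- c()
  for (i in seq_along(ramp$spectra)) {
    sp <- ramp$spectra[[i]]
    v <- ramp$voltages[i]
    res <- tryCatch({
      peaks <- detect_peaks(sp, min_snr = min_snr, window_mz = 2 * peak_sigma)
      series <- assign_charge_series(peaks, z_range = z_range,
                                     mass_rel_tol = mass_rel_tol)
      hit <- NULL
      for (s in series) {
        if (abs(s$mass - ramp$complex_mass) <= mass_rel_tol * ramp$complex_mass &&
            all(ramp$charge_subset %in% s$charges)) { hit <- s; break }
      }
      if (is.null(hit)) stop("complex series not found")
      frac <- quantify_species(sp, hit, ramp$charge_subset)
      sel <- hit$charges %in% ramp$charge_subset
      zbar <- weighted_mean_charge(
        stats::setNames(hit$peaks$area[sel], hit$charges[sel]))
      list(pct = 100 * frac, zbar = zbar,
           ecom = center_of_mass_energy(zbar, v, ramp$complex_mass, gas_mass))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("voltage %g V excluded: %s", v, conditionMessage(res)),
              call. = FALSE)
      excluded <- c(excluded, v)
    } else {
      voltages <- c(voltages, v)
      e_com <- c(e_com, res$ecom)
      intensity_pct <- c(intensity_pct, res$pct)
      mean_charge <- c(mean_charge, res$zbar)
    }
  }
  structure(
    list(voltages = voltages, e_com = e_com, intensity_pct = intensity_pct,
         mean_charge = mean_charge, replicate_id = ramp$replicate_id,
         complex_mass = ramp$complex_mass, excluded_voltages = excluded),
    class = "dissociation_curve"
  )
}

#' @export
print.dissociation_curve <- function(x, ...) {
  cat(sprintf("<dissociation_curve> %d points, E_com %.3f-%.3f eV, I %.1f-%.1f%%\n",
              length(x$e_com), min(x$e_com), max(x$e_com),
              min(x$intensity_pct), max(x$intensity_pct)))
  invisible(x)
}

# Decreasing Boltzmann sigmoid
.boltz <- function(par, E) {
  par[["bottom"]] + (par[["top"]] - par[["bottom"]]) /
    (1 + exp((E - par[["e50"]]) / par[["width"]]))
}

# Levenberg-Marquardt fit of the sigmoid with optional fixed parameters.
.boltz_lm <- function(E, I, start, fixed = list(), pin_bottom = FALSE) {
  if (pin_bottom) fixed$bottom <- 0
  free <- setdiff(c("top", "bottom", "e50", "width"), names(fixed))
  lower <- c(top = -Inf, bottom = 0, e50 = -Inf, width = 1e-9)[free]
  resid_fn <- function(p) {
    par <- c(as.list(p), fixed)
    I - .boltz(par, E)
  }
  out <- minpack.lm::nls.lm(par = unlist(start[free]), fn = resid_fn,
                            lower = lower,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  par <- c(as.list(stats::coef(out)), fixed)
  list(par = par[c("top", "bottom", "e50", "width")],
       ssr = sum(out$fvec^2), converged = out$info %in% 1:4)
}

#' Fit a Boltzmann sigmoid to dissociation data
#'
#' Least-squares fit (Levenberg-Marquardt) of the decreasing sigmoid
#' `I(E) = bottom + (top - bottom) / (1 + exp((E - e50) / width))`
#' to intact-complex percentage against centre-of-mass collision energy.
#' With `fit_to_mean = TRUE` (default) the across-replicate mean curve is
#' fitted; otherwise all replicate points are pooled. Five restarts from
#' jittered data-driven starting values guard against local minima.
#'
#' @param curves A `dissociation_curve` or list of them (replicates).
#' @param fit_to_mean Fit the replicate mean (default) rather than pooled
#'   points.
#' @param pin_bottom Fix the lower plateau at 0 instead of fitting it
#'   (bounded at >= 0).
#' @return An object of class `boltzmann_fit` with fields `top`, `bottom`,
#'   `e50`, `width`, `ssr`, `dof`, `ci_e50` (NULL until
#'   [profile_confidence_interval()] is called) and the fitted `data`.
#' @export
fit_boltzmann <- function(curves, fit_to_mean = TRUE, pin_bottom = FALSE) {
  if (inherits(curves, "dissociation_curve") ||
      (is.list(curves) && !is.null(curves$e_com))) curves <- list(curves)
  if (fit_to_mean && length(curves) > 1) {
    ns <- vapply(curves, function(c) length(c$e_com), integer(1))
    if (length(unique(ns)) != 1)
      stop("fit_to_mean requires equal-length replicate curves")
    E <- rowMeans(sapply(curves, function(c) c$e_com))
    I <- rowMeans(sapply(curves, function(c) c$intensity_pct))
  } else {
    E <- unlist(lapply(curves, function(c) c$e_com))
    I <- unlist(lapply(curves, function(c) c$intensity_pct))
  }
  o <- order(E); E <- E[o]; I <- I[o]
  if (length(unique(E)) < 5)
    stop("at least 5 distinct E_com points are required")
  if (diff(range(I)) < 1e-6 * max(abs(I), 1))
    stop("no transition in range: data are flat")
  start <- list(top = max(I), bottom = min(I),
                e50 = E[which.min(abs(I - (max(I) + min(I)) / 2))],
                width = diff(range(E)) / 10)
  best <- NULL
  for (r in 0:4) {
    s <- start
    if (r > 0) {
      s$e50 <- start$e50 + (r - 2.5) * diff(range(E)) / 8
      s$width <- start$width * 2^(r - 2)
    }
    fit <- tryCatch(.boltz_lm(E, I, s, pin_bottom = pin_bottom),
                    error = function(e) NULL)
    if (!is.null(fit) && fit$converged &&
        (is.null(best) || fit$ssr < best$ssr)) best <- fit
  }
  if (is.null(best))
    stop("Boltzmann fit failed to converge after restarts")
  n_free <- if (pin_bottom) 3 else 4
  structure(
    c(best$par,
      list(ssr = best$ssr, dof = length(E) - n_free, ci_e50 = NULL,
           pin_bottom = pin_bottom,
           data = data.frame(e_com = E, intensity_pct = I))),
    class = "boltzmann_fit"
  )
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf(
    "<boltzmann_fit> e50 %.4g eV, width %.4g eV, top %.4g%%, bottom %.4g%%, ssr %.4g (dof %d)\n",
    x$e50, x$width, x$top, x$bottom, x$ssr, x$dof))
  if (!is.null(x$ci_e50))
    cat(sprintf("  e50 CI [%.4g, %.4g]\n", x$ci_e50[1], x$ci_e50[2]))
  invisible(x)
}

#' Profile confidence interval for a sigmoid-fit parameter
#'
#' The chosen parameter is fixed on a sequence of values while the remaining
#' parameters are refitted; the interval contains all values whose residual
#' sum of squares stays below `SSR_min * (1 + qf(p, 1, dof) / dof)`, the
#' standard F-statistic threshold for a single profiled parameter in
#' nonlinear regression. Bounds are refined by bisection to 1e-4 relative.
#'
#' @param fit A `boltzmann_fit`.
#' @param data Fitted points (data.frame `e_com`, `intensity_pct`); taken
#'   from the fit by default.
#' @param param One of "e50", "width", "top", "bottom".
#' @param p Confidence level in (0, 1); 0.68 corresponds to one standard
#'   deviation.
#' @param max_expand Search range in units of the initial step (the bound is
#'   flagged open beyond it).
#' @return Numeric length-2 interval, with attribute `open` marking
#'   unbounded sides.
#' @export
profile_confidence_interval <- function(fit, data = fit$data, param = "e50",
                                        p = 0.68, max_expand = 200) {
  stopifnot(inherits(fit, "boltzmann_fit"), p > 0, p < 1)
  if (!param %in% c("top", "bottom", "e50", "width"))
    stop("unknown parameter: ", param)
  E <- data$e_com; I <- data$intensity_pct
  if (fit$dof < 1) stop("no residual degrees of freedom for profiling")
  threshold <- fit$ssr * (1 + stats::qf(p, 1, fit$dof) / fit$dof)
  start <- fit[c("top", "bottom", "e50", "width")]
  prof_ssr <- function(value) {
    fx <- stats::setNames(list(value), param)
    f <- tryCatch(.boltz_lm(E, I, start, fixed = fx,
                            pin_bottom = fit$pin_bottom),
                  error = function(e) NULL)
    if (is.null(f)) Inf else f$ssr
  }
  centre <- fit[[param]]
  step0 <- max(abs(centre), fit$width, 1e-8) * 0.02
  open <- c(FALSE, FALSE)
  bounds <- numeric(2)
  for (side in 1:2) {
    dir <- if (side == 1) -1 else 1
    lo <- centre; hi <- NA
    step <- step0
    for (k in seq_len(max_expand)) {
      cand <- centre + dir * step
      if (param %in% c("width") && cand <= 0) { cand <- 1e-12 }
      if (prof_ssr(cand) > threshold) { hi <- cand; break }
      lo <- cand
      step <- step * 1.5
      if (param == "width" && cand <= 1e-12) break
    }
    if (is.na(hi)) {
      open[side] <- TRUE
      bounds[side] <- centre + dir * step
      next
    }
    # bisection between last inside point and first outside point
    for (k in 1:60) {
      mid <- (lo + hi) / 2
      if (prof_ssr(mid) > threshold) hi <- mid else lo <- mid
      if (abs(hi - lo) <= 1e-4 * max(abs(centre), abs(hi), 1e-12)) break
    }
    bounds[side] <- (lo + hi) / 2
  }
  interval <- sort(bounds)
  attr(interval, "open") <- open
  interval
}
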