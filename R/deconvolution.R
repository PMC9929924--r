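# Trapezoidal integral of y over x
.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' Detect peaks in a spectrum
#'
#' Finds local intensity maxima above a robust baseline-plus-noise threshold
#' (median plus `min_snr` times the MAD of the intensities), refines each
#' apex position by log-parabolic interpolation (exact for Gaussian peaks),
#' and integrates a trapezoidal area over +/- 3 `window_mz` around the apex.
#' Maxima closer than 3 `window_mz` to a stronger accepted apex are treated
#' as shoulders of that peak and dropped.
#'
#' @param spectrum A [mass_spectrum()].
#' @param min_snr Signal-to-noise threshold (> 0).
#' @param window_mz Expected peak sigma (Thomson); the integration window is
#'   +/- 3 times this value.
#' @return A data.frame with columns `mz`, `area`, `apex_intensity`, sorted
#'   by m/z. Zero rows when nothing exceeds the threshold.
#' @export
detect_peaks <- function(spectrum, min_snr = 3, window_mz = 8) {
  stopifnot(inherits(spectrum, "mass_spectrum"))
  if (min_snr <= 0) stop("min_snr must be positive")
  if (!length(spectrum$mz)) stop("spectrum is empty")
  mz <- spectrum$mz; y <- spectrum$intensity
  n <- length(y)
  empty <- data.frame(mz = numeric(0), area = numeric(0),
                      apex_intensity = numeric(0))
  if (n < 3) return(empty)
  baseline <- stats::median(y)
  noise <- stats::mad(y)
  thr <- baseline + min_snr * max(noise, 1e-12 * max(y, 1e-300))
  apex <- which(y[-c(1, n)] > y[-c(n - 1, n)] & y[-c(1, n)] >= y[-(1:2)]) + 1
  apex <- apex[y[apex] > thr]
  if (!length(apex)) return(empty)
  # strongest-first suppression of shoulders within the integration window
  apex <- apex[order(-y[apex])]
  keep <- integer(0)
  for (i in apex) {
    if (!length(keep) || all(abs(mz[i] - mz[keep]) > 3 * window_mz))
      keep <- c(keep, i)
  }
  res <- lapply(keep, function(i) {
    centre <- mz[i]
    if (i > 1 && i < n && y[i - 1] > 0 && y[i + 1] > 0 && y[i] > 0) {
      a <- log(y[i - 1]); b <- log(y[i]); c <- log(y[i + 1])
      den <- a - 2 * b + c
      if (den < 0) {
        p <- 0.5 * (a - c) / den
        if (abs(p) <= 1) centre <- mz[i] + p * (mz[i + 1] - mz[i])
      }
    }
    sel <- which(abs(mz - centre) <= 3 * window_mz)
    data.frame(mz = centre, area = .trapz(mz[sel], y[sel]),
               apex_intensity = y[i])
  })
  out <- do.call(rbind, res)
  out[order(out$mz), , drop = FALSE]
}

#' Assign charge-state series to detected peaks
#'
#' Greedy search over candidate charges: each peak at m/z under hypothesis z
#' implies a neutral mass `M = z * (mz - 1.00728)`; peaks whose hypothesis
#' masses at consecutive charges agree within `mass_rel_tol` are grouped
#' into a series. A series is emitted only when at least three consecutive
#' charge states agree (two-peak series are ambiguous); each peak belongs to
#' at most one series, strongest series claimed first; ties between charge
#' hypotheses are broken by the smaller relative mass spread.
#'
#' @param peaks data.frame from [detect_peaks()].
#' @param z_range Integer candidate charges, within 1..100.
#' @param mass_rel_tol Relative mass agreement tolerance (default 1e-3,
#'   matching kDa-level mass reporting).
#' @return A list of `charge_series` objects (fields `charges`, `peaks`,
#'   `mass`, `mass_sd`, `summed_area`), sorted by descending summed area;
#'   empty list when no series is found.
#' @export
assign_charge_series <- function(peaks, z_range = 10:40, mass_rel_tol = 1e-3) {
  z_range <- as.integer(z_range)
  if (any(z_range < 1L | z_range > 100L)) stop("z_range must lie in [1, 100]")
  if (mass_rel_tol <= 0) stop("mass_rel_tol must be positive")
  if (!nrow(peaks)) return(list())
  avail <- rep(TRUE, nrow(peaks))
  series_list <- list()

  candidate_for <- function(anchor, z0) {
    M0 <- z0 * (peaks$mz[anchor] - .PROTON)
    idx <- c(anchor); zs <- c(z0)
    for (dir in c(1L, -1L)) {
      z <- z0 + dir
      repeat {
        if (z < min(z_range) || z > max(z_range) || z < 1L) break
        pred <- M0 / z + .PROTON
        cand <- which(avail & abs(peaks$mz * z - z * .PROTON - M0) <= mass_rel_tol * M0)
        cand <- setdiff(cand, idx)
        if (!length(cand)) break
        best <- cand[which.min(abs(peaks$mz[cand] - pred))]
        idx <- c(idx, best); zs <- c(zs, z)
        z <- z + dir
      }
    }
    o <- order(zs)
    list(idx = idx[o], charges = zs[o])
  }

  repeat {
    open <- which(avail)
    if (!length(open)) break
    best <- NULL
    for (anchor in open[order(-peaks$area[open])]) {
      for (z0 in z_range) {
        cand <- candidate_for(anchor, z0)
        if (length(cand$idx) < 3) next
        masses <- cand$charges * (peaks$mz[cand$idx] - .PROTON)
        spread <- stats::sd(masses) / mean(masses)
        score_area <- sum(peaks$area[cand$idx])
        if (is.null(best) ||
            length(cand$idx) > length(best$idx) ||
            (length(cand$idx) == length(best$idx) && spread < best$spread)) {
          best <- c(cand, list(spread = spread, score_area = score_area))
        }
      }
      if (!is.null(best)) break  # strongest unclaimed peak anchored a series
    }
    if (is.null(best)) break
    masses <- best$charges * (peaks$mz[best$idx] - .PROTON)
    w <- peaks$area[best$idx]
    series_list[[length(series_list) + 1L]] <- structure(
      list(charges = best$charges,
           peaks = peaks[best$idx, , drop = FALSE],
           mass = sum(w * masses) / sum(w),
           mass_sd = if (length(masses) > 1) stats::sd(masses) else 0,
           summed_area = sum(w)),
      class = "charge_series")
    avail[best$idx] <- FALSE
  }
  if (!length(series_list)) return(list())
  series_list[order(-vapply(series_list, function(s) s$summed_area, numeric(1)))]
}

#' @export
print.charge_series <- function(x, ...) {
  cat(sprintf("<charge_series> mass %.1f Da (sd %.1f), charges %s, area %.4g\n",
              x$mass, x$mass_sd, paste(range(x$charges), collapse = "-"),
              x$summed_area))
  invisible(x)
}

#' Collapse charge series onto a zero-charge mass spectrum
#'
#' Each series contributes its summed peak area as a Gaussian centred at its
#' inferred neutral mass, with width equal to the spread of its per-peak mass
#' estimates (at least one grid step), on a uniform mass grid.
#'
#' @param spectrum The source [mass_spectrum()] (used only for provenance).
#' @param series List of `charge_series` from [assign_charge_series()].
#' @param mass_grid_step Grid spacing in Da.
#' @param mass_range Optional length-2 mass window; derived from the series
#'   when omitted.
#' @return A data.frame with columns `mass`, `intensity`.
#' @export
zero_charge_spectrum <- function(spectrum, series, mass_grid_step = 10,
                                 mass_range = NULL) {
  if (is.null(mass_range)) {
    if (!length(series)) {
      mass_range <- c(1e4, 3e5)
    } else {
      m <- vapply(series, function(s) s$mass, numeric(1))
      pad <- max(50 * mass_grid_step, 0.01 * max(m))
      mass_range <- c(max(0, min(m) - pad), max(m) + pad)
    }
  }
  grid <- seq(mass_range[1], mass_range[2], by = mass_grid_step)
  intensity <- rep(0, length(grid))
  for (s in series) {
    sdv <- max(s$mass_sd, mass_grid_step)
    intensity <- intensity + s$summed_area * stats::dnorm(grid, s$mass, sdv)
  }
  data.frame(mass = grid, intensity = intensity)
}

#' Quantify a species as a fraction of total ion current
#'
#' Sums the areas of the series peaks at the selected charge states and
#' divides by the total ion current of the spectrum (trapezoidal integral of
#' all intensity).
#'
#' @param spectrum The [mass_spectrum()] the series was detected in.
#' @param series A `charge_series`.
#' @param charge_subset Integer charges to include; empty means all charges
#'   of the series. Must be a subset of `series$charges`.
#' @return Abundance fraction in [0, 1].
#' @export
quantify_species <- function(spectrum, series, charge_subset = integer(0)) {
  stopifnot(inherits(spectrum, "mass_spectrum"),
            inherits(series, "charge_series"))
  tic <- .trapz(spectrum$mz, spectrum$intensity)
  if (tic <= 0) stop("zero total ion current")
  if (!length(charge_subset)) {
    sel <- seq_along(series$charges)
  } else {
    if (!all(charge_subset %in% series$charges))
      stop("charge_subset must be a subset of the series charges")
    sel <- which(series$charges %in% charge_subset)
  }
  min(sum(series$peaks$area[sel]) / tic, 1)
}

#' Assign stoichiometry by mass additivity
#'
#' Enumerates receptor:cargo compositions (i, j) with `0 <= i, j <=
#' max_units`, `i + j >= 1`, and keeps those whose additive mass
#' `i * receptor_mass + j * cargo_mass` matches the observed mass within
#' `mass_rel_tol * mass`, ranked by absolute mass error.
#'
#' @param mass Observed neutral mass (Da).
#' @param receptor_mass,cargo_mass Monomer masses (Da).
#' @param max_units Maximum subunit count per component (default 6, covering
#'   the low-abundance tetramers and hexamers seen for the cargo alone).
#' @param mass_rel_tol Relative mass tolerance (default 1e-3).
#' @return data.frame with columns `stoich_receptor`, `stoich_cargo`,
#'   `mass_error` (Da), sorted by `mass_error`; zero rows if nothing matches.
#' @export
assign_stoichiometry <- function(mass, receptor_mass, cargo_mass,
                                 max_units = 6, mass_rel_tol = 1e-3) {
  if (mass <= 0 || receptor_mass <= 0 || cargo_mass <= 0)
    stop("masses must be positive")
  if (max_units < 1) stop("max_units must be >= 1")
  grid <- expand.grid(stoich_receptor = 0:max_units, stoich_cargo = 0:max_units)
  grid <- grid[grid$stoich_receptor + grid$stoich_cargo >= 1, ]
  grid$mass_error <- abs(mass - (grid$stoich_receptor * receptor_mass +
                                   grid$stoich_cargo * cargo_mass))
  grid <- grid[grid$mass_error <= mass_rel_tol * mass, , drop = FALSE]
  grid <- grid[order(grid$mass_error), , drop = FALSE]
  rownames(grid) <- NULL
  grid
}

#' Mass of a sequence variant or modified protein
#'
#' Adds the average-mass differences of residue substitutions and covalent
#' modifications to a base mass. Average (not monoisotopic) residue masses
#' are used, as appropriate for intact-protein native MS.
#'
#' @param base_mass Base protein mass (Da).
#' @param substitutions List of substitutions, each `c(from, to, count)`
#'   using one-letter residue codes, e.g. `list(c("S", "D", 2))` for two
#'   serine-to-aspartate (phosphomimetic) exchanges.
#' @param modifications List of modifications, each `c(name, count)`;
#'   supported names include `"phosphorylation"` (+79.9663 Da).
#' @return Variant mass in Da.
#' @export
variant_mass <- function(base_mass, substitutions = list(),
                         modifications = list()) {
  if (base_mass <= 0) stop("base_mass must be positive")
  delta <- 0
  for (s in substitutions) {
    from <- as.character(s[[1]]); to <- as.character(s[[2]])
    count <- as.numeric(s[[3]])
    for (res in c(from, to))
      if (!res %in% names(.RESIDUE_AVG))
        stop("unknown residue: ", res)
    delta <- delta + count * (.RESIDUE_AVG[[to]] - .RESIDUE_AVG[[from]])
  }
  for (m in modifications) {
    name <- tolower(as.character(m[[1]])); count <- as.numeric(m[[2]])
    if (!name %in% names(.MOD_MASS))
      stop("unknown modification: ", name)
    delta <- delta + count * .MOD_MASS[[name]]
  }
  base_mass + delta
}
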