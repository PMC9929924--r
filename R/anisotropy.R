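# One-site binding curve; with depletion = TRUE the bound fraction comes
# from the exact quadratic solution for probe at concentration P.
.one_site <- function(par, conc, probe = 0, depletion = FALSE) {
  kd <- par[["kd"]]; af <- par[["a_free"]]; ab <- par[["a_bound"]]
  if (depletion && probe > 0) {
    s <- conc + probe + kd
    fb <- (s - sqrt(pmax(s^2 - 4 * conc * probe, 0))) / (2 * probe)
  } else {
    fb <- conc / (kd + conc)
  }
  af + (ab - af) * fb
}

# Levenberg-Marquardt fit over raw (concentration, anisotropy) points with
# restarts over the kd starting value.
.fit_one_site_points <- function(cc, aa, probe, depletion) {
  o <- order(cc)
  mean_a <- tapply(aa, cc, mean)
  uc <- as.numeric(names(mean_a))
  start <- c(kd = uc[which.min(abs(mean_a - (min(mean_a) + max(mean_a)) / 2))],
             a_free = unname(mean_a[1]), a_bound = unname(mean_a[length(mean_a)]))
  best <- NULL
  for (r in 0:4) {
    s <- start
    if (r > 0) s[["kd"]] <- start[["kd"]] * 4^(r - 2)
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = s,
        fn = function(p) aa - .one_site(as.list(p), cc, probe = probe,
                                        depletion = depletion),
        lower = c(kd = 1e-300, a_free = -Inf, a_bound = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (!is.null(fit) && fit$info %in% 1:4) {
      ssr <- sum(fit$fvec^2)
      if (is.null(best) || ssr < best$ssr)
        best <- list(par = stats::coef(fit), ssr = ssr)
    }
  }
  if (is.null(best))
    stop("one-site fit failed to converge after restarts")
  kd <- unname(best$par[["kd"]])
  structure(
    list(kd = kd, a_free = unname(best$par[["a_free"]]),
         a_bound = unname(best$par[["a_bound"]]),
         ssr = best$ssr, dof = length(aa) - 3,
         unsaturated = kd > max(cc) / 2,
         kd_sd = NA_real_, n_experiments = 1L,
         probe_conc = probe, depletion = depletion,
         data = data.frame(concentration = cc, anisotropy = aa)),
    class = "binding_fit"
  )
}

#' Fit a one-site binding-saturation model to an anisotropy titration
#'
#' Unweighted least-squares fit (Levenberg-Marquardt) of
#' `A(c) = a_free + (a_bound - a_free) * c / (kd + c)` to all replicate
#' points. When the fitted K_D exceeds half the highest titrated
#' concentration, saturation was not approached within the series and the
#' fit is flagged `unsaturated`; the number is still returned but should be
#' read as a lower-confidence estimate.
#'
#' @param titration An [anisotropy_titration()].
#' @param depletion Use the exact quadratic bound-fraction expression that
#'   accounts for probe depletion (relevant when the probe concentration is
#'   comparable to K_D); off by default to match the plain saturation model.
#' @return An object of class `binding_fit` with fields `kd`, `a_free`,
#'   `a_bound`, `ssr`, `dof`, `unsaturated`, `kd_sd` (NA for a single
#'   experiment) and the fitted `data`.
#' @export
fit_one_site <- function(titration, depletion = FALSE) {
  stopifnot(inherits(titration, "anisotropy_titration"))
  conc <- titration$concentrations
  if (length(conc) < 5) stop("at least 5 distinct concentrations are required")
  if (max(conc) / min(conc) < 10)
    stop("concentrations must span at least one decade")
  nrep <- ncol(titration$anisotropy)
  .fit_one_site_points(rep(conc, nrep), as.vector(titration$anisotropy),
                       probe = titration$probe_conc, depletion = depletion)
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit> K_D = %.4g M", x$kd))
  if (!is.na(x$kd_sd)) cat(sprintf(" +/- %.3g", x$kd_sd))
  cat(sprintf(", a_free %.4g, a_bound %.4g, ssr %.3g", x$a_free, x$a_bound,
              x$ssr))
  if (isTRUE(x$unsaturated)) cat("  [unsaturated]")
  cat("\n")
  invisible(x)
}

#' Summarise independent binding experiments
#'
#' Reports the mean and standard deviation of K_D across independent
#' experiment fits; the remaining curve parameters come from a refit that
#' pools all data points.
#'
#' @param fits List of `binding_fit` objects (at least one).
#' @return A `binding_fit` whose `kd` is the across-experiment mean,
#'   `kd_sd` the standard deviation (NA for a single experiment), and whose
#'   other fields come from the pooled refit.
#' @export
summarize_experiments <- function(fits) {
  if (inherits(fits, "binding_fit")) fits <- list(fits)
  if (!length(fits)) stop("at least one fit is required")
  kds <- vapply(fits, function(f) f$kd, numeric(1))
  pooled_data <- do.call(rbind, lapply(fits, function(f) f$data))
  pooled <- .fit_one_site_points(pooled_data$concentration,
                                 pooled_data$anisotropy,
                                 probe = fits[[1]]$probe_conc,
                                 depletion = fits[[1]]$depletion)
  pooled$kd <- mean(kds)
  pooled$kd_sd <- if (length(kds) > 1) stats::sd(kds) else NA_real_
  pooled$n_experiments <- length(kds)
  pooled$unsaturated <- any(vapply(fits, function(f) isTRUE(f$unsaturated),
                                   logical(1)))
  pooled
}

#' Fold change between two binding fits
#'
#' Ratio of dissociation constants `kd_b / kd_a` (how much weaker B binds
#' than A), with first-order error propagation of the per-fit standard
#' deviations when available.
#'
#' @param fit_a,fit_b `binding_fit` objects, or bare positive K_D numbers
#'   (same units for both).
#' @return A list with `ratio` and `sd` (NA when either input carries no
#'   dispersion estimate).
#' @export
fold_change <- function(fit_a, fit_b) {
  get_kd <- function(f) {
    if (is.list(f) && !is.null(f$kd))
      c(f$kd, if (is.null(f$kd_sd)) NA_real_ else f$kd_sd)
    else c(as.numeric(f), NA_real_)
  }
  a <- get_kd(fit_a); b <- get_kd(fit_b)
  if (a[1] <= 0 || b[1] <= 0) stop("dissociation constants must be positive")
  ratio <- b[1] / a[1]
  sd <- if (is.na(a[2]) || is.na(b[2])) NA_real_
        else ratio * sqrt((a[2] / a[1])^2 + (b[2] / b[1])^2)
  list(ratio = ratio, sd = sd)
}
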