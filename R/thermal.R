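#' CD melting curve
#'
#' @param temperatures Temperatures in kelvin, strictly increasing,
#'   >= 20 points.
#' @param signal CD signal at a fixed wavelength.
#' @param wavelength Monitoring wavelength, nm (metadata).
#' @param ligand Optional ligand label (e.g. "ubiquitin").
#' @return A `melt_curve` object.
#' @export
melt_curve <- function(temperatures, signal, wavelength = 215, ligand = NULL) {
  temperatures <- as.numeric(temperatures); signal <- as.numeric(signal)
  stopifnot(length(temperatures) == length(signal))
  if (length(temperatures) < 20L) stop("need at least 20 temperature points")
  if (any(diff(temperatures) <= 0)) stop("temperatures must be strictly increasing")
  structure(list(temperatures = temperatures, signal = signal,
                 wavelength = wavelength, ligand = ligand),
            class = "melt_curve")
}

#' Gibbs-Helmholtz unfolding free energy
#'
#' `dG(T) = dH_m (1 - T/Tm) - dCp ((Tm - T) + T ln(T/Tm))`, the free energy
#' of unfolding at temperature `T` given the van't Hoff enthalpy at the
#' midpoint `Tm` and a temperature-independent heat-capacity change.
#' `dG(Tm) = 0` by construction.
#'
#' @param dh_m Unfolding enthalpy at Tm, kcal/mol.
#' @param tm Melting temperature, K (> 0).
#' @param dcp Heat-capacity change of unfolding, kcal/mol/K.
#' @param temperature Temperature(s) of evaluation, K.
#' @return dG in kcal/mol.
#' @examples
#' gibbs_helmholtz(100, 330, 1.5, 298)
#' @export
gibbs_helmholtz <- function(dh_m, tm, dcp, temperature) {
  stopifnot(tm > 0, all(temperature > 0))
  dh_m * (1 - temperature / tm) -
    dcp * ((tm - temperature) + temperature * log(temperature / tm))
}

melt_profiled_rss <- function(par, tk, y, dcp) {
  tm <- par[1L]; dh <- par[2L]
  if (tm <= 0 || dh <= 0) return(1e300)
  r_kcal <- 1.9872e-3
  dg <- gibbs_helmholtz(dh, tm, dcp, tk)
  fn <- stats::plogis(dg / (r_kcal * tk))  # fraction folded
  x <- cbind(fn, tk * fn, 1 - fn, tk * (1 - fn))
  fit <- try(stats::lm.fit(x, y), silent = TRUE)
  if (inherits(fit, "try-error")) return(1e300)
  sum(fit$residuals^2)
}

#' Two-state fit of a thermal denaturation curve
#'
#' Fits the CD melt to a two-state model with Gibbs-Helmholtz temperature
#' dependence and linear native/denatured baselines (solved by variable
#' projection). The curve is normalised to fraction folded internally from
#' the fitted baselines. `dCp` is held fixed by default — a melt over a
#' ~55 K span does not constrain it — and can be fitted on request.
#'
#' @param curve A [melt_curve()] object.
#' @param dcp Heat-capacity change of unfolding, kcal/mol/K, held fixed
#'   (default 0).
#' @param fit_dcp If `TRUE`, `dcp` is fitted as a third parameter.
#' @return Object of class `thermal_fit`: `tm` (K), `dh_m` (kcal/mol),
#'   `dcp`, `baselines`, standard errors `se`, `fraction_folded`, `rss`.
#' @export
fit_thermal_two_state <- function(curve, dcp = 0, fit_dcp = FALSE) {
  stopifnot(inherits(curve, "melt_curve"))
  tk <- curve$temperatures; y <- curve$signal
  # midpoint guess at steepest change of the smoothed signal
  dy <- abs(diff(y) / diff(tk))
  tm0 <- mean(tk[which.max(dy) + 0:1])
  obj <- if (fit_dcp) {
    function(p) melt_profiled_rss(p[1:2], tk, y, p[3L])
  } else {
    function(p) melt_profiled_rss(p, tk, y, dcp)
  }
  best <- NULL
  for (dh0 in c(50, 100, 150)) {
    p0 <- c(tm0, dh0); if (fit_dcp) p0 <- c(p0, 1)
    opt <- stats::optim(p0, obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 5000))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  best <- stats::optim(best$par, obj, method = "BFGS",
                       control = list(reltol = 1e-14, maxit = 1000))
  tm <- best$par[1L]; dh <- best$par[2L]
  dcp_hat <- if (fit_dcp) best$par[3L] else dcp
  if (tm <= min(tk) || tm >= max(tk)) {
    stop(sprintf("no transition in the scanned range: fitted Tm = %.1f K outside [%.1f, %.1f]",
                 tm, min(tk), max(tk)))
  }
  r_kcal <- 1.9872e-3
  dg <- gibbs_helmholtz(dh, tm, dcp_hat, tk)
  fn <- stats::plogis(dg / (r_kcal * tk))
  x <- cbind(n_int = fn, n_slope = tk * fn, d_int = 1 - fn, d_slope = tk * (1 - fn))
  bl <- stats::lm.fit(x, y)
  rss <- sum(bl$residuals^2)
  # flat-transition guard: the native and denatured branches must differ
  amp <- abs((bl$coefficients[1L] + bl$coefficients[2L] * tm) -
               (bl$coefficients[3L] + bl$coefficients[4L] * tm))
  if (amp < 5 * sqrt(rss / length(y)) ) {
    stop("no resolvable transition: baseline-only curve")
  }
  # standard errors from the full-parameter Jacobian
  resid_fun <- function(p) {
    dgp <- gibbs_helmholtz(p[2L], p[1L], dcp_hat, tk)
    fnp <- stats::plogis(dgp / (r_kcal * tk))
    xp <- cbind(fnp, tk * fnp, 1 - fnp, tk * (1 - fnp))
    stats::lm.fit(xp, y)$residuals
  }
  jac <- numeric_jacobian(resid_fun, c(tm, dh))
  dof <- length(y) - 6L
  cov <- try(solve(crossprod(jac)) * rss / max(dof, 1L), silent = TRUE)
  se <- if (inherits(cov, "try-error")) c(tm = NA_real_, dh_m = NA_real_) else
    c(tm = sqrt(cov[1L, 1L]), dh_m = sqrt(cov[2L, 2L]))
  structure(
    list(tm = tm, dh_m = dh, dcp = dcp_hat,
         ds_m = dh / tm,
         baselines = stats::setNames(bl$coefficients,
                                     c("n_int", "n_slope", "d_int", "d_slope")),
         se = se, fraction_folded = fn, rss = rss,
         temperatures = tk, ligand = curve$ligand),
    class = "thermal_fit"
  )
}

#' @export
print.thermal_fit <- function(x, ...) {
  cat(sprintf("<thermal_fit>%s\n",
              if (!is.null(x$ligand)) paste0(" + ", x$ligand) else ""))
  cat(sprintf("  Tm   = %.2f +/- %.2f K (%.2f C)\n", x$tm, x$se["tm"], x$tm - 273.15))
  cat(sprintf("  dH_m = %.1f +/- %.1f kcal/mol (van't Hoff), dS_m = %.3f kcal/mol/K\n",
              x$dh_m, x$se["dh_m"], x$ds_m))
  cat(sprintf("  dCp  = %.2f kcal/mol/K (%s)\n", x$dcp, "fixed unless fit_dcp"))
  invisible(x)
}

#' Ligand-induced melting-temperature shift
#'
#' Fits both melts and returns `Tm(ligand) - Tm(apo)` with the propagated
#' standard error.
#'
#' @param curve_apo,curve_ligand [melt_curve()] objects (apo and
#'   ligand-bound).
#' @param ... Passed to [fit_thermal_two_state()].
#' @return List with `dtm` (K), `se`, and the two fits.
#' @export
tm_shift <- function(curve_apo, curve_ligand, ...) {
  f1 <- fit_thermal_two_state(curve_apo, ...)
  f2 <- fit_thermal_two_state(curve_ligand, ...)
  list(dtm = f2$tm - f1$tm,
       se = sqrt(f1$se[["tm"]]^2 + f2$se[["tm"]]^2),
       fit_apo = f1, fit_ligand = f2)
}
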