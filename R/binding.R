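#' ITC isotherm container
#'
#' @param cell_concentration Titrand (protein) concentration in the cell, uM.
#' @param syringe_concentration Titrant concentration in the syringe, uM.
#' @param cell_volume Active cell volume, uL.
#' @param injection_volumes Injection volumes, uL.
#' @param heats Integrated heats per injection, ucal (may be `NULL` for a
#'   geometry-only object used in simulation).
#' @param temperature Experiment temperature, K.
#' @return An `itc_isotherm` object.
#' @export
itc_isotherm <- function(cell_concentration, syringe_concentration,
                         cell_volume = 200, injection_volumes = rep(2, 19),
                         heats = NULL, temperature = 298.15) {
  stopifnot(cell_concentration > 0, syringe_concentration > 0,
            cell_volume > 0, all(injection_volumes > 0))
  if (!is.null(heats)) {
    stopifnot(length(heats) == length(injection_volumes), all(is.finite(heats)))
  }
  structure(
    list(cell_concentration = cell_concentration,
         syringe_concentration = syringe_concentration,
         cell_volume = cell_volume,
         injection_volumes = as.numeric(injection_volumes),
         heats = heats, temperature = temperature),
    class = "itc_isotherm"
  )
}

# bound-complex concentration from the closed-form one-site quadratic
one_site_bound <- function(p_tot, x_tot, kd) {
  s <- p_tot + x_tot + kd
  (s - sqrt(s^2 - 4 * p_tot * x_tot)) / 2
}

#' Expected per-injection heats of a one-site binding isotherm
#'
#' Standard total-heat difference scheme for a perfusion cell: each
#' injection first displaces an equal volume of cell content (diluting both
#' titrand and accumulated titrant by `1 - v/V0`), then the heat is
#' `q_i = dH * V0 * ([PX]_i - [PX]_{i-1} (1 - v_i/V0)) + offset`, with the
#' bound-complex concentration from the closed-form single-site quadratic at
#' each step.
#'
#' @param isotherm An [itc_isotherm()] (heats may be `NULL`).
#' @param ka Association constant, M^-1.
#' @param dh Binding enthalpy, kcal/mol.
#' @param n_sites Stoichiometry (multiplies the cell concentration).
#' @param offset_heat Constant per-injection heat offset (dilution heat),
#'   ucal.
#' @return Numeric vector of per-injection heats, ucal.
#' @export
one_site_expected_heats <- function(isotherm, ka, dh, n_sites = 1,
                                    offset_heat = 0) {
  stopifnot(inherits(isotherm, "itc_isotherm"), ka > 0)
  v0 <- isotherm$cell_volume * 1e-6          # L
  p <- n_sites * isotherm$cell_concentration * 1e-6  # binding-site molarity
  xs <- isotherm$syringe_concentration * 1e-6
  kd <- 1 / ka
  x <- 0
  px_prev <- 0
  q <- numeric(length(isotherm$injection_volumes))
  for (i in seq_along(q)) {
    v <- isotherm$injection_volumes[i] * 1e-6
    dil <- 1 - v / v0
    p <- p * dil
    x <- x * dil + xs * v / v0
    px <- one_site_bound(p, x, kd)
    q[i] <- dh * v0 * (px - px_prev * dil) * 1e9 + offset_heat  # kcal -> ucal
    px_prev <- px
  }
  q
}

#' Fit a one-site binding model to an ITC isotherm
#'
#' Least-squares fit of association constant, enthalpy and a constant
#' dilution-heat offset (stoichiometry optionally fitted). The c-value
#' `n Ka [cell]` is checked against the fittable range 0.5-1000 and the fit
#' is flagged outside it.
#'
#' @param isotherm An [itc_isotherm()] with heats.
#' @param fit_n If `TRUE` the stoichiometry is fitted too.
#' @return Object of class `one_site_fit`: `n_sites`, `ka` (M^-1), `kd_um`,
#'   `dh` (kcal/mol), `offset_heat`, `se`, `c_value`, `c_flag`, `rss`.
#' @export
fit_one_site <- function(isotherm, fit_n = FALSE) {
  stopifnot(inherits(isotherm, "itc_isotherm"), !is.null(isotherm$heats))
  q <- isotherm$heats
  if (diff(range(q)) < 1e-6 * max(abs(q), 1e-300) + 1e-300 ||
      stats::sd(q) < 1e-3 * abs(mean(q))) {
    stop("flat isotherm: Ka is unidentifiable")
  }
  dh0 <- sum(q) * 1e-9 / (isotherm$cell_volume * 1e-6 *
                            isotherm$cell_concentration * 1e-6)
  dh0 <- sign(dh0) * max(abs(dh0), 1e-3)
  resid <- function(par) {
    ka <- exp(par[1L])
    n <- if (fit_n) exp(par[4L]) else 1
    q - one_site_expected_heats(isotherm, ka, par[2L], n_sites = n,
                                offset_heat = par[3L])
  }
  best <- NULL
  for (lka in log(10^(4:8))) {
    p0 <- c(lka, dh0, 0); if (fit_n) p0 <- c(p0, 0)
    f <- try(minpack.lm::nls.lm(p0, fn = resid,
                                control = minpack.lm::nls.lm.control(
                                  maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
             silent = TRUE)
    if (inherits(f, "try-error")) next
    if (is.null(best) || sum(f$fvec^2) < sum(best$fvec^2)) best <- f
  }
  if (is.null(best)) stop("one-site fit failed to converge")
  ka <- exp(best$par[1L])
  n <- if (fit_n) exp(best$par[4L]) else 1
  rss <- sum(best$fvec^2)
  npar <- length(best$par)
  cov <- try(solve(best$hessian) * rss /
               max(length(q) - npar, 1L), silent = TRUE)
  se <- if (inherits(cov, "try-error")) {
    rep(NA_real_, 3L)
  } else {
    c(ka * sqrt(cov[1L, 1L]), sqrt(cov[2L, 2L]), sqrt(cov[3L, 3L]))
  }
  c_value <- n * ka * isotherm$cell_concentration * 1e-6
  c_flag <- c_value < 0.5 || c_value > 1000
  if (c_flag) {
    warning(sprintf("c-value %.3g outside the fittable range [0.5, 1000]", c_value))
  }
  structure(
    list(n_sites = n, ka = ka, kd_um = 1e6 / ka, dh = best$par[2L],
         offset_heat = best$par[3L],
         se = stats::setNames(se, c("ka", "dh", "offset_heat")),
         c_value = c_value, c_flag = c_flag, rss = rss,
         temperature = isotherm$temperature),
    class = "one_site_fit"
  )
}

#' @export
print.one_site_fit <- function(x, ...) {
  cat(sprintf("<one_site_fit> T = %.2f K\n", x$temperature))
  cat(sprintf("  Ka = %.4g M^-1 (Kd = %.3g uM), dH = %.3f +/- %.3f kcal/mol\n",
              x$ka, x$kd_um, x$dh, x$se["dh"]))
  cat(sprintf("  n = %.3g, offset = %.3g ucal, c-value = %.3g%s\n",
              x$n_sites, x$offset_heat, x$c_value,
              if (x$c_flag) " [outside fittable range]" else ""))
  invisible(x)
}

#' Global analysis of variable-temperature binding data
#'
#' Joint fit of per-temperature one-site results (Ka, dH) to the
#' constant-dCp model `dH(T) = dH0 + dCp (T - T0)`,
#' `dS(T) = dS0 + dCp ln(T/T0)`, with `ln Ka = -dG(T)/(R T)`. Residuals on
#' the free-energy scale (`RT ln Ka`) and the enthalpy are combined, both in
#' kcal/mol.
#'
#' @param per_temperature Data frame with columns `temperature` (K),
#'   `ka` (M^-1), `dh` (kcal/mol); >= 3 temperatures.
#' @param t0 Reference temperature, K (default 298.15, standard conditions).
#' @return Object of class `binding_thermo`: `dh0` (kcal/mol), `ds0`
#'   (cal/mol/K), `dcp` (kcal/mol/K), derived `dg` (kcal/mol), `tds`
#'   (kcal/mol), `kd_um`, standard errors `se`, `t0`.
#' @export
global_fit_temperature_series <- function(per_temperature, t0 = 298.15) {
  stopifnot(is.data.frame(per_temperature),
            all(c("temperature", "ka", "dh") %in% names(per_temperature)))
  if (length(unique(per_temperature$temperature)) < 3L) {
    stop("dCp is unidentifiable with fewer than 3 temperatures")
  }
  tt <- per_temperature$temperature
  r_kcal <- 1.9872e-3
  dg_obs <- -r_kcal * tt * log(per_temperature$ka)
  resid <- function(p) {
    dh0 <- p[1L]; ds0 <- p[2L] / 1000; dcp <- p[3L]  # ds0 in cal -> kcal
    dh_pred <- dh0 + dcp * (tt - t0)
    ds_pred <- ds0 + dcp * log(tt / t0)
    dg_pred <- dh_pred - tt * ds_pred
    c(dg_obs - dg_pred, per_temperature$dh - dh_pred)
  }
  i0 <- which.min(abs(tt - t0))
  dcp0 <- if (length(tt) > 1L) {
    stats::coef(stats::lm(per_temperature$dh ~ tt))[[2L]]
  } else 0
  ds0_guess <- (per_temperature$dh[i0] - dg_obs[i0]) / tt[i0] * 1000
  fit <- minpack.lm::nls.lm(c(per_temperature$dh[i0], ds0_guess, dcp0),
                            fn = resid,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-15, ptol = 1e-15))
  p <- fit$par
  rss <- sum(fit$fvec^2)
  dof <- 2L * length(tt) - 3L
  cov <- try(solve(fit$hessian) * rss / max(dof, 1L), silent = TRUE)
  se <- if (inherits(cov, "try-error")) rep(NA_real_, 3L) else sqrt(diag(cov))
  dg <- binding_free_energy(p[1L], p[2L], t0)
  structure(
    list(dh0 = p[1L], ds0 = p[2L], dcp = p[3L],
         dg = dg, tds = t0 * p[2L] / 1000,
         kd_um = kd_from_dg(dg, fold_conditions(temperature = t0)),
         se = stats::setNames(se, c("dh0", "ds0", "dcp")),
         t0 = t0, rss = rss, n_temperatures = length(tt)),
    class = "binding_thermo"
  )
}

#' @export
print.binding_thermo <- function(x, ...) {
  cat(sprintf("<binding_thermo> reference T = %.2f K\n", x$t0))
  cat(sprintf("  dH  = %.3f kcal/mol, dS = %.2f cal/mol/K (TdS = %.3f kcal/mol)\n",
              x$dh0, x$ds0, x$tds))
  cat(sprintf("  dCp = %.3f +/- %.3f kcal/mol/K\n", x$dcp, x$se["dcp"]))
  cat(sprintf("  dG  = %.3f kcal/mol, Kd = %.3g uM\n", x$dg, x$kd_um))
  invisible(x)
}

#' Binding free energy from enthalpy and entropy
#'
#' `dG = dH - T dS`, with dS supplied in cal/mol/K as binding entropies
#' usually are.
#'
#' @param dh Binding enthalpy, kcal/mol.
#' @param ds Binding entropy, cal/mol/K.
#' @param temperature Temperature, K (default 298.15).
#' @return dG in kcal/mol.
#' @examples
#' binding_free_energy(-5.63, 11.28) # -8.99 kcal/mol
#' @export
binding_free_energy <- function(dh, ds, temperature = 298.15) {
  dh - temperature * ds / 1000
}

#' Dissociation constant from binding free energy
#'
#' `K_D = exp(dG/RT)` in molar, reported in uM.
#'
#' @param dg Binding free energy, kcal/mol (negative for uM-range binding; a
#'   warning is issued otherwise).
#' @param conditions A [fold_conditions()] object (use
#'   `fold_conditions(temperature = 298.15)` for standard conditions).
#' @return K_D in uM.
#' @examples
#' kd_from_dg(-8.99, fold_conditions(temperature = 298.15)) # ~0.26 uM
#' @export
kd_from_dg <- function(dg, conditions = fold_conditions(temperature = 298.15)) {
  if (any(dg >= 0)) warning("dG >= 0: K_D will be molar-range or weaker")
  exp(dg / rt(conditions)) * 1e6
}
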