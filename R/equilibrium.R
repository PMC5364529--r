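#' Denaturant titration series
#'
#' Container for a spectroscopic titration: one recorded spectrum (CD or
#' fluorescence) per denaturant concentration, stored as a wavelength x
#' concentration matrix. This is the observable of chemical-denaturation
#' equilibrium unfolding.
#'
#' @param denaturant_concs Strictly increasing denaturant concentrations
#'   (mol/L, all >= 0), length `n`.
#' @param signal_matrix Numeric `m x n` matrix; row i is the signal recorded
#'   in channel (wavelength) i across the titration. A vector is accepted for
#'   single-channel data.
#' @param channels Channel labels (typically wavelengths in nm); defaults to
#'   row names or `1:m`.
#' @param probe Label for the probe, e.g. `"fluorescence"`, `"far-UV CD"`,
#'   `"lambda-max"`.
#' @return A `titration_series` object.
#' @export
titration_series <- function(denaturant_concs, signal_matrix,
                             channels = NULL, probe = "fluorescence") {
  denaturant_concs <- as.numeric(denaturant_concs)
  if (is.null(dim(signal_matrix))) {
    signal_matrix <- matrix(signal_matrix, nrow = 1L)
  }
  signal_matrix <- as.matrix(signal_matrix)
  if (any(!is.finite(denaturant_concs)) || any(denaturant_concs < 0)) {
    stop("denaturant concentrations must be finite and >= 0")
  }
  if (any(diff(denaturant_concs) <= 0)) {
    stop("denaturant concentrations must be strictly increasing")
  }
  if (ncol(signal_matrix) != length(denaturant_concs)) {
    stop("signal_matrix must have one column per denaturant concentration")
  }
  if (any(!is.finite(signal_matrix))) {
    stop("signal_matrix contains missing or non-finite values")
  }
  if (is.null(channels)) {
    channels <- rownames(signal_matrix)
    if (is.null(channels)) channels <- as.character(seq_len(nrow(signal_matrix)))
  }
  structure(
    list(
      denaturant_concs = denaturant_concs,
      signal_matrix = signal_matrix,
      channels = as.character(channels),
      probe = probe
    ),
    class = "titration_series"
  )
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf(
    "<titration_series> probe = %s, %d channels x %d titration points, [D] %.2f-%.2f M\n",
    x$probe, nrow(x$signal_matrix), ncol(x$signal_matrix),
    min(x$denaturant_concs), max(x$denaturant_concs)
  ))
  invisible(x)
}

#' Denatured-state population of a two-state protein
#'
#' Linear extrapolation model: the unfolding free energy depends linearly on
#' denaturant, dG(D) = dG_H2O - m * D, and the denatured fraction follows the
#' two-state Boltzmann population
#' `fD = exp(-dG(D)/RT) / (1 + exp(-dG(D)/RT))`.
#'
#' @param dg_h2o Unfolding free energy in water, kcal/mol.
#' @param m_value Denaturant m-value, kcal/mol/M (> 0).
#' @param denaturant Denaturant concentration(s), M.
#' @param conditions A [fold_conditions()] object.
#' @return Denatured fraction in \[0, 1\], same length as `denaturant`.
#' @examples
#' fraction_denatured(9.21, 2.61, 3.53) # ~0.5 at the midpoint
#' @export
fraction_denatured <- function(dg_h2o, m_value, denaturant,
                               conditions = fold_conditions()) {
  if (m_value <= 0) stop("`m_value` must be > 0")
  x <- -(dg_h2o - m_value * denaturant) / rt(conditions)
  stats::plogis(x)
}

#' SVD of a titration series
#'
#' Decomposes the wavelength x concentration signal matrix `M = U S V'`.
#' Columns of `U` are basis spectra, columns of `V` are concentration-
#' dependent coefficients. For each component the first-order autocorrelation
#' of the (unit-norm) U and V columns is computed; smooth, signal-bearing
#' components have autocorrelations near 1 while noise components fall near
#' 0 (the Henry-Hofrichter diagnostic).
#'
#' @param series A [titration_series()] or a plain numeric matrix
#'   (wavelengths in rows).
#' @param threshold Autocorrelation threshold used for the stored
#'   significant-component count (see [count_significant_components()]).
#' @return An object of class `uchfold_svd` with elements `u`, `d`, `v`,
#'   `autocorrelations_u`, `autocorrelations_v`, `n_significant`.
#' @export
svd_decompose <- function(series, threshold = 0.8) {
  m <- if (inherits(series, "titration_series")) series$signal_matrix else as.matrix(series)
  if (nrow(m) < 2L || ncol(m) < 2L) stop("matrix must be at least 2 x 2")
  if (stats::sd(as.vector(m)) == 0) {
    warning("degenerate (constant) matrix: rank-1 result")
  }
  sv <- svd(m)
  res <- structure(
    list(
      u = sv$u, d = sv$d, v = sv$v,
      autocorrelations_u = apply(sv$u, 2L, first_order_autocorrelation),
      autocorrelations_v = apply(sv$v, 2L, first_order_autocorrelation),
      n_significant = NA_integer_
    ),
    class = "uchfold_svd"
  )
  res$n_significant <- count_significant_components(res, threshold)
  res
}

first_order_autocorrelation <- function(w) {
  w <- w / sqrt(sum(w^2))
  sum(w[-length(w)] * w[-1L])
}

#' Count significant SVD components
#'
#' Components are counted contiguously from the first; a component is
#' significant when the first-order autocorrelations of both its basis
#' spectrum (U column) and its coefficient vector (V column) exceed
#' `threshold`, and its singular value is non-negligible.
#'
#' @param svd_result An object from [svd_decompose()].
#' @param threshold Autocorrelation threshold in (0, 1); default 0.8.
#' @return Integer number of significant components.
#' @export
count_significant_components <- function(svd_result, threshold = 0.8) {
  stopifnot(inherits(svd_result, "uchfold_svd"))
  if (threshold <= 0 || threshold >= 1) stop("`threshold` must be in (0, 1)")
  d <- svd_result$d
  nonneg <- d > max(d) * 1e-10
  ok <- svd_result$autocorrelations_u > threshold &
    svd_result$autocorrelations_v > threshold & nonneg
  if (!length(ok) || !ok[1L]) return(0L)
  # contiguous run from the first component
  run <- which(!ok)
  if (!length(run)) length(ok) else run[1L] - 1L
}

#' @export
print.uchfold_svd <- function(x, ...) {
  k <- min(4L, length(x$d))
  frac <- x$d^2 / sum(x$d^2)
  cat(sprintf("<uchfold_svd> %d significant component(s) (threshold on U/V autocorrelation)\n",
              x$n_significant))
  for (i in seq_len(k)) {
    cat(sprintf("  s%-2d %10.4g  (%5.1f%% of signal)  acf(U)=%6.3f acf(V)=%6.3f\n",
                i, x$d[i], 100 * frac[i],
                x$autocorrelations_u[i], x$autocorrelations_v[i]))
  }
  invisible(x)
}

## ---- global two-state equilibrium fit ------------------------------------

# Per-channel baselines enter the model linearly:
#   y(D) = (yN + sN D)(1 - fD) + (yD + sD D) fD
# so for fixed (dG, m) the baseline parameters solve by ordinary least
# squares (variable projection). The outer optimisation is over (dG, m) only.
eq_design_matrix <- function(fd, d, slopes = TRUE) {
  if (slopes) {
    cbind(n_int = 1 - fd, n_slope = d * (1 - fd), d_int = fd, d_slope = d * fd)
  } else {
    cbind(n_int = 1 - fd, d_int = fd)
  }
}

eq_profiled_rss <- function(par, series_list, conditions, slopes = TRUE) {
  dg <- par[1L]; m <- par[2L]
  if (m <= 0) return(1e300)
  total <- 0
  for (s in series_list) {
    fd <- fraction_denatured(dg, m, s$denaturant_concs, conditions)
    x <- eq_design_matrix(fd, s$denaturant_concs, slopes)
    # all channels share the design matrix: one multi-RHS solve
    fit <- try(stats::lm.fit(x, t(s$signal_matrix)), silent = TRUE)
    if (inherits(fit, "try-error")) return(1e300)
    total <- total + sum(fit$residuals^2)
  }
  total
}

eq_baselines <- function(dg, m, series_list, conditions, slopes = TRUE) {
  lapply(series_list, function(s) {
    fd <- fraction_denatured(dg, m, s$denaturant_concs, conditions)
    x <- eq_design_matrix(fd, s$denaturant_concs, slopes)
    coefs <- stats::lm.fit(x, t(s$signal_matrix))$coefficients
    b <- t(coefs)
    colnames(b) <- colnames(x)
    b
  })
}

eq_predict <- function(dg, m, series_list, baselines, conditions, slopes = TRUE) {
  Map(function(s, b) {
    fd <- fraction_denatured(dg, m, s$denaturant_concs, conditions)
    x <- eq_design_matrix(fd, s$denaturant_concs, slopes)
    b %*% t(x)
  }, series_list, baselines)
}

# crude midpoint guess: concentration of steepest change of the first
# V-component (or of the channel-averaged signal)
eq_midpoint_guess <- function(series_list) {
  s <- series_list[[1L]]
  y <- colMeans(s$signal_matrix)
  d <- s$denaturant_concs
  dy <- abs(diff(y) / diff(d))
  mean(d[which.max(dy) + 0:1])
}

#' Global two-state equilibrium unfolding fit
#'
#' Fits the linear extrapolation model to one or several titration series.
#' The thermodynamic parameters (dG_H2O, m) are shared across all series and
#' channels when `share_thermo = TRUE`; each channel keeps its own linear
#' native and denatured baselines, which are solved by variable projection
#' (they enter the model linearly). The outer 2-parameter optimisation runs
#' from multiple starts (midpoint initialised at the concentration of
#' steepest signal change).
#'
#' @param series_list A [titration_series()] or list of them.
#' @param conditions A [fold_conditions()] object.
#' @param share_thermo If `TRUE` (default) one (dG, m) pair is fitted across
#'   all series; if `FALSE` each series is fitted separately and a list of
#'   fits is returned.
#' @param baseline_slopes If `FALSE`, baselines are intercept-only (used for
#'   lambda-max fits).
#' @return An object of class `two_state_eq_fit` with elements `dg_h2o`,
#'   `m_value`, `d50`, standard errors `se`, per-series `baselines`,
#'   `residuals`, `rss`, `n_points`.
#' @examples
#' sim <- simulate_equilibrium_titration(seed = 1)
#' fit <- fit_two_state_equilibrium(sim$series)
#' fit$dg_h2o; fit$m_value; fit$d50
#' @export
fit_two_state_equilibrium <- function(series_list,
                                      conditions = fold_conditions(),
                                      share_thermo = TRUE,
                                      baseline_slopes = TRUE) {
  if (inherits(series_list, "titration_series")) series_list <- list(series_list)
  stopifnot(length(series_list) >= 1L,
            all(vapply(series_list, inherits, TRUE, "titration_series")))
  if (!share_thermo && length(series_list) > 1L) {
    return(lapply(series_list, fit_two_state_equilibrium,
                  conditions = conditions, share_thermo = TRUE,
                  baseline_slopes = baseline_slopes))
  }
  n_points <- sum(vapply(series_list, function(s) length(s$signal_matrix), 1))
  if (any(vapply(series_list, function(s) length(s$denaturant_concs), 1) < 8L)) {
    stop("need at least 8 denaturant points per series")
  }

  d50_0 <- eq_midpoint_guess(series_list)
  starts <- expand.grid(m = c(1, 2, 3, 5), d50 = d50_0 * c(0.8, 1, 1.2))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- c(starts$m[i] * starts$d50[i], starts$m[i])
    opt <- try(stats::optim(p0, eq_profiled_rss, series_list = series_list,
                            conditions = conditions, slopes = baseline_slopes,
                            method = "Nelder-Mead",
                            control = list(reltol = 1e-14, maxit = 4000)), silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("two-state equilibrium fit failed to converge")
  # polish
  best <- stats::optim(best$par, eq_profiled_rss, series_list = series_list,
                       conditions = conditions, slopes = baseline_slopes,
                       method = "BFGS", control = list(reltol = 1e-14, maxit = 1000))
  dg <- best$par[1L]; m <- best$par[2L]
  d50 <- dg / m
  dmin <- min(vapply(series_list, function(s) min(s$denaturant_concs), 1))
  dmax <- max(vapply(series_list, function(s) max(s$denaturant_concs), 1))
  if (d50 <= dmin || d50 >= dmax) {
    stop(sprintf(paste0("transition midpoint (%.2f M) is not bracketed by the ",
                        "data range [%.2f, %.2f] M: fit not converged"),
                 d50, dmin, dmax), call. = FALSE)
  }
  baselines <- eq_baselines(dg, m, series_list, conditions, baseline_slopes)
  pred <- eq_predict(dg, m, series_list, baselines, conditions, baseline_slopes)
  residuals <- Map(function(s, p) s$signal_matrix - p, series_list, pred)
  rss <- sum(vapply(residuals, function(r) sum(r^2), 1))

  # degenerate data: no channel shows a resolvable native-vs-denatured
  # amplitude above the residual noise
  sigma <- sqrt(rss / n_points)
  span <- max(vapply(series_list, function(s) max(abs(s$signal_matrix)), 1))
  amp_max <- max(unlist(Map(function(s, b) {
    if (baseline_slopes) {
      abs((b[, 1L] + b[, 2L] * d50) - (b[, 3L] + b[, 4L] * d50))
    } else {
      abs(b[, 1L] - b[, 2L])
    }
  }, series_list, baselines)))
  if (amp_max < max(5 * sigma, 1e-8 * span)) {
    stop("no resolvable unfolding transition in the data: fit not converged")
  }

  se <- eq_standard_errors(dg, m, series_list, baselines, conditions,
                           baseline_slopes, rss, n_points)
  structure(
    list(
      dg_h2o = dg, m_value = m, d50 = d50,
      se = se,
      baselines = baselines,
      residuals = residuals,
      rss = rss, n_points = n_points,
      probe = paste(vapply(series_list, function(s) s$probe, ""), collapse = "+"),
      conditions = conditions
    ),
    class = "two_state_eq_fit"
  )
}

# covariance of (dG, m) from the full-parameter Jacobian at the optimum
eq_standard_errors <- function(dg, m, series_list, baselines, conditions,
                               slopes, rss, n_points) {
  resid_vec <- function(par) {
    b <- eq_baselines(par[1L], par[2L], series_list, conditions, slopes)
    pred <- eq_predict(par[1L], par[2L], series_list, b, conditions, slopes)
    unlist(Map(function(s, p) as.vector(s$signal_matrix - p), series_list, pred))
  }
  p <- c(dg, m)
  jac <- numeric_jacobian(resid_vec, p)
  npar_baseline <- sum(vapply(baselines, function(b) length(b), 1))
  dof <- n_points - 2L - npar_baseline
  sigma2 <- rss / max(dof, 1L)
  jtj <- crossprod(jac)
  cov <- try(sigma2 * solve(jtj), silent = TRUE)
  if (inherits(cov, "try-error")) {
    sv <- svd(jtj)
    bad <- c("dg_h2o", "m_value")[which.max(abs(sv$v[, which.min(sv$d)]))]
    stop(sprintf("singular Jacobian: parameter `%s` is not identifiable", bad))
  }
  se_dg <- sqrt(cov[1L, 1L]); se_m <- sqrt(cov[2L, 2L])
  grad_d50 <- c(1 / m, -dg / m^2)
  se_d50 <- sqrt(drop(t(grad_d50) %*% cov %*% grad_d50))
  c(dg_h2o = se_dg, m_value = se_m, d50 = se_d50)
}

numeric_jacobian <- function(f, p, eps = 1e-6) {
  f0 <- f(p)
  jac <- matrix(0, length(f0), length(p))
  for (j in seq_along(p)) {
    h <- eps * max(abs(p[j]), 1)
    pp <- p; pp[j] <- p[j] + h
    pm <- p; pm[j] <- p[j] - h
    jac[, j] <- (f(pp) - f(pm)) / (2 * h)
  }
  jac
}

#' @export
print.two_state_eq_fit <- function(x, ...) {
  cat(sprintf("<two_state_eq_fit> probe: %s\n", x$probe))
  cat(sprintf("  dG(H2O) = %.3f +/- %.3f kcal/mol\n", x$dg_h2o, x$se["dg_h2o"]))
  cat(sprintf("  m       = %.3f +/- %.3f kcal/mol/M\n", x$m_value, x$se["m_value"]))
  cat(sprintf("  [D]50%%  = %.3f +/- %.3f M\n", x$d50, x$se["d50"]))
  cat(sprintf("  RSS = %.4g over %d points\n", x$rss, x$n_points))
  invisible(x)
}

#' Two-state fit of the emission-maximum wavelength
#'
#' The wavelength of maximum fluorescence emission as a function of
#' denaturant is fitted to the same two-state linear-extrapolation model,
#' with scalar (intercept-only) native and denatured baselines.
#'
#' @param denaturant_concs Denaturant concentrations, M.
#' @param lambda_max Wavelength of the emission maximum per titration point, nm.
#' @param conditions A [fold_conditions()] object.
#' @return A `two_state_eq_fit` object.
#' @export
fit_lambda_max <- function(denaturant_concs, lambda_max,
                           conditions = fold_conditions()) {
  s <- titration_series(denaturant_concs, matrix(lambda_max, nrow = 1L),
                        channels = "lambda_max", probe = "lambda-max")
  fit_two_state_equilibrium(s, conditions = conditions, baseline_slopes = FALSE)
}

#' Wavelength of maximum signal per titration point
#'
#' @param series A [titration_series()] whose channel labels are numeric
#'   wavelengths.
#' @return Numeric vector of per-concentration wavelengths of maximum signal.
#' @export
extract_lambda_max <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  wl <- suppressWarnings(as.numeric(series$channels))
  if (any(is.na(wl))) stop("channel labels must be numeric wavelengths")
  wl[apply(series$signal_matrix, 2L, which.max)]
}
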