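#' Stopped-flow kinetic trace
#'
#' @param times Observation times in seconds, strictly increasing.
#' @param signal Fluorescence/CD signal (arbitrary units).
#' @param final_denaturant Denaturant concentration after mixing, M.
#' @param dead_time Instrument dead time in seconds; points recorded before
#'   it are discarded at fit time. Default 2 ms, typical of stopped-flow
#'   mixers.
#' @return A `kinetic_trace` object.
#' @export
kinetic_trace <- function(times, signal, final_denaturant = NA_real_,
                          dead_time = 0.002) {
  times <- as.numeric(times); signal <- as.numeric(signal)
  stopifnot(length(times) == length(signal), dead_time >= 0)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(
    list(times = times, signal = signal,
         final_denaturant = final_denaturant, dead_time = dead_time),
    class = "kinetic_trace"
  )
}

## ---- multi-exponential fitting -------------------------------------------

# y(t) = offset + sum_i A_i exp(-k_i t); for fixed rates the amplitudes and
# offset are linear (variable projection)
multiexp_design <- function(t, rates) {
  cbind(offset = rep(1, length(t)),
        vapply(rates, function(k) exp(-k * t), numeric(length(t))))
}

multiexp_rss <- function(log_rates, t, y) {
  k <- exp(log_rates)
  if (any(!is.finite(k))) return(1e300)
  x <- multiexp_design(t, k)
  fit <- try(stats::lm.fit(x, y), silent = TRUE)
  if (inherits(fit, "try-error")) return(1e300)
  sum(fit$residuals^2)
}

fit_multiexp_n <- function(t, y, n, n_starts = 6L) {
  span <- range(t)
  k_lo <- 1 / (span[2L] - span[1L])
  k_hi <- 1 / (2 * min(diff(t)))
  best <- NULL
  for (s in seq_len(n_starts)) {
    # log-spaced guesses, jittered deterministically by start index
    base <- seq(log(k_lo), log(k_hi * 0.5), length.out = n + 2L)[1L + seq_len(n)]
    p0 <- base + (s - (n_starts + 1) / 2) * 0.4
    opt <- if (n == 1L) {
      o <- stats::optimize(function(p) multiexp_rss(p, t, y),
                           interval = c(log(k_lo) - 3, log(k_hi)),
                           tol = 1e-12)
      list(par = o$minimum, value = o$objective)
    } else {
      stats::optim(p0, multiexp_rss, t = t, y = y,
                   method = "Nelder-Mead",
                   control = list(reltol = 1e-14, maxit = 3000))
    }
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  # Levenberg-Marquardt polish on the profiled residuals
  resid_fun <- function(lp) {
    k <- exp(lp)
    x <- multiexp_design(t, k)
    fit <- try(stats::lm.fit(x, y), silent = TRUE)
    if (inherits(fit, "try-error")) return(rep(1e6, length(y)))
    fit$residuals
  }
  pol <- try(minpack.lm::nls.lm(best$par, fn = resid_fun,
                                control = minpack.lm::nls.lm.control(
                                  maxiter = 200, ftol = 1e-15, ptol = 1e-15)),
             silent = TRUE)
  if (!inherits(pol, "try-error") && sum(pol$fvec^2) < best$value) {
    best <- list(par = pol$par, value = sum(pol$fvec^2))
  }
  k <- sort(exp(best$par), decreasing = TRUE)
  x <- multiexp_design(t, k)
  lf <- stats::lm.fit(x, y)
  list(rates = k, amplitudes = unname(lf$coefficients[-1L]),
       offset = unname(lf$coefficients[1L]),
       rss = sum(lf$residuals^2), fitted = x %*% lf$coefficients)
}

#' Multi-exponential fit of a kinetic trace with F-test phase selection
#'
#' Fits `signal(t) = offset + sum_i A_i exp(-k_i t)` for 1 to `max_phases`
#' exponential phases and selects the smallest number of phases such that
#' adding one more is not justified by the extra-sum-of-squares F test at
#' level `alpha`. Phases whose rates are separated by less than a factor of
#' 1.5 are merged. Points before the instrument dead time are discarded.
#'
#' @param trace A [kinetic_trace()] object (or list with `times`, `signal`).
#' @param max_phases Maximum number of exponential phases (1-3).
#' @param alpha Significance level of the extra-sum-of-squares F test.
#' @return An object of class `multiexp_fit` with `n_phases`, `rates`
#'   (s^-1, descending), `amplitudes`, `offset`, `rss`, `n_points`,
#'   `flat` flag and `f_tests` (one row per tested model pair).
#' @examples
#' tr <- simulate_kinetic_trace(rates = c(10, 0.8), amplitudes = c(0.8, 0.2),
#'                              noise_cv = 0, seed = 1)
#' fit_multiexponential(tr)$rates
#' @export
fit_multiexponential <- function(trace, max_phases = 3L, alpha = 0.05) {
  t <- trace$times; y <- trace$signal
  dead <- if (!is.null(trace$dead_time)) trace$dead_time else 0
  keep <- t >= dead
  t <- t[keep] - t[keep][1L]; y <- y[keep]
  n <- length(t)
  if (n < 10 * 3) stop("need at least 30 points after the dead time")
  max_phases <- min(max_phases, floor((n / 10 - 1) / 2))

  # flat trace: no resolvable signal change
  lin <- stats::lm.fit(cbind(1, t), y)
  flat <- stats::sd(y) < 1e-12 * max(1, abs(mean(y))) ||
    (sum(lin$residuals^2) / max(stats::var(y) * (n - 1), .Machine$double.eps)) > 0.999 &&
    abs(lin$coefficients[2L]) * diff(range(t)) < 1e-6 * max(stats::sd(y), 1e-300)

  fits <- list(fit_multiexp_n(t, y, 1L))
  f_tests <- NULL
  n_sel <- 1L
  if (!flat) {
    ss_tot <- sum((y - mean(y))^2)
    while (n_sel < max_phases) {
      # stop once the current fit is at numerical noise: the F test is
      # meaningless on machine-epsilon residuals
      if (fits[[n_sel]]$rss <= 1e-18 * ss_tot) break
      cand <- fit_multiexp_n(t, y, n_sel + 1L)
      ft <- extra_ss_f_test(fits[[n_sel]]$rss, 2L * n_sel + 1L,
                            cand$rss, 2L * (n_sel + 1L) + 1L, n, alpha = alpha)
      f_tests <- rbind(f_tests,
                       data.frame(simple = n_sel, complex = n_sel + 1L,
                                  F = ft$F, p_value = ft$p_value,
                                  accept_complex = ft$accept_complex))
      fits[[n_sel + 1L]] <- cand
      if (!ft$accept_complex) break
      n_sel <- n_sel + 1L
    }
  } else {
    warning("flat or non-decaying trace: forcing a single-phase fit")
  }
  sel <- fits[[n_sel]]

  # merge poorly separated rates
  while (n_sel > 1L && any(sel$rates[-n_sel] / sel$rates[-1L] < 1.5)) {
    warning("rates separated by < 1.5x: merging phases")
    n_sel <- n_sel - 1L
    sel <- fits[[n_sel]]
  }
  nyquist <- 1 / (2 * min(diff(t)))
  span <- diff(range(y))
  at_bound <- sel$rates >= nyquist * 0.999 & abs(sel$amplitudes) > 1e-6 * max(span, 1e-300)
  if (!flat && any(at_bound)) {
    stop(sprintf("fitted rate %.3g /s reaches the sampling bound %.3g /s",
                 max(sel$rates), nyquist))
  }
  structure(
    list(n_phases = n_sel, rates = sel$rates, amplitudes = sel$amplitudes,
         offset = sel$offset, rss = sel$rss, n_points = n,
         flat = flat, f_tests = f_tests, fitted = drop(sel$fitted),
         times = t),
    class = "multiexp_fit"
  )
}

#' @export
print.multiexp_fit <- function(x, ...) {
  cat(sprintf("<multiexp_fit> %d phase(s), RSS = %.4g over %d points%s\n",
              x$n_phases, x$rss, x$n_points, if (x$flat) " [flat trace]" else ""))
  for (i in seq_len(x$n_phases)) {
    cat(sprintf("  k%-2d = %10.4g /s   A = %10.4g\n", i, x$rates[i], x$amplitudes[i]))
  }
  cat(sprintf("  offset = %.4g\n", x$offset))
  invisible(x)
}

#' Extra-sum-of-squares F test for nested least-squares models
#'
#' `F = ((rss_simple - rss_complex)/(p_complex - p_simple)) /
#'      (rss_complex/(n - p_complex))`, compared against the F distribution
#' with `(p_complex - p_simple, n - p_complex)` degrees of freedom.
#'
#' @param rss_simple,rss_complex Residual sums of squares of the nested fits.
#' @param p_simple,p_complex Numbers of fitted parameters (complex > simple).
#' @param n Number of data points.
#' @param alpha Significance level for `accept_complex`.
#' @return List with `F`, `p_value`, `accept_complex`.
#' @examples
#' extra_ss_f_test(2, 3, 1, 5, 105) # F = 50
#' @export
extra_ss_f_test <- function(rss_simple, p_simple, rss_complex, p_complex, n,
                            alpha = 0.05) {
  stopifnot(p_complex > p_simple, n > p_complex)
  if (rss_complex > rss_simple) {
    return(list(F = 0, p_value = 1, accept_complex = FALSE))
  }
  df1 <- p_complex - p_simple
  df2 <- n - p_complex
  if (rss_complex == 0) {
    # both fits perfect -> no evidence for the complex model; only the
    # complex one perfect -> unambiguous support
    if (rss_simple == 0) return(list(F = 0, p_value = 1, accept_complex = FALSE))
    return(list(F = Inf, p_value = 0, accept_complex = TRUE))
  }
  f <- ((rss_simple - rss_complex) / df1) / (rss_complex / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  list(F = f, p_value = p, accept_complex = p < alpha)
}

## ---- chevron analysis -----------------------------------------------------

#' Observed relaxation rate of a two-state folder
#'
#' Chevron equation: `k_obs(D) = kf_h2o exp(mf D / RT) + ku_h2o exp(mu D / RT)`
#' with `mf < 0` (refolding arm) and `mu > 0` (unfolding arm).
#'
#' @param kf_h2o,ku_h2o Folding and unfolding rates in water, s^-1.
#' @param mf,mu Kinetic m-values, kcal/mol/M.
#' @param denaturant Denaturant concentration(s), M.
#' @param conditions A [fold_conditions()] object.
#' @return k_obs in s^-1.
#' @examples
#' chevron_kobs(0.14, -1.09, 8.1e-9, 1.88, 6) # ~1.5 /s
#' @export
chevron_kobs <- function(kf_h2o, mf, ku_h2o, mu, denaturant,
                         conditions = fold_conditions()) {
  stopifnot(all(denaturant >= 0))
  rt_ <- rt(conditions)
  kf_h2o * exp(mf * denaturant / rt_) + ku_h2o * exp(mu * denaturant / rt_)
}

#' Unfolding free energy from folding and unfolding rates
#'
#' `dG = RT ln(kf / ku)`.
#'
#' @param kf,ku Folding and unfolding rates in water, s^-1 (> 0).
#' @param conditions A [fold_conditions()] object.
#' @return Free energy of unfolding, kcal/mol.
#' @examples
#' delta_g_from_rates(0.14, 8.1e-9) # ~9.87 kcal/mol
#' @export
delta_g_from_rates <- function(kf, ku, conditions = fold_conditions()) {
  stopifnot(all(kf > 0), all(ku > 0))
  rt(conditions) * log(kf / ku)
}

chevron_resid <- function(par, d, log10_kobs, rt_) {
  pred <- log10(exp(par[1L] * log(10)) * exp(par[2L] * d / rt_) +
                  exp(par[3L] * log(10)) * exp(par[4L] * d / rt_))
  log10_kobs - pred
}

#' Fit a chevron plot
#'
#' Least squares on `log10(k_obs)` against the two-state chevron equation.
#' Rates span many orders of magnitude across a chevron, so fitting in log
#' space keeps errors homoscedastic. Initial values come from linear
#' regressions of `log10(k_obs)` on denaturant within each arm. Derived
#' quantities (`dg = RT ln(kf/ku)`, `m_kin = mu - mf`, `d50 = dg/m_kin`) are
#' populated with delta-method standard errors.
#'
#' @param data Data frame with columns `denaturant` (M) and `k_obs` (s^-1),
#'   optionally `branch` (`"refolding"`/`"unfolding"`); when absent, points
#'   are split at the chevron minimum.
#' @param conditions A [fold_conditions()] object.
#' @return An object of class `chevron_fit` with `kf_h2o`, `mf`, `ku_h2o`,
#'   `mu`, `dg`, `m_kin`, `d50`, standard errors `se`, and the fit residuals.
#' @export
fit_chevron <- function(data, conditions = fold_conditions()) {
  stopifnot(is.data.frame(data), all(c("denaturant", "k_obs") %in% names(data)))
  if (any(data$k_obs <= 0)) stop("all k_obs must be > 0")
  d <- data$denaturant
  lk <- log10(data$k_obs)
  rt_ <- rt(conditions)

  if ("branch" %in% names(data)) {
    refold <- data$branch == "refolding"
  } else {
    # split at the concentration of minimum observed rate
    dmin <- d[which.min(lk)]
    refold <- d <= dmin
  }
  if (sum(refold) < 4L) stop("unidentifiable chevron: refolding arm has < 4 points")
  if (sum(!refold) < 4L) stop("unidentifiable chevron: unfolding arm has < 4 points")

  cf <- stats::lm.fit(cbind(1, d[refold]), lk[refold])$coefficients
  cu <- stats::lm.fit(cbind(1, d[!refold]), lk[!refold])$coefficients
  p0 <- c(log10_kf = unname(cf[1L]), mf = unname(cf[2L]) * rt_ * log(10),
          log10_ku = unname(cu[1L]), mu = unname(cu[2L]) * rt_ * log(10))

  fit <- minpack.lm::nls.lm(
    par = p0, fn = chevron_resid, d = d, log10_kobs = lk, rt_ = rt_,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15, ptol = 1e-15)
  )
  p <- fit$par
  if (p["mf"] >= 0 || p["mu"] <= 0) {
    stop("chevron fit did not converge to mf < 0 < mu; check the arm coverage")
  }
  n <- length(d)
  rss <- sum(fit$fvec^2)
  sigma2 <- rss / max(n - 4L, 1L)
  cov <- try(sigma2 * solve(fit$hessian), silent = TRUE)
  if (inherits(cov, "try-error")) cov <- matrix(NA_real_, 4L, 4L)

  ln10 <- log(10)
  kf <- 10^p[["log10_kf"]]; ku <- 10^p[["log10_ku"]]
  dg <- rt_ * ln10 * (p[["log10_kf"]] - p[["log10_ku"]])
  m_kin <- p[["mu"]] - p[["mf"]]
  d50 <- dg / m_kin
  # delta method for derived quantities, parameter order (log10kf, mf, log10ku, mu)
  g_dg <- c(rt_ * ln10, 0, -rt_ * ln10, 0)
  g_mk <- c(0, -1, 0, 1)
  g_d50 <- g_dg / m_kin - dg * g_mk / m_kin^2
  dm <- function(g) sqrt(drop(t(g) %*% cov %*% g))
  se <- c(
    kf_h2o = kf * ln10 * sqrt(cov[1L, 1L]), mf = sqrt(cov[2L, 2L]),
    ku_h2o = ku * ln10 * sqrt(cov[3L, 3L]), mu = sqrt(cov[4L, 4L]),
    log10_kf = sqrt(cov[1L, 1L]), log10_ku = sqrt(cov[3L, 3L]),
    dg = dm(g_dg), m_kin = dm(g_mk), d50 = dm(g_d50)
  )
  structure(
    list(kf_h2o = kf, mf = p[["mf"]], ku_h2o = ku, mu = p[["mu"]],
         dg = dg, m_kin = m_kin, d50 = d50, se = se,
         residuals = fit$fvec, rss = rss, n_points = n,
         conditions = conditions),
    class = "chevron_fit"
  )
}

#' @export
print.chevron_fit <- function(x, ...) {
  cat("<chevron_fit>\n")
  cat(sprintf("  kf(H2O) = %.4g /s (log10: %.3f +/- %.3f), mf = %.3f +/- %.3f\n",
              x$kf_h2o, log10(x$kf_h2o), x$se["log10_kf"], x$mf, x$se["mf"]))
  cat(sprintf("  ku(H2O) = %.4g /s (log10: %.3f +/- %.3f), mu = %.3f +/- %.3f\n",
              x$ku_h2o, log10(x$ku_h2o), x$se["log10_ku"], x$mu, x$se["mu"]))
  cat(sprintf("  dG = %.3f +/- %.3f kcal/mol, m_kin = %.3f, [D]50%% = %.3f M\n",
              x$dg, x$se["dg"], x$m_kin, x$d50))
  invisible(x)
}

#' @export
predict.chevron_fit <- function(object, denaturant, ...) {
  chevron_kobs(object$kf_h2o, object$mf, object$ku_h2o, object$mu,
               denaturant, object$conditions)
}
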