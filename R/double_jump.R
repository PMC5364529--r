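#' Mixing scheme arithmetic for (double-)jump experiments
#'
#' Tracks denaturant and protein concentrations through a sequence of mixing
#' steps. At each step the protein-carrying solution (the previous step's
#' output) is mixed with an added buffer at a given volume ratio; the
#' resulting concentrations are volume-weighted averages.
#'
#' @param steps List of steps, each a list/vector with `added_denaturant`
#'   (M), `ratio_added` and `ratio_carried` (relative volumes of added
#'   buffer and protein-carrying solution).
#' @param protein_start Starting protein concentration, uM.
#' @param start_denaturant Denaturant concentration of the starting protein
#'   solution, M.
#' @return Data frame with one row per step: `denaturant` (M) and `protein`
#'   (uM) after the step.
#' @examples
#' # 20 uM protein in 8 M urea diluted 10:1 with buffer: 1.8 uM, 0.73 M
#' final_concentration(list(list(added_denaturant = 0, ratio_added = 10,
#'                               ratio_carried = 1)),
#'                     protein_start = 20, start_denaturant = 8)
#' @export
final_concentration <- function(steps, protein_start, start_denaturant) {
  den <- start_denaturant
  prot <- protein_start
  out <- data.frame(denaturant = numeric(0), protein = numeric(0))
  for (st in steps) {
    ra <- st$ratio_added; rc <- st$ratio_carried
    if (is.null(ra) || is.null(rc) || ra <= 0 || rc <= 0) {
      stop("mixing ratios must be positive")
    }
    den <- (st$added_denaturant * ra + den * rc) / (ra + rc)
    prot <- prot * rc / (ra + rc)
    out <- rbind(out, data.frame(denaturant = den, protein = prot))
  }
  out
}

#' Interrupted-refolding series
#'
#' A set of kinetic traces recorded after a variable refolding (aging)
#' period, all measured at the same final denaturant concentration.
#'
#' @param aging_times Aging times t_age in seconds, one per trace.
#' @param traces List of [kinetic_trace()] objects.
#' @return An `interrupted_refolding_series` object.
#' @export
interrupted_refolding_series <- function(aging_times, traces) {
  stopifnot(length(aging_times) == length(traces),
            all(vapply(traces, inherits, TRUE, "kinetic_trace")))
  fd <- vapply(traces, function(x) x$final_denaturant, 1)
  if (any(!is.na(fd)) && diff(range(fd, na.rm = TRUE)) > 1e-6) {
    stop("all traces must share the same final denaturant concentration")
  }
  structure(list(aging_times = as.numeric(aging_times), traces = traces),
            class = "interrupted_refolding_series")
}

#' Global multi-exponential fit with rates shared across aging times
#'
#' Fits all traces of an interrupted-refolding series jointly: one set of
#' `n_phases` exponential rates common to every trace, with per-trace
#' amplitudes and offsets free (solved linearly at each rate iterate). The
#' per-phase amplitudes as a function of aging time are the substrate of
#' [fit_amplitude_buildup()].
#'
#' @param series An [interrupted_refolding_series()] (>= 3 aging times).
#' @param n_phases Number of shared exponential phases.
#' @return List with `rates` (s^-1, descending), `amplitudes`
#'   (`n_phases` x n_aging matrix), `offsets`, `rss`, `aging_times`.
#' @export
global_fit_shared_rates <- function(series, n_phases) {
  stopifnot(inherits(series, "interrupted_refolding_series"))
  if (length(series$aging_times) < 3L) stop("need at least 3 aging times")
  tr <- lapply(series$traces, function(x) {
    keep <- x$times >= x$dead_time
    list(t = x$times[keep] - x$times[keep][1L], y = x$signal[keep])
  })
  joint_rss <- function(log_rates) {
    k <- exp(log_rates)
    if (any(!is.finite(k))) return(1e300)
    sum(vapply(tr, function(z) {
      x <- multiexp_design(z$t, k)
      f <- try(stats::lm.fit(x, z$y), silent = TRUE)
      if (inherits(f, "try-error")) return(1e300)
      sum(f$residuals^2)
    }, 1))
  }
  t_all <- unlist(lapply(tr, `[[`, "t"))
  k_lo <- 1 / max(t_all); k_hi <- 1 / (2 * min(vapply(tr, function(z) min(diff(z$t)), 1)))
  best <- NULL
  for (s in 1:5) {
    base <- seq(log(k_lo), log(k_hi * 0.5), length.out = n_phases + 2L)[1L + seq_len(n_phases)]
    p0 <- base + (s - 3) * 0.5
    opt <- stats::optim(p0, joint_rss, method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 5000))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  k <- sort(exp(best$par), decreasing = TRUE)
  if (n_phases > 1L && any(k[-n_phases] / k[-1L] < 1.5)) {
    warning("shared rates collapsed (< 1.5x separation); consider fewer phases")
  }
  amps <- matrix(NA_real_, n_phases, length(tr))
  offs <- numeric(length(tr))
  rss <- 0
  for (i in seq_along(tr)) {
    x <- multiexp_design(tr[[i]]$t, k)
    f <- stats::lm.fit(x, tr[[i]]$y)
    offs[i] <- f$coefficients[1L]
    amps[, i] <- f$coefficients[-1L]
    rss <- rss + sum(f$residuals^2)
  }
  list(rates = k, amplitudes = amps, offsets = offs, rss = rss,
       aging_times = series$aging_times)
}

#' Amplitude build-up versus aging time
#'
#' For each kinetic phase, fits the observed amplitude as a function of
#' aging time to a single exponential build-up
#' `A(t_age) = A_inf (1 - exp(-k t_age))`. A phase is lag-flagged when a
#' delayed-onset (sequential two-step) build-up improves the fit by the
#' extra-sum-of-squares F test at `alpha` — lags too subtle for the eye are
#' detected statistically.
#'
#' @param amplitudes `n_phases x n_aging` matrix (e.g. from
#'   [global_fit_shared_rates()]); a vector is treated as one phase.
#' @param aging_times Aging times in seconds (>= 5, spanning the build-up).
#' @param alpha Significance level of the lag test.
#' @return Object of class `amplitude_buildup`: data frame with one row per
#'   phase: `a_inf`, `buildup_rate` (s^-1, `NA` when the amplitude does not
#'   build up), `se_rate`, `lag_flag`; plus attributes `aging_times`,
#'   `amplitudes`.
#' @export
fit_amplitude_buildup <- function(amplitudes, aging_times, alpha = 0.05) {
  if (is.null(dim(amplitudes))) amplitudes <- matrix(amplitudes, nrow = 1L)
  stopifnot(ncol(amplitudes) == length(aging_times), length(aging_times) >= 5L)
  res <- lapply(seq_len(nrow(amplitudes)), function(i) {
    a <- abs(amplitudes[i, ])  # sign of the spectroscopic response is arbitrary
    t <- aging_times
    if (diff(range(a)) < 1e-3 * max(abs(a), 1e-300) + 1e-300) {
      return(data.frame(a_inf = mean(a), buildup_rate = NA_real_,
                        se_rate = NA_real_, lag_flag = FALSE))
    }
    single <- function(p) a - p[1L] * (1 - exp(-exp(p[2L]) * t))
    k0 <- log(1 / t[which.min(abs(a - max(a) / 2))])
    f1 <- minpack.lm::nls.lm(c(max(a), k0), fn = single,
                             control = minpack.lm::nls.lm.control(maxiter = 300,
                                                                  ftol = 1e-15))
    # single-exponential fit already at numerical noise: no lag resolvable
    if (sum(f1$fvec^2) <= 1e-16 * sum(a^2)) {
      cov1 <- try(solve(f1$hessian) * sum(f1$fvec^2) / max(length(t) - 2L, 1L),
                  silent = TRUE)
      k1 <- exp(f1$par[2L])
      se1 <- if (inherits(cov1, "try-error")) NA_real_ else k1 * sqrt(cov1[2L, 2L])
      return(data.frame(a_inf = f1$par[1L], buildup_rate = k1,
                        se_rate = se1, lag_flag = FALSE))
    }
    # sequential A -> B -> C: delayed accumulation of the end species
    seqm <- function(p) {
      k1 <- exp(p[2L]); k2 <- exp(p[3L])
      if (abs(k1 - k2) < 1e-12 * max(k1, k2)) k2 <- k1 * (1 + 1e-6)
      a - p[1L] * (1 - (k2 * exp(-k1 * t) - k1 * exp(-k2 * t)) / (k2 - k1))
    }
    f2 <- minpack.lm::nls.lm(c(f1$par[1L], f1$par[2L] + 1, f1$par[2L] - 1),
                             fn = seqm,
                             control = minpack.lm::nls.lm.control(maxiter = 300,
                                                                  ftol = 1e-15))
    ft <- extra_ss_f_test(sum(f1$fvec^2), 2L, min(sum(f2$fvec^2), sum(f1$fvec^2)),
                          3L, length(t), alpha = alpha)
    cov <- try(solve(f1$hessian) * sum(f1$fvec^2) / max(length(t) - 2L, 1L),
               silent = TRUE)
    k_hat <- exp(f1$par[2L])
    se_k <- if (inherits(cov, "try-error")) NA_real_ else k_hat * sqrt(cov[2L, 2L])
    data.frame(a_inf = f1$par[1L], buildup_rate = k_hat, se_rate = se_k,
               lag_flag = ft$accept_complex)
  })
  out <- do.call(rbind, res)
  out$phase <- seq_len(nrow(out))
  structure(out[, c("phase", "a_inf", "buildup_rate", "se_rate", "lag_flag")],
            class = c("amplitude_buildup", "data.frame"),
            aging_times = aging_times, amplitudes = amplitudes)
}

## ---- linear three-state kinetics -----------------------------------------

three_state_rate_matrix <- function(k_ab, k_ba, k_bc, k_cb) {
  matrix(c(-k_ab, k_ab, 0,
           k_ba, -(k_ba + k_bc), k_bc,
           0, k_cb, -k_cb), 3L, 3L)
}

#' Relaxation spectrum of a linear three-state scheme A <-> B <-> C
#'
#' Builds the 3x3 first-order rate matrix, returns the two nonzero
#' relaxation rates (negated eigenvalues) and the amplitude weights with
#' which each exponential mode contributes to each species' population for
#' the given initial condition: `p_i(t) = sum_j W[i,j] exp(lambda_j t)`.
#'
#' @param k_ab,k_ba,k_bc,k_cb Microscopic rate constants, s^-1 (>= 0, not
#'   all zero).
#' @param p0 Initial populations of (A, B, C); must sum to 1. Default: pure
#'   A (the denatured state in interrupted refolding).
#' @return List with `relaxation_rates` (ascending), `eigenvalues`
#'   (including 0), `weights` (3 x 3, species x mode), `equilibrium`
#'   populations, and `populations(t)` — a function evaluating the analytic
#'   population time courses.
#' @examples
#' three_state_relaxation(1, 1, 1, 1)$relaxation_rates # 1 and 3
#' @export
three_state_relaxation <- function(k_ab, k_ba, k_bc, k_cb, p0 = c(1, 0, 0)) {
  rates <- c(k_ab, k_ba, k_bc, k_cb)
  if (any(rates < 0)) stop("rates must be >= 0")
  if (all(rates == 0)) stop("all rates are zero")
  stopifnot(length(p0) == 3L, abs(sum(p0) - 1) < 1e-9, all(p0 >= -1e-12))
  K <- three_state_rate_matrix(k_ab, k_ba, k_bc, k_cb)
  eig <- eigen(K)
  ev <- Re(eig$values)
  V <- Re(eig$vectors)
  cvec <- solve(V, p0)
  W <- V %*% diag(cvec, 3L)
  ord <- order(-ev)   # 0 first, then increasingly negative
  ev <- ev[ord]; W <- W[, ord, drop = FALSE]
  relax <- sort(-ev[-1L])
  i_eq <- 1L
  equilibrium <- W[, i_eq] / sum(W[, i_eq])
  pops <- function(t) {
    out <- vapply(t, function(tt) drop(W %*% exp(ev * tt)), numeric(3L))
    rownames(out) <- c("A", "B", "C")
    t(out)
  }
  list(relaxation_rates = relax, eigenvalues = ev, weights = W,
       equilibrium = equilibrium, populations = pops)
}

#' Fit a linear three-state scheme to amplitude build-up curves
#'
#' The amplitudes of two kinetic phases as a function of aging time are
#' interpreted as (scaled) populations of the intermediate B and the native
#' state C in the scheme A <-> B <-> C, starting from pure denatured A.
#' Microscopic rates are obtained by least squares on both curves jointly,
#' from multiple starts. Both curves share one spectroscopic response scale
#' (solved linearly at each iterate): with independent per-curve scales the
#' four microscopic rates are not identifiable — a second, distinct rate set
#' reproduces both curve shapes exactly — so the fit assumes the two folded
#' species contribute equally per molecule to the unfolding amplitude, the
#' conventional reading of interrupted-refolding amplitudes. A nested
#' two-state scheme (A <-> B only, both curves reporting on B) is fitted for
#' comparison; when the F test does not justify the extra rates, the simpler
#' scheme is preferred.
#'
#' @param amplitudes 2 x n matrix: phase-amplitude build-up curves for the
#'   species-B-like and species-C-like phases (rows), across aging times.
#' @param aging_times Aging times, seconds.
#' @param p0 Initial populations (default pure A).
#' @param alpha Level of the scheme-comparison F test.
#' @return Object of class `linear_three_state`: list with `rates`
#'   (k_ab, k_ba, k_bc, k_cb), `scales`, `rss`, `scheme_preference`
#'   (`"three-state"` or `"two-state"`), `f_test`, and `fitted` matrix.
#' @export
fit_linear_three_state <- function(amplitudes, aging_times, p0 = c(1, 0, 0),
                                   alpha = 0.05) {
  stopifnot(nrow(amplitudes) == 2L, ncol(amplitudes) == length(aging_times))
  a_obs <- abs(amplitudes)
  t <- aging_times

  model_resid <- function(logk) {
    k <- exp(logk)
    rel <- try(three_state_relaxation(k[1L], k[2L], k[3L], k[4L], p0), silent = TRUE)
    if (inherits(rel, "try-error")) return(rep(1e6, 2L * length(t)))
    p <- rel$populations(t)          # n x 3 (A, B, C)
    pops <- t(p[, 2:3])              # B for phase row 1, C for row 2
    sc <- sum(a_obs * pops) / max(sum(pops^2), 1e-300)  # shared response scale
    as.vector(a_obs - sc * pops)
  }
  # heuristics: the C-like curve builds at ~ the slow relaxation rate, the
  # B-like curve at ~ the fast one
  bu <- fit_amplitude_buildup(a_obs, t)
  k_slow <- bu$buildup_rate[2L]; k_fast <- bu$buildup_rate[1L]
  if (is.na(k_slow)) k_slow <- 1 / stats::median(t)
  if (is.na(k_fast)) k_fast <- 5 / stats::median(t)
  starts <- list(
    log(c(k_slow, k_slow / 10, k_fast, k_fast / 10)),
    log(c(k_fast, k_fast / 10, k_slow, k_slow / 10)),
    log(c(k_slow, k_slow, k_fast, k_fast)),
    log(rep(1 / stats::median(t), 4L)),
    log(c(k_slow / 3, k_slow / 30, k_fast * 3, k_fast / 3))
  )
  best <- NULL
  for (p0i in starts) {
    f <- try(minpack.lm::nls.lm(p0i, fn = model_resid,
                                control = minpack.lm::nls.lm.control(
                                  maxiter = 400, ftol = 1e-15, ptol = 1e-15)),
             silent = TRUE)
    if (inherits(f, "try-error")) next
    if (is.null(best) || sum(f$fvec^2) < sum(best$fvec^2)) best <- f
  }
  if (is.null(best)) stop("three-state fit failed from all starts")
  k <- exp(best$par)
  rss3 <- sum(best$fvec^2)

  # nested two-state alternative: one building species, so the two curves
  # are the same shape up to per-curve response scales
  two_resid <- function(logk) {
    kab <- exp(logk[1L]); kba <- exp(logk[2L])
    pop <- (kab / (kab + kba)) * (1 - exp(-(kab + kba) * t))
    unlist(lapply(1:2, function(i) {
      sc <- sum(a_obs[i, ] * pop) / max(sum(pop^2), 1e-300)
      a_obs[i, ] - sc * pop
    }))
  }
  f2 <- minpack.lm::nls.lm(log(c(k_slow, k_slow / 10)), fn = two_resid,
                           control = minpack.lm::nls.lm.control(maxiter = 400,
                                                                ftol = 1e-15))
  rss2 <- sum(f2$fvec^2)
  n <- 2L * length(t)
  ft <- extra_ss_f_test(max(rss2, rss3), 4L, min(rss3, rss2), 5L, n, alpha = alpha)
  pref <- if (rss3 < rss2 && ft$accept_complex) "three-state" else "two-state"

  rel <- three_state_relaxation(k[1L], k[2L], k[3L], k[4L], p0)
  p <- rel$populations(t)
  pops <- t(p[, 2:3])
  sc <- sum(a_obs * pops) / max(sum(pops^2), 1e-300)
  scales <- c(sc, sc)
  fitted <- sc * pops
  structure(
    list(rates = stats::setNames(k, c("k_ab", "k_ba", "k_bc", "k_cb")),
         scales = scales, rss = rss3, scheme_preference = pref,
         f_test = ft, fitted = fitted, aging_times = t,
         relaxation_rates = rel$relaxation_rates),
    class = "linear_three_state"
  )
}

#' @export
print.linear_three_state <- function(x, ...) {
  cat("<linear_three_state> A <-> B <-> C\n")
  cat(sprintf("  k_ab = %.4g, k_ba = %.4g, k_bc = %.4g, k_cb = %.4g /s\n",
              x$rates[1L], x$rates[2L], x$rates[3L], x$rates[4L]))
  cat(sprintf("  relaxation rates: %.4g, %.4g /s; preferred scheme: %s\n",
              x$relaxation_rates[1L], x$relaxation_rates[2L],
              x$scheme_preference))
  invisible(x)
}
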