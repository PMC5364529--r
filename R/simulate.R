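#' @title Seeded synthetic-data generators
#' @description Every analysis in the package can be exercised without
#'   instrument data: each generator emits a dataset in the module-native
#'   container together with the ground-truth parameter record, under a fixed
#'   seed. Defaults reproduce the experimental design the package targets
#'   (41-point urea titrations, log-sampled stopped-flow traces with a 2 ms
#'   dead time, log-spaced aging times from 10 ms to 100 s, four-temperature
#'   ITC series) with instrument-grade noise (1% proportional on spectra and
#'   traces, 2% on ITC heats).
#' @name simulate
NULL

# run a generator under a fixed seed without disturbing the session RNG
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Published parameter presets for the three UCH paralogs
#'
#' Registry of the fitted thermodynamic and kinetic parameter sets for
#' UCH-L1, UCH-L3 and the UCH-L5 catalytic domain (N-terminal 1-240
#' construct) used as generator defaults: equilibrium unfolding (dG, m),
#' chevron parameters of the four stopped-flow kinetic phases, and
#' ubiquitin-binding thermodynamics. Each entry carries a `provenance`
#' string describing the experiment it summarises.
#'
#' @return Nested list with elements `equilibrium`, `chevron`, `binding`.
#' @export
uchfold_presets <- function() {
  list(
    equilibrium = list(
      uchl5_global = list(dg_h2o = 9.21, m_value = 2.61,
                          provenance = "UCH-L5(1-240) urea unfolding, fluorescence + far-UV CD global fit"),
      uchl5_fluorescence = list(dg_h2o = 9.56, m_value = 2.73,
                                provenance = "UCH-L5(1-240) urea unfolding, intrinsic fluorescence"),
      uchl5_cd = list(dg_h2o = 9.05, m_value = 2.60,
                      provenance = "UCH-L5(1-240) urea unfolding, far-UV CD"),
      uchl1 = list(dg_h2o = 8.83, m_value = 2.95,
                   provenance = "UCH-L1 native-to-intermediate transition, global fit"),
      uchl3 = list(dg_h2o = 7.11, m_value = 2.28,
                   provenance = "UCH-L3 urea unfolding, fluorescence")
    ),
    chevron = list(
      uchl5_phase1 = list(kf_h2o = 0.14, mf = -1.09, ku_h2o = 8.1e-9, mu = 1.88,
                          provenance = "UCH-L5(1-240) slowest (dominant) kinetic phase"),
      uchl5_phase2 = list(kf_h2o = 0.80, mf = -0.82, ku_h2o = 1.9e-6, mu = 1.41,
                          provenance = "UCH-L5(1-240) kinetic phase 2"),
      uchl5_phase3 = list(kf_h2o = 10.3, mf = -0.96, ku_h2o = 3.1e-4, mu = 1.07,
                          provenance = "UCH-L5(1-240) kinetic phase 3"),
      uchl5_phase4 = list(kf_h2o = 1120, mf = -1.65, ku_h2o = 3.1e-2, mu = 0.81,
                          provenance = "UCH-L5(1-240) fastest kinetic phase"),
      uchl1 = list(kf_h2o = 0.3, mf = -1.06, ku_h2o = 7.6e-5, mu = 0.74,
                   provenance = "UCH-L1 slowest kinetic phase"),
      uchl3 = list(kf_h2o = 49, mf = -1.28, ku_h2o = 2.6e-4, mu = 0.83,
                   provenance = "UCH-L3 slowest kinetic phase")
    ),
    binding = list(
      uchl1 = list(dh0 = -5.63, ds0 = 11.28, dcp = -0.53, kd_um = 0.26,
                   provenance = "UCH-L1 + ubiquitin, variable-temperature ITC global fit (25 C reference)"),
      uchl3 = list(dh0 = -12.26, ds0 = -13.33, dcp = -0.72, kd_um = 0.85,
                   provenance = "UCH-L3 + ubiquitin, variable-temperature ITC global fit (25 C reference)")
    )
  )
}

#' Simulate an equilibrium denaturant titration
#'
#' Spectra are built from two Gaussian basis bands — a native band and a
#' red-shifted denatured band — whose weights follow the two-state
#' population [fraction_denatured()], with linear native/denatured baseline
#' multipliers. The default design mirrors a 41-aliquot urea gradient read
#' at 121 wavelengths.
#'
#' @param dg_h2o,m_value Two-state parameters (defaults: the UCH-L5 global
#'   fit preset).
#' @param denaturant Denaturant grid, M.
#' @param wavelengths Recorded wavelengths, nm.
#' @param centers,widths,heights Gaussian band centres/widths/heights for
#'   (native, denatured).
#' @param baseline_slopes Linear dependence of each band amplitude on
#'   denaturant (per M, relative).
#' @param noise_cv Proportional Gaussian noise (sd as a fraction of the
#'   local signal); default 1%.
#' @param seed RNG seed.
#' @param conditions A [fold_conditions()] object.
#' @return List with `series` (a [titration_series()]) and `truth`.
#' @export
simulate_equilibrium_titration <- function(dg_h2o = 9.21, m_value = 2.61,
                                           denaturant = seq(0, 6, length.out = 41),
                                           wavelengths = seq(300, 420, by = 1),
                                           centers = c(330, 350),
                                           widths = c(25, 30),
                                           heights = c(1, 0.55),
                                           baseline_slopes = c(-0.01, 0.01),
                                           noise_cv = 0.01, seed = 1,
                                           conditions = fold_conditions()) {
  fd <- fraction_denatured(dg_h2o, m_value, denaturant, conditions)
  band <- function(center, width) exp(-((wavelengths - center)^2) / (2 * width^2))
  native <- heights[1L] * band(centers[1L], widths[1L])
  denatured <- heights[2L] * band(centers[2L], widths[2L])
  m <- outer(native, (1 + baseline_slopes[1L] * denaturant) * (1 - fd)) +
    outer(denatured, (1 + baseline_slopes[2L] * denaturant) * fd)
  if (noise_cv > 0) {
    scale <- max(abs(m))
    m <- with_seed(seed, m + matrix(stats::rnorm(length(m), 0, noise_cv * scale),
                                    nrow(m)))
  }
  list(
    series = titration_series(denaturant, m, channels = wavelengths,
                              probe = "fluorescence"),
    truth = list(dg_h2o = dg_h2o, m_value = m_value, d50 = dg_h2o / m_value,
                 noise_cv = noise_cv, seed = seed)
  )
}

#' Simulate a stopped-flow kinetic trace
#'
#' Sum of exponentials with an offset, sampled on a log-spaced grid starting
#' at the dead time, with proportional Gaussian noise.
#'
#' @param rates Phase rates, s^-1.
#' @param amplitudes Phase amplitudes (same length).
#' @param offset Signal offset.
#' @param t_max Last observation time, s; defaults to 5 / min(rates).
#' @param n_points Number of samples.
#' @param dead_time Instrument dead time, s.
#' @param final_denaturant Final denaturant concentration, M (metadata).
#' @param noise_cv Proportional noise level.
#' @param seed RNG seed.
#' @return List with `trace` (a [kinetic_trace()]) and `truth`.
#' @export
simulate_kinetic_trace <- function(rates, amplitudes, offset = 1,
                                   t_max = NULL, n_points = 400,
                                   dead_time = 0.002,
                                   final_denaturant = NA_real_,
                                   noise_cv = 0.01, seed = 1) {
  stopifnot(length(rates) == length(amplitudes), all(rates > 0))
  if (is.null(t_max)) t_max <- 5 / min(rates)
  times <- exp(seq(log(dead_time), log(t_max), length.out = n_points))
  y <- offset + colSums(amplitudes * exp(-outer(rates, times)))
  if (noise_cv > 0) {
    y <- with_seed(seed, y + stats::rnorm(length(y), 0, noise_cv * max(abs(y))))
  }
  list(
    trace = kinetic_trace(times, y, final_denaturant, dead_time),
    truth = list(rates = rates, amplitudes = amplitudes, offset = offset,
                 noise_cv = noise_cv, seed = seed)
  )
}

#' Simulate a chevron dataset
#'
#' Observed rates from the two-state chevron equation on refolding and
#' unfolding arms, with log-normal multiplicative noise (errors on rates are
#' proportional, so noise is applied on the log scale).
#'
#' @param kf_h2o,mf,ku_h2o,mu Chevron parameters (defaults: slowest UCH-L5
#'   phase preset).
#' @param d_refold,d_unfold Denaturant grids of the two arms, M.
#' @param noise_lnsd Standard deviation of the noise on ln(k_obs); default
#'   5%.
#' @param seed RNG seed.
#' @param conditions A [fold_conditions()] object.
#' @return List with `data` (data frame `denaturant`, `k_obs`, `branch`) and
#'   `truth` (including the derived dg, m_kin, d50).
#' @export
simulate_chevron <- function(kf_h2o = 0.14, mf = -1.09, ku_h2o = 8.1e-9,
                             mu = 1.88,
                             d_refold = seq(0.5, 3.0, length.out = 15),
                             d_unfold = seq(4.0, 8.0, length.out = 15),
                             noise_lnsd = 0.05, seed = 3,
                             conditions = fold_conditions()) {
  d <- c(d_refold, d_unfold)
  branch <- rep(c("refolding", "unfolding"), c(length(d_refold), length(d_unfold)))
  k <- chevron_kobs(kf_h2o, mf, ku_h2o, mu, d, conditions)
  if (noise_lnsd > 0) {
    k <- with_seed(seed, k * exp(stats::rnorm(length(k), 0, noise_lnsd)))
  }
  dg <- delta_g_from_rates(kf_h2o, ku_h2o, conditions)
  list(
    data = data.frame(denaturant = d, k_obs = k, branch = branch),
    truth = list(kf_h2o = kf_h2o, mf = mf, ku_h2o = ku_h2o, mu = mu,
                 dg = dg, m_kin = mu - mf, d50 = dg / (mu - mf),
                 noise_lnsd = noise_lnsd, seed = seed)
  )
}

#' Simulate an interrupted-refolding (double-jump) series
#'
#' Refolding proceeds through the linear scheme A (denatured) <-> B
#' (intermediate) <-> C (native), propagated exactly via the rate-matrix
#' eigendecomposition for each aging time. The second jump back to
#' denaturing conditions converts each folded species into an unfolding
#' exponential whose amplitude is proportional to that species' population
#' at t_age.
#'
#' @param k_ab,k_ba,k_bc,k_cb Microscopic refolding-scheme rates, s^-1.
#' @param aging_times Aging-time grid, s; default 8 log-spaced points
#'   between 10 ms and 100 s.
#' @param unfold_rates Unfolding rates of species (B, C) after the second
#'   jump, s^-1.
#' @param responses Spectroscopic response per unit population of (B, C).
#' @param final_denaturant Final denaturant after the second jump, M.
#' @param offset Signal offset.
#' @param n_points Samples per trace.
#' @param noise_cv Proportional noise on each trace.
#' @param seed RNG seed.
#' @return List with `series` (an [interrupted_refolding_series()]) and
#'   `truth` (rates, populations at each aging time, unfold rates).
#' @export
simulate_interrupted_refolding <- function(k_ab = 0.03, k_ba = 0.003,
                                           k_bc = 0.3, k_cb = 0.03,
                                           aging_times = exp(seq(log(0.01), log(100),
                                                                 length.out = 8)),
                                           unfold_rates = c(5, 0.5),
                                           responses = c(1, 1),
                                           final_denaturant = 4.64,
                                           offset = 0.2, n_points = 300,
                                           noise_cv = 0.02, seed = 11) {
  rel <- three_state_relaxation(k_ab, k_ba, k_bc, k_cb, p0 = c(1, 0, 0))
  pops <- rel$populations(aging_times)   # n x 3
  t_max <- 5 / min(unfold_rates)
  dead <- 0.002
  times <- exp(seq(log(dead), log(t_max), length.out = n_points))
  traces <- with_seed(seed, lapply(seq_along(aging_times), function(i) {
    amp_b <- responses[1L] * pops[i, "B"]
    amp_c <- responses[2L] * pops[i, "C"]
    y <- offset + amp_b * exp(-unfold_rates[1L] * times) +
      amp_c * exp(-unfold_rates[2L] * times)
    if (noise_cv > 0) y <- y + stats::rnorm(length(y), 0, noise_cv * max(abs(y)))
    kinetic_trace(times, y, final_denaturant, dead)
  }))
  list(
    series = interrupted_refolding_series(aging_times, traces),
    truth = list(rates = c(k_ab = k_ab, k_ba = k_ba, k_bc = k_bc, k_cb = k_cb),
                 relaxation_rates = rel$relaxation_rates,
                 populations = pops, unfold_rates = unfold_rates,
                 responses = responses, noise_cv = noise_cv, seed = seed)
  )
}

#' Simulate per-residue HDX intensity decays
#'
#' Observed exchange rates are `k_int / 10^log_pf` per residue; intensities
#' decay exponentially from 1 with proportional Gaussian noise on a
#' log-spaced sampling grid scaled to each residue's decay.
#'
#' @param sequence One-letter sequence.
#' @param log_pf Named or positional vector of log10 protection factors for
#'   the residues to simulate (names = residue indices; defaults to residues
#'   2..N excluding prolines).
#' @param n_times Time points per residue.
#' @param pd,temperature Exchange conditions.
#' @param noise_cv Proportional intensity noise.
#' @param seed RNG seed.
#' @return List with `series_list` (named list of `times`/`intensities`,
#'   ingestible by [hdx_protection_factors()]) and `truth`.
#' @export
simulate_hdx_series <- function(sequence, log_pf, n_times = 12, pd = 8.0,
                                temperature = 298, noise_cv = 0.05, seed = 2) {
  seq_vec <- strsplit(sequence, "")[[1]]
  if (is.null(names(log_pf))) {
    idx_all <- setdiff(2:length(seq_vec), which(seq_vec == "P"))
    stopifnot(length(log_pf) <= length(idx_all))
    names(log_pf) <- idx_all[seq_along(log_pf)]
  }
  idx <- as.integer(names(log_pf))
  ref <- hdx_reference_table()
  k_int <- intrinsic_exchange_rate(sequence, idx, pd = pd,
                                   temperature = temperature, reference = ref)
  k_obs <- k_int / 10^log_pf
  series_list <- with_seed(seed, {
    out <- lapply(seq_along(idx), function(i) {
      times <- exp(seq(log(0.05 / k_obs[i]), log(5 / k_obs[i]),
                       length.out = n_times))
      y <- exp(-k_obs[i] * times)
      if (noise_cv > 0) y <- pmax(y + stats::rnorm(n_times, 0, noise_cv), 0)
      list(times = times, intensities = y)
    })
    names(out) <- names(log_pf)
    out
  })
  list(series_list = series_list,
       truth = list(log_pf = log_pf, k_int = k_int, k_obs = k_obs,
                    noise_cv = noise_cv, seed = seed))
}

#' Simulate a CD melting curve
#'
#' Gibbs-Helmholtz two-state melt with linear native/denatured baselines and
#' additive Gaussian noise.
#'
#' @param tm Melting temperature, K.
#' @param dh_m van't Hoff enthalpy at Tm, kcal/mol.
#' @param dcp Heat-capacity change, kcal/mol/K.
#' @param temperatures Scan grid, K; default 25-80 C at 0.5 K steps.
#' @param baselines Named vector (n_int, n_slope, d_int, d_slope).
#' @param noise_frac Noise sd as a fraction of the signal span; default 1%.
#' @param seed RNG seed.
#' @param ligand Optional ligand label.
#' @return List with `curve` (a [melt_curve()]) and `truth`.
#' @export
simulate_melt_curve <- function(tm = 328, dh_m = 100, dcp = 0,
                                temperatures = seq(298.15, 353.15, by = 0.5),
                                baselines = c(n_int = -20, n_slope = 0.01,
                                              d_int = -4, d_slope = 0.005),
                                noise_frac = 0.01, seed = 4, ligand = NULL) {
  r_kcal <- 1.9872e-3
  dg <- gibbs_helmholtz(dh_m, tm, dcp, temperatures)
  fn <- stats::plogis(dg / (r_kcal * temperatures))
  y <- (baselines["n_int"] + baselines["n_slope"] * temperatures) * fn +
    (baselines["d_int"] + baselines["d_slope"] * temperatures) * (1 - fn)
  y <- unname(y)
  if (noise_frac > 0) {
    span <- diff(range(y))
    y <- with_seed(seed, y + stats::rnorm(length(y), 0, noise_frac * span))
  }
  list(curve = melt_curve(temperatures, y, ligand = ligand),
       truth = list(tm = tm, dh_m = dh_m, dcp = dcp, baselines = baselines,
                    noise_frac = noise_frac, seed = seed))
}

#' Simulate a one-site ITC isotherm
#'
#' Heats from [one_site_expected_heats()] (perfusion-cell displacement
#' bookkeeping) with additive Gaussian noise scaled to the largest
#' injection heat.
#'
#' @param ka Association constant, M^-1.
#' @param dh Binding enthalpy, kcal/mol.
#' @param isotherm Geometry from [itc_isotherm()] (heats ignored); default:
#'   27.5 uM cell, 275 uM syringe, 200 uL cell, 19 x 2 uL injections.
#' @param offset_heat Constant dilution heat per injection, ucal.
#' @param noise_frac Noise sd as a fraction of max |heat|; default 2%.
#' @param seed RNG seed.
#' @return List with `isotherm` (heats filled in) and `truth`.
#' @export
simulate_itc_isotherm <- function(ka = 3.85e6, dh = -5.63,
                                  isotherm = itc_isotherm(27.5, 275),
                                  offset_heat = 0, noise_frac = 0.02,
                                  seed = 6) {
  q <- one_site_expected_heats(isotherm, ka, dh, offset_heat = offset_heat)
  if (noise_frac > 0) {
    q <- with_seed(seed, q + stats::rnorm(length(q), 0, noise_frac * max(abs(q))))
  }
  out <- isotherm
  out$heats <- q
  list(isotherm = out,
       truth = list(ka = ka, dh = dh, offset_heat = offset_heat,
                    noise_frac = noise_frac, seed = seed))
}

#' Simulate a variable-temperature ITC series
#'
#' Per-temperature Ka and dH follow the constant-dCp model used by
#' [global_fit_temperature_series()]; one isotherm is generated per
#' temperature.
#'
#' @param dh0 Binding enthalpy at `t0`, kcal/mol.
#' @param ds0 Binding entropy at `t0`, cal/mol/K.
#' @param dcp Heat-capacity change, kcal/mol/K.
#' @param temperatures Experiment temperatures, K; default 20/25/30/37 C.
#' @param t0 Reference temperature, K.
#' @param isotherm Shared cell geometry.
#' @param noise_frac Heat noise level per isotherm.
#' @param seed Base RNG seed (one substream per temperature).
#' @return List with `isotherms`, `per_temperature` ground-truth data frame
#'   (`temperature`, `ka`, `dh`), and `truth`.
#' @export
simulate_itc_temperature_series <- function(dh0 = -5.63, ds0 = 11.28,
                                            dcp = -0.53,
                                            temperatures = c(293.15, 298.15,
                                                             303.15, 310.15),
                                            t0 = 298.15,
                                            isotherm = itc_isotherm(27.5, 275),
                                            noise_frac = 0.03, seed = 8) {
  r_kcal <- 1.9872e-3
  dh_t <- dh0 + dcp * (temperatures - t0)
  ds_t <- ds0 / 1000 + dcp * log(temperatures / t0)
  dg_t <- dh_t - temperatures * ds_t
  ka_t <- exp(-dg_t / (r_kcal * temperatures))
  isotherms <- lapply(seq_along(temperatures), function(i) {
    geom <- isotherm
    geom$temperature <- temperatures[i]
    simulate_itc_isotherm(ka_t[i], dh_t[i], geom, noise_frac = noise_frac,
                          seed = seed + i)$isotherm
  })
  list(isotherms = isotherms,
       per_temperature = data.frame(temperature = temperatures, ka = ka_t,
                                    dh = dh_t),
       truth = list(dh0 = dh0, ds0 = ds0, dcp = dcp, t0 = t0,
                    noise_frac = noise_frac, seed = seed))
}
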