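test_that("denatured fraction follows the linear extrapolation model", {
  # midpoint symmetry at D = dG/m for several parameter sets
  for (p in list(c(9.21, 2.61), c(8.83, 2.95), c(7.11, 2.28))) {
    expect_equal(fraction_denatured(p[1], p[2], p[1] / p[2]), 0.5,
                 tolerance = 1e-12)
  }
  # global-fit parameters put the midpoint at the reported 3.53 M
  expect_equal(fraction_denatured(9.21, 2.61, 3.53), 0.500, tolerance = 0.003)
  # native baseline: essentially no denatured molecules in water
  expect_lt(fraction_denatured(9.21, 2.61, 0), 2e-7)
  # strictly increasing in denaturant and decreasing in stability
  d <- seq(0, 8, by = 0.1)
  expect_true(all(diff(fraction_denatured(9.21, 2.61, d)) > 0))
  dgs <- seq(12, 2, by = -0.5)
  expect_true(all(diff(sapply(dgs, fraction_denatured, m_value = 2.6,
                              denaturant = 3)) > 0))
  expect_error(fraction_denatured(9, -1, 3), "m_value")
})

test_that("SVD of a titration matrix satisfies the decomposition identities", {
  # rank-1 noiseless outer product has exactly one nonzero singular value
  u <- exp(-((300:420) - 340)^2 / 800)
  v <- seq(1, 2, length.out = 41)
  sv1 <- svd_decompose(outer(u, v))
  expect_equal(sum(sv1$d > 1e-10 * sv1$d[1]), 1L)
  expect_equal(sv1$n_significant, 1L)

  # two basis spectra weighted by a two-state population: exactly rank 2
  d <- seq(0, 6, length.out = 41)
  fd <- fraction_denatured(9.21, 2.61, d)
  m <- outer(u, 1 - fd) + outer(exp(-((300:420) - 360)^2 / 1200), fd)
  sv2 <- svd_decompose(m)
  expect_equal(sum(sv2$d > 1e-10 * sv2$d[1]), 2L)

  # full-rank reconstruction to machine precision
  set.seed(1)
  mm <- matrix(rnorm(30 * 12), 30)
  sv <- svd_decompose(mm)
  rec <- sv$u %*% diag(sv$d) %*% t(sv$v)
  expect_lt(norm(mm - rec, "F") / norm(mm, "F"), 1e-12)

  expect_warning(svd_decompose(matrix(1, 5, 5)), "degenerate")
})

test_that("autocorrelation threshold counts two components for a two-state titration", {
  sim <- simulate_equilibrium_titration(noise_cv = 0.01, seed = 1)
  sv <- svd_decompose(sim$series)
  expect_equal(count_significant_components(sv, 0.8), 2L)

  # pure noise carries no contiguous significant component
  set.seed(7)
  noise <- matrix(rnorm(121 * 41), 121)
  expect_equal(svd_decompose(noise)$n_significant, 0L)

  # component count is invariant to positive rescaling of the matrix
  sv_scaled <- svd_decompose(sim$series$signal_matrix * 137.2)
  expect_equal(sv_scaled$n_significant, sv$n_significant)

  expect_error(count_significant_components(sv, 1.2), "threshold")
})

test_that("global two-state fit recovers generating parameters", {
  # noiseless: exact recovery
  sim0 <- simulate_equilibrium_titration(noise_cv = 0)
  f0 <- fit_two_state_equilibrium(sim0$series)
  expect_equal(f0$dg_h2o, 9.21, tolerance = 1e-6)
  expect_equal(f0$m_value, 2.61, tolerance = 1e-6)
  expect_equal(f0$d50 * f0$m_value, f0$dg_h2o, tolerance = 1e-9)

  # instrument-grade noise: recovery within the documented bands
  sim <- simulate_equilibrium_titration(noise_cv = 0.005, seed = 1)
  f <- fit_two_state_equilibrium(sim$series)
  expect_lt(abs(f$dg_h2o - 9.21), 0.3)
  expect_lt(abs(f$m_value - 2.61), 0.1)
  expect_true(all(is.finite(f$se)))

  # fluorescence-style parameter set reports d50 = dG/m near 3.50 M
  simf <- simulate_equilibrium_titration(dg_h2o = 9.56, m_value = 2.73,
                                         noise_cv = 0.005, seed = 2)
  ff <- fit_two_state_equilibrium(simf$series)
  expect_equal(ff$d50, 3.50, tolerance = 0.02)
})

test_that("shared-thermo global fit agrees with single-series fits on clean data", {
  s1 <- simulate_equilibrium_titration(noise_cv = 0)$series
  s2 <- simulate_equilibrium_titration(noise_cv = 0, centers = c(222, 240),
                                       wavelengths = seq(210, 250, by = 1))$series
  s2$probe <- "far-UV CD"
  joint <- fit_two_state_equilibrium(list(s1, s2))
  sep <- fit_two_state_equilibrium(list(s1, s2), share_thermo = FALSE)
  expect_equal(joint$dg_h2o, sep[[1]]$dg_h2o, tolerance = 1e-6)
  expect_equal(joint$m_value, sep[[2]]$m_value, tolerance = 1e-6)
})

test_that("unbracketed transitions are reported as non-convergence", {
  # midpoint at 8 M but data stop at 3 M: no transition in range
  sim <- simulate_equilibrium_titration(dg_h2o = 16, m_value = 2,
                                        denaturant = seq(0, 3, length.out = 21),
                                        noise_cv = 0.002, seed = 5)
  expect_error(fit_two_state_equilibrium(sim$series), "not|transition")
})

test_that("emission-maximum wavelength follows the same two-state model", {
  d <- seq(0, 6, length.out = 41)
  fd <- fraction_denatured(9.21, 2.61, d)
  lmax <- 330 * (1 - fd) + 350 * fd
  f <- fit_lambda_max(d, lmax)
  expect_equal(f$dg_h2o, 9.21, tolerance = 1e-6)
  expect_equal(f$m_value, 2.61, tolerance = 1e-6)

  # lambda-max extracted from spectra whose basis bands shift 330 -> 350 nm
  sim <- simulate_equilibrium_titration(noise_cv = 0.002, seed = 9,
                                        centers = c(330, 350),
                                        heights = c(1, 1), widths = c(25, 25),
                                        baseline_slopes = c(0, 0))
  fx <- fit_lambda_max(d, extract_lambda_max(sim$series))
  expect_lt(abs(fx$d50 - 9.21 / 2.61), 0.05)

  # no transition: flat wavelength trace
  expect_error(fit_lambda_max(d, rep(340, 41)), "transition|resolvable")
})
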