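test_that("generators are byte-identical under a fixed seed", {
  a <- simulate_equilibrium_titration(seed = 5)
  b <- simulate_equilibrium_titration(seed = 5)
  expect_identical(a$series$signal_matrix, b$series$signal_matrix)

  t1 <- simulate_kinetic_trace(c(3, 0.2), c(1, 0.4), seed = 9)
  t2 <- simulate_kinetic_trace(c(3, 0.2), c(1, 0.4), seed = 9)
  expect_identical(t1$trace$signal, t2$trace$signal)

  i1 <- simulate_itc_isotherm(seed = 4)$isotherm$heats
  i2 <- simulate_itc_isotherm(seed = 4)$isotherm$heats
  expect_identical(i1, i2)

  # and the generators do not disturb the session RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(simulate_equilibrium_titration(seed = 5))
  expect_identical(rnorm(1), before)
})

test_that("preset registry stores self-consistent published parameter sets", {
  p <- uchfold_presets()
  # equilibrium midpoints dG/m land where the unfolding transitions sit
  d50 <- sapply(p$equilibrium, function(e) e$dg_h2o / e$m_value)
  expect_true(all(d50 > 2.5 & d50 < 4))
  expect_equal(unname(d50["uchl5_global"]), 3.53, tolerance = 0.01)
  # chevron presets: folding always faster than unfolding in water
  for (cv in p$chevron) expect_gt(cv$kf_h2o, cv$ku_h2o)
  # slowest-phase chevron at 0 M urea equals the sum of the two rates
  cv1 <- p$chevron$uchl5_phase1
  sim <- simulate_chevron(cv1$kf_h2o, cv1$mf, cv1$ku_h2o, cv1$mu,
                          d_refold = c(0, 1, 2, 3), noise_lnsd = 0)
  expect_equal(sim$data$k_obs[1], 0.14 + 8.1e-9, tolerance = 1e-12)
  # binding presets close the dG = dH - T dS identity near the reported Kd
  for (b in p$binding) {
    dg <- binding_free_energy(b$dh0, b$ds0, 298.15)
    expect_equal(kd_from_dg(dg, fold_conditions(temperature = 298.15)),
                 b$kd_um, tolerance = 0.02)
  }
})

test_that("fitted-parameter uncertainty grows with generator noise", {
  ses <- sapply(c(0.005, 0.01, 0.02, 0.05), function(cv) {
    sim <- simulate_equilibrium_titration(noise_cv = cv, seed = 17)
    fit_two_state_equilibrium(sim$series)$se[["dg_h2o"]]
  })
  expect_true(all(diff(ses) > 0))
})

test_that("noiseless datasets round-trip through their fitters", {
  # the package-wide integration property: generate -> fit -> recover
  eqf <- fit_two_state_equilibrium(simulate_equilibrium_titration(noise_cv = 0)$series)
  expect_equal(eqf$dg_h2o, 9.21, tolerance = 1e-6)

  chf <- fit_chevron(simulate_chevron(noise_lnsd = 0)$data)
  expect_equal(chf$mu, 1.88, tolerance = 1e-6)

  mf <- fit_thermal_two_state(simulate_melt_curve(noise_frac = 0)$curve)
  expect_equal(mf$tm, 328, tolerance = 1e-3)

  itf <- fit_one_site(simulate_itc_isotherm(noise_frac = 0)$isotherm)
  expect_equal(itf$ka, 3.85e6, tolerance = 1e-6)

  hx <- simulate_hdx_series(uch_test_sequence(), c(`5` = 4.5, `8` = 6.2),
                            noise_cv = 0)
  pf <- hdx_protection_factors(hx$series_list, uch_test_sequence())
  expect_equal(pf$log10_pf, c(4.5, 6.2), tolerance = 1e-6)
})
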