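test_that("one-site expected heats match a mass-balance bisection oracle", {
  geom <- itc_isotherm(27.5, 275)
  ka <- 3.85e6; dh <- -5.63
  q <- one_site_expected_heats(geom, ka, dh)

  # zero enthalpy: no heat
  expect_equal(one_site_expected_heats(geom, ka, 0), rep(0, 19))
  # saturating tail approaches the offset
  q_off <- one_site_expected_heats(geom, 1e9, dh, offset_heat = -0.3)
  expect_equal(q_off[19], -0.3, tolerance = 1e-3)

  # oracle: replay the same dilution bookkeeping but solve each injection's
  # free-ligand mass balance by bisection instead of the closed-form quadratic
  v0 <- 200e-6  # 200 uL in litres
  p <- 27.5e-6; x <- 0; kd <- 1 / ka; px_prev <- 0
  q_oracle <- numeric(19)
  for (i in 1:19) {
    v <- 2e-6  # 2 uL
    dil <- 1 - v / v0
    p <- p * dil
    x <- x * dil + 275e-6 * v / v0
    f <- function(xf) xf + p * xf / (kd + xf) - x  # free ligand balance
    xf <- uniroot(f, c(0, x), tol = 1e-18)$root
    px <- p * xf / (kd + xf)
    q_oracle[i] <- dh * v0 * (px - px_prev * dil) * 1e9
    px_prev <- px
  }
  expect_equal(q, q_oracle, tolerance = 1e-9)
})

test_that("one-site fits recover the binding parameters", {
  sim0 <- simulate_itc_isotherm(noise_frac = 0)
  f0 <- fit_one_site(sim0$isotherm)
  expect_equal(f0$ka, 3.85e6, tolerance = 1e-6)
  expect_equal(f0$dh, -5.63, tolerance = 1e-6)

  sim <- simulate_itc_isotherm(noise_frac = 0.02, seed = 6)
  f <- fit_one_site(sim$isotherm)
  expect_lt(abs(f$ka - 3.85e6) / 3.85e6, 0.20)
  expect_lt(abs(f$dh - (-5.63)) / 5.63, 0.05)

  # c-value far below the fittable window is flagged
  weak <- simulate_itc_isotherm(ka = 400, dh = -8, noise_frac = 0)
  expect_warning(fw <- fit_one_site(weak$isotherm), "c-value")
  expect_true(fw$c_flag)

  # flat isotherm: Ka unidentifiable
  flat <- itc_isotherm(27.5, 275, heats = rep(-0.2, 19))
  expect_error(fit_one_site(flat), "unidentifiable")
})

test_that("variable-temperature global fits recover the heat-capacity change", {
  fit_series <- function(sim) {
    per <- do.call(rbind, lapply(sim$isotherms, function(it) {
      f <- fit_one_site(it)
      data.frame(temperature = it$temperature, ka = f$ka, dh = f$dh)
    }))
    global_fit_temperature_series(per)
  }
  # strongly exothermic-compensated set
  g1 <- fit_series(simulate_itc_temperature_series(noise_frac = 0.03, seed = 8))
  expect_lt(abs(g1$dcp - (-0.53)) / 0.53, 0.15)
  # larger-|dCp| set: sign and magnitude
  g3 <- fit_series(simulate_itc_temperature_series(dh0 = -12.26, ds0 = -13.33,
                                                   dcp = -0.72,
                                                   noise_frac = 0.03, seed = 8))
  expect_lt(abs(g3$dcp - (-0.72)) / 0.72, 0.15)

  # dCp = 0 generator: fitted dCp consistent with zero
  g0 <- fit_series(simulate_itc_temperature_series(dcp = 0, noise_frac = 0.02,
                                                   seed = 12))
  expect_lt(abs(g0$dcp), 3 * max(g0$se["dcp"], 0.02))

  # exact round trip on noiseless per-temperature values
  clean <- simulate_itc_temperature_series(noise_frac = 0)
  ge <- global_fit_temperature_series(clean$per_temperature)
  expect_equal(ge$dh0, -5.63, tolerance = 1e-8)
  expect_equal(ge$ds0, 11.28, tolerance = 1e-6)
  expect_equal(ge$dcp, -0.53, tolerance = 1e-8)

  two_t <- clean$per_temperature[1:2, ]
  expect_error(global_fit_temperature_series(two_t), "unidentifiable")
})

test_that("binding free energy and dissociation constant follow the identities", {
  expect_equal(binding_free_energy(-5.63, 11.28, 298.15), -8.99, tolerance = 0.005)
  expect_equal(binding_free_energy(-12.26, -13.33, 298.15), -8.29, tolerance = 0.01)
  expect_equal(binding_free_energy(-7.5, 0), -7.5)

  cond25 <- fold_conditions(temperature = 298.15)
  expect_equal(kd_from_dg(-8.99, cond25), 0.26, tolerance = 0.02)
  expect_warning(kd0 <- kd_from_dg(0, cond25), "dG >= 0")
  expect_equal(kd0, 1e6)
  expect_equal(kd_from_dg(-rt(cond25) * log(1e6), cond25), 1.0, tolerance = 1e-9)
  # monotone in dG
  dgs <- seq(-12, -4, by = 0.5)
  expect_true(all(diff(sapply(dgs, kd_from_dg, conditions = cond25)) > 0))
})

test_that("enthalpy-entropy bookkeeping closes to machine precision", {
  clean <- simulate_itc_temperature_series(noise_frac = 0)
  g <- global_fit_temperature_series(clean$per_temperature)
  expect_equal(g$dg - g$dh0 + g$tds, 0, tolerance = 1e-9)
  # and the weaker-binding parameter set computes Kd near the reported one
  g3 <- global_fit_temperature_series(
    simulate_itc_temperature_series(dh0 = -12.26, ds0 = -13.33, dcp = -0.72,
                                    noise_frac = 0)$per_temperature)
  expect_equal(g3$kd_um, 0.85, tolerance = 0.02)
})
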