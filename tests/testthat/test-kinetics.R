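test_that("multi-exponential fits select the generating phase count", {
  # noiseless double exponential: phases and rates exact
  tr0 <- simulate_kinetic_trace(c(10, 0.8), c(0.8, 0.2), noise_cv = 0)$trace
  f0 <- fit_multiexponential(tr0)
  expect_equal(f0$n_phases, 2L)
  expect_equal(f0$rates, c(10, 0.8), tolerance = 1e-6)
  # amplitudes refer to the first observed point (the dead time)
  expect_equal(f0$amplitudes, c(0.8, 0.2) * exp(-c(10, 0.8) * 0.002),
               tolerance = 1e-6)

  # rates like the two intermediate stopped-flow phases, 4:1 amplitudes, 1% noise
  tr <- simulate_kinetic_trace(c(10.3, 0.80), c(0.8, 0.2),
                               noise_cv = 0.01, seed = 7)$trace
  f <- fit_multiexponential(tr)
  expect_equal(f$n_phases, 2L)
  expect_lt(abs(f$rates[1] - 10.3) / 10.3, 0.10)
  expect_lt(abs(f$rates[2] - 0.80) / 0.80, 0.10)

  # offset-only trace is forced to one phase with negligible amplitude
  flat <- kinetic_trace(seq(0.002, 1, length.out = 120), rep(5, 120))
  expect_warning(ff <- fit_multiexponential(flat), "flat")
  expect_equal(ff$n_phases, 1L)
  expect_true(ff$flat)
  expect_lt(abs(ff$amplitudes[1]), 1e-8)
})

test_that("extra-sum-of-squares F test follows its closed form", {
  # equal residuals: no support for the complex model
  ft0 <- extra_ss_f_test(1.3, 3, 1.3, 5, 80)
  expect_equal(ft0$F, 0)
  expect_false(ft0$accept_complex)

  # worked arithmetic: ((2-1)/2) / (1/100) = 50
  ft <- extra_ss_f_test(2.0, 3, 1.0, 5, 105)
  expect_equal(ft$F, 50.0, tolerance = 1e-12)
  expect_true(ft$accept_complex)
  expect_equal(ft$p_value, pf(50, 2, 100, lower.tail = FALSE), tolerance = 1e-12)

  # tiny improvement stays below the 5% critical value
  ft2 <- extra_ss_f_test(1.0, 3, 0.99, 5, 50)
  expect_false(ft2$accept_complex)

  # a worse complex fit can never be accepted
  ft3 <- extra_ss_f_test(1.0, 3, 1.1, 5, 50)
  expect_equal(ft3$F, 0)
  expect_false(ft3$accept_complex)
})

test_that("chevron equation reproduces hand-evaluated observed rates", {
  # in water the observed rate is the sum of the two arms
  expect_equal(chevron_kobs(0.14, -1.09, 8.1e-9, 1.88, 0), 0.14 + 8.1e-9,
               tolerance = 1e-12)
  # slowest-phase parameters at 6 M urea (hand-evaluated closed form)
  expect_equal(chevron_kobs(0.14, -1.09, 8.1e-9, 1.88, 6), 1.5169,
               tolerance = 1e-3)
  # the two arms cross exactly at D* = RT ln(kf/ku) / (mu - mf)
  rt298 <- rt(fold_conditions())
  dstar <- rt298 * log(0.14 / 8.1e-9) / (1.88 - (-1.09))
  expect_equal(0.14 * exp(-1.09 * dstar / rt298),
               8.1e-9 * exp(1.88 * dstar / rt298), tolerance = 1e-9)
})

test_that("free energy from rates matches the published kinetic tables", {
  expect_equal(delta_g_from_rates(1, 1), 0)
  # slowest phase: RT ln(0.14 / 8.1e-9)
  expect_equal(delta_g_from_rates(0.14, 8.1e-9), 9.87, tolerance = 0.005)
  # cross-paralog values
  expect_equal(delta_g_from_rates(49, 2.6e-4), 7.19, tolerance = 0.01)
  expect_equal(delta_g_from_rates(0.3, 7.6e-5), 4.90, tolerance = 0.01)
  # antisymmetry under folding/unfolding exchange
  expect_equal(delta_g_from_rates(0.14, 8.1e-9),
               -delta_g_from_rates(8.1e-9, 0.14), tolerance = 1e-12)
})

test_that("chevron fits recover generating parameters and derived thermodynamics", {
  # noiseless: exact recovery and exact reproduction of k_obs
  ch0 <- simulate_chevron(noise_lnsd = 0)
  f0 <- fit_chevron(ch0$data)
  expect_equal(f0$kf_h2o, 0.14, tolerance = 1e-6)
  expect_equal(f0$mf, -1.09, tolerance = 1e-6)
  expect_equal(log10(f0$ku_h2o), log10(8.1e-9), tolerance = 1e-6)
  expect_equal(predict(f0, ch0$data$denaturant), ch0$data$k_obs,
               tolerance = 1e-8)
  # derived-quantity identities hold exactly
  expect_equal(f0$m_kin, f0$mu - f0$mf, tolerance = 1e-12)
  expect_equal(f0$d50 * f0$m_kin, f0$dg, tolerance = 1e-9)
  expect_equal(f0$dg, rt(fold_conditions()) * log(f0$kf_h2o / f0$ku_h2o),
               tolerance = 1e-9)

  # 5% log-normal noise: water-extrapolated unfolding rate is soft, dG less so
  ch <- simulate_chevron(noise_lnsd = 0.05, seed = 3)
  f <- fit_chevron(ch$data)
  expect_lt(abs(log10(f$ku_h2o) - log10(8.1e-9)), 0.5)
  expect_lt(abs(f$dg - ch$truth$dg), 0.6)

  # single-arm data name the missing arm
  refold_only <- ch0$data[ch0$data$branch == "refolding", ]
  expect_error(fit_chevron(refold_only), "unfolding arm")
  unfold_only <- ch0$data[ch0$data$branch == "unfolding", ]
  expect_error(fit_chevron(unfold_only), "refolding arm")
})

test_that("fastest-phase parameters expose the published m_kin inconsistency", {
  # the four fitted phase-4 parameters imply d50 = RT ln(kf/ku)/(mu - mf)
  # = 2.52 M, consistent with the printed midpoint but not with the printed
  # m_kin of 1.73 (|mf| + mu = 2.46): regression-documented here
  rt298 <- rt(fold_conditions())
  dg4 <- delta_g_from_rates(1120, 3.1e-2)
  m_kin4 <- 0.81 - (-1.65)
  expect_equal(dg4 / m_kin4, 2.52, tolerance = 0.01)
  expect_equal(m_kin4, 2.46, tolerance = 1e-12)
  expect_gt(abs(m_kin4 - 1.73), 0.7)
  # and d50 computed with the printed m_kin would NOT match the printed d50
  expect_gt(abs(dg4 / 1.73 - 2.52), 1)
})
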