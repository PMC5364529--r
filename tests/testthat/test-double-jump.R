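test_that("mixing arithmetic reproduces the dilution bookkeeping", {
  # 10:1 buffer:protein, 20 uM protein in 8 M urea -> 1.8 uM, 0.73 M
  one <- final_concentration(list(list(added_denaturant = 0, ratio_added = 10,
                                       ratio_carried = 1)),
                             protein_start = 20, start_denaturant = 8)
  expect_equal(one$protein, 20 / 11, tolerance = 1e-12)
  expect_equal(one$denaturant, 8 / 11, tolerance = 1e-12)
  expect_equal(round(one$protein, 1), 1.8)

  # 7.7 M stock diluted 5:1 into refolding buffer, then 1:1 into 8 M urea
  two <- final_concentration(
    list(list(added_denaturant = 0, ratio_added = 5, ratio_carried = 1),
         list(added_denaturant = 8, ratio_added = 1, ratio_carried = 1)),
    protein_start = 20, start_denaturant = 7.7)
  expect_equal(two$denaturant[1], 7.7 / 6, tolerance = 1e-12)
  expect_equal(two$denaturant[2], (7.7 / 6 + 8) / 2, tolerance = 1e-12)
  expect_equal(two$denaturant[2], 4.64, tolerance = 0.005)

  expect_error(final_concentration(list(list(added_denaturant = 0,
                                             ratio_added = -1,
                                             ratio_carried = 1)), 20, 8),
               "positive")
})

test_that("shared-rate global fits recover the trace rates across aging times", {
  sim0 <- simulate_interrupted_refolding(noise_cv = 0)
  g0 <- global_fit_shared_rates(sim0$series, 2)
  expect_equal(g0$rates, sim0$truth$unfold_rates, tolerance = 1e-6)
  # noiseless shared fit equals independent per-trace fits
  ind <- fit_multiexponential(sim0$series$traces[[5]], max_phases = 2)
  expect_equal(g0$rates, ind$rates, tolerance = 1e-4)

  sim <- simulate_interrupted_refolding(noise_cv = 0.02, seed = 11)
  g <- global_fit_shared_rates(sim$series, 2)
  expect_lt(max(abs(g$rates - sim$truth$unfold_rates) / sim$truth$unfold_rates),
            0.15)

  single <- interrupted_refolding_series(sim0$series$aging_times[1],
                                         sim0$series$traces[1])
  expect_error(global_fit_shared_rates(single, 2), "3 aging times")
})

test_that("amplitude build-up fitting detects rates and sequential lags", {
  t_age <- exp(seq(log(0.05), log(60), length.out = 12))
  # exactly exponential build-up
  a <- 2 * (1 - exp(-0.5 * t_age))
  bu <- fit_amplitude_buildup(a, t_age)
  expect_equal(bu$buildup_rate[1], 0.5, tolerance = 1e-6)
  expect_false(bu$lag_flag[1])

  # sequential A -> B -> C end-species accumulation carries a lag
  k1 <- 0.03; k2 <- 0.3
  t2 <- exp(seq(log(0.5), log(300), length.out = 14))
  cpop <- 1 - (k2 * exp(-k1 * t2) - k1 * exp(-k2 * t2)) / (k2 - k1)
  bu2 <- fit_amplitude_buildup(rbind(cpop), t2)
  expect_true(bu2$lag_flag[1])

  # constant amplitude: no build-up rate
  bu3 <- fit_amplitude_buildup(rep(1.4, 12), t_age)
  expect_true(is.na(bu3$buildup_rate[1]))
})

test_that("three-state relaxation matches the analytic symmetric case", {
  rel <- three_state_relaxation(1, 1, 1, 1)
  expect_equal(rel$relaxation_rates, c(1, 3), tolerance = 1e-12)

  # detailed balance at equilibrium
  rel2 <- three_state_relaxation(0.3, 0.05, 0.2, 0.02)
  eq <- rel2$equilibrium
  expect_equal(eq[1] * 0.3, eq[2] * 0.05, tolerance = 1e-10)
  expect_equal(eq[2] * 0.2, eq[3] * 0.02, tolerance = 1e-10)

  # population conservation along the full time course
  tgrid <- exp(seq(log(1e-3), log(1e3), length.out = 100))
  pops <- rel2$populations(tgrid)
  expect_equal(unname(rowSums(pops)), rep(1, 100), tolerance = 1e-10)
  expect_true(all(pops > -1e-12))

  # relabelling A<->C with swapped rates leaves the relaxation spectrum fixed
  rel_fwd <- three_state_relaxation(0.11, 0.31, 0.07, 0.015)
  rel_rev <- three_state_relaxation(0.015, 0.07, 0.31, 0.11)
  expect_equal(rel_fwd$relaxation_rates, rel_rev$relaxation_rates,
               tolerance = 1e-10)

  expect_error(three_state_relaxation(0, 0, 0, 0), "zero")
})

test_that("analytic populations agree with numerical ODE propagation", {
  k <- c(k_ab = 0.04, k_ba = 0.004, k_bc = 0.25, k_cb = 0.02)
  rel <- three_state_relaxation(k[1], k[2], k[3], k[4])
  tgrid <- c(0, exp(seq(log(0.01), log(500), length.out = 60)))
  rhs <- function(t, p, parms) {
    list(c(-k[1] * p[1] + k[2] * p[2],
           k[1] * p[1] - (k[2] + k[3]) * p[2] + k[4] * p[3],
           k[3] * p[2] - k[4] * p[3]))
  }
  num <- deSolve::ode(c(1, 0, 0), tgrid, rhs, NULL,
                      rtol = 1e-12, atol = 1e-12)
  ana <- rel$populations(tgrid)
  expect_lt(max(abs(ana - num[, 2:4])), 1e-8)
})

test_that("linear three-state inference recovers microscopic rates", {
  t_age <- exp(seq(log(0.01), log(100), length.out = 8))
  truth <- c(0.03, 0.003, 0.3, 0.03)
  rel <- three_state_relaxation(truth[1], truth[2], truth[3], truth[4])
  amps <- t(rel$populations(t_age)[, 2:3])

  fit0 <- fit_linear_three_state(amps, t_age)
  expect_equal(unname(fit0$rates), truth, tolerance = 0.01)
  expect_equal(fit0$scheme_preference, "three-state")

  # heavy noise: order-of-magnitude recovery only
  set.seed(5)
  ampsn <- amps * (1 + matrix(rnorm(length(amps), 0, 0.10), 2))
  fitn <- fit_linear_three_state(ampsn, t_age)
  expect_true(all(fitn$rates / truth < 2 & fitn$rates / truth > 0.5))

  # data generated by a two-state scheme prefer the simpler scheme
  pop2 <- (0.05 / 0.055) * (1 - exp(-0.055 * t_age))
  fit2 <- fit_linear_three_state(rbind(pop2, 0.8 * pop2), t_age)
  expect_equal(fit2$scheme_preference, "two-state")
})

test_that("interrupted-refolding containers enforce a common final denaturant", {
  tr1 <- kinetic_trace(seq(0.002, 1, length.out = 50), rnorm(50), 4.64)
  tr2 <- kinetic_trace(seq(0.002, 1, length.out = 50), rnorm(50), 5.2)
  expect_error(interrupted_refolding_series(c(0.1, 1), list(tr1, tr2)),
               "same final denaturant")
})
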