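test_that("exchange decays are fitted or reported below detection", {
  # 12 log-spaced sampling points spanning ~5 decay lifetimes
  k_true <- 1e-4
  tgrid <- exp(seq(log(0.05 / k_true), log(5 / k_true), length.out = 12))
  # noiseless single exponential: exact rate
  f0 <- fit_exchange_decay(tgrid, exp(-k_true * tgrid))
  expect_equal(f0$k_obs, k_true, tolerance = 1e-6)
  expect_equal(f0$status, "ok")

  # 5% intensity noise: typical (median over seeds) accuracy ~10%
  errs <- sapply(1:10, function(sd) {
    sim <- simulate_hdx_series(uch_test_sequence(), c(`10` = 5),
                               noise_cv = 0.05, seed = sd)
    f <- fit_exchange_decay(sim$series_list[["10"]]$times,
                            sim$series_list[["10"]]$intensities)
    abs(f$k_obs - sim$truth$k_obs) / sim$truth$k_obs
  })
  expect_lt(median(errs), 0.10)
  expect_lt(max(errs), 0.30)

  # flat series: below detection with an upper bound instead of a rate
  ff <- fit_exchange_decay(tgrid, rep(0.98, 12) + c(0.001, rep(0, 11)))
  expect_equal(ff$status, "below_detection")
  expect_true(is.na(ff$k_obs))
  expect_true(ff$k_upper_bound > 0)
})

test_that("intrinsic rates follow the additive log-factor model", {
  s <- uch_test_sequence()
  # identical neighbours give identical rates: A-L-A at two places
  s2 <- "GALAGGALAG"
  expect_equal(intrinsic_exchange_rate(s2, 3), intrinsic_exchange_rate(s2, 8),
               tolerance = 1e-12)

  # base-catalysed regime: +1 pD unit multiplies the rate by ~10
  k7 <- intrinsic_exchange_rate(s, 10, pd = 7)
  k8 <- intrinsic_exchange_rate(s, 10, pd = 8)
  expect_equal(k8 / k7, 10, tolerance = 0.01)

  # invariant under sequence extension beyond nearest neighbours
  expect_equal(intrinsic_exchange_rate("GALAG", 3),
               intrinsic_exchange_rate("WWGALAGWW", 5), tolerance = 1e-12)

  # proline and out-of-range positions have no observable amide
  expect_error(intrinsic_exchange_rate(s, 15), "proline")
  expect_error(intrinsic_exchange_rate(s, 1), "no observable amide")
  expect_error(intrinsic_exchange_rate("GAXAG", 3), "unknown residue")
})

test_that("intrinsic rates agree with an independent implementation", {
  s <- uch_test_sequence()
  # six interior amides, skipping prolines
  no_amide <- which(strsplit(s, "")[[1]] == "P")
  idx <- setdiff(c(3, 6, 10, 22, 35, 40, 50, 58), no_amide)[1:6]
  for (i in idx) {
    expect_equal(intrinsic_exchange_rate(s, i, pd = 8.0, temperature = 298),
                 kint_oracle(s, i, 8.0, 298), tolerance = 0.05)
  }
  # and at a different temperature / pD
  expect_equal(intrinsic_exchange_rate(s, 22, pd = 7.2, temperature = 310),
               kint_oracle(s, 22, 7.2, 310), tolerance = 0.05)
})

test_that("protection factors are ratios with the documented edge handling", {
  p <- protection_factor(1, 1)
  expect_equal(p$pf, 1)
  expect_equal(p$log10_pf, 0)
  # top of the colour scale: k_int/k_obs = 1e8
  expect_equal(protection_factor(1, 1e-8)$log10_pf, 8, tolerance = 1e-12)
  # faster-than-intrinsic exchange is anomalous
  expect_true(protection_factor(1, 2)$anomalous)
  # scale invariance
  for (cc in c(1e-3, 1, 42)) {
    expect_equal(protection_factor(cc * 2, cc * 0.5)$pf,
                 protection_factor(2, 0.5)$pf, tolerance = 1e-12)
  }
  # below-detection decays give bounds
  pb <- protection_factor(1, NA_real_, k_upper_bound = 1e-6)
  expect_true(pb$bound)
  expect_equal(pb$log10_pf, 6, tolerance = 1e-12)
})

test_that("the per-residue pipeline recovers a synthetic protection landscape", {
  s <- uch_test_sequence()
  set.seed(3)
  lp <- runif(30, 3, 8)
  sim <- simulate_hdx_series(s, lp, noise_cv = 0.05, seed = 2)
  pf <- hdx_protection_factors(sim$series_list, s, pd = 8.0, temperature = 298)
  err <- pf$log10_pf - sim$truth$log_pf[as.character(pf$residue)]
  expect_lt(sqrt(mean(err^2)), 0.15)
  expect_true(all(pf$pf > 0))
})

test_that("profile comparison orders proteins by protection", {
  segs <- data.frame(segment = c("helix1", "sheet1"),
                     start = c(5, 20), end = c(15, 35))
  base <- data.frame(residue = 2:40, log10_pf = 5 + sin(2:40 / 5))
  profiles <- list(
    most = transform(base, log10_pf = log10_pf + 1),
    mid = base,
    least = transform(base, log10_pf = log10_pf - 1)
  )
  cmp <- compare_pf_profiles(profiles, segs)
  expect_equal(cmp$ordering, c("most", "mid", "least"))
  expect_equal(cmp$segment_medians[, "most"] - cmp$segment_medians[, "least"],
               c(helix1 = 2, sheet1 = 2), tolerance = 1e-12)

  # identical profiles give identical medians
  cmp2 <- compare_pf_profiles(list(a = base, b = base), segs)
  expect_equal(cmp2$segment_medians[, "a"], cmp2$segment_medians[, "b"])

  expect_error(compare_pf_profiles(profiles, segs[0, ]), "empty")
})
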