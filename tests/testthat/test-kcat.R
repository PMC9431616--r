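test_that("SASA is the 3/4 power of molecular weight", {
  expect_equal(sasa(1), 1)
  expect_equal(sasa(16), 8)
  expect_equal(sasa(31.09), 31.09^0.75)
  expect_error(sasa(0), "positive")
  expect_error(sasa(-2), "positive")
})

test_that("kcat assignment is exact at the anchor and scales as mw^(3/4)", {
  expect_equal(assign_kcat(31.09), 234000)
  expect_equal(assign_kcat(16 * 31.09), 8 * 234000)
  mws <- sort(runif(20, 1, 500))
  ks <- assign_kcat(mws)
  expect_true(all(diff(ks) > 0))   # monotone in mw
})

test_that("per-site turnover converts to enzyme-level day^-1", {
  expect_equal(convert_per_site_kcat(1, 1), 86400)
  expect_equal(convert_per_site_kcat(6.6, 2), 2 * 6.6 * 86400)
  expect_equal(convert_per_site_kcat(3.7, 8), 8 * 3.7 * 86400)
  expect_error(convert_per_site_kcat(-1, 2), "positive")
  expect_error(convert_per_site_kcat(1, 0), ">= 1")
})

test_that("Arrhenius temperature scaling is anchored and order-preserving", {
  sc <- temperature_scale(T_ref = 303, activation_energy = 50)
  expect_equal(temperature_scale_kcat(1000, 303, sc), 1000)
  expect_lt(temperature_scale_kcat(1000, 290, sc), 1000)
  # hand-evaluated scalar check
  ratio <- exp(-(50 / 0.008314) * (1 / 292 - 1 / 303))
  expect_equal(temperature_scale_kcat(1, 292, sc), ratio, tolerance = 1e-12)
  # multiplicative: ordering across enzymes preserved at any fixed T
  k1 <- c(100, 300, 900)
  k2 <- temperature_scale_kcat(k1, 285, sc)
  expect_equal(order(k2), order(k1))
  expect_equal(k2 / k1, rep(k2[1] / k1[1], 3))
  expect_error(temperature_scale_kcat(1, -3, sc), "positive")
})
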