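# Bespoke constraints: rubisco coexpression, ATP caps, nitrogenases.

test_that("ATP caps resolve from the table and from yield ratios", {
  expect_equal(atp_cap_spec("acetate")$cap, 54.0)
  expect_equal(atp_cap_spec("succinate")$cap, 45.7)
  expect_equal(atp_cap_spec("butyrate")$cap, 56.7)
  expect_equal(atp_cap_spec("p-coumarate")$cap, 85.4)
  expect_error(atp_cap_spec("glucose"), "unknown substrate")
  # equal yields reproduce the acetate reference exactly
  sp <- atp_cap_spec("x", v_psii_ace = 54, phi_s = 0.3, phi_ace = 0.3)
  expect_equal(sp$cap, 54)
  # cap ratios equal yield ratios
  s1 <- atp_cap_spec("a", v_psii_ace = 54, phi_s = 0.42, phi_ace = 0.3)
  s2 <- atp_cap_spec("b", v_psii_ace = 54, phi_s = 0.21, phi_ace = 0.3)
  expect_equal(s1$cap / s2$cap, 0.42 / 0.21)
})

test_that("applying a cap bounds the ATP synthase flux", {
  m <- apply_atp_cap(toy_model(), "p-coumarate")
  i <- match("ATPS", m$reactions$id)
  expect_equal(m$reactions$ub[i], 85.4)
  sol <- pfba_fluxes(m, 0.2, c(`p-coumarate` = 2))
  expect_lte(unname(sol$fluxes["ATPS"]), 85.4 + 1e-9)
})

test_that("the coexpression bracket evaluates to the analytic values", {
  spec <- rubisco_coexpression_spec(mu_max = 0.4, sum_vco2_max = 10)
  # bracket vanishes at the calibration point and at the origin
  expect_equal(eval_rubisco_coexpression(spec, 0.4, 10), 0)
  expect_equal(eval_rubisco_coexpression(spec, 0, 0), 0)
  # direct evaluation at mu_max/2 with no CO2 production
  expect_equal(eval_rubisco_coexpression(spec, 0.2, 0), 5 * 3.7 / 6.6)
})

test_that("the applied constraint holds with tight residual in solves", {
  m0 <- toy_model()
  spec <- calibrate_rubisco_coexpression(m0, "succinate", 3, tol = 1e-3)
  m <- apply_rubisco_coexpression(capped(m0), spec)
  # at a sub-maximal operating point the constraint forces form I flux
  mu <- 0.6 * spec$mu_max
  sol <- pfba_fluxes(m, mu, c(succinate = 3))
  w <- co2_producing_reactions(m)
  sum_vco2 <- sum(w * sol$fluxes[names(w)])
  implied <- eval_rubisco_coexpression(spec, mu, sum_vco2)
  vI <- unname(sol$fluxes["RBC_I"])
  expect_gte(vI, 0)
  # nonneg mode: v_I equals the clipped bracket (parsimony keeps it at
  # the floor); residual within solver precision
  expect_lt(abs(vI - max(0, implied)), 1e-6)
})

test_that("strict mode surfaces an infeasible negative bracket", {
  m0 <- toy_model()
  # force a large CO2 sum relative to the calibration: bracket < 0
  spec <- rubisco_coexpression_spec(mu_max = 1, sum_vco2_max = 0)
  m <- apply_rubisco_coexpression(capped(m0), spec, mode = "strict")
  # any operating point that produces CO2 now demands v_I < 0: infeasible
  expect_false(is_feasible(m, 0.1, c(succinate = 3),
                           on_failure = "infeasible"))
  # the nonneg default stays feasible at the same point
  m2 <- apply_rubisco_coexpression(capped(m0), spec, mode = "nonneg")
  expect_true(is_feasible(m2, 0.1, c(succinate = 3)))
})

test_that("parsimony expresses only the Mo nitrogenase in the wild type", {
  m <- capped(toy_model())
  sol <- max_growth(m, c(succinate = 5), tol = 1e-3, guard_scan = FALSE)
  expect_gt(unname(sol$fluxes["NFIX_Mo"]), 0.1)
  expect_lt(abs(unname(sol$fluxes["NFIX_V"])), 1e-6)
  expect_lt(abs(unname(sol$fluxes["NFIX_Fe"])), 1e-6)
})

test_that("mutant growth ordering follows the ATP cost of nitrogen fixation", {
  m0 <- toy_model()
  mus <- vapply(c("WT", "Mo", "V", "Fe"), function(s) {
    max_growth(capped(nitrogenase_mutant(m0, s)), c(succinate = 5),
               tol = 1e-3, guard_scan = FALSE, compute_fluxes = FALSE)$mu
  }, 0)
  expect_equal(mus[["WT"]], mus[["Mo"]], tolerance = 2e-3)
  expect_gt(mus[["Mo"]], mus[["V"]] + 1e-3)
  expect_gt(mus[["V"]], mus[["Fe"]] + 1e-3)
})
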