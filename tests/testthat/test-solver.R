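# Growth solving: LP assembly, feasibility, bisection, pFBA, flux ranges.

test_that("assembled LPs differ across mu only in coupling and the dilution pin", {
  m <- toy_model()
  lp1 <- assemble_lp(m, 0.1, c(succinate = 2))
  lp2 <- assemble_lp(m, 0.3, c(succinate = 2))
  diffs <- which(lp1$A != lp2$A, arr.ind = TRUE)
  coupled_species <- unique(unlist(lapply(m$reactions$mu_coupled, names)))
  expect_true(all(rownames(lp1$A)[diffs[, 1]] %in% coupled_species))
  j <- match("BIOMASS_DILUTION", lp1$ids)
  expect_equal(lp1$lb[j], 0.1); expect_equal(lp2$lb[j], 0.3)
  # mu-coupled entries scale linearly with mu
  expect_equal(lp2$A[diffs], 3 * lp1$A[diffs], tolerance = 1e-12)
})

test_that("solver breakdown is never reported as infeasibility", {
  # on_failure = "error" is the public contract; the conservative mode is
  # opt-in for bracketing only
  expect_error(is_feasible(toy_model(), -1), "nonnegative")
})

test_that("bisection matches the exhaustive grid scan across seeds", {
  step <- 5e-3
  for (seed in 1:5) {
    m <- capped(toy_model(seed))
    ub <- c(succinate = 3)
    sol <- max_growth(m, ub, tol = step, guard_scan = FALSE,
                      compute_fluxes = FALSE)
    scan <- grid_scan_mu(m, ub, step)
    expect_lt(abs(sol$mu - scan), step + 1e-9, label = paste("seed", seed))
  }
})

test_that("growth is monotone and saturating in the uptake bound", {
  m <- capped(toy_model())
  grid <- c(1, 2.5, 4, 6, 9)
  mus <- vapply(grid, function(u) {
    max_growth(m, c(succinate = u), tol = 1e-3, guard_scan = FALSE,
               compute_fluxes = FALSE)$mu
  }, 0)
  expect_true(all(diff(mus) > -1e-3))
  # plateau: the last step changes the growth rate by less than tol
  expect_lt(mus[5] - mus[4], 2e-3)
  # while the first step changes it a lot
  expect_gt(mus[2] - mus[1], 0.05)
})

test_that("pFBA solutions are parsimonious, balanced and bounded", {
  m <- capped(toy_model())
  ub <- c(succinate = 3)
  mu <- 0.15
  sol <- pfba_fluxes(m, mu, ub)
  expect_equal(sol$status, "optimal")
  expect_lt(sol$residual, 1e-6)
  expect_equal(unname(sol$fluxes["BIOMASS_DILUTION"]), mu, tolerance = 1e-8)
  lp <- assemble_lp(m, mu, ub)
  expect_true(all(sol$fluxes >= lp$lb[seq_along(sol$fluxes)] - 1e-6))
  expect_true(all(sol$fluxes <= lp$ub[seq_along(sol$fluxes)] + 1e-6))
  # any feasible point found without the objective has at least this
  # total flux
  r <- palme:::solve_lp_presolved(rep(0, ncol(lp$A)), lp$A, lp$b, lp$lb, lp$ub)
  expect_gte(sum(abs(r$x[seq_len(lp$n_rxn)])), sol$total_flux - 1e-6)
  expect_error(pfba_fluxes(m, 5, ub), "infeasible")
})

test_that("flux ranges pin the dilution and expose blocked reactions", {
  m <- capped(toy_model())
  ub <- c(succinate = 2)
  mu <- 0.1
  fr <- flux_range(m, mu, "BIOMASS_DILUTION", ub)
  expect_equal(unname(fr), c(mu, mu), tolerance = 1e-7)
  # acetate is not being fed: its catabolism is structurally blocked
  fr2 <- flux_range(m, mu, "CAT_ac", ub)
  expect_equal(unname(fr2), c(0, 0), tolerance = 1e-9)
  # pinning the total flux can only narrow a range
  fr3 <- flux_range(m, mu, "ETFD", ub)
  fr4 <- flux_range(m, mu, "ETFD", ub, within_pfba = TRUE)
  expect_gte(fr4[["min"]], fr3[["min"]] - 1e-6)
  expect_lte(fr4[["max"]], fr3[["max"]] + 1e-6)
  expect_error(flux_range(m, mu, "NOPE", ub), "unknown")
})

test_that("steady state holds for every returned flux vector", {
  m <- capped(toy_model())
  for (u in c(1, 3)) {
    sol <- max_growth(m, c(succinate = u), tol = 1e-3, guard_scan = FALSE)
    lp <- assemble_lp(m, sol$mu, c(succinate = u))
    nmet <- nrow(m$metabolites)
    resid <- max(abs(lp$A[seq_len(nmet), seq_len(lp$n_rxn)] %*%
                       sol$fluxes[lp$ids]))
    expect_lt(resid, 1e-6)
  }
})
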