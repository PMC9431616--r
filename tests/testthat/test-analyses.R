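# Analysis stages: region classification, fold-change validation,
# oxidation states, profile consistency.

test_that("region classification recovers designed shapes", {
  u <- 1:10
  # linear growth: everything nutrient-limited
  expect_true(all(classify_regions(u, 0.1 * u) == "SNL"))
  # flat after point k: proteome-limited tail
  mu <- c(1, 2, 3, 4, 4, 4, 4, 4, 4, 4) / 10
  labs <- classify_regions(u, mu)
  expect_true(all(labs[6:10] == "SPL"))
  expect_true(any(labs == "SNL"))
  # ramp-then-plateau curve: three contiguous blocks in order
  mu2 <- pmin(u, 6) / 10
  labs2 <- classify_regions(u, mu2)
  expect_true(all(diff(match(labs2, c("SNL", "Janusian", "SPL"))) >= 0))
  expect_setequal(unique(labs2), c("SNL", "Janusian", "SPL"))
  # invariant to uniform rescaling of the grid
  expect_identical(labs2, classify_regions(10 * u, mu2))
  expect_error(classify_regions(1:3, c(1, 2, 3) / 10), "4 grid points")
  expect_error(classify_regions(u, rev(mu2)), "non-decreasing")
})

test_that("fold-change validation reproduces hand counts and printed accuracies", {
  fx25 <- make_expression_fixture(seed = 9, n_mismatches = 2,
                                  gene_ids = sprintf("g%02d", 1:25))
  expect_equal(fold_change_validation(fx25)$accuracy_percent, 92)
  fx37 <- make_expression_fixture(seed = 9, n_mismatches = 12,
                                  gene_ids = sprintf("g%02d", 1:37))
  r37 <- fold_change_validation(fx37)
  expect_equal(r37$accuracy_percent, 68)
  expect_equal(r37$n_correct, 25)
  # hand count on a tiny explicit fixture
  res <- fold_change_validation(
    flux_A = c(a = 2, b = 1, c = 5, d = 0.1),
    flux_B = c(a = 1, b = 2, c = 1, d = 1),
    experimental_directions = c(a = "up", b = "up", c = "up", d = "down"))
  expect_equal(res$n_correct, 3)   # b contradicts
  expect_equal(res$accuracy_percent, 75)
  # permutation invariance
  perm <- sample(25)
  expect_equal(fold_change_validation(fx25[perm, ])$accuracy_percent, 92)
})

test_that("ties and zero baselines follow the pseudo-flux rule", {
  res <- fold_change_validation(
    flux_A = c(a = 1, b = 0), flux_B = c(a = 1, b = 0),
    experimental_directions = c(a = "up", b = "up"))
  # identical fluxes: fold change exactly 1, classified unchanged and
  # excluded from the denominator
  expect_equal(res$n_ties, 2)
  expect_equal(res$n_compared, 0)
  expect_true(is.na(res$accuracy_percent))
  # zero baseline with signal uses the pseudo-flux and is flagged
  res2 <- fold_change_validation(
    flux_A = c(a = 1), flux_B = c(a = 0),
    experimental_directions = c(a = "up"))
  expect_equal(res2$accuracy_percent, 100)
  expect_equal(res2$n_pseudo, 1)
  expect_error(fold_change_validation(
    flux_A = c(a = 1), flux_B = c(b = 1),
    experimental_directions = c(c = "up")), "overlap")
})

test_that("substrate oxidation states span the documented range", {
  expect_equal(mean_carbon_oxidation_state("C4H6O4"), 0.5)
  expect_equal(mean_carbon_oxidation_state("C2H4O2"), 0)
  expect_equal(mean_carbon_oxidation_state("C4H8O2"), -1)
  expect_equal(mean_carbon_oxidation_state("C9H8O3"), -2 / 9)
})

test_that("growth excess percentages recompute from the reference rates", {
  ex <- growth_excess_percent()
  expect_equal(unname(ex[c("succinate", "butyrate", "acetate")]), c(6, 5, 4))
})

test_that("profile growth rates match independent single-point solves", {
  m0 <- toy_model()
  prof <- growth_profile(m0, "butyrate", c(1, 2, 3, 5), tol = 1e-3,
                         guard_scan = FALSE)
  expect_true(all(diff(prof$mu) > -1e-3))
  single <- max_growth(apply_atp_cap(m0, "butyrate"), c(butyrate = 2),
                       tol = 1e-3, guard_scan = FALSE,
                       compute_fluxes = FALSE)$mu
  expect_equal(prof$mu[2], single, tolerance = 1e-9)
  # nitrogen fixation tracks growth
  expect_equal(order(prof$v_nfix), order(prof$mu))
})

test_that("electron flow through ferredoxin balances at every sweep point", {
  m <- capped(toy_model())
  sol <- pfba_fluxes(m, 0.1, c(succinate = 2), pin_uptake = TRUE)
  lp <- assemble_lp(m, 0.1, c(succinate = 2), pin_uptake = TRUE)
  fd_row <- lp$A["fd_red_c", seq_len(lp$n_rxn)]
  expect_lt(abs(sum(fd_row * sol$fluxes[lp$ids])), 1e-7)
})
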