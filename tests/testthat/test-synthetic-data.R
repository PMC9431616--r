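# Properties of the toy network generator.

test_that("a fixed seed reproduces the model byte for byte", {
  a <- build_toy_me_model(toy_network_config(seed = 42))
  b <- build_toy_me_model(toy_network_config(seed = 42))
  expect_identical(serialize_me_model(a), serialize_me_model(b))
  c2 <- build_toy_me_model(toy_network_config(seed = 43))
  expect_false(identical(serialize_me_model(a), serialize_me_model(c2)))
})

test_that("model building leaves the caller's RNG stream untouched", {
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(build_toy_me_model(toy_network_config(seed = 7)))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("every metabolic reaction conserves elements", {
  m <- toy_model()
  formulas <- stats::setNames(lapply(m$metabolites$formula, parse_formula),
                              m$metabolites$id)
  kinds <- stats::setNames(m$metabolites$kind, m$metabolites$id)
  n_checked <- 0L
  for (i in seq_len(nrow(m$reactions))) {
    if (m$reactions$rclass[i] != "metabolic") next
    st <- m$reactions$stoich[[i]]
    if (!all(kinds[names(st)] == "small-molecule")) next
    imb <- palme:::stoich_element_imbalance(st, formulas)
    expect_length(imb, 0)
    n_checked <- n_checked + 1L
  }
  expect_gt(n_checked, 40)  # the whole metabolic core was actually checked
})

test_that("nitrogenase ATP ordering is enforced at construction", {
  expect_error(toy_network_config(nitrogenase_atp_costs = c(Mo = 30, V = 24, Fe = 40)),
               "Mo < V < Fe")
  expect_error(register_nitrogenases(toy_model(), costs = c(Mo = 16, V = 16, Fe = 40)),
               "Mo < V < Fe")
  # non-strict mode admits ties (degenerate isozyme choice)
  m <- register_nitrogenases(toy_model(expression_layer = FALSE),
                             costs = c(Mo = 16, V = 16, Fe = 16),
                             fd_costs = c(Mo = 8, V = 8, Fe = 8),
                             strict = FALSE)
  st_mo <- m$reactions$stoich[[match("NFIX_Mo", m$reactions$id)]]
  st_v <- m$reactions$stoich[[match("NFIX_V", m$reactions$id)]]
  expect_equal(st_mo[["atp_c"]], st_v[["atp_c"]])
})

test_that("no energy or carbon source means no growth", {
  m <- capped(toy_model())
  # zero uptake on all substrates and photons
  m0 <- set_bounds(m, "EX_photon", lb = 0)
  sol <- max_growth(m0, c(succinate = 0), tol = 1e-3, guard_scan = FALSE,
                    compute_fluxes = FALSE)
  expect_equal(sol$mu, 0)
  # trivial steady state at mu = 0 with everything closed
  expect_true(is_feasible(m0, 0))
})

test_that("expression fixtures encode the requested mismatch count", {
  m <- toy_model()
  fx <- make_expression_fixture(m, seed = 2, n_mismatches = 3)
  model_dir <- ifelse(fx$flux_A / fx$flux_B > 1, "up", "down")
  expect_equal(sum(model_dir != fx$experimental_direction), 3)
  expect_equal(attr(fx, "n_injected_mismatches"), 3L)
  expect_error(make_expression_fixture(m, seed = 1, n_mismatches = 10000),
               "exceeds")
  expect_error(make_expression_fixture(NULL, seed = 1, n_mismatches = 0),
               "expression layer")
})

test_that("nitrogenase stoichiometry ties hydrogen to electron cost", {
  m <- toy_model()
  for (iso in c("Mo", "V", "Fe")) {
    st <- m$reactions$stoich[[match(paste0("NFIX_", iso), m$reactions$id)]]
    e <- -st[["fd_red_c"]]
    expect_equal(st[["h2_c"]], (e - 6) / 2, label = iso)
    expect_equal(st[["nh3_c"]], 2, label = iso)
  }
  # ATP costs from the config, ordered
  atp <- vapply(c("Mo", "V", "Fe"), function(iso) {
    -m$reactions$stoich[[match(paste0("NFIX_", iso), m$reactions$id)]][["atp_c"]]
  }, 0)
  expect_true(atp[["Mo"]] < atp[["V"]] && atp[["V"]] < atp[["Fe"]])
})
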