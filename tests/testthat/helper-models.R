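# Shared fixtures: toy models are expensive to build, so cache one per
# seed for the whole test session.

.toy_cache <- new.env(parent = emptyenv())

toy_model <- function(seed = 1L, expression_layer = TRUE) {
  key <- paste0("s", seed, if (!expression_layer) "_m")
  if (is.null(.toy_cache[[key]])) {
    .toy_cache[[key]] <- build_toy_me_model(
      toy_network_config(seed = seed,
                         include_expression_layer = expression_layer))
  }
  .toy_cache[[key]]
}

capped <- function(model, substrate = "succinate") {
  apply_atp_cap(model, substrate)
}

# grid-scan growth oracle: largest feasible mu walking up from zero
grid_scan_mu <- function(model, uptake_bounds, step) {
  mu <- 0
  repeat {
    nxt <- mu + step
    ok <- is_feasible(model, nxt, uptake_bounds, on_failure = "infeasible")
    if (!ok) return(mu)
    mu <- nxt
    if (mu > 5) stop("grid scan ran away")
  }
}

# independent residue-mass oracle: average masses recomputed from atomic
# composition of each amino acid residue (formula minus water)
AA_RESIDUE_FORMULA <- list(
  A = c(C = 3, H = 5, N = 1, O = 1),           G = c(C = 2, H = 3, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),           P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1),           T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),    L = c(C = 6, H = 11, N = 1, O = 1),
  I = c(C = 6, H = 11, N = 1, O = 1),          N = c(C = 4, H = 6, N = 2, O = 2),
  D = c(C = 4, H = 5, N = 1, O = 3),           Q = c(C = 5, H = 8, N = 2, O = 2),
  K = c(C = 6, H = 12, N = 2, O = 1),          E = c(C = 5, H = 7, N = 1, O = 3),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),    H = c(C = 6, H = 7, N = 3, O = 1),
  F = c(C = 9, H = 9, N = 1, O = 1),           R = c(C = 6, H = 12, N = 4, O = 1),
  Y = c(C = 9, H = 9, N = 1, O = 2),           W = c(C = 11, H = 10, N = 2, O = 1)
)

atomic_mass_oracle <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                        S = 32.06)

residue_mass_oracle <- function(aa) {
  f <- AA_RESIDUE_FORMULA[[aa]]
  sum(f * atomic_mass_oracle[names(f)])
}
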