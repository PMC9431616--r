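# Photoheterotroph-specific constraints: rubisco I/II coexpression tied
# to total CO2 production, and the substrate-specific photosynthetic ATP
# production caps.

#' Table of maximal photosynthetic ATP production rates per substrate
#'
#' mmol ATP/gDW/day, derived from photosynthetic yields.
#' @export
ATP_CAP_TABLE <- c(acetate = 54.0, succinate = 45.7,
                   butyrate = 56.7, `p-coumarate` = 85.4)

#' Photosynthetic ATP cap specification
#'
#' The cap for substrate S scales the acetate reference by the ratio of
#' photosynthetic yields: \code{cap_S = v_ace * phi_S / phi_ace}. When no
#' yields are supplied the tabulated caps are used directly.
#'
#' @param substrate substrate name.
#' @param v_psii_ace acetate reference ATP production rate.
#' @param phi_s,phi_ace photosynthetic yields (dimensionless).
#' @param table named fallback caps, mmol/gDW/day.
#' @return object of class \code{atp_cap_spec} with the resolved
#'   \code{cap}.
#' @export
atp_cap_spec <- function(substrate, v_psii_ace = NULL, phi_s = NULL,
                         phi_ace = NULL, table = ATP_CAP_TABLE) {
  if (!is.null(phi_s) || !is.null(phi_ace) || !is.null(v_psii_ace)) {
    if (is.null(phi_s) || is.null(phi_ace) || is.null(v_psii_ace)) {
      stop("supply v_psii_ace, phi_s and phi_ace together")
    }
    cap <- v_psii_ace * phi_s / phi_ace
  } else {
    if (!substrate %in% names(table)) stop("unknown substrate: ", substrate)
    cap <- table[[substrate]]
  }
  if (cap <= 0) stop("ATP cap must be positive")
  structure(list(substrate = substrate, cap = cap), class = "atp_cap_spec")
}

#' Cap photosynthetic ATP production for a substrate
#'
#' Sets the upper bound of the designated photophosphorylation
#' ATP-production reaction (the pmf-driven ATP synthase in the toy
#' network) to the substrate's cap.
#'
#' @param model an \code{me_model}.
#' @param substrate substrate name (resolved through [atp_cap_spec()]).
#' @param spec optional explicit \code{atp_cap_spec}.
#' @param reaction_id the ATP-production reaction (default \code{"ATPS"}).
#' @return the capped model.
#' @export
apply_atp_cap <- function(model, substrate, spec = NULL,
                          reaction_id = "ATPS") {
  spec <- spec %||% atp_cap_spec(substrate)
  if (!reaction_id %in% model$reactions$id) {
    stop("model has no ATP-production reaction ", reaction_id)
  }
  model <- set_bounds(model, reaction_id, ub = spec$cap)
  model$notes$atp_cap <- c(substrate = spec$substrate, cap = spec$cap)
  model
}

#' Reactions producing cytosolic CO2
#'
#' Returns the production-weighted membership of the total CO2 production
#' sum: every non-exchange reaction with a positive cytosolic CO2
#' coefficient, with that coefficient as weight.
#'
#' @param model an \code{me_model}.
#' @param species CO2 species id.
#' @return named numeric vector reaction id -> CO2 stoichiometry.
#' @export
co2_producing_reactions <- function(model, species = "co2_c") {
  out <- c()
  for (i in seq_len(nrow(model$reactions))) {
    if (model$reactions$rclass[i] == "exchange") next
    st <- model$reactions$stoich[[i]]
    if (species %in% names(st) && st[[species]] > 0) {
      out[model$reactions$id[i]] <- st[[species]]
    }
  }
  out
}

#' Rubisco coexpression specification
#'
#' Ties form I rubisco flux to total CO2 production:
#' \code{v_I = (-sum_vCO2 + (mu/mu_max) * sum_vCO2_max) * kcat_I/kcat_II}.
#' \code{mu_max} and \code{sum_vCO2_max} come from an unconstrained
#' calibration solve (see [calibrate_rubisco_coexpression()]).
#'
#' @param mu_max theoretical maximum growth rate, day^-1 (> 0).
#' @param sum_vco2_max total CO2 production flux at \code{mu_max}.
#' @param kcat_I,kcat_II rubisco turnover rates (the per-site literature
#'   values by default; only their ratio enters).
#' @param v_rubisco_I reaction id of the form I carboxylation flux.
#' @param co2_reactions named weights of CO2-producing reactions; when
#'   \code{NULL}, computed from the model at application time.
#' @return object of class \code{rubisco_coexpression_spec}.
#' @export
rubisco_coexpression_spec <- function(mu_max, sum_vco2_max,
                                      kcat_I = 3.7, kcat_II = 6.6,
                                      v_rubisco_I = "RBC_I",
                                      co2_reactions = NULL) {
  stopifnot(mu_max > 0, sum_vco2_max >= 0, kcat_II > 0, kcat_I > 0)
  structure(list(mu_max = mu_max, sum_vco2_max = sum_vco2_max,
                 kcat_I = kcat_I, kcat_II = kcat_II,
                 v_rubisco_I = v_rubisco_I, co2_reactions = co2_reactions),
            class = "rubisco_coexpression_spec")
}

#' Evaluate the coexpression right-hand side directly
#'
#' The form I flux implied by the constraint at a given growth rate and
#' total CO2 production; used for analytic checks against the applied
#' constraint.
#'
#' @param spec a [rubisco_coexpression_spec()].
#' @param mu growth rate.
#' @param sum_vco2 total CO2 production flux.
#' @return implied v_rubisco_I (may be negative; the default application
#'   mode clips at zero).
#' @export
eval_rubisco_coexpression <- function(spec, mu, sum_vco2) {
  (-sum_vco2 + (mu / spec$mu_max) * spec$sum_vco2_max) *
    spec$kcat_I / spec$kcat_II
}

#' Calibrate the coexpression constraint by an unconstrained solve
#'
#' Two-pass protocol: solve the model without the constraint at the
#' reference condition to obtain the theoretical maximum growth rate and
#' the total CO2 production at that optimum, then build the spec from
#' them.
#'
#' @param model an \code{me_model} (without the constraint).
#' @param substrate substrate name.
#' @param uptake uptake bound for the calibration solve.
#' @param tol bisection tolerance.
#' @param apply_cap also apply the substrate ATP cap during calibration.
#' @param ... passed to [rubisco_coexpression_spec()].
#' @return a calibrated \code{rubisco_coexpression_spec}.
#' @export
calibrate_rubisco_coexpression <- function(model, substrate, uptake,
                                           tol = 1e-4, apply_cap = TRUE, ...) {
  m <- if (apply_cap) apply_atp_cap(model, substrate) else model
  ub <- stats::setNames(uptake, substrate)
  sol <- max_growth(m, ub, tol = tol)
  w <- co2_producing_reactions(m)
  sum_vco2 <- sum(w * sol$fluxes[names(w)])
  rubisco_coexpression_spec(mu_max = sol$mu, sum_vco2_max = sum_vco2, ...)
}

#' Apply the rubisco I/II coexpression constraint
#'
#' Adds the linear row linking form I flux to the CO2-production sum. In
#' the default \code{"nonneg"} mode the constraint is
#' \code{v_I >= (bracket) * kcat_I/kcat_II} together with
#' \code{v_I >= 0}: when the bracket is negative the form I flux floors
#' at zero (the parsimonious objective keeps it at the floor). The
#' \code{"strict"} mode imposes equality and surfaces infeasibility when
#' the implied flux is negative.
#'
#' @param model an \code{me_model}.
#' @param spec a [rubisco_coexpression_spec()].
#' @param mode \code{"nonneg"} (default) or \code{"strict"}.
#' @return the model with the constraint registered (instantiated at
#'   each solve's mu).
#' @export
apply_rubisco_coexpression <- function(model, spec,
                                       mode = c("nonneg", "strict")) {
  mode <- match.arg(mode)
  if (!spec$v_rubisco_I %in% model$reactions$id) {
    stop("unknown form I reaction: ", spec$v_rubisco_I)
  }
  w <- spec$co2_reactions %||% co2_producing_reactions(model)
  ratio <- spec$kcat_I / spec$kcat_II
  coeffs <- c(stats::setNames(1, spec$v_rubisco_I), ratio * w)
  model$constraints[["rubisco_coexpression"]] <- list(
    coeffs = coeffs,
    op = if (mode == "nonneg") ">=" else "=",
    rhs = 0,
    rhs_mu = ratio * spec$sum_vco2_max / spec$mu_max,
    label = "rubisco I/II coexpression"
  )
  model$notes$rubisco_spec <- spec
  model
}
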