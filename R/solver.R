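# Growth solving: fix mu to linearize the coupled problem, test LP
# feasibility, bisect mu to the feasibility boundary, and compute
# parsimonious (minimum total flux) solutions on the mu-pinned polytope.

#' Assemble the mu-pinned linear program of an ME model
#'
#' At a fixed growth rate mu every coupling term mu/kcat becomes a
#' constant, the model is a pure LP: steady-state balance rows for every
#' species, box bounds per reaction, the biomass dilution flux pinned to
#' mu, and any registered extra constraint rows (e.g. the rubisco
#' coexpression equality) instantiated at this mu.
#'
#' @param model an \code{me_model}.
#' @param mu growth rate, day^-1 (>= 0).
#' @param uptake_bounds named vector substrate name -> maximal uptake
#'   (mmol/gDW/day); opens the corresponding exchange.
#' @param pin_uptake force uptake exactly equal to the given values
#'   rather than bounding it from above.
#' @param pins named vector reaction id -> pinned flux value (lb = ub).
#' @param extra_rows list of extra linear rows, each
#'   \code{list(coeffs = c(rxn = w, ...), op = "="|"<="|">=", rhs = r)}.
#' @return list with matrix \code{A}, vector \code{b}, bounds \code{lb},
#'   \code{ub}, reaction ids \code{ids} (columns beyond these are slack
#'   variables), and \code{n_rxn}.
#' @export
assemble_lp <- function(model, mu, uptake_bounds = NULL, pin_uptake = FALSE,
                        pins = NULL, extra_rows = list()) {
  if (!is.finite(mu) || mu < 0) stop("mu must be a nonnegative number")
  rxns <- model$reactions
  n <- nrow(rxns)
  met_ids <- model$metabolites$id
  mrow <- seq_along(met_ids)
  names(mrow) <- met_ids
  A <- matrix(0, length(met_ids), n, dimnames = list(met_ids, rxns$id))
  for (j in seq_len(n)) {
    st <- rxns$stoich[[j]]
    A[mrow[names(st)], j] <- A[mrow[names(st)], j] + st
    mc <- rxns$mu_coupled[[j]]
    if (length(mc) && mu > 0) {
      A[mrow[names(mc)], j] <- A[mrow[names(mc)], j] - mu * mc
    }
  }
  lb <- rxns$lb; ub <- rxns$ub
  names(lb) <- names(ub) <- rxns$id
  if (length(uptake_bounds)) {
    for (s in names(uptake_bounds)) {
      exid <- paste0("EX_", substrate_id(s))
      j <- match(exid, rxns$id)
      if (is.na(j)) stop("model has no exchange for substrate ", s)
      u <- uptake_bounds[[s]]
      if (u < 0) stop("uptake bound must be nonnegative")
      lb[j] <- -u
      ub[j] <- if (pin_uptake) -u else 0
    }
  }
  di <- match(model$biomass_dilution_id, rxns$id)
  if (!is.na(di)) { lb[di] <- mu; ub[di] <- mu }
  if (length(pins)) {
    for (r in names(pins)) {
      j <- match(r, rxns$id)
      if (is.na(j)) stop("unknown pinned reaction: ", r)
      lb[j] <- pins[[r]]; ub[j] <- pins[[r]]
    }
  }
  b <- rep(0, length(met_ids))

  rows <- c(model$constraints, extra_rows)
  for (cr in rows) {
    coef <- cr$coeffs
    j <- match(names(coef), rxns$id)
    if (anyNA(j)) stop("constraint references unknown reaction(s): ",
                       paste(names(coef)[is.na(j)], collapse = ", "))
    row <- rep(0, n)
    row[j] <- coef
    rhs <- (cr$rhs %||% 0) + mu * (cr$rhs_mu %||% 0)
    op <- cr$op %||% "="
    if (op == "=") {
      A <- rbind(A, c(row))
      b <- c(b, rhs)
    } else {
      ## slack column: row +/- s = rhs with s >= 0
      sgn <- if (op == "<=") 1 else -1
      A <- rbind(A, row)
      A <- cbind(A, c(rep(0, nrow(A) - 1L), sgn))
      b <- c(b, rhs)
      lb <- c(lb, 0); ub <- c(ub, Inf)
    }
  }
  list(A = A, b = b, lb = unname(lb), ub = unname(ub),
       ids = rxns$id, n_rxn = n)
}

## split LP for |v| objectives: v = p - q with p, q >= 0
split_lp <- function(lp) {
  n <- lp$n_rxn
  nc <- ncol(lp$A)
  rev_idx <- which(lp$lb[seq_len(n)] < 0)
  A2 <- cbind(lp$A, -lp$A[, rev_idx, drop = FALSE])
  lb2 <- c(pmax(lp$lb, 0)[seq_len(n)],
           if (nc > n) lp$lb[(n + 1L):nc],
           pmax(0, -lp$ub[rev_idx]))
  ub2 <- c(pmax(lp$ub, 0)[seq_len(n)],
           if (nc > n) lp$ub[(n + 1L):nc],
           pmax(0, -lp$lb[rev_idx]))
  ## positive parts of reversible columns keep their column position;
  ## original bounds for irreversible columns are untouched
  lb2[rev_idx] <- pmax(0, lp$lb[rev_idx])
  list(A = A2, b = lp$b, lb = lb2, ub = ub2, ids = lp$ids, n_rxn = n,
       n_slack = nc - n, rev_idx = rev_idx)
}

recover_fluxes <- function(slp, x) {
  n <- slp$n_rxn
  v <- x[seq_len(n)]
  if (length(slp$rev_idx)) {
    qcols <- (n + slp$n_slack + 1L):(n + slp$n_slack + length(slp$rev_idx))
    v[slp$rev_idx] <- v[slp$rev_idx] - x[qcols]
  }
  stats::setNames(v, slp$ids)
}

#' Is an ME model feasible at a given growth rate?
#'
#' @inheritParams assemble_lp
#' @param ... passed to [assemble_lp()].
#' @return \code{TRUE} or \code{FALSE}. A solver breakdown (iteration
#'   limit, numerical failure) raises an error and is never reported as
#'   infeasibility.
#' @export
is_feasible <- function(model, mu, uptake_bounds = NULL, ...,
                        on_failure = c("error", "infeasible")) {
  on_failure <- match.arg(on_failure)
  lp <- assemble_lp(model, mu, uptake_bounds, ...)
  res <- solve_lp_presolved(rep(0, ncol(lp$A)), lp$A, lp$b, lp$lb, lp$ub)
  if (res$status %in% c("maxit", "numerical")) {
    if (on_failure == "error") {
      stop("LP solver failure (", res$status, ") at mu = ", mu)
    }
    return(FALSE)   # conservative: shrinks a bracketing step by < tol
  }
  res$status == "optimal"
}

#' Upper bracket for the growth rate from elemental carbon balance
#'
#' Biomass carbon cannot exceed substrate carbon uptake (net CO2 uptake
#' is closed in the toy network); the bracket is twice that analytic
#' bound, guaranteeing an infeasible right endpoint for the bisection.
#' @keywords internal
mu_upper_bracket <- function(model, uptake_bounds) {
  if (!length(uptake_bounds)) return(0)
  c_in <- 0
  for (s in names(uptake_bounds)) {
    f <- parse_formula(SUBSTRATE_TABLE$formula[match(s, SUBSTRATE_TABLE$name)])
    c_in <- c_in + uptake_bounds[[s]] * f[["C"]]
  }
  di <- match(model$biomass_dilution_id, model$reactions$id)
  st <- model$reactions$stoich[[di]]
  consumed <- -st[st < 0]
  mets <- model$metabolites
  c_bio <- 0
  cp <- model$coupling
  mean_nt_c <- 9.75       # mean carbons per NTP residue
  mean_nt_mw <- mean(RNA_RESIDUE_MASS) / 1000
  for (sp in names(consumed)) {
    i <- match(sp, mets$id)
    kind <- mets$kind[i]
    if (kind == "small-molecule") {
      f <- parse_formula(mets$formula[i])
      if ("C" %in% names(f)) c_bio <- c_bio + consumed[[sp]] * f[["C"]]
    } else if (sp == "biomass_protein") {
      c_bio <- c_bio + consumed[[sp]] * 4 / cp$m_aa
    } else if (sp == "biomass_mrna") {
      c_bio <- c_bio + consumed[[sp]] * mean_nt_c / mean_nt_mw
    }
  }
  ## ATP turnover consumes net carbon only through its phosphate cycle,
  ## which is carbon-neutral; ignore it (atp/adp pairs cancel above only
  ## approximately, so subtract the adp credit explicitly)
  produced <- st[st > 0]
  for (sp in names(produced)) {
    i <- match(sp, mets$id)
    if (mets$kind[i] == "small-molecule") {
      f <- parse_formula(mets$formula[i])
      if ("C" %in% names(f)) c_bio <- c_bio - produced[[sp]] * f[["C"]]
    }
  }
  if (c_bio <= 0) stop("biomass reaction consumes no net carbon")
  2 * c_in / c_bio
}

#' Maximal feasible growth rate by bisection
#'
#' Reproduces the scan-to-infeasibility protocol as a bisection: the
#' largest mu at which the mu-pinned LP is feasible, to within \code{tol}.
#' Feasibility is assumed monotone in mu (true for standard growth
#' coupling); a guard scan at 10 interior points validates the assumption
#' per solve and falls back to a fine linear scan on violation.
#'
#' @inheritParams assemble_lp
#' @param tol bisection tolerance on mu, day^-1.
#' @param guard_scan validate monotone feasibility at 10 interior points.
#' @param compute_fluxes also return parsimonious fluxes at the optimum.
#' @param ... passed to [assemble_lp()] (e.g. \code{pins}).
#' @return object of class \code{growth_solution}: list with \code{mu},
#'   \code{status}, \code{fluxes} (named vector, if computed),
#'   \code{total_flux}, \code{residual}.
#' @export
max_growth <- function(model, uptake_bounds = NULL, tol = 1e-4,
                       guard_scan = TRUE, compute_fluxes = TRUE, ...) {
  if (tol <= 0) stop("tol must be positive")
  if (!is_feasible(model, 0, uptake_bounds, ...)) {
    stop("model infeasible at mu = 0; the network is broken")
  }
  hi <- mu_upper_bracket(model, uptake_bounds)
  if (hi <= 0) {
    return(finish_solution(model, 0, uptake_bounds, compute_fluxes, ...))
  }
  tries <- 0L
  while (is_feasible(model, hi, uptake_bounds, ..., on_failure = "infeasible") && tries < 8L) {
    hi <- hi * 2; tries <- tries + 1L
  }
  if (tries == 8L) stop("could not bracket mu: model feasible at mu = ", hi)
  lo <- 0
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (is_feasible(model, mid, uptake_bounds, ...,
                    on_failure = "infeasible")) lo <- mid else hi <- mid
  }
  if (guard_scan && lo > 0) {
    pts <- seq(0, lo, length.out = 12L)[2:11]
    ok <- vapply(pts, function(mm) {
      is_feasible(model, mm, uptake_bounds, ..., on_failure = "infeasible")
    }, logical(1))
    if (!all(ok)) {
      ## non-monotone feasibility window: fine linear scan from below
      grid <- seq(0, hi, by = tol)
      feas <- vapply(grid, function(mm) {
        is_feasible(model, mm, uptake_bounds, ..., on_failure = "infeasible")
      }, logical(1))
      last <- which(!feas)[1]
      lo <- if (is.na(last)) grid[length(grid)] else grid[max(1L, last - 1L)]
    }
  }
  finish_solution(model, lo, uptake_bounds, compute_fluxes, ...)
}

finish_solution <- function(model, mu, uptake_bounds, compute_fluxes, ...) {
  if (compute_fluxes) {
    sol <- pfba_fluxes(model, mu, uptake_bounds, ...)
  } else {
    sol <- structure(list(mu = mu, status = "optimal", fluxes = NULL,
                          total_flux = NA_real_, residual = NA_real_),
                     class = "growth_solution")
  }
  sol$mu <- mu
  sol
}

#' Parsimonious flux distribution at a fixed growth rate
#'
#' Minimises the total absolute flux over the mu-pinned polytope
#' (reversible fluxes split into nonnegative parts), mirroring the
#' outer-objective flux minimisation used to collapse alternate optima
#' and select the most efficient isozymes.
#'
#' @inheritParams assemble_lp
#' @param ... passed to [assemble_lp()].
#' @return a \code{growth_solution} with named \code{fluxes},
#'   \code{total_flux} = sum(|v|), and the steady-state \code{residual}.
#' @export
pfba_fluxes <- function(model, mu, uptake_bounds = NULL, ...) {
  lp <- assemble_lp(model, mu, uptake_bounds, ...)
  slp <- split_lp(lp)
  obj <- rep(1, ncol(slp$A))
  if (slp$n_slack > 0) obj[(slp$n_rxn + 1L):(slp$n_rxn + slp$n_slack)] <- 0
  res <- solve_lp_presolved(obj, slp$A, slp$b, slp$lb, slp$ub)
  if (res$status %in% c("maxit", "numerical")) {
    stop("LP solver failure (", res$status, ") in pFBA at mu = ", mu)
  }
  if (res$status != "optimal") {
    stop("infeasible at mu = ", mu, "; cannot compute pFBA fluxes")
  }
  v <- recover_fluxes(slp, res$x)
  ## steady-state residual on the species balance rows
  nmet <- nrow(model$metabolites)
  resid <- max(abs((lp$A[seq_len(nmet), seq_len(lp$n_rxn), drop = FALSE] %*% v) -
                     lp$b[seq_len(nmet)]))
  structure(list(mu = mu, status = "optimal", fluxes = v,
                 total_flux = sum(abs(v)), residual = resid),
            class = "growth_solution")
}

#' @export
print.growth_solution <- function(x, ...) {
  cat("<growth_solution> mu =", format(x$mu, digits = 6),
      "status:", x$status, "\n")
  if (!is.null(x$fluxes)) {
    cat("  total |flux| =", format(x$total_flux, digits = 6),
        " residual =", format(x$residual, digits = 3), "\n")
  }
  invisible(x)
}

#' Feasible range of a single reaction flux
#'
#' Minimum and maximum of one flux over the mu-pinned polytope,
#' optionally with the total absolute flux pinned to (just above) its
#' parsimonious optimum, which is how claims about individual fluxes
#' should be made when alternate optima exist.
#'
#' @inheritParams assemble_lp
#' @param reaction_id flux of interest.
#' @param within_pfba restrict to (near-)parsimonious solutions.
#' @param pfba_slack relative slack on the pinned total flux.
#' @param ... passed to [assemble_lp()].
#' @return named numeric \code{c(min, max)}.
#' @export
flux_range <- function(model, mu, reaction_id, uptake_bounds = NULL,
                       within_pfba = FALSE, pfba_slack = 1e-6, ...) {
  j0 <- reaction_index(model, reaction_id)
  lp <- assemble_lp(model, mu, uptake_bounds, ...)
  slp <- split_lp(lp)
  nv <- ncol(slp$A)
  if (within_pfba) {
    base <- pfba_fluxes(model, mu, uptake_bounds, ...)
    cap <- base$total_flux * (1 + pfba_slack) + 1e-9
    ## sum of all nonneg flux parts <= cap
    row <- rep(1, nv)
    if (slp$n_slack > 0) row[(slp$n_rxn + 1L):(slp$n_rxn + slp$n_slack)] <- 0
    A2 <- rbind(slp$A, row)
    A2 <- cbind(A2, c(rep(0, nrow(A2) - 1L), 1))
    b2 <- c(slp$b, cap)
    lb2 <- c(slp$lb, 0); ub2 <- c(slp$ub, Inf)
  } else {
    A2 <- slp$A; b2 <- slp$b; lb2 <- slp$lb; ub2 <- slp$ub
    nv <- ncol(A2)
  }
  obj <- rep(0, ncol(A2))
  obj[j0] <- 1
  qpos <- match(j0, slp$rev_idx)
  if (!is.na(qpos)) obj[slp$n_rxn + slp$n_slack + qpos] <- -1
  lo <- solve_lp_presolved(obj, A2, b2, lb2, ub2)
  hi <- solve_lp_presolved(-obj, A2, b2, lb2, ub2)
  bad <- c(lo$status, hi$status)
  if (any(bad %in% c("maxit", "numerical"))) stop("LP solver failure in flux_range")
  if (any(bad == "infeasible")) stop("infeasible at mu = ", mu)
  vmin <- if (lo$status == "unbounded") -Inf else sum(obj * lo$x)
  vmax <- if (hi$status == "unbounded") Inf else -sum(-obj * hi$x)
  c(min = vmin, max = vmax)
}
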