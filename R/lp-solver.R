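# Dense bounded-variable primal simplex.
#
# The ME growth problem at fixed mu is a small, dense-ish LP:
#   min c'x  s.t.  A x = b,  l <= x <= u
# with a few hundred variables and at most a couple of hundred balance rows.
# No LP package is available in this installation, so the backend is a
# two-phase simplex written for exactly this problem class: equality rows,
# finite-or-infinite box bounds, warm refactorization, Bland's rule as an
# anti-cycling fallback. quadprog serves as an independent feasibility
# cross-check in the test suite, never as the production path.

#' Solve a linear program with equality constraints and box bounds
#'
#' Minimises \code{sum(obj * x)} subject to \code{A x = b} and
#' \code{lb <= x <= ub}. This is the numerical core behind
#' [is_feasible()], [max_growth()], [pfba_fluxes()] and [flux_range()].
#'
#' @param obj numeric objective vector (length n). Use zeros for a pure
#'   feasibility solve.
#' @param A dense numeric constraint matrix (m x n).
#' @param b right-hand side (length m).
#' @param lb,ub variable bounds; \code{-Inf}/\code{Inf} allowed.
#' @param control list of tolerances: \code{tol_d} (dual/reduced-cost),
#'   \code{tol_p} (primal feasibility, used to declare phase-1 success),
#'   \code{tol_piv} (pivot magnitude), \code{maxit}, \code{refactor_every}.
#' @return list with \code{status} ("optimal", "infeasible", "unbounded" or
#'   "maxit"), \code{x} (primal solution when optimal), \code{objval}, and
#'   \code{iter}.
#' @keywords internal
solve_lp <- function(obj, A, b, lb, ub, control = list()) {
  ## retry ladder: near the feasibility boundary the basis can go sour;
  ## re-solving with more frequent refactorization (and finally Bland
  ## pricing throughout) resolves borderline cases before giving up.
  ## An "infeasible" verdict is additionally confirmed by a conservative
  ## re-solve, because a stalled degenerate phase 1 can masquerade as
  ## infeasibility.
  ## fast Dantzig config first; an "infeasible" or breakdown escalates to
  ## the near-exact configuration (refactorization every 2 pivots, Bland
  ## pricing), whose verdict is authoritative -- a stalled degenerate
  ## phase 1 in the fast config can masquerade as infeasibility
  ladders <- list(list(),
                  list(refactor_every = 2L, bland = TRUE, maxit = 30000L),
                  list(refactor_every = 2L, bland = TRUE, perturb = 1e-9,
                       maxit = 30000L))
  res <- NULL
  for (k in seq_along(ladders)) {
    res <- solve_lp_once(obj, A, b, lb, ub,
                         utils::modifyList(control, ladders[[k]]))
    if (res$status == "numerical" && !is.null(res$x)) {
      ## crossover cleanup: clamp near-bound variables and re-solve the
      ## remaining square system exactly; rescues solves whose basis was
      ## right but whose iterates drifted (or were bound-perturbed)
      pol <- polish_lp_solution(res$x, obj, A, b, lb, ub)
      if (!is.null(pol)) return(pol)
    }
    if (res$status %in% c("optimal", "unbounded")) return(res)
    if (res$status == "infeasible" && k >= 2L) return(res)
  }
  res
}

solve_lp_once <- function(obj, A, b, lb, ub, control = list()) {
  ctl <- utils::modifyList(list(
    tol_d = 1e-7, tol_p = 1e-9, tol_piv = 1e-7,
    maxit = 8000L, refactor_every = 25L, bland = FALSE, perturb = 0
  ), control)

  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m, length(lb) == n, length(ub) == n)
  if (any(lb > ub + 1e-12)) stop("inconsistent bounds: lb > ub")

  ## --- equilibration: geometric-mean row/column scaling ------------------
  ## Coupling coefficients (mu/kcat ~ 1e-6) and macromolecule masses
  ## (hundreds of kDa) coexist in one matrix; scaling keeps pivots honest.
  rs <- rep(1, m); cs <- rep(1, n)
  Aw <- abs(A)
  gm <- function(v) { v <- v[v > 0]; if (!length(v)) 1 else sqrt(max(v) * min(v)) }
  for (pass in 1:10) {
    rmax <- apply(Aw, 1L, gm)
    rmax[rmax == 0 | !is.finite(rmax)] <- 1
    Aw <- Aw / rmax
    rs <- rs * rmax
    cmax <- apply(Aw, 2L, gm)
    cmax[cmax == 0 | !is.finite(cmax)] <- 1
    Aw <- sweep(Aw, 2L, cmax, "/")
    cs <- cs * cmax
    spread <- range(Aw[Aw > 0])
    if (spread[2] / spread[1] < 1e4) break
  }
  As <- sweep(sweep(A, 1L, rs, "/"), 2L, cs, "/")
  bs <- b / rs
  lbs <- lb * cs; ubs <- ub * cs
  objs <- obj / cs
  if (ctl$perturb > 0) {
    ## deterministic outward bound perturbation to break degenerate ties;
    ## relaxing (never tightening) preserves feasibility
    h <- ((seq_len(n) * 2654435761) %% 104729) / 104729
    eps <- ctl$perturb * (1 + abs(lbs)) * (0.5 + h)
    lbs <- ifelse(is.finite(lbs), lbs - eps, lbs)
    eps2 <- ctl$perturb * (1 + abs(ubs)) * (0.5 + rev(h))
    ubs <- ifelse(is.finite(ubs), ubs + eps2, ubs)
  }

  ## --- augmented system: n structural + m artificial columns -------------
  ## Nonbasic start: each structural at its finite bound nearest zero.
  x_start <- ifelse(is.finite(lbs) & is.finite(ubs),
                    ifelse(abs(lbs) <= abs(ubs), lbs, ubs),
             ifelse(is.finite(lbs), lbs, ifelse(is.finite(ubs), ubs, 0)))
  r0 <- as.vector(bs - As %*% x_start)
  art_sign <- ifelse(r0 >= 0, 1, -1)

  N  <- n + m
  Afull <- cbind(As, diag(art_sign, m))
  lbf <- c(lbs, rep(0, m))
  ubf <- c(ubs, rep(Inf, m))

  basis <- (n + 1L):N
  ## status of nonbasic structurals: 1 at lb, 2 at ub, 3 free-at-zero
  nb_stat <- integer(N)
  nb_stat[seq_len(n)] <- ifelse(x_start == lbs & is.finite(lbs), 1L,
                         ifelse(is.finite(ubs) & x_start == ubs, 2L, 3L))
  xN <- numeric(N)
  xN[seq_len(n)] <- x_start
  Binv <- diag(1 / art_sign, m)   # inverse of diag(art_sign)
  xB <- as.vector(abs(r0))

  nb_value <- function(j) xN[j]

  recompute_xB <- function() {
    nb <- setdiff(seq_len(N), basis)
    rhs <- bs - Afull[, nb, drop = FALSE] %*% xN[nb]
    v <- as.vector(Binv %*% rhs)
    ## one step of iterative refinement against the true basis columns
    e <- rhs - Afull[, basis, drop = FALSE] %*% v
    as.vector(v + Binv %*% e)
  }

  refactor <- function() {
    B <- Afull[, basis, drop = FALSE]
    Bi <- tryCatch(solve(B), error = function(e) NULL)
    if (is.null(Bi)) Bi <- MASS::ginv(B)
    Bi
  }

  in_basis <- rep(FALSE, N); in_basis[basis] <- TRUE

  run_phase <- function(cost, phase, tol_d = ctl$tol_d) {
    iter <- 0L; stall <- 0L; use_bland <- isTRUE(ctl$bland)
    last_obj <- Inf
    repeat {
      iter <- iter + 1L
      if (iter > ctl$maxit) return(list(status = "maxit", iter = iter))
      if (iter %% ctl$refactor_every == 0L) {
        Binv <<- refactor(); xB <<- recompute_xB()
      }
      cB <- cost[basis]
      y <- as.vector(crossprod(Binv, cB))          # B^T y = cB
      d <- cost - as.vector(crossprod(Afull, y))   # reduced costs, all cols
      elig <- !in_basis &
        ((nb_stat == 1L & d < -tol_d) |
         (nb_stat == 2L & d >  tol_d) |
         (nb_stat == 3L & abs(d) > tol_d))
      if (phase == 2L && m > 0L) elig[(n + 1L):N] <- FALSE
      if (!any(elig)) {
        return(list(status = "optimal", iter = iter))
      }
      cand <- which(elig)
      q <- if (use_bland) cand[1L] else cand[which.max(abs(d[cand]))]
      dirn <- if (nb_stat[q] == 2L || (nb_stat[q] == 3L && d[q] > 0)) -1 else 1

      w <- as.vector(Binv %*% Afull[, q])
      ## ratio test: basic vars hitting a finite bound, plus the entering
      ## variable flipping to its opposite bound.
      delta <- dirn * w
      lo_b <- lbf[basis]; hi_b <- ubf[basis]
      t_vec <- rep(Inf, m)
      dec <- delta > ctl$tol_piv & is.finite(lo_b)
      inc <- delta < -ctl$tol_piv & is.finite(hi_b)
      t_vec[dec] <- (xB[dec] - lo_b[dec]) / delta[dec]
      t_vec[inc] <- (hi_b[inc] - xB[inc]) / (-delta[inc])
      t_vec[t_vec < 0] <- 0
      theta <- suppressWarnings(min(t_vec))
      leave <- 0L; leave_bound <- NA_real_; leave_stat <- 0L
      if (is.finite(theta)) {
        ## two-pass (Harris-style) ratio test: among near-minimal ratios
        ## pick the row with the largest pivot magnitude, which keeps the
        ## basis well conditioned through degenerate steps
        near <- which(t_vec <= theta + 1e-9 * (1 + theta))
        leave <- near[which.max(abs(delta[near]))]
        theta <- t_vec[leave]
        if (dec[leave]) { leave_bound <- lo_b[leave]; leave_stat <- 1L }
        else            { leave_bound <- hi_b[leave]; leave_stat <- 2L }
      }
      flip_theta <- if (is.finite(lbf[q]) && is.finite(ubf[q])) ubf[q] - lbf[q] else Inf
      if (flip_theta < theta) {
        ## bound flip: entering variable crosses to its other bound
        xB <<- xB - delta * flip_theta
        xN[q] <<- if (dirn > 0) ubf[q] else lbf[q]
        nb_stat[q] <<- if (dirn > 0) 2L else 1L
        next
      }
      if (!is.finite(theta)) {
        return(list(status = if (phase == 1L) "numerical" else "unbounded",
                    iter = iter))
      }
      ## pivot
      xB <<- xB - delta * theta
      enter_val <- nb_value(q) + dirn * theta
      lv <- basis[leave]
      xN[lv] <<- leave_bound
      nb_stat[lv] <<- leave_stat
      in_basis[lv] <<- FALSE
      in_basis[q] <<- TRUE
      basis[leave] <<- q
      xB[leave] <<- enter_val
      ## rank-1 update of Binv
      piv <- w[leave]
      if (abs(piv) < ctl$tol_piv) {
        Binv <<- refactor(); xB <<- recompute_xB()
      } else {
        Brow <- Binv[leave, ] / piv
        Binv <<- Binv - outer(w, Brow)
        Binv[leave, ] <<- Brow
      }
      ## objective progress bookkeeping for anti-cycling
      cur <- sum(cost[basis] * xB) + sum(cost[!in_basis] * xN[!in_basis])
      if (cur < last_obj - 1e-12) stall <- 0L else stall <- stall + 1L
      if (stall > 3L * m) use_bland <- TRUE   # sticky: stay with Bland
      last_obj <- cur
    }
  }

  ## ---- phase 1 ----------------------------------------------------------
  c1 <- c(rep(0, n), rep(1, m))
  scale_b <- max(1, max(abs(bs)))
  iters1 <- 0L
  art_val <- Inf
  for (td in unique(c(ctl$tol_d, 1e-9, 1e-11))) {
    p1 <- run_phase(c1, 1L, tol_d = td)
    iters1 <- iters1 + p1$iter
    if (p1$status != "optimal") {
      return(list(status = if (p1$status == "maxit") "maxit" else "numerical",
                  x = NULL, objval = NA_real_, iter = iters1))
    }
    Binv <- refactor(); xB <- recompute_xB()
    art_val <- sum(abs(xB[basis > n]))
    if (art_val <= 1e-9 * scale_b) break
  }
  p1 <- list(iter = iters1)
  if (art_val > 1e-7 * scale_b) {
    return(list(status = "infeasible", x = NULL, objval = NA_real_, iter = iters1))
  }
  ## pin leftover (degenerate) artificials to zero
  ubf[(n + 1L):N] <- 0

  ## ---- phase 2 ----------------------------------------------------------
  c2 <- c(objs, rep(0, m))
  p2 <- run_phase(c2, 2L)
  if (p2$status == "maxit") {
    return(list(status = "maxit", x = NULL, objval = NA_real_, iter = p2$iter))
  }
  if (p2$status == "unbounded") {
    return(list(status = "unbounded", x = NULL, objval = -Inf, iter = p2$iter))
  }
  Binv <- refactor(); xB <- recompute_xB()
  xfull <- xN
  xfull[basis] <- xB
  xs <- xfull[seq_len(n)]
  x <- xs / cs
  ## snap values that drifted marginally outside their bounds; anything
  ## worse is a numerical failure, never silently repaired
  span <- pmax(1, abs(x))
  snap <- 1e-6 * span
  x <- ifelse(x < lb & x > lb - snap, lb, x)
  x <- ifelse(x > ub & x < ub + snap, ub, x)
  if (any(x < lb - snap) || any(x > ub + snap)) {
    return(list(status = "numerical", x = x, objval = NA_real_,
                iter = p1$iter + p2$iter))
  }
  resid <- max(abs(A %*% x - b))
  if (resid > 1e-6 * max(1, max(abs(b)), max(abs(x)))) {
    return(list(status = "numerical", x = x, objval = NA_real_,
                iter = p1$iter + p2$iter))
  }
  list(status = "optimal", x = x, objval = sum(obj * x),
       iter = p1$iter + p2$iter)
}

## Crossover cleanup: given an approximately optimal point, clamp
## variables sitting (numerically) on a bound and solve the remaining
## square/over-determined equality system exactly. Returns a result list
## on success, NULL when the candidate cannot be repaired.
polish_lp_solution <- function(x, obj, A, b, lb, ub) {
  for (tol_act in c(1e-7, 1e-5, 1e-3)) {
    pol <- polish_lp_at(x, obj, A, b, lb, ub, tol_act)
    if (!is.null(pol)) return(pol)
  }
  NULL
}

polish_lp_at <- function(x, obj, A, b, lb, ub, tol_act) {
  n <- length(x)
  span <- pmax(1, abs(x))
  at_lb <- is.finite(lb) & (x - lb) < tol_act * span
  at_ub <- is.finite(ub) & (ub - x) < tol_act * span
  xc <- x
  xc[at_lb] <- lb[at_lb]
  xc[at_ub & !at_lb] <- ub[at_ub & !at_lb]
  free <- which(!(at_lb | at_ub))
  if (length(free) > nrow(A)) return(NULL)
  rhs <- b - (if (length(free) < n)
    A[, -free, drop = FALSE] %*% xc[-free] else 0)
  if (length(free)) {
    fit <- tryCatch(qr.solve(A[, free, drop = FALSE], rhs, tol = 1e-12),
                    error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    xc[free] <- fit
  }
  scale <- max(1, max(abs(b)), max(abs(xc)))
  if (max(abs(A %*% xc - b)) > 1e-7 * scale) return(NULL)
  if (any(xc < lb - 1e-7 * span) || any(xc > ub + 1e-7 * span)) return(NULL)
  ## tiny residual bound noise from the exact solve
  xc <- pmin(pmax(xc, lb), ub)
  list(status = "optimal", x = xc, objval = sum(obj * xc), iter = NA_integer_)
}
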