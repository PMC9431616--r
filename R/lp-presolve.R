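# LP presolve for flux-balance systems.
#
# Growth LPs carry many structurally forced fluxes: substrates that are
# not being fed, dead-end filler conversions, knocked-out expression
# chains. Removing them before the simplex both shrinks the problem and
# eliminates the degenerate zero-pivots they cause.
#
# Reductions (to fixpoint):
#   * variables with lb == ub are substituted into the right-hand side;
#   * an equality row with a zero right-hand side in which every term of
#     one sign comes from variables pinned at zero forces the remaining
#     one-sided fluxes to zero (no-producer / no-consumer rule);
#   * singleton rows fix their single variable (or prove infeasibility);
#   * empty rows are dropped (infeasible if b != 0).

presolve_lp <- function(A, b, lb, ub, tol = 1e-11) {
  m <- nrow(A); n <- ncol(A)
  fixed_val <- rep(NA_real_, n)
  lb <- as.numeric(lb); ub <- as.numeric(ub)
  row_live <- rep(TRUE, m)
  col_live <- rep(TRUE, n)
  b <- as.numeric(b)

  fix_col <- function(j, val) {
    ## substitute x_j = val
    if (val < lb[j] - 1e-7 * (1 + abs(val)) ||
        val > ub[j] + 1e-7 * (1 + abs(val))) {
      return(FALSE)
    }
    if (val != 0) b <<- b - A[, j] * val
    fixed_val[j] <<- val
    col_live[j] <<- FALSE
    TRUE
  }

  ## fixed bounds first
  for (j in seq_len(n)) {
    if (is.finite(lb[j]) && is.finite(ub[j]) && ub[j] - lb[j] <= tol) {
      if (!fix_col(j, (lb[j] + ub[j]) / 2)) {
        return(list(status = "infeasible"))
      }
    }
  }

  repeat {
    changed <- FALSE
    for (i in which(row_live)) {
      cols <- which(col_live & abs(A[i, ]) > tol)
      if (!length(cols)) {
        if (abs(b[i]) > 1e-9) return(list(status = "infeasible"))
        row_live[i] <- FALSE
        next
      }
      if (length(cols) == 1L) {
        j <- cols
        if (!fix_col(j, b[i] / A[i, j])) return(list(status = "infeasible"))
        row_live[i] <- FALSE
        changed <- TRUE
        next
      }
      if (abs(b[i]) <= 1e-12) {
        ## no-producer / no-consumer rule: if every positive-contribution
        ## term is impossible (variable can only push the row negative or
        ## is stuck at zero), all contributors must vanish
        can_pos <- (A[i, cols] > 0 & ub[cols] > tol) |
                   (A[i, cols] < 0 & lb[cols] < -tol)
        can_neg <- (A[i, cols] > 0 & lb[cols] < -tol) |
                   (A[i, cols] < 0 & ub[cols] > tol)
        if (!any(can_pos) || !any(can_neg)) {
          ok <- TRUE
          for (j in cols) ok <- ok && fix_col(j, 0)
          if (!ok) return(list(status = "infeasible"))
          row_live[i] <- FALSE
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }

  keep_rows <- which(row_live)
  keep_cols <- which(col_live)
  list(status = "reduced",
       A = A[keep_rows, keep_cols, drop = FALSE],
       b = b[keep_rows],
       lb = lb[keep_cols], ub = ub[keep_cols],
       keep_cols = keep_cols, fixed = fixed_val, n = n)
}

## solve with presolve + simplex; returns same contract as solve_lp
solve_lp_presolved <- function(obj, A, b, lb, ub, control = list()) {
  ps <- presolve_lp(A, b, lb, ub)
  if (ps$status == "infeasible") {
    return(list(status = "infeasible", x = NULL, objval = NA_real_, iter = 0L))
  }
  if (!length(ps$keep_cols)) {
    x <- ps$fixed
    return(list(status = "optimal", x = x, objval = sum(obj * x), iter = 0L))
  }
  res <- solve_lp(obj[ps$keep_cols], ps$A, ps$b, ps$lb, ps$ub, control)
  if (res$status != "optimal") {
    res["x"] <- list(NULL)
    return(res)
  }
  x <- ps$fixed
  x[ps$keep_cols] <- res$x
  list(status = "optimal", x = x, objval = sum(obj * x), iter = res$iter)
}
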