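# The LP backend is validated against quadprog (independent quadratic
# feasibility oracle) and closed-form linear programs.

qp_feasible <- function(A, b, lb, ub) {
  n <- ncol(A)
  fl <- which(is.finite(lb)); fu <- which(is.finite(ub))
  Amat <- t(rbind(A, diag(n)[fl, , drop = FALSE], -diag(n)[fu, , drop = FALSE]))
  bvec <- c(b, lb[fl], -ub[fu])
  r <- tryCatch(quadprog::solve.QP(diag(n), rep(0, n), Amat, bvec,
                                   meq = nrow(A)),
                error = function(e) NULL)
  !is.null(r)
}

test_that("solver reproduces closed-form optima and detects structure", {
  r <- palme:::solve_lp(c(-1, -1), matrix(c(1, 1), 1, 2), 2, c(0, 0),
                        c(Inf, Inf))
  expect_equal(r$objval, -2)
  r <- palme:::solve_lp(c(1, 1), matrix(c(1, 1), 1, 2), 2, c(0, 0),
                        c(Inf, Inf))
  expect_equal(r$objval, 2)
  r <- palme:::solve_lp(c(-1, 0), matrix(c(0, 1), 1, 2), 1,
                        c(-Inf, -Inf), c(Inf, Inf))
  expect_equal(r$status, "unbounded")
  r <- palme:::solve_lp(c(0, 0), matrix(c(1, 1), 1, 2), 10, c(0, 0), c(1, 1))
  expect_equal(r$status, "infeasible")
})

test_that("feasibility verdicts agree with the quadratic-programming oracle", {
  set.seed(11)
  agree <- 0L; total <- 0L
  for (trial in 1:40) {
    n <- sample(15:60, 1); m <- sample(8:min(30, n - 5), 1)
    A <- matrix(0, m, n)
    for (j in 1:n) {
      rows <- sample(m, min(m, sample(1:3, 1)))
      A[rows, j] <- round(runif(length(rows), -3, 3), 2)
    }
    lb <- ifelse(runif(n) < 0.8, 0, -5)
    ub <- ifelse(runif(n) < 0.9, 10, Inf)
    target <- runif(n, pmax(lb, 0), pmin(ub, 3))
    b <- as.vector(A %*% target)
    if (trial %% 2 == 0) b <- b + rnorm(m) * 5   # usually infeasible
    obj <- runif(n)
    res <- palme:::solve_lp(obj, A, b, lb, ub)
    ok_qp <- qp_feasible(A, b, lb, ub)
    total <- total + 1L
    if ((res$status == "optimal") == ok_qp) agree <- agree + 1L
    if (res$status == "optimal") {
      expect_lt(max(abs(A %*% res$x - b)), 1e-6)
      expect_true(all(res$x >= lb - 1e-6) && all(res$x <= ub + 1e-6))
      # optimality: the known feasible reference point is never cheaper
      if (max(abs(A %*% target - b)) < 1e-9) {
        expect_lte(res$objval, sum(obj * target) + 1e-6)
      }
    }
  }
  # quadprog itself occasionally breaks on ill-scaled cases; near-perfect
  # agreement is the expectation
  expect_gte(agree / total, 0.95)
})

test_that("presolve never changes the verdict and reconstructs solutions", {
  set.seed(5)
  for (trial in 1:15) {
    n <- sample(20:50, 1); m <- sample(10:18, 1)
    A <- matrix(0, m, n)
    for (j in 1:n) {
      rows <- sample(m, min(m, sample(1:3, 1)))
      A[rows, j] <- sample(c(-2, -1, 1, 2), length(rows), replace = TRUE)
    }
    lb <- rep(0, n); ub <- rep(10, n)
    lb[1] <- ub[1] <- 0.5          # fixed variable
    target <- runif(n, 0, 3); target[1] <- 0.5
    b <- as.vector(A %*% target)
    obj <- runif(n)
    r1 <- palme:::solve_lp(obj, A, b, lb, ub)
    r2 <- palme:::solve_lp_presolved(obj, A, b, lb, ub)
    expect_equal(r2$status, r1$status)
    if (r1$status == "optimal") {
      expect_equal(r2$objval, r1$objval, tolerance = 1e-6)
      expect_lt(max(abs(A %*% r2$x - b)), 1e-6)
      expect_equal(r2$x[1], 0.5, tolerance = 1e-9)
    }
  }
})
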