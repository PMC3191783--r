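test_that("Jacobian-vector products reproduce exact matvecs", {
  set.seed(31)
  M <- diag(12) * 3 + matrix(rnorm(144, sd = 0.2), 12, 12)
  bvec <- rnorm(12)
  lin <- function(u) as.vector(M %*% u) - bvec
  u <- rnorm(12); v <- rnorm(12)
  jv <- jacobian_vector_product(lin, u, v)
  expect_equal(jv, as.vector(M %*% v), tolerance = 1e-6)
  # zero direction: exact zero, no operator evaluation
  grid <- grid_spec(10)
  edge <- compute_edge_field(disk_image(10), mcf_params(), grid)
  op <- make_implicit_operator(matrix(0, 10, 10), edge, mcf_params(), grid,
                               dtau = 0.1)
  expect_identical(jacobian_vector_product(op, rnorm(op$n), numeric(op$n)),
                   numeric(op$n))
  expect_identical(op$count(), 0L)
})

test_that("matrix-free products match the dense finite-difference Jacobian", {
  # segmentation residual on an 8x8 grid against a column-by-column
  # central-difference Jacobian oracle
  grid <- grid_spec(8)
  edge <- compute_edge_field(disk_image(8, r = 0.22), mcf_params(), grid)
  u0 <- make_seed_function(grid, c(0.5, 0.5), 0.15)
  op <- make_implicit_operator(segmentation_state(u0), edge, mcf_params(),
                               grid, dtau = 0.1)
  u <- mcfseg:::interior_vec(u0, grid)
  J <- dense_fd_jacobian(op$residual, u)
  set.seed(32)
  for (k in 1:5) {
    v <- rnorm(length(u))
    jv <- jacobian_vector_product(op, u, v)
    ref <- as.vector(J %*% v)
    expect_lte(sqrt(sum((jv - ref)^2)) / sqrt(sum(ref^2)), 1e-5)
  }
})

test_that("Newton converges in one step on linear systems", {
  set.seed(33)
  M <- diag(15) * 4 + matrix(rnorm(225, sd = 0.3), 15, 15)
  bvec <- rnorm(15)
  lin <- function(u) as.vector(M %*% u) - bvec
  # one-sided FD matvecs carry ~1e-8 relative rounding noise, so the
  # inner solve is asked for 1e-6 (one clean Krylov cycle) and Newton
  # for 1e-4: one exact Newton step on a linear map then suffices
  out <- jfnk_solve(lin, numeric(15),
                    jfnk_config(newton_tol = 1e-4, tol_mode = "relative",
                                inner_rtol = 1e-6))
  expect_true(out$report$converged)
  expect_identical(out$report$newton_steps, 1L)
  expect_equal(out$u, solve(M, bvec), tolerance = 1e-4)
})

test_that("componentwise square root shows quadratic Newton decay", {
  sq <- function(u) u^2 - 4
  out <- jfnk_solve(sq, rep(1, 6),
                    jfnk_config(newton_tol = 1e-12, tol_mode = "absolute",
                                inner_rtol = 1e-13))
  expect_true(out$report$converged)
  expect_equal(out$u, rep(2, 6), tolerance = 1e-10)
  h <- out$report$residual_history
  expect_true(all(diff(h) < 0))              # line search is monotone
  n <- length(h)
  p <- log(h[n] / h[n - 1]) / log(h[n - 1] / h[n - 2])
  expect_gte(p, 1.7)
})

test_that("evaluation counter matches the analytic count of a clean run", {
  # caching contract of the Jacobian products first: one new evaluation
  # per product with a cached base, two without
  grid <- grid_spec(10)
  edge <- compute_edge_field(disk_image(10), mcf_params(), grid)
  op <- make_implicit_operator(matrix(0, 10, 10), edge, mcf_params(), grid,
                               dtau = 0.1)
  u <- rnorm(op$n); v <- rnorm(op$n)
  hi <- op$residual(u)                       # 1 evaluation
  jacobian_vector_product(op, u, v, hi_u = hi)
  expect_identical(op$count(), 2L)           # cached base: +1
  jacobian_vector_product(op, u, v)
  expect_identical(op$count(), 4L)           # uncached: +2
  # full solve with a known trace: no backtracking on a linear map, so
  # f = 1 (initial) + sum(k_inner) + steps (residual after each cycle)
  #   + steps (one accepted line-search try per Newton step)
  set.seed(34)
  M <- diag(9) * 3 + matrix(rnorm(81, sd = 0.1), 9, 9)
  bvec <- rnorm(9)
  env <- new.env(); env$f <- 0L
  lin_op <- list(residual = function(u) { env$f <- env$f + 1L
                                          as.vector(M %*% u) - bvec },
                 count = function() env$f)
  out <- jfnk_solve(lin_op, numeric(9),
                    jfnk_config(newton_tol = 1e-4, inner_rtol = 1e-6))
  expect_identical(out$report$newton_steps, 1L)
  expect_identical(out$report$f_evals,
                   1L + sum(out$report$inner_iterations) +
                     2L * out$report$newton_steps)
})

test_that("failure modes are reported, not hidden", {
  # no root: HI(u) = u^2 + 1 > 0 forces line-search/step exhaustion
  bad <- function(u) u^2 + 1
  out <- jfnk_solve(bad, rep(0.5, 4),
                    jfnk_config(newton_tol = 1e-10, tol_mode = "absolute",
                                max_newton = 8L))
  expect_false(out$report$converged)
  expect_true(!is.null(out$report$failure))
})
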