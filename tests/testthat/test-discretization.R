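params_default <- mcf_params()

edge_of <- function(img, grid, sigma = 1) {
  compute_edge_field(img, mcf_params(sigma = sigma), grid)
}

test_that("sparse assembly matches the dense hand-assembled oracle", {
  for (dims in list(c(5L, 5L), c(8L, 6L))) {
    grid <- grid_spec(dims[1], dims[2])
    set.seed(dims[1])
    img <- matrix(runif(dims[1] * dims[2]), dims[1], dims[2])
    edge <- edge_of(img, grid)
    u_ref <- random_smooth_field(grid, seed = dims[2])
    A <- assemble_spatial_operator(u_ref, edge, params_default, grid)
    O <- dense_operator_oracle(u_ref, edge$g, params_default$epsilon, grid)
    expect_equal(as.matrix(A), O, tolerance = 1e-13, ignore_attr = TRUE)
  }
})

test_that("stencil is five-point with symmetric pattern", {
  grid <- grid_spec(12)
  edge <- edge_of(disk_image(12), grid)
  A <- assemble_spatial_operator(random_smooth_field(grid, 4), edge,
                                 params_default, grid)
  nnz_per_row <- Matrix::rowSums(A != 0)
  expect_true(all(nnz_per_row <= 5))
  P <- A != 0
  expect_identical(as.matrix(P), t(as.matrix(P)))
})

test_that("flat reference with unit edge field reduces to the scaled Laplacian", {
  grid <- grid_spec(8)
  edge <- edge_of(matrix(0.5, 8, 8), grid)       # g identically 1
  A <- assemble_spatial_operator(matrix(0, 8, 8), edge, params_default, grid)
  expect_equal(as.matrix(A), dense_laplacian_oracle(8),
               tolerance = 1e-12, ignore_attr = TRUE)
  # constant vectors are annihilated except where the stencil touches
  # the eliminated Dirichlet boundary
  ones <- rep(1, nrow(A))
  r <- as.vector(A %*% ones)
  interior_rows <- which(Matrix::rowSums(A != 0) == 5)
  expect_equal(max(abs(r[interior_rows])), 0, tolerance = 1e-10)
  expect_true(all(r[-interior_rows] > 0))
})

test_that("semi-implicit system obeys the M-matrix and row-sum contracts", {
  grid <- grid_spec(16)
  edge <- edge_of(tiny_phantom(n = 16)$image, grid)
  for (s in 1:10) {
    u_prev <- random_smooth_field(grid, seed = s)
    sys <- assemble_si_system(u_prev, edge, params_default, grid, dtau = 0.16)
    HS <- as.matrix(sys$HS)
    expect_true(all(diag(HS) > 0))
    off <- HS; diag(off) <- 0
    expect_true(all(off <= 0))
    expect_true(all(diag(HS) + 1e-12 >= rowSums(abs(off))))
    full_rows <- which(rowSums(HS != 0) == 5)
    expect_equal(max(abs(rowSums(HS)[full_rows] - 1)), 0, tolerance = 1e-12)
  }
  # zero step gives the identity system
  sys0 <- assemble_si_system(random_smooth_field(grid, 1), edge,
                             params_default, grid, dtau = 0)
  expect_equal(as.matrix(sys0$HS), diag(nrow(sys0$HS)),
               tolerance = 1e-15, ignore_attr = TRUE)
})

test_that("explicit step honors fixed points, CFL guard and first-order splitting", {
  grid <- grid_spec(24)
  ph <- tiny_phantom(n = 24)
  edge <- edge_of(ph$image, grid)
  zero <- segmentation_state(matrix(0, 24, 24))
  st0 <- explicit_step(zero, edge, params_default, grid, dtau = 1e-5)
  expect_identical(st0$u, zero$u)
  u0 <- make_seed_function(grid, c(0.5, 0.5), 0.15)
  st <- segmentation_state(u0)
  expect_identical(explicit_step(st, edge, params_default, grid, 0)$u, u0)
  expect_error(explicit_step(st, edge, params_default, grid, dtau = 0.1),
               "CFL")
  expect_warning(explicit_step(st, edge, params_default, grid, dtau = 0.1,
                               cfl_action = "warn"), "CFL")
  # explicit vs semi-implicit differ at O(dtau^2): halving dtau shrinks
  # the gap about fourfold
  gap <- function(dt) {
    ue <- explicit_step(st, edge, params_default, grid, dt)$u
    sys <- assemble_si_system(st, edge, params_default, grid, dt)
    usi <- Matrix::solve(sys$HS, sys$rhs)
    sqrt(sum((mcfseg:::interior_vec(ue, grid) - as.vector(usi))^2))
  }
  dt0 <- cfl_max_dtau(st, edge, params_default, grid) / 4
  ratio <- gap(dt0) / gap(dt0 / 2)
  expect_gt(ratio, 2.8)
  expect_lt(ratio, 5.5)
})

test_that("implicit residual vanishes at fixed points and scales with dtau", {
  grid <- grid_spec(16)
  edge <- edge_of(tiny_phantom(n = 16)$image, grid)
  zero <- matrix(0, 16, 16)
  expect_identical(implicit_residual(zero, zero, edge, params_default, grid,
                                     dtau = 0.1),
                   rep(0, mcfseg:::n_interior(grid)))
  # residual of the exact semi-implicit solution vanishes as dtau -> 0:
  # the two one-step maps agree to O(dtau^2), so doubling dtau scales
  # the Crank-Nicolson residual of the SI solution about fourfold
  u0 <- make_seed_function(grid, c(0.5, 0.5), 0.2)
  st <- segmentation_state(u0)
  res_of <- function(dt) {
    sys <- assemble_si_system(st, edge, params_default, grid, dt)
    usi <- mcfseg:::full_field(matrix(Matrix::solve(sys$HS, sys$rhs),
                                      14, 14), grid)
    sqrt(sum(implicit_residual(usi, st, edge, params_default, grid, dt)^2))
  }
  r2 <- res_of(2e-4); r1 <- res_of(1e-4)
  expect_lt(r1, r2)                       # residual vanishes with the step
  expect_gt(r2 / r1, 2.8)
  expect_lt(r2 / r1, 5.5)
})

test_that("residual operator counts its evaluations", {
  grid <- grid_spec(12)
  edge <- edge_of(disk_image(12), grid)
  op <- make_implicit_operator(matrix(0, 12, 12), edge, params_default, grid,
                               dtau = 0.1)
  expect_identical(op$count(), 0L)
  v <- rnorm(op$n)
  op$residual(v); op$residual(v); op$residual(2 * v)
  expect_identical(op$count(), 3L)
})
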