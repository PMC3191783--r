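#' Segmentation state at one scale step
#'
#' @param u matrix field on the grid (zero on the boundary ring)
#' @param scale_index integer step index i (0 for the initial state)
#' @param tau scale value \eqn{\tau_i}
#' @return object of class `segmentation_state`
#' @export
segmentation_state <- function(u, scale_index = 0L, tau = 0) {
  if (!all(is.finite(u))) stop("segmentation_state: non-finite field")
  bnd <- c(u[1, ], u[nrow(u), ], u[, 1], u[, ncol(u)])
  if (any(bnd != 0))
    stop("segmentation_state: field must vanish on the boundary ring (zero Dirichlet)")
  structure(list(u = u, scale_index = as.integer(scale_index), tau = tau),
            class = "segmentation_state")
}

as_state <- function(x) {
  if (inherits(x, "segmentation_state")) x else segmentation_state(x)
}

## Face diffusion coefficients and outer factor for the divergence form
##   Q(x) * div( g grad(.) / q(x) ),   q = sqrt(eps^2 + |grad u_ref|^2),
## with g and q averaged onto faces arithmetically and Q = q at centers.
## Returns matrices aligned with the interior block (nx-2) x (ny-2).
mcf_coeffs <- function(u_ref, edge, params, grid) {
  check_field(u_ref, grid, "u_ref")
  nx <- grid$nx; ny <- grid$ny
  q <- regularized_gradient_magnitude(u_ref, params$epsilon, grid)
  g <- edge$g
  # face value = arithmetic mean of the two adjacent cell values
  gfx <- (g[1:(nx - 1), ] + g[2:nx, ]) / 2       # between l and l+1
  qfx <- (q[1:(nx - 1), ] + q[2:nx, ]) / 2
  gfy <- (g[, 1:(ny - 1)] + g[, 2:ny]) / 2       # between m and m+1
  qfy <- (q[, 1:(ny - 1)] + q[, 2:ny]) / 2
  dfx <- gfx / qfx
  dfy <- gfy / qfy
  li <- 2:(nx - 1); mi <- 2:(ny - 1)
  list(dE = dfx[li, mi, drop = FALSE],           # face (l, l+1)
       dW = dfx[li - 1L, mi, drop = FALSE],      # face (l-1, l)
       dN = dfy[li, mi, drop = FALSE],           # face (m, m+1)
       dS = dfy[li, mi - 1L, drop = FALSE],      # face (m-1, m)
       Q  = q[li, mi, drop = FALSE])
}

## Nonlinear right-hand side F(u) of the flow, evaluated on the interior
## block: F(u) = Q(u) * div( g grad u / q(u) ). Returns an interior matrix.
mcf_rhs_interior <- function(u, edge, params, grid, coeffs = NULL) {
  if (is.null(coeffs)) coeffs <- mcf_coeffs(u, edge, params, grid)
  nx <- grid$nx; ny <- grid$ny
  li <- 2:(nx - 1); mi <- 2:(ny - 1)
  uc <- u[li, mi, drop = FALSE]
  div <- (coeffs$dE * (u[li + 1L, mi] - uc) -
          coeffs$dW * (uc - u[li - 1L, mi])) / grid$hx^2 +
         (coeffs$dN * (u[li, mi + 1L] - uc) -
          coeffs$dS * (uc - u[li, mi - 1L])) / grid$hy^2
  coeffs$Q * div
}

#' Assemble the spatial operator of the flow
#'
#' Builds the sparse five-point operator \eqn{A} such that
#' \eqn{A u = -Q\,\nabla\cdot(g\,\nabla u / q)} on the interior cells,
#' with \eqn{q = \sqrt{\epsilon^2 + |\nabla u_{ref}|^2}} averaged onto
#' faces from the adjacent cell centers and \eqn{Q = q} at the cell
#' center. Boundary unknowns are eliminated (zero Dirichlet). The
#' semi-implicit step then reads \eqn{(I + \Delta\tau A)\,u_i = u_{i-1}}.
#'
#' @param u_ref field supplying the lagged gradient terms
#' @param edge an [compute_edge_field()] result
#' @param params an [mcf_params()]
#' @param grid a [grid_spec()]
#' @return a `dgCMatrix` of dimension `n_int x n_int` where
#'   `n_int = (nx-2)*(ny-2)`; interior cells are flattened x-fastest
#' @export
assemble_spatial_operator <- function(u_ref, edge, params, grid) {
  cf <- mcf_coeffs(u_ref, edge, params, grid)
  nxi <- grid$nx - 2L; nyi <- grid$ny - 2L
  n <- nxi * nyi
  idx <- matrix(seq_len(n), nxi, nyi)   # interior numbering, x fastest
  cE <- cf$Q * cf$dE / grid$hx^2
  cW <- cf$Q * cf$dW / grid$hx^2
  cN <- cf$Q * cf$dN / grid$hy^2
  cS <- cf$Q * cf$dS / grid$hy^2
  diagv <- cE + cW + cN + cS
  ii <- c(seq_len(n),
          as.vector(idx[-nxi, ]), as.vector(idx[-1, ]),
          as.vector(idx[, -nyi]), as.vector(idx[, -1]))
  jj <- c(seq_len(n),
          as.vector(idx[-1, ]), as.vector(idx[-nxi, ]),
          as.vector(idx[, -1]), as.vector(idx[, -nyi]))
  xx <- c(as.vector(diagv),
          -as.vector(cE[-nxi, , drop = FALSE]),   # east couplings
          -as.vector(cW[-1, , drop = FALSE]),     # west couplings
          -as.vector(cN[, -nyi, drop = FALSE]),   # north couplings
          -as.vector(cS[, -1, drop = FALSE]))     # south couplings
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
}

#' Assemble the semi-implicit step system
#'
#' Forms `HS = I + dtau * A(u_{i-1})` and the right-hand side
#' `u_{i-1}` (interior), the linear system of one semi-implicit scale
#' step. `HS` is a block-pentadiagonal M-matrix: positive diagonal,
#' nonpositive off-diagonals, diagonally dominant with row sums equal to
#' 1 away from the boundary.
#'
#' @param prev previous [segmentation_state()] (or plain matrix)
#' @param edge edge field
#' @param params model parameters
#' @param grid grid
#' @param dtau scale step (defaults to `params$dtau`)
#' @return object of class `assembled_system` with components `HS`,
#'   `rhs`, `grid`, `dtau`
#' @export
assemble_si_system <- function(prev, edge, params, grid, dtau = params$dtau) {
  if (dtau < 0) stop("assemble_si_system: dtau must be >= 0")
  prev <- as_state(prev)
  A <- assemble_spatial_operator(prev$u, edge, params, grid)
  n <- nrow(A)
  HS <- Matrix::Diagonal(n) + dtau * A
  structure(list(HS = HS, rhs = interior_vec(prev$u, grid),
                 grid = grid, dtau = dtau),
            class = "assembled_system")
}

#' @export
print.assembled_system <- function(x, ...) {
  cat(sprintf("<assembled_system> %d unknowns, %d nonzeros, dtau = %g\n",
              nrow(x$HS), Matrix::nnzero(x$HS), x$dtau))
  invisible(x)
}

#' Stability bound for the explicit scheme
#'
#' Largest forward-Euler step that keeps the explicit update a convex
#' combination of neighboring values (positivity / discrete maximum
#' principle): the reciprocal of the largest diagonal entry of the
#' spatial operator, of order \eqn{h^2 / (4 \max g)}.
#'
#' @inheritParams assemble_si_system
#' @return positive scalar
#' @export
cfl_max_dtau <- function(prev, edge, params, grid) {
  prev <- as_state(prev)
  A <- assemble_spatial_operator(prev$u, edge, params, grid)
  1 / max(Matrix::diag(A))
}

#' One explicit (forward Euler) scale step
#'
#' \eqn{u_i = u_{i-1} + \Delta\tau\, F(u_{i-1})} with all nonlinear
#' terms evaluated at the previous step. Subject to a CFL-type
#' restriction; violations are reported per `cfl_action`.
#'
#' @inheritParams assemble_si_system
#' @param cfl_action `"error"`, `"warn"` or `"ignore"` when `dtau`
#'   exceeds [cfl_max_dtau()]
#' @return the updated [segmentation_state()]
#' @export
explicit_step <- function(prev, edge, params, grid, dtau = params$dtau,
                          cfl_action = c("error", "warn", "ignore")) {
  cfl_action <- match.arg(cfl_action)
  if (dtau < 0) stop("explicit_step: dtau must be >= 0")
  prev <- as_state(prev)
  if (dtau > 0 && cfl_action != "ignore") {
    dmax <- cfl_max_dtau(prev, edge, params, grid)
    if (dtau > dmax) {
      msg <- sprintf("explicit_step: dtau = %g exceeds CFL bound %g", dtau, dmax)
      if (cfl_action == "error") stop(msg) else warning(msg)
    }
  }
  Fi <- mcf_rhs_interior(prev$u, edge, params, grid)
  u <- prev$u
  u[2:(grid$nx - 1), 2:(grid$ny - 1)] <-
    u[2:(grid$nx - 1), 2:(grid$ny - 1)] + dtau * Fi
  segmentation_state(u, prev$scale_index + 1L, prev$tau + dtau)
}

#' Nonlinear residual operator of the Crank-Nicolson step
#'
#' Builds the per-step operator
#' \deqn{HI(u) = u - u_{i-1} - \Delta\tau\,
#'   \big[\tfrac12 F(u_{i-1}) + \tfrac12 F(u)\big]}
#' (interior unknowns, x-fastest) whose root is the fully implicit
#' Crank-Nicolson update. The forward-Euler half involving
#' \eqn{u_{i-1}} is precomputed; every evaluation of the operator
#' increments an evaluation counter (accessible via `$count()`), the
#' quantity that dominates the cost of the Jacobian-free Newton-Krylov
#' solver.
#'
#' @inheritParams assemble_si_system
#' @param theta implicitness weight: 0.5 is Crank-Nicolson (the
#'   scheme's definition and the default), 1 is backward Euler (used
#'   internally for startup smoothing of nonsmooth initial data)
#' @return object of class `mcf_residual_op` with elements
#'   `residual(v)` (vector-in, vector-out), `count()`, `n`
#' @export
make_implicit_operator <- function(prev, edge, params, grid,
                                   dtau = params$dtau, theta = 0.5) {
  if (dtau <= 0) stop("make_implicit_operator: dtau must be > 0")
  if (theta < 0.5 || theta > 1) stop("theta must lie in [0.5, 1]")
  prev <- as_state(prev)
  u_prev_int <- interior_vec(prev$u, grid)
  f_prev <- as.vector(mcf_rhs_interior(prev$u, edge, params, grid))
  n <- n_interior(grid)
  env <- new.env(parent = emptyenv())
  env$f <- 0L
  residual <- function(v) {
    if (length(v) != n) stop("implicit residual: length mismatch")
    env$f <- env$f + 1L
    u <- full_field(matrix(v, grid$nx - 2L, grid$ny - 2L), grid)
    f_new <- as.vector(mcf_rhs_interior(u, edge, params, grid))
    v - u_prev_int - dtau * ((1 - theta) * f_prev + theta * f_new)
  }
  structure(list(residual = residual,
                 count = function() env$f,
                 n = n, grid = grid, dtau = dtau),
            class = "mcf_residual_op")
}

#' Evaluate the Crank-Nicolson residual once
#'
#' Convenience wrapper over [make_implicit_operator()] for a single
#' candidate field.
#'
#' @param candidate matrix field satisfying the Dirichlet condition
#' @inheritParams assemble_si_system
#' @return residual vector over the interior cells
#' @export
implicit_residual <- function(candidate, prev, edge, params, grid,
                              dtau = params$dtau) {
  check_field(candidate, grid, "candidate")
  op <- make_implicit_operator(prev, edge, params, grid, dtau)
  op$residual(interior_vec(candidate, grid))
}
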