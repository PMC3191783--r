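#' Uniform cell grid on the unit square
#'
#' Defines the finite-volume grid used throughout the package: `nx * ny`
#' square cells covering \eqn{[0,1] \times [0,1]}, with cell-centered
#' unknowns at \eqn{x_l = (l - 1/2) h_x}, \eqn{y_m = (m - 1/2) h_y}.
#' The outermost ring of cells carries the zero Dirichlet boundary
#' condition of the flow; all solvers operate on the interior cells only.
#'
#' @param nx number of cells along x (at least 3)
#' @param ny number of cells along y (defaults to `nx`)
#' @return an object of class `grid_spec` with fields `nx`, `ny`,
#'   `hx = 1/nx`, `hy = 1/ny`
#' @export
grid_spec <- function(nx, ny = nx) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 3L || ny < 3L)
    stop("grid_spec: need at least 3 cells per side, got ", nx, " x ", ny)
  structure(list(nx = nx, ny = ny, hx = 1 / nx, hy = 1 / ny),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells on [0,1]^2 (h = %.4g x %.4g)\n",
              x$nx, x$ny, x$hx, x$hy))
  invisible(x)
}

#' Cell-center coordinates
#'
#' @param grid a [grid_spec()]
#' @return list with vectors `x` (length `nx`) and `y` (length `ny`)
#' @export
cell_centers <- function(grid) {
  list(x = (seq_len(grid$nx) - 0.5) * grid$hx,
       y = (seq_len(grid$ny) - 0.5) * grid$hy)
}

## interior index helpers: unknowns are cells l = 2..nx-1, m = 2..ny-1,
## flattened x-fastest (column-major over the interior block).

n_interior <- function(grid) (grid$nx - 2L) * (grid$ny - 2L)

interior_vec <- function(u, grid) {
  as.vector(u[2:(grid$nx - 1L), 2:(grid$ny - 1L)])
}

full_field <- function(v, grid) {
  u <- matrix(0, grid$nx, grid$ny)
  u[2:(grid$nx - 1L), 2:(grid$ny - 1L)] <- v
  u
}

check_field <- function(u, grid, what = "field") {
  if (!is.matrix(u) || nrow(u) != grid$nx || ncol(u) != grid$ny)
    stop(what, ": expected a ", grid$nx, " x ", grid$ny,
         " matrix matching the grid")
  if (!all(is.finite(u))) stop(what, ": non-finite values")
  invisible(u)
}

#' Gradient of a cell-centered field
#'
#' Central differences at interior cells, one-sided differences on the
#' boundary ring, matching the second-order spatial target of the
#' discretization.
#'
#' @param u matrix field on `grid`
#' @param grid a [grid_spec()]
#' @return list of matrices `gx`, `gy`
#' @export
field_gradient <- function(u, grid) {
  check_field(u, grid)
  nx <- grid$nx; ny <- grid$ny
  gx <- matrix(0, nx, ny); gy <- matrix(0, nx, ny)
  gx[2:(nx - 1), ] <- (u[3:nx, ] - u[1:(nx - 2), ]) / (2 * grid$hx)
  gx[1, ]  <- (u[2, ] - u[1, ]) / grid$hx
  gx[nx, ] <- (u[nx, ] - u[nx - 1, ]) / grid$hx
  gy[, 2:(ny - 1)] <- (u[, 3:ny] - u[, 1:(ny - 2)]) / (2 * grid$hy)
  gy[, 1]  <- (u[, 2] - u[, 1]) / grid$hy
  gy[, ny] <- (u[, ny] - u[, ny - 1]) / grid$hy
  list(gx = gx, gy = gy)
}
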