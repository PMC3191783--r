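# Independent oracles, written with scalar loops / dense algebra so they
# share no code path with the package internals they check.

# Random smooth field vanishing on the boundary ring: a few low-order
# Fourier sine modes evaluated at cell centers, ring forced to zero.
random_smooth_field <- function(grid, seed, amplitude = 1) {
  set.seed(seed)
  cc <- cell_centers(grid)
  u <- matrix(0, grid$nx, grid$ny)
  for (k in 1:3) for (l in 1:3) {
    a <- amplitude * rnorm(1) / (k + l)
    u <- u + a * outer(sin(k * pi * cc$x), sin(l * pi * cc$y))
  }
  u[1, ] <- 0; u[grid$nx, ] <- 0; u[, 1] <- 0; u[, grid$ny] <- 0
  u
}

# Dense hand assembly of the spatial operator from its definition:
# row by row, with its own central-difference q and arithmetic face means.
dense_operator_oracle <- function(u_ref, g, epsilon, grid) {
  nx <- grid$nx; ny <- grid$ny; hx <- grid$hx; hy <- grid$hy
  grad_at <- function(l, m) {
    gx <- if (l == 1) (u_ref[2, m] - u_ref[1, m]) / hx
          else if (l == nx) (u_ref[nx, m] - u_ref[nx - 1, m]) / hx
          else (u_ref[l + 1, m] - u_ref[l - 1, m]) / (2 * hx)
    gy <- if (m == 1) (u_ref[l, 2] - u_ref[l, 1]) / hy
          else if (m == ny) (u_ref[l, ny] - u_ref[l, ny - 1]) / hy
          else (u_ref[l, m + 1] - u_ref[l, m - 1]) / (2 * hy)
    c(gx, gy)
  }
  qv <- matrix(0, nx, ny)
  for (l in 1:nx) for (m in 1:ny) {
    gr <- grad_at(l, m)
    qv[l, m] <- sqrt(epsilon^2 + gr[1]^2 + gr[2]^2)
  }
  nxi <- nx - 2L; nyi <- ny - 2L
  n <- nxi * nyi
  A <- matrix(0, n, n)
  id <- function(l, m) (l - 1L) + (m - 2L) * nxi  # interior numbering, x fastest
  for (m in 2:(ny - 1)) for (l in 2:(nx - 1)) {
    row <- id(l, m)
    Q <- qv[l, m]
    face <- function(l2, m2) {
      (g[l, m] + g[l2, m2]) / 2 / ((qv[l, m] + qv[l2, m2]) / 2)
    }
    dE <- face(l + 1, m); dW <- face(l - 1, m)
    dN <- face(l, m + 1); dS <- face(l, m - 1)
    A[row, row] <- Q * ((dE + dW) / hx^2 + (dN + dS) / hy^2)
    if (l + 1 <= nx - 1) A[row, id(l + 1, m)] <- -Q * dE / hx^2
    if (l - 1 >= 2)      A[row, id(l - 1, m)] <- -Q * dW / hx^2
    if (m + 1 <= ny - 1) A[row, id(l, m + 1)] <- -Q * dN / hy^2
    if (m - 1 >= 2)      A[row, id(l, m - 1)] <- -Q * dS / hy^2
  }
  A
}

# Dense 5-point Laplacian (negated divergence) on the interior of an
# n x n unit-square grid: the heat-equation operator oracle.
dense_laplacian_oracle <- function(n) {
  h <- 1 / n
  ni <- n - 2L
  N <- ni * ni
  L <- matrix(0, N, N)
  id <- function(l, m) l + (m - 1L) * ni
  for (m in 1:ni) for (l in 1:ni) {
    row <- id(l, m)
    L[row, row] <- 4 / h^2
    if (l > 1)  L[row, id(l - 1, m)] <- -1 / h^2
    if (l < ni) L[row, id(l + 1, m)] <- -1 / h^2
    if (m > 1)  L[row, id(l, m - 1)] <- -1 / h^2
    if (m < ni) L[row, id(l, m + 1)] <- -1 / h^2
  }
  L
}

# All-pairs brute-force Hausdorff distance with explicit loops.
hausdorff_bruteforce <- function(P, Q) {
  directed <- function(A, B) {
    worst <- 0
    for (i in seq_len(nrow(A))) {
      best <- Inf
      for (j in seq_len(nrow(B))) {
        d <- sqrt(sum((A[i, ] - B[j, ])^2))
        if (d < best) best <- d
      }
      if (best > worst) worst <- best
    }
    worst
  }
  max(directed(P, Q), directed(Q, P))
}

# Dense finite-difference Jacobian (central differences, column by column)
# of a residual operator at u.
dense_fd_jacobian <- function(res_fun, u, h = 1e-6) {
  n <- length(u)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    e <- numeric(n); e[j] <- h
    J[, j] <- (res_fun(u + e) - res_fun(u - e)) / (2 * h)
  }
  J
}

# Small test phantom shared across files.
tiny_phantom <- function(n = 48, seed = 0, noise = 0) {
  generate_phantom(n = n, shape = blob_shape(), noise_sigma = noise,
                   seed = seed)
}

# Hand-made dark-disk image for grids below the phantom generator's
# minimum size (e.g. the 8x8 dense-Jacobian oracle checks).
disk_image <- function(n, r = 0.28, interior = 0.2, background = 0.9) {
  grid <- grid_spec(n)
  cc <- cell_centers(grid)
  img <- matrix(background, n, n)
  img[outer((cc$x - 0.5)^2, (cc$y - 0.5)^2, `+`) < r^2] <- interior
  img
}
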