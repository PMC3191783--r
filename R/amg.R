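#' Configuration of the algebraic multigrid preconditioner
#'
#' @param max_levels maximum hierarchy depth (default 25)
#' @param coarse_size stop coarsening once a level has at most this many
#'   unknowns; that level is solved directly (sparse LU)
#' @param theta strength-of-connection threshold: entry (i, j) is strong
#'   when \eqn{|a_{ij}| \ge \theta \sqrt{|a_{ii} a_{jj}|}}
#' @param npre,npost Gauss-Seidel pre-/post-smoothing sweeps per level
#' @param rtol relative residual tolerance when AMG is iterated
#'   standalone (default 1e-7)
#' @return list of class `amg_config`
#' @export
amg_config <- function(max_levels = 25L, coarse_size = 40L, theta = 0.08,
                       npre = 1L, npost = 1L, rtol = 1e-7) {
  stopifnot(max_levels >= 1L, coarse_size >= 1L, theta >= 0,
            npre >= 0L, npost >= 0L, rtol > 0)
  structure(list(max_levels = as.integer(max_levels),
                 coarse_size = as.integer(coarse_size),
                 theta = theta, npre = as.integer(npre),
                 npost = as.integer(npost), rtol = rtol),
            class = "amg_config")
}

## Greedy strength-based aggregation. A is dgCMatrix. Returns an integer
## vector of aggregate ids (1..nagg) covering every unknown.
amg_aggregate <- function(A, theta) {
  n <- nrow(A)
  Ap <- A@p; Ai <- A@i; Ax <- A@x
  d <- abs(Matrix::diag(A))
  agg <- integer(n)             # 0 = unassigned
  # strong neighbor lists in CSC order (pattern symmetric for our stencils)
  strong <- vector("list", n)
  for (j in seq_len(n)) {
    k <- (Ap[j] + 1L):Ap[j + 1L]
    rows <- Ai[k] + 1L
    vals <- abs(Ax[k])
    keep <- rows != j & vals >= theta * sqrt(d[rows] * d[j])
    strong[[j]] <- rows[keep]
  }
  nagg <- 0L
  # pass 1: roots whose strong neighborhood is entirely unassigned
  for (j in seq_len(n)) {
    if (agg[j] != 0L) next
    nb <- strong[[j]]
    if (all(agg[nb] == 0L)) {
      nagg <- nagg + 1L
      agg[c(j, nb)] <- nagg
    }
  }
  # pass 2: attach leftovers to a neighboring aggregate (or start one)
  for (j in seq_len(n)) {
    if (agg[j] != 0L) next
    nb <- strong[[j]]
    hit <- nb[agg[nb] != 0L]
    if (length(hit) > 0L) {
      agg[j] <- agg[hit[1L]]
    } else {
      nagg <- nagg + 1L
      agg[j] <- nagg
    }
  }
  agg
}

## Spectral radius estimate of D^-1 A by a deterministic power iteration.
amg_rho_dinv_a <- function(A) {
  n <- nrow(A)
  dinv <- 1 / Matrix::diag(A)
  v <- sin(seq_len(n))          # fixed, seed-independent start vector
  v <- v / sqrt(sum(v^2))
  rho <- 1
  for (k in 1:12) {
    w <- dinv * as.vector(A %*% v)
    nw <- sqrt(sum(w^2))
    if (nw == 0) break
    rho <- nw
    v <- w / nw
  }
  rho
}

#' Build an algebraic multigrid hierarchy
#'
#' Smoothed-aggregation setup: unknowns are grouped into aggregates by a
#' greedy strength-of-connection pass, the piecewise-constant tentative
#' prolongator over the aggregates is smoothed by one damped-Jacobi step
#' \eqn{P = (I - \omega D^{-1} A)\,\hat P} with
#' \eqn{\omega = (4/3)/\rho(D^{-1}A)}, restriction is \eqn{R = P^T}, and
#' coarse operators follow the Galerkin rule
#' \eqn{A_{lv+1} = R_{lv} A_{lv} P_{lv}} exactly. Coarsening stops at
#' `coarse_size` unknowns or `max_levels` levels; the coarsest system is
#' factorized (sparse LU) once.
#'
#' @param A square sparse matrix (coercible to `dgCMatrix`)
#' @param config an [amg_config()]
#' @return object of class `amg_hierarchy`; its `levels` list carries
#'   `A`, `P`, `R`, cached triangular parts for the Gauss-Seidel
#'   smoother, and the coarse factorization on the last level
#' @export
build_amg_hierarchy <- function(A, config = amg_config()) {
  A <- methods::as(methods::as(A, "generalMatrix"), "CsparseMatrix")
  if (nrow(A) != ncol(A)) stop("build_amg_hierarchy: matrix must be square")
  levels <- list()
  cur <- A
  repeat {
    lev <- list(A = cur)
    n <- nrow(cur)
    last <- (n <= config$coarse_size) || (length(levels) + 1L >= config$max_levels)
    if (!last) {
      agg <- amg_aggregate(cur, config$theta)
      nagg <- max(agg)
      if (nagg >= n) last <- TRUE   # no coarsening progress
    }
    if (last) {
      lev$solve <- Matrix::lu(cur)
      levels[[length(levels) + 1L]] <- lev
      break
    }
    P_tent <- Matrix::sparseMatrix(i = seq_len(n), j = agg, x = 1,
                                   dims = c(n, nagg))
    omega <- (4 / 3) / amg_rho_dinv_a(cur)
    Dinv <- Matrix::Diagonal(n, 1 / Matrix::diag(cur))
    P <- P_tent - omega * (Dinv %*% (cur %*% P_tent))
    P <- methods::as(P, "CsparseMatrix")
    R <- Matrix::t(P)
    lev$P <- P
    lev$R <- R
    lev$L <- Matrix::tril(cur)    # lower triangle incl. diagonal
    lev$U <- Matrix::triu(cur)    # upper triangle incl. diagonal
    levels[[length(levels) + 1L]] <- lev
    cur <- methods::as(R %*% (cur %*% P), "CsparseMatrix")
  }
  structure(list(levels = levels, config = config,
                 lv_max = length(levels)),
            class = "amg_hierarchy")
}

#' @export
print.amg_hierarchy <- function(x, ...) {
  sizes <- vapply(x$levels, function(l) nrow(l$A), integer(1))
  cat(sprintf("<amg_hierarchy> %d level(s): %s unknowns\n",
              x$lv_max, paste(sizes, collapse = " -> ")))
  invisible(x)
}

## one forward (or backward) Gauss-Seidel sweep: x + T^-1 (b - A x)
gs_sweep <- function(lev, x, b, backward = FALSE) {
  r <- b - as.vector(lev$A %*% x)
  tri <- if (backward) lev$U else lev$L
  x + as.vector(Matrix::solve(tri, r))
}

amg_cycle_level <- function(h, lv, b, x) {
  lev <- h$levels[[lv]]
  if (!is.null(lev$solve))
    return(as.vector(Matrix::solve(lev$solve, b)))
  for (k in seq_len(h$config$npre)) x <- gs_sweep(lev, x, b)
  r <- b - as.vector(lev$A %*% x)
  rc <- as.vector(lev$R %*% r)
  ec <- amg_cycle_level(h, lv + 1L, rc, numeric(length(rc)))
  x <- x + as.vector(lev$P %*% ec)
  for (k in seq_len(h$config$npost)) x <- gs_sweep(lev, x, b, backward = TRUE)
  x
}

#' Apply one AMG V-cycle
#'
#' Runs a single V-cycle of the hierarchy on `b` starting from `x0`.
#' With `x0 = 0` this is the preconditioner application \eqn{M^{-1} b}
#' used inside GMRES.
#'
#' @param h an [build_amg_hierarchy()] result
#' @param b right-hand side vector
#' @param x0 starting iterate (default zero)
#' @return improved iterate
#' @export
amg_vcycle <- function(h, b, x0 = numeric(length(b))) {
  if (length(b) != nrow(h$levels[[1L]]$A) || length(x0) != length(b))
    stop("amg_vcycle: dimension mismatch")
  amg_cycle_level(h, 1L, b, x0)
}

#' Solve a system by iterated V-cycles
#'
#' Standalone AMG iteration to relative residual `rtol`
#' (default 1e-7 from the hierarchy's config).
#'
#' @inheritParams amg_vcycle
#' @param rtol relative residual target
#' @param max_cycles cycle budget
#' @return list with `x`, `cycles`, `rel_residual`, `converged`
#' @export
amg_solve <- function(h, b, rtol = h$config$rtol, max_cycles = 200L) {
  A <- h$levels[[1L]]$A
  nb <- sqrt(sum(b^2))
  if (nb == 0) return(list(x = numeric(length(b)), cycles = 0L,
                           rel_residual = 0, converged = TRUE))
  x <- numeric(length(b))
  for (k in seq_len(max_cycles)) {
    x <- amg_vcycle(h, b, x)
    rr <- sqrt(sum((b - as.vector(A %*% x))^2)) / nb
    if (rr <= rtol)
      return(list(x = x, cycles = k, rel_residual = rr, converged = TRUE))
  }
  list(x = x, cycles = max_cycles, rel_residual = rr, converged = FALSE)
}
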