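#' Configuration of the Jacobian-free Newton-Krylov solver
#'
#' @param newton_tol nonlinear residual tolerance (default 1e-10)
#' @param tol_mode `"relative"` (to the initial residual norm, with a
#'   tiny absolute floor) or `"absolute"`
#' @param max_newton maximum Newton steps
#' @param inner_rtol relative tolerance of the inner GMRES solves
#'   (fixed forcing term; the default 1e-5 sits safely above the noise
#'   floor of one-sided finite-difference Jacobian products — tighten it
#'   for small, well-scaled systems)
#' @param inner_restart restart length of the inner GMRES
#' @param inner_max_iter inner iteration budget per Newton step
#' @param armijo sufficient-decrease constant of the backtracking line
#'   search on \eqn{\tfrac12\|HI\|_2^2}
#' @param shrink backtracking shrink factor in (0, 1)
#' @param max_backtracks backtracking budget per Newton step
#' @return list of class `jfnk_config`
#' @export
jfnk_config <- function(newton_tol = 1e-10,
                        tol_mode = c("relative", "absolute"),
                        max_newton = 50L,
                        inner_rtol = 1e-5, inner_restart = 30L,
                        inner_max_iter = 500L,
                        armijo = 1e-4, shrink = 0.5, max_backtracks = 30L) {
  tol_mode <- match.arg(tol_mode)
  stopifnot(newton_tol > 0, inner_rtol > 0, shrink > 0, shrink < 1,
            armijo > 0, max_newton >= 1L, max_backtracks >= 1L)
  structure(list(newton_tol = newton_tol, tol_mode = tol_mode,
                 max_newton = as.integer(max_newton),
                 inner_rtol = inner_rtol,
                 inner_restart = as.integer(inner_restart),
                 inner_max_iter = as.integer(inner_max_iter),
                 armijo = armijo, shrink = shrink,
                 max_backtracks = as.integer(max_backtracks)),
            class = "jfnk_config")
}

## default perturbation: rho = sqrt(eps_mach) (1 + ||u||) / ||v||
jfnk_default_rho <- function(u, v) {
  sqrt(.Machine$double.eps) * (1 + sqrt(sum(u^2))) / sqrt(sum(v^2))
}

#' Finite-difference Jacobian-vector product
#'
#' Approximates \eqn{J(u)\,v} of a residual operator by the one-sided
#' difference \eqn{[HI(u + \rho v) - HI(u)]/\rho}. The base evaluation
#' `hi_u = HI(u)` may be supplied (it is cached across all products at
#' the same Newton iterate), so each product costs exactly one new
#' operator evaluation. A zero direction returns an exact zero without
#' evaluating the operator.
#'
#' @param op an operator with element `residual(v)` (e.g.
#'   [make_implicit_operator()]), or a plain function
#' @param u evaluation point (vector)
#' @param v direction (vector)
#' @param hi_u optional cached value of `HI(u)`
#' @param rho_rule function `(u, v) -> rho`; default
#'   \eqn{\sqrt{\epsilon_{mach}}\,(1 + \|u\|_2)/\|v\|_2}
#' @return approximation of `J(u) %*% v`
#' @export
jacobian_vector_product <- function(op, u, v, hi_u = NULL,
                                    rho_rule = jfnk_default_rho) {
  res <- if (is.function(op)) op else op$residual
  if (!any(v != 0)) return(numeric(length(v)))
  if (!all(is.finite(v))) stop("jacobian_vector_product: non-finite direction")
  if (is.null(hi_u)) hi_u <- res(u)
  rho <- rho_rule(u, v)
  (res(u + rho * v) - hi_u) / rho
}

#' Solve a nonlinear system by Jacobian-free Newton-Krylov
#'
#' Newton iteration on \eqn{HI(u) = 0} in which each correction solves
#' \eqn{J(u_n)\,\delta = -HI(u_n)} by (optionally preconditioned)
#' GMRES with matrix-free Jacobian-vector products
#' ([jacobian_vector_product()]), globalized by a backtracking Armijo
#' line search on \eqn{\tfrac12\|HI\|_2^2}. An accepted step never
#' increases the residual norm.
#'
#' @param op residual operator (see [make_implicit_operator()]) or a
#'   plain function `HI(u)`
#' @param u_init starting vector
#' @param config a [jfnk_config()]
#' @param precond optional inner-GMRES preconditioner `function(r)`
#'   (e.g. a frozen-operator [amg_preconditioner()]); default none
#' @return list with the solution `u` and `report`, a `newton_report`
#'   with fields `newton_steps`, `inner_iterations` (vector, one entry
#'   per Newton step), `residual_history`, `f_evals`, `converged`
#' @export
jfnk_solve <- function(op, u_init, config = jfnk_config(), precond = NULL) {
  res <- if (is.function(op)) op else op$residual
  count0 <- if (is.function(op)) NULL else op$count()
  u <- u_init
  hi <- res(u)
  rnorm0 <- sqrt(sum(hi^2))
  target <- switch(config$tol_mode,
                   relative = config$newton_tol * rnorm0 + 1e-300,
                   absolute = config$newton_tol)
  hist <- rnorm0
  inner <- integer(0)
  converged <- rnorm0 <= target
  failure <- NULL
  steps <- 0L
  while (!converged && steps < config$max_newton) {
    jv <- function(v) jacobian_vector_product(op, u, v, hi_u = hi)
    sol <- gmres_solve(jv, -hi, precond = precond,
                       rtol = config$inner_rtol,
                       restart = config$inner_restart,
                       max_iter = config$inner_max_iter)
    delta <- sol$x
    inner <- c(inner, sol$report$iterations)
    # backtracking Armijo line search on phi = 0.5 ||HI||^2
    phi0 <- 0.5 * sum(hi^2)
    slope <- -2 * phi0            # model slope along the Newton direction
    lambda <- 1
    ok <- FALSE
    for (bt in seq_len(config$max_backtracks)) {
      u_try <- u + lambda * delta
      hi_try <- res(u_try)
      phi_try <- 0.5 * sum(hi_try^2)
      if (is.finite(phi_try) &&
          phi_try <= phi0 + config$armijo * lambda * slope) {
        ok <- TRUE
        break
      }
      lambda <- lambda * config$shrink
    }
    steps <- steps + 1L
    if (!ok) {
      failure <- "line search failed to find sufficient decrease"
      break
    }
    u <- u_try
    hi <- hi_try
    rn <- sqrt(sum(hi^2))
    hist <- c(hist, rn)
    converged <- rn <= target
  }
  if (!converged && is.null(failure) && steps >= config$max_newton)
    failure <- "maximum Newton steps exceeded"
  f_evals <- if (is.null(count0)) NA_integer_ else op$count() - count0
  report <- structure(list(newton_steps = steps,
                           inner_iterations = inner,
                           residual_history = hist,
                           f_evals = f_evals,
                           converged = converged,
                           failure = failure),
                      class = "newton_report")
  list(u = u, report = report)
}

#' @export
print.newton_report <- function(x, ...) {
  cat(sprintf("<newton_report> %d Newton step(s), final ||HI|| = %.3g%s\n",
              x$newton_steps, utils::tail(x$residual_history, 1),
              if (x$converged) " (converged)"
              else paste0(" (NOT converged: ", x$failure, ")")))
  if (length(x$inner_iterations))
    cat("  inner GMRES iterations:",
        paste(x$inner_iterations, collapse = ", "), "\n")
  invisible(x)
}
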