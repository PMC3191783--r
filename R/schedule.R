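#' Match semi-implicit and implicit step sizes at equal error
#'
#' The semi-implicit scheme is first-order accurate in scale while the
#' Crank-Nicolson implicit scheme is second-order; requiring the same
#' discretization error magnitude couples the steps as
#' \eqn{\Delta\tau_{SI} = \Delta\tau_I^2}.
#'
#' @param dtau_implicit implicit scheme step \eqn{\Delta\tau_I}
#' @return named vector `c(dtau_si = dtau_implicit^2, dtau_implicit)`
#' @export
plan_step_sizes <- function(dtau_implicit) {
  if (!is.numeric(dtau_implicit) || dtau_implicit <= 0)
    stop("plan_step_sizes: dtau_implicit must be > 0")
  if (dtau_implicit > 1)
    warning("plan_step_sizes: dtau_implicit > 1; squaring enlarges the step")
  c(dtau_si = dtau_implicit^2, dtau_implicit = dtau_implicit)
}

#' Number of scale steps for a horizon
#'
#' \eqn{N = \lceil T / \Delta\tau \rceil}, with a small relative guard
#' so that exact ratios are not pushed up by floating-point division
#' (0.4/0.04 must give 10; 0.4/0.16 = 2.5 gives 3).
#'
#' @param T scale horizon
#' @param dtau scale step
#' @return integer step count, at least 1
#' @export
num_scale_steps <- function(T, dtau) {
  if (!is.numeric(T) || T <= 0 || !is.numeric(dtau) || dtau <= 0)
    stop("num_scale_steps: T and dtau must be > 0")
  r <- T / dtau
  max(1L, as.integer(ceiling(r * (1 - 1e-9) - 1e-12)))
}

#' Schedule for a segmentation run
#'
#' @param scheme `"semi_implicit"`, `"implicit"` or `"explicit"`
#' @param dtau scale step
#' @param T scale horizon (default 0.4, suited to clean synthetic
#'   objects; use e.g. 2 for harder real images)
#' @param n_steps number of steps; default `num_scale_steps(T, dtau)`.
#'   An explicit `n_steps = 0` is accepted and leaves the initial state
#'   untouched
#' @return list of class `schedule_plan`
#' @export
schedule_plan <- function(scheme = c("semi_implicit", "implicit", "explicit"),
                          dtau, T = 0.4,
                          n_steps = num_scale_steps(T, dtau)) {
  scheme <- match.arg(scheme)
  if (dtau <= 0 || T <= 0) stop("schedule_plan: dtau and T must be > 0")
  if (n_steps < 0L) stop("schedule_plan: n_steps must be >= 0")
  structure(list(scheme = scheme, dtau = dtau, T = T,
                 n_steps = as.integer(n_steps)),
            class = "schedule_plan")
}

#' @export
print.schedule_plan <- function(x, ...) {
  cat(sprintf("<schedule_plan> %s scheme: %d step(s) of dtau = %g (T = %g)\n",
              x$scheme, x$n_steps, x$dtau, x$T))
  invisible(x)
}

#' Steady-state test between consecutive scale steps
#'
#' Residual \eqn{\|u_i - u_{i-1}\|_2 / (\Delta\tau\,\|u_i\|_2 + f)} with
#' a tiny floor \eqn{f = 10^{-30}} against all-zero states; the flow is
#' declared stationary once it drops below `tol` (default 1e-9).
#'
#' @param u_curr,u_prev fields (matrices or vectors) on the same grid
#' @param dtau scale step used between them
#' @param tol tolerance
#' @return list with `reached` (logical) and `residual`
#' @export
steady_state_reached <- function(u_curr, u_prev, dtau, tol = 1e-9) {
  if (length(u_curr) != length(u_prev))
    stop("steady_state_reached: fields differ in size")
  num <- sqrt(sum((u_curr - u_prev)^2))
  den <- dtau * sqrt(sum(u_curr^2)) + 1e-30
  res <- num / den
  list(reached = res <= tol, residual = res)
}
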