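## ---- reproduction experiments --------------------------------------------
## Shared by the test suite and scripts/acceptance.R so the measured
## quantities are computed by one code path.

#' Measure the temporal convergence order of a scheme
#'
#' Starting from a smoothed state (a few semi-implicit steps from the
#' seed bump, so that startup transients do not pollute the
#' asymptotics), evolves the flow over a window `T_window` with a
#' halving sequence of scale steps and compares against a tiny-step
#' Crank-Nicolson reference. The fitted slope of log error versus log
#' step recovers the scheme's temporal order (semi-implicit: 1,
#' Crank-Nicolson implicit: 2).
#'
#' @param phantom an `mcf_phantom` (a smooth 64 by 64 object is ample)
#' @param scheme scheme to measure
#' @param seed_radius seed circle radius
#' @param T_window scale window over which errors are measured
#' @param dt_divisors `T_window / dt_divisors` is the step sequence
#' @param ref_divisor divisor for the reference step
#' @param params an [mcf_params()]
#' @return list with `order` (fitted slope), `errors`, `dtaus`
#' @export
temporal_order_experiment <- function(phantom,
                                      scheme = c("semi_implicit", "implicit"),
                                      seed_radius = 0.12,
                                      T_window = 0.2,
                                      dt_divisors = c(16, 32, 64),
                                      ref_divisor = 512,
                                      params = mcf_params()) {
  scheme <- match.arg(scheme)
  grid <- phantom$grid
  u0 <- make_seed_function(grid, c(0.5, 0.5), seed_radius)
  # presmooth: the mollifier bump carries stiff content; two lagged
  # diffusion steps damp it so the order measurement sees the smooth regime
  pre <- run_segmentation(phantom$image, u0, params,
                          schedule_plan("semi_implicit", dtau = 0.025, T = 0.1),
                          grid = grid)
  ustart <- pre$state$u
  ctrl <- mcf_control(rannacher_startup = FALSE,
                      jfnk = jfnk_config(inner_rtol = 1e-8, newton_tol = 1e-12))
  run_to <- function(scheme, dtau) {
    r <- run_segmentation(phantom$image, ustart, params,
                          schedule_plan(scheme, dtau = dtau, T = T_window),
                          control = ctrl, grid = grid)
    if (!r$record$status %in% c("completed", "steady state"))
      stop("temporal_order_experiment: solver failure (", r$record$status, ")")
    r$state$u
  }
  ref <- run_to("implicit", T_window / ref_divisor)
  dtaus <- T_window / dt_divisors
  errors <- vapply(dtaus, function(dt)
    sqrt(mean((run_to(scheme, dt) - ref)^2)), numeric(1))
  order <- unname(stats::coef(stats::lm(log(errors) ~ log(dtaus)))[2])
  list(order = order, errors = errors, dtaus = dtaus)
}

#' Newton residual decay exponent of one implicit step
#'
#' Runs the Jacobian-free Newton-Krylov solver on a single
#' Crank-Nicolson step of a coarse phantom segmentation with tight
#' inner solves, and estimates the local convergence order from the
#' last three residuals: \eqn{p = \log(r_n/r_{n-1}) / \log(r_{n-1}/r_{n-2})}.
#' Quadratic local convergence gives exponents near 2.
#'
#' @param n coarse grid size (default 24)
#' @param dtau scale step of the probed Crank-Nicolson system
#' @param seed phantom seed
#' @return list with `exponent`, `residual_history`, `report`
#' @export
newton_decay_experiment <- function(n = 24L, dtau = 0.1, seed = 0L) {
  ph <- generate_phantom(n = n, seed = seed)
  grid <- ph$grid
  params <- mcf_params()
  edge <- compute_edge_field(ph$image, params, grid)
  u0 <- make_seed_function(grid, c(0.5, 0.5), 0.15)
  op <- make_implicit_operator(segmentation_state(u0), edge, params, grid,
                               dtau = dtau)
  sol <- jfnk_solve(op, interior_vec(u0, grid),
                    jfnk_config(newton_tol = 1e-11, inner_rtol = 1e-12,
                                inner_restart = 100L, inner_max_iter = 2000L))
  h <- sol$report$residual_history
  nh <- length(h)
  if (nh < 3) stop("newton_decay_experiment: too few Newton steps to estimate")
  exponent <- log(h[nh] / h[nh - 1]) / log(h[nh - 1] / h[nh - 2])
  list(exponent = exponent, residual_history = h, report = sol$report)
}

#' Compare schemes on a phantom at matched discretization error
#'
#' Segments a phantom with the implicit scheme at the given step(s) and
#' with the semi-implicit scheme at its step(s), and scores every
#' contour against the analytic truth with the Hausdorff distance — the
#' scheme-robustness comparison of the package.
#'
#' @param phantom an `mcf_phantom`
#' @param dtau_implicit implicit steps to try
#' @param dtau_si semi-implicit steps to try
#' @param T scale horizon (default 0.4)
#' @param seed_center,seed_radius seed circle
#' @param control an [mcf_control()]
#' @return data frame with scheme, dtau, n_steps, hausdorff (unit-square
#'   units), plus the fits as attribute `fits`
#' @export
scheme_comparison_experiment <- function(phantom,
                                         dtau_implicit = c(0.4, 0.04),
                                         dtau_si = 0.016,
                                         T = 0.4,
                                         seed_center = c(0.5, 0.5),
                                         seed_radius = 0.12,
                                         control = mcf_control()) {
  runs <- rbind(
    data.frame(scheme = "implicit", dtau = dtau_implicit),
    data.frame(scheme = "semi_implicit", dtau = dtau_si))
  fits <- vector("list", nrow(runs))
  out <- vector("list", nrow(runs))
  for (k in seq_len(nrow(runs))) {
    fit <- mcf_segment(phantom, seed_center, seed_radius,
                       scheme = runs$scheme[k], dtau = runs$dtau[k], T = T,
                       control = control)
    fits[[k]] <- fit
    out[[k]] <- data.frame(scheme = runs$scheme[k], dtau = runs$dtau[k],
                           n_steps = nrow(fit$record$steps),
                           hausdorff = hausdorff_distance(
                             fit, phantom$truth_contour))
  }
  res <- do.call(rbind, out)
  attr(res, "fits") <- fits
  res
}
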