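#' Model parameters for the mean curvature flow
#'
#' Collects the tunables of the segmentation PDE
#' \deqn{u_\tau = \sqrt{\epsilon^2 + |\nabla u|^2}\,
#'       \nabla\cdot\!\Big(g(|\nabla I^0|)\,
#'       \frac{\nabla u}{\sqrt{\epsilon^2 + |\nabla u|^2}}\Big)}
#' with zero Dirichlet boundary conditions.
#'
#' @param epsilon regularization \eqn{\epsilon} of the gradient magnitude;
#'   larger values push the flow toward plain edge-weighted diffusion.
#'   Default 1.0.
#' @param beta Perona-Malik contrast parameter \eqn{\beta} of the edge
#'   detector \eqn{g(v) = 1/(1 + v^2/\beta)}. Default 1.0.
#' @param sigma standard deviation, in pixels, of the Gaussian presmoothing
#'   applied to the image before its gradient enters the edge detector;
#'   `sigma = 0` disables presmoothing. Default 1.0.
#' @param T scale horizon: the flow is integrated over \eqn{\tau \in [0,T]}.
#'   Default 0.4 (adequate for clean synthetic objects; harder images need
#'   longer horizons, e.g. 2).
#' @param dtau default scale step \eqn{\Delta\tau}. Default 0.16.
#' @return an object of class `mcf_params`
#' @export
mcf_params <- function(epsilon = 1.0, beta = 1.0, sigma = 1.0,
                       T = 0.4, dtau = 0.16) {
  if (!is.numeric(epsilon) || epsilon <= 0) stop("epsilon must be > 0")
  if (!is.numeric(beta) || beta <= 0) stop("beta must be > 0")
  if (!is.numeric(sigma) || sigma < 0) stop("sigma must be >= 0")
  if (!is.numeric(T) || T <= 0) stop("T must be > 0")
  if (!is.numeric(dtau) || dtau <= 0 || dtau > T)
    stop("dtau must satisfy 0 < dtau <= T")
  structure(list(epsilon = epsilon, beta = beta, sigma = sigma,
                 T = T, dtau = dtau),
            class = "mcf_params")
}

#' @export
print.mcf_params <- function(x, ...) {
  cat(sprintf(
    "<mcf_params> epsilon = %g, beta = %g, sigma = %g px, T = %g, dtau = %g\n",
    x$epsilon, x$beta, x$sigma, x$T, x$dtau))
  invisible(x)
}
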