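#' Perona-Malik edge-stopping function
#'
#' \eqn{g(v) = 1 / (1 + v^2/\beta)}: equal to 1 where the (presmoothed)
#' image gradient vanishes, decaying to 0 at strong edges, so that the
#' diffusion of the segmentation function is blocked at object boundaries.
#'
#' @param v nonnegative gradient magnitude(s)
#' @param beta contrast parameter, strictly positive
#' @return values in (0, 1], same shape as `v`
#' @export
perona_malik <- function(v, beta = 1.0) {
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0)
    stop("perona_malik: beta must be a positive scalar")
  if (any(v < 0)) stop("perona_malik: gradient magnitude must be >= 0")
  1 / (1 + v^2 / beta)
}

## Separable Gaussian convolution with reflective image extension.
## Kernel truncated at 4 sigma; sigma in pixel units.
gaussian_blur <- function(u, sigma) {
  if (sigma < 0) stop("gaussian_blur: sigma must be >= 0")
  if (sigma == 0) return(u)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  reflect_idx <- function(n) {
    # indices 1..n extended by r on both sides, reflected at the frame
    idx <- (1L - r):(n + r)
    idx[idx < 1L] <- 2L - idx[idx < 1L]
    idx[idx > n]  <- 2L * n - idx[idx > n]
    idx
  }
  conv_cols <- function(m) {
    # smooth down each column
    n <- nrow(m)
    ext <- m[reflect_idx(n), , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k))
      out <- out + k[j] * ext[j:(j + n - 1L), , drop = FALSE]
    out
  }
  t(conv_cols(t(conv_cols(u))))
}

#' Edge indicator field of an image
#'
#' Computes \eqn{g(|\nabla (G_\sigma * I^0)|)} on the grid: the image is
#' presmoothed by a Gaussian of width `params$sigma` pixels (reflective
#' extension at the frame), its gradient magnitude is taken by central
#' differences, and the Perona-Malik function is applied. The result is
#' static for a segmentation run.
#'
#' @param image matrix of intensities in \[0, 1\] on `grid`
#' @param params an [mcf_params()]
#' @param grid a [grid_spec()]; defaults to a grid matching `image`
#' @return object of class `edge_field` with matrix component `g`
#' @export
compute_edge_field <- function(image, params = mcf_params(),
                               grid = grid_spec(nrow(image), ncol(image))) {
  check_field(image, grid, "image")
  smoothed <- gaussian_blur(image, params$sigma)
  gr <- field_gradient(smoothed, grid)
  v <- sqrt(gr$gx^2 + gr$gy^2)
  g <- perona_malik(v, params$beta)
  structure(list(g = g, sigma = params$sigma, beta = params$beta,
                 source_image_id = attr(image, "image_id")),
            class = "edge_field")
}

#' @export
print.edge_field <- function(x, ...) {
  cat(sprintf("<edge_field> %d x %d, g in [%.3g, %.3g] (sigma = %g, beta = %g)\n",
              nrow(x$g), ncol(x$g), min(x$g), max(x$g), x$sigma, x$beta))
  invisible(x)
}

#' Regularized gradient magnitude
#'
#' Pointwise \eqn{\sqrt{\epsilon^2 + |\nabla u|^2}} at cell centers, the
#' quantity that turns degenerate curvature motion into the
#' epsilon-regularized Riemannian flow (always at least \eqn{\epsilon}).
#'
#' @param u matrix field
#' @param epsilon regularization, strictly positive
#' @param grid a [grid_spec()]; defaults to a grid matching `u`
#' @return matrix of the same shape as `u`
#' @export
regularized_gradient_magnitude <- function(u, epsilon,
                                           grid = grid_spec(nrow(u), ncol(u))) {
  if (!is.numeric(epsilon) || epsilon <= 0)
    stop("regularized_gradient_magnitude: epsilon must be > 0")
  gr <- field_gradient(u, grid)
  sqrt(epsilon^2 + gr$gx^2 + gr$gy^2)
}
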