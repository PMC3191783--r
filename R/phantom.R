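#' Shape descriptor for synthetic phantoms
#'
#' Star-shaped smooth blob given in polar form around a center:
#' \eqn{r(\theta) = r_0 (1 + \sum_k a_k \cos(k\theta + \phi_k))} with
#' small perturbation amplitudes, so the object stays smooth,
#' non-self-intersecting and has an analytic ground-truth contour.
#'
#' @param r0 base radius (unit-square units)
#' @param harmonics integer wave numbers k of the radial perturbation
#' @param amplitudes amplitudes \eqn{a_k} (their absolute sum must stay
#'   below 1 to keep the radius positive; in practice keep it small)
#' @param phases phase offsets \eqn{\phi_k}
#' @param center blob center
#' @return list of class `blob_shape` including the radius function
#'   `radius(theta)`
#' @export
blob_shape <- function(r0 = 0.25, harmonics = c(2L, 3L, 5L),
                       amplitudes = c(0.06, 0.04, 0.02),
                       phases = c(0.5, 1.7, 0.3),
                       center = c(0.5, 0.5)) {
  if (r0 <= 0) stop("blob_shape: degenerate shape (zero radius)")
  if (length(harmonics) != length(amplitudes) ||
      length(phases) != length(amplitudes))
    stop("blob_shape: harmonics, amplitudes and phases must have equal length")
  if (sum(abs(amplitudes)) >= 1)
    stop("blob_shape: perturbation too large; radius would vanish")
  radius <- function(theta) {
    pert <- rep(1, length(theta))
    for (j in seq_along(harmonics))
      pert <- pert + amplitudes[j] * cos(harmonics[j] * theta + phases[j])
    r0 * pert
  }
  structure(list(r0 = r0, harmonics = as.integer(harmonics),
                 amplitudes = amplitudes, phases = phases,
                 center = center, radius = radius),
            class = "blob_shape")
}

## evaluate expr with a private, seeded RNG stream; caller's stream intact
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic test phantom
#'
#' Produces a grayscale image of one smooth dark object on a light
#' background (default intensities 0.2 / 0.9, the contrast situation of
#' a pigmented lesion under epiluminescence imaging) together with its
#' analytic ground-truth contour, optionally degraded by additive
#' Gaussian noise clipped to \[0,1\]. Identical `(parameters, seed)`
#' give bit-identical phantoms.
#'
#' @param n grid size per side (at least 16)
#' @param shape a [blob_shape()]
#' @param noise_sigma additive Gaussian noise standard deviation
#'   (intensity units; default 0, i.e. a clean image)
#' @param seed integer RNG seed for the noise
#' @param interior,background object and background intensities
#' @return object of class `mcf_phantom` with `image`, `truth_contour`
#'   (a [contour_set()] with vertex spacing at most one cell),
#'   `grid`, `shape`, `noise_sigma`, `seed`
#' @export
generate_phantom <- function(n = 840L, shape = blob_shape(),
                             noise_sigma = 0, seed = 0L,
                             interior = 0.2, background = 0.9) {
  n <- as.integer(n)
  if (n < 16L) stop("generate_phantom: n must be at least 16")
  if (noise_sigma < 0) stop("generate_phantom: noise_sigma must be >= 0")
  if (!inherits(shape, "blob_shape")) stop("generate_phantom: shape must be a blob_shape")
  grid <- grid_spec(n, n)
  cc <- cell_centers(grid)
  dx <- outer(cc$x - shape$center[1], rep(1, n))
  dy <- outer(rep(1, n), cc$y - shape$center[2])
  theta <- atan2(dy, dx)
  inside <- sqrt(dx^2 + dy^2) < shape$radius(theta)
  img <- matrix(background, n, n)
  img[inside] <- interior
  if (abs(interior - background) < 0.1)
    stop("generate_phantom: interior/background contrast below minimum (0.1)")
  if (noise_sigma > 0) {
    img <- with_seed(seed, img + matrix(stats::rnorm(n * n, 0, noise_sigma), n, n))
    img <- pmin(pmax(img, 0), 1)
  }
  # contour sampled with vertex spacing <= one cell
  r_max <- max(shape$radius(seq(0, 2 * pi, length.out = 720L)))
  if (shape$center[1] - r_max <= 0 || shape$center[1] + r_max >= 1 ||
      shape$center[2] - r_max <= 0 || shape$center[2] + r_max >= 1)
    stop("generate_phantom: object exits the unit square")
  n_theta <- max(64L, as.integer(ceiling(4 * pi * r_max / grid$hx)))
  th <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  r <- shape$radius(th)
  truth <- contour_set(cbind(shape$center[1] + r * cos(th),
                             shape$center[2] + r * sin(th)),
                       source = "analytic truth")
  structure(list(image = img, truth_contour = truth, grid = grid,
                 shape = shape, noise_sigma = noise_sigma,
                 seed = as.integer(seed),
                 interior = interior, background = background),
            class = "mcf_phantom")
}

#' @export
print.mcf_phantom <- function(x, ...) {
  cat(sprintf(
    "<mcf_phantom> %d x %d image, blob r0 = %g, noise sigma = %g, seed = %d\n",
    x$grid$nx, x$grid$ny, x$shape$r0, x$noise_sigma, x$seed))
  invisible(x)
}

#' @export
plot.mcf_phantom <- function(x, ...) {
  cc <- cell_centers(x$grid)
  graphics::image(cc$x, cc$y, x$image, col = grDevices::gray.colors(256),
                  asp = 1, xlab = "x", ylab = "y", main = "phantom", ...)
  tp <- x$truth_contour$points
  graphics::lines(rbind(tp, tp[1, , drop = FALSE]), col = "dodgerblue")
  invisible(x)
}
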