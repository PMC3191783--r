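#' Contour point set
#'
#' @param points two-column matrix of (x, y) positions in unit-square
#'   coordinates
#' @param level level value the contour was extracted at (optional)
#' @param source provenance tag (optional)
#' @return object of class `contour_set`
#' @export
contour_set <- function(points, level = NA_real_, source = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("contour_set: points must have two columns")
  if (nrow(points) == 0L) stop("contour_set: empty point set")
  if (!all(is.finite(points))) stop("contour_set: non-finite coordinates")
  colnames(points) <- c("x", "y")
  structure(list(points = points, level = level, source = source),
            class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  cat(sprintf("<contour_set> %d points%s\n", nrow(x$points),
              if (is.na(x$level)) "" else sprintf(" at level %.4g", x$level)))
  invisible(x)
}

as_points <- function(x) {
  if (inherits(x, "contour_set")) x$points
  else if (inherits(x, "mcf_segmentation")) x$contour$points
  else as.matrix(x)
}

#' Extract a level line from a field
#'
#' Sub-cell contour points by linear interpolation along cell edges
#' (marching squares), at the requested level. Points are returned in
#' unit-square coordinates; where the level set is a single closed
#' curve, they are ordered along it.
#'
#' @param u matrix field, or an `mcf_segmentation` fit (whose final
#'   field is used with default level half its maximum)
#' @param level contour level, strictly between `min(u)` and `max(u)`
#' @param grid a [grid_spec()]; defaults to a grid matching `u`
#' @return a [contour_set()]
#' @export
extract_contour <- function(u, level = 0.5 * max(u),
                            grid = grid_spec(nrow(u), ncol(u))) {
  if (inherits(u, "mcf_segmentation")) {
    grid <- u$grid
    u <- u$u
    if (missing(level)) level <- 0.5 * max(u)
  }
  check_field(u, grid, "u")
  if (level <= min(u) || level >= max(u))
    stop("extract_contour: level ", level,
         " is outside the open range of the field (",
         min(u), ", ", max(u), "); no crossing exists")
  cc <- cell_centers(grid)
  lines <- grDevices::contourLines(cc$x, cc$y, u, levels = level)
  if (length(lines) == 0L)
    stop("extract_contour: no level crossing found")
  pts <- do.call(rbind, lapply(lines, function(l) cbind(l$x, l$y)))
  contour_set(pts, level = level)
}

#' Hausdorff distance between two finite point sets
#'
#' \deqn{d_H(C_1, C_2) = \max\{h(C_1, C_2),\, h(C_2, C_1)\}, \quad
#'       h(C_1, C_2) = \max_{a \in C_1} \min_{b \in C_2} \|a - b\|_2.}
#' Computed exactly over all pairs (vectorized); distances are in the
#' coordinates of the inputs (unit-square coordinates for contours from
#' [extract_contour()]; divide by `h` for cells).
#'
#' @param C1,C2 [contour_set()]s, two-column matrices, or
#'   `mcf_segmentation` fits
#' @return nonnegative scalar, symmetric in the arguments
#' @export
hausdorff_distance <- function(C1, C2) {
  P <- as_points(C1); Q <- as_points(C2)
  if (nrow(P) == 0L || nrow(Q) == 0L)
    stop("hausdorff_distance: point sets must be nonempty")
  if (!all(is.finite(P)) || !all(is.finite(Q)))
    stop("hausdorff_distance: non-finite coordinates")
  # squared distances of all pairs, blockwise to bound memory
  directed <- function(Amat, Bmat) {
    worst <- 0
    nb <- nrow(Bmat)
    step <- max(1L, floor(2e6 / nb))
    for (s in seq(1L, nrow(Amat), by = step)) {
      e <- min(s + step - 1L, nrow(Amat))
      blk <- Amat[s:e, , drop = FALSE]
      d2 <- outer(blk[, 1], Bmat[, 1], `-`)^2 +
            outer(blk[, 2], Bmat[, 2], `-`)^2
      worst <- max(worst, max(apply(d2, 1L, min)))
    }
    sqrt(worst)
  }
  max(directed(P, Q), directed(Q, P))
}
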