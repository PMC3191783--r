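#' Load a grayscale image as a field on the unit square
#'
#' Reads PNG or TIFF, converts to grayscale (channel mean) if needed,
#' and min-max normalizes intensities to \[0,1\]. The returned matrix
#' is oriented as a field `u[l, m]` with `l` the x index and `m` the y
#' index counted upward, so a square image maps onto the unit square.
#'
#' @param path image file (.png, .tif, .tiff)
#' @return matrix field with attributes `grid` (a [grid_spec()]) and
#'   `image_id` (the file name)
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("load_image: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("load_image: unsupported extension .", ext))
  if (length(dim(raw)) == 3L) raw <- rowMeans(raw, dims = 2L)
  rng <- range(raw)
  if (diff(rng) == 0)
    stop("load_image: zero dynamic range (constant image)")
  raw <- (raw - rng[1]) / diff(rng)
  # image rows run top-down; the field's y axis runs bottom-up
  u <- t(raw[nrow(raw):1, , drop = FALSE])
  attr(u, "grid") <- grid_spec(nrow(u), ncol(u))
  attr(u, "image_id") <- basename(path)
  u
}

#' Save a field as a grayscale image
#'
#' Values are clipped to \[0,1\]; TIFF output is written with 16 bits
#' per sample, PNG with 8.
#'
#' @param u matrix field (x by y, y upward)
#' @param path output file (.png, .tif, .tiff)
#' @return `path`, invisibly
#' @export
save_image <- function(u, path) {
  img <- pmin(pmax(t(u)[ncol(u):1, , drop = FALSE], 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(img, path),
         tif = ,
         tiff = tiff::writeTIFF(img, path, bits.per.sample = 16L),
         stop("save_image: unsupported extension .", ext))
  invisible(path)
}

#' Write / read a contour as CSV
#'
#' Plain `x,y` rows in unit-square coordinates.
#'
#' @param contour a [contour_set()] (or coercible point matrix)
#' @param path CSV file path
#' @return `path` (write) or a [contour_set()] (read)
#' @export
write_contour_csv <- function(contour, path) {
  pts <- as_points(contour)
  utils::write.csv(data.frame(x = pts[, 1], y = pts[, 2]), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_contour_csv
#' @export
read_contour_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("x", "y") %in% names(df)))
    stop("read_contour_csv: expected columns x,y in ", path)
  contour_set(cbind(df$x, df$y), source = basename(path))
}

#' Write a convergence record as CSV
#'
#' @param record the `mcf_record` of a fit
#' @param path CSV file path
#' @export
write_record_csv <- function(record, path) {
  utils::write.csv(record$steps, path, row.names = FALSE)
  invisible(path)
}

#' Run configuration: build, save and load
#'
#' A flat description of one segmentation run (model parameters,
#' scheme, schedule, solver tolerances, seed, paths) that round-trips
#' losslessly through YAML, for reproducible experiment sweeps.
#'
#' @param params an [mcf_params()]
#' @param scheme scheme name
#' @param dtau,T schedule
#' @param seed integer seed
#' @param center,radius seed circle
#' @param control an [mcf_control()]
#' @param paths named list of output paths (optional)
#' @return list of class `run_config`
#' @export
run_config <- function(params = mcf_params(), scheme = "semi_implicit",
                       dtau = params$dtau, T = params$T, seed = 0L,
                       center = c(0.5, 0.5), radius = 0.2,
                       control = mcf_control(), paths = list()) {
  structure(list(model = list(epsilon = params$epsilon, beta = params$beta,
                              sigma = params$sigma),
                 schedule = list(scheme = scheme, dtau = dtau, T = T),
                 seed_circle = list(center_x = center[1], center_y = center[2],
                                    radius = radius),
                 solver = list(linear_rtol = control$linear_rtol,
                               restart = control$restart,
                               amg_max_levels = control$amg$max_levels,
                               amg_rtol = control$amg$rtol,
                               newton_tol = control$jfnk$newton_tol,
                               inner_rtol = control$jfnk$inner_rtol,
                               steady_tol = control$steady_tol),
                 seed = as.integer(seed),
                 paths = paths),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`
#' @param path YAML file path
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
load_run_config <- function(path) {
  structure(yaml::read_yaml(path), class = "run_config")
}

## reconstruct the typed objects a run needs from a run_config
config_to_args <- function(cfg) {
  params <- mcf_params(epsilon = cfg$model$epsilon, beta = cfg$model$beta,
                       sigma = cfg$model$sigma,
                       T = cfg$schedule$T, dtau = cfg$schedule$dtau)
  control <- mcf_control(linear_rtol = cfg$solver$linear_rtol,
                         restart = cfg$solver$restart,
                         amg = amg_config(max_levels = cfg$solver$amg_max_levels,
                                          rtol = cfg$solver$amg_rtol),
                         jfnk = jfnk_config(newton_tol = cfg$solver$newton_tol,
                                            inner_rtol = cfg$solver$inner_rtol),
                         steady_tol = cfg$solver$steady_tol)
  list(params = params, control = control,
       scheme = cfg$schedule$scheme,
       center = c(cfg$seed_circle$center_x, cfg$seed_circle$center_y),
       radius = cfg$seed_circle$radius, seed = cfg$seed)
}

#' Export a sparse operator in MatrixMarket format
#'
#' For external inspection of assembled systems (e.g. the `HS` matrix
#' of an [assemble_si_system()]).
#'
#' @param A sparse matrix or an `assembled_system`
#' @param path output `.mtx` path
#' @export
write_operator_mtx <- function(A, path) {
  if (inherits(A, "assembled_system")) A <- A$HS
  Matrix::writeMM(methods::as(A, "CsparseMatrix"), path)
  invisible(path)
}

#' Write a machine-readable provenance record
#'
#' Full configuration and seed of a run as JSON; for the deterministic
#' paths this suffices to reproduce outputs bit-identically.
#'
#' @param config a [run_config()]
#' @param path JSON file path
#' @export
write_provenance <- function(config, path) {
  jsonlite::write_json(c(unclass(config),
                         list(package = "mcfseg",
                              package_version = as.character(
                                utils::packageVersion("mcfseg")))),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
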