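test_that("image save/load round-trips through 16-bit TIFF", {
  set.seed(61)
  u <- matrix(runif(32 * 32), 32, 32)
  u <- (u - min(u)) / (max(u) - min(u))      # full dynamic range
  path <- withr::local_tempfile(fileext = ".tiff")
  save_image(u, path)
  back <- load_image(path)
  expect_lte(max(abs(back - u)), 1 / 65535 + 1e-9)
  expect_s3_class(attr(back, "grid"), "grid_spec")
})

test_that("image loading normalizes and guards degenerate inputs", {
  path <- withr::local_tempfile(fileext = ".png")
  set.seed(62)
  img <- matrix(runif(64, 0.3, 0.6), 8, 8)
  png::writePNG(img, path)
  u <- load_image(path)
  expect_equal(range(u), c(0, 1))
  flat <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(0.5, 8, 8), flat)
  expect_error(load_image(flat), "dynamic range")
  expect_error(load_image("no-such-file.png"), "not found")
})

test_that("contour CSV and run configuration round-trip losslessly", {
  cs <- contour_set(matrix(runif(20), 10, 2))
  f <- withr::local_tempfile(fileext = ".csv")
  write_contour_csv(cs, f)
  back <- read_contour_csv(f)
  expect_equal(back$points, cs$points, tolerance = 1e-12, ignore_attr = TRUE)
  cfg <- run_config(params = mcf_params(epsilon = 2, sigma = 0.5),
                    scheme = "implicit", dtau = 0.04, T = 2, seed = 9L,
                    center = c(0.4, 0.6), radius = 0.17)
  y <- withr::local_tempfile(fileext = ".yaml")
  save_run_config(cfg, y)
  expect_identical(unclass(load_run_config(y)), unclass(cfg))
})

test_that("assembled operators export to MatrixMarket", {
  grid <- grid_spec(8)
  edge <- compute_edge_field(matrix(0.5, 8, 8), mcf_params(), grid)
  sys <- assemble_si_system(matrix(0, 8, 8), edge, mcf_params(), grid, 0.1)
  f <- withr::local_tempfile(fileext = ".mtx")
  write_operator_mtx(sys, f)
  back <- Matrix::readMM(f)
  expect_equal(as.matrix(back), as.matrix(sys$HS), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("cli: phantom generation is reproducible file-for-file", {
  dir <- withr::local_tempdir()
  a <- file.path(dir, "a"); b <- file.path(dir, "b")
  expect_identical(cli_main(c("phantom", "--n", "32", "--seed", "0",
                              "--out", a)), 0L)
  expect_identical(cli_main(c("phantom", "--n", "32", "--seed", "0",
                              "--out", b)), 0L)
  expect_identical(unname(tools::md5sum(paste0(a, ".tiff"))),
                   unname(tools::md5sum(paste0(b, ".tiff"))))
  expect_identical(readLines(paste0(a, "_truth.csv")),
                   readLines(paste0(b, "_truth.csv")))
})

test_that("cli: segment runs the printed short schedule and logs three steps", {
  dir <- withr::local_tempdir()
  img <- file.path(dir, "ph.tiff")
  ph <- tiny_phantom(n = 48)
  save_image(ph$image, img)
  out <- file.path(dir, "run")
  st <- cli_main(c("segment", "--image", img, "--scheme", "si",
                   "--dtau", "0.16", "--T", "0.4",
                   "--radius", "0.12", "--out", out))
  expect_identical(st, 0L)
  rec <- read.csv(paste0(out, "_record.csv"))
  expect_identical(nrow(rec), 3L)
  expect_true(file.exists(paste0(out, "_contour.csv")))
  expect_true(file.exists(paste0(out, "_provenance.json")))
  prov <- jsonlite::read_json(paste0(out, "_provenance.json"))
  expect_identical(prov$schedule$scheme, "semi_implicit")
  expect_identical(prov$schedule$dtau, 0.16)
})

test_that("cli: evaluate prints zero for identical contours; bad input fails", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "c.csv")
  write_contour_csv(contour_set(matrix(runif(10), 5, 2)), f)
  out <- capture.output(st <- cli_main(c("evaluate", f, f)))
  expect_identical(st, 0L)
  expect_identical(as.numeric(out[1]), 0)
  expect_identical(suppressMessages(cli_main(c("evaluate", f))), 1L)
  expect_identical(suppressMessages(cli_main(c("nonsense"))), 1L)
  expect_identical(suppressMessages(cli_main(c("segment", "--scheme"))), 1L)
})
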