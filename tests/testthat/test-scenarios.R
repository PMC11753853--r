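test_that("preset set covers the full study parameter grid", {
  ps <- paper_presets()
  expect_length(ps, 24L)
  expect_false(anyDuplicated(names(ps)) > 0)
  expect_true(all(vapply(ps, inherits, logical(1), "scenario")))

  # fluid properties identical across all presets
  dens <- vapply(ps, function(s) s$props$density, numeric(1))
  visc <- vapply(ps, function(s) s$props$dynamic_viscosity, numeric(1))
  expect_true(all(dens == 1000) && all(visc == 1e-3))

  dps <- vapply(ps[grep("^dp_", names(ps))], function(s) s$bc$delta_p, numeric(1))
  expect_setequal(dps, c(50, 100, 200, 250))
  ws <- vapply(ps[grep("^width_", names(ps))],
               function(s) s$geometry$width_um, numeric(1))
  expect_setequal(ws, c(1000, 800, 600, 400, 200, 100))
  hs <- vapply(ps[grep("^height_", names(ps))],
               function(s) s$geometry$height_um, numeric(1))
  expect_setequal(hs, c(100, 200, 500, 1000))
  ds <- vapply(ps[grep("^crack_depth_", names(ps))],
               function(s) s$geometry$crack$depth_um, numeric(1))
  expect_setequal(ds, c(100, 50, 20, 10))
  cw <- vapply(ps[grep("^crack_width_", names(ps))],
               function(s) s$geometry$crack$width_um, numeric(1))
  expect_setequal(cw, c(100, 50, 20, 10))
  # both printed readings of the small groove
  expect_equal(ps$small_groove_20x10$geometry$crack$depth_um, 20)
  expect_equal(ps$small_groove_20x10$geometry$crack$width_um, 10)
  expect_equal(ps$small_groove_10x20$geometry$crack$depth_um, 10)
  expect_equal(ps$small_groove_10x20$geometry$crack$width_um, 20)
  # model length is 1500 um everywhere
  expect_true(all(vapply(ps, function(s) s$geometry$length_um, numeric(1)) == 1500))
  # the width study is 3D, the others planar
  expect_true(all(vapply(ps[grep("^width_", names(ps))],
                         function(s) s$geometry$dimensionality, character(1)) ==
                    "full_3d"))
})

test_that("config files round-trip every preset losslessly", {
  for (sc in paper_presets()) {
    path <- tempfile(fileext = ".yaml")
    write_config(sc, path)
    back <- read_config(path)
    expect_equal(back, sc, info = sc$name)
  }
})

test_that("malformed configs are rejected with helpful messages", {
  sc <- paper_presets()[["height_0100"]]
  path <- tempfile(fileext = ".yaml")
  write_config(sc, path)

  txt <- readLines(path)
  bad <- sub("^(\\s*)height_um:.*$", "\\1height_um: -5.0", txt)
  f1 <- tempfile(fileext = ".yaml"); writeLines(bad, f1)
  expect_error(read_config(f1), "height")

  typo <- sub("height_um", "heihgt_um", txt, fixed = TRUE)
  f2 <- tempfile(fileext = ".yaml"); writeLines(typo, f2)
  expect_error(read_config(f2), "height_um")   # nearest-key suggestion

  nom <- txt[!grepl("^name", txt)]
  f3 <- tempfile(fileext = ".yaml"); writeLines(nom, f3)
  expect_error(read_config(f3), "name")
})

test_that("results writer round-trips tables and is stable across runs", {
  sw <- structure(data.frame(value = c(50, 100),
                             peak_fss_pa = c(pi, exp(1)),
                             reynolds = c(1.23456789012345, 2),
                             converged = c(TRUE, TRUE)),
                  varied = "delta_p",
                  class = c("sweep_result", "data.frame"))
  d <- file.path(tempdir(), "rw")
  results_writer(sw, NULL, NULL, d)
  back <- utils::read.delim(file.path(d, "peaks.tsv"))
  expect_identical(back$peak_fss_pa, sw$peak_fss_pa)  # full-precision round trip
  expect_identical(back$reynolds, sw$reynolds)

  # empty results: header-only tables plus a manifest
  d2 <- file.path(tempdir(), "rw_empty")
  results_writer(NULL, NULL, NULL, d2)
  expect_equal(length(readLines(file.path(d2, "peaks.tsv"))), 1L)
  expect_true(file.exists(file.path(d2, "manifest.yaml")))

  # identical manifests modulo the timestamp line
  d3 <- file.path(tempdir(), "rw3")
  results_writer(sw, NULL, NULL, d3)
  strip <- function(p) grep("^timestamp:", readLines(p), value = TRUE,
                            invert = TRUE)
  expect_identical(strip(file.path(d, "manifest.yaml")),
                   strip(file.path(d3, "manifest.yaml")))
})

test_that("run_scenario executes a preset end to end", {
  sc <- paper_presets()[["dp_050"]]
  sc$mesh_size_um <- 50
  run <- run_scenario(sc, n_samples = 64)
  expect_true(run$solution$converged)
  expect_s3_class(run$profile, "wss_profile")
  expect_equal(nrow(run$profile), 64L)
})
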