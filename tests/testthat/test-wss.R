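test_that("uniform shear flow gives FSS = mu * gamma on the bottom wall", {
  mesh <- generate_mesh(gap_geometry(1500, 1000, 100), 25)
  gamma <- 100                      # 1/s
  u <- array(0, dim(mesh$active) + c(1L, 0L, 0L))
  for (k in seq_along(mesh$zc)) u[, , k] <- gamma * mesh$zc[k]
  sol <- structure(list(mesh = mesh,
                        velocity = list(u = u,
                                        v = array(0, dim(mesh$active) + c(0L, 1L, 0L)),
                                        w = array(0, dim(mesh$active) + c(0L, 0L, 1L))),
                        props = water, converged = TRUE),
                   class = "flow_solution")
  field <- compute_wss(sol, mesh, tags = "bottom_wall")
  expect_equal(field$wss_pa, rep(0.1, nrow(field)), tolerance = 1e-12)
})

test_that("a zero-flow solution has identically zero FSS", {
  mesh <- generate_mesh(gap_geometry(1500, 1000, 100, large_groove()), 50)
  sol <- solve_flow(mesh, water, pressure_bc(0, 0), solver_settings("stokes"))
  field <- compute_wss(sol)
  expect_true(all(field$wss_pa < 1e-12))
  gr <- crack_gradient(field)
  expect_true(all(abs(gr$gradient_pa_mm) < 1e-9))
})

test_that("profile sampling is uniform, increasing, and nearest-facet exact", {
  field <- groove_stokes()$field
  pr <- sample_profile(field, 128)
  expect_equal(nrow(pr), 128L)
  expect_true(all(diff(pr$x_um) > 0))
  # constant synthetic field stays constant through sampling
  cf <- make_crack_field(NULL, const = 2.5)
  prc <- sample_profile(cf, 64)
  expect_equal(prc$wss_pa, rep(2.5, 64))
  expect_error(sample_profile(field, 8), "n_samples")
})

test_that("profiles over the groove take the crack-floor value", {
  pr <- sample_profile(groove_stokes()$field, 256)
  over <- pr$over_crack
  expect_gt(sum(over), 0)
  # the in-crack FSS is far below the gap plateau
  expect_lt(max(pr$wss_pa[over]), 0.1 * stats::median(pr$wss_pa[!over]))
})

test_that("peak extraction returns the maximum, optionally end-excluded", {
  expect_equal(peak_fss(make_profile(c(1, 5, 3))), 5)
  expect_equal(peak_fss(make_profile(rep(2, 32))), 2)
  pr <- make_profile(c(9, rep(1, 30), 7))
  expect_equal(peak_fss(pr), 9)
  expect_equal(peak_fss(pr, exclude_ends = 0.1), 1)
  expect_error(peak_fss(make_profile(1:20), exclude_ends = 0.7), "exclude_ends")
})

test_that("crack gradient is zero for constant and exact for linear fields", {
  cf <- make_crack_field(NULL, const = 1.0)
  g0 <- crack_gradient(cf)
  expect_true(all(abs(g0$gradient_pa_mm) < 1e-12))
  # FSS linear in arc length with slope 0.2 Pa/mm = 200 Pa/m
  lf <- make_crack_field(function(s) 200 * s)
  g1 <- crack_gradient(lf)
  expect_equal(g1$gradient_pa_mm, rep(0.2, nrow(g1)), tolerance = 1e-9)
  # arc length covers down, across and up: total 2d + w (facet centroids
  # stop half a facet short of the mouth)
  expect_equal(max(g1$s_mm), 0.25, tolerance = 0.1)
  expect_setequal(unique(g1$region), c("flank_up", "floor", "flank_down"))
})

test_that("profile shapes are classified as inverted_U, flat or other", {
  rising_plateau_falling <- make_profile(c(1, 2, 4, rep(10, 24), 4, 2, 1))
  expect_equal(profile_summary(rising_plateau_falling)$shape, "inverted_U")
  expect_equal(profile_summary(make_profile(rep(3, 40)))$shape, "flat")
  expect_equal(profile_summary(make_profile(seq(1, 10, length.out = 40)))$shape,
               "other")
  s <- profile_summary(make_profile(rep(4, 40)), threshold = 3)
  expect_equal(s$peak, 4)
  expect_equal(s$median, 4)
  expect_equal(s$fraction_above_threshold, 1)
})

test_that("field export writes readable VTK with velocity and pressure", {
  fix <- groove_stokes()
  f <- tempfile(fileext = ".vtk")
  write_field_vtk(fix$sol, f)
  lines <- readLines(f)
  expect_true(any(grepl("VECTORS velocity", lines)))
  expect_true(any(grepl("SCALARS pressure", lines)))
  f2 <- tempfile(fileext = ".vtk")
  write_wss_vtk(fix$field, f2)
  expect_true(any(grepl("SCALARS wss", readLines(f2))))
})
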