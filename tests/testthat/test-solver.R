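test_that("Stokes solve reproduces plane Poiseuille flow", {
  ps <- poiseuille_solution()
  expect_true(ps$sol$converged)
  expect_length(ps$sol$residual_history, 1L)   # a single linear solve
  pr <- sample_profile(ps$field, 64)
  # mid-channel bottom-wall FSS within 1% of H dP / (2 L) = 10 Pa
  expect_equal(pr$wss_pa[32], 10, tolerance = 0.01)
  # flat profile away from the ends
  expect_lt(stats::sd(pr$wss_pa) / mean(pr$wss_pa), 0.001)
  # discrete flow rate near the closed form (midpoint-quadrature accuracy)
  expect_equal(abs(mass_flux(ps$sol, "inlet")),
               plane_poiseuille_flux(300, 1.5e-3, 1e-4), tolerance = 0.01)
})

test_that("zero pressure difference gives zero flow and uniform pressure", {
  mesh <- generate_mesh(gap_geometry(1500, 1000, 100, large_groove()), 50)
  sol <- solve_flow(mesh, water, pressure_bc(5, 5), solver_settings("stokes"))
  expect_true(sol$converged)
  expect_lt(max(abs(sol$velocity$u), abs(sol$velocity$w)), 1e-12)
  expect_equal(range(sol$pressure, na.rm = TRUE), c(5, 5), tolerance = 1e-9)
  expect_equal(mass_flux(sol, "inlet"), 0)
  expect_equal(mass_flux(sol, "outlet"), 0)
})

test_that("Stokes solutions scale exactly linearly with the pressure drop", {
  mesh <- generate_mesh(gap_geometry(1500, 1000, 100, large_groove()), 50)
  s1 <- solve_flow(mesh, water, pressure_bc(300, 0, "static"),
                   solver_settings("stokes"))
  s2 <- solve_flow(mesh, water, pressure_bc(600, 0, "static"),
                   solver_settings("stokes"))
  expect_lt(rel_l2(2 * s1$velocity$u, s2$velocity$u), 1e-8)
  expect_lt(rel_l2(2 * s1$velocity$w, s2$velocity$w), 1e-8)
  expect_lt(rel_l2(2 * s1$pressure[!is.na(s1$pressure)],
                   s2$pressure[!is.na(s2$pressure)]), 1e-8)
})

test_that("mass is conserved and walls carry no flow on converged solves", {
  for (fix in list(groove_stokes(), groove_ns())) {
    expect_true(fix$sol$converged)
    qin <- mass_flux(fix$sol, "inlet"); qout <- mass_flux(fix$sol, "outlet")
    expect_lt(abs(qin + qout) / abs(qin), 1e-6)
    expect_equal(mass_flux(fix$sol, "bottom_wall"), 0)
    expect_equal(mass_flux(fix$sol, "crack_wall"), 0)
    expect_equal(mass_flux(fix$sol, "top_wall"), 0)
  }
  expect_error(mass_flux(groove_ns()$sol, "no_such_tag"), "unknown")
})

test_that("Navier-Stokes tends to Stokes as the driving pressure vanishes", {
  mesh <- generate_mesh(gap_geometry(1500, 1000, 100, large_groove()), 50)
  st <- solve_flow(mesh, water, pressure_bc(0.5, 0, "static"),
                   solver_settings("stokes"))
  ns <- solve_flow(mesh, water, pressure_bc(0.5, 0, "static"),
                   solver_settings("navier_stokes"))
  expect_lt(ns$reynolds, 0.1)
  expect_lt(rel_l2(ns$velocity$u, st$velocity$u), 0.01)
})

test_that("non-convergence is reported, never hidden", {
  mesh <- generate_mesh(gap_geometry(1500, 1000, 1000, large_groove()), 50)
  sol <- solve_flow(mesh, water, pressure_bc(300),
                    solver_settings(newton_max_iter = 1L))
  expect_false(sol$converged)
  expect_gt(tail(sol$residual_history, 1L), sol$settings$newton_tol)
  expect_warning(compute_wss(sol), "non-converged")
})

test_that("solutions on a centered-crack channel are mirror-symmetric", {
  pr <- sample_profile(groove_stokes()$field, 256)
  expect_lt(max(abs(pr$wss_pa - rev(pr$wss_pa))) / max(pr$wss_pa), 0.02)
})

test_that("3D Stokes flow matches the rectangular-duct series solution", {
  mesh <- generate_mesh(gap_geometry(1500, 200, 100,
                                     dimensionality = "full_3d"),
                        c(x = 250, y = 12.5, z = 12.5))
  sol <- solve_flow(mesh, water, pressure_bc(300, 0, "static"),
                    solver_settings("stokes"))
  expect_true(sol$converged)
  duct <- rect_duct_solution(duct_spec(100, 200, 300 / 1.5e-3), 200)
  pr <- sample_profile(compute_wss(sol), 64)
  expect_equal(pr$wss_pa[32], duct$centerline_wall_shear, tolerance = 0.03)
  expect_equal(sol$mean_velocity, duct$mean_velocity, tolerance = 0.03)
})

test_that("mesh convergence study reports shrinking changes and validates input", {
  g <- gap_geometry(1500, 1000, 100)
  tbl <- mesh_convergence_study(g, pressure_bc(300, 0, "static"), water,
                                sizes = c(50, 25, 12.5),
                                settings = solver_settings("stokes"))
  expect_equal(nrow(tbl), 3L)
  # plane Poiseuille is resolved at every size: changes at roundoff level
  expect_equal(tbl$peak_fss_pa, rep(10, 3), tolerance = 1e-9)
  expect_true(all(na.omit(tbl$rel_change) < 0.02))
  expect_true(attr(tbl, "mesh_converged"))
  expect_error(mesh_convergence_study(g, pressure_bc(300), water,
                                      sizes = c(50, 50, 25)), "decreasing")
  expect_error(mesh_convergence_study(g, pressure_bc(300), water,
                                      sizes = c(50, 25)), "3 mesh sizes")
})
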