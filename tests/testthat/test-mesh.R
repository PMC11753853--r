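test_that("boundary tags are complete and partition the boundary", {
  m <- generate_mesh(gap_geometry(1500, 1000, 100), 10)
  expect_setequal(unique(m$facets$tag),
                  c("inlet", "outlet", "bottom_wall", "top_wall"))
  # planar domain boundary measure per unit width: 2L + 2H
  expect_equal(sum(m$facets$area), 2 * 1500e-6 + 2 * 100e-6,
               tolerance = 1e-6)

  mc <- generate_mesh(gap_geometry(1500, 1000, 100, large_groove()), 25, 0.25)
  expect_setequal(unique(mc$facets$tag),
                  c("inlet", "outlet", "bottom_wall", "top_wall", "crack_wall"))
  # the groove replaces w of bottom wall and adds 2d + w of crack wall
  expect_equal(sum(mc$facets$area),
               2 * 1500e-6 + 2 * 100e-6 + 2 * 100e-6, tolerance = 1e-6)
  # every facet carries exactly one tag (tags partition the boundary)
  expect_false(any(duplicated(mc$facets[c("x", "y", "z", "axis", "side")])))

  m3 <- generate_mesh(gap_geometry(600, 300, 100, dimensionality = "full_3d"),
                      50)
  expect_setequal(unique(m3$facets$tag),
                  c("inlet", "outlet", "bottom_wall", "top_wall", "side_walls"))
  L <- 600e-6; W <- 300e-6; H <- 100e-6
  expect_equal(sum(m3$facets$area), 2 * (L * W + L * H + W * H),
               tolerance = 1e-6)
})

test_that("crack wall facet area equals the groove perimeter 2d + w", {
  mc <- generate_mesh(gap_geometry(1500, 1000, 100, large_groove()), 25, 0.25)
  expect_equal(boundary_areas(mc)[["crack_wall"]],
               um_to_m(2 * 100 + 50), tolerance = 0.02)
})

test_that("element count scales like a 2D/3D mesh density under refinement", {
  g <- gap_geometry(1500, 1000, 200)
  n20 <- generate_mesh(g, 20)$n_elements
  n10 <- generate_mesh(g, 10)$n_elements
  expect_gt(n10 / n20, 2)    # ~4x in 2D, within a factor 2
  expect_lt(n10 / n20, 8)
  g3 <- gap_geometry(400, 200, 100, dimensionality = "full_3d")
  n50 <- generate_mesh(g3, 50)$n_elements
  n25 <- generate_mesh(g3, 25)$n_elements
  expect_gt(n25 / n50, 4)    # ~8x in 3D, within a factor 2
  expect_lt(n25 / n50, 16)
})

test_that("meshes conform to the geometry and are mirror-symmetric", {
  g <- gap_geometry(1500, 1000, 100, large_groove())
  m <- generate_mesh(g, 25)
  L <- um_to_m(1500)
  expect_equal(max(m$xf), L, tolerance = 1e-9)
  expect_equal(range(m$zf), um_to_m(c(-100, 100)), tolerance = 1e-9)
  # centered crack: x breakpoints map onto themselves under reflection
  expect_equal(sort(L - m$xf), sort(m$xf), tolerance = 1e-12)
  # groove refinement: elements near the crack are finer by the given factor
  ix <- m$xc > um_to_m(725) & m$xc < um_to_m(775)
  expect_equal(max(m$dx[ix]) / max(m$dx), 0.25, tolerance = 0.3)
})

test_that("invalid meshing requests are rejected", {
  g <- gap_geometry(1500, 1000, 100)
  expect_error(generate_mesh(g, -5), "target_size_um")
  expect_error(generate_mesh(g, 25, 0), "refine_crack_factor")
  expect_error(generate_mesh(g, 25, 1.5), "refine_crack_factor")
})

test_that("VTK export writes well-formed text files", {
  m <- generate_mesh(gap_geometry(300, 100, 100, dimensionality = "full_3d"), 50)
  f1 <- tempfile(fileext = ".vtk")
  write_mesh_vtk(m, f1)
  lines <- readLines(f1)
  expect_match(lines[1], "vtk DataFile")
  npts <- as.integer(strsplit(grep("^POINTS", lines, value = TRUE), " ")[[1]][2])
  expect_equal(npts, nrow(mesh_nodes(m)))
  f2 <- tempfile(fileext = ".vtk")
  write_mesh_vtk(m, f2, "facets")
  expect_match(readLines(f2, n = 2)[2], "tag legend")
  expect_equal(nrow(mesh_cells(m)), m$n_elements)
})
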