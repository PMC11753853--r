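# Shared fixtures: memoized solves (several tests interrogate the same
# reference solutions) and synthetic-object builders.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

water <- fluid_properties()

# plain 2D channel, Stokes: the plane-Poiseuille oracle configuration
poiseuille_solution <- function() cached("poiseuille", {
  mesh <- generate_mesh(gap_geometry(1500, 1000, 100), c(x = 100, z = 10))
  sol <- solve_flow(mesh, water, pressure_bc(300, 0, "static"),
                    solver_settings("stokes"))
  list(mesh = mesh, sol = sol, field = compute_wss(sol))
})

# 2D channel with the large groove, Stokes (for symmetry / conservation)
groove_stokes <- function() cached("groove_stokes", {
  mesh <- generate_mesh(gap_geometry(1500, 1000, 100, large_groove()), 25, 0.25)
  sol <- solve_flow(mesh, water, pressure_bc(300, 0, "static"),
                    solver_settings("stokes"))
  list(mesh = mesh, sol = sol, field = compute_wss(sol))
})

# 2D channel with the large groove, Navier-Stokes at inlet 300 Pa: the
# reference scenario of the gradient study
groove_ns <- function() cached("groove_ns", {
  mesh <- generate_mesh(gap_geometry(1500, 1000, 100, large_groove()), 25, 0.25)
  sol <- solve_flow(mesh, water, pressure_bc(300), solver_settings())
  list(mesh = mesh, sol = sol, field = compute_wss(sol))
})

height_sweep <- function() cached("height_sweep", {
  base <- scenario("h", gap_geometry(1500, 1000, 100, large_groove()),
                   pressure_bc(300))
  run_sweep(sweep_config("gap_height", c(100, 200, 500, 1000), base),
            mesh_size_um = 25)
})

pressure_sweep <- function() cached("pressure_sweep", {
  base <- scenario("p", gap_geometry(1500, 100, 100, large_groove()),
                   pressure_bc(300))
  run_sweep(sweep_config("delta_p", c(50, 100, 200, 250), base),
            mesh_size_um = 25)
})

crack_sweeps <- function() cached("crack_sweeps", {
  base <- scenario("c", gap_geometry(1500, 1000, 100, large_groove()),
                   pressure_bc(300))
  list(depth = run_sweep(sweep_config("crack_depth", c(100, 50, 20, 10), base),
                         mesh_size_um = 25),
       width = run_sweep(sweep_config("crack_width", c(100, 50, 20, 10), base),
                         mesh_size_um = 25))
})

width_pair <- function() cached("width_pair", {
  base <- scenario("w", gap_geometry(1500, 1000, 100, large_groove(), "full_3d"),
                   pressure_bc(300))
  run_sweep(sweep_config("gap_width", c(800, 100), base))
})

# synthetic profile with uniform sampling positions over L = 1500 um
make_profile <- function(values, L = 1500) {
  n <- length(values)
  xs <- seq(L / (2 * n), L - L / (2 * n), length.out = n)
  structure(data.frame(x_um = xs, wss_pa = values,
                       over_crack = rep(FALSE, n)),
            class = c("wss_profile", "data.frame"))
}

# synthetic WSS field on a real groove mesh, with values assigned as a
# function of the facet's crack-arc coordinate s (m); non-crack facets 0
make_crack_field <- function(s_to_wss, const = NULL) {
  mesh <- cached("field_mesh",
                 generate_mesh(gap_geometry(1500, 1000, 100, large_groove()),
                               50, 0.5))
  f <- mesh$facets
  geom <- mesh$geom
  d <- um_to_m(geom$crack$depth_um)
  w <- um_to_m(geom$crack$width_um)
  x0 <- um_to_m(geom$crack$center_x_um - geom$crack$width_um / 2)
  s <- rep(NA_real_, nrow(f))
  cr <- f$tag == "crack_wall"
  up <- cr & f$axis == 1 & f$side == -1
  dn <- cr & f$axis == 1 & f$side == 1
  fl <- cr & f$axis == 3
  s[up] <- -f$z[up]
  s[fl] <- d + (f$x[fl] - x0)
  s[dn] <- d + w + (d + f$z[dn])
  wss <- if (is.null(const)) ifelse(is.na(s), 0, s_to_wss(s)) else
    rep(const, nrow(f))
  out <- cbind(f, wss_pa = wss)
  attr(out, "geom") <- geom
  attr(out, "planar") <- mesh$planar
  class(out) <- c("wss_field", "data.frame")
  out
}

# relative L2 distance between two numeric arrays
rel_l2 <- function(a, b) {
  sqrt(sum((a - b)^2)) / max(sqrt(sum(b^2)), .Machine$double.xmin)
}
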