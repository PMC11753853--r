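# Scenario presets and config-file round-tripping. The study's "data" is
# its parameter space: every scenario is a validated parameter set
# (geometry in um, pressures in Pa) and this module materializes the full
# printed grid of the study as named presets.

#' Simulation scenario
#'
#' Bundles a validated geometry, boundary conditions, fluid properties,
#' solver settings and mesh resolution under a unique name.
#'
#' @param name scenario name (unique within a scenario set).
#' @param geometry a [gap_geometry()].
#' @param bc a [pressure_bc()].
#' @param props a [fluid_properties()].
#' @param solver a [solver_settings()].
#' @param mesh_size_um target element size (um), scalar or named per-axis.
#' @param refine_crack_factor groove refinement ratio for [generate_mesh()].
#' @return an object of class `scenario`.
#' @export
scenario <- function(name, geometry, bc = pressure_bc(300),
                     props = fluid_properties(),
                     solver = solver_settings(),
                     mesh_size_um = 25, refine_crack_factor = 0.25) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  geometry <- build_geometry(geometry)
  structure(list(name = name, geometry = geometry, bc = bc, props = props,
                 solver = solver, mesh_size_um = mesh_size_um,
                 refine_crack_factor = refine_crack_factor),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %s: L=%g W=%g H=%g um, inlet %g / outlet %g Pa (%s)\n",
              x$name, x$geometry$length_um, x$geometry$width_um,
              x$geometry$height_um, x$bc$inlet_pressure,
              x$bc$outlet_pressure, x$solver$model))
  invisible(x)
}

#' The large microcrack groove (depth 100 um, width 50 um)
#' @param center_x_um groove midpoint (default: channel center).
#' @return a [microcrack_spec()].
#' @export
large_groove <- function(center_x_um = NA_real_)
  microcrack_spec(100, 50, center_x_um)

# default aspect-aware mesh resolution: planar runs use `base` um
# isotropically; 3D runs resolve the cross-section (>= 8 cells across the
# width, base/2 across the height) and relax the streamwise direction.
default_mesh_size <- function(geometry, base = 25) {
  if (geometry$dimensionality == "planar_2d") return(unname(base))
  c(x = 2 * base, y = max(geometry$width_um / 8, base / 2), z = base / 2)
}

default_refine <- function(geometry) {
  if (geometry$dimensionality == "planar_2d") 0.25 else 1
}

#' All scenario presets of the parametric study
#'
#' Materializes the full printed parameter grid: the pressure-difference
#' sweep (dP = 50, 100, 200, 250 Pa on the 100 um gap), the gap-width
#' sweep (1000 ... 100 um, 3D, inlet 300 Pa), the gap-height sweep (100,
#' 200, 500, 1000 um), the crack-depth and crack-width sweeps (100, 50,
#' 20, 10 um), and both printed readings of the small groove (depth 20 /
#' width 10, and depth 10 / width 20). All presets share water-like fluid
#' properties (rho = 1000 kg/m^3, mu = 1e-3 Pa s) and carry the large
#' groove unless the crack itself is varied.
#'
#' @return a named list of 24 [scenario()] objects.
#' @export
paper_presets <- function() {
  planar <- function(name, H = 100, W = 1000, crack = large_groove(),
                     inlet = 300)
    scenario(name,
             gap_geometry(1500, W, H, crack, "planar_2d"),
             pressure_bc(inlet),
             mesh_size_um = 25, refine_crack_factor = 0.25)
  out <- list()
  for (dp in c(50, 100, 200, 250))
    out[[sprintf("dp_%03d", dp)]] <-
      planar(sprintf("dp_%03d", dp), H = 100, W = 100, inlet = dp)
  for (W in c(1000, 800, 600, 400, 200, 100)) {
    g <- gap_geometry(1500, W, 100, large_groove(), "full_3d")
    out[[sprintf("width_%04d", W)]] <-
      scenario(sprintf("width_%04d", W), g, pressure_bc(300),
               mesh_size_um = default_mesh_size(g),
               refine_crack_factor = default_refine(g))
  }
  for (H in c(100, 200, 500, 1000))
    out[[sprintf("height_%04d", H)]] <-
      planar(sprintf("height_%04d", H), H = H)
  for (d in c(100, 50, 20, 10))
    out[[sprintf("crack_depth_%03d", d)]] <-
      planar(sprintf("crack_depth_%03d", d), crack = microcrack_spec(d, 50))
  for (w in c(100, 50, 20, 10))
    out[[sprintf("crack_width_%03d", w)]] <-
      planar(sprintf("crack_width_%03d", w), crack = microcrack_spec(100, w))
  # both printed readings of the small groove dimensions
  out[["small_groove_20x10"]] <-
    planar("small_groove_20x10", crack = microcrack_spec(20, 10))
  out[["small_groove_10x20"]] <-
    planar("small_groove_10x20", crack = microcrack_spec(10, 20))
  out
}

# ---- config file IO -------------------------------------------------------

config_keys <- list(
  top = c("name", "geometry", "bc", "fluid", "solver", "mesh"),
  geometry = c("length_um", "width_um", "height_um", "dimensionality", "crack"),
  crack = c("depth_um", "width_um", "center_x_um", "span"),
  bc = c("inlet_pressure", "outlet_pressure", "pressure_type"),
  fluid = c("density", "dynamic_viscosity"),
  solver = c("model", "newton_tol", "newton_max_iter", "continuation_steps"),
  mesh = c("target_size_um", "refine_crack_factor"))

check_keys <- function(x, level) {
  allowed <- config_keys[[level]]
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    key <- bad[1]
    d <- utils::adist(key, allowed)
    hint <- allowed[which.min(d)]
    stopf("unknown config key '%s' in %s section; did you mean '%s'?",
          key, level, hint)
  }
  invisible(x)
}

#' Read / write a scenario config file
#'
#' Scenarios round-trip losslessly through a YAML text format with
#' paper-facing units (micrometers and pascals). Unknown keys are rejected
#' with a nearest-key suggestion; dimensional invariants are re-validated
#' on read.
#'
#' @param path file path.
#' @param sc a [scenario()] (for `write_config`).
#' @return `read_config`: a `scenario`; `write_config`: `path`, invisibly.
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  check_keys(x, "top")
  for (req in c("name", "geometry", "bc"))
    if (is.null(x[[req]])) stopf("config is missing required key '%s'", req)
  check_keys(x$geometry, "geometry")
  g <- x$geometry
  for (req in c("length_um", "width_um", "height_um"))
    if (is.null(g[[req]])) stopf("config geometry is missing '%s'", req)
  crack <- NULL
  if (!is.null(g$crack)) {
    check_keys(g$crack, "crack")
    crack <- microcrack_spec(g$crack$depth_um, g$crack$width_um,
                             g$crack$center_x_um %||% NA_real_,
                             g$crack$span %||% "full_width")
  }
  geometry <- gap_geometry(g$length_um, g$width_um, g$height_um, crack,
                           g$dimensionality %||% "planar_2d")
  check_keys(x$bc, "bc")
  bc <- pressure_bc(x$bc$inlet_pressure, x$bc$outlet_pressure %||% 0,
                    x$bc$pressure_type %||% "total")
  fl <- x$fluid %||% list()
  check_keys(fl, "fluid")
  props <- fluid_properties(fl$density %||% 1000,
                            fl$dynamic_viscosity %||% 1e-3)
  sv <- x$solver %||% list()
  check_keys(sv, "solver")
  solver <- solver_settings(sv$model %||% "navier_stokes",
                            sv$newton_tol %||% 1e-8,
                            sv$newton_max_iter %||% 25L,
                            sv$continuation_steps %||% 1L)
  ms <- x$mesh %||% list()
  check_keys(ms, "mesh")
  tsz <- ms$target_size_um %||% 25
  if (is.list(tsz)) tsz <- unlist(tsz)
  scenario(x$name, geometry, bc, props, solver,
           mesh_size_um = tsz,
           refine_crack_factor = ms$refine_crack_factor %||% 0.25)
}

#' @rdname read_config
#' @export
write_config <- function(sc, path) {
  stopifnot(inherits(sc, "scenario"))
  g <- sc$geometry
  x <- list(
    name = sc$name,
    geometry = c(list(length_um = g$length_um, width_um = g$width_um,
                      height_um = g$height_um,
                      dimensionality = g$dimensionality),
                 if (!is.null(g$crack))
                   list(crack = list(depth_um = g$crack$depth_um,
                                     width_um = g$crack$width_um,
                                     center_x_um = g$crack$center_x_um,
                                     span = g$crack$span))),
    bc = list(inlet_pressure = sc$bc$inlet_pressure,
              outlet_pressure = sc$bc$outlet_pressure,
              pressure_type = sc$bc$pressure_type),
    fluid = list(density = sc$props$density,
                 dynamic_viscosity = sc$props$dynamic_viscosity),
    solver = list(model = sc$solver$model,
                  newton_tol = sc$solver$newton_tol,
                  newton_max_iter = sc$solver$newton_max_iter,
                  continuation_steps = sc$solver$continuation_steps),
    mesh = list(target_size_um = as.list(sc$mesh_size_um),
                refine_crack_factor = sc$refine_crack_factor))
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' Run one scenario end to end
#'
#' Meshes the scenario's geometry, solves the flow, and extracts the WSS
#' field and bottom-wall profile.
#'
#' @param sc a [scenario()].
#' @param n_samples profile sampling density.
#' @return a list with `scenario`, `mesh`, `solution`, `field`, `profile`.
#' @export
run_scenario <- function(sc, n_samples = 256L) {
  stopifnot(inherits(sc, "scenario"))
  mesh <- generate_mesh(sc$geometry, sc$mesh_size_um, sc$refine_crack_factor)
  sol <- solve_flow(mesh, sc$props, sc$bc, sc$solver)
  field <- compute_wss(sol)
  list(scenario = sc, mesh = mesh, solution = sol, field = field,
       profile = sample_profile(field, n_samples))
}

#' Write sweep results, profiles and gradient tables to a directory
#'
#' Writes tab-separated tables with unit-bearing column names
#' (`peaks.tsv`, `profiles.tsv`, `gradients.tsv`) and a `manifest.yaml`
#' recording solver settings, mesh resolutions, per-case Reynolds numbers
#' and the package version. Numeric values are written with full (17
#' significant digit) precision so that rereading reproduces them exactly.
#'
#' @param sweep a [run_sweep()] result (or NULL).
#' @param profiles named list of `wss_profile` objects (or NULL).
#' @param gradients named list of `gradient_field` objects (or NULL).
#' @param dir output directory (created if needed).
#' @param manifest_extra named list merged into the manifest.
#' @return `dir`, invisibly.
#' @export
results_writer <- function(sweep = NULL, profiles = NULL, gradients = NULL,
                           dir, manifest_extra = list()) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) stopf("cannot create output directory '%s'", dir)
  }
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  write_tsv <- function(df, path) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], fmt)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  pk <- if (!is.null(sweep)) as.data.frame(sweep) else
    data.frame(value = numeric(), peak_fss_pa = numeric(),
               reynolds = numeric(), converged = logical())
  write_tsv(pk, file.path(dir, "peaks.tsv"))

  pr <- data.frame(scenario = character(), x_um = numeric(),
                   wss_pa = numeric(), over_crack = logical())
  if (length(profiles))
    pr <- do.call(rbind, lapply(names(profiles), function(nm)
      cbind(scenario = nm, as.data.frame(profiles[[nm]]))))
  write_tsv(pr, file.path(dir, "profiles.tsv"))

  gr <- data.frame(scenario = character(), s_mm = numeric(), x_um = numeric(),
                   z_um = numeric(), region = character(),
                   wss_pa = numeric(), gradient_pa_mm = numeric())
  if (length(gradients))
    gr <- do.call(rbind, lapply(names(gradients), function(nm)
      cbind(scenario = nm, as.data.frame(gradients[[nm]]))))
  write_tsv(gr, file.path(dir, "gradients.tsv"))

  manifest <- c(list(
    package = "trabflow",
    version = as.character(utils::packageVersion("trabflow")),
    units = list(length = "um", pressure = "Pa", wss = "Pa",
                 gradient = "Pa/mm")),
    manifest_extra)
  if (!is.null(sweep)) {
    manifest$varied <- attr(sweep, "varied")
    manifest$reynolds <- as.list(stats::setNames(sweep$reynolds,
                                                 paste0("value_", sweep$value)))
  }
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"), precision = 15L)
  cat(sprintf("timestamp: %s\n", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
      file = file.path(dir, "manifest.yaml"), append = TRUE)
  invisible(dir)
}
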