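#' Fluid properties
#'
#' Bone interstitial fluid is modeled as water at room temperature:
#' density 1000 kg/m^3 and dynamic viscosity 1e-3 Pa s.
#'
#' @param density fluid density, kg/m^3.
#' @param dynamic_viscosity dynamic viscosity, Pa s.
#' @return an object of class `fluid_properties`.
#' @export
fluid_properties <- function(density = 1000, dynamic_viscosity = 1e-3) {
  if (!is.numeric(density) || density <= 0)
    stopf("density must be > 0, got %s", format(density))
  if (!is.numeric(dynamic_viscosity) || dynamic_viscosity <= 0)
    stopf("dynamic_viscosity must be > 0, got %s", format(dynamic_viscosity))
  structure(list(density = density, dynamic_viscosity = dynamic_viscosity),
            class = "fluid_properties")
}

#' Pressure boundary conditions at the gap ends
#'
#' The flow is driven by pressures applied on the open x = 0 (inlet) and
#' x = L (outlet) planes; every other boundary is a no-slip wall. The
#' tangential velocity is constrained to zero on both open planes.
#'
#' `pressure_type` selects how the inlet pressure acts: `"total"`
#' (default) imposes a stagnation pressure, so the static pressure seen by
#' incoming fluid is `inlet_pressure - rho |u_n|^2 / 2` — the fluid is drawn
#' from a quiescent reservoir (the marrow space) and must spend part of the
#' head on its own acceleration, which caps the attainable velocity near
#' sqrt(2 dP / rho) in wide gaps. `"static"` imposes the static pressure
#' directly; in a straight gap this admits the fully developed Poiseuille
#' solution at any Reynolds number. The outlet is always static. The
#' Stokes model has no dynamic head, so both types coincide there.
#'
#' @param inlet_pressure pressure at x = 0, Pa.
#' @param outlet_pressure pressure at x = L, Pa (default 0).
#' @param pressure_type `"total"` or `"static"` (inlet only).
#' @return an object of class `pressure_bc` with `delta_p` field.
#' @export
pressure_bc <- function(inlet_pressure, outlet_pressure = 0,
                        pressure_type = c("total", "static")) {
  pressure_type <- match.arg(pressure_type)
  if (!is.numeric(inlet_pressure) || !is.numeric(outlet_pressure))
    stopf("pressures must be numeric")
  if (inlet_pressure < outlet_pressure)
    stopf("inlet_pressure (%g) must be >= outlet_pressure (%g) for forward flow",
          inlet_pressure, outlet_pressure)
  structure(list(inlet_pressure = inlet_pressure,
                 outlet_pressure = outlet_pressure,
                 pressure_type = pressure_type,
                 delta_p = inlet_pressure - outlet_pressure),
            class = "pressure_bc")
}

#' Solver settings
#'
#' @param model `"navier_stokes"` (Newton iteration on the full convective
#'   system) or `"stokes"` (creeping flow; a single linear solve).
#' @param newton_tol relative residual tolerance, in (0, 1).
#' @param newton_max_iter maximum Newton iterations per continuation step.
#' @param continuation_steps number of pressure-ramp steps; raised
#'   automatically to at least 5 when the estimated Reynolds number
#'   exceeds 100.
#' @return an object of class `solver_settings`.
#' @export
solver_settings <- function(model = c("navier_stokes", "stokes"),
                            newton_tol = 1e-8, newton_max_iter = 25L,
                            continuation_steps = 1L) {
  model <- match.arg(model)
  if (!is.numeric(newton_tol) || newton_tol <= 0 || newton_tol >= 1)
    stopf("newton_tol must lie in (0, 1), got %g", newton_tol)
  if (newton_max_iter < 1) stopf("newton_max_iter must be >= 1")
  if (continuation_steps < 1) stopf("continuation_steps must be >= 1")
  structure(list(model = model, newton_tol = newton_tol,
                 newton_max_iter = as.integer(newton_max_iter),
                 continuation_steps = as.integer(continuation_steps)),
            class = "solver_settings")
}

#' Solve steady incompressible laminar flow in a tagged mesh
#'
#' Solves the steady Stokes or Navier-Stokes equations on the staggered
#' finite-volume discretization of `mesh`, driven by the pressure boundary
#' conditions in `bc`, with no-slip walls everywhere else. The Stokes
#' model is a single sparse linear solve. The Navier-Stokes model starts
#' from an amplitude-rescaled Stokes field and performs damped Newton
#' iterations, ramping the applied pressure in continuation steps when the
#' estimated Reynolds number is large. Non-convergence is reported through
#' `converged = FALSE` and the residual history, never silently.
#'
#' @param mesh a [generate_mesh()] result.
#' @param props [fluid_properties()].
#' @param bc [pressure_bc()].
#' @param settings [solver_settings()].
#' @return an object of class `flow_solution` with staggered `velocity`
#'   component arrays (m/s), cell `pressure` (Pa, NA outside the fluid),
#'   `converged`, `residual_history`, and `reynolds` (rho U_mean H / mu).
#' @export
solve_flow <- function(mesh, props = fluid_properties(),
                       bc = pressure_bc(300),
                       settings = solver_settings()) {
  stopifnot(inherits(mesh, "tagged_mesh"), inherits(props, "fluid_properties"),
            inherits(bc, "pressure_bc"), inherits(settings, "solver_settings"))
  dofs <- build_dofs(mesh)
  ctx <- solver_context(mesh, dofs, props)
  lin <- assemble_stokes(ctx)
  A <- lin$A

  bvec <- function(pin, pout) pin * lin$b_in + pout * lin$b_out
  b_full <- bvec(bc$inlet_pressure, bc$outlet_pressure)
  bnorm <- sqrt(sum(b_full^2))

  if (bnorm == 0) {
    U <- numeric(dofs$n)
    return(finish_solution(mesh, dofs, ctx, U, bc, props, settings,
                           converged = TRUE, history = 0))
  }

  U <- as.numeric(Matrix::solve(A, b_full))
  if (settings$model == "stokes") {
    r <- stokes_rel_residual(A, U, b_full)
    return(finish_solution(mesh, dofs, ctx, U, bc, props, settings,
                           converged = r <= max(settings$newton_tol, 1e-10),
                           history = r))
  }

  # Navier-Stokes: amplitude prescaling of the Stokes guess so that the
  # dynamic head at the inlet is consistent with the applied total pressure
  uref <- if (dofs$n_vel > 0) max(abs(U[seq_len(dofs$n_vel)])) else 0
  dp <- max(bc$delta_p, .Machine$double.eps)
  s <- 1
  if (identical(bc$pressure_type, "total") && uref > 0) {
    q <- props$density * uref^2 / (2 * dp)
    if (q > 1e-8) s <- (sqrt(1 + 4 * q) - 1) / (2 * q)
  }
  re_est <- estimate_reynolds(mesh, dofs, ctx, s * U, props)
  steps <- max(settings$continuation_steps, if (re_est > 100) 5L else 1L)

  history <- numeric(0)
  converged <- FALSE
  Ucur <- s * U * (1 / steps)
  for (st in seq_len(steps)) {
    f <- st / steps
    b_f <- bvec(f * bc$inlet_pressure, f * bc$outlet_pressure)
    bn_f <- sqrt(sum(b_f^2))
    out <- newton_solve(ctx, A, b_f, bn_f, Ucur, bc, settings)
    Ucur <- out$U
    history <- c(history, out$history)
    converged <- out$converged
    if (!converged) break
  }
  finish_solution(mesh, dofs, ctx, Ucur, bc, props, settings,
                  converged = converged, history = history)
}

stokes_rel_residual <- function(A, U, b) {
  r <- as.numeric(A %*% U - b)
  sqrt(sum(r^2)) / sqrt(sum(b^2))
}

newton_solve <- function(ctx, A, b, bnorm, U, bc, settings) {
  history <- numeric(0)
  resid <- function(Uv) {
    nl <- assemble_convection(ctx, Uv, bc, want_jac = FALSE)
    as.numeric(A %*% Uv - b + nl$res)
  }
  Fv <- resid(U)
  r <- sqrt(sum(Fv^2)) / bnorm
  history <- r
  it <- 0L
  while (r > settings$newton_tol && it < settings$newton_max_iter) {
    it <- it + 1L
    nl <- assemble_convection(ctx, U, bc, want_jac = TRUE)
    J <- A + nl$jac
    Fv <- as.numeric(A %*% U - b + nl$res)
    delta <- as.numeric(Matrix::solve(J, -Fv))
    alpha <- 1
    repeat {
      Unew <- U + alpha * delta
      Fn <- resid(Unew)
      rn <- sqrt(sum(Fn^2)) / bnorm
      if (rn <= (1 - 1e-4 * alpha) * r || alpha <= 1 / 64) break
      alpha <- alpha / 2
    }
    U <- Unew
    r <- rn
    history <- c(history, r)
  }
  list(U = U, history = history, converged = r <= settings$newton_tol)
}

estimate_reynolds <- function(mesh, dofs, ctx, U, props) {
  S <- dofs$status[[1L]]
  ids <- S[1, , , drop = TRUE]
  ids <- ids[ids > 0L]
  if (!length(ids)) return(0)
  umean <- mean(abs(U[ids]))
  props$density * umean * um_to_m(mesh$geom$height_um) /
    props$dynamic_viscosity
}

finish_solution <- function(mesh, dofs, ctx, U, bc, props, settings,
                            converged, history) {
  vel <- lapply(1:3, function(comp) {
    S <- dofs$status[[comp]]
    Va <- array(0, dim(S))
    idx <- S > 0L
    Va[idx] <- U[S[idx]]
    Va
  })
  names(vel) <- c("u", "v", "w")
  p <- array(NA_real_, dim(mesh$active))
  p[mesh$active] <- U[dofs$pid[mesh$active]]
  sol <- structure(list(
    mesh = mesh, velocity = vel, pressure = p,
    converged = converged, residual_history = history,
    bc = bc, props = props, settings = settings,
    n_unknowns = dofs$n), class = "flow_solution")
  qin <- mass_flux(sol, "inlet")
  a_in <- sum(mesh$facets$area[mesh$facets$tag == "inlet"])
  sol$mean_velocity <- if (a_in > 0) abs(qin) / a_in else 0
  sol$reynolds <- reynolds_number(props, sol$mean_velocity,
                                  um_to_m(mesh$geom$height_um))
  sol
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf("<flow_solution> %s, %s, dP = %g Pa\n",
              x$settings$model,
              if (x$converged) "converged" else "NOT CONVERGED",
              x$bc$delta_p))
  cat(sprintf("  unknowns: %d; final rel. residual: %.3g; Re = %.3g; U_mean = %.3g m/s\n",
              x$n_unknowns, tail(x$residual_history, 1L), x$reynolds,
              x$mean_velocity))
  invisible(x)
}

#' Volumetric flow rate through a tagged boundary
#'
#' Integrates the outward normal velocity over all facets carrying `tag`.
#' The sign convention is outward-positive, so on a converged solution the
#' inlet and outlet fluxes cancel (global mass conservation) and wall tags
#' return exactly zero. Planar meshes report flow rate per unit width
#' (m^2/s); 3D meshes report m^3/s.
#'
#' @param sol a `flow_solution`.
#' @param tag a boundary tag present in the mesh.
#' @return signed volumetric flow rate.
#' @export
mass_flux <- function(sol, tag) {
  stopifnot(inherits(sol, "flow_solution"))
  f <- sol$mesh$facets
  if (!tag %in% f$tag) stopf("unknown boundary tag '%s'", tag)
  f <- f[f$tag == tag, , drop = FALSE]
  q <- 0
  for (axis in unique(f$axis)) {
    fa <- f[f$axis == axis, , drop = FALSE]
    comp <- sol$velocity[[axis]]
    fi <- fa$i; fj <- fa$j; fk <- fa$k
    off <- (fa$side + 1L) / 2L
    if (axis == 1L) fi <- fi + off
    if (axis == 2L) fj <- fj + off
    if (axis == 3L) fk <- fk + off
    vals <- comp[cbind(fi, fj, fk)]
    q <- q + sum(fa$side * vals * fa$area)
  }
  q
}

#' Mesh-convergence study of the peak wall shear stress
#'
#' Re-solves one scenario on a sequence of successively finer meshes and
#' reports the peak bottom-wall FSS and its successive relative changes.
#' The study is flagged converged when the change between the two finest
#' meshes is below 2%.
#'
#' @param geom a [gap_geometry()].
#' @param bc [pressure_bc()].
#' @param props [fluid_properties()].
#' @param sizes at least 3 strictly decreasing target element sizes (um).
#' @param settings [solver_settings()].
#' @param refine_crack_factor passed to [generate_mesh()].
#' @param n_samples profile sampling density for the peak extraction.
#' @return a data.frame with one row per size (size_um, n_elements,
#'   peak_fss_pa, rel_change) plus attribute `mesh_converged`.
#' @export
mesh_convergence_study <- function(geom, bc, props, sizes,
                                   settings = solver_settings(),
                                   refine_crack_factor = 0.25,
                                   n_samples = 128L) {
  if (length(sizes) < 3L) stopf("need at least 3 mesh sizes, got %d", length(sizes))
  if (any(diff(sizes) >= 0)) stopf("sizes must be strictly decreasing")
  peaks <- numeric(length(sizes))
  nel <- integer(length(sizes))
  for (s in seq_along(sizes)) {
    mesh <- generate_mesh(geom, sizes[s], refine_crack_factor)
    sol <- solve_flow(mesh, props, bc, settings)
    if (!sol$converged)
      stopf("solve at size %g um did not converge (final residual %.3g)",
            sizes[s], tail(sol$residual_history, 1L))
    field <- compute_wss(sol)
    peaks[s] <- peak_fss(sample_profile(field, n_samples = n_samples))
    nel[s] <- mesh$n_elements
  }
  rel <- c(NA_real_, abs(diff(peaks)) / peaks[-length(peaks)])
  out <- data.frame(size_um = sizes, n_elements = nel,
                    peak_fss_pa = peaks, rel_change = rel)
  attr(out, "mesh_converged") <- rel[length(rel)] < 0.02
  out
}
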