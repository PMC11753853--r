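#' Wall shear stress of fully developed plane Poiseuille flow
#'
#' For pressure-driven flow between parallel plates a distance `height`
#' apart, driven by a pressure drop `delta_p` over a length `length`, the
#' fully developed wall shear stress is
#' \deqn{\tau_w = \frac{H \, \Delta P}{2 L}.}
#' This closed form is independent of viscosity (the flow rate is not) and
#' serves as the primary verification oracle for the discrete solver and
#' the wall-shear extraction.
#'
#' @param delta_p pressure difference in Pa (inlet minus outlet).
#' @param length channel length in m.
#' @param height channel (gap) height in m.
#' @param viscosity dynamic viscosity in Pa s (accepted for interface
#'   symmetry with the duct oracle; the wall shear does not depend on it).
#' @return wall shear stress in Pa.
#' @examples
#' plane_poiseuille_wss(300, 1500e-6, 100e-6) # 10 Pa
#' @export
plane_poiseuille_wss <- function(delta_p, length, height, viscosity = 1e-3) {
  if (delta_p < 0) stopf("delta_p must be >= 0, got %g", delta_p)
  if (length <= 0) stopf("length must be > 0, got %g", length)
  if (height <= 0) stopf("height must be > 0, got %g", height)
  if (viscosity <= 0) stopf("viscosity must be > 0, got %g", viscosity)
  height * delta_p / (2 * length)
}

#' Volumetric flow rate per unit width of plane Poiseuille flow
#'
#' \eqn{q = H^3 \Delta P / (12 \mu L)} in m^2/s.
#'
#' @inheritParams plane_poiseuille_wss
#' @return flow rate per unit width, m^2/s.
#' @export
plane_poiseuille_flux <- function(delta_p, length, height, viscosity = 1e-3) {
  if (viscosity <= 0) stopf("viscosity must be > 0, got %g", viscosity)
  height^3 * delta_p / (12 * viscosity * length)
}

#' Rectangular duct cross-section specification
#'
#' Describes fully developed pressure-driven flow in a rectangular duct of
#' height `height_um` (z, the gap height) and width `width_um` (y), driven
#' by a streamwise pressure gradient. Used only by the analytic series
#' oracle; has no dependence on the mesh or solver modules.
#'
#' @param height_um duct height in micrometers.
#' @param width_um duct width in micrometers.
#' @param pressure_gradient magnitude of -dp/dx in Pa/m (positive drives
#'   flow in +x).
#' @param viscosity dynamic viscosity in Pa s.
#' @return an object of class `duct_spec`.
#' @export
duct_spec <- function(height_um, width_um, pressure_gradient, viscosity = 1e-3) {
  for (nm in c("height_um", "width_um", "pressure_gradient", "viscosity")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stopf("%s must be a single positive number", nm)
  }
  structure(list(height_um = height_um, width_um = width_um,
                 pressure_gradient = pressure_gradient,
                 viscosity = viscosity),
            class = "duct_spec")
}

#' Fourier-series solution for Poiseuille flow in a rectangular duct
#'
#' Evaluates the classical eigenfunction expansion for fully developed
#' laminar flow in a rectangular duct (height H along z in \[0, H\], width
#' W along y in \[0, W\], gradient G = -dp/dx):
#' \deqn{u(y,z) = \frac{4 G H^2}{\pi^3 \mu} \sum_{n\ odd}
#'   \frac{1}{n^3}\left[1 - \frac{\cosh(n\pi(y - W/2)/H)}{\cosh(n\pi W/(2H))}\right]
#'   \sin\frac{n\pi z}{H}.}
#' Reports the mean velocity, the wall shear stress at the centerline of
#' the bottom wall (y = W/2, z = 0), and the volumetric flow rate, plus a
#' truncation estimate (magnitude of the last retained term of the shear
#' series). As W/H grows the centerline shear approaches the
#' plane-Poiseuille value G H / 2; for a square duct the side walls retard
#' the flow and the centerline shear is strictly smaller — the mechanism
#' behind the drop of peak shear in narrow trabecular gaps.
#'
#' @param spec a [duct_spec()].
#' @param n_terms number of (odd) series terms, at least 10.
#' @return a list with `mean_velocity` (m/s), `centerline_wall_shear` (Pa),
#'   `flow_rate` (m^3/s), and `truncation` (Pa, last term of shear series).
#' @examples
#' s <- duct_spec(100, 2000, 2e5)
#' rect_duct_solution(s)$centerline_wall_shear # ~ plane value 10 Pa
#' @export
rect_duct_solution <- function(spec, n_terms = 100L) {
  stopifnot(inherits(spec, "duct_spec"))
  if (n_terms < 10L) stopf("n_terms must be >= 10, got %d", n_terms)
  H <- um_to_m(spec$height_um)
  W <- um_to_m(spec$width_um)
  G <- spec$pressure_gradient
  mu <- spec$viscosity
  n <- seq(1L, by = 2L, length.out = n_terms) # odd indices

  # Flow rate: Q = G W H^3/(12 mu) * [1 - 192 H/(pi^5 W) sum tanh(n pi W/(2H))/n^5]
  corr <- sum(tanh(n * pi * W / (2 * H)) / n^5)
  Q <- G * W * H^3 / (12 * mu) * (1 - 192 * H / (pi^5 * W) * corr)
  umean <- Q / (W * H)

  # Centerline bottom-wall shear: tau = mu du/dz at y=W/2, z=0
  #   = 4GH/pi^2 sum (1/n^2)[1 - sech(n pi W/(2H))]
  # evaluated in the exponentially convergent rearrangement
  #   = GH/2 - 4GH/pi^2 sum sech(n pi W/(2H))/n^2
  # (sum over odd n of 1/n^2 is pi^2/8)
  terms <- (1 / cosh(n * pi * W / (2 * H))) / n^2
  tau <- G * H / 2 - 4 * G * H / pi^2 * sum(terms)
  list(mean_velocity = umean,
       centerline_wall_shear = tau,
       flow_rate = Q,
       truncation = 4 * G * H / pi^2 * terms[length(terms)])
}

#' Reynolds number of the gap flow
#'
#' \eqn{Re = \rho U H / \mu}, using the mean velocity and the gap height as
#' the characteristic scale. Used to audit the steady laminar-flow
#' assumption: the solver reports Re with every solution and large values
#' flag parameter points where a steady laminar model is questionable.
#'
#' @param props a [fluid_properties()] object.
#' @param mean_velocity mean streamwise velocity in m/s.
#' @param height gap height in m.
#' @return dimensionless Reynolds number.
#' @examples
#' reynolds_number(fluid_properties(), 0.25, 1e-4) # 25
#' @export
reynolds_number <- function(props, mean_velocity, height) {
  stopifnot(inherits(props, "fluid_properties"))
  if (height <= 0) stopf("height must be > 0, got %g", height)
  if (mean_velocity < 0) stopf("mean_velocity must be >= 0, got %g", mean_velocity)
  props$density * mean_velocity * height / props$dynamic_viscosity
}
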