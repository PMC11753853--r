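# Wall shear stress (FSS) extraction, profiles, peaks and crack gradients.
#
# On an axis-aligned no-slip wall the normal velocity vanishes identically
# along the wall, so the tangential viscous traction reduces to
# mu * d(u_t)/dn per tangential component; the FSS magnitude is the
# Euclidean norm over the tangential components. The normal derivative is
# evaluated with a one-sided quadratic fit through the wall value (0) and
# the two nearest interior cell layers, matching the discretization's wall
# flux (exact for parabolic profiles).

wall_tags <- c("bottom_wall", "crack_wall", "top_wall", "side_walls")

#' Compute the wall-shear-stress field on tagged walls
#'
#' @param sol a [solve_flow()] result (must be converged).
#' @param mesh the mesh (defaults to the solution's mesh).
#' @param tags wall tags to evaluate; defaults to all no-slip walls.
#' @return a `wss_field`: the mesh facet table restricted to `tags` with an
#'   added `wss_pa` column (FSS magnitude, Pa).
#' @export
compute_wss <- function(sol, mesh = sol$mesh, tags = wall_tags) {
  stopifnot(inherits(sol, "flow_solution"))
  if (!sol$converged)
    warning("computing WSS on a non-converged solution", call. = FALSE)
  f <- mesh$facets
  tags <- intersect(tags, unique(f$tag))
  if (!length(tags)) stopf("no facets carry any of the requested tags")
  f <- f[f$tag %in% tags, , drop = FALSE]
  mu <- sol$props$dynamic_viscosity
  csz <- list(mesh$dx, mesh$dy, mesh$dz)
  act <- mesh$active

  tang_axes <- function(a) setdiff(if (mesh$planar) c(1L, 3L) else 1:3, a)

  # tangential component value at the centroid of cell layer `cells`
  layer_value <- function(comp, ci, cj, ck) {
    V <- sol$velocity[[comp]]
    lo <- V[cbind(ci, cj, ck)]
    up <- switch(comp,
                 V[cbind(ci + 1L, cj, ck)],
                 V[cbind(ci, cj + 1L, ck)],
                 V[cbind(ci, cj, ck + 1L)])
    (lo + up) / 2
  }

  wss <- numeric(nrow(f))
  for (a in unique(f$axis)) {
    sel <- which(f$axis == a)
    fa <- f[sel, , drop = FALSE]
    h1 <- csz[[a]][fa[[c("i", "j", "k")[a]]]]
    a1 <- h1 / 2
    # second layer inward: shift owner cell by -side along the facet axis
    i2 <- fa$i; j2 <- fa$j; k2 <- fa$k
    if (a == 1L) i2 <- i2 - fa$side
    if (a == 2L) j2 <- j2 - fa$side
    if (a == 3L) k2 <- k2 - fa$side
    nax <- dim(act)
    ok2 <- i2 >= 1L & i2 <= nax[1] & j2 >= 1L & j2 <= nax[2] &
      k2 >= 1L & k2 <= nax[3]
    act2 <- rep(FALSE, nrow(fa))
    act2[ok2] <- act[cbind(i2[ok2], j2[ok2], k2[ok2])]
    i2s <- ifelse(act2, i2, fa$i); j2s <- ifelse(act2, j2, fa$j)
    k2s <- ifelse(act2, k2, fa$k)
    h2 <- csz[[a]][switch(a, i2s, j2s, k2s)]
    b1 <- a1 + (h1 + h2) / 2
    ssq <- numeric(nrow(fa))
    for (comp in tang_axes(a)) {
      u1 <- layer_value(comp, fa$i, fa$j, fa$k)
      u2 <- layer_value(comp, i2s, j2s, k2s)
      dquad <- (u1 * b1^2 - u2 * a1^2) / (a1 * b1 * (b1 - a1))
      dlin <- u1 / a1
      d1 <- ifelse(act2, dquad, dlin)
      ssq <- ssq + d1^2
    }
    wss[sel] <- mu * sqrt(ssq)
  }
  out <- cbind(f, wss_pa = wss)
  attr(out, "geom") <- mesh$geom
  attr(out, "planar") <- mesh$planar
  class(out) <- c("wss_field", "data.frame")
  out
}

# facets forming the bottom-wall sampling line: gap bottom wall plus the
# groove floor (the profile takes the crack-floor value over the mouth)
profile_facets <- function(field) {
  f <- field[(field$tag == "bottom_wall" & field$axis == 3L) |
               (field$tag == "crack_wall" & field$axis == 3L &
                  field$side == -1L), , drop = FALSE]
  if (!nrow(f)) return(f)
  if (!isTRUE(attr(field, "planar"))) {
    geom <- attr(field, "geom")
    ymid <- um_to_m(geom$width_um) / 2
    # keep, per x position, the facet row closest to the centerline
    f <- f[order(f$x, abs(f$y - ymid)), , drop = FALSE]
    f <- f[!duplicated(f$x), , drop = FALSE]
  }
  f[order(f$x), , drop = FALSE]
}

#' Sample the FSS profile along the flow axis on the bottom wall
#'
#' Samples the FSS magnitude at `n_samples` uniformly spaced x positions
#' on the bottom-wall centerline (y = W/2 in 3D) by nearest-facet lookup.
#' Where the line crosses the groove mouth the crack-floor value is used,
#' producing the characteristic low-FSS dip at the microcrack.
#'
#' @param field a [compute_wss()] result containing bottom-wall facets.
#' @param n_samples number of samples (>= 16).
#' @return a `wss_profile` data.frame with `x_um` (strictly increasing) and
#'   `wss_pa` columns.
#' @export
sample_profile <- function(field, n_samples = 256L) {
  stopifnot(inherits(field, "wss_field"))
  if (n_samples < 16L) stopf("n_samples must be >= 16, got %d", n_samples)
  f <- profile_facets(field)
  if (!nrow(f)) stopf("field has no bottom-wall or crack-floor facets")
  geom <- attr(field, "geom")
  L <- um_to_m(geom$length_um)
  xs <- seq(L / (2 * n_samples), L - L / (2 * n_samples),
            length.out = n_samples)
  nearest <- findInterval(xs, (f$x[-1] + f$x[-nrow(f)]) / 2) + 1L
  out <- data.frame(x_um = m_to_um(xs), wss_pa = f$wss_pa[nearest],
                    over_crack = f$tag[nearest] == "crack_wall")
  attr(out, "geom") <- geom
  class(out) <- c("wss_profile", "data.frame")
  out
}

#' Peak FSS of a profile
#'
#' By default the global maximum of the sampled profile. `exclude_ends`
#' drops the given fraction of the channel length at each end first: the
#' corner where an open pressure boundary meets a no-slip wall carries a
#' boundary-condition-dominated shear spike that grows without bound under
#' mesh refinement, so the peak FSS *in the trabecular gap* reported by
#' the parametric sweeps is the interior (10%-90% of L) maximum, which is
#' mesh-convergent (see the methods vignette).
#'
#' @param profile a [sample_profile()] result.
#' @param exclude_ends fraction of the x-extent excluded at each end
#'   (default 0: global maximum).
#' @param crack_margin_um additionally exclude samples over the groove
#'   mouth and within this margin of its edges (default 0). The groove
#'   mouth corners are sharp reentrant edges whose discrete wall shear is
#'   likewise a non-convergent spike; the parametric sweeps report the
#'   peak on the trabecular wall outside the damage zone with a 50 um
#'   margin.
#' @return peak FSS in Pa.
#' @export
peak_fss <- function(profile, exclude_ends = 0, crack_margin_um = 0) {
  stopifnot(inherits(profile, "wss_profile"))
  if (!nrow(profile)) stopf("empty profile")
  if (exclude_ends < 0 || exclude_ends >= 0.5)
    stopf("exclude_ends must lie in [0, 0.5), got %g", exclude_ends)
  v <- profile$wss_pa
  x <- profile$x_um
  keep <- rep(TRUE, length(v))
  if (exclude_ends > 0) {
    span <- max(x) + min(x)          # samples are symmetric in [0, L]
    keep <- x > exclude_ends * span & x < (1 - exclude_ends) * span
  }
  geom <- attr(profile, "geom")
  if (crack_margin_um > 0 && !is.null(geom) && !is.null(geom$crack)) {
    xr <- crack_x_range(geom)
    keep <- keep & (x < xr[1] - crack_margin_um | x > xr[2] + crack_margin_um)
  }
  if (any(keep)) v <- v[keep]
  max(v)
}

#' FSS gradient along the crack wall, in Pa/mm
#'
#' Parameterizes the crack boundary by arc length s (down the upstream
#' flank from the mouth, across the floor, up the downstream flank) and
#' differentiates the FSS magnitude with respect to s by centered finite
#' differences (one-sided at the two mouth ends). Arc length is measured
#' in millimeters, the scale on which in-crack FSS gradients are reported.
#' In 3D the centerline (y = W/2) section of the groove is used.
#'
#' @param field a [compute_wss()] result covering `crack_wall` facets.
#' @return a `gradient_field` data.frame with columns `s_mm`, `x_um`,
#'   `z_um`, `region` (flank_up / floor / flank_down), `wss_pa` and
#'   `gradient_pa_mm`.
#' @export
crack_gradient <- function(field) {
  stopifnot(inherits(field, "wss_field"))
  f <- field[field$tag == "crack_wall" & field$axis != 2L, , drop = FALSE]
  if (!nrow(f)) stopf("field has no crack_wall facets")
  geom <- attr(field, "geom")
  if (!isTRUE(attr(field, "planar"))) {
    ymid <- um_to_m(geom$width_um) / 2
    f <- f[order(f$x, f$z, f$axis, abs(f$y - ymid)), , drop = FALSE]
    f <- f[!duplicated(f[c("x", "z", "axis", "side")]), , drop = FALSE]
  }
  cr <- geom$crack
  d <- um_to_m(cr$depth_um)
  w <- um_to_m(cr$width_um)
  x0 <- um_to_m(cr$center_x_um - cr$width_um / 2)

  region <- character(nrow(f))
  s <- numeric(nrow(f))
  up <- f$axis == 1L & f$side == -1L      # upstream flank (outward -x)
  dn <- f$axis == 1L & f$side == 1L       # downstream flank
  fl <- f$axis == 3L                      # floor
  region[up] <- "flank_up"; region[fl] <- "floor"; region[dn] <- "flank_down"
  s[up] <- -f$z[up]
  s[fl] <- d + (f$x[fl] - x0)
  s[dn] <- d + w + (d + f$z[dn])

  ord <- order(s)
  f <- f[ord, , drop = FALSE]; region <- region[ord]; s <- s[ord]
  tau <- f$wss_pa
  n <- length(s)
  g <- numeric(n)
  if (n >= 2L) {
    g[1] <- (tau[2] - tau[1]) / (s[2] - s[1])
    g[n] <- (tau[n] - tau[n - 1]) / (s[n] - s[n - 1])
    if (n >= 3L)
      g[2:(n - 1)] <- (tau[3:n] - tau[1:(n - 2)]) / (s[3:n] - s[1:(n - 2)])
  }
  out <- data.frame(s_mm = s * 1e3, x_um = m_to_um(f$x),
                    z_um = m_to_um(f$z), region = region,
                    wss_pa = tau, gradient_pa_mm = g / 1e3)
  attr(out, "geom") <- geom
  class(out) <- c("gradient_field", "data.frame")
  out
}

#' Summary statistics and shape classification of an FSS profile
#'
#' Classifies the profile as `inverted_U` when the means of the first and
#' last position deciles are each below 80% of the central plateau level
#' (the median over the central 60% of positions), `flat` when the
#' coefficient of variation is below 2%, and `other` otherwise.
#'
#' @param profile a [sample_profile()] result.
#' @param threshold FSS level (Pa) for the exceedance fraction (default
#'   3 Pa, the physiological response level reported for bone cells).
#' @return a list with `peak`, `median`, `fraction_above_threshold`, and
#'   `shape`.
#' @export
profile_summary <- function(profile, threshold = 3) {
  stopifnot(inherits(profile, "wss_profile"))
  v <- profile$wss_pa
  n <- length(v)
  if (!n) stopf("empty profile")
  dec <- max(1L, floor(n / 10))
  m_first <- mean(v[seq_len(dec)])
  m_last <- mean(v[(n - dec + 1L):n])
  central <- v[v > -Inf & seq_len(n) > 0.2 * n & seq_len(n) <= 0.8 * n]
  plateau <- stats::median(if (length(central)) central else v)
  mu <- mean(v)
  cov <- if (mu > 0) stats::sd(v) / mu else 0
  shape <- if (plateau > 0 && m_first < 0.8 * plateau && m_last < 0.8 * plateau)
    "inverted_U" else if (cov < 0.02) "flat" else "other"
  list(peak = max(v), median = stats::median(v),
       fraction_above_threshold = mean(v > threshold), shape = shape)
}

#' Export solution fields (velocity, pressure, cell FSS proxy) as VTK
#'
#' Writes the volume mesh with cell-centered velocity vectors (face values
#' averaged to centers) and pressure as an ASCII legacy-VTK unstructured
#' grid for visualization.
#'
#' @param sol a `flow_solution`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_field_vtk <- function(sol, path) {
  mesh <- sol$mesh
  write_mesh_vtk(mesh, path, what = "cells")
  cells <- which(mesh$active, arr.ind = TRUE)
  i <- cells[, 1]; j <- cells[, 2]; k <- cells[, 3]
  uc <- (sol$velocity$u[cbind(i, j, k)] + sol$velocity$u[cbind(i + 1L, j, k)]) / 2
  vc <- if (mesh$planar) rep(0, nrow(cells)) else
    (sol$velocity$v[cbind(i, j, k)] + sol$velocity$v[cbind(i, j + 1L, k)]) / 2
  wc <- (sol$velocity$w[cbind(i, j, k)] + sol$velocity$w[cbind(i, j, k + 1L)]) / 2
  pc <- sol$pressure[cbind(i, j, k)]
  con <- file(path, "a")
  on.exit(close(con))
  writeLines(sprintf("CELL_DATA %d", nrow(cells)), con)
  writeLines("VECTORS velocity double", con)
  write(t(cbind(uc, vc, wc)), con, ncolumns = 3L)
  writeLines(c("SCALARS pressure double 1", "LOOKUP_TABLE default"), con)
  write(pc, con, ncolumns = 1L)
  invisible(path)
}

#' Export a WSS field as VTK points with FSS values
#'
#' @param field a `wss_field`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_wss_vtk <- function(field, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "trabflow wall shear stress (Pa) at facet centroids (m)",
               "ASCII", "DATASET POLYDATA"), con)
  writeLines(sprintf("POINTS %d double", nrow(field)), con)
  write(t(cbind(field$x, field$y, field$z)), con, ncolumns = 3L)
  writeLines(sprintf("POINT_DATA %d", nrow(field)), con)
  writeLines(c("SCALARS wss double 1", "LOOKUP_TABLE default"), con)
  write(field$wss_pa, con, ncolumns = 1L)
  invisible(path)
}
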