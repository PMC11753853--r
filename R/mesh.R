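# Boundary-tagged tensor-product meshes for the gap-plus-groove domain.
#
# The domain is a union of axis-aligned boxes (channel + groove), so grid
# lines are aligned with every boundary plane and each cell is fully inside
# or outside the fluid. Velocity/pressure placement on this grid is
# staggered (MAC), which is inf-sup stable: no pressure stabilization is
# required. Planar (2D) meshes are one cell thick in y with unit (1 m)
# thickness and symmetry side planes, so areas and fluxes are per unit
# width.

# Subdivide [bounds[s], bounds[s+1]] segments with per-segment target size.
seg_breaks <- function(bounds, sizes) {
  stopifnot(length(bounds) == length(sizes) + 1L)
  pts <- bounds[1]
  for (s in seq_along(sizes)) {
    len <- bounds[s + 1L] - bounds[s]
    n <- max(1L, as.integer(ceiling(len / sizes[s] - 1e-9)))
    pts <- c(pts, bounds[s] + len * seq_len(n) / n)
  }
  pts
}

#' Generate a boundary-tagged mesh for a gap geometry
#'
#' Builds a tensor-product grid (cells are rectangles in 2D, boxes in 3D)
#' conforming exactly to the channel and groove boundaries. Grid planes are
#' placed at every geometric boundary (z = 0, the groove flanks and floor),
#' and the groove region is refined by `refine_crack_factor` so that the
#' shear-stress gradient inside the crack is resolved on a scale finer
#' than the groove width. All node coordinates are stored in meters.
#'
#' Boundary facets are tagged `inlet` (x = 0), `outlet` (x = L),
#' `bottom_wall` (z = 0 outside the groove), `crack_wall` (groove flanks
#' and floor), `top_wall` (z = H) and `side_walls` (y = 0, W; only in 3D).
#' The tags partition the boundary: every boundary facet carries exactly
#' one tag.
#'
#' @param geom a [gap_geometry()].
#' @param target_size_um requested element size in micrometers; either a
#'   single value or a named vector like `c(x = 50, y = 25, z = 12.5)` for
#'   per-axis sizes (useful for thin, long channels).
#' @param refine_crack_factor ratio in (0, 1]: element size inside and
#'   around the groove relative to `target_size_um`.
#' @return an object of class `tagged_mesh`.
#' @examples
#' m <- generate_mesh(gap_geometry(1500, 1000, 100), 25)
#' table(m$facets$tag)
#' @export
generate_mesh <- function(geom, target_size_um, refine_crack_factor = 0.25) {
  geom <- build_geometry(geom)
  tgt <- target_size_um
  if (is.null(names(tgt))) {
    if (length(tgt) != 1L) stopf("unnamed target_size_um must be a single size")
    tgt <- c(x = tgt, y = tgt, z = tgt)
  } else {
    miss <- setdiff(c("x", "y", "z"), names(tgt))
    base <- if (length(miss) < 3L) max(tgt) else NA_real_
    full <- c(x = NA_real_, y = NA_real_, z = NA_real_)
    full[names(tgt)] <- tgt
    full[miss] <- base
    tgt <- full
  }
  if (any(!is.finite(tgt)) || any(tgt <= 0))
    stopf("target_size_um must be positive, got (%s)",
          paste(format(tgt), collapse = ", "))
  if (!is.numeric(refine_crack_factor) || refine_crack_factor <= 0 ||
      refine_crack_factor > 1)
    stopf("refine_crack_factor must lie in (0, 1], got %g", refine_crack_factor)

  L <- geom$length_um; W <- geom$width_um; H <- geom$height_um
  cr <- geom$crack
  planar <- geom$dimensionality == "planar_2d"

  if (!is.null(cr)) {
    xr <- crack_x_range(geom)
    if (min(xr[1], L - xr[2], cr$depth_um, cr$width_um) <= 0)
      stopf("degenerate geometry: crack [%g, %g] x depth %g um cannot be meshed",
            xr[1], xr[2], cr$depth_um)
    fine_x <- refine_crack_factor * tgt["x"]
    fine_z <- refine_crack_factor * tgt["z"]
    xb <- seg_breaks(c(0, xr[1], xr[2], L), c(tgt["x"], fine_x, tgt["x"]))
    zb <- seg_breaks(c(-cr$depth_um, 0, H), c(fine_z, tgt["z"]))
  } else {
    xb <- seg_breaks(c(0, L), tgt["x"])
    zb <- seg_breaks(c(0, H), tgt["z"])
  }
  if (planar) {
    yb_m <- c(0, 1)                      # unit thickness in meters
  } else {
    if (!is.null(cr) && !identical(cr$span, "full_width")) {
      y0 <- (W - cr$span) / 2; y1 <- (W + cr$span) / 2
      if (y0 <= 0) stopf("crack span %g um does not fit inside width %g um",
                         cr$span, W)
      yb_m <- um_to_m(seg_breaks(c(0, y0, y1, W),
                                 rep(tgt["y"], 3L)))
    } else {
      yb_m <- um_to_m(seg_breaks(c(0, W), tgt["y"]))
    }
  }
  xf <- um_to_m(xb); zf <- um_to_m(zb); yf <- yb_m
  nx <- length(xf) - 1L; ny <- length(yf) - 1L; nz <- length(zf) - 1L
  xc <- (xf[-1] + xf[-length(xf)]) / 2
  yc <- (yf[-1] + yf[-length(yf)]) / 2
  zc <- (zf[-1] + zf[-length(zf)]) / 2

  active <- array(TRUE, c(nx, ny, nz))
  if (!is.null(cr)) {
    below <- zc < 0
    xr_m <- um_to_m(crack_x_range(geom))
    in_x <- xc > xr_m[1] - 1e-15 & xc < xr_m[2] + 1e-15
    in_y <- rep(TRUE, ny)
    if (!planar && !identical(cr$span, "full_width")) {
      ys <- um_to_m(c((W - cr$span) / 2, (W + cr$span) / 2))
      in_y <- yc > ys[1] & yc < ys[2]
    }
    for (k in which(below))
      active[, , k] <- outer(in_x, in_y, `&`)
  }

  mesh <- structure(list(
    geom = geom, planar = planar,
    xf = xf, yf = yf, zf = zf,
    xc = xc, yc = yc, zc = zc,
    dx = diff(xf), dy = diff(yf), dz = diff(zf),
    nx = nx, ny = ny, nz = nz,
    active = active,
    n_elements = sum(active),
    characteristic_size_um = unname(tgt["x"]),
    refine_crack_factor = refine_crack_factor
  ), class = "tagged_mesh")
  mesh$facets <- extract_facets(mesh)
  mesh
}

# Neighbor activity on a given side of a given axis; cells outside the
# bounding box count as inactive.
neighbor_active <- function(A, axis, side) {
  d <- dim(A)
  B <- array(FALSE, d)
  n <- d[axis]
  if (n == 1L && side %in% c(-1L, 1L)) return(B)
  src <- vector("list", 3L); dst <- vector("list", 3L)
  for (a in 1:3) src[[a]] <- dst[[a]] <- seq_len(d[a])
  if (side == -1L) { dst[[axis]] <- 2:n; src[[axis]] <- 1:(n - 1L) }
  else             { dst[[axis]] <- 1:(n - 1L); src[[axis]] <- 2:n }
  B[dst[[1]], dst[[2]], dst[[3]]] <- A[src[[1]], src[[2]], src[[3]]]
  B
}

extract_facets <- function(mesh) {
  A <- mesh$active
  out <- list()
  axes <- if (mesh$planar) c(1L, 3L) else 1:3
  for (axis in axes) for (side in c(-1L, 1L)) {
    bnd <- A & !neighbor_active(A, axis, side)
    idx <- which(bnd, arr.ind = TRUE)
    if (nrow(idx) == 0L) next
    i <- idx[, 1]; j <- idx[, 2]; k <- idx[, 3]
    fx <- if (axis == 1L) mesh$xf[i + (side + 1L) / 2L] else mesh$xc[i]
    fy <- if (axis == 2L) mesh$yf[j + (side + 1L) / 2L] else mesh$yc[j]
    fz <- if (axis == 3L) mesh$zf[k + (side + 1L) / 2L] else mesh$zc[k]
    area <- switch(axis,
                   mesh$dy[j] * mesh$dz[k],
                   mesh$dx[i] * mesh$dz[k],
                   mesh$dx[i] * mesh$dy[j])
    tag <- character(nrow(idx))
    if (axis == 1L) {
      tag[] <- "crack_wall"
      if (side == -1L) tag[i == 1L] <- "inlet"
      if (side == 1L) tag[i == mesh$nx] <- "outlet"
    } else if (axis == 2L) {
      tag[] <- "crack_wall"                       # groove end caps
      if (side == -1L) tag[j == 1L] <- "side_walls"
      if (side == 1L) tag[j == mesh$ny] <- "side_walls"
    } else {
      if (side == 1L) tag[] <- "top_wall"
      else tag <- ifelse(mesh$zc[k] > 0, "bottom_wall", "crack_wall")
    }
    out[[length(out) + 1L]] <- data.frame(
      tag = tag, x = fx, y = fy, z = fz, area = area,
      i = i, j = j, k = k, axis = axis, side = side)
  }
  f <- do.call(rbind, out)
  rownames(f) <- NULL
  f
}

#' @export
print.tagged_mesh <- function(x, ...) {
  cat(sprintf("<tagged_mesh> %d x %d x %d cells (%d active, %s)\n",
              x$nx, x$ny, x$nz, x$n_elements,
              if (x$planar) "planar 2D" else "full 3D"))
  cat("  boundary facets: ")
  print(table(x$facets$tag))
  invisible(x)
}

#' Mesh node coordinates and cell connectivity
#'
#' Nodes are the tensor-grid vertices (meters); cells index the 8 corner
#' nodes of each active cell (4 in planar meshes, in the x-z plane).
#' These feed the VTK export and are mainly useful for visualization.
#'
#' @param mesh a `tagged_mesh`.
#' @return `mesh_nodes`: a matrix with columns x, y, z (planar: x, z);
#'   `mesh_cells`: an integer matrix, one row per active cell.
#' @export
mesh_nodes <- function(mesh) {
  if (mesh$planar) {
    g <- expand.grid(x = mesh$xf, z = mesh$zf)
    return(cbind(x = g$x, z = g$z))
  }
  g <- expand.grid(x = mesh$xf, y = mesh$yf, z = mesh$zf)
  cbind(x = g$x, y = g$y, z = g$z)
}

#' @rdname mesh_nodes
#' @export
mesh_cells <- function(mesh) {
  idx <- which(mesh$active, arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]; k <- idx[, 3]
  nxp <- mesh$nx + 1L
  if (mesh$planar) {
    n00 <- (k - 1L) * nxp + i        # node (i, k)
    return(cbind(n00, n00 + 1L, n00 + 1L + nxp, n00 + nxp))
  }
  nyp <- mesh$ny + 1L
  nid <- function(ii, jj, kk) ((kk - 1L) * nyp + (jj - 1L)) * nxp + ii
  cbind(nid(i, j, k), nid(i + 1L, j, k), nid(i + 1L, j + 1L, k), nid(i, j + 1L, k),
        nid(i, j, k + 1L), nid(i + 1L, j, k + 1L), nid(i + 1L, j + 1L, k + 1L),
        nid(i, j + 1L, k + 1L))
}

#' Export a mesh (and optionally its boundary tags) in legacy VTK format
#'
#' Writes an ASCII legacy-VTK unstructured grid readable by ParaView and
#' similar tools. `what = "cells"` writes the volume cells; `what =
#' "facets"` writes the boundary facets with an integer `tag` cell field
#' (the tag/integer legend is embedded in the header comment line).
#'
#' @param mesh a `tagged_mesh`.
#' @param path output file path.
#' @param what `"cells"` or `"facets"`.
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path, what = c("cells", "facets")) {
  what <- match.arg(what)
  con <- file(path, "w")
  on.exit(close(con))
  if (what == "cells") {
    nodes <- mesh_nodes(mesh)
    if (ncol(nodes) == 2L) nodes <- cbind(nodes[, 1], 0, nodes[, 2])
    cells <- mesh_cells(mesh)
    ctype <- if (ncol(cells) == 4L) 9L else 12L  # quad / hexahedron
    writeLines(c("# vtk DataFile Version 3.0",
                 "trabflow mesh (coordinates in meters)",
                 "ASCII", "DATASET UNSTRUCTURED_GRID"), con)
    writeLines(sprintf("POINTS %d double", nrow(nodes)), con)
    write(t(nodes), con, ncolumns = 3L)
    writeLines(sprintf("CELLS %d %d", nrow(cells), nrow(cells) * (1L + ncol(cells))), con)
    write(t(cbind(ncol(cells), cells - 1L)), con, ncolumns = 1L + ncol(cells))
    writeLines(sprintf("CELL_TYPES %d", nrow(cells)), con)
    write(rep(ctype, nrow(cells)), con, ncolumns = 1L)
  } else {
    f <- mesh$facets
    tags <- sort(unique(f$tag))
    legend <- paste(sprintf("%d=%s", seq_along(tags), tags), collapse = " ")
    writeLines(c("# vtk DataFile Version 3.0",
                 paste("trabflow boundary facets; tag legend:", legend),
                 "ASCII", "DATASET POLYDATA"), con)
    writeLines(sprintf("POINTS %d double", nrow(f)), con)
    write(t(cbind(f$x, f$y, f$z)), con, ncolumns = 3L)
    writeLines(sprintf("VERTICES %d %d", nrow(f), 2L * nrow(f)), con)
    write(t(cbind(1L, seq_len(nrow(f)) - 1L)), con, ncolumns = 2L)
    writeLines(sprintf("POINT_DATA %d", nrow(f)), con)
    writeLines(c("SCALARS tag int 1", "LOOKUP_TABLE default"), con)
    write(match(f$tag, tags), con, ncolumns = 1L)
    writeLines("SCALARS area double 1", con)
    writeLines("LOOKUP_TABLE default", con)
    write(f$area, con, ncolumns = 1L)
  }
  invisible(path)
}

#' Total boundary area per tag
#'
#' @param mesh a `tagged_mesh`.
#' @return named numeric vector of facet-area sums (m^2; per unit width in
#'   planar meshes) by tag.
#' @export
boundary_areas <- function(mesh) {
  tapply(mesh$facets$area, mesh$facets$tag, sum)
}
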