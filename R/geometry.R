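#' Rectangular microcrack (groove) specification
#'
#' A microcrack is modeled as a rectangular groove recessed into the bottom
#' wall of the trabecular gap: it occupies z in \[-depth, 0\] and
#' x in \[center_x - width/2, center_x + width/2\]. In 3D the groove spans
#' the full model width, which keeps the planar and 3D models nested.
#'
#' @param depth_um groove depth below the bottom wall, micrometers (>= 0).
#' @param width_um groove extent along the flow axis x, micrometers (>= 0).
#' @param center_x_um groove midpoint along x, micrometers. Defaults to the
#'   channel midpoint when the crack is attached to a geometry.
#' @param span either `"full_width"` (default) or a positive span in
#'   micrometers for a y-centered groove (only meaningful in 3D).
#' @return an object of class `microcrack_spec`.
#' @examples
#' microcrack_spec(100, 50) # the large groove
#' @export
microcrack_spec <- function(depth_um, width_um, center_x_um = NA_real_,
                            span = "full_width") {
  if (!is.numeric(depth_um) || depth_um < 0)
    stopf("crack depth_um must be >= 0, got %s", format(depth_um))
  if (!is.numeric(width_um) || width_um < 0)
    stopf("crack width_um must be >= 0, got %s", format(width_um))
  if (!identical(span, "full_width")) {
    if (!is.numeric(span) || span <= 0)
      stopf("span must be \"full_width\" or a positive width in um")
  }
  structure(list(depth_um = as.numeric(depth_um),
                 width_um = as.numeric(width_um),
                 center_x_um = as.numeric(center_x_um),
                 span = span),
            class = "microcrack_spec")
}

is_degenerate_crack <- function(crack) {
  is.null(crack) || crack$depth_um == 0 || crack$width_um == 0
}

#' Trabecular gap geometry
#'
#' The simplified inter-trabecular space: a rectangular channel of length
#' `length_um` along the flow axis x, width `width_um` along y, and height
#' `height_um` along z, optionally with a rectangular microcrack groove in
#' the bottom wall (z = 0). Planar (2D x-z) geometries ignore the width for
#' meshing — the flow is y-invariant — but retain it for reporting.
#'
#' @param length_um channel length L in micrometers (flow direction).
#' @param width_um channel width W in micrometers.
#' @param height_um gap height H in micrometers.
#' @param crack a [microcrack_spec()] or `NULL` for a plain channel.
#' @param dimensionality `"planar_2d"` or `"full_3d"`.
#' @return a validated object of class `gap_geometry`.
#' @seealso [build_geometry()] which validates an existing object.
#' @examples
#' gap_geometry(1500, 1000, 100)                       # plain channel
#' gap_geometry(1500, 1000, 100, microcrack_spec(100, 50))
#' @export
gap_geometry <- function(length_um, width_um, height_um, crack = NULL,
                         dimensionality = c("planar_2d", "full_3d")) {
  dimensionality <- match.arg(dimensionality)
  g <- structure(list(length_um = as.numeric(length_um),
                      width_um = as.numeric(width_um),
                      height_um = as.numeric(height_um),
                      crack = crack,
                      dimensionality = dimensionality),
                 class = "gap_geometry")
  build_geometry(g)
}

#' Validate a gap geometry
#'
#' Checks all dimensional invariants: positive lengths, the crack strictly
#' interior to the bottom wall, and crack width smaller than the channel
#' length. A degenerate crack (zero depth or width) is dropped, making the
#' geometry identical to the no-crack case. The crack center defaults to
#' the channel midpoint x = L/2.
#'
#' @param config a `gap_geometry` (possibly hand-assembled).
#' @return the validated `gap_geometry`; errors name the offending
#'   dimension for impossible configurations.
#' @export
build_geometry <- function(config) {
  if (!inherits(config, "gap_geometry"))
    stopf("config must be a gap_geometry object")
  g <- config
  for (nm in c("length_um", "width_um", "height_um")) {
    v <- g[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stopf("%s must be a single positive length in um, got %s", nm, format(v))
  }
  if (!g$dimensionality %in% c("planar_2d", "full_3d"))
    stopf("dimensionality must be planar_2d or full_3d")
  if (!is.null(g$crack) && !inherits(g$crack, "microcrack_spec"))
    stopf("crack must be a microcrack_spec or NULL")
  if (is_degenerate_crack(g$crack)) {
    g$crack <- NULL
    return(g)
  }
  cr <- g$crack
  if (is.na(cr$center_x_um)) cr$center_x_um <- g$length_um / 2
  if (cr$width_um >= g$length_um)
    stopf("crack width_um (%g) must be smaller than channel length_um (%g)",
          cr$width_um, g$length_um)
  if (cr$center_x_um <= 0 || cr$center_x_um >= g$length_um)
    stopf("crack center_x_um (%g) must lie inside (0, %g)",
          cr$center_x_um, g$length_um)
  x0 <- cr$center_x_um - cr$width_um / 2
  x1 <- cr$center_x_um + cr$width_um / 2
  if (x0 <= 0 || x1 >= g$length_um)
    stopf("crack [%g, %g] um must be strictly interior to the bottom wall (0, %g)",
          x0, x1, g$length_um)
  if (!identical(cr$span, "full_width") && cr$span > g$width_um)
    stopf("crack span (%g) must not exceed channel width_um (%g)",
          cr$span, g$width_um)
  g$crack <- cr
  g
}

#' @export
print.gap_geometry <- function(x, ...) {
  cat(sprintf("<gap_geometry> L=%g um, W=%g um, H=%g um (%s)\n",
              x$length_um, x$width_um, x$height_um, x$dimensionality))
  if (!is.null(x$crack))
    cat(sprintf("  microcrack: depth %g um, width %g um, centered at x=%g um\n",
                x$crack$depth_um, x$crack$width_um, x$crack$center_x_um))
  else cat("  no microcrack\n")
  invisible(x)
}

#' Extent of the crack along x, in micrometers
#' @param geom a `gap_geometry`.
#' @return c(x0, x1) in um, or NULL when no crack is present.
#' @keywords internal
crack_x_range <- function(geom) {
  if (is.null(geom$crack)) return(NULL)
  c(geom$crack$center_x_um - geom$crack$width_um / 2,
    geom$crack$center_x_um + geom$crack$width_um / 2)
}
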