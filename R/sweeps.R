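# Parametric sweeps over pressure difference, gap width/height and crack
# size, with peak-FSS tables, OLS fits and percent-change summaries.

#' Configure a parametric sweep
#'
#' @param varied one of `"delta_p"`, `"gap_width"`, `"gap_height"`,
#'   `"crack_depth"`, `"crack_width"`.
#' @param values at least two distinct positive values (Pa for `delta_p`,
#'   micrometers otherwise).
#' @param base a [scenario()] providing every non-varied parameter.
#' @return an object of class `sweep_config`.
#' @export
sweep_config <- function(varied = c("delta_p", "gap_width", "gap_height",
                                    "crack_depth", "crack_width"),
                         values, base) {
  varied <- match.arg(varied)
  if (length(values) < 2L) stopf("a sweep needs at least 2 values, got %d",
                                 length(values))
  if (any(values <= 0)) stopf("sweep values must be positive")
  if (anyDuplicated(values)) stopf("sweep values must be distinct")
  stopifnot(inherits(base, "scenario"))
  if (varied %in% c("crack_depth", "crack_width") &&
      is.null(base$geometry$crack))
    stopf("crack sweeps need a base scenario with a crack")
  structure(list(varied = varied, values = as.numeric(values), base = base),
            class = "sweep_config")
}

# apply one sweep value to the base scenario
apply_sweep_value <- function(cfg, value) {
  sc <- cfg$base
  g <- sc$geometry
  cr <- g$crack
  switch(cfg$varied,
    delta_p = { sc$bc <- pressure_bc(value + sc$bc$outlet_pressure,
                                     sc$bc$outlet_pressure,
                                     sc$bc$pressure_type) },
    gap_width = { g$width_um <- value },
    gap_height = { g$height_um <- value },
    crack_depth = { cr$depth_um <- value },
    crack_width = { cr$width_um <- value })
  g$crack <- cr
  sc$geometry <- build_geometry(g)
  sc$name <- sprintf("%s_%g", cfg$varied, value)
  sc
}

#' Run a parametric sweep
#'
#' Solves the flow for every requested value of the varied parameter and
#' tabulates the peak FSS in the trabecular gap. The gap peak is taken
#' over the interior 80% of the channel length (the first and last tenth,
#' where the open pressure boundary meets the no-slip wall and the
#' discrete wall shear is boundary-dominated, are excluded; see the
#' methods vignette). Non-converged solves are kept as flagged rows with
#' `NA` peaks, never dropped silently.
#'
#' @param cfg a [sweep_config()].
#' @param mesh_size_um mesh resolution override; `NULL` (default) picks an
#'   aspect-aware resolution per value (25 um planar; finer cross-section
#'   targets in 3D).
#' @param n_samples profile sampling density.
#' @param exclude_ends fraction of the channel length excluded at each end
#'   for the gap-peak extraction (default 0.1).
#' @param crack_margin_um margin around the groove mouth excluded from the
#'   gap-peak extraction (default 50 um); see [peak_fss()].
#' @return a `sweep_result` data.frame with one row per value (`value`,
#'   `peak_fss_pa`, `reynolds`, `converged`) and the sampled profiles in
#'   `attr(, "profiles")`.
#' @export
run_sweep <- function(cfg, mesh_size_um = NULL, n_samples = 256L,
                      exclude_ends = 0.1, crack_margin_um = 50) {
  stopifnot(inherits(cfg, "sweep_config"))
  rows <- vector("list", length(cfg$values))
  profiles <- list()
  for (s in seq_along(cfg$values)) {
    sc <- apply_sweep_value(cfg, cfg$values[s])
    msz <- if (is.null(mesh_size_um)) default_mesh_size(sc$geometry)
      else if (length(mesh_size_um) == 1L && is.null(names(mesh_size_um)))
        default_mesh_size(sc$geometry, mesh_size_um)
      else mesh_size_um
    rcf <- if (sc$geometry$dimensionality == "full_3d")
      default_refine(sc$geometry) else sc$refine_crack_factor
    mesh <- generate_mesh(sc$geometry, msz, rcf)
    sol <- solve_flow(mesh, sc$props, sc$bc, sc$solver)
    peak <- NA_real_
    if (sol$converged) {
      prof <- sample_profile(compute_wss(sol), n_samples)
      profiles[[sc$name]] <- prof
      peak <- peak_fss(prof, exclude_ends = exclude_ends,
                       crack_margin_um = crack_margin_um)
    } else {
      warning(sprintf("sweep point %s = %g did not converge; peak set to NA",
                      cfg$varied, cfg$values[s]), call. = FALSE)
    }
    rows[[s]] <- data.frame(value = cfg$values[s], peak_fss_pa = peak,
                            reynolds = sol$reynolds,
                            converged = sol$converged)
  }
  out <- do.call(rbind, rows)
  attr(out, "varied") <- cfg$varied
  attr(out, "profiles") <- profiles
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> varied: %s\n", attr(x, "varied")))
  print.data.frame(x)
  invisible(x)
}

#' Ordinary least squares fit with coefficient of determination
#'
#' Fits `y ~ x` by OLS (with intercept) and reports the slope, intercept
#' and R-squared = 1 - SS_res/SS_tot. A constant response has R-squared 0
#' by convention.
#'
#' @param x,y equal-length numeric vectors, `length >= 3`; `x` must vary.
#' @return an object of class `regression_summary` with fields `slope`,
#'   `intercept`, `r_squared`, `n`.
#' @export
linear_fit_r2 <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y lengths differ (%d vs %d)",
                                    length(x), length(y))
  if (length(x) < 3L) stopf("need at least 3 points, got %d", length(x))
  if (anyNA(x) || anyNA(y)) stopf("x and y must not contain NA")
  if (stats::sd(x) == 0) stopf("x is degenerate (all values equal)")
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, n = length(x)),
            class = "regression_summary")
}

#' @export
print.regression_summary <- function(x, ...) {
  cat(sprintf("<ols fit> slope=%.6g intercept=%.6g R^2=%.6f (n=%d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Percent change relative to a reference
#'
#' `100 * (reference - value) / reference`: positive when `value` is lower
#' than `reference`.
#'
#' @param reference reference level (> 0).
#' @param value compared level.
#' @return percent change.
#' @examples
#' percent_change(14, 10) # 28.57...
#' @export
percent_change <- function(reference, value) {
  if (!is.numeric(reference) || reference <= 0)
    stopf("reference must be > 0, got %s", format(reference))
  100 * (reference - value) / reference
}

#' Check that the gap peak FSS is invariant to crack size
#'
#' Computes the relative spread (range over mean, in percent) of the peak
#' gap FSS across the crack-depth and crack-width sweeps and passes when
#' the larger spread is at most `tol` percent.
#'
#' @param result_depth,result_width [run_sweep()] results over crack depth
#'   and width.
#' @param tol tolerance in percent (default 5).
#' @return a list with `pass`, `max_spread_pct`, `spread_depth_pct`,
#'   `spread_width_pct`.
#' @export
crack_invariance_check <- function(result_depth, result_width, tol = 5) {
  for (r in list(result_depth, result_width)) {
    stopifnot(inherits(r, "sweep_result"))
    if (!all(r$converged))
      stopf("crack invariance check requires all sweep rows converged")
  }
  spread <- function(x) 100 * (max(x) - min(x)) / mean(x)
  sd_ <- spread(result_depth$peak_fss_pa)
  sw_ <- spread(result_width$peak_fss_pa)
  list(pass = max(sd_, sw_) <= tol, max_spread_pct = max(sd_, sw_),
       spread_depth_pct = sd_, spread_width_pct = sw_)
}

#' Reproduce the full parametric study
#'
#' Drives all four parametric studies (pressure difference, gap height,
#' gap width in 3D, crack depth/width) plus the in-crack gradient study on
#' the large and small grooves, at a configurable mesh resolution, and
#' writes peak tables, OLS fits, percent changes and gradient summaries
#' with provenance metadata to `output_dir`. The run is deterministic:
#' identical configurations produce identical result tables.
#'
#' @param output_dir directory for the result tables (one subdirectory per
#'   study).
#' @param mesh_size_um base mesh resolution in um (planar studies use it
#'   directly; 3D studies derive aspect-aware per-axis sizes from it).
#' @param n_samples profile sampling density.
#' @param widths gap widths for the 3D width study (um).
#' @param quiet suppress progress messages.
#' @return a `reproduction_report` list with the sweep tables, fits,
#'   percent change, crack-invariance result and gradient summaries.
#' @export
reproduce_paper <- function(output_dir, mesh_size_um = 25, n_samples = 256L,
                            widths = c(1000, 800, 600, 400, 200, 100),
                            quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  base2d <- scenario("base", gap_geometry(1500, 100, 100, large_groove()),
                     pressure_bc(300))
  msz2 <- mesh_size_um
  rcf <- 0.25

  say("pressure-difference sweep (2D)...")
  cfg_p <- sweep_config("delta_p", c(50, 100, 200, 250), base2d)
  sw_p <- run_sweep(cfg_p, mesh_size_um = msz2, n_samples = n_samples)
  fit_p <- linear_fit_r2(sw_p$value, sw_p$peak_fss_pa)

  say("gap-height sweep (2D)...")
  base_h <- scenario("base_h", gap_geometry(1500, 1000, 100, large_groove()),
                     pressure_bc(300))
  cfg_h <- sweep_config("gap_height", c(100, 200, 500, 1000), base_h)
  sw_h <- run_sweep(cfg_h, mesh_size_um = msz2, n_samples = n_samples)
  fit_h <- linear_fit_r2(sw_h$value, sw_h$peak_fss_pa)

  say("gap-width sweep (3D)...")
  base_w <- scenario("base_w",
                     gap_geometry(1500, 1000, 100, large_groove(), "full_3d"),
                     pressure_bc(300))
  cfg_w <- sweep_config("gap_width", widths, base_w)
  sw_w <- run_sweep(cfg_w, mesh_size_um = mesh_size_um, n_samples = n_samples)
  pc_w <- if (all(c(800, 100) %in% widths)) {
    percent_change(sw_w$peak_fss_pa[sw_w$value == 800],
                   sw_w$peak_fss_pa[sw_w$value == 100])
  } else NA_real_

  say("crack-size sweeps (2D)...")
  base_c <- scenario("base_c", gap_geometry(1500, 1000, 100, large_groove()),
                     pressure_bc(300))
  sw_d <- run_sweep(sweep_config("crack_depth", c(100, 50, 20, 10), base_c),
                    mesh_size_um = msz2, n_samples = n_samples)
  sw_cw <- run_sweep(sweep_config("crack_width", c(100, 50, 20, 10), base_c),
                     mesh_size_um = msz2, n_samples = n_samples)
  inv <- crack_invariance_check(sw_d, sw_cw)

  say("in-crack gradient study (2D, refined)...")
  grooves <- list(large_groove_100x50 = microcrack_spec(100, 50),
                  small_groove_20x10 = microcrack_spec(20, 10),
                  small_groove_10x20 = microcrack_spec(10, 20))
  gradients <- list()
  grad_summary <- list()
  for (nm in names(grooves)) {
    sc <- scenario(nm, gap_geometry(1500, 1000, 100, grooves[[nm]]),
                   pressure_bc(300), mesh_size_um = msz2,
                   refine_crack_factor = rcf)
    run <- run_scenario(sc, n_samples)
    gr <- crack_gradient(run$field)
    gradients[[nm]] <- gr
    fl <- abs(gr$gradient_pa_mm[gr$region == "floor"])
    grad_summary[[nm]] <- list(
      max_abs_gradient_pa_mm = max(abs(gr$gradient_pa_mm)),
      median_floor_gradient_pa_mm = stats::median(fl),
      fraction_below_0.1 = mean(abs(gr$gradient_pa_mm) < 0.1),
      reynolds = run$solution$reynolds,
      converged = run$solution$converged)
  }

  sweeps <- list(pressure = sw_p, height = sw_h, width = sw_w,
                 crack_depth = sw_d, crack_width = sw_cw)
  for (nm in names(sweeps)) {
    meta <- list(study = nm, mesh_size_um = as.list(msz2),
                 n_samples = n_samples)
    results_writer(sweeps[[nm]], attr(sweeps[[nm]], "profiles"), NULL,
                   file.path(output_dir, nm), manifest_extra = meta)
  }
  results_writer(NULL, NULL, gradients, file.path(output_dir, "gradients"),
                 manifest_extra = list(study = "gradients",
                                       mesh_size_um = as.list(msz2),
                                       refine_crack_factor = rcf))

  report <- list(
    pressure = list(table = sw_p, fit = fit_p),
    height = list(table = sw_h, fit = fit_h,
                  peak_at_1000 = sw_h$peak_fss_pa[sw_h$value == 1000]),
    width = list(table = sw_w, percent_drop_800_to_100 = pc_w),
    crack = list(depth = sw_d, width = sw_cw, invariance = inv),
    gradients = grad_summary,
    settings = list(mesh_size_um = mesh_size_um, n_samples = n_samples))
  class(report) <- "reproduction_report"
  report
}

#' @export
print.reproduction_report <- function(x, ...) {
  cat("<reproduction_report>\n")
  cat(sprintf("  peak FSS vs dP:     R^2 = %.5f\n", x$pressure$fit$r_squared))
  cat(sprintf("  peak FSS vs height: R^2 = %.5f; peak at H=1000 um: %.2f Pa\n",
              x$height$fit$r_squared, x$height$peak_at_1000))
  if (is.finite(x$width$percent_drop_800_to_100))
    cat(sprintf("  width 800 -> 100 um: peak FSS drop %.2f%%\n",
                x$width$percent_drop_800_to_100))
  cat(sprintf("  crack-size invariance: %s (max spread %.2f%%)\n",
              if (x$crack$invariance$pass) "pass" else "FAIL",
              x$crack$invariance$max_spread_pct))
  for (nm in names(x$gradients))
    cat(sprintf("  %s: max |dFSS/ds| = %.3g Pa/mm, median floor %.3g Pa/mm\n",
                nm, x$gradients[[nm]]$max_abs_gradient_pa_mm,
                x$gradients[[nm]]$median_floor_gradient_pa_mm))
  invisible(x)
}
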