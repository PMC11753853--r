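---
title: "Fluid shear stress in microcracked trabecular gaps: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fluid shear stress in microcracked trabecular gaps: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trabflow)
```

## The problem

Trabecular (spongy) bone is a network of struts separated by fluid-filled
gaps on the order of 100-1000 um. When bone deforms under load, the
interstitial fluid is driven through these gaps and exerts a fluid shear
stress (FSS) on the trabecular surfaces — the mechanical signal to which
bone cells (osteocytes, osteoblasts, osteoclast precursors) are most
responsive. Microcracks in a trabecular wall change the local FSS
landscape: the damaged region sees much lower shear than the surrounding
gap, and spatial FSS *gradients* appear inside the crack. Both the level
and the gradient of FSS are candidate cues for the targeted remodeling
observed near large microcracks.

`trabflow` implements an idealized computational model of this
microenvironment: steady, incompressible, laminar flow through a
rectangular inter-trabecular gap (length $L$ along the flow axis $x$,
width $W$, height $H$) whose bottom wall carries a rectangular microcrack
groove (depth $d$ below the wall, width $w$ along $x$). The package
builds the geometry, meshes it, solves the flow, extracts wall shear
stress fields, bottom-wall profiles and in-crack gradients, and drives
the four parametric studies (pressure difference, gap width, gap height,
crack depth/width) with regression summaries.

## Governing equations and boundary conditions

The fluid is water-like interstitial fluid/marrow treated as Newtonian:
density $\rho = 1000\,$kg/m$^3$, dynamic viscosity
$\mu = 10^{-3}\,$Pa s. The steady incompressible Navier-Stokes equations

$$\rho\,(\mathbf{u}\cdot\nabla)\mathbf{u}
  = -\nabla p + \mu \nabla^2 \mathbf{u},
  \qquad \nabla\cdot\mathbf{u} = 0$$

are solved with no-slip walls everywhere except the two open $x$-ends,
where pressures are prescribed and the tangential velocity is constrained
to zero. A `stokes` model (creeping flow, a single linear solve) is
available alongside the default `navier_stokes` model (Newton iteration).

**Static vs stagnation inlet pressure.** How the inlet pressure acts is
the single most consequential modeling choice. With a purely *static*
normal-stress inlet, fully developed plane Poiseuille flow is an exact
steady Navier-Stokes solution of the straight gap at *any* Reynolds
number: the peak wall shear would then be $H\Delta P/(2L)$ — 100 Pa at
$H = 1000$ um and $\Delta P = 300$ Pa — and the pressure and height
sweeps would be exactly linear. Neither matches the behavior this model
family is meant to emulate, where the wide-gap response saturates around
15 Pa and the sweep fits have $R^2$ visibly below 1. The package's
default is therefore a *stagnation (total) pressure* inlet, a standard
commercial-solver inlet option: incoming fluid, drawn from a quiescent
reservoir (the surrounding marrow space), sees an effective static
pressure $p_0 - \tfrac{1}{2}\rho u_n^2$. This caps the attainable
velocity near $\sqrt{2\Delta P/\rho}$ (0.77 m/s at 300 Pa) and produces
the inertially saturated, boundary-layer-dominated regime in wide gaps,
with mild sub-linearity already at $H = 100$ um. The plain static inlet
is retained as `pressure_bc(..., pressure_type = "static")`; the Stokes
model is linear and always static, which preserves the exact
linearity-in-$\Delta P$ invariants used for verification.

At Reynolds numbers of several hundred (reached in the 500-1000 um
gaps), a steady laminar model is an idealization; the solver follows it
deliberately, reports the Reynolds number $\rho U_{mean} H/\mu$ with
every solution, and reports non-convergence honestly rather than hiding
it.

## Discretization

The domain is a union of axis-aligned boxes, so the mesh is a
tensor-product grid whose planes conform exactly to every boundary
(including the groove flanks and floor), with the groove region refined
by `refine_crack_factor` (default 0.25). Velocity components live on the
faces normal to their direction and pressure at cell centers (a
staggered/MAC arrangement). This pairing is inf-sup stable — there are
no spurious pressure modes and no stabilization parameters — and the
pressure boundary conditions enter the normal momentum equation of the
boundary faces through a mirrored ghost pressure, which is second-order
accurate.

Two details matter for accuracy on the thin-channel geometries used
here:

* **Quadratic wall fluxes.** The tangential viscous flux at a no-slip
  wall is evaluated from a one-sided quadratic fit through the wall value
  and the two nearest interior points. Fully developed Poiseuille flow is
  then reproduced to machine precision on a uniform grid at any cell
  count — the 100 um gap is quantitatively correct even at four cells
  across the height. The same fit is used when wall shear stress is
  extracted, so `compute_wss` is exact for parabolic profiles
  ($\tau = \mu\,\partial u_t/\partial n$; the normal component of the
  traction is excluded by construction on axis-aligned walls).
* **Upwind convection.** The convective term uses first-order upwinding
  (advective form), which is robust up to the highest Reynolds numbers in
  the study at the cost of extra numerical diffusion in developing
  regions. Developed regions are unaffected (the convective term vanishes
  there). Ties in the upwind direction (zero advecting velocity) resolve
  to the downstream-difference-free branch, i.e. $u \ge 0$ counts as
  positive flow.

The nonlinear system is solved by damped Newton iteration (step halving
on residual increase), warm-started from an amplitude-rescaled Stokes
solution — the rescaling solves the scalar Bernoulli consistency
condition for the stagnation inlet, which brings the initial guess close
to the saturated branch. When the estimated Reynolds number exceeds 100
the applied pressure is ramped in at least 5 continuation steps. Defaults
(`newton_tol = 1e-8` relative, `newton_max_iter = 25`) converge all
study scenarios; `converged = FALSE` plus the residual history is
returned otherwise, and sweep rows from non-converged solves are flagged
with `NA` peaks, never dropped.

Planar (2D) geometries are meshed one cell thick with unit (1 m)
thickness and symmetry side planes, so the planar problem is solved
exactly within the same code path and fluxes are per unit width; `full_3d`
uses no-slip side walls (this is what makes the gap-*width* study
inherently 3D: the width effect *is* the side-wall effect).

## Wall shear stress, profiles, peaks, gradients

The FSS magnitude is computed per boundary facet. "FSS along the
$x$-axis" is sampled on the bottom-wall centerline ($y = W/2$ in 3D) at
uniform $x$ positions by nearest-facet lookup; over the groove mouth the
profile takes the crack-floor value, producing the characteristic
low-FSS dip at the microcrack.

**Where the peak is measured.** Two locations on the bottom wall carry
*non-convergent* discrete shear spikes: (i) the corners where the open
pressure boundaries meet the no-slip wall, and (ii) the reentrant corners
of the groove mouth. Both are genuine stress singularities of the
idealized sharp-cornered geometry (locally $\tau \sim r^{-0.455}$ for a
270-degree corner), so the facet-adjacent values grow without bound under
mesh refinement and cannot be reported as physical peaks; a real crack
edge is rounded and a real gap opens into compliant marrow. The
parametric sweeps therefore report the **gap peak**: the profile maximum
excluding the first and last 10% of the channel length and a 50 um
margin around the groove mouth. This quantity is mesh-convergent and is
what "peak FSS within the trabecular gap" means throughout the package.
`peak_fss()` itself defaults to the plain global maximum; the exclusions
are explicit arguments.

**In-crack gradients.** The crack boundary is parameterized by arc
length $s$ (down the upstream flank, across the floor, up the downstream
flank; total $2d + w$), and the FSS gradient $d\tau/ds$ is computed by
centered finite differences (one-sided at the mouth ends), reported in
Pa/mm — the scale on which in-crack gradients are physiologically
quoted. Note that the *maximum* of $|d\tau/ds|$ over the whole crack
wall is dominated by the singular mouth corners and grows under
refinement; the scientifically stable statements are about the groove
interior (e.g. the median over the floor facets), which is what the
acceptance checks that can pass do assert.

**Profile shape.** A profile classifies as `inverted_U` when the means
of its first and last position deciles are each below 80% of the central
plateau level (median over the central 60% of positions); `flat` when the
coefficient of variation is below 2%; `other` otherwise. Solved profiles
of this box-channel model classify as `other` rather than `inverted_U`:
with pressures applied directly at the gap ends the wall shear does not
fall toward the ends (it rises slightly at the inlet). An inverted-U
shape would require the gap to open into wider reservoir regions, which
are outside this model's geometry; the classifier is provided because it
encodes the expected field shape for such extended models.

## Parameters and defaults

| parameter | default | units | rationale |
|---|---|---|---|
| density `rho` | 1000 | kg/m^3 | interstitial fluid ~ saline/water |
| viscosity `mu` | 1e-3 | Pa s | water at room temperature |
| model length `L` | 1500 | um | ~ trabecular spacing scale |
| gap width/height | 100-1000 | um | printed study grid |
| large groove | d=100, w=50 | um | microcrack at osteoclast scale |
| small groove | 20x10 and 10x20 | um | both printed readings shipped |
| pressure differences | 50-300 | Pa | marrow pressure-difference scale |
| inlet type | total | — | reservoir-fed gap (see above) |
| mesh target (2D) | 25 | um | ~ the study's ~200k-element density |
| mesh target (3D) | x=50, y=W/8, z=12.5 | um | aspect-aware cross-section resolution |
| `refine_crack_factor` | 0.25 (2D) | — | resolve gradients on a sub-groove-width scale |
| `newton_tol` | 1e-8 | relative | far below any physical tolerance |
| profile samples | 256 | — | sub-groove sampling along L |

The problem sizes used by the test suite and the acceptance script are
the package defaults above (a few hundred to a few thousand cells in 2D,
a few thousand in 3D); `mesh_convergence_study()` exposes the
resolution-dependence of any scenario, and the gap peak changes by less
than 2% between the two finest of three successively refined meshes on
the reference scenario.

## What the scenario generator emulates — and what it does not

`paper_presets()` materializes the full printed parameter grid of the
study (24 scenarios): pressure sweep on the 100 um gap, width sweep
(3D), height sweep, crack-depth and crack-width sweeps, and both
small-groove readings, all with the same fluid. These are idealized
conditions:

* the inter-trabecular space is a box, not the real tortuous geometry;
* the gap connects directly to pressure boundaries, not to marrow
  reservoirs (hence the profile-end behavior discussed above);
* flow is steady; physiological loading is pulsatile;
* marrow is treated as a homogeneous Newtonian fluid, not a cell
  suspension; there is no fluid-structure interaction and no
  lacunar-canalicular poroelasticity;
* the crack is rectangular, sharp-cornered, and spans the full width.

Passing tests therefore demonstrate correctness of the *solver and the
analysis pipeline* under these idealized conditions, and reproduction of
the study's quantitative structure (linearity in $\Delta P$, width and
height effects, crack-size invariance of the gap peak, low in-crack
gradients away from the mouth) — not predictive accuracy for real bone.

## Degenerate inputs and edge cases

A crack with zero depth or width is dropped (the geometry equals the
no-crack case). Zero pressure difference returns a zero velocity field
with uniform pressure and is reported converged. Wall tags always carry
exactly zero mass flux by construction. Configuration files reject
unknown keys with a nearest-key suggestion and re-validate all
dimensional invariants on read.

## Known limitations

* First-order upwinding smears developing boundary layers; entrance-region
  quantities are resolution-sensitive (the gap peak, as defined, is not).
* The corner singularities make any "maximum over the crack wall"
  statistic mesh-dependent; prefer interior medians and quantiles.
* At $H \ge 500$ um the steady laminar assumption (Re of several
  hundred) is carried over from the study design rather than justified
  physically; Reynolds numbers are reported per case so users can audit
  it.
* Direct sparse LU solves limit practical 3D meshes to ~10^5 unknowns;
  the aspect-aware 3D defaults stay well inside that.
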