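---
title: "Models and methods behind depcyto"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind depcyto}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(depcyto)
```

depcyto simulates and analyses a dielectrophoresis (DEP) imaging flow
cytometer: a wide, shallow microfluidic channel with a coplanar
electrode pair on its floor, imaged from above at high frame rate.
Cells advected by the laminar flow are displaced vertically by the DEP
force as they cross the electrodes; because the flow profile is
parabolic, a change in height is observed as a change in downstream
velocity. The difference between a cell's incoming and outgoing
velocity (`vdiff = vi - vo`), together with its optically measured
size, is inverted to the real part of its Clausius-Mossotti factor
(Re{Kcm}), the quantity that discriminates viable (pDEP, Re{Kcm} > 0
at 6 MHz) from non-viable (nDEP) cells.

This vignette records the models, the tunable parameters, the design
choices made where the design was genuinely open, and the known
limitations.

## Dielectric model

A particle in a medium of complex permittivity
`em = eps0 * eps_rm - i * sigma_m / omega` experiences a DEP force
proportional to `Re{Kcm}`, with
`Kcm = (ep - em) / (ep + 2 em)`. For nucleated cells, `ep` comes from
the double-shell model: four concentric compartments (nucleoplasm,
nuclear envelope, cytoplasm, plasma membrane) collapsed pairwise by the
confocal shelled-sphere reduction

```
eps_eq = eps_shell * (g^3 + 2 K) / (g^3 - K),
g = r_outer / r_inner,  K = (eps_inner - eps_shell)/(eps_inner + 2 eps_shell)
```

applied three times from the inside out. The reduction is an exact
identity for a matched shell or a zero-thickness shell, which the test
suite asserts to machine precision. `r_n` is interpreted as the outer
nucleus radius including the envelope, so the nucleoplasm radius is
`r_n - d_n`; this keeps the separately listed envelope thickness
meaningful. Polystyrene microspheres are modelled as homogeneous
spheres with a surface conductance `Ksurf` contributing an effective
conductivity `2 Ksurf / r`.

Fixed constants and defaults:

* `eps0 = 8.854187817e-12` F/m.
* Frequency grids are logarithmic, 10 kHz to 1 GHz, 400 points —
  covering the beta-dispersion window where membrane polarisation
  dominates.
* DI water is taken as `eps_r = 78`, `sigma = 5.5e-6` S/m. The relative
  permittivity of the PSS suspension medium is not critical: at 1 MHz
  the medium's conductive loss is negligible against `omega * eps`, so
  Re{Kcm} of a microsphere changes only in the fourth decimal across
  any plausible DI-water permittivity. Both values are configurable.
* Crossover frequencies are located by sign change on the grid plus
  bisection to a relative tolerance of 1e-6.

Sensitivity bands vary one parameter at a time by a fraction (default
±20 %); for `r_cell` the nucleus radius is co-scaled as
`0.55 * r_cell` so the cell keeps its proportions. Whether published
±20 % response bands derive from size, cytoplasm conductivity or joint
variation is not documented anywhere we could rely on, so only
single-parameter bands are exposed.

## Electrostatic field

The paper-scale device drives two 35 µm electrodes separated by a
25 µm gap, spanning the full 8 mm channel width. Because the
electrodes run the entire width, the field is modelled in the 2-D
(x, h) cross-section. The potential solves the Laplace equation on a
uniform grid (five-point stencil) with a direct sparse factorisation;
Dirichlet values ±V0/2 (V0 = Vpp/2, symmetric anti-phase drive) are
imposed on the floor nodes under the electrodes and every other
boundary is a mirror (insulating) node. The drive convention —
whether the second electrode is grounded or driven anti-phase is not
observable from the force field, which depends only on the potential
difference; anti-phase is used and configurable through the layout.

Defaults: grid step 0.5 µm, x-extent ten electrode pitches (the test
suite checks the solution is insensitive to the boundary placement),
residual tolerance 1e-8·V0 (direct solves reach ~1e-12). E_rms is
|∇φ|/√2 for sinusoidal drive; ∇(E_rms²) is computed by central
differences and interpolated bilinearly. Validation: in the
semi-infinite-electrode limit the solver matches the conformal-map
solution for two coplanar half-planes,
`|E|(0, h) = V0 / (pi * sqrt(a^2 + h^2))` with `a` the gap half-width,
within 2 %, and refinement from 0.5 µm to 0.25 µm moves ∇E² probes by
less than 1 %.

## Particle transport

Micron-scale particles in creeping flow are overdamped: inertia is
neglected and the force balance gives instantaneous velocities
(particle Reynolds and Stokes numbers for the reference conditions are
~2e-2 and ~3e-4; `check_overdamped()` warns if either approaches 1).
The forces are:

* Stokes drag against the parabolic profile
  `v(h) = 6 vbar (h/H)(1 - h/H)`; the vertical drag carries the
  two-wall hindrance factor `lambda(h)`, the horizontal drag does not.
* Net gravity/buoyancy `-(4/3) pi g r^3 (rho_p - rho_m)`, downward for
  a dense particle regardless of sign conventions in intermediate
  algebra.
* DEP force `2 pi eps0 eps_rm r^3 Re{Kcm} grad(E_rms^2)`.
* A near-wall lift force, discussed below.

`lambda(h)` is the product of two single-wall perpendicular
corrections, each the truncated reciprocal series
`1 / (1 - (9/8) xi + xi^3 / 2)`, `xi = r/distance`. Exact two-wall
tabulations exist in the literature but are not reproduced; the
interface accepts a user-supplied `lambda` function for that purpose.

### The lift closure

The published description of this device class does not pin down the
functional form of the hydrodynamic lift, and the candidate readings
are not dimensionally equivalent. The package's default closure is

```
F_lift = 6 C eta vbar r^3 (r/H)^2 / gap^2,   C = 0.31,
```

signed away from the nearest wall (zero at mid-channel), with `gap`
the clearance between the particle surface and that wall. The
confinement factor `(r/H)^2` was chosen on physical grounds: with it,
the lift/weight equilibrium of 9-16 µm cells (density contrast
32.5 kg/m³, mean flow 1000 µm/s, H = 50 µm) sits at heights of
roughly 8-13 µm above the floor, where the advection velocity is
800-1200 µm/s — exactly the operating band in which this class of
device is run — and the vertical relaxation back to equilibrium is
slow compared with the electrode transit, so the DEP-induced height
change persists into the outgoing-velocity window. Without the
confinement factor the same coefficient produces a lift that exceeds
the cells' weight everywhere in the channel, drives every particle to
mid-channel within the field of view, and erases the differential
velocity signal that the instrument measures. The unscaled form
remains available (`lift_clearance_sq`) and the closure is pluggable
per `transport_params(lift_form = ...)`.

One consequence worth flagging: under this closure the pDEP response
|vdiff| *increases* with entry height (and hence with vi), because
near the floor the 1/gap² lift stiffens faster than the DEP force
grows. Published simulations of the reference device show the
opposite, residence-time-dominated trend. The suite therefore asserts
the model's own monotonicity (vdiff strictly monotone in entry
height), which is also what makes the velocity-to-height inversion
well posed.

Trajectories are integrated with x as the independent variable
(`dh/dx = vh/vx`, `dt/dx = 1/vx`) using an adaptive solver at relative
tolerance 1e-6. Wall contact terminates the trajectory and flags it
`captured`; the same flag is raised when the advection velocity of any
segment collapses below 2 % of the mean flow, which happens when a
strong-pDEP cell riding the lubrication floor meets the opposing
horizontal DEP slip at the downstream electrode edge — a pDEP trap.
A fixed-step RK4 oracle at 1/100 of the output step agrees with the
adaptive integration within 0.5 % in vdiff. Incoming and outgoing
velocities are least-squares slopes of x(t) outside a 50 µm exclusion
margin around the electrode pair, mirroring what the optical tracker
measures.

## Velocity-to-Kcm mapping

The forward map tabulates vdiff on a (r, Re{Kcm}, vi) grid. The entry
height for each (r, vi) node is found by a secant root-find on the
*fitted* incoming velocity (tolerance 1 % of vi), restricted to the
lower half-channel: cells settle below the centreline and the
height-velocity relation is two-valued over the full channel. Because
cells rise quickly when released close to the floor, the fitted vi has
a radius-dependent floor (roughly 80 % of the equilibrium-height
velocity); grid nodes below it are marked invalid, and a build with
more than 20 % invalid nodes errors out. The default axes
(r = 4.5-7.5 µm, Kcm = -0.3-0.5, vi = 780-1480 µm/s) keep the invalid
corner away from any observation produced by the population generator.

Inversion interpolates the vdiff(Kcm) profile bilinearly in (r, vi)
and inverts it by monotone 1-D interpolation; the reported interval
inverts vdiff ± one measurement-noise unit (default 56 µm/s, the
device class's no-DEP differential-velocity standard deviation, used
here as a default parameter). Observations outside the attainable
vdiff range are clamped to the nearest axis endpoint and flagged.

One structural limitation matters at the 8 Vpp drive: the vertical DEP
velocity of a strong-pDEP cell over the gap (hundreds of µm/s) far
exceeds the lift scale, so such cells are pressed onto the floor
during transit and vdiff saturates in Kcm — profiles at operating
incoming velocities are nearly flat beyond Kcm of roughly 0.1-0.3
(the knee position rises with vi). Inversion in that regime returns a
confident lower bound in the pDEP regime, not a quantitative value;
sign discrimination (the instrument's main job) is unaffected, and
nDEP inversion remains quantitative throughout. The round-trip tests
demonstrate both behaviours: quantitative recovery below the knee and
at nDEP, and sign-preserving clamps above it.

## Synthetic data generator

The generator defines the study conditions for every downstream test.

* **Population**: two CHO components, 45 % viable / 55 % non-viable.
  Diameters are truncated normals — viable 12.5 ± 1.25 µm on [10, 15],
  non-viable 11 ± 1.25 µm on [9, 14] — matching the 20 % size spreads
  and ranges quoted for this cell system; Re{Kcm} per component comes
  from the bundled double-shell presets evaluated at the drive
  frequency. Arrivals are Poisson (10 cells/s), lateral positions
  uniform.
* **Entry heights** default to the lift/weight equilibrium plus an
  upward half-normal jitter (sd 2 µm): cells that reach the imaging
  region before settling completely sit above, not below, their
  equilibrium. An alternative `vi_range` mode draws a target incoming
  velocity and inverts the parabolic profile on its lower branch.
  With equilibrium entry, the generated incoming velocities land in
  the 800-1200 µm/s operating band by construction of the transport
  model rather than by fiat.
* **Frames**: a static background (smooth illumination gradient, two
  darker electrode stripes at the true layout positions, fixed-pattern
  texture) plus each cell drawn as a radially symmetric bright-rimmed
  disk — the quasi-darkfield signature of an index-matched cell.
  The bright annulus has a 1-pixel Gaussian edge and is inset 2.8 px
  from the geometric radius so that the detectable footprint (the
  Gaussian skirt down to realistic thresholds) spans the cell's true
  diameter; this is the renderer's photometric calibration, made so
  that area-based sizing is unbiased. Signal-dependent shot noise,
  Gaussian read noise and 8-bit quantisation follow. Optics defaults:
  0.62 µm/pixel, 226 fps, 1080 × 1442 px.

What the generator does **not** emulate: physical optics (defocus with
height, diffraction rings), cell-to-cell photometric variability,
debris, and hydrodynamic interactions. Tests passing on these renders
demonstrate the pipeline's internal consistency, not robustness to
real microscope data.

## Tracking pipeline

Background is the pixelwise temporal median of up to 200 uniformly
subsampled frames — robust to cells that cover a pixel less than half
the time. Detection smooths |frame - background| with a 1 px Gaussian,
thresholds at `k = 4` times the MAD about zero (with a 2.5-grey-level
floor so noise-free stacks keep a finite threshold), labels
8-connected components, fills holes, and measures intensity-weighted
sub-pixel centroids, equivalent-circle diameters
(`2 sqrt(area/pi) * um_per_pixel`) and eccentricity from binary
central second moments (`sqrt(1 - lambda_minor/lambda_major)`).
Components outside 5-30 µm or with eccentricity above 0.9 (merged
cells, debris) are rejected, as are components whose footprint touches
the frame border (truncation biases both centroid and size). The size
and eccentricity cutoffs are this package's defaults; the reference
instrument's values are not published.

Linking is frame-to-frame minimum-cost assignment on squared
displacement between predicted positions (last position plus last
velocity) and detections, gated at `max_disp`. The gated bipartite
graph is decomposed into connected subnets which are solved exactly by
enumeration (subnets beyond 12 tracks fall back to greedy with a
warning); unmatched tracks survive up to `memory = 2` frames and
tracks shorter than 5 detections are dropped. The suite checks the
assignment against a brute-force enumeration oracle and an independent
implementation of the same linking model.

Velocities are OLS slopes of x(t) before/after the electrode window
with a 50 µm margin, exactly as in the transport module, so simulated
and tracked observations are directly comparable.

## Population analysis

The two-component Gaussian mixture is fit by full-covariance EM with
10 seeded random restarts (log-likelihood tolerance 1e-8, diagonal
regularisation on near-singular covariances); the component with the
larger mean vdiff is labelled pDEP, making labels deterministic on
separable data. The spread of recovered weights across restarts is
reported as a stability diagnostic — a single blob forced into two
components shows a large spread. The installed mclust package serves
as an independent cross-check in the tests, never as the
implementation. Probability ellipses are Mahalanobis contours at the
chi-squared(2) quantile of the requested level; the published figures
for this device used 71 % and 75 % levels, which are not hard-coded.
Viability is the pDEP fraction; per-cluster diameters get sample and
maximum-likelihood normal fits.

## Problem sizes used by the suite

The test and acceptance runs use: field grids at 0.5 µm (default
device) and 0.25 µm (refinement check); a 4 × 5 × 5 mapping grid;
100 round-trip inversion draws; 400-cell end-to-end mixtures; and
cropped 120 × 500 px frame stacks for the imaging closure. These sizes
were chosen so each stage's statistical checks are well resolved while
a full run stays desk-scale.

## Known limitations

* The lift closure is a modelling choice, not a measured law; all
  quantitative vdiff values inherit it. The mapping/inversion round
  trip is self-consistent by construction and says nothing about how
  well the closure matches a physical device.
* Electrode polarisation, double-layer screening, medium heating and
  AC electro-osmosis are outside the model.
* No Brownian motion or particle-particle interactions; arrival rates
  high enough for frequent co-occupancy only stress the linker, not
  the physics.
* Multi-frequency inversion to compartment dielectric parameters is
  out of scope; the package recovers a single Re{Kcm} at the drive
  frequency.
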