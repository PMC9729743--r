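---
title: "Virtual design of extracardiac Fontan conduits: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual design of extracardiac Fontan conduits: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fontanflow)
```

# Scope

`fontanflow` compares candidate extracardiac conduits for the total
cavopulmonary connection (TCPC) — a single T conduit against bifurcated
Y-grafts of increasing branch calibre — on four hemodynamic indicators:
caval-to-pulmonary pressure gradient, conduit section velocity, energy
efficiency, and the left/right split of inferior-vena-cava (IVC) flow.
Everything runs at desk scale on one CPU core. This vignette records the
models, the numerical choices, and what the synthetic test bed does and does
not establish.

# Flow model

Blood is treated as an incompressible Newtonian fluid (density
1060 kg/m^3, dynamic viscosity 0.0035 Pa s) in laminar flow with gravity
neglected and rigid, no-slip vessel walls. The momentum and continuity
equations are solved on the lumen of the junction. Respiratory modulation
drives the caval return: inlets carry a velocity waveform over a 2.54 s
cycle, and results are averaged over one converged cycle (2,540 steps at the
0.001 s reference time step).

These assumptions mirror standard practice for Fontan CFD at venous
Reynolds numbers (roughly 300–1,600 across rest to heavy exercise in these
geometries); no turbulence model is applied. Wall elasticity
(fluid–structure interaction), non-Newtonian rheology and wall shear-stress
metrics are out of scope.

# Discretization

**Grid.** The lumen is voxelized onto a uniform staggered Cartesian (MAC)
grid: pressures at cell centres, velocity components on faces. The wall is a
stair-step immersed boundary: a cell belongs to the lumen when its centre
lies inside the union of the vessel capsules. Port planes are snapped to the
lattice so every inlet/outlet lies exactly on a domain face. Voxelization
requires at least three cells per vessel radius and refuses coarser
spacings.

**Projection.** Each step is a Chorin projection: an explicit
advection–diffusion predictor, prescribed boundary faces, then a pressure
Poisson solve (matrix-free conjugate gradients with an incomplete-Cholesky
diagonal preconditioner, warm-started from a linear-in-time extrapolation
of the previous pressure)
whose gradient restores a divergence-free field on every lumen cell to the
configured relative tolerance (default 1e-6; 1e-5 in the demo settings).
Exact global mass closure is built into the outlet update, so the
compatibility condition of the Neumann Poisson problem holds to round-off.

**Advection.** The default scheme (`"quick"`) uses the third-order
upwind-biased QUICK derivative with Adams–Bashforth-2 time integration.
Where a wall cuts the four-point stencil the scheme falls back to an evenly
blended first-order-upwind/central difference: pure upwinding there acts
like a large artificial viscosity (of order `u h / 2`, many times the
physical one at 1.5 mm spacing) and visibly inflates pressure losses, while
pure central differencing rings at the stair corners. A fully first-order
scheme (`"upwind1"`, forward Euler) is kept as a maximally robust
alternative. Stability bounds enforced at run time: advective CFL
`max|u| dt/dx` ≤ 0.5 (exceeding it raises an error naming the offending
time step) and the AB2 explicit-diffusion limit `dt ≤ h²/(12 ν)`.

**No-slip.** Wall-normal face velocities are pinned to zero on the wall
face itself; wall-tangential stencils use the ghost value `-u`, placing the
zero-velocity plane halfway to the neighbouring face. On a straight tube at
20 cells per diameter this reproduces the Hagen–Poiseuille pressure drop
within 5% (using the voxelized cross-section radius `sqrt(A/π)`, which is
the radius the discrete domain actually has) and the parabolic profile
within 5% L2 — the package's standing validation test.

**Time stepping across exercise levels.** Local jet speeds reach about
twice the peak inlet speed, so the pipeline divides the reference 0.001 s
step by 2 (QUICK headroom), by the exercise flow multiplier, and by the
design's branch-contraction factor (2 for the diameter-preserving graft,
whose branches double the trunk velocity); a CFL violation additionally
restarts the run with the step halved. Runs start from rest (zero velocity
and gauge pressure); the first cycle(s) absorb the start-up transient, and
only the final cycle is averaged. This matters even for nominally steady
runs: averaging a window that includes spin-up adds the acceleration head
`ρ Δu/T` to every mean pressure gradient, a bias of several tens of Pa at
venous velocities.

# Boundary conditions

**Inlets.** Plug velocity profiles modulated by a truncated harmonic
waveform `v(t) = v̄ (1 + Σ a_m sin(2π h_m t/T + φ_m))`; the time mean is
exactly `v̄` and non-negativity is enforced by `Σ|a_m| ≤ 1`. Defaults: IVC
mean 0.30 m/s, SVC mean 0.25 m/s — inside the 0.24–0.41 m/s band of
measured anastomotic velocities in this setting — with one respiratory
harmonic of relative amplitude 0.3. The echo-derived patient waveform is not
available; a single-harmonic surrogate keeps the pulsatility realistic
without inventing detail.

**Outlets.** Each pulmonary artery is closed by a lumped linear resistance
`P = R Q` (reference pressure 0 gauge). The default per-outlet resistance,
1.888e7 Pa s/m^3, corresponds to a total pulmonary vascular resistance of
1.18 Wood units split over two parallel lungs — the catheterization value
measured in this patient group postoperatively. Outlet faces copy the
interior velocity profile rescaled to the target flux (convective outflow);
forcing a plug there measurably distorts the near-port pressure. The two
outlet flows satisfy the network relation `R_L Q_L − R_R Q_R = P_L − P_R`
with exact mass closure, via an under-relaxed per-step update. The
relaxation factor is set from the fluid column's inertance `ρL/(A dt)`,
which dominates the per-step pressure response and otherwise makes the
fixed-point iteration oscillate.

**Exercise.** Levels scale the rest set exactly: IVC flow ×1/2/3/4, SVC
×1 (×1.5 at heavy only), both outlet resistances ×1.00/0.95/0.90/0.85.
Whether the resistance reduction should apply per outlet or to the lumped
total is not specified anywhere authoritative; it is applied per outlet
uniformly, which for equal resistances is the same thing.

# Synthetic junction geometry

No patient CTA is available, so geometry is generated parametrically: the
pulmonary artery is a straight 16 mm tube along x (left hilum at negative
x), the caval axes are perpendicular to it, and conduits are unions of
straight circular segments (smooth capsule blends at anastomoses). The
hilum outlets sit 50 mm (or more) beyond the outermost anastomosis, which
stabilises the outlet flow before the measurement plane. Default
anastomosis offsets: ±15 mm for the T conduit/SVC pair and for the Y
branches, SVC at the midline between the Y branches. The four reference
designs share this layout: A = 20 mm T; B/C/D = Y-grafts with 10/12/14 mm
branches on a 20 mm trunk (B diameter-preserving, D area-preserving within
5% — 2·7²/10² = 0.98).

What this test bed emulates: the topology and calibre rules of the design
family, realistic venous flows and pressures, and the relative standing of
the designs. What it does not: patient-specific curvature, tapering, offset
asymmetries and smooth flared anastomoses. The idealized junctions meet at
comparatively blunt angles and therefore dissipate more than a surgical
anastomosis; passing tests show the solver and the comparison machinery are
sound on this family, not that any patient's absolute numbers are
reproduced. Concretely, the rest pressure gradients computed by
`scripts/acceptance.R` land near 1.5 mmHg for the T and area-preserving
designs and near 3.5 mmHg for the diameter-preserving 10 mm graft — above
the sub-1 mmHg expected of smooth patient-specific anatomy — and a grid
study (2.0 → 1.0 mm on a well-resolved junction) shows this is a property
of the geometry, not of under-resolution. The qualitative orderings
(efficiency D > C > B, pressure gradient D < C < B, branch velocity
B > C > D) are reproduced and tested.

# Indicators

* **Pressure gradient**: `[(P_SVC + P_IVC) − (P_LPA + P_RPA)] / 2`,
  cycle-averaged area-mean pressures at the port planes, converted at
  1 mmHg = 133.322 Pa. Cycle averages (not peaks) are used throughout.
* **Section velocity**: mean velocity magnitude over the lumen cells of an
  axis-aligned plane one trunk diameter downstream of the Y bifurcation
  (the same height for the T conduit), restricted to the conduit region.
  Horizontal cuts through slanted branches widen by `1/cos θ`; the
  mass-consistency test corrects for this known factor.
* **Energy flux and efficiency**: the discrete surface integral of
  `(p + ½ρ|u|²) u·n` over each port with outward normal, accumulated every
  step and cycle-averaged; efficiency is the outflux/influx magnitude ratio
  so that the inlet term is a positive influx. For dissipative flow it lies
  in (0, 1] and the complement times the influx is the dissipated power.
* **Flow split**: massless tracers seeded flux-weighted across the IVC
  inlet (a fixed RNG seed makes runs reproducible), advected by
  fourth-order Runge–Kutta through trilinearly interpolated snapshot fields
  (linear and cycle-periodic in time), captured at first crossing of an
  outlet plane. Tracers still in transit when the window closes (release
  over one cycle plus two drain cycles by default) count as escaped and are
  excluded from the percentages. Balance is summarised as the mean
  |LPA% − 45| across exercise levels (scored) and the LPA% range across
  levels (reported as stability, not scored).

# Scoring

Within each indicator the best design earns 4 points down to 1 (ties share
the mean of the tied scores); lower is better for pressure gradient,
section velocity and imbalance, higher for efficiency. Indicator values are
aggregated across exercise levels by their mean before ranking — the
aggregation is not dictated by anything stronger, so the mean is the
default and the table interface accepts any pre-aggregated values. With
four designs each indicator's scores sum to 10 and the totals to 40, which
the tests enforce for arbitrary inputs including ties. Total ties break
towards the lower pressure gradient. The velocity indicator is scored on
the measured section (trunk for T, branch for Y); the balance indicator is
scored by imbalance with stability reported alongside.

# Problem sizes and numerical settings used by the tests

The suite builds everything it needs in code at run time. The standing
configurations: Poiseuille validation on a 10 mm × 40 mm tube at 0.5 mm
spacing with viscosity raised to 0.04 Pa s so the parabola develops within
0.7 s (Re ≈ 13); a compact symmetric Y (20–14–14 mm, ±10 mm offsets) at
2 mm spacing for symmetry, efficiency-monotonicity and particle checks,
with ≥ 10^5 tracers for the 50/50 split; the four reference designs at
1.5 mm spacing, 2.54 s cycles — pulsatile two-cycle runs at rest, and
settled steady analogues at heavy exercise for the ordering checks; and a
four-design miniature pipeline (0.12 s period, 2 mm grid) for the
counting/determinism contracts. Steady runs always simulate two equal
windows and average only the second.

# Known limitations

* Stair-step walls overestimate junction losses at coarse spacing; the
  absolute pressure gradients carry a geometry- and resolution-dependent
  surcharge even though orderings are stable.
* The convective outflow assumes outward mean flow; strongly reversed
  outlet flow falls back to a plug profile for that step.
* The outlet model is a single linear resistance per lung — no compliance,
  no respiratory venous-return coupling.
* Particle capture tests plane crossing only; a tracer trapped in a
  recirculation simply times out and is reported as escaped.
* The synthetic layout is planar; real conduits leave the plane and the
  SVC rarely opposes the trunk exactly.
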