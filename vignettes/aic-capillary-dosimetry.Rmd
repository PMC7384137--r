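---
title: "Modelling AIC transport and microdosimetry in a capillary"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling AIC transport and microdosimetry in a capillary}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In targeted alpha therapy (TAT) an alpha-emitting radionuclide is coupled
to a targeting molecule (an alpha-immuno-conjugate, AIC). Once
administered, a fraction of the conjugate and of the recoiling decay
daughters is carried along the vasculature by blood flow, so the
irradiation sources seen by any given cell are neither homogeneous nor
stationary. Because alpha particles deposit their energy over tens of
micrometres, the dose to a cell nucleus near a capillary is extremely
sensitive to the micro-scale source distribution, and the conventional
assumption of motionless, uniformly distributed activity can badly
misestimate it.

`aicdosim` couples four components to quantify this effect in a single
capillary segment:

1. **Capillary flow** — 2D incompressible Newtonian flow in a rectangular
   lumen (reference 30 x 8 um, 750 x 200 cells), solved by an
   Euler-implicit finite-volume method with a SIMPLE-style
   pressure-correction iteration on a staggered grid.
2. **Immersed particles** — AIC aggregates represented as circular
   immersed boundaries via a ghost-cell method, advected by the flow with
   Stokes-drag relaxation, interacting through a hard-sphere collision
   model.
3. **Decay kinetics** — analytic (Bateman) evolution of the radionuclide
   populations, activities and cumulated activities.
4. **Microdosimetry** — Monte Carlo single-hit specific-energy spectra
   for each source-target pair, accumulated over time and sources into
   the cumulated specific energy $z(t)$ and its variance $\sigma_t^2$.

## Flow model and numerics

The flow obeys conservation of mass and momentum for an incompressible
Newtonian fluid (density 1.025 g/cm^3, viscosity 4e-3 Pa s). At capillary
scale the Reynolds number is ~6e-4, so the equations are strongly
diffusion dominated and each implicit time step is close to a steady
Stokes solve.

Numerical choices, made where the physical description leaves the scheme
open:

* **Staggered (MAC) arrangement** with `u` on vertical faces, `v` on
  horizontal faces and pressure at cell centres — avoids checkerboard
  pressure modes without momentum-interpolation machinery.
* **First-order upwind convection, central diffusion.** At a cell Peclet
  number of ~1e-8 the upwinding error is immaterial; convective mass
  fluxes are lagged from the step-start fields so each step's matrices
  are assembled and factorised once (sparse LU) and reused across the
  pressure-correction loop.
* **SIMPLE iteration** with under-relaxation 0.7 (velocity) and 0.3
  (pressure); the loop stops when the max-norm change between iterates,
  normalised by the inlet velocity, falls below 0.5e-6. An iteration cap
  (default 5000) is an error, not a silent pass, and a monotonically
  growing residual raises a solver error with its history.
* **Boundaries**: Dirichlet plug inlet (0.03 cm/s), no-slip walls,
  zero-gradient outlet with a global mass-flux correction; the pressure
  correction treats the outlet as its zero datum, which also pins the
  otherwise-singular Poisson system.
* **Units**: all fields are SI internally; configuration files accept
  um, cm/s, g/cm^3 and Bq/mg and are converted on load.

The solver is validated against plane Poiseuille flow: on a 150 x 40
grid the mid-domain profile matches `6 u_mean (y/H)(1 - y/H)` to an L2
error of ~0.06%, the centreline-to-mean ratio is 1.498, and the
post-correction divergence of every fluid cell is at solver precision
(~1e-13 1/s).

## Immersed particles

AIC aggregates (radius 0.2 um; physically nanometre-scale conjugates are
assumed aggregated at this size, e.g. in polymersome carriers) are
circular immersed boundaries. Grid points inside a particle are solid;
solid points adjacent to fluid are ghosts whose values are mirrored from
fluid-side image points so that, in the frame moving with the particle,
the tangential velocity gradient and the normal velocity vanish at the
surface (slip + impermeability). Three stabilising choices matter for
the interleaved pressure-correction loop, and all keep the scheme's
fixed point intact:

* image-point values are interpolated from open (non-solid) faces only,
  with renormalised weights, so a ghost never feeds back on itself (the
  unmasked form has a near-unit negative gain for marginally resolved
  particles and makes the loop diverge);
* particles whose radius falls below two grid cells — where the mirror
  geometry cannot be represented at all — revert to direct forcing: all
  their solid faces carry the particle velocity (the code warns about
  this regime);
* particles within one cell of the inlet or outlet are released from the
  mask entirely, since an immersed boundary straddling the zero-gradient
  outlet conflicts with the outflow condition (it produced a residual
  limit cycle, not an error, which is why it is excluded rather than
  just capped).

The particle equation of motion is not prescribed by the physical
description beyond "accelerated up to the velocity of the surrounding
fluid"; we adopt Stokes-drag relaxation towards the locally interpolated
fluid velocity with
$\tau = m_p / (6 \pi \mu a) \approx 2.3\,\mathrm{ns}$ for the reference
aggregate. Because $\tau \ll \Delta t$, the update uses the exact
exponential solution
$u_p \leftarrow u_f + (u_p - u_f) e^{-\Delta t/\tau}$, which is stable
for any step and reduces to a perfect tracer as $\tau \to 0$ (also
available as `drag: tracer`). When the particle's own immersed boundary
occupies the interpolation stencil, the fluid velocity is sampled as the
mean over non-solid faces in a thin shell just outside the particle
surface instead.

Collisions apply the restitution-based normal impulse with
equal-and-opposite signs so momentum is conserved exactly (the
as-printed same-sign form would not conserve it); kinetic energy is
conserved at restitution 1, and the loss equals
$\tfrac12 m_\mathrm{eff}(1-\varepsilon^2)(u_{12}\cdot e)^2$ in general.
Simultaneous contacts are resolved sequentially in sorted pair order with
the approach condition re-checked, followed by a symmetric positional
de-overlap projection; wall contacts reflect the normal velocity with the
same restitution. The default restitution is 1 (elastic), the
energy-conserving choice where no value is prescribed. Particle mass uses
the 3D sphere at fluid density (the aggregates are physical spheres; only
the flow is 2D). Exited particles keep their exit velocity and continue
ballistically — they still irradiate the targets from outside the domain.

## Decay kinetics

The payload model is Bi-213 with half-life 45.6 min (2736 s) — the value
consistent with the administered-activity arithmetic
(1.184e8 Bq -> 4.67e11 atoms); the rounded "46 min" figure would give
4.72e11. Two built-in chains are provided: the single-line
simplification used in the coupled scenario (every Bi-213 decay counted
as one 8.3 MeV alpha, yield 1), and an approximate branched chain
(97.9% beta to Po-213 followed by an 8.375 MeV alpha; 2.1% direct
5.87 MeV alpha to Tl-209; Pb-209 terminal at this time scale, with
Po-213 at 3.72 us and Tl-209 at 2.16 min). Populations evolve by the
closed-form exponential-sum (Bateman) solution with branching; a
fine-tolerance ODE integration serves as the oracle in the test suite.
Cumulated activity uses the exact exponential integral
$(A_0/\lambda)(e^{-\lambda t_0} - e^{-\lambda t_1})$ everywhere, even
though $\lambda\,\Delta t \approx 2.5\times10^{-9}$ makes the per-step
activity effectively constant.

## Microdosimetry

Each source is an isotropic point emitter in the plane of the flow
domain; the target nucleus is a sphere (radius 4 um inside a 5 um cell,
reference perivascular positions (-75, 22) and (105, 22) um in the
domain frame — deliberately outside the 8 um lumen). All intervening
material is water.

For a source at distance $d$ from the nucleus centre the geometric hit
probability is the subtended cone fraction
$p = (1 - \sqrt{1 - (r_n/d)^2})/2$ (1 inside the nucleus). The Monte
Carlo spectrum samples the polar cosine uniformly within that cone,
computes chord entry and exit by ray-sphere intersection, and deposits
$\Delta E = E(R(E_0) - L_{in}) - E(R(E_0) - L_{out})$ by the
continuous-slowing-down residual-range method (no straggling or
delta-ray escape). The specific energy per hit is
$z = \Delta E \times 1.602\times10^{-13} / m_n$ with
$m_n = 2.68\times10^{-13}$ kg for the 4 um water nucleus. In-cone
emissions that stop before reaching the nucleus are retained as
zero-deposit samples, so $p$ stays purely geometric and the moments are
unbiased per in-cone emission — the package's recorded convention where
the original methodology leaves it open.

The range-energy relation ships as a small table generated from a
Bragg-Kleeman-style parameterisation
$R(E) = 2.263\,E^{1.706} + 1.2\,E^{0.75}$ um, calibrated to widely
published alpha ranges in liquid water (~50 um at 5.8 MeV, ~85-90 um at
8.3-8.4 MeV); interpolation is log-log linear, making the forward and
inverse lookups exact mutual inverses. This stands in for the original
fitted polynomial, which is not published.

An independent deterministic reference, `single_hit_moments_oracle()`,
evaluates the same moments by a midpoint rule over the polar cosine
(4096 nodes by default; self-converges to <1e-4). For the verification
path of a 5.8 MeV source moving from (-15, 0) to (15, 0) um past a 5 um
nucleus, the 50000-sample Monte Carlo means agree with the quadrature to
within ~0.5% at every position, mirroring the sub-1% agreement reported
for the original code against a full transport calculation. The
quadrature, not a transport code, is the reference here: it shares the
residual-range physics, so this checks sampling correctness, not the
stopping-power data themselves.

Expected hits per window are $n_i = A_i \Delta t\, Y_\alpha\, p_i$
(deterministic expectation by default; a seeded Poisson mode is
available — the expectation removes Monte Carlo noise from the headline
curves). Dose accumulates as
$z(t) = \sum_k \sum_i n_i \langle z_{1i} \rangle$ and
$\sigma_t^2 = \sum_k \sum_i n_i \langle z_{1i}^2 \rangle$. Spectra are
cached per source-target pair and recomputed once a source has moved
more than 0.5 um (a pure performance device, switchable via
`mc.recompute_distance_um`; $\langle z_1 \rangle$ varies smoothly with
distance).

## The coupled scenario and its derived quantities

The reference scenario mirrors a melanoma clinical trial: specific
activity 1.184e8 Bq/mg (3.2 mCi/mg). The lumen cylinder (radius 4 um,
length 30 um) contains a water-equivalent conjugate mass of 1.508e-6 mg,
hence a total activity of 178.5 Bq, 1.13 Bq for each of the 158 sources,
7.05e5 Bi-213 atoms, and a motionless cumulated activity of 17.85 Bq s
over the 0.1 s window. The mass conversion deliberately uses water
density (1000 kg/m^3), the choice consistent with this whole chain of
published values and with the water-equivalence of all tissue in the
model; using the blood density (1025) would shift every number by 2.5%.

Sources are released at rest: the first at (7.25, 4.0) um, the rest
placed by a seeded uniform rejection sampler in [3, 25] x [1, 7] um with
a minimal surface gap of 0.1 um. The placement seed is part of the
configuration; the exact positions of the original 158-source experiment
are not published, so the seeded generator defines this package's
canonical scenario and exact dose values of the original run are not
reproduction targets — the moving-versus-stationary ordering and the
closed-form stationary slope are.

The stationary reference freezes positions at release and holds the
activity at its initial value, making $z(t)$ exactly linear
($z(T) = T\sum_i A_i Y p_i \langle z_{1i}\rangle$); over 0.1 s the decay
correction would be below 3e-5 relative, far smaller than any quantity
of interest, and the exact linearity gives the test suite a sharp
closed-form anchor. The moving run evolves populations exactly.

## Problem sizes used by the tests

The full 750 x 200 configuration is available but expensive in pure R;
the package's own working scale, used throughout the tests and chosen to
preserve every physics regime (diffusion-dominated flow, under-relaxed
pressure correction, in/out-of-range source kinematics), is:

* flow benchmark and coupled runs: 150 x 40 cells, dt 1e-4 s, 0.01 s
  window, 20 sources;
* the plateau property (sources leaving alpha range) needs the sources
  to travel ~20 um, i.e. the full 0.1 s window; it is checked on a
  60 x 16 grid with dt 5e-4 s, where the kinematics are identical and
  the immersed boundaries are sub-cell (the flow then simply advects the
  sources, which is the regime that matters for this property);
* spectra: 50000 samples as in the reference methodology.

At the desk scale the 0.2 um aggregates span about one grid cell, below
the ~2-cell resolution the ghost-cell method needs for faithful local
boundary layers; the code warns about this. The dose-side conclusions
are insensitive to it (they depend on source kinematics, not on the
sub-cell flow detail), which is why the desk scale is acceptable for
testing; full-fidelity immersed boundaries require the reference grid.

## What the synthetic scenario does and does not show

The generator emulates the administered activity, aggregate size, source
count and placement statistics of the reference experiment. It does not
emulate red-blood-cell interactions (excluded by assumption), binding or
adhesion kinetics, aggregate breakup, daughter recoil transport, 3D
lumen geometry, or any biological response — passing tests say nothing
about those. Quantities tied to the unpublished random source layout
(exact final doses and variances) are scenario-specific by construction.

## Known limitations

* 2D flow; the dosimetry treats sources and target as 3D points in the
  z = 0 plane (distances are planar Euclidean).
* Energy deposition is continuous-slowing-down along straight chords: no
  straggling, no delta rays, no scattering.
* The stationary mode's constant-activity idealisation (above).
* Pure-R flow solver: the reference 750 x 200 grid at dt 1e-5 s is
  feasible but slow (hours); the desk scale exists for routine use.
* The embedded range-energy parameterisation is accurate to a few
  percent against published ranges, which matches the fidelity of the
  single-hit methodology, but it is not a measured stopping-power
  table.

## Reproducing the headline numbers

```{r}
library(aicdosim)

# administered-activity bookkeeping
derive_scenario_quantities(load_config())

# channel-flow benchmark
solve_channel_flow(nx = 150, ny = 40)$l2_error

# moving vs stationary doses at desk scale
cfg <- load_config(desk = TRUE)
mov <- run_simulation(cfg)
sta <- run_stationary_reference(cfg)
compare_moving_stationary(mov, sta)
plot(mov, reference = sta)
```
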