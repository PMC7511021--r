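---
title: "The 3D brain unit: model, discretization and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The 3D brain unit: model, discretization and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainunit3d)
```

## The model

The brain capillary bed is the main site of drug exchange between blood and
brain. `brainunit3d` simulates the smallest repeating unit of that bed: a
cube of brain tissue of edge $x_r = d_{cap} + 2r$ (55 µm for rat parameters)
whose twelve ribs carry blood capillaries of square cross-section $r \times
r$. Blood enters the capillary network at one corner box ($U_{in}$, fed by an
arteriole), flows away from it along every rib at a common velocity
$v_{blood}$, and drains at the opposite corner ($U_{out}$, a venule). The
space between the capillaries is brain extracellular fluid (ECF); the
blood–brain barrier (BBB) is the interface between the two.

Four fields are tracked, all in µmol/L:

* $C_{pl}(x,t)$ — unbound drug in capillary plasma,
* $C_{ECF}(x,t)$ — unbound drug in the brain ECF,
* $B_1(x,t)$ — drug bound to specific (target) sites,
* $B_2(x,t)$ — drug bound to non-specific tissue sites.

**Plasma.** After a single oral dose, the inlet box follows the Bateman
function
$$C_{in}(t) = \frac{F\,k_a\,\mathrm{Dose}}{V_d\,(k_a-k_e)}
  \left(e^{-k_e t}-e^{-k_a t}\right),$$
(the degenerate case $k_a = k_e$ uses its analytic limit), and inside the
capillaries the drug is advected, $\partial_t C_{pl} = -v_{blood}\,
\partial_s C_{pl}$, along each rib's flow axis. Plasma diffusion is
neglected, plasma protein binding is not modelled (all plasma drug is
unbound), and the velocity is the same in every capillary.

**ECF.** Free drug diffuses with the tortuosity-corrected coefficient
$D^* = D/\lambda^2$, is carried by the unidirectional ECF bulk flow
$v_{ECF}$ (x-directed), and binds reversibly:
$$\partial_t C_{ECF} = D^*\nabla^2 C_{ECF} - v_{ECF}\,\partial_x C_{ECF}
 - \sum_{i=1,2}\left[k_{i,on} C_{ECF}(B_i^{max}-B_i) - k_{i,off}B_i\right],$$
$$\partial_t B_i = k_{i,on} C_{ECF}(B_i^{max}-B_i) - k_{i,off}B_i .$$
Binding sites are extracellular, immobile, evenly distributed and of
constant capacity; cells appear only through the tortuosity.

**BBB exchange.** On every interface face the area flux density (positive
into the ECF) is
$$f(u,v) = 10^3\,P\,(u-v)
 + \frac{T_{m\text{-}in}\,u}{SA_{BBB}(K_{m\text{-}in}+u)}
 - \frac{T_{m\text{-}out}\,v}{SA_{BBB}(K_{m\text{-}out}+v)},$$
with $u = C_{pl}$, $v = C_{ECF}$. The passive permeability can be composed
from its transcellular and paracellular routes,
$P = P_{trans}f_{trans} + (D_{para}/W_{PCS})\,f_{para}$. The factor $10^3$
is the single litre-to-cubic-metre conversion point of the code base: $P(u-v)$
(m/s × µmol/L) and the saturable terms (µmol s⁻¹ m⁻²) can only be summed in
µmol m⁻² s⁻¹. Everything is stored as concentrations in µmol/L and geometry
in metres, and the conversion appears exactly once, in the flux assembly.

**Boundary conditions.** The inlet box is clamped to $C_{in}(t)$
(an algebraic constraint: its cell is removed from the ODE state), the
outlet box on the cube surface is clamped to zero, the remaining outer
plasma faces carry zero axial gradient, and the outer ECF faces carry zero
normal gradient.

## Parameters

Defaults are the published rat-brain reference set for a hypothetical drug
(`fixture("table2_default")`):

| parameter | unit | default | meaning |
|---|---|---|---|
| `d_cap`, `r` | m | 5e-5, 2.5e-6 | intercapillary distance, capillary radius |
| `F`, `Dose`, `Vd` | –, µmol, L | 1, 0.5, 0.2 | bioavailability, oral dose, distribution volume |
| `ka`, `ke` | s⁻¹ | 2e-4, 5e-5 | absorption, elimination rate constants |
| `v_blood` | m s⁻¹ | 5e-4 | capillary blood flow velocity |
| `D_star` | m² s⁻¹ | 0.5e-10 | effective (tortuosity-corrected) diffusion |
| `v_ecf` | m s⁻¹ | 0.5e-6 | ECF bulk flow velocity |
| `P` | m s⁻¹ | 1e-9 | total passive BBB permeability |
| `Tm_in/out`, `Km_in/out` | µmol s⁻¹, µmol L⁻¹ | 0, 100 | Michaelis–Menten active transport |
| `SA_BBB` | m² | 1e-10 (fixture) | BBB area of one capillary side |
| `B1max`, `k1on`, `k1off` | µmol L⁻¹, (µmol L⁻¹ s)⁻¹, s⁻¹ | 0.05, 1, 0.01 | specific (target) binding |
| `B2max`, `k2on`, `k2off` | 〃 | 50, 0.01, 1 | non-specific binding |

Two tabulated values conflict in the source material: the BBB side area is
printed both as 1.25e-10 m² (with its defining footnote; equal to
$d_{cap}\,r$) and as 1e-10 m². `bbb_params()` defaults to 1.25e-10; the
`table2_default` fixture reproduces 1e-10 as printed. The specific
dissociation constant is printed with a corrupted exponent ("1·1^-2"); we
use 1e-2 s⁻¹, the only reading inside its own tabulated range. Parameters
outside the physiological ranges are accepted with a flag — the published
flow-velocity sweep itself goes below range — while negative values are hard
errors.

## Discretization

The mesh is a geometry-aligned, cell-centred tensor-product grid: along each
axis the cell edges are $\{0, r, \text{uniform interior}, x_r - r, x_r\}$,
with `n` grid lines in total (default 18, the published reference
resolution). This alignment has three consequences worth stating:

* plasma cells carry the exact physical capillary cross-section $r^2$ at
  *every* resolution (the near-rib band is always one cell wide);
* BBB faces have exact areas — one rib side sums to $d_{cap}\,r =$
  1.25e-10 m², the tabulated `SA_BBB`;
* plasma/ECF volumes are exact, so no geometric error converges away.

A uniform grid could not do this: at 18 lines per dimension the spacing
(3.2 µm) exceeds the capillary radius (2.5 µm).

Diffusion uses the standard 7-point second-order flux stencil on the
non-uniform grid; ECF and plasma advection are first-order upwind (an
oscillation-free scheme is required because plasma has no diffusion to damp
wiggles). Where a capillary begins at a junction corner box, the upwind
value is the unweighted mean of the adjacent capillary cells whose flow
points into the box — the symmetric choice, since the model prescribes equal
velocities everywhere and says nothing about merging. Two modelling
consequences are deliberate and *reported rather than suppressed*:

* with equal velocities, volumetric flow is not conserved at branch/merge
  vertices; the audit integrates this junction imbalance term exactly;
* the zero-normal-gradient ECF boundary makes the bulk-flow inflow face
  advect drug in at the local concentration; the audit's boundary terms
  expose the effect. No fluid crosses the BBB (blocked advective faces).

The interface condition is applied as a conservative source/sink
($\pm f\cdot A/V$) on both sides of each face, which keeps drug mass exactly
conserved across the BBB. The plasma-side form printed as a diffusive
condition would contradict the no-plasma-diffusion assumption, so the
conservative reading is used.

**Probes** are snapped to the nearest cell centre of the matching domain
(plasma or ECF) and the snap distance is logged in `probe_info`. At the
default resolution the ECF middle probe and the mid-capillary plasma probe
land exactly on cell centres; the corner probes sit within one cell
diagonal.

## Time integration and numerical choices

The binding kinetics ($k_{1,on}B_1^{max}$, $k_{2,off}$ ~ 1 s⁻¹) against the
10⁵ s horizon make the system stiff, so the default integrator is `lsodes`
with an analytically assembled Jacobian sparsity pattern (the coupled
stencil, face and kinetic structure is known exactly, which avoids the
solver's structure-probing calls and its work-array guesswork; the LU
work array is sized empirically with retry). Default tolerances are
`rtol = 1e-6`, `atol = 1e-10`; integration always starts from the all-zero
state at $t = 0$ and the output grid defaults to 51 log-spaced points over
1–10⁵ s.

Sparse LU factorization is the cost driver and grows steeply with mesh
size: on a single CPU it is impractical beyond roughly 30 grid lines per
dimension. For short horizons and fine meshes the package therefore offers
a fixed-step classical RK4 (`method = "rk4"`) whose step obeys the
advective/diffusive stability bound; it agrees with `lsodes` to ~1e-5
relative where both run. The mesh-convergence study in the test suite uses
RK4 on `n = 12, 18, 36` to $t = 5$ s for exactly this reason — one scheme on
all three meshes, temporal error $O(\Delta t^4)$ far below the spatial
differences being measured — and estimates the spatial order from the two
successive probe differences (the aligned grids have non-dyadic interior
ratios, so the order is solved numerically rather than read off a log2).

The saturable transport terms are evaluated at `pmax(c, 0)` because a stiff
integrator may undershoot zero by ~`atol`; the passive (linear) term is left
untouched. With the BBB switched off, zero fields have exactly zero
derivatives and remain exactly zero.

**Nondimensionalization.** `nondimensionalize()` rescales length by $x_r$,
time by the diffusion time $x_r^2/D^*$ (60.5 s for the defaults) and
concentration by the plasma scale $F\,\mathrm{Dose}/V_d$, producing a
configuration whose cube edge and effective diffusivity are 1. The exact
scalings of the original supplementary derivation are not reproduced here;
the internal scaling is validated instead by the property that matters: the
dimensional and nondimensional integration paths agree to integration
accuracy (they cannot agree to machine precision, because an adaptive
integrator's step selection is path-dependent).

**Mass audit.** Alongside the state, the solver integrates the cumulative
BBB exchange, inlet inflow, outlet outflow, junction imbalance and ECF
boundary-advection terms as extra ODEs, so the ledger closes to integrator
accuracy. In a closed-ECF configuration the relative residual is at the
1e-12 level; in the default run the residual is orders of magnitude below
1% of the cumulative BBB influx.

## Experiments and the extraction validation

`run_sweep()` drives the published sensitivity designs, shipped as fixtures
(`fig3_vblood_sweep`, `fig5_influx_sweep`, `fig6_efflux_sweep`,
`fig7_interplay`, `fig8_interplay`, `fig10_grid`); member values outside the
physiological ranges are flagged per run, not rejected. Derived quantities
include the peak midpoint exposure and the time the target pool spends at
≥90% of its maximum (computed with linear interpolation at threshold
crossings).

`renkin_crone_check()` validates the capillary description against the
Renkin–Crone law $E = 1-\exp(-PS/Q)$. The published comparison does not
print its exact extraction definition, so ours is stated explicitly: the
unidirectional-influx configuration (ECF clamped to zero, no active
transport, constant inlet concentration $C_0$) is run to steady state and
$E_{sim} = 1 - C_{out}/C_0$, the extraction along one flow path. The
dimensionless group uses the per-path surface $S = 6\,d_{cap}\,r$ (three rib
segments, two exposed faces each) and the single-capillary flow
$Q = v_{blood}\,r^2$; both are reported in the output so the group can be
audited. With equal velocities everywhere, concentration-based extraction is
the quantity the law describes; a whole-unit flux ratio would double-count
the flow created at branch points. A run whose extraction still drifts more
than 0.1% over the final decade of integration time is rejected as
non-steady. The inlet-to-outlet reference pathway used for spatial profiles
runs along three rib segments and measures $3\,d_{cap}$ = 150 µm for the
default geometry.

## Two model properties worth knowing before comparing to figures

Two behaviours of the model surface in quantitative checks but are invisible
at log-scale figure precision:

* **Delivery delay.** Drug reaches the BBB only after advection from the
  inlet. The BBB area is distributed 6/12/6 over the three `d_cap`-long
  spans of the inlet-to-outlet paths, so the area-weighted mean delivery
  delay has the closed form $\bar\tau = 1.5\,d_{cap}/v_{blood}$ (0.15 s for
  the defaults). Any well-mixed compartment reduction of this unit must
  delay its plasma input by $\bar\tau$; the undelayed reduction
  over-predicts the early ECF build-up by $2\bar\tau/t$ (free drug) and
  $3\bar\tau/t$ (bound drug), which the test suite verifies.
* **Flow-limited influx plateau.** For maximal influx rates
  $T_{m\text{-}in} \gtrsim 10^{-6}$ µmol/s the equivalent active
  permeability makes every capillary fully flow-limited: total uptake is
  capped by delivery, the exposure curves for different $T_{m\text{-}in}$
  coincide to ~0.1%, and a *stronger* pump shifts uptake toward the inlet
  corner, so the midpoint exposure can sit ~0.15% *below* that of a weaker
  pump (tolerance-independent). "More influx, more exposure" therefore holds
  at figure precision but not as a strict pointwise ordering; the
  corresponding strict assertion in the acceptance tests fails by exactly
  this margin and documents it in place.

Relatedly, concentration values below ~10³ times the solver's absolute
tolerance (the first seconds of a run, six orders of magnitude below peak)
are not controlled to relative accuracy by any tolerance-based integrator;
comparisons between runs are only made where the curves are numerically
resolved.

## What the fixtures do and do not establish

All inputs are scalar parameter sets; the "synthetic data" of this package
are the named fixtures reproducing the published parameter tables and sweep
designs, plus closed-form forcing. Passing tests therefore establishes that
the implementation solves *this* model correctly (analytic oracles,
conservation, convergence, the qualitative sensitivity findings) — not that
the model describes any particular real brain or compound. Real tissue has
non-cubic vascular topology, heterogeneous binding-site densities,
intracellular uptake, plasma protein binding and transmural fluid flow, all
of which are outside this model by construction.

## Problem sizes used in the shipped tests

The test suite runs the full model at the reference resolution (n = 18,
4 913 cells, ~14 000 ODEs, ~30 s per 10⁵-s run) for the acceptance
properties, smaller meshes (n = 8–12) for unit-level properties, and the
n = 12/18/36 RK4 trio for the convergence study. These sizes are the
package's choice of desk-scale verification; the solver accepts finer
meshes and longer horizons at the cost documented above.

## Known limitations

* Single unit only; no multi-unit networks, arteriole/venule interiors, or
  curved capillary geometry.
* No intracellular exchange or intracellular binding; no plasma protein
  binding; no transporter inhibition or asymmetric transporter placement.
* First-order upwind advection is diffusive; sharp plasma fronts at very
  low `v_blood` are smeared at coarse resolution (the convergence study
  quantifies the rate at which this vanishes).
* The equal-velocity junction rule creates/destroys volumetric flow at
  vertices by construction; use the audit's junction term to bound its
  effect for any given configuration.
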