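---
title: "Model and numerical methods behind scarsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and numerical methods behind scarsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scarsim)
```

## The biological problem and the model

After a deep dermal wound, fibroblasts repopulate the injured area, some
differentiate into contractile myofibroblasts under growth-factor
signaling, and the cell population rebuilds a collagen-rich matrix. When
myofibroblast apoptosis is disrupted, the population persists, keeps
pulling on the matrix, and the healing tissue grows markedly thicker than
the surrounding dermis — a hypertrophic scar — before regressing slowly as
the myofibroblasts finally disappear.

`scarsim` simulates this process on a two-dimensional plane-strain slice
through the symmetry plane of a long rectangular wound: the slice spans
$-15.96 \le Y \le 15.96$ cm laterally and the dermal thickness
$-0.15 \le Z \le 0$ cm. Four constituents are modeled: the fibroblast
density $N$, the myofibroblast density $M$, a generic signaling molecule
$c$ (a stand-in for growth factors such as TGF-$\beta$ and PDGF) and the
collagen concentration $\rho$. Each obeys a conservation law on the
deforming tissue,

$$\frac{\partial z_i}{\partial t} + \nabla\cdot(z_i\,\mathbf v)
  = -\nabla\cdot\mathbf J_i + R_i,$$

with fluxes (cell-density-dependent random motility plus chemotaxis for
the cells, Fickian diffusion for the signal, no transport for collagen)
and reaction kinetics implemented in `reaction_fibroblast()`,
`reaction_myofibroblast()`, `reaction_signal()`, `reaction_collagen()`
and `mmp_level()`. Proteolysis of both the signal and the collagen is
mediated by a generic matrix metalloproteinase whose level is the
algebraic function $g = F\rho/(1 + a_c^{III} c)$, $F = N + M$.

The mechanical state is quasi-static: inertial forces are negligible on
wound-healing time scales, so the displacement $\mathbf u$ solves
$-\nabla\cdot\boldsymbol\sigma = \mathbf f$ at every instant. The dermis
is a heterogeneous, isotropic, *compressible neo-Hookean* solid whose
Young modulus stiffens with collagen as $E(\rho) = E^I\sqrt{\rho}$;
myofibroblast pulling enters as an isotropic traction stress
$\boldsymbol\psi = \xi M \rho/(R^2+\rho^2)\,\mathbf I$ whose divergence is
the body force. Two non-trivial equilibrium facts anchor the model:

* the growth-law exponent $p$ is not free — it is fixed by requiring that
  fibroblast division balances apoptosis at the unwounded density
  (`derive_p()`, about $-0.42$ at the defaults); and
* the collagen secretion rate $k_\rho$ is fixed by collagen equilibrium,
  $k_\rho = \delta_\rho\bar\rho^2$ (`derive_k_rho()`, $6\times10^{-8}$
  g/(cells day)).

Both are recomputed from the free parameters at construction time, with a
consistency warning if they drift more than 2% from their published
two-digit values.

## Parameters that matter

All constants live in `scar_params()` (units in its help page). The two
quantities varied across study scenarios are:

* `delta_M`, the myofibroblast apoptosis rate (per day). The interesting
  range is $(2\text{–}60)\times10^{-3}$/day: the `high_apoptosis` preset
  ($6\times10^{-2}$) produces a normal-scar-like response, the
  `low_apoptosis` preset ($2\times10^{-3}$) a hypertrophic-like one with
  a much larger myofibroblast peak and a thicker dermis.
* `c_II_shape`, the wound half-width (3–5 cm), with `c_I_shape = 2` cm
  controlling the steepness of the smoothed wound edge.

The initial conditions paint the wound with the profile
`wound_profile()` built from a piecewise-sine smoothed Heaviside: inside
the wound the fibroblast and collagen levels start at the fractions
`N_w = rho_w = 0.2` of their equilibria and the signal at
`c_w = 1e-8` g/cm³; myofibroblasts start at zero everywhere, which makes
the initial displacement exactly zero.

Boundary conditions: the lateral boundaries hold Dirichlet equilibrium
values for $N$, $M$, $c$; the top (epidermal) and bottom (subcutaneous)
boundaries are zero-flux. Collagen needs no boundary condition at all —
it has no spatial operator — and none is imposed. Mechanically the
bottom and lateral boundaries carry spring-like Robin tractions
proportional to the local collagen concentration and displacement
($s_1\rho u_z$ and $s_2\rho u_y$ respectively), evaluated on the
*deformed* boundary; the epidermal boundary is traction-free. Evaluating
the springs in the deformed configuration is the literal reading of the
boundary tractions, and it is the choice made here.

## Non-dimensionalization

The package defines characteristic scales (`scar_scales()`: 1 cm, 1 day,
$\bar N$, $c^w$, $\bar\rho$, $E^I\sqrt{\bar\rho}$) and exact
`nondimensionalize()`/`redimensionalize()` maps whose round trip is the
identity to machine precision. The solver itself works in dimensional
variables: each constituent is solved in its own linear system, so no
ill-conditioning arises from mixing the $10^4$ cells/cm³ and $10^{-8}$
g/cm³ scales, and scale-independence of the physical solution is
guaranteed by the round-trip property rather than by rescaling the
arithmetic.

## Discretization

**Mesh.** `generate_mesh()` builds a deterministic structured
triangulation: node rows spaced $\approx\sqrt3/2$ of the horizontal
spacing with alternating rows offset by half a spacing, so the bulk is
equilateral (quality measure $\alpha = 1$; see `triangle_quality()`).
The offset tapers to zero at the lateral boundaries and at the symmetry
plane, producing short columns of right triangles ($\alpha \approx
0.86$) that keep the boundary straight; the right half is the exact
floating-point mirror of the left, so the mesh is Y-mirror-symmetric by
construction. A force-equilibrium (signed-distance) mesh generator would
also do the job, but a deterministic construction gives the same quality
guarantee ($\alpha \ge 0.85$ at the working resolutions, verified per
mesh), reproducibility without a random-seed dependence, and exact
symmetry, which the test suite exploits. The extreme domain aspect ratio
(31.92 cm × 0.15 cm) is handled simply by the row structure; the default
working resolution of $3.46\times10^{-2}$ cm gives 4–5 element rows
through the thickness.

**Space.** Linear triangular elements for all fields. Interior integrals
use the second-order vertex (Newton–Cotes) rule, boundary integrals a
two-point Gauss rule; both exactness contracts are tested. The
chemotactic velocity needs $\nabla c$ at nodes, recovered by the
variational (lumped mass) projection of the element gradients
(`recover_gradient()`), which is exact for linear fields.

**Moving grid.** The mesh convects with the material: after each
mechanics solve the nodes move by the displacement increment and the
mesh velocity is the backward difference of displacement. With the grid
velocity equal to the material velocity, the advective term
$\nabla\cdot(z\mathbf v)$ is absorbed exactly into the change of the
mass matrix between configurations, so the discrete transport equation is
$(m^{n+1} z^{n+1} - m^n z^n)/\Delta t = (\text{diffusion} +
\text{chemotaxis} + \text{reactions})^{n+1}$. Element inversion during
motion triggers a step rejection rather than remeshing — the
deformations of interest are moderate and never tangle the mesh in
practice; remeshing is out of scope.

**Positivity.** Cell densities and concentrations must stay
non-negative. Two ingredients guarantee it:

* *Flux-corrected transport*: the Galerkin transport operator is turned
  into a positivity-preserving low-order operator by discrete upwinding;
  the difference is reintroduced as antidiffusive fluxes limited by a
  Zalesak limiter (`fct_limit()`) so that no nodal value leaves the
  local bounds set by the low-order and previous solutions. The limiter
  is verified against an independently coded reference implementation.
* *Patankar source splitting*: every reaction is written as production
  minus destruction with the destruction proportional to its own
  variable (`patankar_split()`); production is treated explicitly,
  destruction implicitly, making the update non-negative for any step
  size. The split is exact at the kinetics' equilibria, so the
  unwounded state is preserved to machine precision.

**Time.** Backward Euler with adaptive step control: the local
truncation error is estimated from the second divided difference of the
two most recent steps, the step is accepted when the estimate is below
`tol_lte` ($10^{-3}$ relative by default), and the next step is scaled
by $\mathrm{safety}\sqrt{\mathrm{tol}/\mathrm{est}}$ clamped to
$[0.1, 2]$. After acceptance the same curvature estimate is used as a
local extrapolation to sharpen the constituent fields one order
(clipped at zero to preserve positivity); the displacement is not
extrapolated because the quasi-static mechanics is recomputed exactly
each step.

**Coupling.** Within each step the constituents and the mechanics are
solved segregated and iterated (fixed-point defect correction) until the
relative inter-iterate change falls below `tol_fp` ($10^{-6}$); the
bounds the iteration must meet are configurable in `solver_control()`,
with defaults `tol_mech` $10^{-8}$ and at most 25 coupling iterations.
Non-convergence halves the step and retries.

**Mechanics.** The finite-strain weak form is assembled on the deformed
configuration. The traction stress enters *everywhere through the weak
form* — $+\int\boldsymbol\psi:\nabla\varphi\,dx
-\oint(\mathbf n\cdot\boldsymbol\psi)\cdot\varphi\,ds$ — so a spatially
constant $\boldsymbol\psi$ correctly exerts no force and no explicit
divergence of $\boldsymbol\psi$ is ever formed. The nonlinear system is
solved by damped Newton iteration; the tangent is assembled by forward
finite differences of the fully local element and edge residuals (6 and
4 degrees of freedom respectively), which captures the material and the
geometric stiffness together while keeping the residual itself exact.
If full-load Newton fails, the traction is ramped up in increments with
warm starts; persistent failure rejects the time step. Poisson ratio
0.49 with linear triangles implies some volumetric locking; this is a
known accuracy (not stability) limitation shared by any P1
discretization of this model.

## What the scenario runs emulate — and what they do not

The package needs no external data: a scenario is fully described by the
parameter set, the wound geometry and the duration, and all reference
quantities are computed from runs. The study conditions mirror the
published setup: wound half-widths 3–5 cm, apoptosis rates
$(2\text{–}60)\times10^{-3}$/day, tracked material point at the wound
center mid-depth $(0, -0.075)$ cm (configurable, since the published
location is only approximate), traces every 5 days, snapshots at
$\{0, 25, 50, 100, 200, 400\}$ days, and a default duration of 400 days
(the figures of record span roughly a year; the exact end time is not
stated and is configurable).

Passing tests demonstrate internal consistency of the model and the
solver — equilibrium preservation, positivity, symmetry, convergence
orders, and the qualitative high-versus-low apoptosis contrast. They do
not validate the model against clinical scar-thickness measurements
(external data, out of scope), and the model itself cannot represent
permanent contractures, anisotropic fiber orientation, viscoelasticity
or the epidermal layer.

## Problem sizes used by the test suite

The automated tests use desk-scale versions of the study runs, chosen as
the package's own trade-off between resolution and runtime: coarse
meshes with a mean edge of 0.1 cm (two element rows through the
thickness, about 960 nodes) for the 20-day equilibrium-preservation run,
the 400-day high-apoptosis run and the 200-day low-apoptosis run (the
low-apoptosis thickness peak occurs well within 200 days at this
resolution), and 0.1 versus 0.07 cm for the mesh-sensitivity comparison.
Convergence orders are measured on small rectangles with manufactured or
closed-form solutions. The full working resolution of
$3.46\times10^{-2}$ cm is exercised by the mesh-quality checks; running
the full coupled solver at that resolution is feasible but slow in R and
is left to users who need production fields.

## Numerical edge cases and tie-breaks

* Reaction terms are evaluated with non-negativity guards inside the
  solver (`max(z, 0)`), while the exported pointwise kinetics functions
  reject negative inputs outright so that unit tests stay strict.
* A crowding factor $1-\kappa_F F < 0$ (possible only far above
  equilibrium) flips the logistic growth term negative; the Patankar
  split then moves it into the destruction coefficient, keeping the
  reconstruction identity $R = P - Dz$ exact.
* The limiter cancels antidiffusive fluxes directed down the low-order
  gradient (prelimiting) and takes no correction at Dirichlet nodes.
* `derive_p()` refuses $\kappa_F \bar N \ge 1$ (no positive logistic
  equilibrium) and $\bar N = 1$ (exponent undetermined).
* The quality measure returns 0 (not an error) for coincident points —
  degenerate triangles are reported as worst-quality, which the
  generator treats as a failure.
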