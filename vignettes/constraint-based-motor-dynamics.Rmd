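---
title: "Constraint-based dynamics of motor-driven filament assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based dynamics of motor-driven filament assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(filamotor)
```

## The model

`filamotor` simulates suspensions of rigid spherocylindrical filaments
(microtubule proxies) crosslinked and driven by two-headed motor proteins in
an overdamped solvent. Three ingredients define the model.

**Rigid filaments.** Each filament is a spherocylinder: a centerline segment
of length $L$ swept by a sphere of diameter $D$, tracked by its center
$\mathbf{x}$ and a unit quaternion $\theta$. The director $\hat{\mathbf p}$
points from the minus end (arc coordinate $s=-L/2$) to the plus end
($+L/2$). Inertia is negligible at these scales, so velocities follow from
forces through a block-diagonal slender-body mobility,
$U = \mathcal{M} F$, with drags
$\zeta_\parallel = 2\pi\eta L/\log(2L/D)$,
$\zeta_\perp = 2\zeta_\parallel$ and
$\zeta_\mathrm{rot} = \pi\eta L^3/(3\log(2L/D))$.
The combined drag $4\pi\eta L/\log(2L/D)$ is what sets the relaxation rate
of crosslink springs between parallel filaments (see below). Axial spin of
a spherocylinder has no observable effect and is projected out of the
angular velocity.

**Four-state crosslinking motors.** A motor is a Hookean tether (stiffness
$\kappa_{xl}$, rest length $\ell_0$) with two binding heads. Its states are
U (free), S$_A$/S$_B$ (one head bound) and D (both bound). The tether spans
the gap between filament *surfaces*:
$\ell_f = |\mathbf r_A - \mathbf r_B| - (D_A + D_B)/2$, where
$\mathbf r_{A,B}$ are centerline attachment points. With this convention
two filaments crosslinked by a relaxed motor sit at a center-to-center
distance $\ell_0 + D$, which is what places the second minus-end RDF peak
of the aster scenario at $D + \ell_0$. Transition rates (per head, sampled
once per step with probability $1-e^{-R\,\Delta t}$ from start-of-step
geometry):

| transition | rate |
|---|---|
| U $\to$ S | $k_{o,S}\, \frac{3\epsilon K_a}{4\pi r_{c}^3} \sum_i L_{\mathrm{in},i}(\mathbf x)$ |
| S $\to$ U | $k_{o,S}$ |
| S $\to$ D | $k_{o,D}\,\epsilon K_e \sum_j \int_{L_j} ds\, e^{-(1-\lambda)\beta E(\ell_f(s))}$ |
| D $\to$ S | $k_{o,D}\, e^{\lambda \beta E(\ell_f)}$ |

with $E(\ell) = \tfrac12 \kappa_{xl}(\ell-\ell_0)^2$ and
$L_{\mathrm{in},i}$ the centerline arclength inside the capture sphere of
radius $r_c$. The S$\leftrightarrow$D pair satisfies detailed balance for
*every* energy-partition factor $\lambda \in [0,1]$: the site-wise
equilibrium constant is $\epsilon K_e\, e^{-\beta E}$, so the passive limit
($v_m = 0$) relaxes to the correct Boltzmann occupancy. Note that the
exponent of the D $\to$ S rate carries $\beta$ explicitly; a rate of the
form $k_{o,D}\exp[\lambda E]$ without $\beta$ would be dimensionally
inconsistent with the energy and would not close the Boltzmann equilibrium
constant. Bound active heads walk toward their preferred end at the
clamped linear force-velocity law
$v_F = v_m \max(0, \min(1, 1 + F_\mathrm{proj}/F_\mathrm{stall}))$, where
$F_\mathrm{proj}$ is the tether-force component along the stepping
direction. A head reaching a filament end either pauses there or detaches,
per species. A force-dependent binding variant (replacing $E$ by the
tether force in the exponents) exists in the code as a hook but is off by
default and not validated.

**Constraint-based implicit timestep.** Steric exclusion is enforced as a
complementarity constraint on every near-contact pair: signed gap
$\Phi_u \ge 0$, contact force $\gamma_u \ge 0$, $\Phi_u \gamma_u = 0$.
Every doubly bound motor contributes a bilateral Hookean constraint
$K(\Phi_b - \Phi_{b0}) = -\gamma_b$. Linearizing the gap functions over
one step ($\Phi^{k+1} \approx \Phi^k + h\, D^T U$, with $D$ the contact
Jacobian mapping force magnitudes to wrenches) turns the step into one
convex quadratic program over
$\gamma = (\gamma_u, \gamma_b)$:
$$\min_\gamma \tfrac12 \gamma^T \mathcal{M} \gamma + q^T \gamma,
\qquad \gamma_u \ge 0,$$
$$\mathcal{M} = D^T M D + \mathrm{diag}(0, K^{-1}/h), \qquad
q = \begin{pmatrix} \Phi_u/h + D_u^T M F_{nc} \\
(\Phi_b - \Phi_{b0})/h + D_b^T M F_{nc} \end{pmatrix}.$$
All non-constraint forcing (including thermal kicks) enters through
$F_{nc}$, so steric constraints resist thermal motion inside the same
solve. The rigid-joint limit $K^{-1} \to 0$ is supported. Because the
springs are handled implicitly, the step size is not limited by their
relaxation time $\tau = \zeta/(N\kappa_{xl})$ — about $3\times10^{-6}$ s
for ten 100 pN/um tethers on a 1 um microtubule — and the integrator runs
stably at $h = 10^{-4}$ s, two orders of magnitude beyond the explicit
stability limit (`spring_relaxation_time()`, and the stability tests,
demonstrate this).

## Solving the quadratic program

The QP is solved matrix-free with Barzilai-Borwein projected gradient
descent (BBPGD): the gradient $\mathcal{M}\gamma + q$ costs one
scatter-gather over constraints plus one mobility application, the
projection clamps only the collision block, and the step size alternates
the two BB formulas after a conservative first step
($10^{-4}/\|\mathcal{M}\|_\mathrm{est}$). Convergence is declared when the
projected-gradient infinity norm falls below
$\mathrm{tol}\cdot\max(1, \|q\|_\infty)$; with the default
$\mathrm{tol}=10^{-6}$ the post-step linearized gap error is below
$10^{-9}$ um in all of the small test problems.

Dense, heavily crosslinked systems deserve comment. Thousands of tethers
sharing a few hundred filaments make $\mathcal{M}$ severely
ill-conditioned (condition numbers of order $10^6$ survive exact Jacobi
preconditioning), and binding/unbinding churn perturbs the solution every
step. The production path therefore adds, around the same BBPGD core:

* exact Jacobi (diagonal) preconditioning;
* warm starts with linear extrapolation of $\gamma$ from the two previous
  steps, plus spring-law initialization of newly created tethers;
* a few projected Gauss-Seidel sweeps as a local smoother before the
  global iteration;
* a two-point contact manifold for nearly parallel rod pairs (one
  constraint at each end of the projected overlap interval) — a single
  closest-point contact lets jammed parallel bundles grind overlap in at
  the rod ends.

For the dense scenario presets the solve is run warm-started with a looser
tolerance ($10^{-3}$–$2\times10^{-3}$) and an iteration cap of a few
hundred; at those settings the residuals correspond to per-step gap errors
of well under a nanometre, but transient surface overlaps of a few
nanometres (10–40% of a filament radius, the worst pairs in the jammed
cores) do occur and are reported honestly in the per-step run log
(`min_separation`). Fully converged solves reduce these overlaps several
fold at roughly five times the cost; the observables used by the shipped
analyses (transport velocities, straining velocity, RDF peak positions)
were checked to be insensitive to this choice at the scales simulated.

## Tunable parameters

| parameter | meaning | default | unit |
|---|---|---|---|
| `h` | timestep | 1e-4 | s |
| `kbt` | thermal energy (300 K) | 4.141e-3 | pN um |
| `eta` | solvent viscosity | 0.01 (water: 0.001) | pN s/um^2 |
| `buffer` | collision detection margin | 0.3 D | um |
| `kappa` | tether stiffness | 100 | pN/um |
| `ell0` | tether rest length | 0.05-0.053 | um |
| `vm` | unloaded motor speed | species | um/s |
| `fstall` | stall force | 1-5 | pN |
| `ko_s`, `ko_d` | off rates | ~1 | 1/s |
| `ka` (um^3), `ke` (-) | association constants | 5e-4, 5 | |
| `eps` | binding-site line density | 400 | 1/um |
| `rc` | capture radius | 0.1 | um |
| `lambda` | energy partition | 0.5 | - |

Only a few of these are pinned by measurements: the gliding motor speed
(1.0 um/s, which matches the experimental sliding velocity at an all-active
surface), the tube motor speed (46 nm/s, the NCD estimate), the aster
motor rest length (53 nm) and walking time ($L/v_m \approx 5$ s). The
remaining kinetic constants are literature-typical reconstructions for
kinesin-family motors, chosen once and shipped as editable presets
(`kinesin1_params()`, `ncd_params()`, `aster_motor_params()`,
`dynein_params()`); they should be treated as order-of-magnitude
plausible, not measured. Two architectural choices matter: gliding-assay
motors have one permanently surface-anchored inert head (the substrate is
an immobile rod so anchors reuse the ordinary attachment bookkeeping), and
the NCD/XCTK2-like tube motor walks with *one* motor-domain head while its
tail head grips the partner filament passively, as in kinesin-14 — giving
a free antiparallel sliding speed of $v_m$, not $2 v_m$.

## Scenario generators and what they emulate

All generators are pure functions of their parameters and a seed, and the
dense ones run a short athermal, motor-free relaxation so the initial
state is overlap-free.

* `scenario_gliding_assay()` — one microtubule over `n` surface-anchored
  motors (`n_active` of them motile) on a lawn of parallel immobile rails,
  periodic in x and y (the rails tile into an unbounded lawn). Three
  geometric choices make the assay well-posed: anchored motors' free heads
  bind only the mobile filament (never the substrate); rails are spaced
  just outside binding reach of a centered filament, so at hover every
  tether sits near its rest length and unbinding stays at its calm
  force-independent rate (closely spaced rails would bind pre-stretched
  side tethers, squeezing the filament down and churning); and the assay
  runs at room temperature with Brownian motion on. The thermal motion
  matters: a short filament held only by motors can tilt its leading tip
  out of binding reach, and without fluctuations to bring the tip back the
  tilt runs away and the filament is lost — with them, it is recaptured
  within fractions of a second and transport proceeds at the free motor
  speed (fitted speeds 0.9-1.0 um/s across seeds for v_m = 1 um/s, with
  occasional brief stall episodes).
* `scenario_nematic_tube()` — ~300 filaments of 0.5 um at 30% volume
  fraction in an x-periodic impermeable cylinder (0.5 um diameter),
  exactly balanced +/-x polarity, ~20 NCD-like motors per filament.
  Before release, motor binding is equilibrated for ~1.5 s with filaments
  frozen (the kinetics are equilibrium-correct, so this merely removes the
  artificial binding-wave transient). A finite-size caveat: at this scale
  the mean sampling-plane straining velocity settles at ~0.85 v_m (about
  40 nm/s for 46 nm/s motors). In a much larger tube — thousands of
  filaments, diameter twice the filament length — the wider, denser
  antiparallel network hinders sliding far more strongly and the straining
  velocity drops to roughly half of v_m; the thin desk-scale tube cannot
  reproduce that hindrance. The value here is insensitive to solver
  fidelity (identical at six times the iteration budget) and shows no
  trend over time, so it is a genuine property of the reduced geometry and
  is reported as computed.
* `scenario_bulk_isotropic()` — dilute isotropic suspension in a periodic
  box with end-pausing minus-end motors; forms asters within
  $\sim 2 L/v_m$.
* `scenario_spherical_shell()`, `scenario_confined_cylinder()` —
  confinement studies; impermeable walls are one-sided complementarity
  constraints against static geometry (outer walls act on the endcap
  spheres, which is exact for convex containment; the inner shell wall
  acts at the closest centerline point), and unbound motors reflect at
  walls.

The desk-scale presets are deliberate reductions of the much larger
systems these assemblies form in experiments and in large parallel
simulations (hundreds of filaments here against tens of thousands). They
preserve the microscopic parameters, packing fractions and boundary types,
but not system-spanning structure: long-wavelength phenomena (bundle
buckling, aster coarsening statistics, polar lane formation) are outside
what these presets can show, and passing tests on them demonstrates the
correctness of the mechanics and kinetics, not quantitative agreement of
emergent large-scale morphology with experiments.

## Numerical choices

* **RNG.** A counter-based generator keyed by (seed, step, channel,
  entity, draw): trajectories are reproducible from one integer and
  independent of how the step loop is chunked. Chunking can still change
  the warm-started QP iteration count, so trajectories of differently
  chunked runs agree to solver tolerance rather than bitwise; identical
  call patterns are bitwise identical.
* **Brownian step.** Body-frame Euler-Maruyama: anisotropic translational
  and rotational increments with covariance $2 k_BT \mathcal{M} h$,
  delivered as an equivalent non-constraint force. No drift correction is
  needed for the rod's transversely isotropic mobility beyond excluding
  axial spin; correctness is asserted through the Einstein-relation and
  director-decorrelation tests rather than scheme identity with any
  particular reference code.
* **S->D discretization.** The Boltzmann-weighted binding density is
  integrated on a midpoint grid (default 256 nodes; dense presets use 64)
  restricted to the arc window where $\beta E \le 20$; the same grid
  drives inverse-transform site sampling. At 256 nodes the rate is within
  0.1% of adaptive quadrature; the window truncation error is below
  $e^{-20}$ relative.
* **Degeneracies.** Exactly parallel centerlines take the midpoint of the
  projected overlap interval as the closest-point pair; coincident
  centerlines get a deterministic perpendicular normal; rods exactly on a
  cylinder/sphere axis generate no wall constraint (the gap is maximal
  there).
* **One transition per head per step**, and conflicting same-step firings
  resolved by a fair coin, consistent with the first-order truncation of
  the inhomogeneous-Poisson sampling; U and D are never connected within
  one step.

## Known limitations

* Filaments are rigid: no flexibility, growth, shrinkage or branching.
* Hydrodynamic coupling between filaments is neglected (local slender-body
  drag only).
* Motor-motor steric exclusion is neglected.
* In jammed, heavily crosslinked cores the capped production solves leave
  nanometre-scale transient overlaps (see the solver section); fully
  converged solves are available at higher cost via `tol`/`maxit`.
* The scaled-down presets cannot reproduce system-spanning morphology of
  much larger published simulations; see above.

## A small worked example

```{r gliding, eval = FALSE}
st <- scenario_gliding_assay(n = 100, n_active = 100, seed = 1)
cfg <- step_config(h = 1e-4, brownian = FALSE)
res <- simulate_run(st, cfg, duration = 10, record_every = 0.1)
fit_transport_velocity(res$trajectory, t_min = 1, ids = 2)
# the fitted speed equals the free motor speed (1 um/s) within a few
# percent, and autoplot(res$trajectory) shows the linear displacement
```
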