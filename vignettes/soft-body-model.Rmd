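---
title: "Viscoelastic mass-spring-dampers with compliant constraints: the model behind softsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Viscoelastic mass-spring-dampers with compliant constraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(softsim)
```

## The model

`softsim` simulates deformable soft bodies — the motivating application is
soft biological tissue in virtual-surgery training — by splitting the
behaviour into two cooperating layers:

* a **nonlinear viscoelastic mass-spring-damper (MSD) layer** that carries the
  time- and rate-dependent material response (nonlinear elasticity, creep,
  stress relaxation), evaluated as explicit forces; and
* a **compliant position-based constraint layer** (the XPBD family) that
  carries hard geometric behaviour — incompressibility, stretch limits,
  contact — by projecting node positions directly, which is what makes the
  method stable at large timesteps.

A body is a set of point masses connected by springs along the unique edges of
a tetrahedral mesh (solid, "entity" organs such as liver) or a closed triangle
surface mesh (hollow, "cavity" organs such as gallbladder).

### Forces

Each spring of rest length $l_0$ produces a restoring force of magnitude

$$
f(\Delta l) =
\begin{cases}
k_1 \Delta l + k_2 \Delta l^3 & |\Delta l| \le \Delta l_c\\[2pt]
\big(A + B(|\Delta l| - \Delta l_c)\big)\,\mathrm{sgn}(\Delta l) &
|\Delta l| > \Delta l_c
\end{cases}
\qquad
\begin{aligned}
A &= k_1 \Delta l_c + k_2 \Delta l_c^3\\
B &= k_1 + 3 k_2 \Delta l_c^2
\end{aligned}
$$

with $\Delta l = \lVert x_i - x_j\rVert - l_0$: cubic (progressively
stiffening) at small strain, linear beyond the crossover $\Delta l_c$, odd,
and $C^1$ at $\pm\Delta l_c$. Each node additionally carries a
**displacement-scaled damper**

$$
f_{\text{damp}} = -\big(b_0 + b_1 \lVert x_i - x_i^0\rVert\big)\, \dot{x}_i ,
$$

a drag whose coefficient grows with the node's distance from its rest
position $x_i^0$. This single element is what produces both creep (under
constant load the body flows toward equilibrium at a rate $\propto 1/b_1$) and
stress relaxation (under constant displacement the neighbourhood keeps
flowing, letting the reaction force decay). It is deliberately
frame-referenced: it damps motion relative to the rest pose, so it is not
momentum-conserving — a modelling choice, acceptable for organs anchored in a
body cavity, that we exclude from the momentum tests below.

### Constraints

Every constraint is a scalar function $C(x)$ with analytic gradients:

* distance: $C = \lVert q-p\rVert - l_0$ (also the sphere–sphere contact with
  $l_0 = r_1 + r_2$, unilateral);
* tetrahedral volume: $C = \tfrac16\,((p_2{-}p_1)\times(p_3{-}p_1))\cdot(p_4{-}p_1) - V_0$,
  one per tet of an entity model;
* closed-surface volume: $C = \tfrac16\sum_t (p_{t1}\times p_{t2})\cdot p_{t3} - V_0$,
  a single global constraint for a cavity model (the $1/6$ makes $V_0$ a true
  geometric volume, consistent with the tet form and with `mesh_volume()`);
* overstretch/compression band: $C = (k_r l_0)^2 - (\lVert p_1-p_2\rVert - l_0)^2$,
  unilateral and rigid, clamping spring strain to $|\Delta l| \le k_r l_0$
  (this is what suppresses the "superelastic" artifact of point loads on
  spring lattices);
* vertex–triangle plane distance: $C = (q - p_1)\cdot n - r$ for sphere–triangle
  and triangle–triangle contacts.

For the vertex–triangle constraint we use the **exact** derivatives of the
unit normal with respect to the triangle vertices rather than the common
constant-normal approximation: the exact form is what matches finite
differences (our gradient acceptance check), and it is translation-invariant,
so projection still conserves momentum. The constant-normal shortcut would be
a valid engineering simplification but would fail a derivative audit.

Projection follows the compliant (XPBD) update with $\tilde\alpha = \alpha/\Delta t^2$:

$$
\Delta\lambda = \frac{-\,(C + \tilde\alpha\lambda)}
{\sum_k w_k \lVert\nabla_k C\rVert^2 + \tilde\alpha},
\qquad
\Delta x_k = w_k\, \nabla_k C\, \Delta\lambda ,
$$

with $\lambda$ accumulated within a timestep and reset to zero at its start.
$\alpha = 0$ recovers classical position-based projection exactly (a property
we test against an independent reference implementation); $\alpha > 0$ makes
the converged constraint violation satisfy $C = -\tilde\alpha\lambda$
independent of iteration count, decoupling stiffness from the iteration
budget. Unilateral constraints (contacts, the overstretch band) project only
while violated. Constraints are processed in Gauss–Seidel order: edge distance
constraints (only present in the pure-PBD comparison mode), overstretch
bands, volume constraints, then contacts — so contacts are resolved last and
committed positions are penetration-free to solver precision.

### The timestep

Each `step`: evaluate spring forces at $x^n$; predict

$$
x^* = x^n + \frac{(x^n - x^{n-1}) + w\,f\,\Delta t^2}{1 + \gamma},
\qquad
\gamma = w\,\big(b_0 + b_1\lVert x - x^0\rVert\big)\,\Delta t ,
$$

run spatial-hash collision detection on $x^*$, reset multipliers, run the
projection loop, commit, and update velocities as
$(x^{n+1} - x^n)/\Delta t$.

Two integrator details matter and are worth stating explicitly:

* **The damper is folded in semi-implicitly.** Treating
  $-b\dot x$ as an explicit force is unstable whenever
  $\gamma \gtrsim 1$, and the study conditions reach $\gamma \sim 10^2$
  ($b_1$ up to 4000 with millimetre displacements). Dividing the whole
  predictor increment by $1+\gamma$ is exact for linear drag and gives the
  correct terminal velocity $f/b$. Dividing only the inertial term — a
  superficially similar scheme — saturates the terminal velocity at
  $w f \Delta t$, which silently erases the $1/b_1$ scaling of creep and
  relaxation; we state this because it is an easy integrator bug to write and
  its only symptom is wrong rheology, not instability.
* **Half-step start.** On a fresh run, $x^{n-1}$ is shifted by
  $\tfrac12 w f \Delta t^2$ so the first step carries half an acceleration
  increment; constant-force trajectories are then exact (standard for
  position-Verlet).

Kinematic boundary conditions (fixed nodes, prescribed velocity) are realized
by zeroing the inverse mass for the scheduled window and moving the node
before projection. The reaction force reported at a driven probe node is
$m a - f_{\text{spring}} - f_{\text{damp}} - f_{\text{constraint}}$, with the
constraint force reconstructed from the accumulated multipliers,
$\sum_c \lambda_c \nabla C_c / \Delta t^2$ — i.e. the external force a
manipulator would need to hold the node on its trajectory.

## Units and parameters

Positions are in mm, time in s, mass in g; forces are therefore in
$\mathrm{g\,mm\,s^{-2}}$ and standard gravity is $9810\,\mathrm{mm\,s^{-2}}$.
Node masses lump the total mass (default: volume at
$10^{-3}\,\mathrm{g\,mm^{-3}}$, i.e. tissue-like 1 g/cm³) uniformly.

| parameter | meaning | default | notes |
|---|---|---|---|
| `k1` | linear/nonlinear spring stiffness | 0.25 | per mm of elongation |
| `k2` | cubic stiffness coefficient | 10 | per mm³ |
| `dl_c` | cubic→linear crossover | `0.1 * l0` | fractional by default; absolute override |
| `b0` | baseline damping | 2 | stabilizing drag |
| `b1` | viscoelastic damping | 1000 | sets creep/relaxation time scales |
| `k_ratio` | stretch-limit band | 0.5 | overstretch triggers at 50% strain |
| `alpha` | constraint compliance | 0 | 0 = rigid (classical PBD limit) |
| `dt` | timestep | 0.005 s | stable well beyond; see stability test |
| `iterations` | Gauss–Seidel sweeps | 10 | |

The force-law values (`k1`, `k2`, `b0`, `b1` per experiment) are treated as
being in these internal units; no published unit system accompanies them.

## The scripted experiments and what they show

All experiments run on synthetic geometry generated by the package itself:

* **Cube rheometry** (`cube_rig()`): a 60 mm cube, six cells per direction
  (343 nodes, 1080 tets, 1638 edge springs), bottom face fixed, probe at the
  exact centre node of the top face (even division counts guarantee one).
  These runs use springs + dampers + overstretch bands *without* volume
  constraints: volume constraints belong to the organ archetypes, and rigid
  volume projection would add a damping-independent, position-level
  relaxation pathway that masks exactly the viscous time scales these tests
  probe (we observed relaxation decay become $b_1$-independent with tet
  constraints on).
* **`run_nonlinearity()`** drives the probe down at constant speeds
  (4, 8, 16 mm/s to 24 mm — the source figures print no speeds, so these are
  package choices recorded in the metadata). The raw reaction curves are
  pointwise ordered by speed (viscous contribution). Because the probe's own
  damper contributes a term *linear* in displacement that dominates the raw
  curve, the elastic convexity of the cubic regime is read from the
  first-order viscous elimination $2F(d,v) - F(d,2v)$
  (`quasi_static_curve()`), whose slope grows with displacement below
  $\sim 2.5$ mm.
* **`run_creep()`** applies a constant 60-unit load at the probe for
  $b_1 \in \{250, 1000, 4000\}$. Displacement at any fixed time is inversely
  ordered in $b_1$, and all curves share the damping-independent equilibrium
  plateau (≈5.9 mm; spread ≈0.02% in our runs). Because settling time grows
  linearly in $b_1$, each run's duration scales as $12\,\mathrm{s} \times b_1$
  (verified by the exact collapse of the $b_1=4000$ curve onto the $b_1=250$
  curve under a 16-fold time rescaling). The runs are deeply overdamped, so a
  0.05 s timestep is used.
* **`run_stress_relaxation()`** ramps the probe 20 mm down in 0.5 s, holds it,
  and samples the reaction for 2 s (0.1 s moving-average smoothing). The
  smoothed force decays for every $b_1 > 0$ and the fractional decay is
  inversely ordered in $b_1$ (7.6% / 1.7% / 0.35% in our runs); $b_1 = 0$
  settles to a constant purely elastic force.
* **`run_volume_tests()`**: a clamped 60×20×20 mm beam sagging under gravity
  with per-tet volume constraints holds $|V/V_0 - 1|$ to 0.04% (2% required;
  1.3% without constraints), and a 15 mm icosphere shell falling onto a plane
  with one global surface-volume constraint holds it to $\sim 10^{-9}$%
  (5% required; 16% without). The 2%/5% tolerances are package choices — the
  source material reports only qualitative "acceptably low" drift.
* **`run_stability()`** crushes the cube's top face to 20% height, holds,
  releases. With constraints on, the cube recovers to <5% of the edge length
  within 5 s and stays bounded for $\Delta t$ up to 0.05 s; the pure
  mass-spring mode settles in a crumpled state ≈43 mm from rest, reproducing
  the recover/fail contrast that motivates the integration. Two scenario
  choices: $b_1 = 0$ (recovery should measure the constraint-stabilized
  elastic response, not creep — any large $b_1$ turns recovery into slow
  flow) and volume compliance $\alpha = 50$. The compliance matters: rigid
  volume constraints conflict with the stretch-limit bands in the deeply
  crushed state and can lock the mesh in a crumpled local minimum; recovery
  is robust for $\alpha \in [5, 100]$.
* **`q_statistic()`** implements the whole-surface node-distance score
  $Q = \sum_i \lvert p^{\text{model}}_i - p^{\text{ref}}_i\rvert$ used for
  cross-model comparisons, together with the
  `integrated | pbd_only | msd_only` mode switch on every runner. A
  finite-element reference solution (and hence absolute $Q$ values against
  one) is outside this package's scope.

## What the synthetic data do and do not show

The generators (cube/beam lattices with a conforming 5-tet split, icospheres)
reproduce the regular geometry the reference experiments use, and the tests
demonstrate the *constitutive phenomenology* — orderings, plateaus, decay
trends, volume bounds, recovery — on that geometry. They do not establish
patient-specific accuracy: real organ meshes are irregular, anatomically
heterogeneous, and anchored by ligaments and vessels; real tissue parameters
must be identified against measured force data, and the damper's rest-pose
reference makes bulk rigid motion lossy. Passing tests therefore validate the
mechanics of the method, not clinical fidelity.

## Numerical choices and edge cases

* Degenerate springs/constraints (node spacing below $10^{-9}$ mm) are
  skipped with a warning rather than propagating infinities.
* Contact requires *strict* penetration; exactly touching primitives generate
  no constraint. Vertex–triangle contacts fire only when the projection falls
  inside the face (no edge/vertex Voronoi regions).
* The broad phase registers AABBs (inflated by an optional margin) in every
  overlapped cell of the pinned three-prime XOR hash
  $((73856093\,i)\oplus(19349663\,j)\oplus(83492791\,k)) \bmod m$, deduplicates
  pairs, re-checks AABB overlap and drops node-sharing pairs, so its output
  equals brute-force all-pairs intersection (tested against that oracle).
  Defaults: cell size = 2× mean sphere radius, table size = 2× primitive
  count.
* Non-finite positions abort the step with a solver error naming the node;
  the stability runner converts this into a reported `diverged` flag.
* Cube cells are tetrahedralized with the alternating-parity 5-tet split
  (conforming faces, no added nodes); tets are re-oriented to positive signed
  volume on construction and on file import. Internally all indices are
  1-based; OFF (0-based) and TetGen files are converted at the reader
  boundary.
* Problem sizes: the full cube rig is 343 nodes / ~3300 constraints; a full
  acceptance pass (all experiments, including the b1-scaled creep runs of up
  to 48 000 simulated seconds) takes a few minutes on one CPU core.

## Known limitations

Single-threaded; no continuous (swept) collision detection, no self-collision
unless configured, no friction; no strain-energy/bending/rod constraints; no
anisotropy or strain-rate-dependent stiffness; no finite-element reference
model. The damper's rest-pose reference is inappropriate for freely tumbling
bodies.
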