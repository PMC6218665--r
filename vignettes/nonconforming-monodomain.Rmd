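---
title: "Non-conforming hexahedral finite elements for the cardiac monodomain equation: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-conforming hexahedral finite elements for the cardiac monodomain equation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

The package solves the normalized monodomain equation on a tissue domain
$\Omega \subset \mathbb{R}^3$ over $[0, T]$,

$$\frac{\partial \phi}{\partial t} = \nabla\!\cdot(D\nabla\phi) + f(\phi, r),
\qquad \frac{\partial r}{\partial t} = g(\phi, r),$$

for the normalized transmembrane potential
$\phi = (V_m - V_r)/(V_p - V_r)$ and a scalar recovery variable $r$.
$D = d_t I + (d_l - d_t)\, \mathbf{f}\otimes\mathbf{f}$ is the normalized
conductivity tensor (mm²/ms) built from longitudinal/transverse
diffusivities and the myocyte fiber direction $\mathbf{f}$. Boundaries
are zero-flux unless a Neumann influx (surface stimulus) or Dirichlet
data are imposed; all shipped experiments use pure zero-flux boundaries.

The reaction terms are the modified Aliev–Panfilov model,

$$f(\phi, r) = c_1\phi(\phi - \alpha)(1 - \phi) - c_2 r \phi, \qquad
g(\phi, r) = \Big(\gamma + \frac{\mu_1 r}{\mu_2 + \phi}\Big)
\big({-r} - c_2\phi(\phi - b - 1)\big),$$

a two-variable phenomenological description: the cubic term switches the
membrane between the resting ($\phi = 0$) and excited ($\phi = 1$)
states across the threshold $\alpha$, and $r$ gates the repolarizing
current. Defaults (`aliev_panfilov_params()`): $\alpha = 0.05$,
$c_1 = 52$, $c_2 = 8$, $\mu_1 = 0.1$, $\mu_2 = 0.3$, $b = 0.25$,
$\gamma = 0.002$, $V_r = -85$ mV, $V_p = 15$ mV, initial recovery
$r_0 = 0.1146$ (the resting steady-state regime; it is not an exact
fixed point of $g$ at $\phi = 0$ and decays on the $1/\gamma$ time
scale, which is intended).

**Time units.** The kinetic functions above are dimensionless-time
rates; physical milliseconds enter through the classic Aliev–Panfilov
conversion $\tau$ = 12.9 ms per model time unit, carried by the
parameter set and applied in the PDE coupling ($f/\tau$) and in the
gating update ($\Delta t/\tau$). Three independent observables fix this
convention: with $D = 0.0952$ mm²/ms the converged plane-wave CV is
$\approx 37$ cm/s (per-ms kinetics would give $\sqrt{12.9}\times$ more,
an unphysiological 134 cm/s), the action-potential duration is
$\approx 200$ ms, and an S2 stimulus delivered 280 ms after S1 lands in
the repolarization tail — which is precisely what the S1–S2 protocol
requires. Stimulus amplitudes are physical per-ms rates (20 mV/ms over
the 100 mV span is 0.2/ms) and are **not** rescaled by $\tau$.

## Spatial discretization

Meshes are structured hexahedral boxes (`build_box_mesh()`): each axis
is tiled with `floor(L/h)` elements of size `h` plus one smaller
remainder element when needed, mirroring shrink-to-fit boundary layers;
if `h` exceeds an axis length the axis becomes a single element. Three
families are provided (`element_family()`):

| family | basis | element DOFs | quadrature |
|--------|-------|--------------|------------|
| Q1 | trilinear Lagrange | 8 | 2×2×2 |
| Q2 | triquadratic Lagrange | 27 | 3×3×3 |
| Q1NC | Q1 + 3 incompatible modes | 8 + 3 internal | 2×2×2 |

The Q1NC element augments the trilinear basis with the internal bubbles
$1-\xi_1^2,\ 1-\xi_2^2,\ 1-\xi_3^2$ on the reference cube. They vanish
on all six faces, so continuity is violated only in element interiors
(the "non-conforming" construction); in exchange the element represents
full quadratics and largely removes the coarse-mesh CV inflation of Q1.
The mode gradients use the per-quadrature-point Jacobian of the standard
isoparametric map (plain Wilson modes, not the centroid-Jacobian
correction): on the (near-)regular parallelepiped meshes generated here
the two coincide, and the patch test — exact reproduction of linear
fields through Dirichlet data — passes for all three families, also on
remainder meshes and with anisotropic $D$.

Notation note: the composition of reference basis functions with the
inverse isoparametric map is implemented as composition (standard
isoparametric practice) wherever a product could be misread.

Node ordering is the canonical corner numbering of the trilinear brick
(the same order VTK uses for hexahedra); Q2 nodes follow the
lexicographic 3×3×3 lattice with the first reference axis fastest. VTK
export writes Q1/Q1NC elements as linear hexahedra and decomposes each
Q2 element into eight linear sub-cells, keeping files readable by any
VTK tool without the triquadratic cell type.

## Semi-implicit scheme and static condensation

With backward differences in time, diffusion evaluated at $t_{n+1}$ and
reaction at $t_n$, the element update couples nodal values $u$ and mode
coefficients $\alpha$ through

$$K_u^e u_{n+1}^e + L^{eT}\alpha_{n+1}^e = p_u^e, \qquad
L^e u_{n+1}^e + K_\alpha^e \alpha_{n+1}^e = p_\alpha^e,$$

where each block combines consistent mass over $\Delta t$ with
stiffness (`element_blocks()`), and the loads integrate
$(u_n^h + \alpha_n^h)/\Delta t + f(\cdot)/\tau + I_{app}$ against the
respective test functions. Eliminating $\alpha_{n+1}$ per element
(`condense()`) leaves the Schur complement
$A^e = K_u^e - L^{eT}\{K_\alpha^e\}^{-1}L^e$ and a condensed load; the
global system $A u_{n+1} = \hat p_n$ has Q1 size, $A$ is constant in
time, and it is factorised **once** by sparse supernodal Cholesky
(Matrix/CHOLMOD) — the algebraic realization of "invert once and store";
a dense inverse is never formed. After each solve the modes are
recovered element-wise,
$\alpha_{n+1}^e = \{K_\alpha^e\}^{-1}(p_\alpha^e - L^e u_{n+1}^e)$, and
the gating field advances by forward Euler at each quadrature point.
Tests verify to $10^{-10}$ that one condensed step equals one step of
the monolithic system that keeps every $\alpha$ as an explicit unknown,
and that constraining $\alpha \equiv 0$ reproduces the Q1 trajectory bit
for bit.

On the structured meshes used here at most a handful of distinct element
shapes exist, so element blocks are computed per shape group; the
per-step load assembly and gating sweep run in compiled code.

The fully-implicit comparator (`fi_step()`) evaluates everything at
$t_{n+1}$ and solves the monolithic $(u, \alpha)$ system by Newton
iteration with the analytic reaction Jacobian; $\alpha$ is **not**
condensed there, because the nonlinear reaction at $t_{n+1}$ couples the
modes into $f$ and the element-level elimination holds only for the
linear semi-implicit update. Gating uses an inner backward-Euler solve
per quadrature point (solved by a few scalar Newton steps), refreshed
before each outer iteration — a staggered coupling, stated here because
the choice is genuinely open. Newton tolerance defaults to $10^{-9}$ on
the max-norm update, cap 20 iterations; at cardiac time steps it
converges in about two.

## Stimuli and experiment protocols

Volume stimuli add a normalized current (1/ms) at every quadrature point
inside a box region; surface stimuli integrate a Neumann influx (mm/ms)
over boundary faces into a nodal load. Amplitudes printed in mV are
divided by $V_p - V_r = 100$ mV (`normalize_stimulus()`). Events are
active on $[t_{start}, t_{start} + t_{dur})$ and evaluated at the
reaction time level.

* **Rod** (`protocol_rod()`): 25 mm long, one element of size $h$ per
  transverse axis — the cross-section is unstated in the source
  experiments; a plane wave is invariant across it, so CV is
  unaffected. Isotropic $D = 0.0952$ mm²/ms: the rod conductivity is
  likewise not printed anywhere, and this package adopts the cuboid's
  longitudinal value — the choice reproduces the published converged CV
  of 36.9 cm/s to within 1%, which is the strongest available
  confirmation. Stimulus: 0.2/ms for 2 ms over the first element layer
  but at least 0.5 mm deep. A strictly one-layer source would deposit a
  charge proportional to $h$ and falls below threshold for
  $h \lesssim 0.1$ mm; the fixed minimum depth makes the deposited
  charge mesh-independent on fine meshes while leaving coarse meshes
  (one full layer) unchanged. CV is measured between the nodes nearest
  x = 18 and 22 mm — probes are nearest mesh nodes, and the actual node
  coordinates enter the CV quotient, so off-grid probe positions do not
  bias the estimate.
* **Cuboid benchmark** (`protocol_cuboid()`): 20 × 7 × 3 mm, fibers
  along the long axis, $d_l/d_t = 0.0952/0.0126$ mm²/ms, 2 ms corner
  stimulus in a 1.5 mm cube with amplitude 50000/28000 × 0.2/ms
  (the printed current density on the rod's normalization scale).
  Activation times are compared along the corner-to-corner diagonal.
* **S1–S2 spiral** (`protocol_spiral()`): 50 × 50 mm sheet realized as a
  one-element-thick box — with zero-flux faces the 2-D dynamics are
  exact, and one element formulation serves all experiments. S1:
  0.12 mm/ms surface influx at x = 0 for 2 ms; S2: 0.15/ms in the
  quadrant x, y < 25 mm at 280–285 ms. The sheet conductivity is not
  stated for this experiment; the package defaults to isotropic
  0.0952 mm²/ms (the longitudinal cuboid value), flagged in the shipped
  configuration file.

## Numerical choices

* **Time steps.** Rod: 0.001 ms (reference) and 0.005 ms (refinement
  sweeps); spiral: 0.005 ms. For the cuboid benchmark, whose source
  leaves $\Delta t$ unstated, the package default is 0.02 ms: the
  explicit-reaction stability bound is governed by
  $\max|\partial f/\partial\phi|/\tau \approx 5$/ms, so
  $\lambda\Delta t \approx 0.1$, and the benchmark compares activation
  profiles between discretizations run at the same $\Delta t$, where
  temporal error largely cancels.
* **Activation time** is the first discrete sample with $\phi > 0.5$,
  with no sub-step interpolation — the literal first-crossing rule; at
  the time steps used the quantization error is negligible. An
  interpolating variant exists in `activation_map()` consumers but is
  off by default.
* **No lumping, no under-integration.** Consistent mass matrices and the
  full quadrature rules of the table above are used everywhere; with
  pure diffusion the consistent-mass integral of $\phi$ is conserved to
  solver precision (verified over hundreds of steps).
* **Quiescence early-exit.** Optional (`quiet_after`): once the latest
  stimulus has ended and $\max\phi$ falls below $10^{-4}$, the tissue
  can only relax to rest, and long quiet tails are skipped. The spiral
  comparison uses it; a run that sustains activity never triggers it.
* **Degenerate inputs.** Non-positive Jacobians, singular mode blocks,
  empty stimulus regions, non-activated probes and non-finite potentials
  are rejected with informative errors rather than propagated.

## What the experiments do and do not show

All inputs are generated procedurally — regular boxes, homogeneous
parameters, a single fiber direction, noise-free kinetics — which is
exactly the setting of the published verification experiments the
package reproduces. Passing them demonstrates correctness of the
discretization and of the non-conforming machinery, including the
emergent coarse-mesh physics (CV inflation of Q1, its suppression by
Q1NC, spiral genesis versus failure). It does not exercise anatomical
geometries, unstructured or size-graded meshes, heterogeneous or
stochastic tissue properties, or biophysically detailed ionic models;
conclusions about real hearts require those ingredients. Tetrahedral
elements, serendipity bricks, operator splitting, adaptive stepping and
spiral-tip tracking are out of scope.

## Problem sizes used in the shipped verification

The refinement study runs the rod at $h \in \{0.2, 0.1, 0.05\}$ mm with
$\Delta t = 0.005$ ms (the reference value 36.9 cm/s is approached to
within 1% at $h = 0.05$ mm); scheme agreement uses $h = 0.5$ mm at
$\Delta t = 0.001$ ms; the cuboid baseline is Q1 at $h = 0.2$ mm against
the coarse pair at $h = 0.8$ mm; the spiral pair runs at $h = 1$ mm to
600 ms. These sizes keep the full verification within tens of minutes on
a single core while preserving every qualitative contrast and the
quantitative CV anchor.
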