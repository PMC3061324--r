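---
title: "Symmetric boundary element forward modeling: models, numerics and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symmetric boundary element forward modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symbem)
```

## The physical model

In the quasistatic regime the electric potential $V$ in the head obeys

$$\nabla\cdot(\sigma \nabla V) = \nabla\cdot J^p,
\qquad \sigma\,\partial_n V = j \text{ on the scalp},$$

where $\sigma$ is a piecewise-constant conductivity field on nested domains
$\Omega_1 \subset \dots \subset \Omega_N$ (brain to scalp, separated by
closed triangulated interfaces $S_1,\dots,S_N$), $J^p$ the primary (neural)
current, and $j$ the injected scalp current density ($j = 0$ for EEG/MEG).
All quantities are SI: meters, S/m, A·m, volts, tesla.

Sources are either pointwise current dipoles $(r_0, q)$ or a surfacic
distribution $J^p(r) = \sum_i \phi_i(r)\,J_i\,n(r)$ on a source mesh with
per-vertex intensities. Sensors are projected point electrodes (EEG),
weighted point/direction collections (MEG magneto- and gradiometers),
current-injection electrodes resolved to their nearest scalp triangle (EIT),
and interior measurement points (intracranial potentials, IP).

## The symmetric boundary element system

On each interface both the potential $V_i$ (piecewise-linear P1 basis
$\phi$) and the normal current $p_i = (\sigma\partial_n V)_{S_i}$
(piecewise-constant P0 basis $\psi$) are discretized; the scalp carries no
$p$ block because the normal current vanishes there. Writing $G(r,r') =
1/(4\pi\|r-r'\|)$, the Galerkin blocks are built from three boundary
integral operators:

* single layer $S$: $\int\!\!\int \psi_k(r)\,G(r,r')\,\psi_l(r')$,
* double layer $D$ (and its adjoint $D^*$):
  $\int\!\!\int \psi_k(r)\,\partial_{n'}G(r,r')\,\phi_j(r')$ with the
  principal-value convention on co-planar pairs,
* hypersingular $N$, assembled in the integration-by-parts (surface-curl)
  form $\int\!\!\int G\,(n\times\nabla\phi_i)\cdot(n'\times\nabla\phi_j)$,
  which is symmetric positive semidefinite with the constants as kernel and
  reuses the single-layer triangle-pair integrals
  ($n\times\nabla\phi_i = (p_j - p_k)/2A$ is constant per triangle).

The head matrix is assembled domain-wise: domain $\Omega_d$ with boundary
orientations $or_a = +1$ (outer interface) / $-1$ (inner) contributes
$-\sigma_d\,or_a or_b\,W_{ab}$ between potential blocks (where $W$ is the
positive curl-form operator; the analytic hypersingular operator
$\partial_n D$ of the representation-theorem derivation equals $-W$, hence
the sign), $+\sigma_d^{-1}\,or_a or_b\,S_{ab}$ between current blocks and
$-or_a or_b\,D_{ab}$ couplings. Summed over domains this reproduces the
familiar coefficients $(\sigma_i + \sigma_{i+1})$, $-\sigma_{\text{shared}}$,
$(\sigma_i^{-1} + \sigma_{i+1}^{-1})$ and $\mp 2$ / $\pm 1$ on the $D$
blocks. The matrix is exactly symmetric by construction (each off-diagonal
block is computed once and mirrored).

Because every block carries a coefficient that is constant, linear in some
$\sigma_d$, or linear in some $\sigma_d^{-1}$, the operator blocks are
stored once and the head matrix for any new conductivity vector is
re-contracted without quadrature (`update_head_matrix`). Direct assembly is
the same contraction, so reassembly is entrywise identical — this is what
makes conductivity sweeps (EIT parameter fitting) cheap.

**Deflation.** The pure-Neumann problem fixes $V$ only up to a constant: the
vector that is constant on every $V$ block spans the null space. A rank-one
term $\omega\,m m^\top$ on the scalp potential block ($m$ = mass-lumped
vertex areas, $\omega$ = mean absolute diagonal over $\|m\|^2$) removes it
while leaving zero-mean solutions untouched. Reported EEG gains are
average-referenced; IP gains keep the raw gauge and comparisons re-reference
both fields over the same evaluation set.

**Dipole right-hand sides.** For a dipole in domain $j$ with unit-σ
infinite-medium potential $v = q\cdot(r - r_0)/(4\pi\|r-r_0\|^3)$, the
source column is supported on the interfaces bounding $\Omega_j$ only:
$+or_a\,\langle\phi, \partial_n v\rangle$ on potential rows and
$-or_a\,\sigma_j^{-1}\langle\psi, v\rangle$ on current rows. This compact
form follows from applying the interior/exterior Calderón identities to $v$,
which is harmonic away from the source; it was re-derived from the
representation theorem and is pinned end-to-end by the sphere oracles.

**EIT.** The injected current is uniform on each electrode's nearest scalp
triangle (density $I_k/\text{area}$). With the scalp current $j$ known, the
system keeps the same unknowns and only the right-hand side changes:
$(D^*_{NN} - \tfrac12 M)\,j$ on scalp potential rows, $-D^*_{N-1,N}\,j$ and
$+\sigma_N^{-1} S_{N-1,N}\,j$ on the neighboring blocks ($M$ = P1×P0 mass
matrix; the identity term survives because only one domain borders the
scalp).

**MEG.** The field splits into the primary part, the closed-form
Biot–Savart field of the sources, and the Ohmic part carried by the volume
currents, which for piecewise-constant $\sigma$ reduces to surface
integrals:
$$B_{\text{ohmic}}(r) = -\frac{\mu_0}{4\pi}\sum_i (\sigma_i -
\sigma_{i+1}) \int_{S_i} V(r')\, n'(r')\times\frac{r-r'}{\|r-r'\|^3}\,ds'.$$
The sign follows from the curl theorem applied to $\sigma\nabla V \times
\nabla'(1/R)$ domain by domain and is confirmed by the Sarvas oracle. Both
parts are kept separately on the gain object; on spherical geometry the
Ohmic part of the radial field vanishes (a runtime diagnostic), which is
why the validation also uses magnetometers oriented along $(1,0,1)$ — for
those, with dipole moments parallel to the sensor orientation, the primary
triple product vanishes identically and the reading is *purely* Ohmic, the
hardest case.

**Internal potentials.** For $x \in \Omega_i$, the Green representation
$V(x) = -D_i V_i + \sigma_i^{-1} S_i p_i + D_{i-1} V_{i-1} -
\sigma_i^{-1} S_{i-1} p_{i-1}$ evaluates the potential anywhere inside from
the boundary solution; when the evaluation point shares the source's domain
the infinite-medium term $v(x)/\sigma_j$ is added separately, so the
boundary part stays smooth even arbitrarily close to the dipole. The rows
use the analytic per-triangle integrals and remain stable near interfaces.

## Quadrature

Inner (trial-side) integrals of the single and linear double layer over
flat triangles are analytic: edge-log terms plus the signed solid angle
(van Oosterom–Strackee), with the principal value (zero) on co-planar
evaluation points. Outer (test-side) integrals use a 7-point degree-5 Gauss
rule. With adaptivity on, an outer triangle is recursively quartered until
the estimate changes by less than `tol` (default $10^{-4}$, depth cap 10).
Two practical details matter:

* *Stopping floor.* A purely relative criterion never terminates on entries
  that are small through sign cancellation (nearly co-planar double-layer
  pairs); the criterion therefore adds an absolute floor seeded from the
  unsigned level-1 child sum, decaying by 4 per level.
* *Near gate.* Operator adaptivity only engages for triangle pairs closer
  than `near_gate` (default 0.5) times the summed triangle diameters: for
  separated pairs the analytic-inner integrand is smooth and the base rule
  is already converged (measured end-to-end effect below $10^{-3}$ relative,
  at ~15× the cost when refined everywhere). Dipole source integrals always
  use a wide gate (4 diameters): they are cheap, and for sources close to an
  interface they dominate the forward error — this is precisely where the
  adaptive and non-adaptive modes differ most on coarse and random
  meshes.

Non-adaptive mode performs a single base-rule pass everywhere and is
exposed both programmatically (`quadrature_options(adaptive = FALSE)`) and
on the command line (`--nonadaptive`).

## Analytic sphere oracles

Validation rests on concentric-sphere solutions computed independently of
the BEM path:

* *EEG/IP series*: per Legendre degree $l$, a $(2N-1)$-dimensional
  interface-transfer system couples per-layer radial solutions, written in
  the scaled bases $(r/\rho_i)^l$ and $(\rho_{i-1}/r)^{l+1}$ so that degrees
  up to several hundred neither overflow nor underflow. The dipole enters as
  the analytic source-position gradient of the monopole kernel. The
  infinite-medium term is added in closed form for evaluation points in the
  source layer (its degree expansion converges arbitrarily slowly near the
  source radius); points in deeper layers receive the degree-0 jump
  $-q\cdot\hat y/(4\pi\sigma_j b^2)$. Default truncation $L = 100$
  over-converges for the benchmark depths; a tail diagnostic warns
  otherwise.
* *MEG*: the Sarvas closed form. Its own test oracle is the surface
  (curl-theorem) form of the volume-current integral evaluated with series
  potentials on a fine mesh — the naive volume quadrature is ill-defined at
  the dipole's delta contribution, so the equivalent surface form is used.
* *EIT series*: per-degree Neumann solutions for spherical-cap electrodes
  with uniform density; electrode fields superpose and the incompatible
  degree-0 data cancels for zero-sum patterns. The series is cross-checked
  against the closed-form Neumann Green function of the ball (image point
  plus logarithmic term).

## The synthetic world and what a green test establishes

The generators reproduce the standard validation geometry: three concentric
spheres of radii 0.088, 0.092, 0.100 m with conductivities 1, 1/80 (skull),
1 S/m; regular icosphere meshes with 42/162/642 vertices per layer, or
uniformly random spherical meshes triangulated by their convex hull; five
dipoles on the $z$-axis with moment $(1,0,1)$ at depths
$\{0.50, 0.70, 0.85, 0.93, 0.97\}\,\rho_1$ (spanning shallow-to-near-
boundary regimes; the benchmark convention fixes only "various distances"),
EEG electrodes at every scalp vertex, and magnetometers at radius
$1.2\,\rho_N$, radial or $(1,0,1)$-oriented.

This world exercises the solver's numerics — singular integration, the
high-contrast skull layer, near-boundary sources, mesh irregularity — but
not features of real data: anatomical (non-spherical) interfaces, mesh
defects from segmentation, anisotropic conductivity (outside the method's
scope), sensor noise, or realistic electrode montages. A green suite
establishes correctness and convergence of the forward operator on nested
piecewise-homogeneous models, not fidelity of any particular head
anatomy.

Runtime scaling: the random-mesh robustness comparison runs 8 paired models
of 300 vertices per layer (instead of 100 × 600/800 in the original study)
so the suite stays within its budget; the adaptive-vs-non-adaptive
interquartile contrast is large (often an order of magnitude for shallow
sources) and survives the scaling comfortably.

## Numerical choices and degenerate inputs

* Vertex indices are 1-based throughout the R API; the `.tri` format keeps
  its native 0-based convention on disk.
* Sources and interior points must keep a configurable distance
  $\varepsilon$ (default $10^{-6}$ m) from every interface; violations are
  errors, never silent perturbations.
* `nearest_triangle` ties break to the lowest index; electrode projection
  uses exact point-triangle distance.
* The random mesher retries (seeded, bounded) on degenerate convex hulls;
  on a sphere every sample is extreme, so the hull has exactly $2n-4$
  facets.
* EIT with sub-triangle electrodes has an intrinsic P1 resolution limit at
  the injection site: the solution peak under the electrode is not
  representable, so analytic comparisons are made away from the electrodes
  (or against equal-area-cap models); away from the injection region the
  level-3 solution agrees with the exact-electrode Green oracle to RDM
  $\approx 0.004$.
* The head matrix condition is estimated before inversion; a non-deflated
  matrix is rejected with a pointed error message.

## Known limitations

Dense $O(n^2)$ storage and $O(n^3)$ inversion bound practical mesh sizes
(about $10^3$–$10^4$ vertices per layer on one core); no fast-multipole or
H-matrix compression. Only nested geometries are supported — no disjoint or
touching compartments — and conductivity must be isotropic and constant per
domain. Electrode models are idealized (points, or uniform current on one
triangle): no impedance or extended-contact models. MAG values on coarse
meshes sit a few percent above 1 because the inscribed polyhedral surfaces
are slightly smaller than the target spheres; the bias shrinks with
refinement as observed in the level-2 → level-3 acceptance numbers.
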