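---
title: "Pore-scale permeability of cellular solids: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pore-scale permeability of cellular solids: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What the package computes

`poreflow` estimates the intrinsic (Darcy) permeability of a binary
pore-space image — a 2D slice or a 3D stack in which white voxels are pore
and black voxels are solid — by simulating steady creeping flow directly on
the voxel grid with a lattice Boltzmann (LB) solver, and relates that
permeability to image-derived structural descriptors: porosity, effective
porosity, directional connectivity, the local-thickness pore-size
distribution (D10/D50/D90), skeleton tortuosity, and junction counts.  The
target material is a cellular solid such as bread crumb: large gas bubbles
connected by small wall perforations, imaged by micro-CT at a voxel size of
order 20 µm.

## The flow model

The solver advances particle distribution functions $f_i(\mathbf{x}, t)$ on
a D2Q9 (2D) or D3Q27 (3D) lattice with $\Delta x = \Delta t = 1$ and
$c_s^2 = 1/3$.  Each time step is a collision, a body-force update, a
streaming shift, and the boundary rule:

* **Collision** acts in *central-moment* space: the moments
  $k_{x^m y^n z^p} = \sum_i f_i\, (c_{x,i}-u_x)^m (c_{y,i}-u_y)^n
  (c_{z,i}-u_z)^p$ are each relaxed towards the central moments of the
  third-order truncated equilibrium, $k^\star = k + \omega\,(k^{eq} - k)$.
  Shifting by the local fluid velocity before relaxing (rather than relaxing
  raw moments) improves Galilean invariance over raw-moment MRT.  The
  transform is evaluated as three tensor-product D1Q3 contractions per node;
  its inverse is the closed-form inverse of the shifted 1D Vandermonde
  stages, so the collision costs $O(Q \cdot 3)$ rather than $O(Q^2)$ per
  node.
* **Relaxation frequencies.** Conserved moments are untouched.  The
  second-order shear moments carry $\omega_v = 1/\tau$, which sets the
  kinematic viscosity $\nu = c_s^2(\tau - 1/2)$.  The third-order moments
  carry the "magic" frequency $\omega_m = 8(2 - 1/\tau)/(8 - 1/\tau)$,
  chosen so that $(1/\omega_v - 1/2)(1/\omega_m - 1/2) = 3/16$: with
  half-way bounce-back this pins the no-slip wall exactly mid-link and makes
  channel permeability independent of $\tau$ (verified in the test suite to
  $10^{-8}$ relative across $\tau \in \{0.6, 0.8, 1.0\}$).  In 2D the trace
  and fourth-order moments use 1.6 and 1.8; in 3D the remaining moments use
  1.
* **Forcing** is Guo-style, applied in central-moment space: the central
  moments of the Guo source term (closed forms in $\mathbf{u}$ and
  $\mathbf{F}$, derived symbolically from the same truncated equilibrium)
  are added with the per-moment factor $1 - \omega/2$, and the macroscopic
  velocity carries the half-force correction
  $\mathbf{u} = (\sum_i \mathbf{c}_i f_i + \mathbf{F}/2)/\rho$.  One step
  then adds exactly $\mathbf{F}$ of momentum per unit volume (asserted to
  $10^{-13}$ in the tests).  With all frequencies equal the operator reduces
  exactly to BGK with Guo forcing, which the tests check against an
  independently coded BGK update.
* **Boundaries.** All outer faces are periodic (one ghost copy of the
  opposite boundary, implemented as an index wrap).  Solid voxels anywhere
  act through half-way bounce-back: a population leaving a fluid node into a
  solid neighbour returns reversed on the next step, placing the wall
  half-way along the cut link.  Channel walls are just one-voxel solid
  layers, so a single mechanism serves both simple and complex geometries.

### Steady state and convergence

Runs are driven by a uniform body-force density $F$ along one axis, the
periodic equivalent of a pressure gradient $\partial P/\partial x = F$.
Convergence is monitored on the full flattened velocity vector field: every
100 iterations (configurable) the relative L2 change against the previous
check is divided by the interval, approximating the per-iteration relative
change, and the run stops when this drops below $\varepsilon = 10^{-10}$.
Running the FCC benchmark ten times longer than the stopping point changes
the permeability by less than 0.3%, so the cadence does not bias results.
Divergence (non-finite fields, or $|u| > 0.3$ in lattice units — the
low-Mach validity guard) raises a distinct error condition.

A run that cannot conduct along the forced axis (no spanning pore path)
decays towards rest and never meets the *relative* criterion; such runs are
capped by `max_iter` and reported as non-converged with $k \approx 0$,
which is the physically correct answer.

### Permeability extraction

The superficial (Darcy) velocity $U_d$ is the volume average of the
flow-axis velocity over the *total* volume, solids counted as zero — using
the pore-averaged velocity instead would inflate $k$ by $1/\phi$.  Darcy's
law for body-force driving gives, in lattice units,
$k = \bar\rho\, U_d\, \nu / F$, converted to SI with $k_{SI} = k\,\Delta
x^2$ and to Darcy with $1\,\mathrm{D} = 9.869233\times 10^{-13}\,
\mathrm{m^2}$ (the conversion constant is not part of the lattice model; it
is needed to report values in the unit the field uses).  A Reynolds number
from the mean interstitial speed and a declared characteristic length is
attached to every result and warned about when it reaches 1, the limit of
the Darcy regime.

## Benchmarks

Three analytic/reference cases validate the solver; all are regenerated
from scratch by the test suite and by `scripts/acceptance.R`:

* **Plane Poiseuille flow** (channel at Re = 1, magic-set relaxation):
  the computed profile matches $u(x) = 4 u_{max} x (L - x)/L^2$ at the node
  centres to a relative L2 error around $10^{-7}$ — the wall really sits
  half-way, so the spatial error is at the convergence floor, well below
  the $3.93\times10^{-6}$ acceptance bound.
* **Hexagonal cylinder array** (transverse creeping flow): the simulated
  $k/R^2$ follows the Gebart closed form
  $\tfrac{16}{9\pi\sqrt6}\bigl(\sqrt{\pi/(2\sqrt3(1-\phi))} - 1\bigr)^{5/2}$
  within 5% for porosities at and above 0.7 (measured: about −1.6% at
  $\phi = 0.75$, −3.7% at $\phi = 0.85$ on a 111×64 cell), with the
  deviation growing towards the touching-cylinder porosity as expected from
  staircase resolution of narrow gaps.
* **FCC sphere packing**: the close-packed face-centred-cubic cell —
  spheres of radius $\sqrt2 L/4$ at the cube corners and face centres,
  touching along the face diagonals — has analytic void fraction
  $1 - \pi/(3\sqrt2) = 0.25952$; the voxelised porosity converges to it
  with resolution.  Simulated $k/D^2$ (sphere diameter $D = L/\sqrt2$,
  $\tau = 0.6$, $F = 10^{-7}$) approaches the published Stokes reference
  $1.7360\times10^{-4}$ from below: −6.7% at $L = 32$, −10% at $L = 64$,
  and −4.8% at both $L = 96$ and $L = 128$.

### Why the coarse-grid FCC values are resolution-limited

At $L = 32$–$64$ the flow through a *touching* sphere packing is controlled
by throats only a few voxels wide, and the finite-resolution error of any
bounce-back LB code is dominated by the sub-voxel position of the staircase
surface inside those throats: a ±0.2-voxel shift of the effective surface
moves $k$ by roughly ±10–20% at $L = 32$.  Published LB results for this
geometry show errors of comparable magnitude but varying sign at these
resolutions, depending on the voxelisation registration and the residual
$\tau$-sensitivity of bounce-back on staircase (non-planar) walls — our
code measures +5% between $\tau = 0.6$ and $\tau = 1$ at $L = 32$, even
though plane-channel permeability is $\tau$-independent to $10^{-8}$.  We
deliberately keep the principled construction (node-centre-in-solid test,
exact radius, symmetric half-voxel registration) rather than fitting a
sub-voxel radius offset to any particular published coarse-grid number;
the discretisation error vanishes with resolution, which is the claim that
matters.

## The synthetic foam generator

No public micro-CT data of the target material exists, so studies run on a
seeded synthetic emulation of bread crumb: a Boolean model of ellipsoidal
gas bubbles with lognormal radii (median 0.25 mm, sdlog 0.35 at the default
18.7 µm voxel size), carved from a solid block until a target porosity
(default 0.70, matching the 0.65–0.74 range typical of sandwich bread) is
reached, followed by "broken holes": with probability `perforation_prob`,
each pair of adjacent bubbles is connected by a channel of radius 0.06 mm
(about 3 voxels) carved through their shared wall along the centre-to-centre
chord.  Bubbles are elongated by a factor 1.3 along the second axis,
emulating the cell elongation produced by proofing; this is what gives the
synthetic material a directional anisotropy, so that connectivity along and
across the flow direction can differ, as in real crumb.  Because the
perforation volume depends on the realised bubble pattern, the generator
re-runs itself from the seed with a corrected bubble-phase target until the
final porosity lands within ±0.01 of the request.

What the generator does *not* emulate: wall-thickness distributions from
dough films, curvature-correlated wall rupture, partial wall collapse, or
scanner noise and segmentation artefacts.  Passing tests on these foams
therefore demonstrates that the *pipeline* behaves correctly on structures
with the right porosity, two-scale pore system and anisotropy — not that
any particular real bread would give the same descriptor values.

## Structural descriptors: definitions and choices

* **Labelling** uses face connectivity (4/6-neighbour): bounce-back blocks
  flow through diagonal-only contacts, so this is the flow-relevant
  equivalence.  Labels are deterministic (size-ranked, ties by first
  voxel).
* **Effective porosity** is the pore fraction in *spanning* components —
  components touching two opposite faces along at least one axis.  This is
  a direction-independent definition chosen because the isolated closed
  pores it excludes are precisely those that raise porosity without
  contributing to permeability; it is implemented as a separate function so
  an alternative definition can be swapped in.
* **Local thickness** is the Hildebrand–Rüegsegger construction: an exact
  Euclidean distance transform gives each candidate centre a sphere of
  radius $d_{solid} - 1/2$ (the interface sits half-way between voxel
  centres, consistent with the solver's wall convention), and each pore
  voxel records the diameter of the largest sphere covering it.  Tests
  compare against exhaustive sphere enumeration on small images.  The
  pore-size quantiles D10/D50/D90 are voxel-volume-weighted quantiles
  (midpoint interpolation) of this map.
* **Skeletonisation** is sequential topology-preserving thinning (simple
  points by local connectivity-number tests, object 8/26-connected,
  background 4/6-connected, curve endpoints preserved, directional
  sub-iterations).  Branch arc length accumulates Euclidean step weights
  $1, \sqrt2, \sqrt3$ — unit steps would bias tortuosity low on diagonal
  runs — and branch tortuosity is arc length over endpoint chord.  A
  *valid* branch has distinct endpoints and a chord longer than one voxel;
  loops are excluded and counted separately; the reported tortuosity is the
  unweighted mean over valid branches.  Sequential thinning is only
  approximately rotation-equivariant; the tests allow 5% on the mean
  tortuosity under a 90° rotation.
* **Junction counts**: adjacent junction voxels are clustered into one
  junction node; triple/quadruple points are nodes with exactly 3/4
  incident branches.

## Workflows

`directional_permeability()` re-runs the solver with only the force axis
and sign changed; paired opposite directions agree within 0.1% (flow
reversibility of creeping flow), so anisotropy is carried by the
between-axis ratios.  `rev_analysis()` computes porosity and directional
permeability on nested centred crops and flags the size beyond which the
curves stabilise.  `ensemble_study()` generates a seeded foam ensemble,
computes the full descriptor table plus permeability per image, and reports
Spearman rank correlations (tie-corrected; exact permutation p-values below
n = 10, t-approximation otherwise) with the conventional significance stars and
*no* multiple-testing correction — the correlations are descriptive, and
the output says so.

On a 100-image perforation-probability sweep of the default foams, main
connectivity shows the largest positive correlation with permeability and
secondary (cross-flow) connectivity a negative one, porosity at fixed
target shows almost none — the mechanism being that cross-connected but
axially-disconnected structures divert or block axial transport.  These
sign patterns, not the numeric coefficients, are the reproducible content:
the coefficients depend on the ensemble's parameter ranges.

## Problem sizes and numerical settings used by the shipped tests

The test suite and acceptance script choose sizes that exercise every
claim at desk scale: the Poiseuille acceptance grid is 100×100; the Gebart
cell is 111×64 (aspect ratio $\approx \sqrt3$, preserving the hexagonal
tiling); the FCC study runs $L = 32$ and 64 (the resolution trend above
was measured up to $L = 128$); ensemble foams are 48², 100 images; the
coarsening check uses a 192² foam at factor 4.  Convergence uses
$\varepsilon = 10^{-10}$ throughout; ensembles cap `max_iter` at 12000 so
that non-conducting images (which cannot meet a relative criterion) finish
in bounded time.

## Known limitations

* Newtonian, single-phase, steady creeping flow only; no non-Newtonian
  rheology, capillarity or swelling.
* Bounce-back staircase walls: first-order geometry representation, with
  the coarse-grid sensitivity discussed above for touching-sphere throats.
* Pressure-difference (non-periodic) inlet/outlet boundary conditions are
  not implemented; all driving is body-force periodic.
* The thinning skeleton is a curve skeleton; surface-like pore spaces in 3D
  are reduced to curves, which can oversimplify sheet-like voids.
* 2D permeabilities are systematically below 3D values for the same
  material (no out-of-plane paths); ensemble conclusions are comparative,
  not absolute.
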