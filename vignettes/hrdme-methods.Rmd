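---
title: "Methods: the hierarchical RDME solver"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the hierarchical RDME solver}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrdme)
```

## The model and its assumptions

The reaction–diffusion master equation (RDME) describes molecules as
point particles on a mesh: diffusion is a jump process between adjacent
voxels, and reactions are well-mixed *within* a voxel. `hrdme`
implements the RDME on a stack of nested cubic meshes over a cubic
domain. Level 0 is a single voxel — the well-mixed chemical master
equation — and each level halves the voxel width, so level $l$ has
$(2^l)^3$ voxels of width $h_l = V^{1/3}/2^l$. Because each refinement
is a strict octree subdivision, parent/child lookups are pure index
arithmetic (`floor(ijk/2)` and $2\,ijk + \delta$) and cost nothing to
store.

Every molecule is tracked individually (the *next-particle method*): a
global event queue holds one tentative diffusion event per mobile
molecule, one unimolecular event per molecule with unimolecular
chemistry (sampled once at birth — diffusion does not disturb it), one
event per co-located reactive pair per channel, and one pending event
per zeroth-order channel. Events are executed in time order; events
invalidated by a move or a death are discarded lazily when they surface
at the queue head. All waiting times are exponential and all draws come
from R's seeded RNG stream, so a run is reproducible bit for bit from
its seed.

Key assumptions inherited from the mesoscopic framework:

* reactions inside a voxel are well-mixed and molecules are point
  particles — excluded-volume (crowding) effects are not represented;
* diffusion is normal (a single diffusion constant per species);
* the domain is a closed cube; boundaries are reflective (see below).

## Bimolecular rates and the critical mesh size

Microscopic association rates $k_a$ (volume/time) are converted to the
per-pair in-voxel firing rate

$$k^{meso} = \frac{k_a}{h^d}\Bigl(1 + \frac{k_a}{D}\,G(h,\sigma)\Bigr)^{-1},
\qquad
G(h,\sigma) = \frac{1}{4\pi\sigma} - \frac{C_3}{6h} \quad (3D),$$

with $\sigma$ the sum of the two reaction radii, $D$ the sum of the two
diffusion constants, and $C_3 \approx 1.5164$ a lattice constant. The
correction vanishes at the critical mesh size
$h^* = \tfrac{2}{3}\pi C_3 \sigma \approx 3.2\sigma$
(`criticalMeshSize()`), where the mesoscopic mean binding time equals
the microscopic one; on finer meshes the lattice model degrades again,
so $h^*$ is the optimal resolution. Meshes below $h^*$ are allowed but
reported (a consolidated note at model preparation; a `warning()` from
`mesoRate()` when called directly) — the benchmark systems sit
marginally below $h^*$ at their finest level by construction, which is
the regime the method is designed for.

The two-dimensional branch of $G$,
$\frac{1}{2\pi}\log(\pi^{-1/2} h/\sigma) - \frac{1}{4}\frac{3}{2\pi} + C_2$
with $C_2 \approx 0.1951$, is exposed by `greenCorrection(dim = 2)` for
reference — its logarithmic growth in $h$ reflects the absence of a
well-mixed limit in 2D — but the simulator itself is 3D only and the 2D
branch is exercised only by formula-level tests.

## Per-species mesh levels

For each species, the solver finds the *coarsest* level whose width
satisfies $k_a/(1+\epsilon) < k^{meso} h^3$ — equivalently a relative
mean-rebind-time error $W(h) = (k_a/D)G(h,\sigma) < \epsilon$ — for
every bimolecular channel the species joins (`assignSpeciesLevels()`).
The inequality is treated as strict, the conservative reading of the
criterion. Species with no bimolecular involvement are assigned level 0.
If even the finest level fails, the finest level is used and a warning
is emitted: the benchmark parameterisations operate exactly at this
edge, where only the $64^3$ mesh is admissible at $\epsilon = 0.025$.
The default $\epsilon = 0.025$ is the tolerance at which the two-step
dissociation–rebinding chain is known to be resolution-limited; larger
tolerances monotonically coarsen the assignment.

## Level coupling

**Reacting across levels.** Two molecules may react when they share a
voxel on the same level or when the finer molecule's voxel lies inside
the coarser molecule's voxel. The pair fires at the mesoscopic rate of
the *coarser* of the two levels. This is the choice that preserves the
mean binding time: with reaction probability
$P_{react} = k_r^{meso}/(k_r^{meso}+k_{diff})$ per event and waiting
time $t_{event} = (k_r^{meso}+k_{diff})^{-1}$, the mean time to
reaction is $\tau = P_{react}^{-1} t_{event} = 1/k_r^{meso}$
independent of the diffusion rate, so choosing the coarse-level rate
reproduces the coarse-mesh mean binding time exactly. The acceptance
suite verifies this empirically (one immobile coarse molecule, one
diffusing fine molecule, $10^4$ replicates).

**Fine to coarse.** Each molecule records the simulation time since its
birth or last transfer. Once it exceeds
$t_{transfer} = (C h_l)^2 / (6D)$ — the time to diffuse an RMS distance
of $C$ voxel widths, i.e. to become well-mixed on the voxel scale — the
molecule is promoted into its parent voxel. Promotion happens only
immediately after one of the molecule's own diffusion events, before
new tentative events are sampled: a transfer is operationally a
diffusion event (new voxel, resample bimolecular partners and the
diffusion clock), so piggybacking avoids both extra work and the bias
of discarding pending reaction events at arbitrary times. The clock
resets on every level change, so multi-level promotion proceeds one
level at a time. Demotion never happens spontaneously — only product
placement moves molecules to finer meshes.

**Coarse to fine.** Reaction products are created on their own species'
finest level. If that level is finer than the reactant's, the product
voxel is a uniformly sampled descendant of the reactant voxel (iterated
uniform child choice); if coarser, the unique ancestor; if equal, the
same voxel. The two products of a dissociation that target the *same*
level share one sampled voxel — co-placement is what preserves the fast
rebinding statistics, and it mirrors the microscopic picture of
products born in contact. Products of the same reaction with
*different* target levels are placed independently by the same rule;
nothing in the benchmark systems constrains that case more strongly.

## Design choices made where the design was open

* **Transfer constant** $C = 20$ by default. The rebinding benchmark
  passes already at $C = 1$ (the package tests both), but $C = 20$ is
  kept as the safe default for systems where no such calibration
  exists; the cost of a larger $C$ is a few hundred extra fine-level
  jumps per molecule ($\approx C^2$ events per level).
* **Boundary condition: reflective.** Absent faces are simply removed
  from the jump process (a corner voxel fires at half the interior
  rate). On a closed domain this preserves the uniform stationary
  distribution, which the well-mixed limit presupposes; the diffusion
  tests verify uniform long-run occupancy (chi-squared) and
  $\langle r^2 \rangle = 6Dt$ away from the boundary.
* **Per-pair bimolecular clocks.** When a voxel holds several potential
  partners, every co-located (pair, channel) combination carries its
  own exponential clock. The sum of per-pair rates equals the
  mass-action propensity $k x_1 x_2$, so the well-mixed marginal is
  exact — confirmed by the distributional equivalence test against the
  direct SSA on one level.
* **Bimolecular product anchor.** When the two reactants sit on
  different levels, product placement is anchored at the *finer*
  reactant's voxel. The finer voxel is contained in the coarser one, so
  this choice is consistent with the coarse-rate rule while retaining
  the maximal positional information available.
* **Tie-breaking.** Event times are continuous so ties have measure
  zero, but the queue still orders equal times by insertion sequence to
  keep runs deterministic.
* **Dissociation rate of the rebind benchmark.** The rebinding-time
  distribution — dissociation to next association — does not depend on
  how fast the bound complex dissociates, because dissociation is
  memoryless and the complex's position at dissociation is uniform
  either way. The fixture uses 10/s so that most simulated time is
  spent in the informative unbound phase.
* **Eq.-style SSA oracle.** The well-mixed oracle uses the one-voxel
  mesoscopic rate ($h = V^{1/3}$) for bimolecular propensities, exactly
  how the coarsest hierarchy level reacts; pure mass-action $k/V$ is
  available behind `massAction = TRUE` for comparison. Propensities are
  recomputed from the state each step — with a handful of channels
  incremental bookkeeping would only add failure modes.

## What the built-in models emulate — and what they do not

The four fixtures (`rdFixture()`) are fully parameterised benchmark
systems, not data sets: a reversible pair for rebinding statistics, a
two-step and a four-step dissociation–rebinding chain whose mean
behaviour hinges on resolving fast rebinding, and a MAPK
phosphorylation–dephosphorylation cascade in the parameter regime where
a well-mixed model is qualitatively wrong. They emulate the features
that make spatial stochastic simulation hard — diffusion-limited
association ($k_a/(4\pi\sigma D) \gg 1$), product pairs born in
contact, copy numbers in the tens to hundreds — under idealised
conditions: a unit cube, uniform initial placement, equal diffusion
constants, no crowding, no geometry. Passing tests on these systems
shows that the hierarchy reproduces its own fine-mesh limit and the
well-mixed limit; it does not show agreement with off-lattice
microscopic dynamics below $h^*$, nor robustness to complex geometries,
which are outside the mesoscopic framework used here.

In the MAPK fixture all species are pinned to the finest mesh — no
coarse-graining assumption is made for any species — with the
criterion-based assignment available via `autoLevels = TRUE`. The
starred enzyme forms relax at $k_7 = 693147.18$ ($\approx \ln 2 \times
10^6$), carried verbatim; the phosphatase channels reuse the kinase
channel rate values.

## Numerical and implementation notes

* The event loop is compiled (Rcpp): a binary heap with lazy
  invalidation (liveness flags plus per-molecule version stamps on
  bimolecular events), per-level hash-map occupancy registries in which
  each molecule is registered at its own voxel and at every ancestor
  voxel, and an early-exit registry update that touches only the levels
  where a move actually changes the ancestor chain.
* Co-location scans walk the ancestor chain of the moved molecule
  (coarser partners at their own level, finer partners through the
  subtree registry), skipping levels with no partner species present.
* Molecules on level 0, and molecules with $D = 0$, carry no diffusion
  event (a single voxel has no neighbours under the reflective
  boundary); they consequently are never promoted, which is the
  intended behaviour in both cases.
* Degenerate inputs: a zero microscopic rate gives a zero mesoscopic
  rate; a bimolecular channel whose pair diffusion constant is zero is
  rejected (the correction is undefined); meshes so fine that
  $1 + (k_a/D)G \le 0$ are rejected as outside the validity of the rate
  conversion.

## Problem sizes used by the test and acceptance runs

The statistical checks were sized to give comfortable power while
staying quick on one core: 250–500 trajectories for the ensemble
moments of the two-step chain (standard error of the mean
$\approx 0.2$–$0.3$ molecules against a band of $\pm 0.9$);
$10^4$ rebinding events per arm for the distribution comparisons
(two-sample Kolmogorov–Smirnov at the 5% level resolves differences of
about 2% in distribution); $10^4$ replicates for the mean-binding-time
rule (three standard errors $\approx 3\%$); and 100–300 trajectories
per resolution for the mesh-refinement error trend over
$8^3 \to 16^3 \to 32^3$ against a $64^3$ reference on a horizon of
2.5 s. The trend check asserts monotonic decrease only: the absolute
error values depend on the reference and on the species included in
the metric.

## Known limitations

* Accuracy is bounded by the critical mesh size: phenomena that require
  sub-$h^*$ resolution (strong microscopic rebinding, crowding) are not
  captured — this limit is inherent to the mesoscopic model, not to the
  hierarchy.
* Cartesian octree meshes only; no unstructured meshes, no periodic
  boundaries, no 2D simulation driver (only the 2D rate formula is
  exposed).
* The trajectory-error metric normalises by the summed reference means;
  it is a pseudometric on mean series and is reported alongside its
  unnormalised numerator.
* Transfers are controlled by a single global constant $C$; there is no
  adaptive, per-molecule or spatially varying refinement criterion.
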