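---
title: "Model and methods: filament-level Brownian dynamics of lamellipodial actin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: filament-level Brownian dynamics of lamellipodial actin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actoflow)
```

## The model

`actoflow` simulates a 2-um-wide strip of lamellipodium as a network of
semiflexible bead-spring actin filaments in three dimensions. The box is
periodic along x (the leading-edge direction), unbounded along y (retrograde
flow points towards +y, the leading edge sits at y = 0), and confined to a
0.2-um slab along z by soft walls. Each filament is a chain of beads at rest
spacing l0 = 0.1 um; one bead-spring-bead segment stands for 37 actin
monomers. Beads evolve by overdamped (Brownian) dynamics,

$$\zeta_i \, \dot{\mathbf r}_i = \mathbf F_i^{spring} + \mathbf F_i^{bend} +
\mathbf F_i^{crosslink} + \mathbf F_i^{excluded} + \mathbf F_i^{leading} +
\mathbf F_i^{motor} + \mathbf F_i^{confine} + \mathbf F_i^{thermal},$$

integrated with the explicit Euler-Maruyama scheme at dt = 1e-5 s. The drag
coefficient per bead is the orientation-averaged cylinder drag
$\zeta_b = 4\pi\eta l_0/[\ln(l_0/d)+0.84]$, which evaluates to 0.108 pN s/um
for cytoplasmic viscosity 0.3 Pa s and filament diameter 7 nm:

```{r drag}
bead_drag_coefficient(0.3, 0.1, 0.007)
```

Force channels:

* **Bond springs**: Hookean, $k^{actin} = 1000$ pN/um. Deliberately softer
  than a real filament's longitudinal stiffness so the 1e-5 s time step is
  stable; consequences for elastic moduli are probed by the
  mechanical-characterization rig.
* **Bending**: for each interior triplet,
  $E = (\kappa/l_0)(1-\cos\theta)$ with flexural rigidity
  $\kappa = k_BT\,l_p$ and persistence length $l_p = 17$ um. The forces are
  the exact analytic gradient (verified against finite differences in the
  test suite).
* **Crosslinkers**: springs between beads of different filaments,
  $k^{crosslink} = 100$ pN/um, rest length 35 nm. Permanent links model
  Arp2/3-complex connectivity; dynamic links model transient crosslinkers
  (alpha-actinin/filamin/plastin) with exponential lifetime (rate 1/s).
* **Excluded volume**: when the closest approach between two filament
  segments falls below 7 nm, a linear repulsion of stiffness 1690 pN/um acts
  along the closest-approach direction, distributed to the four endpoint
  beads by the lever rule. This is the stiff interaction that limits the
  time step; the bond-crossing audit confirms pass-throughs stay negligible.
* **Leading-edge pushing**: every filament with at least one bead at
  y <= 0 receives 1.5 pN total (0.136 pN per bead of an intact 11-bead
  filament), directed along its barbed-to-pointed axis as defined by the
  pointed-end segment. Beads below y = -0.5 um are rare transients and are
  treated as qualifying, which keeps the force continuous as beads cross
  that depth.
* **Motor pulling**: `uniform` (0.002 pN on every bead, +y), `back`
  (0.004 pN on beads with y > 3.25 um), or `membrane` (0.02 pN on beads
  within 20 nm of the substrate and outside the adhesion, along the
  filament's barbed-to-pointed axis).
* **Confinement**: a constant 1 pN restoring force outside 0 < z < 0.2 um.
  The top wall can be disabled for buckling studies.
* **Branch restraint**: in branching runs,
  $E = \epsilon(\cos\theta_{ijk}-\cos 70^\circ)^2$ with
  $\epsilon = 1$ pN um holds mother-daughter angles near 70 degrees.
* **Thermal forces**: independent Gaussian kicks of per-component variance
  $2 k_BT \zeta/\Delta t$. Temperature is not a printed parameter; we fix
  kBT = 4.11e-3 pN um (about 298 K), overridable in the configuration.
  Adhesion-bound beads fluctuate with their elevated drag
  $\kappa_{FA}\zeta_b$ so that the fluctuation-dissipation balance holds at
  the bead level (configurable via `thermal_fa_drag`).

## The molecular clutch

The nascent focal adhesion is a capsule-shaped region (0.25 um wide, 1.25 um
long, 0.1 um high, long axis along x, front edge at y = 1 um by default).
Beads inside bind and unbind by a discrete-time kinetic scheme (rates 10/s
and 1/s, probabilities $1-e^{-k\Delta t}$), giving a bound fraction of 10/11
at equilibrium; bound beads move with drag $\kappa_{FA}\zeta_b$. The single
dimensionless ratio $\kappa_{FA}$ (adhesion to cytoplasm viscosity) sets the
clutch strength; $\kappa_{FA} = 1$ is the no-adhesion limit.

## Network turnover

Filaments are inserted near the leading edge at a fixed rate of 23.4/s using
a deterministic fractional accumulator (reproducible by construction; the
rate is a constant, not a Poisson intensity). Each new filament is 1 um long
(11 beads), pointed end at y = 0.5 um, in-plane axis uniform on (-70, 70)
degrees and out-of-plane tilt uniform on (-10, 10) degrees. On insertion up
to five permanent crosslinks are created to beads of other filaments within
0.03-0.04 um, chosen uniformly at random (the candidate pool is usually
small; a nearest-first rule would bias the geometry without support in the
model definition). Dynamic crosslinks are topped up every 0.025 s to a cap
equal to the concentration `C_dynamic` over the box volume within 9.5 um of
the leading edge (the y-extent is taken as [0, 9.5] um; the alternative
[-0.5, 9.5] would change the cap by about 5%). Every actin bond receives a
severing time $\tau = \tau_{age} - \ln(u)/r_{age}$ at creation
(minimum 125 s, mean 130 s); expired mid-chain bonds split the filament, the
barbed-side fragment keeping the filament identity so pushing-direction
bookkeeping survives severing, and single-bead filaments are pruned together
with their crosslinks.

Event ordering within a step is fixed for reproducibility: forces,
displacement, wrapping, adhesion kinetics, expiry/pruning, dynamic-crosslink
refresh, insertion. All stochastic draws come from one xoshiro256++ stream
stored in the network state and seeded from R's RNG, so `set.seed()` governs
an entire run and checkpointed runs continue bit-identically.

## Scenarios

* **Clutch sweep** (`run_clutch_sweep`): networks grown from scratch per
  $\kappa_{FA}$; mean retrograde speed is the all-bead average of dy/dt
  between recorded frames. The `paired = TRUE` option applies common random
  numbers (the RNG state is restored before each $\kappa$) so that
  between-$\kappa$ comparisons are differences between paired trajectories
  rather than independent ones; at reduced scale this cuts the comparison
  noise several-fold and is the recommended way to resolve the ordering.
* **Polymerization inhibition** (`cytochalasin_protocol`): insertion and
  pushing switch off at steady state; the speed ratio after/before reports
  the motor contribution to flow.
* **Arcs** (`arc_scenario`): adhesion moved to y = 2.375 um,
  $\kappa_{FA} = 250$, sweeping `C_dynamic` with permanent or long-lived
  (finite mean lifetime) crosslinkers. Bundling is quantified by an
  x-density histogram and a 2D nematic order parameter, since visual
  assessment is not testable.
* **Microspikes** (`microspike_scenario`): half of insertions are exactly
  vertical, placed 35 nm from an existing filament or at random x.
  Alternation is deterministic (every other insertion) rather than
  Bernoulli, which fixes the 50/50 split exactly.
* **Branching** (`spawn_filaments(mode = "branch")`): daughters nucleate on
  mother beads with y in [0.20, 0.25] um at 70 degrees in-plane; the
  junction is a stiff spring ($k^{actin}$, rest length 7 nm) between mother
  bead and daughter pointed bead plus the angular restraint; pushing is
  reduced to 30% in this mode. The junction spring constant is a model
  choice: the junction must not stretch visibly, and reusing the actin bond
  stiffness adds no new parameter.

## Mechanical characterization

`extract_mechanical_patch` freezes turnover, equilibrates without external
forces, tiles the periodic box once along x while reconnecting the
periodic bonds across the new interface, severs the remaining seam, and cuts
to a 4 x 4 x 0.2 um open patch. `uniaxial_test` clamps beads within 0.25 um
of the two y faces and moves the clamps apart or together, split
symmetrically, at an engineering strain rate of 0.05/s by default (relative
clamp speed 0.2 um/s on the 4-um gauge; the printed rate's units are
ambiguous between um/s and 1/s, and since the loading is near-quasistatic
either reading gives the same moduli within noise). The tensile stress
$\sigma_T = \sigma_{yy} - (\sigma_{xx}+\sigma_{zz})/2$ comes from the virial
stress tensor over bonds, crosslinks, excluded-volume contacts and the
pairwise-decomposed bending/branch triplets, excluding clamped beads, with
the sign convention that tension is positive; the elastic modulus is
$\sigma_T(0.2)/0.2$. Compression reports $-\sigma_T$, and removing the top
wall permits buckling.

`build_synthetic_patch` generates a small crossed-lattice network (filaments
along x and y, 40 nm apart in z, crosslinked at every near-intersection) for
desk-scale mechanical tests. It is synthetic by construction and is labelled
as such: it reproduces the qualitative elasticity of the extracted patch
(stress-stiffening, extension stiffer than compression, stiffness growing
with $k^{actin}$) at a fraction of the cost, but its absolute moduli are not
those of the steady-state network.

## Problem sizes and what the tests show

Reference-scale runs (2-um box, 23.4 filaments/s, 125-s segment lifetime)
reach steady state with roughly 3 x 10^4 beads after several hundred
simulated seconds; that regime is cluster-scale. The package's tests and
examples use a desk profile: a 1-um box, insertion at 4-6/s, segment
lifetimes of 6-10 s, and equilibration/measurement windows of about 7/4 s.
These networks have a few hundred beads and reach their (shorter)
steady state within seconds of simulated time. The physics — force laws,
kinetics, per-bead and per-filament force magnitudes — is unchanged, so
desk runs support exact analytic checks, equilibrium-statistics checks
(persistence length, fluctuation-dissipation, binding equilibria) and
ordering/monotonicity checks (clutch braking, inhibition ratios, stiffening),
but not the absolute flow speeds or moduli printed for the reference scale:
the desk lamellipodium is shorter than the 9.5-um crosslinker slab and its
speed plateau sits higher. The clutch effect also saturates earlier in
$\kappa_{FA}$ at desk scale, because the short network engages the adhesion
capsule with fewer beads; sweeps therefore probe the responsive range
$\kappa_{FA} \lesssim 100$.

One scale effect deserves emphasis: after a simulated polymerization halt,
the adhesion-strength dependence of the flow ratio $v_{after}/v_{before}$
is not reliably resolvable at desk scale. With the shortest desk lifetimes
the braked baseline speed at high $\kappa_{FA}$, combined with a pull- and
fragment-driven residual flow floor, systematically inverts the ordering;
with the longer-lived desk network (10-s segment lifetime, early post-halt
window) the ordering outcome varies from seed to seed, because the
reference-scale effect is itself only of order ten percent relative and
single desk-scale pairs carry comparable noise. The inhibition protocol
therefore reports the ratio itself (which is robustly inside (0, 1));
resolving its $\kappa_{FA}$ ordering requires either the reference scale or
many paired replicates.

What the synthetic-data generators emulate: steady retrograde flow with
realistic per-filament forces, turnover and crosslink connectivity. What
they do not: force-dependent polymerization, discrete motors, a deformable
leading edge, adhesion maturation, or bending-induced severing — all outside
the model.

## Numerical choices

* Time step 1e-5 s, set by the excluded-volume stiffness; an instability
  guard aborts if any bead moves more than l0/2 in one step.
* Neighbor search: cell list over segment midpoints (edge l0 + cutoff),
  verified against true segment-segment distance within a 20-nm skin, and
  rebuilt when any bead drifts more than half the skin or the topology
  changes. Completeness under the displacement cap is guaranteed by the
  skin construction and tested against an all-pairs oracle.
* Parallel-segment closest-approach ties resolve to the midpoint witness
  pair (deterministic and symmetric); exactly coincident segments receive a
  random infinitesimal kick, which is counted and reported.
* Bond-crossing audit: a diagnostic detector (orientation-determinant sign
  flip while segments are close with interior witnesses) that monitors
  unphysical pass-throughs without correcting them.
* Degenerate inputs: two-bead filaments carry no bending term; filaments
  shorter than 11 beads split the fixed 1.5 pN push over their current bead
  count; empty candidate pools (crosslink seeding, branch nucleation) are
  skipped and logged.

## Known limitations

Desk-scale results are qualitative by design (see above). The dynamic
crosslinker scheme does not satisfy detailed balance (links are inserted at
a capped rate and removed exponentially), which is acceptable for the
steady-flow questions the model addresses but would bias equilibrium
ensembles. The adhesion is a friction region, not a molecular clutch with
load-dependent bonds, so stick-slip phenomena are out of scope.
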