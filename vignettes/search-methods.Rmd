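---
title: "Diversity-guided swarm search for flexible ligand docking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diversity-guided swarm search for flexible ligand docking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swarmdock)
```

## The problem

Flexible ligand docking searches for the translation, orientation and
internal torsion angles that place a small molecule into a rigid
receptor's binding site at minimal energy. The decision vector (the
*genotype*) is `7 + Ntor` real numbers: 3 translation components in
Angstrom, 4 quaternion components encoding the rigid-body rotation, and
`Ntor` torsion angles in radians, wrapped into `[-pi, pi)`. The
landscape is rugged and high-dimensional, so docking engines pair a
stochastic global search with a gradient-free local search. This
package implements one such hybrid: random drift particle swarm
optimization (RDPSO) with a two-phased diversity control strategy
(2PDC) and Solis-Wets local search, abbreviated DGLRDPSO, plus two
baselines run under the same harness (LPSO, an inertia-weight particle
swarm, and LRDPSO, the plain RDPSO hybrid).

## The search algorithms

**Canonical PSO (LPSO baseline).** Each of `M` particles carries a
position `X`, velocity `V` and personal best `P`; the best of all
personal bests is `G`. The velocity update is
`V <- w V + c1 r (P - X) + c2 R (G - X)` with fresh uniform draws `r, R`
per particle and dimension, followed by a componentwise clamp to
`[-Vmax, Vmax]` where `Vmax` is half the dimension's range. The inertia
weight `w` decreases linearly from 0.9 to 0.4 over the run and
`c1 = c2 = 2.05`.

**RDPSO.** The velocity is the sum of a *random* component
`alpha |C - X| phi` with `phi ~ N(0, 1)`, where `C` (the *mbest*) is the
mean of all personal bests, and a *drift* component `beta (p - X)`
toward the particle's local attractor
`p = gamma P + (1 - gamma) G`, `gamma ~ U(0, 1)` per dimension. The
thermal coefficient `alpha` anneals linearly from 0.9 to 0.3 and
`beta = 1.45`; the same `Vmax` clamp applies.

**Two-phased diversity control.** Swarm diversity is the normalized
mean distance from the centroid,
`D = (1/(M A)) sum_i ||X_i - mean(X)||`, with `A` the diagonal of the
search box. The controller keeps `D` inside a corridor:

* a lower bound decaying linearly from `0.75 D(X1)` to `0.002 D(X1)`
  across the iteration horizon (`D(X1)` is the diversity of the initial
  swarm);
* when `D` drops below the bound the swarm switches to a *divergence*
  phase with inflated coefficients `alpha = 9 / Dr`,
  `beta = 3 / Dr^0.7` where `Dr = D / D(X1)`, which scatter the
  particles until `D` recovers to `0.95 D(X1)`;
* if, instead, a convergence phase fails to descend to the bound for
  more than `accr` (0.003) times the horizon, an *acceleration*
  contraction replaces every personal best by its local attractor
  (one re-evaluation per particle).

A fully collapsed swarm (`Dr = 0`) would make both formulas divide by
zero and the random velocity vanish; we cap `Dr` at `1e-6` and inject a
uniform jitter of `1e-6` of each range in that degenerate case.

**Solis-Wets local search.** Applied once per iteration to the particle
with the best current fitness. It draws a deviate with components
`N(bias, rho)`, tries the forward and reverse moves, accepts only
improvements, and adapts: after 4 consecutive successes the step `rho`
doubles, after 4 consecutive failures it halves; it stops below
`rho = 0.01` or after 300 iterations. The classical bias-vector
variant is used (`0.2 bias + 0.4 delta` on forward success,
`bias - 0.4 delta` on reverse success, halved on failure), since the
adaptive-step rule above presumes it. Improvements are written back
Lamarckian-style: the particle's position, its personal best (when
better) and the global best are all updated. `rho` is a single scalar
in native genotype units; the initial value 1.0 is configurable because
published descriptions leave it open.

## Scheduling choices

The evaluation budget (default 2.5 million, production scale; the test
suites use 50 000) counts every objective call: swarm sweeps, local
search trials and acceleration re-evaluations. Two derived quantities
need care:

* **Iteration horizon.** The lower-bound schedule needs a horizon
  `n_max`; we use `ceiling(budget / M)`, the iteration count the budget
  would allow if only swarm sweeps consumed it.
* **Schedule clock.** Because the local search also draws on the
  budget, a run ends well before `n_max` iterations. Driving the
  schedules by the raw iteration index would leave the thermal
  coefficient and the diversity floor permanently stuck near their
  early-run values — the run would end while still exploring. We
  therefore advance the schedules by the *fraction of budget consumed*
  (`n_sched = n_max * evals / budget`, never behind the iteration
  index), so every schedule completes exactly when the budget runs out,
  and reduces to the iteration index in the no-local-search limit.
  This is the one place the driver interprets rather than transcribes
  its sources; with it, late iterations exploit properly and the final
  poses are measurably tighter.

Ties in the personal-best update keep the incumbent, the best particle
for local search breaks ties by lowest index, and one RNG stream (drawn
particle-major, dimension-minor) drives each run, so runs are exactly
reproducible from their seed.

## The surrogate docking problem

The objective mirrors the classic grid-map architecture. Receptor atoms
are precomputed into per-atom-type affinity maps plus an electrostatic
map on a regular lattice (default spacing 0.375 Angstrom) covering the
search box; scoring a pose applies the torsion tree (innermost branch
first, so every rotation axis is used in its reference frame), the
quaternion about the first root atom, the translation, then sums
trilinear interpolations at each atom plus a pairwise internal energy
over ligand atoms three or more bonds apart. The *docked energy*
(optimized) is grid energy plus internal energy; the *binding score*
(used to rank final conformations) replaces the internal energy with a
torsional penalty `0.3 * Ntor`.

The force field is deliberately simple and is **not** a calibrated
semi-empirical model: five atom types (C, N, O, H, X) with tabulated
well depths and radii, Lorentz-Berthelot-style mixing, a
distance-dependent dielectric `eps(r) = 4r` for the Coulomb term, and a
Mie `(m, n)` dispersion-repulsion pair term normalized so its minimum
is `-eps` at the contact distance `req` for any exponent pair. The
*maps* use soft `(4, 2)` exponents rather than the classic `(12, 6)`
(which the ligand's internal energy keeps): wider wells give the
stochastic search a broader catchment per dimension, which compounds
across the 7-13 genotype dimensions of the desk-scale problems this
package targets. Node values are capped (default 10 energy units) so
near-clash regions stay finite and navigable; atoms outside the grid
each add a `1e5` penalty, which keeps the objective finite everywhere
and steers the swarm back into the box.

## Synthetic re-docking fixtures

`generate_fixture(seed, n_torsions)` builds a self-contained case:

* a **ligand**: a self-avoiding random 3-D chain of
  `4 + 2 Ntor` atoms (1.5-Angstrom bonds, tetrahedral angles, random
  dihedrals) with a rigid 4-atom root and one nested 2-atom branch per
  rotatable bond. Random dihedrals make the shape chiral and
  asymmetric, so no rigid motion maps the chain onto its own reversal
  — without this, every fixture has a mirror basin of nearly equal
  energy and pose recovery is ill-posed;
* a **receptor**: a dense shell of atoms placed at pair-equilibrium
  distance around a randomly drawn reference pose, graded
  hierarchically — the rigid root is lined with the deepest sites and
  the chain tip with the shallowest, which funnels searches to agree on
  the root placement first and then collect per-branch rewards;
* **maps** over a focused cubic box (the reference conformation's span
  plus 4 Angstrom — a focused-box convention when the site is
  known), and
* a **reference genotype** that is the energy minimum itself: the
  moulded pose is polished (simplex descent plus repeated stochastic
  descents), probe searches then look for deeper basins, and the
  deepest polished minimum found is adopted as the reference.

Fixtures are *certified*, not assumed: the reference must score below
the 5th percentile of 200 uniformly random genotypes (and below zero),
its torsions must sit clear of the wrap edges, and independent probe
searches must agree on the reference basin — 5 of 6 within 1.5
Angstrom for fixtures with up to 4 torsions, a 3-of-6 majority within
2.0 Angstrom for 5-8 torsions (where endpoint scatter grows), and no
quota above 8 torsions. A candidate failing
any check is discarded and rebuilt from a fresh internal sub-seed, so
the shipped fixtures are by construction cases on which re-docking is a
well-posed question at desk scale. Fixtures are deterministic in their
seed, round-trip losslessly through the PDBQT-subset and map text
formats, and are small enough to regenerate at test time.

What these fixtures do **not** emulate: real chemistry (idealized bond
geometry, no rings, no hydrogens as written), the calibrated
directional hydrogen-bond and desolvation terms of production scoring
functions, receptor flexibility, and the broad, glassy near-degeneracy
of real binding-energy landscapes. Passing the pose-recovery suite
shows the search machinery works on a certified funnel at a 50 000
evaluation budget; it does not predict production success rates on
crystallographic complexes, which use 50 times that budget on much
harder landscapes.

## Evaluation conventions

`rmsd()` is the plain coordinate root-mean-square deviation over
matched atom pairs — no superposition, no symmetry correction (fixture
atoms are uniquely labelled; symmetry-aware RMSD is out of scope). A
run is a *success* when its final pose is within 2.0 Angstrom of the
reference (ties count). Per-case batches report `NS` (successes out of
`R` runs, default 30), the mean and best docked energy, `ME` (mean
binding score), `LE` (lowest binding score among successful runs,
undefined when `NS = 0`) and the rank of the `LE` conformation among
all `R` sorted by binding score (ties broken by run index), recorded as
`R + 1` when no run succeeded. `dref()` subtracts the per-case
reference (minimum) value, so the best algorithm scores 0.

## Numerical and design notes

* Quaternions are treated as four ordinary bounded dimensions during
  swarm updates and renormalized by `repair()` after every move (an
  all-zero quaternion resets to the identity). Diversity and the
  diagonal `A` weigh all dimensions equally, including the quaternion
  block.
* Non-periodic dimensions are clipped to the box after a step; torsions
  wrap. Clipping keeps diversity bounded by the box so the divergence
  exit threshold stays reachable.
* During divergence, fitness is still evaluated and the best-position
  bookkeeping still runs; those evaluations count against the budget.
* Acceleration applies on every iteration the trigger condition holds,
  including in the first convergence phase.
* The internal-energy exclusion is 1-2 and 1-3 bonded pairs; 1-4 and
  beyond enter unscaled.
* Bonds are not part of the PDBQT subset; the parser reconstructs them
  with a 1.9-Angstrom distance cutoff, exact for the idealized
  geometries the generator emits.
* Problem sizes in the test suite: swarms of 10-50 particles, budgets
  of a few thousand evaluations for behavioral checks, and the full
  benchmark protocol (M = 50, 50 000 evaluations, 30 repeats, 2- and
  6-torsion fixtures) for pose recovery.

## Known limitations

Pose identifiability degrades quickly with flexibility. At 2 torsions
(9 genotype dimensions) the benchmark protocol (swarm of 50, 50 000
evaluations, 30 repeats) recovers the reference pose in the large
majority of runs; at 6 torsions (13 dimensions) run endpoints scatter
over several quasi-degenerate packings of the chain and only a minority
of runs land within 2 Angstrom, even though the mean docked energy
still favours the diversity-guided hybrid over plain LRDPSO. This
mirrors the drop in success rates that docking studies report for
flexible ligands, amplified here by a budget roughly 50 times below
production scale. Fixtures with more than ~8 torsions are generated
and certified for funnel shape but carry no recoverability quota at
all. The LGA (genetic algorithm) baseline, simulated annealing,
neighbourhood swarm topologies and receptor flexibility are out of
scope.
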