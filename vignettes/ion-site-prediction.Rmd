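---
title: "Predicting surface-bound ion positions: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting surface-bound ion positions: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionsite)
```

## The problem

Ions that bind protein surfaces non-specifically — electrostatically, with
short residence times and no coordination chemistry — matter for protein
stability, effective net charge, pH response and binding interfaces, yet
they are elusive experimentally: crystallographic occupancies are low and
some observed ions are packing or cryo-salt artifacts. `ionsite` predicts
candidate positions for such ions from a continuum-electrostatics energy
balance: how strongly does the protein's field attract the ion, versus how
much solvation the ion must give up to approach the surface.

## Model

### Smooth dielectric

Instead of a hard molecular surface, every atom carries a Gaussian density
$g_i(\mathbf r) = \exp(-|\mathbf r-\mathbf r_i|^2/\sigma^2 R_i^2)$, where
$R_i$ is its van der Waals radius and $\sigma$ a dimensionless width. The
solute density $g(\mathbf r) = 1-\prod_i\bigl(1-g_i(\mathbf r)\bigr)$
blends two reference permittivities,
$\epsilon(\mathbf r) = g\,\epsilon_{in} + (1-g)\,\epsilon_w$. The
permittivity is therefore a smooth, bounded field: exactly
$\epsilon_{in}$ wherever some $g_i = 1$, bulk water beyond roughly
$6\sigma R$ of every atom, and continuous in between. There is no surface
to construct and no cavity-assignment ambiguity.

### Modified Poisson–Boltzmann equation

With no sharp boundary there is also no hard ion-exclusion region, so the
mobile-ion term must be prevented from placing charge inside the solute.
The package solves

$$\nabla\cdot\epsilon(\mathbf r)\nabla\varphi(\mathbf r)
  = -4\pi\Bigl[\rho_{solute}(\mathbf r)
  + \sum_i q_i c_{bulk} e^{-(q_i\varphi + \Delta G_{solv})/RT}\Bigr]$$

where the Born-style desolvation penalty of a mobile ion of valence $z$
and effective radius $r_0$,

$$\Delta G_{solv}(\mathbf r)
  = \frac{N_A z^2 e^2}{8\pi\varepsilon_0 r_0}
    \Bigl(\frac{1}{\epsilon_r(\mathbf r)} - \frac{1}{\epsilon_w}\Bigr),$$

enters the Boltzmann factor: the local ion density is suppressed smoothly
as the local dielectric drops, and vanishes in the solute body (at
$\epsilon_r = 2$, $\Delta G_{solv} \approx 40$ kcal/mol for $z = 1$, a
Boltzmann weight below $10^{-29}$). The exponent is implemented as
$\exp[-(q_i\varphi + \Delta G_{solv})/RT]$ — the penalty always reduces
local density — which is the reading consistent with the site energy
below, where the same two terms add.

### Site energy and ranking

After solving for $\varphi$ (in kT/e), every grid node outside the van der
Waals surface is scored by

$$G(s) = q_{ion}\,\Phi(s) + \Delta G_{solv}\bigl(\epsilon_r(s)\bigr)$$

with $\epsilon_r(s)$ the arithmetic mean of the six grid-edge midpoint
permittivities around the node. Only negative-$G$ sites are kept; a binary
min-heap pops them in energy order through two filters: a steric test
(discard when closer than $R_{ion}+R_{atom}$ to any atom; the boundary
case passes) and a mutual proximity test (accepted sites must be more than
6 Å apart, about two ion diameters). Survivors get ranks $1, 2, \dots$ up
to the requested maximum.

## Parameters

| parameter | default | units | meaning / why this value |
|---|---|---|---|
| `scale` | 2 | grids/Å | resolution/speed tradeoff of the production method |
| `perfil` | 70 | % | solute fill of the cubic box; boundary far enough for the Debye–Hückel condition |
| `eps_in` | 2 | — | solute reference dielectric (electronic polarisation only) |
| `eps_w` | 80 | — | bulk water |
| `sigma` | 0.93 | — | Gaussian width; the conventional value in smooth-dielectric PB practice. Results depend on it, so it is exposed |
| `salt` | 0.5 | mol/L | 1:1 bulk electrolyte; the value at which the method performs best in its calibration range (0.1–0.5 M) |
| `ion_radius` (`r0`) | 2.0 | Å | single effective Born radius for cations and anions |
| `clash_radius` | 2.0 | Å | steric ion radius; defaults to `r0` since no separate value is established |
| `temperature` | 298.15 | K | standard laboratory temperature |
| `tolerance` | 1e-4 | kT/e | max per-sweep potential update at convergence |
| `min_sep` | 6 | Å | mutual separation of accepted sites |

The four built-in species are Ca²⁺, Mg²⁺, Zn²⁺ (z = +2) and Cl⁻ (z = −1);
`ion_spec()` accepts any valence for custom species.

## Numerical choices

- **Grid.** Vertex-centred cubic lattice, 0-based indexing, node count
  forced odd so a central node exists. The box side is the solute's
  largest radius-inclusive extent divided by `perfil`/100, rounded up to a
  whole number of spacings; including radii means the fill fraction
  measures the solute body, not just atom centres.
- **Permittivity staggering.** $\epsilon$ is evaluated at edge midpoints
  (three staggered arrays) because the flux-conservative 7-point stencil
  needs face values; the six-midpoint average reused by the site energy
  comes from the same arrays.
- **Charges.** Trilinear (cloud-in-cell) spreading to the 8 surrounding
  nodes; total grid charge equals the structure's net charge to 1e-12.
- **Boundary condition.** Screened-Coulomb superposition
  $\sum_a q_a e^{-\kappa d_a}/(\epsilon_w d_a)$ on the box faces, with
  $\kappa$ from first principles ($\kappa^{-1} \approx 4.34$ Å at 0.5 M,
  298.15 K, $\epsilon_w = 80$).
- **Relaxation.** Gauss–Seidel with over-relaxation $\omega = 1.85$ in
  linear mode; plain sweeps ($\omega = 1$) with one local Newton step per
  node visit in nonlinear mode. Non-convergence within the sweep budget is
  flagged on the result and warned about, never silent. A typical 65³
  linear solve converges in ~200 sweeps.
- **Linear vs nonlinear.** The ranking consumes only $\varphi$, and the
  production method's mode is not established, so the linearised equation
  is the default; the nonlinear mode is provided and agrees with the
  linear one wherever the potential is weak. (For a bare point charge with
  no exclusion region the two genuinely diverge near the charge — the
  classic counterion-collapse behaviour — which is physics, not a solver
  artifact.)
- **Ties and determinism.** Equal site energies are ordered by
  lexicographic grid index (x, then y, then z); the same rule is used by
  the Coulomb placer, so identical inputs always give identical outputs.
- **Filters.** Strict inequalities follow the algorithm's stated forms:
  discard when $r_{S,A} < R_{ion}+R_{atom}$ (so the boundary case is
  kept), accept when separation $> 6$ Å.
- **No sub-grid refinement.** Candidate sites are grid nodes and $\Phi(s)$
  is the node value, not an interpolation — the ranking operates on the
  solver's own lattice.
- **Degenerate inputs.** A zero-charge solute gives $\varphi \equiv 0$
  and, since $\Delta G_{solv} \ge 0$, an empty site list — empty output is
  a valid result, distinct from failure.

## Synthetic fixtures: what they do and do not show

All tests run on generated structures with known analytic behaviour, none
larger than a 65³ grid at the default resolution:

- `make_born_ion()` — a single charged atom; exercises the Coulomb,
  Debye–Hückel and Born limits against closed forms.
- `make_dipole()` — a neutral two-charge system; superposition and
  far-field decay.
- `make_charged_patch()` — a slab of uncharged atoms with one charged
  face atom and a seeded jitter; ground truth for directional recovery
  (a counter-ion's rank-1 site must sit on the patch side at the first
  allowed shell; a like ion must stay away).
- `make_random_cluster()` — seeded random geometry and charges for
  property tests (symmetries, round trips, oracle equivalence).
- `make_buried_pocket()` — a cup of large beads with a charged bead at
  the bottom and a blocking base. Its defining property, verified by a
  test, is that clash-allowed pocket positions see a substantially
  lowered dielectric (≈41 against ≈79 outside) while being the solute's
  closest-approach region. This separates the two terms of $G(s)$: pure
  electrostatics pulls the ion into the pocket, desolvation pushes it
  out. The contrast experiment runs at 0.1 M salt — within the method's
  calibration range — because at 0.5 M the exterior sites' screened
  potential no longer clears the negative-energy threshold, and an empty
  list would show nothing.

These fixtures probe limits, invariants and algorithmic identity, not
biological realism: they contain no backbone geometry, no heterogeneous
charge distribution at physiological density, and far fewer atoms than a
protein. Passing them shows the machinery is implemented correctly — the
discretised operator reproduces the continuum limits, the ranking equals
an exhaustive scan, the filters and symmetries hold exactly — not that
predictions on real proteins reach any particular accuracy. That question
requires an experimental benchmark, which is outside the package's test
scope.

Grid sizes in the tests were chosen at desk scale on purpose: the two
closed-form solver checks run at 65³ (the production resolution over a
32 Å box), the oracle-equivalence checks at ≤33³ where an exhaustive scan
is exact and fast, and the metric property checks on 1000 random sets.

## The Coulomb baseline

`place_ions()` emulates the ion placement of molecular-dynamics setup
tools: a uniform-dielectric ($\epsilon = 80$) unscreened Coulomb map,
greedy placement at the minimum of $q_{ion}\varphi$ among nodes more than
6 Å from the van der Waals surface, the map updated with each placed ion's
own contribution. It exists to quantify what the PB + desolvation
treatment adds; it is a spec-level emulation, not a bit-for-bit
reproduction of any particular tool. On the buried-pocket fixture the
baseline and the full method choose different sites, and zeroing the
desolvation term (`desolv_weight = 0`) moves the full method's rank-1 into
the pocket — onto the node the Coulomb criterion picks when granted the
same surface access — demonstrating that the disagreement is attributable
to desolvation, not to the solver.

## Evaluation metrics

`rank1_distance()` is the Euclidean distance from the rank-1 site to the
nearest reference position; `d_min()` is the minimum over the top-k
(default 10) predictions and all references, with the achieving rank
recorded. With several references around one structure the closest is
credited, and `d_min()` also reports a per-reference view (best rank and
distance for each reference), since a single global minimum can hide how
secondary ions are matched. `best_of_n()` implements the protocol for
comparing against an unranked placer that emits N ions: each method is
credited with its best among its first N outputs.

## Known limitations

- Candidate scan covers every exterior node; no near-surface shell
  restriction, so very large boxes cost accordingly.
- One $\sigma$ for all atom types; no super-Gaussian variants, no cavity
  heuristics.
- A single effective ion radius (2 Å) for both Born penalty and steric
  test; species-specific fitted radii are out of scope.
- PQR content is taken as authoritative: no protonation assignment, no
  force-field parameterisation, no PDB→PQR conversion.
- The solver supports neither focusing/multigrid acceleration nor
  periodic boundaries or membrane slabs.
- Specifically coordinated ion sites (geometry/chemistry driven) are a
  different problem and are not predicted by this energy function.
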