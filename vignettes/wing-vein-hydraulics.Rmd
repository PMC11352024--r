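---
title: "Hydraulic circuit analysis of wing vein networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydraulic circuit analysis of wing vein networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(veinflow)
```

## The physical model

Hemolymph flow through a wing's vein network is modelled as steady,
incompressible, Newtonian Poiseuille flow in a planar graph of rigid
cylindrical conduits. The assumptions, and why they are defensible at
wing-vein scale:

* **Creeping flow.** With lumen diameters of order 10 µm, velocities of
  order 100 µm/s, hemolymph density 1.02 × 10³ kg/m³ and viscosity
  1.3 × 10⁻³ Pa·s, the Reynolds number is below 10⁻³
  (`reynolds_number()`). Inertial ("minor") losses at bends and
  junctions are smaller than frictional losses by several orders of
  magnitude and are ignored by construction.
* **Linearity.** Each vein is a hydraulic resistor,
  `r = 128 μ l / (π d⁴)` (`poiseuille_resistance()`), so the network is
  a linear resistive circuit and superposition holds.
* **Rigid, fluid-filled conduits.** Vessel compliance, pulsatility and
  partial filling are out of scope; the boundary condition is a fixed
  volumetric inflow with the outlet grounded at zero pressure.

The quantity of interest is the total inlet-to-outlet frictional loss
`Δp_total` at fixed inflow `Q_in`: it is proportional to the pumping
power the thoracic wing hearts must supply.

## Two solvers, one contract

`solve_nodal()` assembles the conductance Laplacian over node pressures,
grounds the outlet, injects `Q_in` at the inlet and solves the dense
system directly (networks here have at most a few dozen nodes, so a
dense LAPACK solve in double precision is both simplest and fastest).
Loop-sum consistency is automatic; mass conservation holds to solver
precision.

`solve_mesh()` is the dual loop-current formulation: a spanning tree is
built by union–find, every chord defines a fundamental closed loop, and
Kirchhoff's voltage law over the loop flows gives a symmetric
positive-definite system; the boundary inflow enters as a known loop
current through a virtual source edge. Mass conservation is automatic;
loop sums hold to solver precision.

The two implementations share no linear-algebra route, so their
agreement (tested to 10⁻⁸ relative on more than one hundred seeded
random ladders) is a genuine cross-check, not a tautology. Further
invariants under test: node balance below 10⁻⁹·`Q_in`, loop sums below
10⁻⁹·`Δp_total`, the energy identity `Δp_total·Q_in = Σ r_n q_n²` to
10⁻⁸ relative, invariance under channel reordering and uniform
resistance rescaling, and Rayleigh monotonicity (inserting a crossvein
never increases `Δp_total`).

**Degenerate inputs.** Channels may carry zero resistance in the data
model (a zero-length segment), but both solvers refuse to solve a
network containing one (`veinflow_degenerate_network_error`) rather than
risk a singular or ill-posed system; the repositioning module simply
drops zero-length sub-segments before solving. A disconnected
inlet–outlet pair raises `veinflow_singular_network_error` at
construction. Singularity during the solve itself (e.g. an isolated
subcomponent) is caught and rethrown with the same class.

## The measured wing model

`cyrtoloma_veins()` ships the 25-vein morphometric table (lengths, outer
diameters, lumen diameters, all in mm); `cyrtoloma_topology()` the
ladder graph: edge and base rails of seven veins sharing anterior
(inlet) and posterior (outlet) terminals, six connecting-vein rungs, and
the two crossveins meeting at the cruciform node X. Inner diameters are
the printed per-vein values rather than recomputed as 20% of the rounded
outer diameters — recomputation would discard precision (the fifth base
vein's lumen, for instance, is 7.9 µm, not 8.0). The 20% convention is
still validated on read, as a warning, with a 5% slack matching
two-significant-figure rounding.

Defaults reproduce the published study conditions: viscosity
1.3 × 10⁻³ Pa·s, density 1.02 × 10³ kg/m³, inflow 12 pl/s (the common
fruit fly's assumed rate scaled isometrically by `k³`). The table's
two-significant-digit printing means headline results are reproducible
only to input-rounding propagation, roughly 1–2%: the package computes
0.630 kPa for the crossvein-ablated loss (published rounding: 0.62),
a 3.09% reduction (3.1), a crossvein share of 0.145·`Q_in` (0.14) and a
posterior-crossvein gain of 29.7% (30). Beyond rounding, the 20%
diameter and 1.4% length measurement errors imply computed resistances
between 0.48 and 2.5 times the true values
(`resistance_uncertainty_bounds()`); all comparative statements
(reductions, flow shares, minima locations) are far more robust than
absolute pressures.

`compare_flows()` classifies per-vein changes with a zero-flow threshold
defaulting to 0.1% of `Q_in` (configurable); a direction reversal is
flagged only when both compared magnitudes exceed the threshold, so
numerical noise around zero cannot masquerade as a reversal. Reported
values are rounded (two significant figures) only at presentation —
summaries and logs — never internally.

## Repositioning the crossvein: a calibrated stand-in geometry

Moving the crossvein's connections requires planar coordinates, which
the measured table does not contain. The package's default
(`reposition_geometry()`) is the minimal geometry preserving every
published constraint: the fourth and fifth connecting veins as parallel
straight segments (lengths 4.7 mm and 4.6 mm, the sums of their measured
halves), aligned at their base-side endpoints, with the rail separation
calibrated (0.6185 mm) so the straight crossvein at the actual
connection fractions (a, p) = (0.486, 0.506) has its measured 0.62 mm
length. The posterior-crossvein junction is fixed at fraction
x_pcv = 0.506 — coincident with the crossvein's actual posterior
connection, which is the cruciform contiguity itself. Sub-segments keep
their parent's diameter; every resistance is recomputed from length at
fixed diameter; all other veins keep their measured lengths.

Consequences, verified in tests:

* At the actual position the repositioned network recovers the baseline
  wing model's loss to ~0.01%, and the normalized loss (relative to the
  crossvein-free network) is 0.969 — the 3.1% benefit.
* For `p ≠ x_pcv` a transfer segment of length `|p − x_pcv|·l_C5`
  carries the bypass flow between the crossveins, adding a loss that
  grows with its length (tested with the crossvein length held fixed to
  isolate the effect). This makes contiguity (`p = x_pcv`) a valley
  minimum with a discontinuous gradient, at every anterior position
  sampled.
* The normalized loss decreases monotonically as the anterior connection
  moves toward the edge rail (increasing a) at `p = x_pcv`.

**Known limitation.** Because the true coordinates are unpublished,
surface *values* away from the actual position carry geometry-model
uncertainty even though the minimum's location does not. In this
stand-in geometry, for extreme anterior displacements (a ≤ 0.15, far
from the actual 0.486) a far-distal posterior connection undercuts the
contiguous one by under 0.3 points of normalized loss; the contiguity
valley remains a local minimum everywhere. Tests therefore assert the
valley at every sampled a and the global minimum for a ≥ 0.2. The full
published sweep resolution (0.001 steps, ~10⁶ solves) is supported but
tests and examples use 0.01–0.05 steps for runtime; a full 99 × 99
idealized sweep takes about a second.

## Idealized microchannel circuits

`build_idealized()` abstracts the crossvein-bearing wing region into a
four-section ladder of 2 mm, 10 µm-bore microchannels (connecting halves
1 mm), so every full channel has reference resistance `R` and every half
`0.5 R`. The uniform variant has exact rational solutions, which the
tests pin to 10⁻¹⁰: without the crossvein resistor the
posterior-crossvein resistor carries exactly `Q_in/4` and the loss is
`1.875 R·Q_in`; with it, the crossvein diverts `2Q_in/7`, the fifth
connecting resistor falls silent, the loss is `(12/7) R·Q_in`, and the
reduction is `6/70` = 8.6%.

Two variants probe why the real wing's sweep surface is valley-shaped
where the uniform circuit's is symmetric: `asymmetric` sets the fifth
base channel to `0.2 R` and the sixth edge channel to `200 R` (the
extreme resistances of the corresponding wing region), and
`asymmetric_highC` additionally raises the fourth and fifth connecting
halves to `10 R` (the connecting veins' tenfold resistance relative to
the crossvein; each *half* is set to `10 R` at its initial 1 mm length,
scaling with length thereafter — the published statement names the
halves). Variant overrides are applied directly as resistance values:
physically they would be realized by diameter changes, but only the
resistance enters the linear system. During sweeps the rungs are
parallel segments one channel-length apart, the crossvein's length is
the Euclidean distance between its connections, and the
posterior-crossvein junction stays at the fifth rung's midpoint (by
analogy with the wing's fixed junction; the published minimum-location
statements, which this choice reproduces, are the arbiter). Measured
orderings confirm: uniform sweeps are symmetric under
`(u, v) → (1−u, 1−v)` with their minimum at the initial midpoint
position, every variant's outlet-side minimum sits at the junction, and
the valley steepness (`valley_steepness()`) orders
uniform < asymmetric < asymmetric_highC.

## Allometry and the crossvein's mass cost

The wing-area ratio 8.3 between the Hawaiian and common fruit fly gives
the linear factor `k = sqrt(8.3) = 2.88`, printed as 2.9. The package
keeps `k` at full precision by default and exposes the printed-rounding
convention as an explicit override (`allometry_report(k = 2.9)`),
because the published 65 µg wing mass arises under the rounded
convention (2.7 µg × 2.9³ = 65.9) while full precision gives 64.6 µg;
both round to the same 1.2% relative crossvein cost. The crossvein's
mass is lumen (hemolymph, 1.02 × 10³ kg/m³) plus wall (cuticle,
1150 kg/m³) volume from its measured geometry: 0.027 µg + 0.74 µg here
versus 0.028 + 0.77 published — mass tests use 5% relative tolerance,
reflecting two-significant-digit inputs (the unrounded dimensions behind
the published wall mass are not recoverable). The `k³`-scaled inflow
implies a common-fly reference rate of ~0.5 pl/s, reported for
consistency.

## What the synthetic generator does and does not emulate

`random_ladder()` draws shared-terminal ladders with log-normal lengths
(location log 1.0 mm, scale 0.8) and lumen diameters (location
log 9.6 µm, scale 0.6), chosen once to bracket the measured wing's
ranges (0.16–5.0 mm, 2.9–32 µm); outer diameters follow the 20% rule.
Crossveins can be inserted between rung midpoints, splitting each rung
at a chosen fraction. Seeds are mandatory and fully determine the
output; generated values are stored at six significant digits so a
write/read round trip through the delimited format is exact.

The generator emulates the *structure* the analysis assumes — connected
planar ladders with realistic resistance spreads (about four orders of
magnitude across channels) — not real venation: no spatial embedding, no
correlation between neighbouring veins, no Murray-law-like taper.
Passing property tests therefore certify the solvers and conservation
laws on this family of graphs, not any biological claim about real
wings; the biological claims rest on the measured table.

## Numerical choices

* Dense direct solves; condition failures surface as classed errors
  rather than silent garbage.
* Sign convention: flow is positive from `node_a` to `node_b`; reported
  directions derive from the sign.
* Units: geometry enters in mm (µm for idealized bores) and is converted
  to SI at ingestion; pressures are reported in Pa/kPa and flows in pl/s
  and as fractions of `Q_in`.
* Sweep fast paths reuse the assembled node indexing and update only the
  affected resistances per grid cell, but call the same grounded-
  Laplacian kernel as `solve_nodal()`, so no second code path needs
  validating.
* Test problem sizes: property loops run 100 seeded ladders of 3–6
  rungs; sweep assertions use 0.01-step grids for the idealized circuits
  and 0.05-step (junction-including) grids for the wing repositioning.
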