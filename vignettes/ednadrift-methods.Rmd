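---
title: "Methods: backtracking eDNA source areas and filtering metabarcoding detections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: backtracking eDNA source areas and filtering metabarcoding detections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ednadrift)
```

## The problem

A positive eDNA detection in a water sample is displaced in space and
time from the animal that shed the DNA: tidal currents move a water
parcel tens of kilometres in the days between shedding and sampling.
`ednadrift` treats detected eDNA as a passive tracer and asks where the
water that arrived at the station at the sampling instant could have
been during the preceding decay window. Two largely independent
components feed the answer: a Lagrangian backtracking simulator over
depth-averaged current fields, and the detection-filtering chain that
turns a raw ASV read-count table into defensible presence calls.

## Transport model and its assumptions

Particles obey d**x**/dt = **u**(**x**, t) with the depth-averaged
current **u**. The assumptions this encodes:

* **Well-mixed, shallow water.** Depth-averaged (2-D) currents are a
  good transport proxy where the water column is vertically well mixed
  and the tracer near-neutrally buoyant. The model is not suitable for
  stratified deep water.
* **Passive transport, no added diffusion.** Particles neither swim nor
  settle, and no stochastic sub-grid mixing is added: dispersal comes
  from resolved shear in the velocity field alone. An optional
  diffusion hook was deliberately left out of the tested surface.
* **A hard decay cutoff, not decay kinetics.** The tracking window
  (default 3 days) is a conservative proxy for eDNA persistence
  (detectability estimates in temperate coastal water are ~48 h); no
  concentration decay is modelled inside the window, and every recorded
  position counts equally in downstream products.

### Backtracking

Backtracking is implemented by time reversal: `reverse_field()` negates
both velocity components and mirrors the time axis, re-anchoring it at
zero, so the tracker always integrates forwards. The trajectory record
at elapsed 0 is the arrival constraint — particles sit within the
release disc at the exact sampling time — and elapsed τ means "τ seconds
before sampling". Reversal preserves speed everywhere, and
forward-advecting backtracked endpoints through the original field
returns them to their release positions (this inversion closes to well
under a metre on the synthetic bay; the acceptance checks allow 50 m).

### Release protocol (defaults and units)

| parameter | default | meaning |
|---|---|---|
| `n_particles` | 1000 | particles per release |
| `radius` | 200 m | release disc; covers station-position and model-resolution uncertainty |
| `duration` | 259,200 s (3 d) | decay-proxy tracking window |
| `record_interval` | 300 s | recording cadence (5 min, the hindcast output cadence) |
| `dt` | 60 s | RK4 step; must divide `record_interval` |
| `seed` | 1 | controls the release draw; trajectories are then deterministic |

Release positions use the square-root radial transform
(r = R√U, θ = 2πU′), giving uniform areal density over the disc.

## Numerical choices

* **Interpolation.** Bilinear in space between grid nodes, linear in
  time between stored steps. Node values are recovered exactly; the
  scheme is continuous across cell interiors. At the coast, dry nodes
  get zero weight and the remaining weights are renormalised, so land
  never drags the interpolated velocity; an all-dry neighbourhood
  samples to (0, 0).
* **Integrator.** Fixed-step classical RK4. It is exact for uniform
  fields, integrates the time-interpolated tide to machine-level net
  displacement over integer periods, and shows 4th-order behaviour:
  halving `dt` from 60 s moves 3-day endpoints by far less than a metre
  in the tidal test fields. Determinism (bit-reproducible trajectory
  sets under a fixed seed) was preferred over adaptive stepping.
* **Boundary policy.** A particle whose RK4 step lands on a dry cell is
  flagged `beached`; one leaving the grid bounding box is
  `out_of_domain`. Either way it freezes at its last valid position and
  its frozen records continue to count in density and connectivity
  tallies — this keeps particle numbers conserved, which is what makes
  the heatmap sum exactly 100%. Status transitions are one-way.
* **Grid conventions.** Analysis cells are half-open
  `[origin + i·c, origin + (i+1)·c)`, anchored at the domain lower-left
  corner, 1 km by default. A user-supplied grid is auto-expanded by
  whole cells (anchoring preserved) to cover all positions.
* **Degenerate inputs.** Zero-radius releases collapse to the station;
  a field shorter than the tracking window is a configuration error; a
  campaign release without field coverage is recorded as a per-release
  error without aborting the run.

## Dispersal products

* **Density heatmap**: every particle-record (all particles × all
  recording steps, frozen included) binned on the grid, converted to
  percent of the total so the domain sums to 100.
* **Maximum straight-line distance**: the per-release maximum distance
  of any record from the *station* (not each particle's own release
  point; the difference is bounded by the 200 m release radius), in km.
* **Areal extent**: visited-cell count × cell area. "Surface area
  covered" has no unique definition; the union-of-visited-1 km²-cells
  reading matches the heatmap's framing and is monotone under pooling.
* **Connectivity**: `fraction[i, j]` of station-*i* particles ever
  within 1 km (the heatmap cell scale) of station *j* during the
  window; `fraction > 0` is read as "potentially connected", i.e. the
  two stations may have sampled the same water. The diagonal is 1 by
  construction. Both the radius and the any-visit threshold are
  parameters, since qualitative pair connectivity can be defined either
  on visits or on density.
* **Aggregation**: detection-conditioned statistics are the arithmetic
  mean and sample sd (n − 1) over the releases coinciding with
  detections. Whether to group per station, month, or station × month
  is exposed to the caller (`run_report()` aggregates over distinct
  detection-coincident releases); with a single release the sd is
  reported missing rather than zero.

## The detection-filtering chain

Applied strictly in this order, with per-step attrition logged
(rows dropped, reads removed, cells zeroed):

1. **Paired-control subtraction** — any ASV with ≥ 1 read in a sample's
   own field blank is zeroed in that sample; control columns are then
   dropped. This is deliberately stringent: one leaked read sacrifices
   a real detection rather than risk a false positive. The chain
   supports an optional second subtraction pass at the end (some
   protocols subtract both before and after target filtering); since no
   later filter can increase reads, the second pass is a sensitivity
   switch, off by default.
2. **Target-class filter** — only ASVs class-assigned to the target
   group survive; class-unassigned sequences cannot be confirmed
   in-group and are dropped here (their counts appear in the log).
3. **Singleton removal** — cells with exactly 1 read are zeroed
   per-cell, not per-row, so a taxon can survive via other samples.
4. **Taxonomy rules** — rows must be genus-assigned at ≥ 40%
   classifier confidence (the "moderate" setting); known contaminant
   species are dropped; rows confident to genus but not species are
   retained flagged `genus_only` and excluded from the species-level
   detection matrix. Confidence is consumed as a single per-row value —
   the classifier's output — rather than re-derived per rank.

Anything that survives is a positive detection; extraction and PCR
blanks are screened for target reads and reported but never subtracted
(only the per-sample field blank is a subtraction reference).

Species accumulation curves use sample-based permutation means
(`method = "random"`) or the exact closed form: since the richness of
the first *k* samples depends only on which samples they are,
E[S(k)] = Σ_sp (1 − C(n − m_sp, k)/C(n, k)). The exact method matches
exhaustive order enumeration and vegan's analytic rarefaction;
asymptotic richness extrapolation is out of scope.

## What the synthetic generators emulate — and what they don't

* `make_tidal_field()` reduces the tidal spectrum to a single M2-like
  constituent (44,712 s) plus a residual drift: it preserves the
  oscillation-plus-residual structure that drives dispersal asymmetry,
  not the spring–neap cycle or baroclinic variability.
* `make_bay_field()` builds an enclosed rectangular bay whose interior
  circulation derives from a streamfunction
  ψ = ψ₀ sin(πx/Lx) sin(πy/Ly), modulated by `residual + sin(2πt/P)`.
  Node velocities come from ψ by central differences, so the discrete
  divergence under the matching stencil vanishes identically; the
  one-node border ring is land. Defaults: 30 × 20 km, 500 m resolution,
  0.4 m/s peak speed, 10% residual — peak speeds and excursion scales
  typical of a macrotidal bay. Closed streamlines keep particles
  in-domain, which makes the field a clean test bed for the inversion
  property but means it cannot exercise open-boundary loss (the uniform
  field does that instead).
* `make_survey()` emulates the *output* of a denoising pipeline for a
  10-station × 12-month campaign with one field blank per sample (240
  columns, plus extraction/PCR blanks): planted detections with
  log-normal reads floored at 2, teleost background rows, two
  out-of-region contaminant taxa, one genus-only row at 45% species
  confidence, control leakage, and 1-read singleton noise.
  `detection_prob = 0.09` was set once from the observed order of
  elasmobranch detection rates in temperate coastal surveys (~1 in 11
  species × sample slots); leakage 0.05 and singleton 0.02 are small
  perturbation rates chosen to exercise, not dominate, the filters. The
  generator records every injected artefact and counts, directly off
  the assembled matrix, the cells any correct subtraction and singleton
  rule must zero — so the attrition tests compare two independently
  derived numbers.

Passing tests on these generators show the *algorithms* are correct
(conservation, closed forms, inversion, exact recovery, bookkeeping).
They do not show that real-ocean dispersal estimates are accurate: real
hindcasts have unstructured meshes, wind and river forcing, open
boundaries and spatially varying tides, and real ASV tables have
cross-talk structure, tag jumps and abundance-dependent error that the
read model does not attempt. Headline field results (mean maximum
distances of ~7–15 km, areal extents of tens to hundreds of km²)
require such a hindcast and are outside what the synthetic domain can
or should reproduce.

## Problem sizes

The test suite runs reduced-but-faithful sizes: full 1000-particle
3-day releases where a criterion is about the protocol itself, and
20–200 particles over hours-to-days elsewhere. The acceptance script's
end-to-end campaign uses 10 stations × 12 campaigns × 200 particles at
`dt` = 150 s over the full 3-day window, against a ~5.8-day bay
hindcast whose 12 sampling times sit at distinct tidal phases — the
package's chosen desk-scale stand-in for a year of monthly campaigns
(a year-long 5-min hindcast would be a multi-gigabyte array with no
additional algorithmic content).

## Known limitations

* 2-D only: no vertical structure, no buoyancy, no behaviour.
* The hard 3-day cutoff weights a 71-hour-old record equally with a
  5-minute-old one; concentration-weighted variants would need decay
  kinetics the model deliberately avoids.
* Frozen (beached / out-of-domain) records keep counting in densities;
  under strong onshore flow heatmaps concentrate mass at the coast.
* The structured-grid bilinear interpolation is a stand-in for
  unstructured-mesh hindcasts; land-boundary velocity treatment (weight
  renormalisation) is one defensible choice among several.
* Singleton and control-subtraction rules are deliberately stringent;
  on real data they trade sensitivity for specificity, and the
  attrition log exists precisely so that cost is visible.
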