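---
title: "Methods: volume conduction, montage superposition and ocular-surface locality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: volume conduction, montage superposition and ocular-surface locality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Low-intensity alternating current delivered through skin electrodes around
the eye (tACS at roughly 1 mA and 10 Hz) evokes phosphenes — perceived
flashes whose apparent position tracks the part of the ocular surface that
receives the strongest field. A walking-support application needs *two*
phosphenes presented simultaneously in the lower visual field, which means
two electrode pairs drive neighbouring patches of the lower ocular surface
at the same time. The design questions are then: which pad arrangements
stimulate their intended sub-region *locally*, what relative phase (same or
opposite waveform) the two pairs should use, and how the pair currents must
be balanced when one target (the nasal side) is intrinsically harder to
reach. `ocufield` implements the full simulation pipeline used to answer
these questions on a synthetic head phantom.

## Volume-conduction model

At 10 Hz the tissue is purely resistive to an excellent approximation
(quasi-static regime), so the potential at every instant solves the
conduction equation

$$\nabla \cdot (\sigma \nabla V) = 0$$

with no current through the free skin surface (homogeneous Neumann) and
electrode boundary conditions on the pad contacts. Fields are read out per
element as $\mathbf{E} = -\nabla V$, reported in V/m; the evaluation uses
the element-wise magnitude $|\mathbf{E}|$, which is non-negative by
construction.

Two drive models are provided:

* `solve_pair()` — the pipeline model. The two pads of a pair are fixed
  equipotential surfaces (Dirichlet), the linear solution is then rescaled
  so the net current through the anode contact equals the pair's drive
  current in mA. This reconciles equipotential electrode boundary
  conditions with a current-programmed stimulator.
* `solve_injection()` — a fixed, area-uniform current density over each pad
  contact (inhomogeneous Neumann). Because each pad's load is independent
  of every other pad, solutions of this model superpose *exactly*, which
  makes it the reference for the joint-solve consistency check below.

Units: coordinates in mm, conductivities in S/m, currents in mA, potentials
in volts. With this choice the assembled stiffness matrix maps volts to mA
directly, and gradients convert to V/m with a factor of 1000.

The discretization is a P1 (piecewise-linear) tetrahedral finite-element
method with element-constant fields — matching the per-element field values
the evaluation layer consumes. The reduced symmetric positive-definite
system is solved by a sparse Cholesky factorization (CHOLMOD via the Matrix
package). A direct factorization was chosen over an iterative scheme
because the systems involved (1e4–1e5 unknowns) factor in seconds in R and
the factorization is reused; the relative residual of every solve is still
computed a posteriori, stored in the `FieldSolution`, and required to be
below 1e-6 (observed: ~1e-15). Current conservation (anode flux = −cathode
flux) is checked at the same tolerance.

Phase is not a complex quantity here: under quasi-statics a 10 Hz two-pair
drive is, at every instant, a static problem whose pair drives are scaled
by the two sinusoids. Same-phase operation corresponds to the sign pattern
(+1, +1) and anti-phase to (+1, −1) applied to the per-pair static
solutions; `superpose()` sums field *vectors* with those signs and only
then takes magnitudes. Flipping every sign leaves all magnitudes unchanged,
so the two anti-phase half-cycles are equivalent.

### Known limitation: electrode shunting

Superposing per-pair *Dirichlet* solutions ignores that an idle conductor
pad would slightly redistribute the other pair's field (shunting). The
package treats pads as current sources for superposition purposes, which is
the standard quasi-static treatment; the joint-solve check is therefore run
in the injection model, where superposition is mathematically exact and the
comparison verifies the implementation rather than the shunting physics.

## The synthetic head/orbit phantom

No head-MRI-derived mesh is bundled; the phantom is a layered sphere that
preserves the current-path structure periocular montages exploit:

* head radius 80 mm with a 4 mm skin shell and an 8 mm bone shell;
* two 12 mm-radius spherical eyeballs (adult eye ≈ 24 mm diameter) centred
  at (±25, 61, 0) mm, piercing the bone shell anteriorly and touching the
  skin layer;
* a conical orbital aperture (half-angle 16°) around each eye axis: within
  it the bone shell is replaced by a conductive aqueous compartment
  (labelled `csf`), standing in for the orbital soft contents — in a real
  orbit, bone never wraps the eyeball equator. Without this cavity the
  bone shell clamps the field to the small skin-contact disc and the
  characteristic same-phase "flooding" of the upper/nasal surface cannot
  occur;
* brain-like interior (gray matter label; optional white-matter core and
  CSF layer).

The mesh is a Kuhn subdivision of a structured cubic lattice mapped onto
the ball by the classical elliptical cube-to-ball mapping, which carries
the lattice boundary *exactly* onto the sphere — a boundary-conforming mesh
rather than a voxel staircase (a staircase boundary was measured to cost
several percent of field accuracy everywhere). Node positions are jittered
by a seeded uniform perturbation scaled to the local minimum edge length so
that element centroids are in general position; surface nodes are jittered
tangentially and re-projected, and a damped validity pass guarantees
strictly positive element volumes. The mesh is built on the half-space
x ≥ 0 and mirrored, so it is *exactly* mirror-symmetric about the
midsagittal plane — this makes the anti-phase antisymmetry check an exact
property of the discrete model instead of a discretization-limited one.
One integer seed controls all randomness and is recorded in the provenance
block of every output.

Tissue labels are assigned per element from the centroid, so internal
tissue interfaces are resolved at one element. The default element size is
5 mm (about 2 × 10^5 elements, 3.6 × 10^4 nodes); the eyeball volume at
this resolution is within ~4% of the analytic sphere volume. Tests use
8 mm where only structure matters.

Conductivities default to the study table at 10 Hz: white matter 0.027656,
gray matter 0.027512, CSF 2.0, bone 0.020028, head skin 0.0002 and eyeball
0.41113 S/m. The head-skin value is one to two orders of magnitude below
common scalp estimates; it is kept verbatim as the study default and is
overridable (`conductivity_map(skin = ...)`). Electrode gel is 1.0 S/m
(typical saline gel; the reference stimulator specifies a gel pad but no
conductivity) and occupies the skin elements under each pad footprint.

## Electrodes and the montage catalog

Pads are 42 mm × 42 mm squares (the reference stimulator's gel pads),
projected as geodesic squares onto the skin sphere; the pad contact is the
set of exterior skin nodes inside the footprint and the reported contact
area is measured on the radial projection of the contact faces. Montage
sites are specified as (azimuth, elevation) angles, never as hard-coded
mesh coordinates, and left-side sites are exact mirrors of right-side
ones.

The catalog mirrors the studied arrangements: pairs A–E target the
temporal/central/nasal lower ocular surface (A temporal-right, B
temporal-left, C central-right, D central-left, E nasal), combined
pairwise into the seven two-pair arrangements (aliases `electrode_1` …
`electrode_7`), plus revised placements and the boosted (1 & 1.5 mA) and
corrected (0.8 & 1.5 mA) current settings for the nasal arrangements.
Three catalog choices deserve comment:

* the close-contact failure case (`B+D`, electrode-4 analog) uses two
  active pads that cover the left orbital aperture almost identically and
  a single shared lower-cheek return, so its two current paths cross at
  the lower electrode — the geometry the failure was attributed to;
* the nasal active pad sits on the midline browridge/nasal bridge, away
  from both orbital apertures. The phantom has no nose, and this placement
  emulates the documented condition that the nasal ocular surface is
  considerably harder to stimulate than the temporal one (measured
  combined-field ratio ≈ 0.4 at equal currents);
* the nasal pair's catalog return coincides with the temporal-right
  return, so the arrangement combining both (`A+E`) moves the nasal return
  to the opposite cheek, as in the revised design.

## Ocular-surface evaluation

Each eyeball surface triangle is replaced by one point (its centroid) with
one field value (the magnitude of the owning eyeball element). Points are
unwrapped to longitude/latitude about the eye centre: longitude 0 at the
temporal edge of the anterior hemisphere, anterior at π/2 — so the
anterior half is [0, π] — and latitude 0 on the horizontal meridian,
positive up. The left eye uses the mirrored frame, making left/right
longitudes directly comparable. The equirectangular (longitude, latitude,
|E|) representation is used for scoring; a Mercator-style latitude
stretch would not change any maxima, only plots.

The scattered samples are interpolated onto a regular grid (default 1° per
cell) by piecewise-linear interpolation on a Delaunay triangulation of the
scatter (`interp` package); the interpolant reproduces the samples exactly
and grid cells outside the convex hull are masked, never extrapolated.

The lower anterior surface is partitioned into three equal longitude bands
of width π/3 (1.047 rad): temporal [0, π/3], central [π/3, 2π/3], nasal
[2π/3, π], each with latitude ≤ 0. The zone above a band (latitude > 0) is
its "upper" zone, and the lower bands sharing a longitude boundary are its
"adjacent" regions (one for temporal/nasal, two for central). Every grid
cell belongs to exactly one of {three lower regions, upper, posterior
remainder}.

Locality is scored by differences of grid maxima: `delta_upper` and
`delta_adjacent` are the in-region maximum minus the maximum of the upper
or adjacent zone; both may be negative when the outside field dominates.
Maxima are taken on the interpolated grid (as the surface plots are read),
with ties broken toward the smallest longitude, then smallest latitude.
When a montage intentionally stimulates two neighbouring regions, the
pipeline excludes fellow target regions from each other's adjacent set, so
a montage is scored against the *unintended* neighbours; the standalone
`locality_report()` keeps the plain partition adjacency.

`run_arrangement()` solves each pair once, superposes under both phase
options, and recommends the phase maximizing the minimum `delta_adjacent`
over the montage's target regions — a montage is only as local as its worst
target. The narrative decision procedure this operationalizes compares
deltas without a formal rule; the max–min rule is the package's explicit
choice. `current_sweep()` exploits linearity: pairs are solved once at
1 mA and rescaled per current combination (verified in the tests against a
direct re-solve).

## Solver validation against the analytic sphere

The independent oracle is the classical interior solution for a point
current source and sink on the surface of a homogeneous, insulated
conducting sphere,

$$V(r, \gamma) = \frac{I}{4 \pi \sigma R} \sum_{n \ge 1}
\frac{2n+1}{n} \left(\frac{r}{R}\right)^{\!n} P_n(\cos\gamma),$$

implemented both as a truncated Legendre series (configurable order, with
monotone truncation error) and in closed form
($\sum = 2/D - 2 + \log\frac{2}{1 - xu + D}$ with $D = \sqrt{1 - 2xu + x^2}$),
which the tests cross-check against each other and against a
finite-difference gradient.

`fem_sphere_validation()` solves a homogeneous 50 mm sphere with two small
antipodal pads (6 mm, about two elements across) and compares per-element
|E| with the oracle in relative L2 norm, excluding a 15 mm ball around each
source — inside it the pad drive and the point-source idealization differ
by construction ((pad/distance)² corrections), not by discretization error.
A convergence study fixed the defaults: at 3 mm elements (2.4 × 10^5
tetrahedra, ~40 s) the error is ≈ 4.9% and falls to ≈ 4.1% at 2.5 mm; the
near-source exclusion must be held fixed across resolutions or the
non-converging pad-idealization term dominates. The electrode (Dirichlet)
drive is validated because it is what the pipeline uses.

## What the phantom does and does not show

The phantom reproduces the *structure* of the design problem — resistive
skin, a bone shell with orbital openings, conductive eyeballs, pads much
larger than the orbit — and with it the study's qualitative findings, which
the acceptance checks assert as orderings, never magnitudes: anti-phase
beats same-phase on adjacent-region locality for the close-contact
same-eye montage; the shared-return overlap montage self-cancels under
anti-phase (in-region maximum below 0.2 of the same-phase value, a factor
chosen once as "clearly cancelled" before the orderings were measured
across seeds) while same-phase stimulates; the nasal target is weaker than
the temporal one at equal currents and the 0.8/1.5 mA correction strictly
shrinks the imbalance. These orderings are stable across mesh seeds.
Absolute V/m values depend on the phantom's simplified anatomy and are not
comparable to a subject-specific head model; on this phantom they happen to
fall in the same 0.5–5 V/m range at 1 mA. One finding does not transfer:
for the both-eyes arrangements the minimum-delta rule prefers anti-phase on
this phantom, whereas the overall recommendation of the original design
study for well-separated pairs
is same-phase on sharp-attenuation grounds that the delta rule does not
capture; the package reports the deltas and leaves the rule explicit.

Real tissue anisotropy, skin-electrode interface impedance, capacitive
effects, eyelids, the cornea as a distinct layer, and retinal physiology
are all out of scope; the corneal-field-predicts-phosphene-position
assumption enters only through the choice of the evaluation surface.

## Numerical choices, degenerate inputs, determinism

* Element volumes must be strictly positive; degenerate tetrahedra are
  reported by element id.
* Potentials are gauged to zero mean; all reported quantities are
  gauge-independent.
* Pads that resolve to no skin node (too coarse a mesh, too small a pad)
  raise a resolution error; pads within a pair must be node-disjoint.
* Interpolation requires ≥ 3 non-collinear samples; duplicate unwrapped
  coordinates are averaged.
* Grid maxima tie-break: smallest longitude, then smallest latitude.
* All randomness (mesh jitter) flows from one integer seed; identical
  configuration and seed give byte-identical meshes, reports and JSON
  output (modulo the timestamp field).

## Problem sizes used by the checks

The validation and acceptance computations run at: sphere validation
2.4 × 10^5 elements plus one refinement at 3.8 × 10^5; montage studies on
the default 5 mm phantom (2 × 10^5 elements, two to six Dirichlet solves
per study); unit tests on an 8 mm phantom (5 × 10^4 elements). These sizes
were chosen as the coarsest at which the convergence study above holds its
accuracy; the whole suite runs in minutes on one CPU.
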