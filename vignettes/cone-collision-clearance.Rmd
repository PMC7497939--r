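---
title: "Predicting cone collisions from beam's-eye-view geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting cone collisions from beam's-eye-view geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coneclear)
```

## The problem

Stereotactic cones are long, narrow collimators: their sharp penumbra is
bought with a housing that protrudes far from the gantry head, typically
ending only 25–27 cm from the isocenter. For cranial SRS the couch
extension and the infrared positioning array sit within a few centimetres
of that envelope, and non-coplanar arcs sweep the cone past them at
angles that are hard to reason about mentally. `coneclear` predicts the
cone-to-hardware clearance for any couch/gantry combination directly from
the hardware outer contours, so that undeliverable arcs are caught during
planning rather than at the machine.

## Coordinate chain

All geometry lives in millimetres in one of three tagged frames
(`FRAMES`): DICOM patient (LPS, as stored in an RT structure set),
patient support (X toward patient left, Y posterior, Z superior, origin
at the isocenter reference), and collimator/BEV (cone axis = +z toward
the source). For a head-first-supine patient the DICOM-to-support map is
the identity; other orientations are rejected rather than silently
mis-mapped, since every cranial cone setup this package targets is HFS.

`bev_transform()` applies

\[ v_C = R_z(\theta_C)\, S\, R_z(\theta_G)\, R_y(\theta_S)\,(v - \mathrm{iso}) \]

with the elementary rotations

\[ R_y(\theta)=\begin{pmatrix}\cos\theta&0&\sin\theta\\0&1&0\\-\sin\theta&0&\cos\theta\end{pmatrix},\quad
   R_z(\theta)=\begin{pmatrix}\cos\theta&\sin\theta&0\\-\sin\theta&\cos\theta&0\\0&0&1\end{pmatrix},\quad
   S=\begin{pmatrix}1&0&0\\0&0&1\\0&-1&0\end{pmatrix}. \]

Two conventions deserve a note, because descriptions of this chain in
the literature are not perfectly self-consistent:

* **Couch sign.** Some write-ups denote the couch factor "R_y(−θ_S)"
  while printing the matrix above with +θ_S entries. We implement the
  printed matrices verbatim — they are unambiguous, and the test suite
  pins them entry-by-entry against an independently hand-expanded
  symbolic product. Users who need the opposite couch sense can negate
  the angle.
* **Collimator placement.** A collimator rotation physically spins the
  head about the *beam* axis, which after the convention swap is the BEV
  z-axis. `R_z(θ_C)` is therefore applied after `S`. The payoff is a
  provable invariant: since the clearance depends only on `r = √(x²+y²)`
  and `z`, any θ_C leaves every clearance unchanged (asserted to
  1e−9 mm). A circular cone cannot see its own collimator angle, which
  is why all shipped workflows use θ_C = 0.

No perspective (divergent-beam) projection is applied: it would warp the
BEV x, y coordinates that the Euclidean clearance is computed from. The
transform is rigid — pairwise distances are preserved to 1e−9 mm — and
`bev_transform` deliberately avoids BLAS matrix products in favour of
explicit column arithmetic, so results are bit-reproducible across linear
algebra builds and exactly equal to the scalar reference implementation.

## Clearance model

The cone is modeled as the solid cylinder of radius `R` whose distal face
lies at BEV `z = D`, extending toward the source. The two shipped presets
are measured hardware values: BrainLAB cones on TrueBeam STx (outer
diameter 67.5 mm → R = 33.75 mm, face at 26.6 cm → D = 266 mm) and
Varian ICVI cones on Novalis Tx (74.0 mm → R = 37.0 mm, 25.6 cm →
D = 256 mm).

Candidate points satisfy `r ≤ R + m_d` with detection margin
`m_d = 5 mm` by default. The signed clearance of a candidate is the face
gap `D − z` inside the footprint, the distance to the face edge circle
for `r > R`, and the negative penetration depth `−(z − D)` beyond the
face plane. The per-angle clearance is the candidate minimum; a contour
entirely outside the padded footprint yields `+Inf` — a genuinely distant
contour is clearance-unlimited at that angle, not an error.

Three modeling decisions were genuinely open and are resolved as follows:

* **Annulus points beyond the face plane.** A candidate with
  `R < r ≤ R + m_d` and `z > D` is beside, not inside, the cylinder; its
  true surface distance would be `r − R`. We flag it as a collision with
  depth `z − D`, reading the candidate-then-depth rule strictly. This is
  conservative: a point within the detection margin of the cone body and
  beyond its face is nothing a planner should accept.
* **Lateral extent of the body.** How far the cylinder continues toward
  the source is not part of any cone datasheet that matters here; the
  gantry head behind the cone is wider than the cone in every mounting.
  The default is therefore semi-infinite (`length_mm = Inf`).
  `cone_spec()` accepts a finite length for completeness; points beyond
  the capped end are measured to the top rim and not flagged.
* **Margins.** Detection and safety margins both default to 5 mm.
  Residual 6D setup corrections (couch translation/roll/pitch/yaw) are
  *not* modeled — a ~2° correction moves a device edge 15 cm from the
  isocenter by ~5 mm, so clinical use should raise the margins to 10 mm
  or more rather than trust the desk geometry to the millimetre.

## Arc scanning and reporting

`scan_arc()` samples every `step_deg` (default 1°) from the start angle,
strictly increasing modulo 360 — clinical arcs are written directionally
(e.g. 200 → 340, or 350 → 10 through zero), and guessing "the short way
round" would be a safety bug. The exact end angle is appended when off
the grid. The minimum and its first-attaining gantry angle are recorded;
ties break to the earliest angle in traversal order, making reports
deterministic. `collision_free_ranges()` extracts maximal contiguous runs
with clearance at or above the safety margin; nesting (stricter margins
give subset ranges) and coherence (no returned interval contains a
collision sample) are property-tested. `collision_map()` evaluates a
couch × gantry grid for at-a-glance geometry selection.

Reports serialize to JSON (samples plus a summary block) or CSV (one row
per sampled angle). Clearances are rounded to 0.01 mm at serialization
only; the `+Inf` sentinel maps to JSON `null` and is restored on reading.

## Synthetic data and what the tests do (and do not) show

The fixtures module generates the geometries the validation rests on:

* `make_slab()` — a grid on the plane `y = top_depth` emulating a couch
  top's upper surface. Only the surface nearest the cone can attain the
  minimum, so the slab body is not modeled. For an infinite plane the
  candidate-constrained minimum has a closed form
  (`analytic_slab_clearance()`): along the BEV `y = 0` line the depth is
  linear in BEV x, and each branch of the piecewise formula minimizes
  analytically. The oracle is valid for couch 0 and gantry strictly
  inside (90°, 270°); elsewhere the infinite plane either never enters
  the detection cylinder or trivially collides, and it refuses loudly.
* `make_box()` — grid points on all six faces of a box, placed in tests
  so that its far face crosses the cone face plane at known angles; the
  expected collision flags are re-derived point-by-point from the BEV
  formulas independently of the engine.
* `write_synthetic_rtstruct()` — a minimal, standards-conformant
  explicit-VR little-endian RT structure set (verified against an
  independent DICOM implementation in the test suite), so the whole
  pipeline is testable without any clinical export.

Fixtures are deterministic given their spec. They emulate the *geometry*
of couch tops and positioning arrays, not their appearance in a real CT
export: real contours carry segmentation noise, HU-threshold dilation,
finite slice spacing and tens of thousands of unevenly spaced vertices.
Passing tests therefore demonstrate the correctness of the transform and
clearance mathematics and of the I/O plumbing — not that a 5 mm margin is
clinically sufficient for any particular machine, which remains a
commissioning measurement.

One discretization subtlety: engine clearances on a gridded slab converge
to the closed-form value as the spacing shrinks (error bounded by the
grid covering radius), but the error is not *pointwise* monotone — a grid
node can sit lucky or sit pinned just inside the candidate boundary
across one refinement. The convergence tests use the 300 mm slab at a
generic oblique angle (gantry 150°), where refinement behaves typically;
the per-angle checks assert non-increase rather than strict halving.

## Numerical choices

* Internal unit is mm everywhere; config/CLI isocenters are entered in
  cm (the convention treatment-plan tables print) and converted on
  ingest. Angles normalize to [0, 360).
* Transform identities (orthonormality, rigidity, commutation of the
  couch factor, collimator invariance) are asserted at 1e−9 mm;
  matrix-entry checks at 1e−12.
* `brute_force_clearance()` is the naive reference: same formulas,
  explicit per-point/per-angle loops, no candidate vectorization. It
  must (and does) agree *exactly* — not merely within tolerance — with
  `scan_arc()` on shared grid angles, which is why both paths share
  operation order and avoid BLAS.
* Degenerate inputs: empty contours error; empty candidate sets are the
  `Inf` sentinel; frame mismatches error at the API boundary rather than
  propagating wrong geometry.
* Test problem sizes are chosen to exercise the mathematics at sub-second
  cost: slabs of 90k–360k points for oracle comparisons, randomized
  boxes/slabs of a few hundred points for the 50–100-case property
  suites, 12° arcs for the exact scan-vs-reference sweeps.

## Limitations

Only the cone is modeled — not the gantry head behind it, the patient
body, or accessories absent from the contours. Arc traversal assumes a
constant couch angle per arc (dynamic couch-gantry trajectories would
need per-sample couch values). 6D setup corrections are excluded by
design and must be absorbed into margins. The DICOM layer reads
explicit- and implicit-VR little-endian structure sets only, and treats
contours purely as point sets: no surface meshing or slice
interpolation, so the axial point density (CT slice thickness at export
time, optionally tightened by `resample_contours()`) bounds how finely
the hardware surface is represented.
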