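# coneclear

Collision clearance prediction for cone-based stereotactic radiosurgery
(SRS).

Cone-based SRS delivers small circular fields through a long conical
collimator mounted on the linac head. The cone's protrusion leaves only a
narrow gap between the treatment head and the couch extension or the
infrared positioning array near the patient's head, and with non-coplanar
couch/gantry combinations it is hard to judge by eye which arcs are
deliverable. `coneclear` answers that question at planning time, from
geometry alone: given the hardware outer contours (from a DICOM RT
structure set, or synthetic fixtures), it computes the signed clearance
between the cone and the nearest contour point at every gantry angle of an
arc and reports the collision-free gantry sub-arcs. It is aimed at medical
physicists and planners who want a scriptable QA gate for cone plans.

## Method

Hardware contour points `v` (patient-support frame, mm) are mapped into
the beam's-eye-view (collimator) frame for support angle θ_S, gantry angle
θ_G and collimator angle θ_C by the rigid chain

    v_C = R_z(θ_C) · S · R_z(θ_G) · R_y(θ_S) · (v − iso)

where `S` swaps the gantry axes into the collimator convention
((x, y, z) → (x, z, −y)); after the swap +z points from the isocenter
toward the source and the cone axis is the z-axis. No perspective
projection is applied, so BEV x, y stay metric.

The cone is the solid cylinder of radius `R` about the beam axis whose
distal face sits at distance `D` from the isocenter. With `r = √(x²+y²)`
in the BEV, a contour point is a *candidate* if `r ≤ R + m_d` (detection
margin `m_d`, default 5 mm), and its signed clearance is

* `D − z`                      if `z ≤ D` and `r ≤ R` (face gap),
* `√((r−R)² + (D−z)²)`          if `z ≤ D` and `r > R` (edge distance),
* `−(z − D)`                    if `z > D` (collision; penetration depth).

The arc clearance at a gantry angle is the minimum over candidates (`+Inf`
when no point enters the padded footprint). Arcs are sampled every degree
from start to end (increasing modulo 360); gantry angles whose clearance
is at least the safety margin (default 5 mm) form the collision-free
sub-arcs. Shipped presets: BrainLAB cones on TrueBeam STx (R = 33.75 mm,
D = 266 mm) and Varian ICVI cones on Novalis Tx (R = 37.0 mm,
D = 256 mm).

## Worked example

A couch-top slab 50 mm below the isocenter, scanned over a posterior arc
with the BrainLAB preset:

```r
library(coneclear)
couch <- make_slab(slab_spec(top_depth_mm = 50, width_mm = 300,
                             length_mm = 300, grid_spacing_mm = 1))
cone  <- cone_preset("brainlab_truebeam")
res <- scan_arc(couch, arc_spec(c(0, 0, 0), couch_deg = 0,
                                gantry_start_deg = 160,
                                gantry_end_deg = 200), cone)
res
#> <arc_clearance> couch 0.0 deg, 41 gantry samples
#>   min clearance 198.89 mm at gantry 160.0 deg
```

At gantry 180 the beam is vertical and the clearance is the on-axis face
gap `D − depth = 266 − 50 = 216 mm`; toward the arc ends the nearest
point enters through the detection annulus and the minimum over the whole
arc (198.89 mm at gantry 160) is smaller. Adding an obstacle that reaches
beyond the cone face plane produces collisions and splits the safe range:

```r
array <- make_box(box_spec(center = c(0, 272, 0), dims = c(40, 40, 40),
                           grid_spacing_mm = 4))
hw <- point_cloud(rbind(couch$xyz, array$xyz), "support")
res2 <- scan_arc(hw, arc_spec(c(0, 0, 0), 0, 150, 210), cone)
res2
#> <arc_clearance> couch 0.0 deg, 61 gantry samples
#>   min clearance -26.68 mm at gantry 176.0 deg  [COLLISION]
collision_free_ranges(res2, safety_margin_mm = 5)
#> <collision_free_report> safety margin 5.0 mm: 2 interval(s)
#>   gantry 150.0 -> 167.0 deg (18 samples)  [longest]
#>   gantry 193.0 -> 210.0 deg (18 samples)
```

Negative clearance is the penetration depth beyond the cone face; here
the box's far face (292 mm from the isocenter, deeper than D = 266 mm)
collides over 150–210° except for the two reported sub-arcs.

The same pipeline runs from the shell on RT-STRUCT files (exit code 0 =
all arcs clear):

```sh
Rscript exec/coneclear fixture --fixture slab --top-depth-mm 50 --out couch.dcm
Rscript exec/coneclear scan --struct couch.dcm --machine brainlab_truebeam \
    --iso-cm 0,0,0 --couch 0 --gantry-start 160 --gantry-end 200 --out report.json
```

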