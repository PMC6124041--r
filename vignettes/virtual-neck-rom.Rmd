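---
title: "Collision-terminated range of motion for digitized vertebral columns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collision-terminated range of motion for digitized vertebral columns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Necks of extinct long-necked reptiles cannot be manipulated; their mobility
must be inferred from bone. Given surface meshes of consecutive vertebrae, a
widely used protocol poses each pair in a straightened neutral articulation,
rotates the posterior vertebra about a fixed intervertebral pivot, and takes
the largest rotation at which no skeletal surfaces touch as the *osteological*
range of motion (ROM) of that joint. Repeating this for every joint and three
directions of bending — lateral (frontal plane), dorsal and ventral (median
plane) — yields per-joint mobility profiles whose means and totals summarise
neck function, and whose comparison across conditions is a statistical
question about mean directions, i.e. circular statistics.

`neckROM` implements that protocol end to end:

1. **Geometry in** — per-vertebra triangle meshes with labelled anatomical
   parts (centrum, neural spine, paired pre-/postzygapophyses, paired
   cervical ribs), read from OBJ (or ASCII PLY/STL) via a JSON manifest, or
   generated procedurally.
2. **Articulation** — a rigid chain with a pivot placed midway between the
   facing centrum faces of each joint, in two intervertebral-spacing regimes:
   the spacing preserved in the specimen (PCVM, *paired cervical vertebral
   mobility*, the osteological maximum) and the spacing collapsed until the
   centra touch (MISM, *minimum intervertebral space mobility*, the
   osteological minimum).
3. **Search** — per joint and profile, the maximal rotation before
   bone-on-bone contact, found by a coarse sweep plus bisection against an
   exact mesh-to-mesh minimum-distance query.
4. **Statistics** — summary rows (n, mean, s.d., min, max, sum) per
   trial-profile group and Watson–Williams tests for equal mean directions
   between groups.

## Coordinate and joint conventions

Local and world frames use +x anterior, +y left, +z dorsal; a column extends
towards −x from its most anterior vertebra. Each joint stores two axes
derived from the anterior vertebra's frame: lateral flexion is rotation about
the dorsal axis (motion in the frontal plane, positive towards the right),
dorsoventral flexion is rotation about the left-lateral axis (motion in the
median plane, dorsal positive). Lateral ROM is reported one-sided (a bend to
one side); on bilaterally symmetric anatomy the two sides agree, which the
test suite asserts to 0.05°.

The pivot is the midpoint of the segment joining the anterior vertebra's
posterior-face centroid and the posterior vertebra's anterior-face centroid.
This operationalises "centre of the intervertebral disc" with surface data
only: the disc occupied the lens between the two opposing concave (amphicoelous)
centrum faces, and the midpoint of the inter-face segment is the most robust
surface-derived stand-in. In minimum-spacing mode the pivot is recomputed
after the reduction, at the collapsed gap, so manipulations start from the
contacted configuration. Manipulation is pairwise by default — the anterior
vertebra of each pair stays fixed in world space — with an explicit
whole-chain mode (`chain = TRUE`) for visualisation-style full-neck sweeps.

Landmarks for real meshes are estimated when not supplied: the
anterior/posterior face centroids are area-weighted centroids of centrum
triangles whose outward normals lie within 45° of the ±anterior axis, and
the dorsal reference is the highest centrum vertex. Supplying measured
landmarks in the manifest overrides the estimate.

## Contact and the search

Contact is defined as a minimum inter-surface distance at or below a
tolerance ε (`epsilon_mm`, default 0.1 mm), not triangle interpenetration:
this emulates rigid bodies that cannot pass through one another while being
robust to scanning noise at sub-millimetre scale. The distance kernel (C++)
computes exact triangle-triangle distances (vertex-face and edge-edge
candidates, with an explicit edge-crossing test so intersecting surfaces
report 0), pruned by per-triangle bounding boxes and an early-exit threshold
for yes/no queries.

A contact *rule* lists which part pairs may terminate motion. The preserved-
spacing trial uses the wildcard rule (any part against any part). The
minimum-spacing trial first translates each posterior vertebra along the
chain axis until the centrum-centrum distance falls in [0, ε_red]
(`reduction_epsilon_mm`, default 0.01 mm, solved by root finding on the
distance-versus-translation curve, which is monotone over the closing gap),
and then excludes centrum-centrum contact from the rule — those surfaces
begin in contact, so they cannot define the end of motion.

The search brackets the angle in [0°, 90°] by default (wider brackets can be
requested for fixtures with wide-open geometry), walks forward in 1° steps
to the *first* contact — guarding against non-monotone contact that appears
and disappears — and then bisects to `tol_deg` (default 0.01°). Degenerate
starts are well-defined: contact already at 0° reports 0° (the
minimum-spacing trial begins in contact); no contact within the bracket
reports the bracket with an explicit `limit` flag; a joint none of whose
part pairs are included in the rule is likewise bracket-limited rather than
an error. Damaged joints are computed but flagged, never reconstructed, and
the statistics exclude flagged, bracket-limited and missing entries, so
group sizes vary with preservation exactly as they do with real, partially
damaged columns.

The angle of record is the commanded joint angle. `measure_line_angle()`
exists to validate the manual measurement protocol the numbers emulate —
lines fitted along each vertebra's centrum axis, projected to the median
plane (dorsoventral) or frontal plane (lateral), intersected, with
triplicate averaging and optional Gaussian measurement jitter — against the
commanded rotation; with zero jitter the two agree to well below 0.1°.

## The synthetic column

No vertebral dimensions are published for the digitized specimen this
protocol is modelled on, so the generator's defaults are documented
conventions, chosen once for plausibility at small-plesiosaur cervical scale
and so that the qualitative stop inventory reported for such columns is
geometrically reproduced:

| parameter | default | role |
|---|---|---|
| `centrum_radius` | 10 mm | barrel radius; sets the centrum-face stop lever |
| `centrum_length` | 20 mm | face planes at ±10 mm |
| `concavity_depth` | 2 mm | amphicoelous cup depth at each face |
| `spine_height` | 20 mm | dorsal extent of the neural spine tip |
| `spine_posterior_angle` | 0° | posterior tilt, increases along the column |
| `zygapophysis_angle` | 10° | facet-plate inclination from horizontal |
| `zygapophysis_offset` | 6 mm | facet distance from the median plane |
| `rib_length` | 30 mm | lateral rib projection; lateral stop lever |
| `mesh_resolution` | 16 | segments per revolution |
| gap g | 2.6 → 2.0 mm | preserved spacing, narrowing posteriorly |

With these proportions the preserved-spacing stops are: **lateral — cervical
ribs** (long lateral levers meet across the inter-rib gap first), **dorsal —
neural spines** (tall, nearly abutting plates; zygapophyseal facets engage
dorsally only after the spines), **ventral — centrum faces** (the ventral
rims of the opposing cups pinch). The default 24-vertebra study column
(`default_column_spec()`) adds per-index gradients — spines heighten
(+0.15 mm) and tilt posteriorly (+0.8°), facets steepen (+0.5°), ribs
shorten (−0.3 mm) — and a damage mask removing the neural spines and ribs of
C7–C9, emulating excavation damage; joints touching those vertebrae are
flagged and drop out of the summaries, giving the varying per-group n.

The gap gradient's lower end (2.0 mm) keeps every joint inside the regime
where the spine, not the centrum rim, is the dorsal stop: the two cross at
g ≈ 1.6–1.9 mm for these proportions, and the fixture is meant to embody the
stated stop inventory unambiguously.

Two generator behaviours are worth knowing. First, facet plates are placed
anatomically (prezygapophyses ventral to the anterior vertebra's
postzygapophyses, 1 mm clearance); in minimum spacing the *ventral* profile
is stopped by those facets (the rising prezygapophysis meets the facet above
it) at a larger angle than the preserved-spacing ventral stop — so the
minimum ≤ preserved ordering, which holds for lateral and dorsal bending,
does not hold ventrally on this synthetic morphology. That ordering is a
property of convex geometry with a shared contact rule, and the package
asserts it on sphere chains, where it is exact. Second, all generation is
deterministic (identical parameters and seed give bitwise-identical meshes);
the only stochastic option, surface jitter, is off by default.

The sphere-pair fixture is the analytic anchor: two spheres of radius r with
gap g, pivot at mid-gap, have the closed-form maximal rotation
φ\* = arccos(2r²/(r + g/2)² − 1), strictly increasing in g. The bisection
search reproduces φ\* to within 2·`tol_deg` plus a mesh-discretisation term
(the chord sagitta of both sphere meshes plus ε, divided by the gap-closing
rate at contact) — the suite checks this over a 12-point (r, g) grid.

## Statistics

Descriptive rows use ordinary arithmetic on degrees: the intervertebral
angles are small (≪ 90°), and the tabulation convention sum = n × mean then
holds exactly, which a circular mean would not guarantee. The
Watson–Williams test uses the circular construction on radians: per-group
resultant lengths R\_i, pooled resultant R, and

F = K · (N − k)(ΣR\_i − R) / ((k − 1)(N − ΣR\_i)),

with K = 1 + 3/(8κ̂) and κ̂ obtained from the weighted mean resultant length
by the standard piecewise A⁻¹ inversion; p comes from F(k−1, N−k). The test
names the construction only — the original analyses were run in a
general-purpose statistics program — so the textbook form is adopted and
cross-checked three ways in the suite: identical groups give F ≈ 0, p ≈ 1;
the F statistic matches an independently hand-coded resultant computation to
1e−12; and p agrees with a label-permutation test of the mean-direction
difference within Monte-Carlo and approximation error. Calibration is
checked by simulation: under equal-mean von Mises sampling (κ = 4, two
groups of 20, 2000 replicates, Best–Fisher sampler) the empirical type-I
error at α = 0.05 must land in [0.035, 0.065]. Assumption flags are raised
for low concentration (κ̂ < 1) or strongly heterogeneous group
concentrations; perfectly concentrated degenerate groups (zero within-group
dispersion, possible on idealised synthetic columns) are handled explicitly
rather than producing 0/0. No multiplicity correction is applied to the
pairwise matrix, matching the source protocol; the significance mark is
fixed at p ≤ 0.05.

## Numerical choices, sizes, limitations

* Tolerances: ε = 0.1 mm contact, ε_red = 0.01 mm reduction, `tol_deg` =
  0.01° bisection, 1° pre-sweep; all exposed as arguments.
* The validation battery runs at deliberately modest sizes — sphere meshes
  at 32 segments, vertebra meshes at 16, the full study column at 24
  vertebrae with `tol_deg` 0.01–0.05 — chosen as the points where further
  refinement stopped changing results at the tolerances asserted.
* What passing tests show: the search, articulation and statistics machinery
  are correct against analytic, brute-force and independently coded oracles,
  and the pipeline is deterministic end to end. What they do not show:
  anything about a particular fossil. The generator emulates morphology
  *classes* (cupped centra, angled spines, overlapping facets, lateral
  ribs), not any specimen's shape; real scan meshes bring segmentation
  noise, asymmetry and damage patterns the synthetic column only gestures
  at via optional jitter and the damage mask.
* Out of scope by design: soft tissues (discs, capsules, ligaments,
  musculature) — bone-on-bone maxima are osteological brackets, not life
  ranges; translational (shear) degrees of freedom; axial torsion; CT
  reconstruction and segmentation, which are upstream of the mesh inputs.

## A worked example

```r
library(neckROM)

col <- make_column(default_column_spec(24))
bundle <- run_pipeline(run_config(spec = default_column_spec(24),
                                  out_dir = "rom_out"))
bundle$summaries   # n / mean / s.d. / min / max / sum per trial x profile
bundle$ww          # pairwise Watson-Williams matrix

# statistics only, from an externally measured angle table:
csv <- system.file("extdata", "synthetic_raw_angles.csv", package = "neckROM")
run_pipeline(run_config(angle_csv = csv))
```

The bundled `synthetic_raw_angles.csv` is a synthetic-labelled fixture
patterned on the two-trial, three-profile study design (group sizes 20/20/20
and 20/18/19); it exists to exercise the ingest path and is not measured
data.
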