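---
title: "Measuring the bell-shape index from depth frames: models, parameters and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the bell-shape index from depth frames}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chestshape)
```

This vignette is the package's account of its own methods: the geometric
model behind the bell-shape index, the numerical choices in each stage,
what the torso simulator does and does not emulate, and the limits of what
the test suite demonstrates.

## 1. From depth frames to surfaces

A depth camera above a supine child delivers frames of per-pixel distances
in millimetres (16-bit single-channel PNG, 0 marking sensor dropout).  The
camera model is the standard pinhole: pixel $(u, v)$ at depth $d$
deprojects to

$$\mathbf{p} = \Big(\frac{(u - c_x)\,d}{f_x},\ \frac{(v - c_y)\,d}{f_y},\ d\Big)$$

in camera coordinates (x right, y down, z away from the camera; pixels are
0-based with the origin at the top-left).  This convention is declared once
and used everywhere — landmark files, meshes, the simulator.

`buildMesh()` turns a frame into a triangulated surface: every valid pixel
becomes a vertex, every 2×2 valid block contributes two triangles split
along its **shorter 3D diagonal**, and any triangle with a 3D edge longer
than `maxEdgeMm` (default 30 mm) is discarded.  The pruning threshold is
the one mesh parameter that matters: without it, triangles would bridge the
depth discontinuity at the torso silhouette and geodesic paths could
tunnel from the chest to the bed.  30 mm is far above the pixel footprint
at clinical distances (≈ 1–3 mm) and far below the torso-to-bed depth gap
(tens of mm), so the default is insensitive over a wide range.

## 2. Euclidean and geodesic distances

The straight-line distance between two landmarks ignores the chest
surface; the geodesic distance is the length of the shortest path
constrained to the surface, and is never smaller.  The solver is
first-order fast marching over the triangle mesh with a *virtual-source*
update: for a triangle $(A, B, C)$ with known values $T_A, T_B$, a source
point $S$ is placed in the triangle's plane with $|SA| = T_A$,
$|SB| = T_B$ on the far side of edge $AB$, and $T_C = |SC|$ is accepted
when the segment $S\!\to\!C$ crosses the edge (otherwise the one-sided
edge update applies, which keeps the scheme causal on obtuse or degenerate
triangles).  On planar meshes the virtual source coincides with the true
source, so planar distances are exact to rounding error; on developable
surfaces (cylinders) the test suite shows agreement with the analytic arc
length to a few parts in $10^5$ at 2 mm vertex spacing — comfortably
within the 1 % contract the package promises for geodesics.  Because every
edge relaxation is also considered, the solver's result can never exceed
the edge-graph shortest path, and it is bounded below by the straight-line
distance; both bounds are asserted in the tests against an independent
Dijkstra implementation.

Landmarks arrive as pixel coordinates (annotators mark the anterior
axillary points at nipple height and the chest contour at sub-xiphoid
height).  A landmark on a dropped-out pixel snaps to the nearest valid
pixel within 5 px (ties towards smaller row, then column); beyond that the
measurement fails loudly rather than guessing.

### Spatial denoising

Stereo-depth noise (≈ 1.5 mm at 1 m, i.i.d. per pixel) roughens the
triangulated surface and *inflates* on-surface path lengths — by several
percent at typical footprints, far more than it perturbs straight-line
distances.  `measureFrame()` therefore smooths the depth image before
meshing with a masked (normalised) Gaussian, σ = 1 px by default: the
kernel is applied to `depth × valid` and to `valid` separately and the
results divided, so depths never bleed across the silhouette.  The
bandwidth was calibrated on simulated ground truth as a bias–variance
trade-off: σ below ≈ 0.5 px leaves enough roughness to bias geodesics
upward, σ above ≈ 1.5 px measurably flattens the steep lateral chest wall
(where the landmarks sit) and shortens geodesics.  σ = 1 px leaves the
cohort-mean index unbiased to about ±0.005.  Temporal filtering across
frames is deliberately not performed; frames are averaged only at the
level of measured distances.

## 3. The index and its statistics

For one recording, five consecutive quiet-breathing frames are selected —
manually (the reference protocol) or by a flagged stand-in heuristic that
minimises the temporal variance of mean valid depth over a sliding window.
The four distances are averaged across the frames and the index is the
**ratio of frame-averaged distances**, not the average of per-frame ratios
(per-frame ratios are still emitted for diagnostics).  At the cohort
level, however, group summaries average **per-subject ratios** — the two
conventions differ in general, and printed cohort tables in this field are
consistent with the latter.

Classification uses a configurable cutoff on the Euclidean index (default
0.95).  No accepted numeric boundary between "bell" and "rectangular"
exists — the literature says "smaller than 1" versus "larger or close to
1" — so the continuous index is the primary output and the cutoff is
always echoed next to the label.

Group comparison uses the Mann–Whitney U test with U computed by midrank
pair counting (ties count ½).  The two-sided p-value is the permutation
tail mass $P(|U - n_1 n_2/2| \ge |U_{obs} - n_1 n_2/2|)$, computed
*exactly* — also under ties — by a dynamic programme over doubled
midranks (counting subsets of each size by rank sum), which is feasible
even at $n_1 n_2$ values where direct enumeration of label assignments is
not.  `auto` mode uses the exact computation up to $n_1 n_2 \le 400$
(which covers 14 vs 28) and a tie- and continuity-corrected normal
approximation beyond.  Fisher's exact test wraps the standard
implementation; the tests verify it against direct hypergeometric
enumeration of all tables with the observed margins.  Two-sided tests at
α = 0.05 throughout; reports print p to two decimals, machine outputs keep
full precision.

The radiograph comparator is intentionally minimal: rib-edge pixel pairs ×
pixel spacing, levels 2/9 and 4/8, ratios only — a radiograph is a
projection, so no geodesic analogue exists, and ratios are independent of
the (often unknown) magnification.

## 4. The synthetic torso

The simulator exists so that every pipeline stage has a ground truth.  The
surface is a height field over the bed plane:

$$z(x, y) = D - h(y)\,\big(1 - |x/w(y)|^p\big)^{1/p},\qquad |x| \le w(y),$$

superellipse cross-sections (exponent $p \ge 2$, default 2) with
half-width $w$ and sagittal depth $h$ tapering linearly between the lower
landmark row ($y = +L/4$) and the upper one ($y = -L/4$) and held constant
beyond them (the clamp keeps extreme tapers inside the camera's view; only
the segment between the landmark rows affects the index).  Because paired
landmarks sit symmetrically at $x = \pm\,\ell\,w(y)$ (landmark fraction
$\ell = 0.9$) and share $y$ and $z$, the **true Euclidean index equals the
width-taper ratio exactly**; the **true geodesic** at a landmark row is
the cross-section arc length, by adaptive quadrature to < 0.01 %.  The
fixed-row arc is exact for an untapered surface (unrolling a generalized
cylinder) and an upper bound with second-order error under the mild tapers
simulated here; a dense-mesh solver cross-check in the test suite bounds
the discrepancy below 0.4 %.

Defaults emulate a young child viewed from 700 mm: lower half-width and
sagittal depth 88 mm (lower landmark separation 15.84 cm; arc/chord
≈ 1.24, matching the observed geodesic/Euclidean gap), torso length
300 mm, 15 Hz, 2 % sinusoidal sagittal breathing with a 3 s period,
Gaussian depth noise of 1.5 mm (typical stereo error at this range — an
assumption, not a measured value; the truth CSV header flags all synthetic
assumptions).  The default simulated sensor is 160 × 213 px with
$f = 400$ px (1.75 mm footprint at 700 mm); `simulationIntrinsics(scale)`
refines it, `scale = 3` matching a 480 × 640 sensor.

### Cohort generation

`generateCohort()` turns a prescribed index distribution (mean, SD) into
subjects:

* **Stratified draws.**  Per-subject target ratios are drawn by inverse
  CDF of the truncated normal (bounds 0.5–1.5) over equal-probability
  strata in random order.  Marginally each subject is still a
  truncated-normal draw, but a 14-subject cohort then *represents* the
  prescribed distribution: with i.i.d. draws the sampling error of the
  cohort mean (SE ≈ 0.02–0.03 at these n and SDs) would dominate any
  comparison of recovered group means, measuring draw luck rather than the
  pipeline.
* **Root-finding.**  The width-taper ratio is solved (1-D, to $10^{-6}$)
  so that the *true* target quantity — Euclidean or geodesic index of the
  analytic surface — equals the draw.  Unachievable targets raise an
  error naming the subject.
* **Sagittal coupling.**  The upper sagittal depth follows the width
  taper, $h_{up}/h_{low} = 1 + 1.5\,(w_{up}/w_{low} - 1)$.  Coupling
  above 1 flattens the narrowed upper chest relative to its width, which
  (a) reproduces the clinical pattern of geodesic indices sitting
  slightly *below* Euclidean ones in bell-shaped chests, and (b) extends
  the achievable geodesic-index range to the full draw window — with
  constant depth, a narrow-but-deep arch cannot produce geodesic ratios
  below ≈ 0.78.
* **Body size.**  A per-subject size multiplier (SD 0.15, truncated
  0.6–1.4) scales half-width, sagittal depth and torso length, emulating
  the ≈ 20 % spread of absolute chest distances in young mixed-age
  cohorts.  Size leaves every shape ratio untouched but decorrelates the
  pixel-grid phase across subjects; with identical geometry for all
  subjects, landmark-pixel rounding would act as a fixed cohort-level
  bias instead of averaging out.
* **Framing.**  The camera backs off its 700 mm base distance just enough
  to keep each subject in view, as an operator would.

Rendering casts each pixel ray against the analytic surface (fixed-point
iteration on the height field; silhouette-grazing rays that fail to
converge are dropped as a real sensor would), adds noise, and quantises to
the 0.1 mm PNG storage grid, so on-disk and in-memory pipelines agree
bit-for-bit.  Everything is deterministic given the cohort seed: draws,
per-subject render seeds, frames.

### What the simulator does not emulate

Real recordings contain posture asymmetry, scoliosis, clothing and skin
artefacts, correlated (non-i.i.d.) sensor noise, asynchronous
thoraco-abdominal motion, and annotator variability in landmark placement.
None of these are modelled.  Passing the recovery tests therefore shows
that the geometry engine, the index definition and the statistics are
implemented correctly and are robust to the modelled noise — it does not
validate the method on real patients.

## 5. Numerical choices and degenerate inputs

* Geometry is computed in mm; reports print cm (two decimals for 3D
  distances, one for radiograph distances, two for ratios).
* Deprojection is pure algebra and accepts virtual pixels beyond the
  sensor (the renderer needs them); bounds are enforced wherever a frame
  provides them.
* Meshes with fewer than 3 valid pixels, landmarks with no valid pixel
  within 5 px, landmark pairs in different mesh components, empty
  measurement sets, single-group cohorts, non-positive distances and
  malformed tables all raise errors naming the offending entity; zero
  margins in Fisher tables return p = 1; single-value groups report
  SD = 0 with a flag.
* Frame-selection ties resolve to the earliest window; the auto heuristic
  labels its output `auto-heuristic` so downstream consumers can tell it
  from expert selection.
* Problem sizes in the tests: the recovery suites run the published
  cohort sizes (14 and 28) at the 160 × 213 px simulated sensor with
  5 frames per subject; resolution-sensitive invariance checks
  (camera-distance drift) run at the native 480 × 640 scale; geodesic
  oracle meshes use ≤ 2 mm spacing.  These sizes were chosen to exercise
  the study conditions faithfully while keeping the default suite quick.

## 6. Known limitations

* Landmark-pixel quantisation is the dominant measurement error at coarse
  renders; it is amplified on the steep lateral chest wall (slope ≈ 2–3
  at the 0.9 landmark fraction) and mirrored by the torso's symmetry, so
  individual recordings at 1.75 mm footprints carry index uncertainties
  of up to ±0.02 (geodesic) even noise-free.  Cohort means average this
  out; single-subject classification near the cutoff should use finer
  renders or real-sensor resolution.
* First-order fast marching converges from above on smooth non-developable
  surfaces; its error is negligible here but unbounded meshes with highly
  obtuse triangles would degrade toward edge-graph accuracy.
* The exact Mann–Whitney p is defined through the symmetric deviation
  $|U - n_1 n_2/2|$; under heavy ties other two-sided conventions
  (doubling the smaller tail) can differ slightly.  The brute-force
  enumeration in the tests pins down the convention implemented.
* The auto frame selector is a stand-in for expert review and is flagged
  as such in every output.
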