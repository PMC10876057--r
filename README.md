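# chestshape

Non-ionizing quantification of chest-wall shape from depth-camera
recordings of a supine torso.

Children with spinal muscular atrophy (SMA) develop a characteristic
**bell-shaped chest**: intercostal muscle weakness leaves the upper thorax
narrower than the lower thorax.  Detecting this deformity early matters for
respiratory management, but conventional quantification relies on chest
radiographs (ionizing) or optoelectronic plethysmography (36 markers,
specialist hardware).  A bedside depth camera offers a cheap, contact-free
alternative: one short recording of the chest while the child lies supine
and breathes quietly.

`chestshape` implements the complete analysis pipeline for such
recordings, plus a chest-radiograph comparator, the small-sample group
statistics, and a parametric torso simulator so every stage can be tested
end to end without patient data.

## The index

Each depth frame is deprojected through the pinhole model into a
triangulated 3D chest surface.  Two landmark pairs are measured on it:

* **upper chest** — right and left anterior axillary lines at nipple
  height;
* **lower chest** — chest contour edges at sub-xiphoid height.

For each pair the pipeline computes the straight-line (**Euclidean**)
distance d\_E and the on-surface shortest-path (**geodesic**) distance
d\_G ≥ d\_E, averages each over five consecutive quiet-breathing frames,
and forms the **bell-shape index**

> R = upper distance / lower distance,

once with Euclidean and once with geodesic distances.  R ≈ 1 indicates a
rectangular chest; R < 1 indicates a bell shape.  Geodesic distances follow
the chest curvature (soft tissue included), which makes the geodesic index
the more sensitive of the two.

Radiographs, being 2D projections, only admit Euclidean rib-edge distances
(lateral edges of ribs 2/9 and 4/8); `cxrDistance()`/`cxrTable()` reproduce
that comparator.  Group contrasts use the exact Mann–Whitney U test
(permutation distribution with midrank ties) and Fisher's exact test —
sample sizes in this setting are far too small for parametric assumptions.

## Worked example

Simulate a small two-group cohort with known ground truth, measure every
recording through the full pipeline, and compare the groups:

```r
library(chestshape)

td <- file.path(tempdir(), "demo")
groups <- data.frame(group = c("sma", "control"), n = c(3, 3),
                     mean = c(0.92, 1.00), sd = c(0.05, 0.05),
                     target = "euclidRatio")
cmdSimulate(td, groups, seed = 7)
idx <- cmdMeasure(td, file.path(td, "intrinsics.json"),
                  file.path(td, "landmarks.csv"), file.path(td, "out"))
idx[, c("recordingId", "euclidRatio", "geodesicRatio", "classification")]
#>   recordingId euclidRatio geodesicRatio classification
#> 1  control_01      1.0538        1.0716    rectangular
#> 2  control_02      1.0244        1.0408    rectangular
#> 3  control_03      0.9083        0.9023           bell
#> 4      sma_01      0.9337        0.9253           bell
#> 5      sma_02      0.8895        0.8759           bell
#> 6      sma_03      0.9587        0.9591    rectangular
```

Each row is one recording: the frame-averaged upper/lower ratio for both
distance types and the shape label at the default 0.95 cutoff.  The
simulated SMA-like subjects (generated around a true Euclidean ratio of
0.92) come out below the controls (generated around 1.00); per-subject
deviations reflect the prescribed 0.05 between-subject spread plus
measurement noise.  A single recording prints as:

```r
rec <- renderDepthSequence(torsoParams(widthRatio = 0.9, noiseSd = 0),
                           simulationIntrinsics(), 1, 1)
ms <- measureFrame(rec$frames[[1]], simulationIntrinsics(), rec$landmarks)
computeBellIndex(averageMeasurements(ms), 1L)
#> BellShapeIndex (1 frames)
#>  Euclidean: upper 14.23 cm / lower 15.91 cm = 0.894
#>  Geodesic:  upper 18.37 cm / lower 19.93 cm = 0.922
```

`cmdCohort()` then aggregates measured indices with group labels into a
per-variable report (group means, SDs, exact Mann–Whitney U and p, with a
significance flag column).

A thin shell wrapper over the same functions ships as
`inst/cli/chestshape` with subcommands `simulate | measure | cohort | cxr`.

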