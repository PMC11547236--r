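---
title: "Boundary-preserving threshold iteration: model, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boundary-preserving threshold iteration: model, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bounti)
```

## The model

The method assumes a grey-value volume in which the objects of interest
(bones, typically) are bright, the material joining them (sutures,
cartilage) is dimmer, and the background dimmer still. Under that
assumption there exists a *high* threshold `IT` at which the objects
appear as separate connected components, and a *low* threshold `TT` at
which each object is well delineated but the objects are merged through
the joints. Neither threshold alone gives a usable multi-part
segmentation; the method combines them.

### Procedure

1. **Seeding.** Threshold the volume at `IT` (inclusive: voxels with
   grey value `>= IT`), label the 3D connected components, order them by
   decreasing voxel count, and keep the `NS` largest as segments
   1..`NS`. Optionally dilate the seed by one voxel (26-neighbourhood);
   a voxel adjacent to two different segments is *contested* and stays
   background, so dilation can never merge segments.
2. **Iterative growth.** Lower the threshold linearly over `NI`
   iterations,

   $$ TS = \frac{IT - TT}{NI}, \qquad CIT_{CI} = IT - TS \cdot CI,
      \quad CI = 0, \dots, NI, $$

   and at each `CIT` let all segments grow *simultaneously* into the
   unlabeled voxels at or above `CIT` that are connected to them. Growth
   is one multi-source breadth-first expansion per iteration: a voxel is
   claimed by the segment whose wavefront reaches it first; a voxel
   reached by two wavefronts at the same distance goes to the smaller
   label. Labels are never reassigned.

Because labels are never reassigned, the separation obtained at `IT` is
preserved all the way down to `TT` (*boundary preservation*). Because
the last iteration runs at exactly `TT`, the union of the final
segments equals the union of the `TT`-superlevel connected components
that contain a seed voxel — the result never includes a voxel a direct
`TT` threshold would exclude, and within the reachable components it
misses nothing. The iteration count therefore does not change *which*
voxels are segmented, only how the joint regions are *apportioned*
between adjacent segments: coarse schedules let wavefronts race further
per step.

## Parameters

| Parameter | Meaning | Default / typical |
|---|---|---|
| `initialThreshold` (IT) | seed threshold; must disarticulate the objects | data-dependent (e.g. 35000 on 16-bit micro-CT bone) |
| `targetThreshold` (TT) | final threshold with the desired object definition | data-dependent (e.g. 27000) |
| `numIterations` (NI) | schedule length | 10–200; larger values give finer apportioning of joint regions |
| `numSegments` (NS) | seed components kept | the number of anatomical parts expected |
| `connectivity` | 6, 18 or 26 neighbourhood | 26 |
| `dilate` | one-voxel seed dilation | `FALSE` |

`iterationsForStep(it, tt, step)` converts a desired threshold
decrement into an iteration count, which is how a sweep over `IT` can
hold the step fixed (`runSweep(..., sweepSpec("initial_threshold",
values, keepStep = ...))`).

## Numerical choices

These are deliberate and frozen; the test suite pins each one.

* **Inclusive thresholds.** A voxel passes a threshold `t` when its
  value is `>= t`, at seeding and at every growth iteration.
* **Schedule rounding.** `CIT` values are rounded half-up
  (`floor(x + 0.5)`) to integers; the last entry is forced to `TT`
  exactly and the sequence is made non-increasing. The *reported*
  integer step is `floor(TS)` — e.g. `IT=35000, TT=27000, NI=150`
  reports step 53.
* **Component ordering.** Connected components are labeled 1..K by
  decreasing size; equal sizes break by scan order of the first voxel,
  so labeling is deterministic.
* **Growth ties.** Equidistant contested voxels go to the smaller
  label. Together with deterministic seeding this makes the whole run
  bit-reproducible.
* **Simultaneous, not sequential, growth.** All segments expand in one
  shared breadth-first pass per iteration. Sequential per-segment
  growth would privilege low labels systematically; simultaneous growth
  splits joint regions by geodesic distance, which matches the intended
  "wavefronts meet in the middle of the suture" behaviour.
* **Dilation contested rule.** A background voxel 26-adjacent to two or
  more distinct segments is left unlabeled, preserving disjointness.
* **Bit-depth conversion** (`convertToU16`): unsigned 8-bit input is
  *widened* to 0–255, not stretched, so grey values keep their
  physical meaning; signed 16-bit and 32-bit float inputs are mapped
  affinely through a user-supplied `[low, high]` range, values outside
  it clipped, and rounded half-up (so the midpoint of the full signed
  range maps to 32768). Clipping rather than rescaling by the observed
  range keeps thresholds transferable across scans.
* **Connectivity default 26.** Thin or obliquely oriented structures
  stay connected under 26-adjacency where 6-adjacency would fragment
  them; 6 and 18 remain available for stricter topology.

## The phantom generator

`makePhantom(phantomSpec())` renders the minimal geometry the method is
designed for: bright spherical bodies (default two, radius 6 on a 48³
grid, grey value 40000) joined by a dimmer cylindrical bridge
(thickness 3, grey value 30000) over a dark background (5000), then
applies a separable Gaussian blur (σ = 0.5 voxel) and additive Gaussian
noise (σ = 500) with a fixed RNG seed, clipped back to 16-bit. Ground
truth assigns each body its index and splits bridge voxels by nearest
body centre.

What it emulates: the bright-part/dim-joint/dark-background intensity
ordering, partial-volume softening at edges (blur), and detector noise.
What it does not: beam hardening, ring artefacts, anisotropic voxels,
contact regions with no intensity dip, and realistic anatomical shape —
so phantom scores are an upper bound on real-scan performance, and the
phantom's role here is correctness testing, not benchmarking.

## Problem sizes and limitations

The package is exercised on phantoms up to 48³ and is practical for
typical downsampled micro-CT working volumes (hundreds of voxels per
side); `downsampleVolume()` provides block-mean reduction for a
resolution sweep. Memory is the binding constraint: the volume, the
label array and the engine's working copies are held in RAM.

Limitations inherent to the method: it cannot separate parts that are
already merged at every usable `IT` (no intensity dip at the joint);
the split *inside* a joint region depends on `NI` and on the tie rules,
so joint-interior voxel assignment is a convention, not an estimate;
and the result is sensitive to the operator's choice of `IT` — too high
and small parts vanish from the seed, too low and parts merge before
seeding. `seedPreview()` exists precisely to check the seed before
committing to a run.
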