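---
title: "Modelling 3D hippocampal spatial cells with a linear autoencoder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling 3D hippocampal spatial cells with a linear autoencoder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Rodents navigating volumetric environments show place and grid cells whose
firing fields are markedly anisotropic: fields elongate along the gravity
axis in mazes where vertical movement is restricted (climbing lattices,
pegboards, helical tracks). This package implements a minimal trainable
model of that phenomenon and the complete statistical battery used to
characterise it.

The model has three stages.

**Head-direction (HD) layer.** A basis of preferred directions is built
from `n1` equally spaced azimuths $\theta_i \in [0, 2\pi)$ crossed with
`n2` equally spaced pitches $\phi_j$ spanning $[0, \pi]$:
$$U_i = (\sin\phi_i\cos\theta_i,\ \sin\phi_i\sin\theta_i,\ \cos\phi_i),$$
and the response of HD cell $i$ to the agent's velocity $v$ is
$HD_i = v \cdot U_i$. Pitches are sampled endpoint-inclusive, so `n2 = 3`
gives $\{0, \pi/2, \pi\}$; the poles duplicate across azimuths (every
azimuth at $\phi = 0$ is the same vertical vector) but are informative:
they encode pure vertical displacement. A single pitch (`n2 = 1`) sits at
$\pi/2$, i.e. tuning restricted to the horizontal plane.

**Path-integration (PI) layer.** Each PI neuron integrates its HD input
over time with a modulation factor $\beta$:
$$PI_i = \cos\Big(\beta \int_0^t v \cdot U_i\, dt\Big)
       = \cos(\beta\, z \cdot U_i),$$
where $z$ is the displacement from the starting position. The time
integral of velocity *is* displacement, so the package evaluates the
closed spatial form directly; the responses are purely functions of
position, periodic with spatial period $2\pi/\beta$ along each preferred
direction. The autoencoder input concatenates the cosine and sine terms,
giving $2\,n_1 n_2$ features in $[-1, 1]$.

**Autoencoder.** A linear three-layer autoencoder
(input $\to$ 50 $\to$ 50 $\to$ input) is trained to reconstruct the PI
features under mean squared error (10 epochs, contiguous 4:1
train/validation split, Adam with step size $10^{-3}$ and batch size 256,
seeded uniform fan-in initialisation). With linear activations the
network's optimum is the PCA subspace of the bottleneck width, and its
hidden units develop periodic and localised spatial tuning. The first
hidden layer is read out as the bottleneck (configurable, since both
hidden layers have 50 units).

## Experiment protocols

`run_experiment()` trains on a flat arena, classifies the 50 bottleneck
units as place/grid cells there, and then tests the classified units on a
3D maze:

| protocol | arena | points | n1 × n2 | β | maze |
|---|---|---|---|---|---|
| `lattice_aligned` / `lattice_tilted` | 5×5 | 50,000 | 20 × 3 | 3.0 | 5×5×5 lattice |
| `helix` | 2×2 | 50,000 | 20 × 1 | 7.5 | 5-coil helix |
| `pegboard` | 10×10 | 100,000 | 20 × 1 | 1.5 | 1×10×10 pegboard |

$\beta$ is never stated in the source literature beyond "depends on the
size of the environment"; the package scales it inversely with arena side
($\beta = 15/L$), chosen once so the PI spatial period is a fixed
fraction (~0.42) of the arena. Larger $\beta$ gives smaller fields — the
helical aspect ratios in particular inherit this sensitivity.

### Trajectories

* **Flat arena** — a constant-speed random walk with heading persistence
  (Gaussian heading increments, SD 0.4 rad per step; step 1/100 of the
  arena side) and specular wall reflection, implemented by mirror-folding
  the free path into the box. Coverage is uniform in the long run, which
  is the only property the downstream analysis needs.
* **Lattice** — a node walk on the 6×6×6 bar intersections. Aligned:
  vertical hops with probability 0.2, horizontal hops restricted to a
  180° field of view about the heading (forward, left, right). Tilted:
  the three lattice axes equiprobable, and the whole maze rotated 45°
  about the x axis (the rotation angle is configurable; no value is
  stated in the source). Node sequences are smoothed by a natural cubic
  spline and resampled to equidistant arc length, so speed is constant.
* **Helix** — five coils, height 5, track annulus radii 0.5–1. The
  unwound angle advances monotonically; the radial position follows a
  smooth reflected random walk (control points every 6° of track); height
  is linear in the unwound angle; up and down traversals are generated
  separately and analysed together.
* **Pegboard** — pegs on a 2-unit square grid in the 10×10 board plane;
  2000 hops to neighbouring diagonal pegs without immediate backtracking
  (a corner peg has a single neighbour, where returning is the only legal
  move), the along-peg x coordinate uniform in [0, 1]; the hop sequence
  is spline-smoothed and interpolated to 100,000 points. The source
  states both a 2-unit peg spacing and a $\sqrt 2$ diagonal, which are
  mutually inconsistent; the package defaults to the stated spacing
  (diagonal $2\sqrt 2$) and exposes `peg_spacing = 1` for the literal
  $\sqrt 2$.

## Classification

The classifier needs a non-negative "firing rate" for each linear unit.
Two constructions are used, for different purposes:

* **Counting events** (`threshold_events()`): trajectory points where the
  activation reaches its per-unit 80th percentile. These are the firing
  events entering the maze analyses — the 2D binned and 3D voxel rate
  maps of the field-geometry statistics.
* **Graded rate proxy** (`activation_rate()`): the activation is
  mean-centred, its sign corrected so the heavier tail points upward
  (linear units are sign-ambiguous), and activity is the exceedance over
  the per-unit 85th percentile. This drives the place/grid
  classification.

The distinction matters. Event counts at a fixed percentile make Skaggs
sparsity nearly identical across units (it reduces to the event fraction
times a smoothing smear), so gates on sparsity cannot discriminate
localised from periodic units. The graded proxy retains amplitude: a unit
with one dominant bump concentrates its suprathreshold mass and scores a
low sparsity, a periodic unit spreads it. The 85th-percentile threshold
is the one deliberately calibrated parameter of the pipeline — the
classification fraction rises steeply with it — and was fixed so that
suprathreshold activity occupies about 15% of samples, the occupancy
fraction of a typical rodent place field in an open arena. Classification
statistics (and their shuffle nulls) are computed on **unsmoothed**
binned rates, the classical form of the Skaggs statistics; smoothing a
20×20 map inflates the apparent active area severalfold and would push
every unit past the sparsity gate.

A unit is a **place cell** when all four gates pass: spatial information
$\sum_i P_i (R_i/R)\log_2(R_i/R) > 0.3$ bits/spike; Skaggs sparsity
$(\sum_i P_i R_i)^2 / \sum_i P_i R_i^2 < 0.1$; information above the 99th
percentile and sparsity below the 1st percentile of a 1000-fold
circular-shift null (uniform shifts, at least 5% of the series away from
zero). The sparsity formula is sometimes printed in reciprocal form
($\sum P_i R_i^2 / R^2$), which is $\ge 1$ for every map and cannot fall
below a 0.1 gate; `sparsity(..., printed_form = TRUE)` evaluates that
form, the Skaggs form is the default.

A unit is a **grid cell** by rotate-and-correlate gridness of the
spatial autocorrelogram (per-lag Pearson over overlapping pixels, at
least 20 pixels per lag), evaluated on an annulus that excludes the
central peak (inner radius at the first minimum of the radial mean):
$$HGS = \min[r_{60}, r_{120}] - \max[r_{30}, r_{90}, r_{150}], \qquad
  SGS = r_{90} - \max[r_{45}, r_{135}].$$
Hexagonal if $HGS > 0.3$ (and $\ge SGS$), square if $SGS > 0.3$; square
grid cells are excluded from downstream analyses.

## Field analyses

* **3D fields** (lattice): Eq.-style voxel rate maps on a 20×20×20 grid —
  kernel-weighted event counts over kernel-weighted occupancy, the kernel
  a Gaussian of one voxel SD truncated to the 26-neighbourhood —
  binarised at 20% of peak, 26-connected components larger than 50 voxels.
  Principal axes from voxel second moments; extents are 4 SD, floored at
  one voxel; elongation is the longest extent over the geometric mean of
  the other two (1 for a sphere). Statistics: per-axis centroid medians
  against a uniform-points null (1000 draws, 2.5/97.5 percentiles);
  orientation counts within 30° of each frame axis against a uniform
  orientation null, plus the cartesian/rotated count ratio against its
  1/99 percentile band; erosion connectivity with line structuring
  elements (surviving voxels per axis and length, expressed as the
  proportion across axes).
* **Helix fields**: each coil unwound into 60 angular bins; per-coil
  profiles (events/occupancy) circularly smoothed with a 1-bin Gaussian
  before detection at 20% of peak — unsmoothed profiles flicker around
  threshold through occupancy noise and split fields that are continuous
  across coils. Per-coil fields at the same track position (overlapping
  angular bins, or centroids within 0.3 units) merge into one helical
  field; axes come from the 3D second moments of the member events.
* **Pegboard fields**: 20×20 board-plane (YZ) maps, x marginalised;
  8-connected components of at least 3 bins; second-moment ellipse axes
  (minor floored at one bin); vertical extent counted over five equal
  2-unit layers; axis-wise spatial information from profiles collapsed by
  averaging across rows or columns.

## Numerical choices and degenerate inputs

Unvisited bins/voxels carry rate 0 and are excluded from statistics and
field extraction. Constant activations produce a warning and no events;
degenerate autocorrelograms signal an `undefined_statistic` condition, as
do maps with zero mean rate. Collinear 2D fields floor the minor axis at
one bin width; planar 3D fields floor extents at one voxel. All
stochastic stages derive their seeds from one master seed by fixed
offsets, so an experiment is reproducible byte for byte and stages can be
re-run in isolation.

## What the synthetic data does and does not emulate

The trajectory generators reproduce the movement *statistics* the
analyses depend on — bounded uniform coverage, constant speed, the stated
vertical-hop probabilities, the helical track geometry, diagonal peg
hopping — not locomotor dynamics, speed modulation, behavioural states,
or sensory input. Because the PI layer is evaluated in its exact spatial
closed form, every bottleneck unit is a noiseless function of position;
shuffle-null gates therefore pass for any spatially structured unit, and
the binding constraints are the absolute information/sparsity gates.
Passing tests show the pipeline's statistics behave correctly on such
idealised data; they do not show robustness to spike noise, electrode
drift, or the path-integration error of real animals.

## Known limitations

* The place-cell fraction depends steeply on the calibrated firing
  threshold (see above); the reported fractions should be read with that
  sensitivity in mind, as should the source values they are compared to.
* Helical field sizes in the track plane scale with $1/\beta$; with
  $\beta = 15/L$ the in-plane fields are small enough that weak fields
  are sometimes undetected on individual coils, which depresses the
  coils-spanned percentages relative to an analysis with larger fields.
* Gridness rotations use bilinear interpolation; scores carry a small
  (<0.05) interpolation bias at non-multiples of 90°.
* The vignette-level problem sizes (50,000–100,000 points, 1000
  shuffles, five replicates) are the package defaults; they were chosen
  as the smallest sizes at which the headline statistics stabilise.
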