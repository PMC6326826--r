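---
title: "Methods: quantitative 2D enamel rod morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative 2D enamel rod morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rodmap)
```

## The measurement problem

A transverse section of a rodent incisor exposes the full enamel band from
its lateral to its mesial cementoenamel junction (CEJ). Enamel rods — one
per ameloblast — are cut open as small profiles: elongated ovals in the
thick inner layer, organised into rows that alternate between a mesial and
a lateral tilt; diamond-shaped profiles in the thin outer layer; and
disordered profiles near the two CEJs. Four quantities characterise this
architecture:

1. **Composition** — how many profiles of each category a section contains;
2. **Orientation** — the tilt angle of each profile in the section plane,
   summarised by circular statistics per tilt category and per region;
3. **Row organisation** — rows per section, rods per row (RPR), and the
   angles between adjacent alternating rows (decussation angle; its
   supplement, the alternating inter-row angle);
4. **Packing** — inter-centroid spacing within rows (inner layer) and
   nearest-neighbour distances (outer layer, CEJ).

`rodmap` computes all four from color-coded category layers plus band
geometry annotations, and ships a synthetic generator whose maps carry
exact per-rod ground truth, so the whole pipeline can be validated by
parameter recovery rather than by eye.

## Measurement conventions

* **Coordinates.** World x increases lateral → mesial, y increases
  DEJ → surface. Angles are degrees counterclockwise from the 3 o'clock
  direction, in [0°, 180°). All raw measurements are in pixels and are
  converted with an explicit pixels-per-micrometre factor — the scale is
  always an input, never inferred.
* **Particles.** Foreground components are 8-connected (two squares
  touching at one corner are a single particle). The convex hull is built
  on pixel *corners*, not centres, so a 1 px particle has a long Feret of
  √2 and a minimum caliper width of 1 rather than zero.
* **Feret statistics.** `feret_max` is the hull diameter (maximum caliper
  width); `feret_min` is the minimum caliper width from rotating calipers
  over hull edges; the Feret angle is the direction of the maximal chord.
  When several chords are exactly maximal the angle is the axial
  (doubled-angle) mean of the tied directions, which keeps vertically
  symmetric particles exactly vertical; tie sets with no defined axial mean
  (the two diagonals of a square) fall back to the smallest angle, so an
  axis-aligned square measures 45°.
* **Directions, not axes.** Circular means use the plain direction
  statistics (mean direction from atan2 of mean sines and cosines,
  resultant length R̄, circular SD √(−2 ln R̄)). Orientations in
  [0°, 180°) are *not* doubled before averaging: this is the convention
  under which the mean of {30°, 60°, 80°} is 57° to the nearest degree,
  and it matches how tilt summaries are reported in this field.
* **Regions.** Normalized ("virtual") coordinates rescale centroids to
  [0, 1] by the bounding rectangle of the enamel layer. Regions 1–4 are the
  half-open quarters of normalized x, right edge closed at 1; region 1 is
  lateral, region 4 mesial. The bin edges are a package choice — only the
  "four equally spaced regions" partition itself is standard.
* **Thickness.** Measured along the inward surface normal at the point of
  maximum convexity of the (smoothed) outer surface: total to the DEJ,
  split at the inner/outer layer boundary. On a constant-curvature arc all
  surface points are equally convex, so the apex is taken; a flat band uses
  its mid-x point.
* **DEJ-relative angles.** The local DEJ tangent is a total-least-squares
  line fit over a sliding window (default 50 μm) of the DEJ polyline;
  the DEJ-relative angle is (θ − tangent) mod 180°. On curved bands this
  removes the component of the lateral→mesial angle gradient that is pure
  band curvature.

## Row assembly

The reference workflow outlined each row by hand with an irregular polygon.
`rodmap` automates this: profiles of one tilt category are linked to their
nearest same-category neighbour within a gating distance (default 2.5× the
category's median nearest-neighbour distance), plus their second-nearest
neighbour when that link extends the chain on the opposite side (direction
consistency). Connected components of the link graph are the rows. Chains
shorter than `min_chain` (default 3) are kept as flagged orphan rows —
never silently dropped.

Within a row, members are ordered along the row's principal axis; for rows
that run laterally this reduces to the classic sort by centroid x (with
ties broken by y), and for rows that cross the band depth-wise it follows
the chain. Row ids are assigned by the depth of the row midpoint below the
DEJ, quantized to 25 μm bins with ties broken lateral → mesial: rows at a
common depth are thereby numbered in spatial order, which makes
"depth-adjacent" pairs spatially adjacent and the decussation pairing
deterministic. Adjacent pairs that fail to alternate tilt are skipped and
counted, not fabricated.

The midpoint of an even-RPR row is the mean of the two central centroids (a
definition this package fixes; only odd counts have a literal middle
member). `distance_from_dej` is anchored at the row midpoint.

Decussation is reported two ways, side by side: computed from regional
grand-mean directions of the two tilt categories, and as the mean of
row-by-row angle differences between adjacent alternating pairs
(`decussation_regional()`). The inter-row angle is defined as exactly
180° minus the decussation angle of the same pair, so the two columns are
supplements by construction.

## The synthetic generator

### What it emulates

The default `rod_config()` describes one cross-section at the published
grand means: a 121 μm thick band (inner 100, outer 21 μm), 7233 profiles
split 70/27/3 % between inner, outer and CEJ categories by
largest-remainder apportionment (5063/1953/217), the inner profiles in 124
rows alternating mesial/lateral tilt, regional circular-mean anchors of
58.4°→147.0° (mesial tilt) and 29.9°→75.6° (lateral tilt) across regions
1→4 with the corresponding circular SDs, an outer-layer gradient pooling to
≈69.5°, CEJ orientation 101° ± 43.9°, and per-region spacing anchors in
which lateral-tilt spacing roughly doubles from region 3 to region 4 while
the outer layer packs tighter than the inner. CEJ profiles split 5:1
mesial:lateral. Inner rods render as 1.8 × 0.6 μm ellipses, outer rods as
1.3 × 0.65 μm rhombi, CEJ rods as randomly perturbed superellipses, at a
default scale of 16 px/μm.

Several defaults are calibration choices the data source does not pin
down numerically, made once: the band width (744 μm — 124 rows at a 6 μm
lateral pitch), rod profile dimensions (chosen so the default census packs
without overlap; profile sizes are not published), the interior (region 2
and 3) anchor values (linear in the published per-region step sizes), and
the spacing anchors (chosen to reproduce the published qualitative
gradients and the row count/row length accounting: ~41 rods per row at
~2.2 μm spacing spans the 100 μm inner layer).

### Layout model

Rows are generated as near-straight chains running from the DEJ toward the
layer boundary along the local band normal — one chain per lane, lanes
alternating tilt lateral → mesial. Rod *orientations* (what the pipeline
measures) are drawn from the regional angle field independently of the
chain direction. This decoupling is deliberate: genuinely decussating
sheets interdigitate in a real section and cannot be rendered overlap-free
at realistic densities, while the lane model preserves every quantity the
pipeline measures — counts, row structure, orientation statistics, spacing,
and decussation (which is computed from member-angle means, not from chain
geometry). The rendered picture is therefore a statistical emulation, not a
visual replica: interrod enamel, abutting profiles, etching texture and
montage artifacts are all absent, and real maps will stress segmentation in
ways these clean layers cannot. Passing recovery tests validates the
measurement chain, not robustness to imaging noise.

Within a lane, rods per row come from capacity-capped largest-remainder
apportionment of the inner census (lanes with tighter spacing receive more
rods — which also reproduces the published slight mesial-tilt excess
without an explicit parameter), gaps are jittered ±2 %, lateral positions
±0.25 μm, and every placement guarantees a 2 px rendered clearance, so the
rendering → extraction round trip preserves counts exactly. Infeasible
requests (a census that cannot fit) fail with an error naming the limiting
region rather than silently under-filling.

### Angular noise

Angle draws are normal around the local field mean, then *reflected* (not
folded mod 180) into [0°, 180°): a draw just below 0° maps to a direction
just above 0°, never to the far side of the half-circle. Reflection
respects the axial topology of orientation data; modular folding teleports
the spilled tail by 180° and visibly biases the directional circular mean
for wide distributions, while truncation biases it by shaving one tail.
With reflection, the recovered circular mean stays within a fraction of a
degree of the configured mean for the SD range of the default field, and
the circular SD is preserved to a few per cent for SDs up to ≈35°. For very
wide cells (the lateral-tilt lateral region, SD 52.8°) *no* distribution
supported on a half-circle can reproduce both the stated mean and SD
unchanged; the generator stores the realised truth per rod, and recovery is
always judged against that truth.

### The regional field

Field values interpolate the four region anchors piecewise-linearly in
normalized x, with knots at the region boundaries ± 0.025: constant
plateaus inside each region joined by narrow ramps. A centre-to-centre
linear interpolation was rejected because it shifts the *regional average*
of edge regions by an eighth of the inter-region step (several degrees
here), which would make the generator's regional means disagree with its
own anchors. The ramp half-width is exposed as
`transition_halfwidth`.

### Frames and curvature

The band may be flat or an arc (`curvature_radius_um`). The angle field is
anchored in the section frame by default, so configured regional means are
what a section-plane measurement recovers regardless of curvature;
`angle_frame = "dej"` anchors it in the DEJ-parallel frame instead, which
is the physically motivated choice for curved bands and reproduces the
characteristic flattening of the lateral→mesial gradient when angles are
re-measured relative to the DEJ. The default band is flat: curvature adds
nothing to the measured statistics in the section frame, and the arc mode
is exercised separately (thickness invariance, DEJ-frame flattening).

## Numerical choices and degenerate inputs

* Feret widths agree with an exhaustive 0.1°-step rotation oracle to
  0.05 px; the oracle lives only in the test suite.
* Orientation precision of the Feret angle scales with profile length and
  aspect ratio: the maximal-chord direction is flat near its maximum, so
  half-pixel corner noise moves the argmax by ~√(1/L) radians. Pooled and
  regional circular means of the default rods are accurate to well under a
  degree; single-profile recovery at the 2° level needs elongated profiles
  (aspect ratio ≳ 3 at ≳ 100 px length), which the recovery tests use.
* Empty masks yield zero particles and valid empty tables end to end;
  empty spacing groups are absent from tables, not zero.
* A degenerate bounding box, out-of-range normalized coordinates,
  non-positive scales or bandwidths, profiles outside the band, and
  same-tilt row pairs passed to the inter-row angle all raise immediate
  errors naming the offender.
* DWLS smoothing (`dwls_surface()`) is local *linear* regression with
  Gaussian distance weights (bandwidth: 0.25 of the data range). It is
  exact on planar inputs by construction and is visualisation support
  only — no numeric conclusion depends on it.
* The pipeline contains no randomness: one seed fixes a map bit-exactly,
  and re-running an identical configuration reproduces every CSV byte for
  byte (the run manifest records config, seed, parameters, stage counts and
  output digests).

## Problem sizes used in validation

The test suite exercises most operations on small bands (a few hundred
profiles, 12 rows) and validates full-scale behaviour on a handful of
7233-profile maps: counts, row count and thickness on one map; regional
circular-mean recovery pooled over four maps; pooled grand-mean recovery on
two maps whose angle fields are held constant at the published grand means.
The acceptance script uses five seeds for each stochastic quantity. These
sizes were chosen to make stochastic checks well-powered (≥ 2000 angles per
cell) while keeping a full run in minutes on a single CPU.

## Known limitations

* 2D only: rows are treated strictly within the section; row branching or
  merging in 3D, and the incisal (out-of-plane) tilt of rods, are out of
  scope.
* No automatic category classification or DEJ/surface tracing from raw
  grayscale micrographs: color-coded layers and geometry annotations are
  inputs.
* The generator's lane architecture does not emulate interrod enamel or
  interdigitating sheets (see above); its realism is statistical, not
  textural.
* Descriptive statistics only — no inferential tests are computed.
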