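---
title: "Methods: voxel extraction, surface quantification, and the synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxel extraction, surface quantification, and the synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aive)
```

## The model

Semantic segmentation of volume-EM data yields per-voxel class
probabilities $P \in [0,1]$. Binarizing $P$ at a decision threshold places
the object surface at the model's least certain voxels, and independently
trained models disagree there by tens of nanometers. AI-directed voxel
extraction replaces the decision threshold with the electron signal: after
contrast normalization the 8-bit intensity $I$ is multiplied voxel-wise
into the (Gaussian-smoothed) probability,

$$V_\mathrm{out} = \mathrm{round}(P \cdot I),$$

so that voxels with no electron signal contribute nothing regardless of
the model's opinion, and the surface extracted from $V_\mathrm{out}$ is
anchored to the stain. Because $V_\mathrm{out}$ is a product of two
independent dynamic ranges, the center of its range is 25%, not 50%: two
mid-range inputs give $0.5 \times 128 = 64$, which is the default
isosurface threshold everywhere in the package.

Assumptions: the EM volume, the probability maps and the label volume are
co-registered on one anisotropic grid (axis order $(z,y,x)$, spacing
$(c,b,a)$ nm, voxel centers as positions); intensities are 8-bit with
membranes brighter than their surroundings (osmium contrast polarity);
organelle labels are approximate regions that *identify* an instance
without defining its boundary.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `tile_nm` (CLAHE) | 416 | nm | physical sliding-window size; per-axis window is `round(tile_nm / spacing)` px, so anisotropic voxels give rectangular windows (e.g. 26×80 px in XZ at 10/3.255 nm) |
| `clip_limit` | 3 | – | CLAHE histogram clip factor |
| median `radius_nm` | ≥ max spacing | nm | shot-noise suppression; per-axis half-width `round(r / spacing)` |
| `sigma_nm` | 10 | nm | Gaussian pre-blur of probabilities and of label masks |
| `isovalue` | 64 | 8-bit | surface threshold for AIVE-derived grids |
| contact `threshold_nm` | 35 | nm | membrane-contact-site criterion |
| histogram `bin_nm`, range | 5, 0–250 | nm | area-weighted separation brackets |
| probe `dilation_nm` | 35 | nm | probe eligibility shell around membranes |
| `closing_radius_nm` | 150 | nm | cavity-detection closing element; covers the reported inscribed radii (≤ 50.6 nm) and depths (several hundred nm) |
| `min_depth_nm` | 50 | nm | geodesic depth below which an indentation is not an intrusion |

The CLAHE tile (416 nm ≈ 128 px in-plane) and clip limit are conventional
CLAHE settings; they are surfaced in the configuration because no single
value suits all acquisitions. How the three orthogonal CLAHE passes merge
is genuinely open; the voxel-wise arithmetic mean is the default (symmetric
and bounded) with `min`/`max` available for sensitivity checks. Membrane
subclasses (Memb, Vesc) merge by probability **maximum**, which cannot
leave $[0,1]$; summation could.

## Surface extraction

No marching-cubes implementation exists in the R stack this package
builds on, so isosurface extraction is authored here in C++. Each grid
cell is split into the six Freudenthal tetrahedra sharing the cell's main
diagonal and each tetrahedron is triangulated by linear interpolation
along its edges at the isovalue crossing. This decomposition is consistent
across shared cell faces, so closed level sets give watertight,
crack-free meshes without the face-ambiguity cases of the classic
cube-based table; the trade-off is roughly twice as many triangles and a
slightly faceted surface. The 256 corner configurations of the cube-based
formulation and their reduction to 15 canonical cases under rotations with
complementation are reproduced programmatically by
`cube_config_classes()` as a documentation check.

Vertices interpolate *between voxel centers*: binary data meshed at the
mid-level isovalue place vertices at exact edge midpoints, which is what
limits the smallest measurable nonzero separation of binarized objects to
$\sqrt{(a/2)^2 + (b/2)^2}$ over the two smallest voxel dimensions
(2.3 nm at 10 × 3.255 × 3.255 nm). Scalar AIVE grids place vertices
anywhere along the edge and escape that lattice; the package asserts both
facts empirically (1,000 random binarized pairs never measure a nonzero
distance below $a/\sqrt2$ on a unit grid).

Faceting inflates raw triangle area by a few percent, which depresses
sphericity $36\pi V^2/A^3$. `smooth_mesh()` (Taubin $\lambda|\mu$
smoothing, defaults $\lambda = 0.5$, $\mu = -0.53$, 10 passes) restores an
analytic sphere's area to within ~1% without volume shrinkage and is
applied before morphometric measures; enclosed volume is accurate to
well under 1% even unsmoothed.

Numerical conventions: round-half-up when converting to 8-bit;
`fill_organelle` saturates at 255; meshes are cleaned of duplicate
vertices (10⁻⁶ nm quantization) and zero-area triangles; volume and
sphericity are reported only for watertight meshes (open meshes keep area
and are flagged); empty isosurfaces are valid empty meshes, not errors.

## Distances, probes, histograms

All distances are Euclidean in nm, computed in physical coordinates.
Surface separations are point-to-nearest-triangle against an AABB tree,
exact with respect to a brute-force oracle (asserted to 10⁻⁶ nm). The
side of the nearest triangle is retained for containment queries; the
magnitude is what all summaries use. Separation histograms weight each
query vertex by one third of its incident triangle area (the natural
vertex quadrature; the alternative — unweighted vertices — biases toward
finely triangulated regions), use half-open 5-nm brackets and pool
everything at or beyond the range maximum into an overflow bin, so the
percentages always total 100.

Probe placement samples voxel centers uniformly from the eligibility
shell (within 35 nm of a membrane, not inside one, optionally also within
35 nm of a class label). The upstream work seeded candidate points with a
diffusion-limited-aggregation simulation whose parameters are not
recorded; since the shell filter dominates where probes can end up,
uniform rejection sampling inside the shell is used instead, seeded and
reproducible. Probe consistency is summarized by the range
($\max - \min$) and the relative absolute deviation
$\mathrm{RAD} = \overline{|x_i - \bar x|}/\bar x$ (undefined at zero mean,
flagged rather than silently dropped).

When the raw and blurred probability conditions are benchmarked against
AIVE, their surfaces are extracted at **half of each map's own maximum** —
the "center of the dynamic range" decision-threshold logic applied to the
range the map actually occupies (a 10-nm blur of a 20-nm band peaks well
below 1, so a fixed 0.5 threshold would sit near the peak where crossings
are unstable). AIVE grids always use isovalue 64.

## Morphometry

Equivalent-ellipsoid axes come from the voxel covariance with the
per-voxel second moment $\mathrm{diag}(s^2/12)$ added, so a digitized box
measures its true side ratios; elongation is major/minor. Skeletons are
computed by topology-preserving 3D thinning (simple-point removal in six
directional sub-iterations with curve-endpoint preservation, candidates
re-checked sequentially), and the longest optimal path is the maximum over
endpoint pairs of the geodesic length through the skeleton graph (edges
weighted by physical step length; for skeletons without degree-1 endpoints
— pure cycles — all vertices are candidate endpoints). Thinning with
directional passes is only near-equivariant under grid rotations: lengths
are reproducible to about two voxel diagonals, which is the tolerance the
tests assert.

A nanotunnel is flagged when the thresholded matrix of one connected
organelle splits into two or more components — a membrane tube without
matrix joining matrix lobes — and is an error to ask of a disconnected
solid.

Intrusion cavities are not observable as simple thresholded voids: an
intrusion is a narrow invagination of the outer membrane reaching into the
interior. The detector closes the solid with a spherical element
(`closing_radius_nm`), subtracts the solid, and keeps candidate components
that (a) reach the exterior through an opening — components sealed inside
are inclusions, not intrusions — and (b) are deeper than `min_depth_nm`
along the geodesic from the exterior through the non-solid space. The
grid is padded by the closing radius so the element is never clipped at
the dataset border. A cavity is "filled" by another organelle when more
than 50% of its voxels carry a foreign label; the majority label's class
names the category, otherwise the cavity is empty. Metrics per cavity:
volume (voxel count × voxel volume), largest inscribed sphere radius (max
of the interior distance transform) and the major axis as the **extent
along the principal covariance axis** — for an elongated cavity of length
$L$ this measures $\approx L$, whereas a moment-ellipsoid axis would
overshoot a cylinder's length by 29%.

Instances whose solid touches the dataset border are flagged and excluded
from whole-organelle shape metrics but retained for distance analyses.
The Poisson occurrence model uses $\hat\lambda$ = events/instances
(50/186 = 0.269 in the motivating data) with the standard pmf.

## The inverse needle problem

The probability that a linear intrusion of length $L$ lies fully inside a
section of depth $d$ is one minus the classical Buffon crossing
probability (planar formulation, uniform orientation angle), which
reproduces the printed landmark values exactly at $L/d = 3.675$, $1$ and
$0.0735$; a 3D-orientation variant does not, which is why the planar form
is used. The half-intrusion curve is the intact probability of a needle
of length $L/2$; its analytic value at $L = 367.5$, $d = 100$ is
0.17798, which agrees with the reported 0.177964 to three decimals — the
package asserts three-decimal agreement only, since the upstream numeric
procedure is not recorded. The Monte-Carlo oracle (`p_intact_mc`) drops
needles with uniform center offset and angle; the test suite bounds each
of six $L/d$ ratios at 4 standard errors and the joint $\chi^2$ statistic
at its 99.9% quantile (six simultaneous 3-SE checks would false-alarm at
the ~2% family level).

## What the synthetic generator emulates — and what it does not

Phantoms render membranous shells, tubes, dumbbells and intruded sphere
pairs on the 10 × 3.255 × 3.255-nm grid with a one-voxel membership ramp
at boundaries, 8-bit intensities (membrane 200, matrix 140, cytosol 60),
additive Gaussian noise (sd 8) and salt-and-pepper shot noise (0.5% of
voxels). Instance labels extend 30 nm beyond each object (nearest object
wins where margins overlap), reflecting that annotators draw labels
generously around organelles rather than tracing boundaries.

Simulated AI variants model three empirically motivated components of
inter-model disagreement:

1. **boundary displacement** — a divergence-free random warp
   (curl of a smoothed vector potential, correlation length 5 nm,
   amplitude `boundary_jitter_nm` = 10 nm sd per axis). Divergence-free
   matters: models disagree about where a boundary runs, not whether a
   membrane exists, so thin structures must translate locally, not
   compress or vanish. The short correlation length encodes that
   disagreement between independently trained algorithms is localized at
   the scale of individual image features;
2. **confidence graininess** — per-voxel Gaussian noise (sd 0.05) on the
   probability scale;
3. **false-positive clutter** — isolated speckle voxels (rate 0.002,
   confidence U(0.5, 1)), the component that makes surfaces from raw
   per-voxel classifier output unreliable and that the 10-nm pre-blur
   suppresses.

Interiors sit at `interior_conf` = 0.9. With all three components at
their defaults the generator reproduces, at fixed seed, the orderings
that motivate the method: mean pairwise ΔV and probe range/RAD each
decrease from raw predictions to blurred predictions to AIVE output.

What the phantoms do **not** emulate: real classifier textures (RF/CNN
idiosyncrasies), FIB-SEM curtaining, charging and milling artifacts,
registration error between slices, cristae-level interior structure, and
correlated multi-organelle geometry. Passing tests therefore demonstrate
that the implementation behaves correctly *mechanistically* — that the
multiplication, meshing and measurement chain preserves geometry and that
the benchmark orderings follow from the modeled disagreement structure —
not that any particular biological dataset would yield the same numbers.

## Problem sizes

The test and acceptance suites run on deliberately desk-scale volumes:
the trend rehearsal uses a 44×120×120-voxel shell phantom with six
variants and 30 probes; the intruded-contact benchmark uses full
128-voxel-diameter sphere pairs (≈ 5×10⁶ voxels, ≈ 4.6×10⁵ triangles);
the binarized-pair sweep uses 1,000 pairs on 14³ grids; the Monte-Carlo
needle oracle uses 10⁶ trials per ratio. These sizes were chosen so the
whole suite completes in a few minutes while every quantity remains
well-resolved.

## Known limitations

- The tetrahedral decomposition roughly doubles triangle counts relative
  to cube-based tables; raw (unsmoothed) areas carry a few percent of
  faceting inflation — use `smooth_mesh()` before area-sensitive measures.
- HDF5 volumes are not read; supported formats are multi-page TIFF and
  MRC2014 (TIFF carries no physical spacing here, so `spacing` must be
  supplied).
- Thinning-based lengths are reproducible to ~2 voxel diagonals under
  grid rotation, not exactly.
- `mask_by_label` with a tight label and a large blur attenuates
  probabilities at the organelle's own boundary; labels should be
  generous (the phantom generator's 30-nm margin reflects this).
- The cavity detector's closing-difference heuristic is this package's
  operationalization of "intrusion"; the opening width and depth
  thresholds are exposed rather than canonical.
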