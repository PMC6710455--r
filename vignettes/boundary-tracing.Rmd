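---
title: "Continuous boundary tracing of densely packed nuclei: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous boundary tracing of densely packed nuclei}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleotrace)
```

## The problem

Confocal stacks of brain tissue image cell nuclei as bright, roughly
convex blobs whose axial (z) resolution is about three times worse than
the lateral one. In densely populated regions -- the granular layer of
the hippocampal dentate gyrus is the extreme case -- neighbouring nuclei
approach each other so closely that on many z-sections they appear to
overlap with no visible border, while intranuclear structure
(chromocenters, inhomogeneous chromatin) can be more contrasted than
the border itself. Threshold- or watershed-style segmentation breaks
such images at the wrong places: thresholds split nuclei at internal
inhomogeneities and merge them at seams.

`nucleotrace` instead relies on three weak assumptions about nuclei:

1. **Membrane continuity** -- between adjacent thin optical sections the
   boundary changes only slightly;
2. **Separability somewhere** -- for almost every nucleus there is some
   z-section on which it is well separated from its neighbours;
3. **Convexity** -- the cross-sectional area along z rises to a single
   maximum and falls, so a renewed area increase signals that the trace
   has slid into a neighbour stacked above or below.

No intensity threshold is applied anywhere in the tracer, which makes
the segmentation invariant under global intensity scaling and robust to
poor or varying contrast.

## The procedure

**Seed detection.** Every z-plane is convolved with a disk-mean
(circular matched) filter of radius half the minimal nucleus diameter.
Local maxima of the response become seed candidates; the response value
is the seed's *priority weight*. A seed with high weight sits near the
in-plane centre of a nucleus on a section where that nucleus is well
separated -- exactly where tracing should start. Candidates are then
screened twice:

* *Ring-contrast stability*: mean intensity over concentric rings
  (width `ring_width`) must change by at most `tau_contrast`
  relatively between consecutive rings inside the minimal nucleus
  radius, and the ring fluctuation (sd/mean) must stay below
  `tau_fluct`. Seeds at the junction of two touching nuclei fail this,
  because a dark seam crosses their inner rings.
* *Moment gate*: intensity-weighted dipole/quadrupole moments of the
  surrounding region, computed literally from their defining sums with
  a step-function cutoff at radius `r_m` and a regulariser `eps`.
  Oval, centred regions score near zero; displaced or obliquely
  elongated regions score high and are rejected. Two quirks of the
  defining formulas are preserved deliberately rather than "fixed":
  the `(a^2 - x^2)` numerator makes the xx-component vanish
  identically, so the quadrupole determinant reduces to `-q_xy^2` and
  responds only to obliquely oriented anisotropy; and the magnitude
  names pair the dipole components with the "q" label. Both are
  documented at `?multipole_moments`; the literal formulas are covered
  by brute-force oracle tests.

**Contour tracing** (per plane). From the seed, `n_rays` equally
spaced rays sample the image bilinearly at unit steps. On each ray the
boundary candidate is the maximum of the profile's convolution with an
antisymmetric box-derivative mask of half-width `mask_halfwidth`
(bright-to-dark steps score positive; the zero-sum mask gives zero on
constants). Candidates are chain-clustered cyclically: consecutive
points within `max_dev` (the *maximal intracluster deviation*) share a
cluster; singleton points are discarded. The largest cluster is trusted
and the remaining rays are re-searched one by one, each restricted to
`+- max_dev` of its neighbour's accepted radius, until the contour
closes. Rays that still find no edge are filled by cyclic linear
interpolation (the extrapolation any human tracer applies across holes
and artifacts) and flagged; more than 25 % interpolated rays is a
tracing failure. Seeded tracing runs two such passes -- the first over
the full radial window, the second restricted to `+- delta_pass` of the
first pass's radii.

**Edge confidence floor.** A degenerate (constant) profile would
otherwise yield an arbitrary argmax, so an edge is accepted only when
its response exceeds `kappa_edge` times the median absolute response
of the profile. The median is taken over the *full* valid radius range
rather than the current search window: in the tight re-search windows
(7 samples wide at the default `max_dev = 3`) the window itself
straddles the edge, its median is edge-sized, and a window-local floor
would reject nearly every ray of even a perfectly clean disk. The
full-profile median keeps the intended protection (constant profiles
still yield "no edge"; noise maxima must beat 3x the typical response)
without that pathology.

**Quality gating and propagation.** Each contour gets a laminar
quality `Q`: for every boundary point, image brightness is integrated
over a layer of width `delta_r` just inside and just outside the
boundary, along the ray from the contour's mass centre; `Q` is the
fraction of points whose inner integral strictly exceeds the outer one.
(The defining expression printed as a step function of the layer ratio
is degenerate -- identically 1 for positive intensities -- so the
stated intent, an inside/outside comparison, is what is implemented;
ties count as failures, so a contour inside a uniform region scores 0.)
Tracing proceeds to the adjacent plane, restricted to the tubular
neighbourhood `+- delta_tube` of the previous contour, and repeats in
both z-directions until one of the termination rules fires:

* `quality` -- `Q < q_min` or the trace fails;
* `point-like` -- contour area below that of a circle of diameter
  `a_point_factor * d_min_xy`;
* `low-signal` -- mean intensity inside the contour below the
  background estimate (median + 1 sd of the 1st-20th percentile band
  of the starting plane, computed once per stack);
* `area-regrowth` -- area increases on two consecutive planes after a
  monotone decrease of at least two planes; the regrowth planes are
  discarded (this is what separates z-stacked touching nuclei);
* `z-limit` -- stack border, or more than `z_max` planes traced.

Accepted surfaces must span `z_min` to `z_max` planes. Seeds inside an
accepted nucleus are eliminated, and the next-highest-weight seed
starts the next nucleus. Surfaces touching the lateral stack walls, or
whose propagation hit the first/last plane, are set aside as cropped:
their morphometry would be biased.

## Tunable parameters

| key | unit | default | role |
|---|---|---|---|
| `d_min_xy`, `d_max_xy` | px | 24, 80 | min/max in-plane nucleus diameter; drive the filter radius, ring extent, ray length |
| `z_min`, `z_max` | planes | 4, 40 | min/max axial extent of an accepted nucleus |
| `w_min` | intensity | estimated | minimal priority weight; default background mean + 2 sd per plane |
| `ring_width` | px | 2 | ring width of the contrast filter |
| `tau_contrast` | -- | 0.25 | max relative ring-to-ring mean change inside `d_min_xy/2` |
| `tau_fluct` | -- | 0.6 | max ring sd/mean inside `d_min_xy/2` |
| `r_m`, `eps` | px | `d_min_xy/2`, 0.5 | moment analysis radius and regulariser |
| `mq_max`, `md_max` | -- | 0.008, 0.05 | moment gates, in units of `I_ref * r_m^2` (phantom-calibrated, see below) |
| `n_rays` | -- | 90 | boundary sampling (4 degrees) |
| `mask_halfwidth` | px | 4 | edge mask half-width |
| `max_dev` | px | 3 | maximal intracluster deviation |
| `delta_tube` | px | 4 | tubular search half-width between planes |
| `kappa_edge` | -- | 3 | edge confidence floor multiplier |
| `q_min` | -- | 0.85 | laminar quality threshold |
| `delta_r` | px | 4 | laminar layer width |
| `theta_detect`, `theta_defect` | -- | 0.3, 0.05 | evaluation: detection overlap floor; PS voxel-defect bound |

Notes on the defaults that are genuinely open choices:

* `q_min = 0.85`: the quality threshold is user-set by design; 0.85
  tolerates a modest fraction of ambiguous boundary points while
  rejecting contours that drift into background (where `Q` collapses
  towards 0.5 and below). It is a required, documented knob, not a
  constant of the method.
* `mq_max`, `md_max`: the literal moment magnitudes scale with
  intensity and region size, so the gates are expressed in units of
  `I_ref * r_m^2` (`I_ref` = 90th intensity percentile of the plane).
  The shipped values were calibrated once on ellipsoid phantoms:
  centred nuclear sections score ~0, a section displaced by `r_m/2`
  scores ~0.015 on the dipole magnitude, an obliquely oriented 10:1
  bar scores ~0.19 on the quadrupole magnitude. Gates of 0.008 and
  0.05 sit between those regimes. They are phantom-calibrated, not
  tissue-derived, and should be re-examined per imaging modality.
* The edge mask is a box derivative: the published account shows the
  mask's bipolar shape but no formula, and a box derivative matches
  that form with a single parameter (`mask_halfwidth`).
* Sub-pixel edge localisation is out of scope; radii are whole pixels.

## The phantom generator

`generate_phantom()` renders ellipsoids of known centre, semi-axes and
orientation into a voxel grid: interior intensity combined by
**maximum** (not sum), so touching nuclei show the realistic "no clear
border" seam rather than a bright ridge; optional chromocenter blobs;
per-channel internal spheres standing in for FISH-labelled alleles;
separable Gaussian blur (defaults 1.5 px lateral, 1.0 plane axial,
approximating the ~3x worse axial optical resolution at 80/200 nm
sampling); additive Gaussian noise (the noise level is a required
field -- validation phantoms must state it); optional small bright
background particles mimicking unspecific stain binding (default
density 0). Identical spec + seed gives bit-identical voxels. Voxels
inside two or more ellipsoids are labelled by the smallest normalised
ellipsoid distance and recorded in an ambiguity mask.

What phantoms do **not** emulate: a physically accurate point-spread
function, photon (Poisson) noise, spectral crosstalk, true chromatin
texture, or glial-vs-neuronal identity. Passing the phantom suite
therefore demonstrates geometric correctness of the algorithm and its
measurements, not tissue-level performance; the published manual
validation on real stacks is represented here only by its category
counts (see `reference_category_counts()`).

### Validation geometry

The recovery phantom is a 256 x 256 x 60 stack at 0.25 x 0.25 x 0.5 um
voxels (64 x 64 x 30 um) holding 8 randomly oriented ellipsoids with
semi-axes 4-6 um and additive noise of 10 % of the interior intensity.
At the raw acquisition sampling of 80 nm laterally a single nucleus
would span most of a 256-pixel tile, so the phantom uses this 2-4x
coarser, still realistic voxel size at which a dense field of granule
cell nuclei fits the tile; this also keeps the full phantom suite
running in minutes. The same reasoning fixes the smaller sphere
phantoms (64 x 64 x 32) used for the morphometry cross-check.

## Morphometry

Volume integrates the per-plane shoelace areas over the plane spacing.
Membrane area comes from a triangulated shell: rings stitched between
adjacent planes, pole caps fanned to an apex half a plane spacing
beyond the end contours; the mesh is closed (each edge borders exactly
two triangles). Because traced radii are quantised to whole pixels, the
raw shell is microscopically rough, and roughness only ever *inflates*
a surface area (~11 % on a clean 4-um sphere). The mesh therefore
de-quantises the radii first with a narrow (1,2,1)/4 moving average --
twice around the contour, once across planes -- which reduces the
sphere's area error to under 2 % while being far too narrow to erase
real shape; `surface_mesh(..., smooth = FALSE)` gives the raw shell.
The form factor is the sphericity `pi^(1/3) (6V)^(2/3) / A` (1 for a
sphere; the published account does not define its "form factor", and
sphericity is the standard dimensionless choice).

Internal objects (alleles) are extracted per nucleus: Otsu's threshold
on the channel histogram restricted to that nucleus mask, 26-connected
components, ranked by integrated brightness, top two kept. Distances
to the nuclear envelope are reported both from the object surface and
from its centroid, since either convention appears in practice; both
are minimal point-to-triangle distances in physical micrometres with
the axial anisotropy applied.

## Evaluation scheme

`categorize()` reproduces the six outcome categories from the overlap
matrix. Ordering is deliberate: under-segmentation is resolved first
(a prediction claiming two or more truths), then over-segmentation
(a truth claimed by two or more remaining predictions), then 1:1 pairs
split into precise (IoU at least `1 - theta_defect`, i.e. defects up to
5 % of voxels), non-precise (IoU at least 0.5), or no match at all
(truth not detected, prediction false positive). `quality_counts()`
folds the categories into TP/FP/FN at quality level I (only precise
counts as found) or II (non-precise also counts), and
`segmentation_metrics()` computes recall, precision, F-measure and
accuracy. The bundled reference tables reproduce the published
validation of seven real stacks cell by cell at the printed rounding
(`round_half_up`, since printed tables round half away from zero).

## Numerical and degenerate-input choices

* Coordinates are 1-based voxel-centre coordinates, `x` the
  fastest-varying axis; physical micrometres enter only in morphometry
  (`(i - 0.5) * dx`). A single conversion point avoids unit bugs.
* Edge-response ties break toward the smallest radius; largest-cluster
  ties break toward the cluster holding the highest-confidence point.
* A contour whose laminar layer leaves the plane excludes those points
  from `Q` (all clipped: quality undefined, trace stops).
* Empty seed queues, zero-ellipsoid phantoms, all-zero masks and
  all-zero count tables are all legal inputs with defined outputs;
  metrics with zero denominators return `NA`, never 0.
* Label masks write 8/16/32-bit TIFF pages as the label count demands;
  32-bit pages are float-sampled and exact up to 2^24 - 1 labels.
* Overlapping accepted contours (rare) rasterise first-come: the
  higher-priority nucleus keeps the voxel, the conflict is counted and
  reported, and no split is invented.

## Known limitations

* Only star-shaped (about the seed/centroid) cross-sections can be
  traced; strongly non-convex nuclei violate the method's assumptions.
* Over-segmented fragments are not re-merged and defective surfaces
  are not repaired.
* The moment gates, although dimensionless, were calibrated on
  phantoms; tissue with very different texture may need new values.
* Stacks whose nuclei never separate on any plane (the published
  lowest-quality stack is of this kind) defeat the seed-priority
  logic; the method reports honest rejections rather than guesses.
* Otsu's threshold assumes a bimodal histogram. When an internal-object
  channel is noise-dominated (spot voxels a tiny fraction of the
  nucleus and noise sd comparable to the blurred spot amplitude) the
  threshold falls into the noise and the brightest "objects" are noise
  blobs; the integrated-brightness ranking cannot rescue that case.
  Keep FISH channels background-subtracted or low-noise, as their
  acquisition pipelines normally already do.

## Reproducing the validation numbers

`scripts/acceptance.R` recomputes, from scratch: the published-table
reproduction, oracle equivalence of the estimators, the 8-ellipsoid
recovery (problem sizes as above), touching-pair separation, the
analytic morphometry cross-check, and the streaming/intensity-scale
invariances. See the README for invocation.
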