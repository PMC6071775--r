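---
title: "Quantifying the reforming nuclear envelope: vesicles, gaps and rim curvature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the reforming nuclear envelope: vesicles, gaps and rim curvature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

During open mitosis the nuclear envelope (NE) disassembles and reforms
around the segregated chromatin. In volume electron microscopy of telophase
cells the reforming NE shows discontinuities ("gaps"), surrounded by small
membrane vesicles, and the mature envelope carries nuclear pores whose
inner and outer membranes join through a region of very high curvature, the
NE rim. Perturbations of membrane-lipid composition (in particular of
diacylglycerol, a negatively curved lipid) are expected to show up in
exactly these fine structural readouts long before the envelope fragments
grossly.

`nemorph` implements the corresponding quantitative readouts as a tested
pipeline:

1. **Vesicle morphometry** — detect and size vesicles in a 3D label volume
   by the "similar x, y and z diameter" sphericity rule.
2. **Gap morphometry and vicinity statistics** — find NE discontinuities,
   measure them as (x-edge separation) x (z extent), classify them into
   small/medium/large, and count vesicles in 1 um sampling fields (close
   disc of 500 nm, far annulus to 1000 nm) around gap endpoints and random
   NE control points.
3. **Rim curvature at nuclear pores** — extract a 3D clip around each pore,
   align the envelope, find the en-face orientation on a 10 degree grid,
   rotate back by 90 degrees, trace the membrane midlines, read off the two
   rim diameters where the membranes "just become parallel", and convert to
   curvature by kappa = 2/RD.
4. **Group statistics** — Shapiro-Wilk gating between one-way ANOVA +
   Tukey's HSD and Kruskal-Wallis + Dunn's post hoc, median +/- IQR/2
   summaries, and the star mapping * <= 0.05 through **** <= 0.0001.

No raw EM volumes accompany the source study, so the package ships a
synthetic phantom generator whose scenes carry exact ground truth; every
measurement stage is validated by parameter recovery on those phantoms.

## Conventions

Axis order is (z, y, x) everywhere; physical units are nm; index origin is
voxel 1 whose center sits at the grid `origin`. TIFF files carry no
trustworthy 3D voxel size, so readers demand an explicit override for TIFF
and trust the MRC header only when its cell spacing is present and nonzero;
the code never silently assumes 1 nm voxels.

## The phantom generator

`make_telophase_scene()` renders an NE double-membrane sheet — two dark
bands whose midlines sit `perinuclear_spacing` apart (default 40 nm, a
typical perinuclear cisterna; the source data do not constrain it) — with
rectangular gaps cut through it, plus spherical vesicle shells. Membranes
render 7 nm wide (FWHM; a typical stained bilayer in plastic-section EM) as
dark density on a bright background, followed by Gaussian blur and additive
Gaussian noise. A vesicle's stated diameter is its outer diameter: the
shell band occupies [r - 7 nm, r], so the physical bounding box of the
rasterized object equals the true diameter up to voxel quantization.
Vesicle centers are placed 100-1000 nm from the sheet by dart throwing; a
placement margin guarantees that two rasterized shells can never merge
under 26-connectivity, and the generator errors out after bounded retries
when a packing is infeasible.

`make_pore_volume()` renders one nuclear pore: two flat membrane midplanes
separated by the rim diameter RD, joined through a half-toroidal rim (tube
diameter RD) around a circular fenestration of the stated pore diameter.
With this geometry "rim diameter" is well defined as the membrane-midline
separation where the two membranes become parallel, which is exactly what
the measurement protocol reads off. The whole envelope is rotated by a tilt
about x and an azimuth about z before rasterization, so the ground-truth
en-face angle equals the tilt. Rim diameters below the voxel size set a
`subresolution` flag.

What the phantoms deliberately do **not** emulate: the missing wedge and
anisotropic PSF of tomographic reconstruction, membrane tortuosity beyond a
gentle undulation, section compression, and organelle clutter (ER,
chromatin, centrioles). Recovery results on phantoms therefore demonstrate
correctness of the measurement chain, not robustness to every real-world
artifact; on real tomograms the angle-bias QC (below) plays that role.

Defaults chosen where the source conditions are silent: background 200,
membrane contrast 140, noise SD 10 (membrane depth 14 noise SDs — strong
but realistic plastic-section contrast), blur sigma 1.5 nm, tortuosity
amplitude 15 nm with a 900 nm wavelength.

## Vesicle sizing

Detection runs on label volumes (the source segmentations were manual;
detection from raw intensity is out of scope). Connected components use
26-connectivity; per component the physical bounding-box extents (dz, dy,
dx) are measured and the summary diameter is their arithmetic mean, the
simplest faithful reading of a diameter measured on micrographs. The
equivalent-sphere diameter from the voxel volume is emitted as an extra
column since the source does not say which convention produced its printed
means. The sphericity rule "similar x, y and z diameter" is quantified as
max/min extent ratio <= 1.5 (configurable; the source gives no number), and
thick-section stacks can exclude z from the ratio (`ignore_z_axis`),
because a 57 nm vesicle spans a single 50-70 nm section and its z "extent"
is a section count, not a diameter. Two sampling caveats discovered on
phantoms and worth knowing about on real data: at 50-70 nm section pitch a
sub-section sphere can fall entirely between section planes (it is then
invisible, not mis-sized), and a thin shell can split into cap and equator
components; both disappear at near-isotropic pitch, which is the regime of
the sizing studies.

## Gaps and vicinity fields

A gap is measured per z-slice from the in-plane NE occupancy projected
onto x: a run of empty columns strictly between occupied columns, bounded
by the two converging NE edges. The "not exceeding 140 nm" qualifier of the
source's gap definition is ambiguous; the adopted reading caps the
per-slice x-separation at 140 nm (two 70 nm sections) so that large gap
areas remain reachable through multi-section z extents, and a config switch
(`cap = "dz"`) selects the alternative z-cap reading. Slice discontinuities
overlapping in x across consecutive slices merge into one gap with dx the
minimum separation and dz the slice count times the pitch; the area is
exactly dx * dz, with no rounding before classification.

The printed class ranges (small 5,800-9,900; medium 11,000-82,000; large
100,000-350,000 nm^2) leave dead zones between them; default midpoint
thresholds (10,450 and 91,000 nm^2) close the zones, and a strict mode
returns `unclassified` inside them instead.

Sampling fields are 1 um discs subdivided at 500 nm (the "close" contact
range given for vesicle-NE fusion; the subdivision radius is only
inferable from the text). Distances are 3D Euclidean by default — the
physically meaningful superset of the micrograph measurement — with a
`projected_2d` switch for strict in-plane counting. Densities are per area
(um^-2), matching "number of vesicles per area". Control points are drawn
on the NE surface with a pairwise minimum separation (default 500 nm) and,
by default, at least 1 um from every gap endpoint, since control fields are
meant to probe gap-free envelope; both are configurable because the source
does not state either rule.

## The rim-curvature protocol

Working resolution is ~3 nm voxels (bin by 4 from ~0.75 nm reconstructions;
the whole volume is binned and windowed to 8 bit before clips are cut, so
every clip shares one intensity scale). Each completely enclosed pore
yields a cubic clip with margin. The stages:

* **Alignment.** The dominant planar dark structure (principal axes of
  below-Otsu voxels) defines the membrane normal; the clip is rotated
  about z so the normal loses its x component and the membranes run along
  x. A planarity score (smallest/middle eigenvalue <= 0.35) rejects clips
  without a plate-like dark structure.
* **En-face search.** The clip is rotated about x in 10 degree steps over
  [0, 180). At each angle a 60 nm slab around the center is projected
  along the membrane normal with a minimum-intensity projection; the pore
  aperture is the bright connected region fully enclosed by membrane. The
  protocol's by-eye "as near to a circle as possible" is automated as the
  angle maximizing the aperture area, with ties broken toward the smaller
  angle. The originally considered criterion — isoperimetric circularity
  4piA/P^2 of the aperture, which is reported in the search profile — turns
  out to be nearly invariant under small residual tilt (foreshortening a
  disc to aspect cos(10 deg) changes it by ~0.1%) so threshold and raster
  noise dominate its argmax; the aperture area falls by ~7% per 10 degrees
  and picks the grid optimum reliably. A 1 degree golden-section-style
  refinement exists but is off by default so that default behavior matches
  the 10 degree protocol.
* **Back-rotation and measurement.** The clip is rotated back by 90
  degrees; the membranes now appear as two dark bands interrupted by the
  pore. On the axial slice where the lumen is widest (three slices
  averaged), each column's two membrane midlines are located as sub-voxel
  quadratic-refined intensity minima on either side of the estimated
  mid-plane. Walking outward from the pore axis on each side, the midline
  separation d(s) rises along the rim and plateaus at RD; "just become
  parallel" is operationalized as the first s where the least-squares
  slope of d over a 15 nm window stays below 0.05 (both configurable and
  recorded). A per-step |delta d / delta s| criterion was rejected: at 3 nm
  pitch single-column trace noise of ~0.3 nm alone produces slopes of ~0.1.
  The pore diameter is the distance between the innermost membrane-bearing
  columns — the junction points where the midlines merge — consistent with
  the midline-to-midline reading of the rim measurement. Columns beyond a
  break in the traced run (e.g. outside the rotated cube's valid region)
  are not trusted. Failures set QC flags (`no_plateau_*`, `no pore`)
  rather than fabricating numbers.
* **Curvature.** kappa = 2/RD per side; each pore contributes both sides
  (i and ii) to downstream statistics by default, with per-pore averaging
  available since the source does not say which was used.

Section shrinkage in the electron beam (~30% in z, 2-8% in-plane) is not
corrected numerically; following the protocol, `angle_bias_check()` screens
for a dependence of the measured quantities on the en-face angle (Pearson,
two-sided) and is a gate, not a correction.

Residual tilt after the grid search is at most half a step; geometrically
it inflates RD by 1/cos(5 deg) < 0.4%, far below the trace noise.

## Numerical choices and degenerate inputs

Rotations compose into a single matrix and are applied by one trilinear
resampling from the stored base clip, so repeated stages never stack
interpolation error. Out-of-lattice samples take the border-median fill.
Binning uses block means and drops partial edge blocks. Windowing defaults
to the 0.5/99.5 percentiles ("suitable windowing" is otherwise
unspecified); constant volumes map to zero with a warning. Quartiles use
linear interpolation (type 7), stated in the output because IQR/2 is
convention-sensitive. Identical groups short-circuit to p = 1 in both test
families; Dunn's z uses the tie-corrected variance and Holm adjustment by
default (the source names no adjustment; Bonferroni and none are
selectable, and the method is written into every result). The descriptive
dip statistic reported per group is the sup-distance from the empirical
cdf to the nearest unimodal cdf (convex/concave hull envelopes, minimized
over mode placement); it carries no p-value and feeds no decision.

## Problem sizes of the recovery studies

The shipped studies use 500 vesicles at 4.5 nm isotropic voxels (and a
30-vesicle variant at mean 71 nm for the enlarged, contrast-labeled
population), and 40 pores per condition at 3 nm voxels in 120^3 phantoms
with tilts drawn uniformly from [0, 40] degrees — enough for the sample
medians and the rank tests to be stable, while a full study runs in
minutes on a laptop. The t-style recovery targets reproduce the published
summary numbers (57 nm and 71 nm vesicle means; median kappa 0.077 and
0.060 1/nm for rim diameters 26 and 33.3 nm; Dunn p < 0.0001 between the
two curvature groups) from phantom truth, not from the original cells:
agreement shows the measurement chain is faithful, not that the biology is
re-derived.

## Known limitations

* The gap finder assumes the NE crosses the field of view as an open sheet
  per slice (the situation in the source micrographs); a closed envelope
  ring would need an unrolled parametrization first.
* One pore per phantom volume: several pores with different rim diameters
  cannot share one flat envelope whose membrane separation *is* the rim
  diameter.
* Detection from raw intensity (without labels) and tomographic
  reconstruction itself are out of scope; the pipeline consumes label
  volumes and reconstructed grayscale volumes.
* Curvature is reported as 2/RD, i.e. the rim is treated as a semicircular
  arc; no local curvature fitting is attempted below the resolution of
  that model.
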