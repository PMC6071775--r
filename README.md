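# nemorph

Morphometry of the reforming nuclear envelope (NE) from volume electron
microscopy.

When the NE reassembles around telophase chromatin it is transiently
discontinuous: the envelope sheet carries gaps, small (~57 nm) vesicles
cluster near those gaps, and the mature envelope's nuclear pores are rimmed
by the most highly curved membrane of the cell. `nemorph` is for
microscopists and image analysts who want those three readouts as numbers
with units:

* **Vesicles** — 3D connected components of a label volume, accepted when
  their bounding-box axis extents satisfy max/min ≤ 1.5 ("similar x, y, z
  diameter"), sized as the mean of the three physical extents, summarized
  as mean ± SEM with a 5 nm histogram.
* **Gaps** — per-slice discontinuities of the NE trace, measured as
  dx · dz (x edge separation times z extent, with a 140 nm converging-edge
  cap), classified small / medium / large against the published area
  ranges, with vesicle densities (per µm²) counted in 1 µm sampling fields
  split into a close disc (≤ 500 nm) and a far annulus around gap endpoints
  and random NE control points.
* **Rim curvature** — for every nuclear pore fully enclosed in a tomogram:
  bin to ~3 nm voxels, window to 8 bit, cut a clip, align the envelope to
  the x axis, rotate about x in 10° steps until the pore is en face, rotate
  back by 90°, trace the two membrane midlines, read the rim diameter RD
  where the membranes just become parallel on each side of the pore, and
  convert to curvature by **κ = 2/RD** (nm⁻¹). Pore diameter is measured
  across the lumen between the membrane junction points.
* **Statistics** — Shapiro–Wilk gating between one-way ANOVA + Tukey HSD
  and Kruskal–Wallis + Dunn's post hoc (Holm-adjusted), median ± IQR/2
  summaries, significance stars `* ≤ 0.05 … **** ≤ 0.0001`.

Because no raw EM data accompany the source study, the package includes a
synthetic phantom generator (telophase-like scenes and single-pore tomogram
clips with exact ground truth) so that every stage of the pipeline is
verified by parameter recovery.

## Worked example

Measure a phantom pore population with a known 26 nm rim diameter:

```r
library(nemorph)

study <- simulate_pore_study(8, rim_diameter = 26, seed = 5)
study$measurements[1:3, c("pore_id", "en_face_angle_deg",
                          "rim_d_i_nm", "rim_d_ii_nm", "pore_d_nm")]
#>   pore_id en_face_angle_deg rim_d_i_nm rim_d_ii_nm pore_d_nm
#> 1       1                10   25.46740    25.51913        81
#> 2       2                30   25.61869    26.07962        87
#> 3       3                40   25.15048    25.89070        87
median(study$kappa)
#> [1] 0.07822029
```

Each row is one pore: the recovered en-face tilt, the rim diameter on the
two sides (i, ii) of the pore, and the pore diameter, all in nm. The median
curvature 0.078 nm⁻¹ recovers the ground truth 2/26 = 0.077 nm⁻¹ within a
voxel-scale measurement error.

Vesicle sizing and group comparison follow the same pattern:

```r
ves <- simulate_vesicle_study(500, mean_nm = 57, sd_nm = 8, min_nm = 20,
                              voxel_size = 4.5, seed = 1)
ves$summary
#> <vesicle_summary> n = 500 accepted vesicles
#>   mean diameter: 57.1 +/- 0.4 nm (mean +/- SEM)
#>   histogram: 12 bins of 5 nm

cmp <- kruskal_dunn(list(control  = simulate_pore_study(8, 26,   seed = 5)$kappa,
                         depleted = simulate_pore_study(8, 33.3, seed = 6)$kappa))
```

Real data enter through `read_volume()` (multi-page TIFF or MRC2014, voxel
sizes in nm, never assumed), `label_volume()` for segmentations, and then
`extract_candidates()`, `find_gaps()`, `sample_vicinity()` and
`run_pore_pipeline()`.

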