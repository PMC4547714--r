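# canalcurve

Quantifying the 3-D shape of the lumbar spine from CT volumes — without
vertebral landmarks.

Classical lordosis measures (Cobb angle, TRALL, posterior tangents) reduce
the spinal curve to a single 2-D angle between bone features, which makes
them blind to local shape differences and sensitive to osteophytes and
endplate irregularities. `canalcurve` instead treats the **centerline of
the spinal canal** as the lumbar curve: the canal is a tubular structure
whose medial axis is insensitive to local bony changes, and the whole
curve — not one angle — is analyzed.

The pipeline, per scan:

1. **Canal segmentation** — a seed inside the canal is detected from shape,
   size and bone-enclosure criteria; a morphological region-growing pass
   propagates the canal cross-section slice by slice under area and
   circularity screening; a narrow-band active-surface refinement sharpens
   the boundary against Gaussian-gradient edges.
2. **Centerline extraction** — a fast-marching minimal path through a
   speed map equal to the normalized distance-to-boundary (so the optimal
   path hugs the medial axis), back-traced with sub-voxel steps.
3. **Normalization** — the curve is cropped between the T12-inferior and
   S1-superior endplate planes, rotated so ventral is +Y, translated so the
   caudal endpoint B is the origin, and divided by the projected
   cranial-caudal extent `Az − Bz`, making curves of different subjects
   dimensionless and comparable. For endpoints A (cranial) and B (caudal)
   and lordosis peak P (the most ventral point), six descriptors are
   computed:

   | descriptor | definition | units |
   |---|---|---|
   | segment length | ‖A − B‖ | mm |
   | curve length | Σ‖pᵢ₊₁ − pᵢ‖ | mm |
   | curvedness | curve length / (Az − Bz) | — |
   | peak location | Pz (from the caudal end) | — |
   | cranial peak height | Py − Ay | — |
   | caudal peak height | Py − By | — |

4. **Population models and comparison** — a model curve is the per-station
   (constant-Z cross-section) component-wise median of all curves, with
   per-station SD; two populations are compared per descriptor and at 20
   stations along Z (the caudal origin dropped) with two-tailed pooled
   t-tests at α = 0.05, deliberately without multiple-testing correction
   (neighboring stations are strongly dependent).

A seeded **phantom generator** supplies ground truth for every stage:
CT-like volumes containing a canal tube with bright bone rings, weak-edge
disc bands and lateral nerve-root windows, plus synthetic curve populations
whose descriptors follow per-sex Gaussians from a published reference
cohort of 158 adults (81 males, 77 females).

## Worked example

```r
library(canalcurve)

# ground-truthed phantom scan (256 x 256 x 300 voxels, 0.8/0.8/1.5 mm)
ph <- synthesize_volume(phantom_spec(rng_seed = 1))

mask <- segment_canal(ph$volume)
dice_overlap(mask, ph$mask)
#> [1] 0.9710103

ctr  <- extract_centerline(mask)
curve_distance(ctr, ph$curve)$mean     # mm, against the analytic truth
#> [1] 0.2286466

norm <- normalize_curve(crop_to_landmarks(ctr, ph$landmarks))
compute_features(norm)[, 1:6]
#> # A tibble: 1 x 6
#>   segment_length_mm curve_length_mm curvedness peak_location
#> 1              179.            182.       1.02         0.282
#>   cranial_peak_height caudal_peak_height
#> 1              0.0934             0.0583
```

The recovered descriptors sit on the generating values (peak location
0.274, cranial height 0.092, caudal height 0.061, segment 179 mm) to
within the voxel discretization. Population-level analysis:

```r
males   <- sample_population(reference_group_params("male"),   81, rng_seed = 2)
females <- sample_population(reference_group_params("female"), 77, rng_seed = 3)
rep <- compare_models(males, females, K = 20)
rep
#> <comparison_report> male (n = 81) vs female (n = 77), alpha = 0.05
glance(rep)          # significant station counts per axis
tidy(rep)            # the 19-location pointwise table, cranial first
autoplot(rep$pointwise)
```

A thin command-line front end with the same stages lives at
`inst/exec/canalcurve` (subcommands `phantom`, `simulate-group`, `segment`,
`centerline`, `normalize`, `features`, `report`, `model`, `compare`,
`run`).

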