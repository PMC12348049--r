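# lipoquant

Quantification of lipofuscin autofluorescence in brain tissue imaging.

Lipofuscin — the autofluorescent pigment that accumulates in neurons with
age — appears in long-wavelength two-photon autofluorescence images as
bright granular particles on a smooth tissue background, and is implicated
in Alzheimer's disease (AD) and chronic traumatic encephalopathy (CTE).
`lipoquant` is for researchers who need to turn such images into
region-resolved, statistically comparable lipofuscin measurements. It
implements:

* **Granule segmentation**: the image is divided by a 50 µm mean-smoothed
  copy of itself, and the resulting ratio image is binarized at
  `max(huang_threshold, 1.15)` — Huang's minimum-fuzziness threshold with a
  fixed lower bound on the normalized ratio — followed by
  connected-component extraction.
* **FLIM validation tools**: phasor transform
  (`G = Σ cₖ cos ωtₖ / Σ cₖ`, `S = Σ cₖ sin ωtₖ / Σ cₖ`,
  `ω = 2π/window`), elliptical phasor-cluster selection with
  back-annotation, decay pooling, and Poisson maximum-likelihood fitting of
  1- or 2-component truncated-exponential decays — lipofuscin is the
  ~400 ps component.
* **Structural stratification**: scattering coefficients `μs` from A-scan
  depth profiles (`I(z) = I₀e^(−2μs z)`), gray/white matter and
  supragranular/infragranular masks, crest/sulcus ROI polygons.
* **Sliding-window metrics**: mean granule radius (µm), number density
  (mm⁻²) and area fraction (%) on a 100 × 100 µm grid with 50% overlap.
* **Group statistics**: sulcus-over-crest ratios (SOCR), exact-enumeration
  two-tailed Mann-Whitney tests (the small-sample 5 vs 5 comparison is
  exact: complete separation gives p = 2/252), and age regressions.
* **A synthetic-data generator** that plants granule fields, TCSPC decay
  stacks, scattering volumes and whole cohorts with known ground truth, so
  every stage of the pipeline is testable end to end.

## Worked example

Simulate a 1 mm² autofluorescence field with 500 planted granules per mm²,
segment it, and map the three metrics:

```r
library(lipoquant)

field <- generate_granule_image(granule_field_spec(
  image_shape_px = c(334, 334), pixel_size_um = 3,
  particle_density_per_mm2 = 500, particle_contrast = 2, seed = 42))

seg <- segment_lipofuscin(field$image)
nrow(field$truth$particles)   # 502  planted
nrow(seg$particles)           # 446  detected
seg$threshold                 # 1.15 (Huang value 0.988 is below the floor)

maps <- metric_maps(seg$mask, seg$particles, window_spec(100, 0.5))
aggregate_region(maps)
#>                   metric    mean n_windows n_slices
#> 1         mean_radius_um   2.295       356        1
#> 2 number_density_per_mm2 444.581       361        1
#> 3      area_fraction_pct   0.785       361        1
```

The recovered density (445 mm⁻²) sits below the planted 500 mm⁻² because
sub-resolution granules in the planted size distribution are missed at
3 µm pixels — the mechanism the validation benchmark quantifies.

Group comparison of SOCR values (here AD-like vs control-like inputs):

```r
mann_whitney_exact(c(1.45, 1.39, 1.52, 1.48, 1.61),
                   c(0.97, 1.04, 0.92, 1.08, 0.99))
#> Mann-Whitney (exact enumeration): U = 25.0, two-tailed p = 0.0079365 (n = 5 vs 5)
```

A full config-driven run — cohort simulation, segmentation, metrics, SOCR,
comparison tables, age trends — is one call:

```r
run_pipeline(system.file("extdata", "demo_config.json", package = "lipoquant"),
             out_dir = "demo_out")
```

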