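# cellpolarity

Quantify cell polarity, morphology, intracellular intensity patterns and
cell–cell junction organisation from multi-channel 2D fluorescence
microscopy — one row of features per segmented cell, plus the circular
statistics needed to describe what the cell *collective* is doing.

The package is aimed at quantitative cell biologists analysing monolayer
assays (the motivating system is endothelial cells under flow-induced shear
stress, where cells elongate, align with the flow axis, and reposition
their Golgi upstream of the nucleus), but it applies to any experiment
that can be decomposed into per-cell instance masks.

## What it computes

**Per cell**, from instance masks and channel images:

- *Localisation*: centre of mass of cell, nucleus and organelle, from raw
  image moments `m_ij = Σ_x Σ_y x^i y^j I(x,y)`.
- *Morphology*: area, perimeter, circularity `4πA/P²`, eccentricity; shape
  orientation `φ = σ·½·atan2(2μ₁₁, μ₂₀−μ₀₂) (mod π)` from central moments
  (an axial quantity in [0°, 180°)); length-to-width ratio (LWR) from the
  intensity-equivalent ellipse axes; a cue-referenced mirror-symmetry
  score (IoU of the two cell halves after reflection about the axis
  perpendicular to the cue).
- *Polarity*: directed front–rear angles
  `α = σ·atan2(ȳ_f−ȳ_r, x̄_f−x̄_r) (mod 2π)` — nucleus→Golgi, cell
  centre→nucleus, cell centre→marker-intensity centre — and the cue
  directional intensity ratio `s_r = 1 − 2·(rear-half intensity
  fraction) ∈ [−1, 1]`.
- *Intensity*: area/total/mean per compartment (cell, nucleus, cytosol =
  cell∖nucleus, membrane band) and the nucleus:cytosol ratio.
- *Junctions*: a dilated-outline interface band (one parameter: the
  thickness) with interface occupancy (Otsu-positive fraction), intensity
  per interface area, and cluster density.

**Per image**, from the feature table:

- Polarity index `R = ‖(1/N) Σ (cos α_i, sin α_i)‖` (circular variance
  `S = 1 − R`), circular mean with 95% CI, signed polarity index
  `V = R·cos(ᾱ − α_p)` against a known cue direction `α_p`.
- Uniformity tests: Rayleigh, V-test (known direction), Watson's U²,
  Rao's spacing (Monte-Carlo null). Axial data (orientations) are doubled
  (`θ = 2φ`) before analysis, halved after.
- Circular–linear (Mardia) and circular–circular (Jammalamadaka–SenGupta)
  correlation; rose histograms with axial duplication.
- DABEST-style bootstrap estimation of between-condition differences
  (`bootstrap_mean_diff`, `compare_conditions`) on per-image summaries.

A synthetic-monolayer generator (`synthetic_spec` / `generate_monolayer`)
renders Voronoi-clipped elliptical cells with nuclei, organelles, junction
bands and marker gradients — with exact ground truth — so every feature is
validated by parameter recovery.

## Worked example

```r
library(cellpolarity)

# a 49-cell synthetic monolayer whose Golgi bearings are drawn from a
# von Mises distribution at 210 deg (kappa = 4), i.e. polarised against a
# cue pointing at 30 deg
spec <- synthetic_spec(n_cells = 49, seed = 11,
  organelle = list(radius = 2.5, distance_frac = 0.6,
                   bearing = list(type = "vonmises", mu = 210, kappa = 4)))
img <- generate_monolayer(spec)

features <- extract_features(img$channels, img$cell_mask, img$nucleus_mask,
                             alpha_p = 30, junction_thickness = 2)
dim(features)
#> [1] 49 36

golgi <- angle_sample(features$angle_nucleus_golgi_deg)
circ_summary(golgi, alpha_p = 210)
#> Circular summary (directional), n = 49
#>   mean direction : 212.33 deg
#>   polarity index R = 0.8352  (circular variance S = 0.1648)
#>   signed polarity index V = 0.8345  (alpha_p = 210.0 deg)
#>   95% CI of mean: [202.40, 222.26] deg (dispersion)

v_test(golgi, 210)
#> 	V-test (specified direction)
#> data:  angle sample
#> u = 8.2615, p-value < 2.2e-16
```

The mean nucleus→Golgi direction (212°) recovers the generating 210° well
inside the CI; the polarity index R ≈ 0.84 sits close to the theoretical
von Mises mean resultant length A(4) = I₁(4)/I₀(4) ≈ 0.864 for κ = 4; and
the V-test, referenced to the expected polarisation direction, rejects
uniformity decisively. With real data you would start from
`run_pipeline("run.yml")` (single image, stack, or condition-folder
layouts) or the `exec/cellpolarity` command-line wrapper
(`extract`, `stats`, `compare`, `synth` subcommands), which write per-image
feature CSVs, circular-summary CSVs, a log and the resolved configuration.

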