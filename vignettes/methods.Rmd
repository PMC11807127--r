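---
title: "Quantifying single-cell polarity, morphology and junctions: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying single-cell polarity, morphology and junctions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellpolarity)
```

This vignette explains the measurement models behind the package, the
conventions and tunable parameters that matter, what the synthetic data
generator does and does not emulate, and the numerical choices made where
the design was genuinely open.

## Coordinate conventions

All pixel coordinates are 0-based with pixel centres at integer `(x, y)`;
`x` is the column index and `y` the row index. Because raster images store
row 0 at the top, the stored y axis points *down*; the sign convention
`σ ∈ {+1, −1}` (default `−1`, i.e. y down) converts every reported angle
into the conventional counter-clockwise, y-up frame. Directed angles live
on `[0°, 360°)`; axial angles (orientations of undirected axes) on
`[0°, 180°)`. Internally everything is radians; all I/O is degrees.

## Image moments and shape

Raw moments of a (masked) intensity image are
$$m_{ij} = \sum_x \sum_y x^i y^j I(x,y),$$
the centre of mass is $(\bar x,\bar y) = (m_{10}/m_{00}, m_{01}/m_{00})$,
and central moments $\mu_{ij}$ are taken about it. Binary shape moments
use $I \equiv 1$ on the mask. Moments are computed to order 3; no feature
needs more.

**Shape orientation.** The major-axis angle is
$$\phi = \sigma\,\tfrac12\,\mathrm{atan2}(2\mu_{11},\, \mu_{20}-\mu_{02}) \bmod \pi .$$
The argument order was fixed by a rotation-recovery oracle: rasterised
ellipses at known angles must be recovered within 1°, and a horizontal bar
must report 0°. The mirrored argument order `(μ02 − μ20)`, which one
sometimes sees written, reflects every recovered angle about 45° and fails
that oracle. Isotropic shapes (disc, square) have no major axis and return
`NA` — returning an arbitrary 0° would manufacture fake collective
alignment downstream.

**Axis lengths and elongation.** The eigenvalues λ₁ ≥ λ₂ of the
normalised second-moment matrix give full axis lengths $4\sqrt{\lambda}$
of the intensity-equivalent ellipse; LWR = major/minor. For a rasterised
ellipse with semi-axes a, b this recovers 2a and 2b within ~2%.

**Perimeter.** The 8-connected outer contour is traced and step lengths
summed with the Proffitt–Rosen corrected weights (0.948 per rook step,
1.340 per diagonal step). Plain 1/√2 weights overestimate smooth
boundaries by 5–8%, which would push the circularity of a perfect disc
down to ~0.91; with corrected weights a radius-20 disc scores ≥ 0.95.
Circularity is clipped at 1.

**Cue-referenced shape symmetry.** The mask is split by the line through
its area centroid perpendicular to the cue; the rear half is reflected
across that line (continuous coordinates, nearest-pixel resampling) and
scored against the front half by intersection-over-union. Pixels exactly
on the split line belong to neither half — they are fixed points of the
reflection, and assigning them to one side would cap the score of a
perfectly mirror-symmetric odd-width shape below 1. Limitation: when the
mirror axis is not lattice-aligned, nearest-pixel rounding collides for
roughly a fifth of boundary pixels, so even an exactly symmetric shape
scores ~0.8 rather than 1; scores are therefore comparable within an
experiment but are not an absolute symmetry measure for tilted cues.

## Directed polarity and intensity asymmetry

Front–rear polarity is the bearing from a "rear" reference centroid to a
"front" target centroid,
$\alpha = \sigma\,\mathrm{atan2}(\bar y_f-\bar y_r,\ \bar x_f-\bar x_r)$:
nucleus→Golgi (organelle centroid intensity-weighted within its mask —
binary-mask weighting is available by passing no channel), cell→nucleus,
and cell→marker-intensity-centre. Coincident centroids (e.g. a uniform
marker) yield `NA`, never 0.

The cue directional intensity ratio splits the cell through its *shape*
centroid perpendicular to the cue α_p and compares intensity between the
halves: $s_r = 1 - 2\,\Sigma_{rear} I / \Sigma_{cell} I \in [-1, 1]$.
The rear half is the set of pixels whose displacement projects negatively
on the cue unit vector; pixels with exactly zero projection are assigned
to the front (a fixed, documented tie rule — relevant only when the
centroid x or y coordinate is an exact pixel coordinate). Reversing the
cue flips the sign exactly (up to that tie set). The ratio measures the
*magnitude* of a gradient along the cue but saturates for off-axis
gradients; marker polarity measures the *direction* but not the
magnitude. On an elongated cell a linear gradient's weighted centroid is
pulled toward the major axis (the displacement is the second-moment
tensor applied to the gradient direction), so the two readouts are
complementary, not redundant.

## Intensity compartments

Cytosol = cell ∖ nucleus is the only strict partition, so
`total(nucleus) + total(cytosol) = total(cell)` exactly. The membrane band
(cell-contour band of configurable thickness, clipped to the cell)
overlaps the cytosol and is reported separately rather than subtracted.
The nucleus:cytosol ratio uses mean intensities by default (`ratio_mode =
"total"` switches to totals), the standard readout for nuclear
translocation of a reporter such as a KLF4 stain.

## Junction morphometrics

The one-pixel cell outline is dilated to the set of pixels within
Euclidean distance *t* (the single junction parameter) of the contour —
computed as an exact distance criterion, not an approximate brush, so the
band equals its distance-transform definition pixel for pixel. The band
deliberately straddles both sides of the boundary and is not clipped to
the cell's own mask: junction protein lives on both sides of a shared
boundary, and neighbouring cells' bands may overlap. Within the band,
Otsu's threshold (256 bins spanning the in-band range; fixed dialect,
since Otsu outcomes depend on binning) defines the junction-protein area,
giving interface occupancy (protein/band area), intensity per interface
area (mean over band) and cluster density (mean over protein area).
Constant in-band intensity leaves the Otsu split undefined: occupancy is
then missing, the band mean still reported. Otsu is per cell by default
(`threshold` can be supplied for image-global comparability). Note the
between-class variance is flat across an empty histogram gap, so any cut
inside the gap is an equally valid Otsu threshold; the package cuts at the
low edge of the plateau, which classifies identically to other dialects.

## Segmentation

Precomputed masks (integer TIFF) are the first-class path. The built-in
classical backend — global Otsu + hole filling + connected components for
nuclei, then seeded region growing over the junction channel
(EBImage `propagate`, a marker-controlled watershed-style partition in
which bright junction ridges act as barriers) for cells — exists so the
package is testable end to end without any deep-learning model; adapter
slots for external DL backends raise an explicit error when the backend is
not plugged in, never a silent fallback. Nuclei are matched to cells by
majority area overlap (ties to the lower cell label, for determinism);
cells with zero or several nuclei, and by default cells touching the
image border (whose truncated shapes would bias every feature), are
dropped with logged reasons, and retained + dropped always reconciles
with the total.

## Circular statistics

For directional angles the mean resultant vector
$\mathbf r = \frac1N \sum_i (\cos\alpha_i, \sin\alpha_i)$ gives the
polarity index $R = \|\mathbf r\|$, circular variance $S = 1-R$, and the
circular mean. Against a known cue direction the signed polarity index is
$V = R\,\cos(\bar\alpha - \alpha_p)$. Axial samples are doubled
(θ = 2φ), analysed as directional data, and means/CIs halved; V uses the
doubled reference. For the V-test the reference must be the *expected
polarisation* direction, which for nucleus→Golgi polarity under a cue is
opposite to the cue — `summarise_features` therefore defaults that
feature's reference to α_p + 180°.

Confidence intervals for the mean direction use the circular-dispersion
large-sample formula $\bar\theta \pm \arcsin(z\sqrt{\hat\delta/n})$ with
$\hat\delta = (1-\hat\rho_2)/(2R^2)$, falling back to a seeded percentile
bootstrap (B = 2000) when n < 25 or the arcsine argument is out of range.
Both constructions are cross-checked against each other in the tests; at
n = 1000, κ = 4 they agree within 2°.

Uniformity tests: Rayleigh (Z = nR², series p-value), the V-test
(u = V√(2n), one-sided normal p — the recommended test when a direction
is known a priori), Watson's U² (finite-sample modified statistic with
the asymptotic series; statistics at or below the lattice minimum report
p = 1), and Rao's spacing test (U = ½Σ|spacing − 360/n|), whose p-value
comes from a seeded Monte-Carlo null (10,000 uniform samples per sample
size, cached) rather than printed critical-value tables — editions of
those tables disagree, a simulated null is reproducible and testable. All
four hold their nominal 5% size within ±2 percentage points at n = 100
over 2000 replicates (verified in the acceptance tests). These tests
apply to *per-image* collectives: cells within a monolayer are spatially
correlated, so pooling single cells across images would overstate
evidence; the summary layer therefore groups by image, and
between-condition inference is left to estimation statistics.

Correlations: Mardia's circular–linear r (in [0, 1]) and the
Jammalamadaka–SenGupta circular–circular ρ (in [−1, 1]); both undefined
inputs (constant covariate, zero resultant denominators) return `NA`.

## Estimation statistics

`bootstrap_mean_diff` reports the mean difference between two groups with
a percentile bootstrap CI (BCa optional), resampling within groups,
fully determined by its seed. The unit of analysis is intended to be
per-image summaries (e.g. R, V, or a mean intensity ratio per image), not
single cells. Nominal 95% intervals achieve 93–97% empirical coverage at
n = 50 per group in the acceptance simulation (1000 replicates, 1000
resamples each; the function default of 5000 resamples is reduced there
purely as a simulation problem size — coverage is insensitive to it).

## The synthetic monolayer generator

`generate_monolayer` renders, from a `synthetic_spec`: elliptical cells on
a jittered grid, clipped by the Voronoi partition of their seed points (so
regions can never overlap); one circular nucleus per cell, displaced from
the cell centre by a drawn bearing; one organelle disc per cell at a drawn
bearing from the nucleus; a junction channel painted on a band of width w
around all cell outlines with a fraction q of bright pixels; and a marker
channel that is uniform, a linear gradient at a drawn bearing, or a
nucleus:cytosol ratio model. Gaussian noise (sd 0.01 by default, on a
[0, 1] intensity scale with background 0.05) is added to every channel.
Defaults (300×300 px, 49 cells, LWR ~ N(1.8, 0.25), axial von Mises
orientations at κ = 4) emulate a moderately aligned, moderately elongated
monolayer at a scale where a full pipeline run takes seconds.

Geometry choices that make ground truth exact rather than approximate:
cell and nucleus centres are snapped to the half-pixel grid, where
rasterised discs and ellipses are point-symmetric and binary centroids
equal the drawn centres exactly; the organelle disc is rendered with 4×4
sub-pixel coverage so its intensity-weighted centroid is sub-0.05 px
accurate; the organelle offset is raised to clear the nucleus and capped
analytically so the disc always fits inside the cell — if the drawn
nucleus position leaves too little room along the drawn bearing, the
nucleus displacement is shrunk (bearing preserved) until a minimum 4 px
offset fits, and the achieved positions are what the truth table records.
With `confluent = TRUE` cells instead fill their whole Voronoi polygon —
the tightly packed case used for the segmentation benchmark, where
parametric shape truth is approximate but mask-level truth is exact.

What the generator does *not* emulate: optics (no point-spread function,
no shot noise), intensity inhomogeneity, touching/overlapping nuclei,
multinucleation, or curved "swirly" cell shapes. Passing recovery tests
on synthetic stacks therefore validates the *measurement* layer — moments,
angles, bands, statistics — on known geometry; it does not certify
segmentation quality on real micrographs, which is why segmentation
backends are pluggable and precomputed masks are the primary input path.

Tolerances used by the recovery tests (orientation 1°, bearings 3°, LWR
5%, s_r sign exact, occupancy 0.05, nucleus:cytosol ratio 5%) are the
generator's achievable rasterisation accuracy at the default cell size
(~20 px semi-axis), verified across seeds. Where a check compares a
50-cell draw against *population* values (mean bearing 210°, R = A(4)),
the sampling noise of a single draw (≈ 4.4° on the circular mean) exceeds
the 5° check, so those checks pool 8 replicate images while the per-image
extraction error is held to 2°/0.02 against each image's drawn sample.

## Determinism

Every stochastic component (von Mises sampler, bootstraps, Monte-Carlo
nulls, the generator) is seed-determined, and functions that seed
internally restore the caller's RNG state, so a pipeline run is
reproducible end to end from the config seed and re-running into a
different output directory produces byte-identical CSVs (the provenance
hash excludes the output path). Problem sizes in the test-suite
simulations (2000 uniform replicates for test calibration, 1000
bootstrap replicates for coverage, 200 for CI coverage) were chosen so
the whole suite completes in about a minute on one CPU while keeping
Monte-Carlo error well below the asserted tolerances.
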