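---
title: "Quantitative melasma typing from photoacoustic microscopy volumes"
author: "pamclass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative melasma typing from photoacoustic microscopy volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pamclass)
```

## The measurement problem

Melasma is typed along two axes that jointly determine treatment: how deep
the excess melanin sits (epidermal vs. mixed, i.e. reaching the dermis) and
whether the lesion is vascularised beyond its surroundings (M vs. M+V).
Photoacoustic microscopy (PAM) sees both absorbers at once — melanin and
haemoglobin dominate optical absorption at 532 nm — as a 3D volume of
non-negative envelope amplitudes, one depth-resolved A-line per lateral
position. `pamclass` turns a pair of such volumes (lesional site and
matched non-lesional control from the same patient) into the four-way call
*Epidermal/Mixed × M/M+V*, with every intermediate quantity exposed.

The decision procedure uses five measured quantities:

* **Z** — the epidermis/dermis boundary depth below the skin surface, per
  volume;
* **D** — the maximum pigmentation depth of the lesional skin, the depth at
  which the melanin area–depth curve reaches zero;
* **Φ~ls~, Φ~ns~** — mean dermal vessel diameter in lesional and
  non-lesional skin;
* **ρ~ls~, ρ~ns~** — dermal vessel area density (vascular pixels over total
  pixels of the analysed region).

The rules are: *epidermal* if D ≤ Z, *mixed* if D > Z; *M+V* if **both**
Φ~ls~ > Φ~ns~ and ρ~ls~ > ρ~ns~ (strict), otherwise *M*. Ties therefore
fall to "epidermal" and to "M". The tie rule on depth is not incidental: a
lesion whose pigment runs exactly to the boundary is an epidermal lesion,
and in practice D and Z are estimated from the same melanin boundary, so
epidermal cases typically measure D = Z exactly.

## Pipeline

### Conditioning and surface extraction

Each A-line is median-filtered along depth (default window 3 samples, the
smallest spike-rejecting width) and thresholded at a background floor
estimated as the 99th percentile of the shallowest three samples of every
A-line — a region that lies in the coupling medium, above any skin, and
carries only system noise. Thresholding is a hard cut: values at or below
the floor become 0, values above are untouched.

The skin surface at each lateral position is the depth of the first local
maximum of the A-line above the floor ("first extreme point"), with plateau
ties resolved to the shallowest sample. Two robustness passes follow, both
motivated by the lateral continuity of real skin: isolated A-lines with no
extremum are filled from the median of their valid neighbours, and isolated
depth outliers (more than 2 samples from their local 3×3 median) are
replaced by it. The second pass matters because a percentile-based floor
leaves, by construction, a corresponding fraction of A-lines in which a
noise extremum precedes the true surface; unrepaired, a handful of such
columns contaminate the flattened volume far out of proportion to their
number.

All downstream analysis happens in surface-relative coordinates: every
column is shifted so its surface sample sits at depth 0, which removes the
skin curvature ("flattening").

### Boundary depth Z

In clinical reading, Z is determined visually: lower a cut-off depth until
vascular morphology appears on the maximum amplitude projection (MAP) of
what lies below. We automate exactly that criterion. For each candidate
depth (every axial sample between 30 and 330 µm by default) the dermal MAP
is read off a precomputed running suffix-maximum, and a tubularity score is
computed: the fraction of *strong* pixels (above half the robust maximum of
the above-floor pixels) whose structure-tensor coherence exceeds 0.5.
Superficial melanin projects as a blanket covering essentially the whole
field with isotropic texture and scores near zero; vessels are sparse,
anisotropic structures and score high. The smallest candidate whose score
exceeds 0.15 is Z. If no candidate qualifies (e.g. avascular volumes), the
best-scoring depth is returned with a low-confidence flag, and a manual
`boundary_z` override is available and logged — preserving the original
visual workflow as an escape hatch.

The half-maximum convention used throughout deserves a note: a uniform
absorber layer blurred by a symmetric axial point spread crosses half its
plateau amplitude exactly at its true edge, so thresholds pinned at half
height localise blurred boundaries without bias. This is why both the Z
transition and the melanin floor (below) sit at 50%.

### Melanin quantification

The epidermal XY MAP is analysed in grayscale: mean amplitude over
above-floor pixels and the above-floor fraction. The area–depth curve
counts, per flattened depth slice, pixels above the *melanin floor*: half
the median above-floor amplitude of the deeper half of the epidermis. The
deeper half excludes the bright superficial peak (stratum-corneum /
superficial-melanin entrance signal), which would otherwise inflate the
floor and truncate D. In the pipeline, a pixel counts toward a slice's
area only if at least two of its in-slice neighbours are also above the
floor: genuine pigment is spatially clustered and keeps its area, while
scattered noise pixels at the blurred layer edge are isolated and drop
out. D is then the deepest slice whose area exceeds `min_area_frac`
(0.5%) of the valid columns. Without these two guards, edge noise extends
D by one axial sample for some noise realisations — exactly enough to
flip an epidermal case (D = Z) to mixed; any genuine dermal deposit, even
a few punctate spots, clears both thresholds easily.

Because a single wavelength cannot separate melanin from haemoglobin
spectrally, dermal disambiguation is geometric: the segmented vessel
footprint, dilated by 4 pixels to cover point-spread tails, is excluded
from the area–depth curve. Punctate dermal pigment between vessels (the
interstitial pattern characteristic of mixed-type lesions) survives this
exclusion and is what D responds to in mixed cases.

### Vessel quantification

Vessels are measured on the dermal XY MAP, not in 3D — the reference
analysis counts vascular pixels on lateral projections, and 3D vascular
statistics are explicitly future work. The vessel MAP starts
`vessel_offset_um` (22.5 µm, three samples) below Z: the projection over
the remaining depth still sees every deeper vessel at its full amplitude
(a suffix maximum is monotone in the start depth), but the blurred tail of
the epidermal melanin boundary, which sits just below half-maximum at Z
itself, dies off within those samples and stays out of the vessel image.

Segmentation: light Gaussian smoothing (σ = 1 px), Otsu's threshold on the
above-floor amplitudes to find the vessel mode, then a refined cut at 40%
of the segmented structures' robust peak. The refinement corrects a bias
specific to maximum projections of thin tubes: toward a tube's lateral
edge, the axial chord shortens below the axial PSF length and the projected
amplitude sags, so a half-maximum cut erodes the apparent width; 40% was
validated on cylinder phantoms spanning radii 30–80 µm against the 10%
recovery requirement. Components smaller than 10 px are speckle; compact
components are removed by a scale-free shape criterion (area over squared
maximal inscribed radius ≥ 5; a disc scores π, a tube 4·length/width) so
punctate pigment does not masquerade as vasculature.

Morphometry: ρ is an exact pixel ratio over the analysed region. Φ is the
classic skeleton estimator — Zhang–Suen thinning to the centerline, local
diameter 2·(EDT − 0.5) at each skeleton pixel (EDT = Euclidean distance to
background), averaged and scaled by the pixel pitch; on straight bands of
width 3–20 px it is exact for odd widths and one pixel low for even ones.
The diameter–density correlation r is computed over a 32×32-px tile grid
(no standard sampling unit exists for such correlations; tiles are the
most reproducible choice and the size is recorded in every report), with a
two-sided t-test on n − 2 degrees of freedom. Zero variance across tiles
makes r undefined and is flagged as such, never reported as 0.

### Classification and statistics

`classify_case()` composes the calls from the assembled metrics. Per-tile
diameters and densities serve as replicates for a two-sided Welch t-test
(Mann–Whitney available) comparing lesional against control; the p-values
are reported alongside but do not gate the call by default — the decision
procedure itself uses the inequalities only. A configuration flag
(`require_significance`) additionally demands p < α on both vessel
comparisons before calling M+V, for users who want the stars to gate.

## The phantom: what it emulates, what it does not

`phantom_spec()` builds volumes with exact ground truth: a gently curved
surface (sinusoidal bumps, ±7.5 µm by default), an epidermal melanin layer
from the surface to Z_true with a strong superficial peak, optional
punctate dermal deposits spanning Z_true to D_true placed away from
vessels, and straight cylindrical vessel tubes of known radius below the
epidermis. The absorption map is blurred by a separable Gaussian PSF
(7 µm lateral, 50 µm axial FWHM — the resolution regime of the target
instrument class) and perturbed by additive half-normal noise, keeping
amplitudes non-negative without clipping bias.

Default geometry: 128 × 128 × 96 voxels at 5 × 5 × 7.5 µm. The 7.5 µm
axial pitch is an inference: the reference boundary and pigment depths
(112.5, 135, 165 µm) are all multiples of 7.5 µm, suggesting the sampling
grid, but it is not a documented instrument parameter. The
superficial melanin peak is integrated over each voxel's depth extent so
that its post-blur maximum falls within one sample of the absorber onset
regardless of the sub-voxel phase of the surface — without this, the
recoverable surface would wander by up to two samples with the surface
phase. Ground truth reports the *rasterised* surface (depth of the first
absorber voxel per column), which is the surface a discrete volume can
express.

Four presets encode the four classes. Lesional melanin amplitude is twice
the control's; the M+V presets give the lesional site about twice the
control vessel diameter and about four times the density, the M presets
give the lesional site *smaller* diameters with comparable density —
mirroring the reference pattern in which density alone can exceed the
control even in M-type lesions. Noise σ is 0.05 of the structure
amplitude; no quantitative noise characterisation exists for the original
data, so this value is chosen to be clearly synthetic-but-plausible (the
surface peak sits ~100σ above the floor, the vessel plateau ~20σ) and is
*not* calibrated to the instrument.

What the phantom does not emulate: acoustic propagation and transducer
bandpass, speckle statistics, vessel branching and tortuosity, spatially
varying melanin concentration, probe-skin coupling artefacts. Passing the
phantom benchmarks therefore demonstrates that the estimators recover known
geometry through the PSF-and-noise forward model — it does not certify
performance on clinical volumes, where the visual-override and
low-confidence pathways exist for a reason.

## Numerical choices and degenerate inputs

* Half-open layer intervals: the epidermis is [0, Z), the dermis [Z, max];
  every flattened sample belongs to exactly one layer, and depth D = Z
  classifies as epidermal.
* Boundary candidates and Z are multiples of the axial pitch; anything else
  is rejected rather than silently rounded.
* Empty structures degrade explicitly: an all-zero MAP yields an empty
  vessel mask (Φ = 0, ρ = 0), an empty area curve yields D = 0, fewer than
  three vessel-bearing tiles is an error, not a correlation.
* Identical replicate groups compare at p = 1; distinct constant groups at
  p = 0 (the Welch statistic is undefined for both).
* Volumes round-trip losslessly through NIfTI (float64 with voxel spacing
  in the header). Multi-page TIFF is supported as uint16 (exact for
  integer counts) and float32 restricted to [0, 1]; the reader clips
  negative stored values to zero with a warning and treats pages as depth
  slices in file order, never reordering.
* Validation problem sizes: unit tests run 64 × 64 × 96 phantoms; the
  acceptance benchmarks run the full 128 × 128 × 96 geometry, a six-radius
  diameter sweep, and 100 noise replicates per preset.

## Known limitations

Vessel morphometry is 2D-projective: overlapping vessels merge in the MAP,
and diameters are apparent widths, biased for tubes thinner than the axial
PSF. The melanin/vessel separation is geometric, not spectral; melanin
deposited *on* a vessel wall is invisible to it. A single Z per volume is
assumed (one value per volume, as in per-patient reporting); spatially varying
epidermal thickness within a field is not modelled. The global
fraction-of-peak vessel threshold assumes vessels of broadly similar
amplitude within one field; fields mixing strongly and weakly absorbing
vessels would need the per-component machinery exposed via
`segment_vessels(threshold = )`.
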