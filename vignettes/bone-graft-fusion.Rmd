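---
title: "Relating Raman-based segmentations to micro-CT gray values"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relating Raman-based segmentations to micro-CT gray values}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanfuse)
```

## The analysis problem

A bone sample containing a graft substitute is imaged twice: a µ-CT slice
records X-ray absorption (a density proxy, 16-bit gray values), and a Raman
map records one full spectrum per pixel of a coarser XY grid (50 µm step,
50–3300 cm⁻¹). The analysis asks how far the density information matches the
chemical information: can a gray value tell bone from graft granulate from
a mineralization front? `ramanfuse` operationalizes the question as a
pipeline — Raman feature images, redundancy filtering, hierarchical pixel
clustering, and cross-modal statistics on the co-registered gray values —
plus a synthetic phantom that makes every stage testable.

## The model, stage by stage

### Baseline correction

Raman spectra of mineralized tissue sit on a strong, smooth fluorescence
background. We estimate it by asymmetric least squares: the baseline $z$
minimizes

$$\sum_i w_i (y_i - z_i)^2 + \lambda \sum_i (\Delta^2 z_i)^2,$$

with weights iteratively set to `asymmetry` ($p$) above the current
baseline and $1-p$ below, so the fit hugs the spectrum's lower envelope and
passes under the bands. The system is pentadiagonal and is solved by a
banded Cholesky factorization in compiled code (sub-second for a full map).
Defaults: `smoothness` $\lambda = 10^6$ (in units of the sample grid to the
fourth power — stiff enough to keep a polynomial-grade background, loose
enough to follow the broad luminescence bump), `asymmetry` $p = 0.01$, at
most 10 reweighting iterations. Two properties are contractual and tested:
a pure constant background corrects to within ±1 cps of zero, and an
isolated band on zero background keeps its height within 2 %.

One consequence of the lower-envelope convention: corrected noise is not
zero-mean but sits slightly above zero. The band signal-to-noise ratio is
therefore computed as the mean band intensity divided by the RMS of the
noise-window fluctuation *about its per-pixel mean* — the noise itself, not
the residual offset. A noiseless map has no defined SNR and returns an
`Inf` sentinel flagged `noiseless`.

### Feature layers

A *band image* is the baseline-corrected intensity at the axis sample
nearest the band position (no peak fitting), clipped to a per-band contrast
window and linearly scaled so `lo -> 0`, `hi -> 255` with round-half-up.
The default band list (`raman_bands()`) covers the bone-relevant modes:
phosphate ν₂/ν₄/ν₁ (438, 589, 961 cm⁻¹, the ν₁ window reaching 400 cps),
B-type carbonate substitution (1075 cm⁻¹), amide III/I (1256, 1677 cm⁻¹)
and C–H bending/stretching (1457, 2937 cm⁻¹, window to 500 cps). Narrow
windows deliberately saturate strong pixels to enhance weak-band contrast.

A *correlation map* holds, per pixel, the Pearson COC between the pixel
spectrum and a candidate material's reference spectrum, by default over the
full recorded range (a `range` override exists). The signed raw COC is kept
alongside the 8-bit display values (negative COC clips to 0 on the display
scale only) because the attribution statistic squares the raw value.
Zero-variance pixel spectra have no defined correlation; they get COC 0 and
are flagged in the layer's validity mask.

### Redundancy filter

Pairs of layers with $|COC| > 0.9$ (strict) duplicate information. The
filter scans pairs greedily in stack order and drops the later member, so
the outcome is deterministic and user-controllable through the stack
order. The pipeline stacks correlation maps first and band images after:
reference correlation maps carry the most specific material information,
so when a band image merely restates one (the phosphate band images
typically restate the mineral correlation maps) the band image is the one
to go. The filter is idempotent, and removing layers can only remove
pairs, so no surviving pair exceeds the threshold.

### Segmentation

The surviving layers are flattened (row-major pixel order) into the raw
data matrix of 0–255 gray values — one row per pixel, one column per layer.
Columns are *not* re-standardized: the shared 8-bit scale is the common
unit. Pixels are clustered by `stats::hclust` on Euclidean distances with
unweighted average linkage (UPGMA), whose merge heights are monotone
non-decreasing; the tree is cut at `cut_fraction` of its maximum merge
height, grouping leaves into the clusters existing strictly below the cut
(a merge at exactly the cut height stays above it; numerically the cut is
taken at `cut_height * (1 - 1e-12)`). A degenerate all-zero-height tree is
one cluster. Segments are renumbered by descending size, and segments
smaller than `min_segment_size` (default 20 pixels) are flagged as
faulty-measurement candidates but kept — scattered poor-SNR pixels tend to
gather in small stray clusters, which is exactly how the faulty
measurements are discriminated.

The cut fraction is a per-dataset tuning choice, set to avoid visible
over- and under-segmentation; sample composition is assumed known (as it
is in graft-substitute studies), so "under-segmented" is detectable as
fewer segments than constituents. For the default phantom (four materials
plus the kerf stripe) 0.45 of the total distance achieves this across
seeds, and is the packaged default; the tissue measurements this pipeline
emulates needed 0.57 and 0.55. We deliberately do not automate the choice:
a relative cut depends on the outlier structure at the dendrogram root,
and silent auto-tuning would hide exactly the decision a practitioner
should review.

### Cross-modal statistics

The 16-bit CT slice maps to 8 bit by `round(v / 257)` — monotone and
endpoint-exact (0 → 0, 65535 → 255). An affine registration transform
(`ct = A [row, col] + offset`; in practice derived from fiducials such as
saw kerfs, identity for phantoms) carries each Raman pixel into CT
coordinates; gray values are picked by nearest neighbor (default) or
bilinear interpolation, with out-of-bounds pixels masked and excluded.

On the segment-labeled gray values the package computes:

* a one-way fixed-effects ANOVA (`F = (SS_b/df_b)/(SS_w/df_w)`, fitted via
  `lm`; degenerate inputs are handled explicitly — zero within-segment
  variance with distinct means gives `F = Inf, p = 0`, fully constant data
  gives `F = 0, p = 1`);
* per-segment box statistics: median and quartiles by linear interpolation
  of order statistics (quantile type 7 — chosen so the oracle tests are
  exact), whiskers at the most extreme points within 1.5 IQR of the box,
  outliers counted beyond;
* normalized gray-value histograms (256 one-gray-level bins, relative
  frequencies summing to 1);
* the COD table: COD(material, segment) = (mean raw COC over the segment's
  valid pixels)², with row-max attribution. The aggregation rule is a
  design decision — squaring the segment-mean COC; the alternative (mean
  per-pixel squared COC) is available as `cod_method = "mean_cod"`. The
  attribution table is computed from *all* reference correlation maps,
  including any removed by the redundancy filter: the filter de-duplicates
  the clustering input, but attribution needs one row per candidate
  material.

## The phantom: what it emulates, and what it does not

`simulate_phantom()` generates the full co-registered study. Materials are
specified as Gaussian band lists (center, height, width) plus an optional
raised-cosine luminescence bump and a CT gray-value Gaussian mixture on
the 8-bit scale. The defaults (`bone_graft_materials()`) encode:

* **graft granulate** ("biooss"): strong mineral bands (ν₁ 961 at 400 cps,
  carbonate 1075 at 180 cps) and a luminescence bump over 1200–2000 cm⁻¹
  (amplitude 60 cps) — reproducing the known confound that amide-region
  band images light up inside granulate areas; CT mode 140;
* **bone**: full mineral + matrix band set; CT grays from a bimodal
  mixture, modes 60 (weight 0.85, σ 4) and 115 (weight 0.15, σ 6) — the
  dark/bright accumulation a segment of mixed soft and dense tissue
  shows. The unequal weights keep the mixture's median on the dominant
  mode's shoulder, where the CDF is steep and the sample median is stable;
  an even split would put the median in the flat inter-mode region where
  it is statistically meaningless;
* **tricalcium phosphate**: mineral doublet at 949/970 cm⁻¹; CT mode 115,
  or — with `shared_density = TRUE` — exactly the bone mixture, producing
  the density-ambiguity phantom: two chemically distinct materials that no
  gray value can separate;
* **fat**: C–H dominated spectrum; two close CT modes (55/62);
* **background** (air/alcohol, also the saw-kerf stripe): no bands, CT
  mode 18.

Geometry is a seeded Voronoi partition (contiguous blobs, each ≥ 1 % of
pixels) with an optional ~3-pixel-wide kerf stripe — wide enough that its
core survives partial-volume mixing. Pixel spectra are the material
references, mixed at region borders by 3×3 label-fraction smoothing
(partial-volume pixels that make clustering nontrivially hard; the mixing
strength is a free phantom parameter, not a claim about real interfaces),
plus a per-pixel random low-order-polynomial baseline scaled by
`baseline_amp` (100 cps default) and i.i.d. Gaussian noise (`noise_sd` 8
cps, putting the ν₁PO₄ band SNR near 50 and the weak bands in the
single-digit range typical of mapping measurements). A `faulty_fraction`
(1 %) of pixels is replaced by noise-only spectra — arbitrarily
distributed failed acquisitions. CT grays are drawn per pixel from the
material's mixture on the 8-bit scale, rounded, and stored ×257 in 16 bit,
so the bit-depth mapping round-trips exactly. All randomness flows from
one integer seed; outputs are byte-identical across runs.

The phantom does **not** emulate: real Raman line shapes (Voigt profiles,
the ~5 cm⁻¹ apparatus function is only echoed in the default widths),
wavenumber-dependent noise, cosmic-ray spikes, spatially correlated CT
noise or reconstruction artifacts, registration error (the phantom
transform is exact), or resorption-gradient chemistry. Passing tests
therefore demonstrate that the *pipeline machinery* is correct and that
the method's logic holds under the assumed statistical structure — not
that any particular tissue conclusion transfers to an instrument data set.

## Numerical choices

* Quantization is round-half-up (`floor(x + 0.5)`), applied to band
  windows, correlation display values and the 16→8-bit mapping; window
  edges saturate exactly.
* Segment labels are 1-based integers renumbered by descending size;
  ties in UPGMA merges are resolved by `hclust`'s deterministic internal
  order (only the multiset of merge heights is contractual).
* Constant layers and zero-variance pixels get COC 0 and are flagged
  rather than propagating `NaN`.
* Problem sizes: the shipped study runs a 60×80-pixel map with 813
  spectral channels (50–3300 cm⁻¹ at 4 cm⁻¹ — two samples per apparatus
  width), five reference materials and thirteen feature layers; a full
  pipeline run takes a few seconds.

## Known limitations

The relative dendrogram cut is sensitive to the outlier structure at the
root: on occasional seeds a fixed fraction under-segments (two materials
merge) and the segment count signals that the cut needs retuning, exactly
as in manual practice. Registration is supplied, not estimated — automatic
fiducial detection is out of scope. The COD aggregation rule follows the
design decision above; on strongly bimodal within-segment correlations the
two offered rules can rank segments differently, which is why both are
exposed.
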