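---
title: "Quantifying primary cilia: models, procedures, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying primary cilia: models, procedures, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciliametrics)
```

# The measurement problem

A primary cilium in a wide-field immunofluorescence image is a thin
(~0.25 µm), gently curved, 1–10 µm long structure: the acetylated-tubulin
axoneme sheathed by an Arl13B-positive membrane, anchored at a
gamma-tubulin basal-body punctum near a DAPI-stained nucleus. The
phenotypes that distinguish experimental conditions are low-dimensional:
the percentage of ciliated cells, cilium length, distal fragmentation,
base-to-tip marker distributions, and marker enrichment over local
background. This package turns those measurements into deterministic,
testable code, and pairs them with a simulator whose per-cilium ground
truth makes every recovery claim checkable.

# The pipeline and its assumptions

## Detection and tracing

Detection runs on the membrane channel when present (the sheath is
continuous even over a fragmented axoneme), otherwise on the axoneme
channel:

1. Pre-smooth with a Gaussian (`smooth_sigma`, default 1 px) so that a
   k-sigma threshold survives realistic pixel noise.
2. Threshold at `median + threshold_k * MAD` (default k = 5). On noiseless
   images the MAD collapses, so the threshold falls back to a fixed
   fraction of the dynamic range above background.
3. Label connected components; estimate each component's width as twice
   the median centerline-to-boundary distance (robust for short cilia,
   where area/length is dominated by end caps) and reject components wider
   than `max_width_um` or shorter than `min_length_um`.
4. Skeletonize (Zhang–Suen) and prune to the longest geodesic path through
   the skeleton graph (orthogonal steps weigh 1, diagonal steps sqrt(2));
   cilia are unbranched, so side twigs are artifacts of thinning. Ties are
   broken by total intensity along the path.
5. Smooth the pixel chain, refine each point to the intensity-weighted
   centroid along the local normal, and extend both ends along the tangent
   to the half-maximum crossing of the smoothed image. Thinning retracts a
   skeleton about half a structure width inside each tip; for an edge
   blurred by a symmetric PSF the half-max point sits at the true edge, so
   this extension is the principled endpoint estimate rather than a tuned
   constant.
6. Resample to ~1 px arc spacing. Length is the calibrated polyline sum.

Orientation uses the basal-body channel: the punctum nearest to either
trace end (among local maxima above a k-sigma threshold, within
`cell_assign_radius_um`) marks the base. Brightness decides only between
equidistant puncta, and an exact two-end tie goes to the end with the
higher integrated basal signal in a 3 px disk. Without a basal-body
channel the trace is flagged orientation-ambiguous; ambiguous profiles are
excluded from oriented group matrices and tip calls require both
orientations to agree.

## Fragments

A fragment is a connected component above the axoneme threshold that is
disjoint from every detected cilium body (with a margin covering the
smoothing halo), lies within `search_radius_um` (default 5 µm) of the
distal tip, spans at least 2 px and at most `max_area_um2` (default
1.5 µm², which excludes neighbouring cilium bodies), and — by default —
is also above threshold in the membrane channel, because the biologically
meaningful objects are membrane-bounded. `require_membrane = FALSE`
supports axoneme-only stainings; requesting membrane confirmation without
a membrane channel is an explicit error, never a silent zero. Both the
count and the binary call are reported, since either can be the axis of a
fragmentation figure.

## Profiles

`sample_path_intensity()` reimplements an improfile-style script: at each
path sample the reported value is the mean of `transverse_px` (default 3)
lookups spaced 1 px across the path. "Above, on, and below" is only
well-defined for near-horizontal paths, so the default offsets follow the
local path normal (rotation-invariant); `transverse_mode = "literal_rows"`
keeps the literal vertical offsets for fidelity. Intensity lookup is
bilinear by default; `interp = "nearest"` reproduces pixel-exact sampling
and is the mode in which the implementation is asserted equal to a
brute-force oracle. Off-image offsets are dropped from the mean.

`bin_profile()` maps a sample at normalized arc position `s` to bin
`min(floor(s * n_bins), n_bins - 1) + 1` — half-open bins with the last
bin closed — and averages within bins. A profile that cannot fill every
bin is rejected with a classed error rather than interpolated, so a
too-short cilium can never silently enter a group matrix. When samples
divide evenly into bins, the mean of bin means equals the mean of samples
(tested to 1e-9 relative), and reversing a trace reverses the bins
exactly.

## Densitometry and normalization

`mean_gray_value()` is exactly sum-over-count. The normalized ciliary
intensity divides the mean gray value over the cilium selection by that of
a surrounding annulus (dilation of the selection by `annulus_outer_px`
minus dilation by `annulus_inner_px`, excluding other cilia and nuclei).
The selection is the traced path widened transversely to `transverse_px`
— the analog of the selection a user draws along the cilium — not the full
threshold component, whose dim halo pixels would dilute the ratio. The
same annulus estimate is the background for tip calls and the
background-subtracted bin columns, so one background concept serves the
whole module.

A physical caveat measured during development: for a ~0.45 µm-wide cilium
imaged with a sigma = 1 px PSF at 0.1 µm/px, diffraction alone depresses
the mean-gray ratio of a 3-fold-enriched marker to about 2.4–2.7. The
enrichment-recovery test therefore runs the simulator with the PSF off
(noise on), isolating the normalization operation from blur physics; with
the PSF on, recovered ratios should be read as lower bounds on true
enrichment.

## Tip calls

A marker is tip-positive when the background-subtracted mean of the distal
bin is at least `fold_threshold` (default 2.0) times the mean of bins
1–8. Bin 9 is deliberately left out of the shaft estimate so a tip
enrichment that leaks proximally does not raise its own reference.

## Group statistics

The t statistic, Welch degrees of freedom, and Tukey HSD adjusted
p-values are computed from their closed forms using the base distribution
functions (`pt`, `ptukey`); `stats::t.test` and `TukeyHSD` serve as
independent oracles in the tests. Zero-variance groups are guarded (equal
means give p = 1, unequal means p = 0, both flagged). Tukey reporting
supports a requested subset of pairs while adjusting over the full family,
as figure legends often do. Per-bin profile tests are one unpaired t test
per bin, proximal to distal, unadjusted by default because ten raw per-bin
p-values are the conventional report; Bonferroni is opt-in.

# The simulator as a stated world

`sim_params()` fixes the world the tests live in:

* **Geometry** — fields of 384×384 px at 0.1 µm/px (the pixel size is a
  stated convention: acquisition metadata typically records the objective
  NA but not the pixel pitch; 0.1 µm/px matches a 100×/1.4 NA camera
  setup). Six cells per field on a jittered grid; placement that cannot
  fit the requested cells raises an explicit error. Cilium centerlines are
  quadratic Béziers with control legs rescaled until the numerically
  integrated arc length matches the drawn target exactly (truth length is
  that integral); curvature is bounded by `curvature_max` (default
  0.3 µm⁻¹, gently curved). Lengths are lognormal, default mean 3 µm,
  SD 1 µm, truncated to 0.5–10 µm.
* **Rendering** — structures are rasterized transversely (flat end caps,
  so the rendered extent equals the true arc and length recovery is
  measured against an unambiguous truth), blurred by a Gaussian PSF
  (sigma 1 px), then degraded by Poisson shot noise and Gaussian read
  noise. The noiseless rendered image equals background plus the blurred
  crisp structures to 1e-9, checked against a direct-convolution oracle.
  `noise_for_snr()` converts a target amplitude-over-background-noise SNR
  into read-noise settings; recovery tests run at SNR 5.
* **Fragments** — short dual-positive segments displaced distally from the
  tip (default first-edge gap 1 µm, well above the PSF, so fragments are
  resolvable at zero noise); the noiseless axoneme mask has exactly
  1 + fragment-count components per cilium. An option renders
  axoneme-only debris as distractors.
* **Markers** — uniform, or a tip/base plateau attaining
  `amplitude`-fold enrichment over `position_frac ± width_frac` (defaults:
  distal 10% of arc). Tip and base enrichments additionally extend one
  plateau half-width past the geometric end, because a protein cap sits
  centered on the cilium end — without this, diffraction halves the
  on-path signal exactly at the tip and no threshold-based call can see
  the stated amplitude. Markers fill the cilium's full width so a
  centerline selection measures marker-positive pixels.

What the simulator does **not** emulate: out-of-focus light and 3D tilt,
uneven illumination, cytoplasmic marker pools, touching cells, or
photobleaching. A green recovery test therefore establishes that the
algorithms are correct under the stated imaging model, not that they are
robust to every real-world artifact; the manual-path entry point exists
precisely so real, interactively segmented data can flow through the same
measurement code.

# Numerical choices and degenerate inputs

* Coordinates are 0-based with pixel centers at integers; all distances
  are micrometres via `pixel_size_um`.
* Robust thresholds fall back to a dynamic-range fraction when the MAD is
  zero (noiseless images); an all-saturated detection channel is an error.
* Nucleus segmentation takes the larger of the Otsu and robust thresholds:
  Otsu separates nuclei when they exist, the robust floor keeps an empty
  field from being split in half, and components below
  `nucleus_min_area_um2` are discarded.
* Empty profile bins reject the profile; empty annuli are an error for the
  normalization ratio and fall back to the robust field background for
  profile background estimates; a field without nuclei reports counts with
  an undefined (flagged) ciliation fraction.
* Seeds are mandatory in the simulator, and identical parameters produce
  bit-identical images and truth tables; condition pairs derive per-field
  seeds deterministically from each condition's master seed.

# Design decisions that were genuinely open

* **Automated tracing replaces interactive segmentation** so that recovery
  against ground truth is measurable; manual paths remain a first-class
  input for fidelity to interactive practice, and the two agree on traced
  length within a few percent on simulated cilia.
* **Detection prefers the membrane channel**: the sheath is continuous
  over fragmented axonemes and specific to cilia.
* **Cilium-to-cell assignment** is nearest nucleus within
  `cell_assign_radius_um` (20 µm): assignment conventions are not part of
  any published procedure, so the package states one and logs it.
* **Unit of replication** for group tests is the cilium by default; field
  means can be compared by passing per-field summaries instead — the
  choice is the caller's and is visible in the comparison's n.
* **Student, not Welch, is the default t variant** because "unpaired
  t test" in figure legends conventionally means the pooled-variance
  test; Welch is one flag away.

# Known limitations

* Pure R raster operations keep fields of a few hundred pixels per side
  comfortable (~0.3 s detection per 384² field); very large tiles would
  need cropping.
* Crossing or touching cilia merge into one component and are traced as
  one; at realistic densities this is rare, and such traces usually fail
  the width filter rather than silently biasing lengths.
* The TIFF codec is deliberately minimal (uncompressed, grayscale,
  8/16-bit unsigned or 32/64-bit float, single sample per pixel); it
  round-trips the package's own output losslessly but does not read
  compressed or OME metadata variants.
* 2D only: the quantified images are single-plane wide-field acquisitions;
  3D reconstruction is out of scope.
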