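# ciliametrics

Quantitative morphometry and intensity profiling of primary cilia in
multi-channel fluorescence microscopy.

Primary cilia are solitary, micrometre-scale sensory organelles. Comparing
conditions (for example a parental cancer cell line against a
kinase-inhibitor-resistant derivative) routinely comes down to a handful of
per-cilium and per-field numbers: the fraction of ciliated cells, cilium
length, whether the distal axoneme has shed membrane-bounded fragments, how a
marker protein distributes from base to tip, and how strongly a marker is
enriched in the cilium over its surroundings. These measurements are usually
made interactively, which makes them hard to audit. `ciliametrics`
reimplements them as an automated, testable pipeline for R, together with a
synthetic-image simulator with full ground truth so every stage can be
verified without microscopy data.

## What it measures

Given a calibrated field with channel roles (axoneme = acetylated tubulin,
membrane = Arl13B, basal body = gamma-tubulin, nucleus = DAPI, plus any
marker channels):

* **Detection and tracing** — robust background threshold (median + k·MAD),
  connected components, skeletonization, longest-geodesic-path pruning, and
  subpixel centerline refinement give one ordered base-to-tip trace per
  cilium. User-clicked polylines (`read_manual_paths()`) reproduce the
  interactive mode.
* **Length** — `L = sum(||p_i+1 - p_i||) * pixel_size` over the subpixel
  trace, in micrometres.
* **Fragmentation** — detached components near the distal tip that are
  positive in both the axoneme and membrane channels (membrane-bounded
  fragments), reported as a per-cilium count and a binary call.
* **Ciliation fraction** — ciliated nuclei / total nuclei, with cilia
  assigned to their nearest nucleus.
* **Axial profiles** — at each path position the mean of 3 transverse
  samples (above / on / below the path), then arc length normalized into 10
  bins (bin `b` collects samples with `floor(s * 10) = b - 1`), proximal to
  distal, so cilia of different lengths are comparable.
* **Background-normalized intensity** — mean gray value (sum of pixel values
  / pixel count) over the cilium selection divided by the mean gray value of
  a surrounding annulus.
* **Group statistics** — unpaired Student t tests (Welch by flag), Tukey's
  HSD via the studentized-range distribution for 3+ groups, and per-bin t
  tests for profile matrices.

## Worked example

Simulate a parental-vs-resistant pair and compare cilium lengths:

```r
library(ciliametrics)

markers   <- list(Kif7 = marker_spec("tip_bump", amplitude = 2.5))
noise     <- noise_for_snr(sim_params(seed = 1), snr = 5)
parental  <- sim_params(seed = 11, ciliation_prob = 0.45, length_mean_um = 2.5,
                        length_sd_um = 0.8, marker_specs = markers, noise = noise)
resistant <- sim_params(seed = 12, ciliation_prob = 0.75, length_mean_um = 4.5,
                        length_sd_um = 1.2, fragment_prob = 0.5,
                        marker_specs = markers, noise = noise)
pair  <- simulate_condition_pair(parental, resistant, n_fields = 3)
quant <- function(set) do.call(rbind, lapply(set, function(s) quantify_field(s$field)$records))
rec_a <- quant(pair$a); rec_b <- quant(pair$b)
t_test_unpaired(rec_a$length_um, rec_b$length_um, measure = "cilium length (um)")
#> <group_comparison> cilium length (um), method = t_test_student
#>   statistic df  p_value mean_a mean_b   sd_a   sd_b n_a n_b
#> 1    -4.007 16 0.001017  2.674  4.509 0.2612 0.8873   4  14
mean(rec_a$fragmented); mean(rec_b$fragmented)
#> [1] 0
#> [1] 0.7142857
```

The detected cilia of the resistant condition are ~1.8 µm longer
(p ≈ 0.001, unpaired t test), 71% of them carry detached dual-positive
fragments, and the simulated tip-enriched Kif7 marker is called tip-positive
from its distal profile bin. Per-cilium records carry the ten raw and ten
background-subtracted bin values per marker; `write_results()` writes them
as CSV plus a per-field JSON summary.

Real images enter through `read_field()` (multi-page TIFF + channel-role
JSON sidecar, or an explicit `role_map`); `inst/scripts/quantify.R` wraps
the pipeline as a command-line tool.

## Acceptance script

`scripts/acceptance.R` re-runs the pipeline from scratch — it simulates a
condition pair at the configured signal-to-noise ratio, quantifies every
field with the installed package, prints the group comparison, and writes
the target report JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
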