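---
title: "Methods: simulating and analyzing sequential chromogenic IHC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing sequential chromogenic IHC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqihc)
```

Sequential chromogenic immunohistochemistry stains one marker per round on a
single tissue section: stain, scan, strip the antibody and chromogen, restain
the next marker, rescan. Because every round images the *same* cells, spatial
coincidence of signal across registered rounds reveals which cells co-express
which markers — without multicolor fluorescence. This vignette documents the
forward model used by the simulator, the analysis chain, and the numerical
and design decisions behind both.

## The forward model

A virtual slide is a field of `rows x cols` pixels at `pixel_size_um` micron
per pixel (origin top-left, `x` along columns, `y` along rows; the pixel in
column `j` has center `x_um = (j - 0.5) * pixel_size_um`).

**Ground truth.** Cells are planted by dart throwing: per co-expression
class, a Poisson-distributed number of cells (expectation = the configured
`count`) is placed uniformly, rejecting positions closer than
`min_spacing_um` to any accepted cell. Radii are truncated-normal around
`cell_radius_um`. Each class fixes an expression level in `[0, 1]` per
marker. The generator exports the full table — positions, radii, classes,
expressions, and each round's true misalignment — so every analysis result
can be scored against known truth.

**Rendering (Beer–Lambert).** Round `r` develops its marker's absorbance
field

> `A(p) = stain_density * sum_cells expr * kernel(p) + puncta + carryover_fraction * A_prev(p)`

where `kernel` is a plateau soma profile (full density out to 0.7 of the
radius, cosine taper to the rim), `puncta` are sub-cellular anti-aliased
discs (`puncta_radius_um`, density `puncta_density` per mm², expression
`puncta_expression`) representing fine stained particles, and the carryover
term models incomplete stripping of the previous round. Pixel transmittance
per channel is `exp(-A * chromogen_od)` with the chromogen's RGB optical
density direction `chromogen_od = (0.30, 0.70, 0.65)` — a red-brown
precipitate absorbing strongly in green/blue. The scan then applies optical
blur (`blur_sigma_um`), the round's rigid misalignment (white fill),
illumination gain, additive Gaussian noise (`noise_sd`), clipping, and
quantization to `bit_depth` bits (default 8, what brightfield slide scanners
deliver). A noise-quantized blank scan accompanies every round as the
white-balance reference.

Two amplitude parameters are deliberately separate: `chromogen_od` fixes the
*hue* of the stain, `stain_density` its *depth* (peak absorbance of a fully
stained soma). The default `stain_density = 24` renders a fully stained soma
below the 8-bit quantization floor in all channels — saturated black, as
heavily developed chromogen appears — which is what makes the multiplicative
overlay dim co-expressing cells completely (see below).

**Realism limits.** The simulator is a phenomenological test harness, not a
physics model: somata are discs, not morphologies; noise is i.i.d. Gaussian,
not Poisson shot noise; misalignment is rigid, with no tissue deformation;
stripping either works (carryover 0) or leaves a spatially uniform fraction.
These simplifications are what make planted ground truth exact.

## The analysis chain

1. **White balance** divides each channel by the blank reference's
   per-channel median, removing illumination color and gain.
2. **Signal extraction** produces a scalar bright-on-dark map per round:
   either `1 - luminance` (the faithful analog of visual color inversion) or
   optical-density projection onto the chromogen direction
   (`mode = "deconvolution"`, linear in absorbance and therefore preferred
   for *quantifying* unsaturated stain).
3. **Registration** estimates each round's rigid offset against the
   reference round by Hann-windowed FFT phase correlation with wrap-aware
   parabolic subpixel refinement; rotation by a coarse-to-fine peak-height
   search over angle. Accuracy on full-size (1024 px) maps is well under
   0.5 px and 0.1 degrees; the angular lever arm scales with field size, so
   very small fields resolve rotation proportionally less precisely.
4. **Overlays.** Three schemes: (a) multiplicative superimposition of an
   *inverted* round onto another round — cells positive only in the inverted
   round glow against the white base, co-expressing cells are dimmed into
   the dark background by the underlying stain (multiplication is the unique
   standard blend with both behaviors); (b) two-color additive pseudocolor
   (green + red, co-expression renders yellow); (c) multi-marker additive
   pseudocolor (green/red/purple).
5. **Cells.** Per map: Gaussian smoothing at half the nominal soma radius,
   robust threshold (background median + 5 MAD of the raw map, floored at
   `min_signal`), connected components, watershed split of multi-maximum
   components, and an area band that rejects puncta and debris. Detections
   are merged across markers by single-linkage clustering at 5 µm; each
   merged cell is quantified by a 10 %-trimmed disc mean per marker, called
   positive against that map's robust threshold, classified by its positive
   combination, and given a relative expression (disc mean over the mean of
   positive cells).
6. **Stripping QC** re-develops a control scan after stripping: the residual
   signal map is smoothed at a 2 µm sub-cellular scale and compared to a
   threshold from the identically smoothed blank; the verdict fails when
   more than `f_max` (default 0.1 %) of pixels show residual stain.

## Design decisions worth knowing

- **Minimum spacing = two mean radii.** One-radius spacing would let somata
  interpenetrate, which neither real tissue nor any area-based detector
  supports; two radii keeps somata disjoint while still allowing abutting
  pairs that exercise the watershed split.
- **Trimmed disc means.** A punctum landing inside the measurement disc of a
  cell *negative* for that marker can push a plain mean over the positivity
  floor and fabricate a double-positive. Trimming 10 % of disc pixels
  rejects those few bright pixels while preserving the linear scaling that
  relative expression relies on.
- **Threshold floors.** Robust thresholds degenerate on noise-free maps
  (median = MAD = 0), so detection and positivity thresholds carry small
  absolute floors (`min_signal = 0.05`, `pos_floor = 0.02`).
- **Smoothed QC maps.** Without the 2 µm smoothing, the pixel-level false
  positive rate of a median + 5 MAD threshold (~1e-3) sits exactly at the
  default `f_max`, making the clean-strip verdict a coin flip; smoothing
  makes the statistic sensitive to stained *structures* instead of single
  noisy pixels.
- **The dimming contract is a noise-free property.** With any clipped
  additive noise, a dark cell's disc mean concentrates at the rectified
  noise mean (~0.40 sd) while the background median sits near 0.24 sd — so
  "co-expressing centers at most 1.5 x background median" cannot hold for
  any stain. The overlay algebra itself is exact; the visibility property is
  therefore stated and tested on noise-free renders, where the default
  saturated stain dims co-expressing centers to exactly zero.
- **Edge handling.** Gaussian smoothing uses replicated (not circular)
  boundaries; circular FFT boundaries wrap stained structure across opposite
  field edges and create phantom edge detections.

## Worked example

```{r example, eval = FALSE}
cfg <- run_config(
  mode = "simulate",
  sim = sim_params(
    field_width_um = 500, field_height_um = 500, pixel_size_um = 1,
    classes = class_table(
      "GAD67-only" = list(expr = c(GAD67 = 1, PV = 0), count = 20),
      "GAD67+PV"   = list(expr = c(GAD67 = 1, PV = 1), count = 15))),
  seed = 7, output_dir = "analysis_out")
res <- run_pipeline(cfg)
res$report                    # co-expression classes and fractions
res$qc                        # stripping verdict
res$transforms                # estimated per-round alignment
```

A ready-made three-marker scenario (`sim_params_cortex3()`) emulates a
2 x 2 mm cortical field where every parvalbumin-positive cell also expresses
GAD67 and parvalbumin/calretinin are disjoint; the pipeline recovers both
facts along with class composition to within a few percentage points in
about 1.5 minutes on one CPU.

## Problem sizes

Defaults target single-CPU practicality: unit-test fields are 300–500 µm at
1 µm/px (seconds), registration is validated at 1024 px working size
(~5 s per round), and the three-marker scenario runs a 2000 px field
end-to-end in under two minutes. Scanner-resolution work (0.5 µm/px) scales
by 4x in pixels; all stages are linear or n log n in pixel count.
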