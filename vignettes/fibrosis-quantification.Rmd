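---
title: "Measuring tubulointerstitial fibrosis in trichrome-stained kidney sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring tubulointerstitial fibrosis in trichrome-stained kidney sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibroquant)
```

## The measurement problem

In murine models of chronic kidney disease, the severity of renal damage is
scored by the fraction of tissue area occupied by fibrotic extracellular
matrix. Masson's trichrome renders the three relevant tissue classes in
distinct colours: collagen blue (Methyl Blue), cytoplasm and muscle red
(Ponceau-fuchsin), and nuclei dark blue-purple (hematoxylin). The quantity
of interest for a photomicrograph is

$$\%\text{fibrosis} = \frac{\text{area occupied by fibrosis}}{\text{total area}} \times 100,$$

with both areas in pixels and *total area* the full frame. Using the frame —
not the count of pixels that survive the exclusion stages — means excluded
structures (tubules, manually-marked glomeruli or vessels) dilute the
percentage exactly as they dilute real tissue. A naive colour threshold
over-reports fibrosis, because hematoxylin-stained tubule rims are
blue-purple and bleed into any blue-selecting criterion; the point of the
pipeline is to segment and remove such normal structures *before* the
collagen threshold.

## The stain model

We assume Beer–Lambert transmission: a pixel's optical density is
$OD_c = -\log_{10} I_c$ per channel $c$, stains contribute additively, and a
stain is a unit-norm absorbance vector $\mathbf{s} \in \mathbb{R}^3_{\ge 0}$.
A pixel carrying concentrations $a_i$ of stains $\mathbf{s}_i$ over
background $B_c$ transmits

$$I_c = B_c \cdot 10^{-\sum_i a_i s_{i,c}}.$$

`unmix_colors()` inverts this per pixel by ordinary least squares on the
span of the chosen stain vectors, flooring negative coefficients at zero.
With two stains the coefficients equal those of the full decomposition onto
{primary, secondary, orthogonal residual}, so no explicit residual direction
is needed; iterative non-negative least squares is deliberately avoided to
keep the stage closed-form and fast. Intensities are floored at
`eps = 1/256` (one quantization step below the darkest 8-bit level) before
the logarithm, capping OD at $-\log_{10}(1/256) \approx 2.41$; the
forward/inverse pair is exact only away from this cap, which is why
round-trip tests pass a smaller `eps`.

The shipped absorbance vectors (hematoxylin, PAS, hematoxylin+PAS from the
standard colour-deconvolution literature; Methyl Blue as a blue-transmitting
dye, its blue absorbance the smallest component; Ponceau-fuchsin
red-transmitting) are defaults, not measurements: absorbance triples vary
with staining protocol and camera, and `stain_library(overrides = ...)` or
the `stain_overrides` config key replaces any of them.

## Stage order and display conventions

`run_pipeline()` executes: unmix the nuclear (hematoxylin+PAS vs PAS)
signal → Gaussian smoothing → tubule identification → tubule masking →
grayscale conversion → optional ROI-file exclusions → identification and
masking of small bright normal-interstitium/intratubular areas → Methyl Blue
vs Ponceau-fuchsin unmixing → inversion → threshold → area measurement.

Concentration maps are kept internally in OD units. For thresholding they
are rendered to `[0, 1]` in two equivalent ways: the tubule stage uses the
stain-bright rendering $1 - 10^{-c}$ directly (tubules are the *lighter*
objects to be identified on the unmixed image), while the collagen stage
renders the transmission image $10^{-c}$ (the slide as it would look with
only that stain) and then passes through an explicit inversion stage —
the same net transform, but preserving the inspectable
unmix → invert → threshold sequence of intermediates. Both renderings are
monotone in concentration, so thresholds act on stain amount either way.

Masked-out pixels are zeroed *and* tracked in a validity mask, because
zeroing alone would corrupt every downstream histogram: thresholds are
computed from the unmasked pixels only, and invalid pixels can never become
foreground. Two maskings compose exactly as masking with the AND of the
masks.

## Thresholding and object identification

`compute_threshold()` implements Otsu's method on a fixed 256-bin histogram
of the valid pixels, regardless of input bit depth: every bin edge is a
candidate split, the weighted intra-class variance is minimized, and ties
break toward the lowest threshold. The result is multiplied by the spec's
*correction factor* and clamped to `[lower_bound, upper_bound]`. The
correction factor is the primary per-lot tuning knob; the bounds act as
guard rails where a histogram can collapse to a single mode (a field with
no collagen at all would otherwise let Otsu split camera noise — the
default fibrosis lower bound of 0.20 pins that case to an empty
foreground). A constant valid region is degenerate by definition and yields
the constant itself, hence empty foreground under the strict `> t` rule.

`identify_primary_objects()` labels the thresholded foreground (8-connected
by default — diagonal continuity suits thin fibrotic septa and annular
rims), then filters by equivalent-circle diameter
$d = 2\sqrt{\text{area}/\pi}$. Two deliberate departures from common
cell-segmentation defaults: *no declumping* (touching tubules merge into one
object, which is equivalent for building an exclusion mask), and
*border-touching objects are kept* (a tubule half in frame must still be
excluded even though counting conventions would drop it). Interactive
freehand exclusion is replaced by declarative per-image YAML polygon files
(`read_roi_file()`, matched by stem name), rasterized by the even-odd rule
at pixel centers (origin top-left, 0-based, centers at integer + 0.5) —
batch automation is the tool's purpose, and a file is reproducible where a
drawing is not.

The reference mode (`reference_measure()`) implements the common
interactive cross-check: one RGB channel (green by default, where blue
collagen and red counterstain separate best) thresholded with a closed
min/max interval over the full frame. It exists to corroborate the pipeline
on clean fields, not as a second implementation of it.

## Default parameters

| Parameter | Default | Why |
|---|---|---|
| `eps` (OD floor) | 1/256 | one step below the darkest 8-bit level |
| `smooth_sigma` | 0.5 px | blur sensor noise without eroding 3–7 px tubule rims |
| tubule filter | d ∈ [10, 120] px, 8-conn | annular rims of 24–48 px tubules, eroded by smoothing |
| tubule threshold | Otsu ×1.0, clamp [0.85, 0.97] | rims are near-saturated in the nuclear channel |
| interstitium filter | d ∈ [2, 30] px | only *small* bright areas (intratubular space); never the bulk interstitium |
| interstitium threshold | Otsu ×1.0, clamp [0.60, 0.95] | bright normal areas sit well above the collagen signal |
| fibrosis threshold | Otsu ×1.0, clamp [0.20, 0.90] | lower bound pins the no-collagen case to 0% |
| `gray_weights` | (0.299, 0.587, 0.114) | Rec. 601 luminance |
| reference interval | green ∈ [0, 0.58] | between the collagen and counterstain green-transmission modes |

All were fixed once against synthetic previews and are expected to need
adjustment for real staining lots — chiefly the correction factors, as with
any automated trichrome morphometry.

## The synthetic generator

`generate_synthetic_kidney()` is the package's test bed: it places
non-overlapping elliptical tubules (hematoxylin rim annulus at OD 1.2, pale
lumen), grows random-walk collagen blobs in the extratubular space until the
fibrotic pixel count first reaches the requested fraction of the frame
(blob growth, unlike ellipses, hits an exact pixel target and mimics the
ramified shape of interstitial fibrosis), counterstains the remaining
interstitium (Ponceau-fuchsin OD 0.25), composites everything through the
same Beer–Lambert forward model on a white background, and adds clipped
Gaussian noise (sd 0.01) in transmission space — camera-like, after
compositing. One master seed drives per-image derived streams, so suites
are reproducible element-wise and bit-identical across runs.

The default frame is 256 × 192 px — the canonical 4:3 microscope frame at a
working resolution that keeps a 20-image suite under half a minute; the
pipeline itself is resolution-agnostic. The standard validation suite spans
fractions 5/15/30/45% with five seeds each; the pipeline recovers the true
fraction within well under 5 percentage points throughout (typically
+0.5–0.7, from partial-rim pixels at tubule borders), and on tubule-free
fields it agrees with the reference channel measurement essentially
exactly.

What the generator does *not* emulate — and what passing tests therefore do
not show about real slides: glomeruli and vessels, staining gradients and
batch variation, uneven illumination and vignetting, JPEG artifacts,
out-of-focus regions, overlapping stain chemistry (real hematoxylin and
Methyl Blue absorbances are far less separable than any synthetic margin),
and the physiological collagen of basement membranes, which the pipeline
cannot distinguish from pathological fibrosis on real tissue either.

## Numerical notes and degenerate inputs

* Otsu ties break to the lowest bin edge; histograms are always 256 bins.
* `apply_threshold` is strict (`> t`), so a threshold of 1 selects nothing.
* Division by zero in `image_math("divide", ...)` yields 0.
* An image with zero valid pixels is an error (`fq_empty_input_error`), and
  a batch image that errors is flagged `failed` in its CSV row, never
  dropped — batch throughput is the tool's purpose.
* Smoothing uses normalized (mask-aware) convolution with the kernel
  truncated at 4σ; constants are preserved everywhere, and mass is
  preserved wherever the kernel support stays inside the valid region.
* Component labels are assigned in raster-scan order of each object's first
  pixel, making label maps deterministic.

## Limitations

PNG, JPEG and TIFF are the supported inputs (BMP is not); whole-slide
pyramidal formats are out of scope, as are watershed declumping,
per-object intensity/texture features, and any distinction between
physiological and pathological collagen. The printed reference values of
the workflow this package automates were measured on study-specific
photomicrographs; validation here is against the synthetic ground truth
described above.
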