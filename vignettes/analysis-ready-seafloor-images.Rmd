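---
title: "From raw seafloor photographs to analysis-ready images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw seafloor photographs to analysis-ready images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Towed-camera platforms photograph the deep seafloor with artificial light
from a varying altitude. Three degradations make the resulting frames
incomparable as scientific sampling units:

1. **The light cone.** The strobe illuminates a central disk strongly and the
   periphery weakly, so image edges are dark regardless of what is on the
   seafloor.
2. **Water-column optics.** Seawater absorbs red light first, leaving a
   blue-green cast and compressed local contrast that both drift from frame
   to frame with altitude.
3. **Scale and footprint variation.** At higher altitude a pixel covers more
   seafloor, so neither lengths nor areas can be compared across images, and
   each frame covers a different physical area.

`benthicready` implements the standard correction chain used for
nodule-province survey imagery — light-cone correction, local contrast
enhancement, color normalization, and footprint standardization — plus the
measurement machinery needed to verify each step (per-channel RMS contrast,
median intensity, footprint variance) and a ground-truthed synthetic scene
generator so the whole chain is testable without any survey data.

## The pipeline

The stages run in a fixed order; scale estimation runs first because it must
see the unmodified red laser dots.

### Scale from laser points

Three lasers at a calibrated separation $d$ cm project red dots onto the
seafloor. Pixels with redness score $R - \max(G, B) \ge 80$ are grouped into
8-connected components; components of 4–500 px become candidate dots (the
bounds reject sensor speckle and large red objects), and the three largest
are kept. The scale of image $i$ is

$$ s_i = \frac{\overline{\lVert p_a - p_b \rVert}}{d} \quad \text{px/cm}, $$

the mean over all detected dot pairs of pixel distance over calibrated
distance. No triangle geometry is assumed, so the estimator works for two
dots or an irregular rig. The redness score rather than a plain red
threshold matters in practice: bright sediment is high in *all* channels and
scores near zero. When fewer than two dots are found the pipeline falls back
to the metadata table's `original_scale_cm_per_px` (reciprocal of px/cm) and
records the fallback in the manifest.

### Light-cone correction

The illumination pattern is a property of the rig geometry, not the scene,
so it is nearly constant over consecutive frames while the scene content
varies. Frames are sorted by acquisition time and split into batches of 50
(a trailing remainder smaller than `max(2, batch_size/5)` merges into the
previous batch). Within a batch, every pixel position and channel is
standardized across the batch:

$$ z_{k}(x, y, c) = \frac{I_k(x, y, c) - \mu(x, y, c)}{\sigma(x, y, c)}, $$

with $\mu$, $\sigma$ the per-position batch mean and *population* standard
deviation (the batch is the entire population of interest). The static cone
cancels in $\mu$; what remains is the scene's deviation from the local
illumination. Positions with $\sigma \le 10^{-6}$ (static pixels) map to 0.
For display and downstream stages, $z$ is clipped to $\pm 3$ and mapped
linearly onto 0–255 with half-up rounding, so $z = 0$ becomes mid-gray 128
and ~99.7% of a Gaussian signal stays inside the linear range. The $\pm 3$
clip and the half-up rule are this package's choices (the display mapping is
not otherwise determined); both are parameters.

Channels are standardized independently: the falloff is channel-dependent
because the artificial light and the water-column absorption are.

### Contrast enhancement

Contrast-limited adaptive histogram equalization (CLAHE, per channel in RGB,
8×8 tiles, clip limit 2.0 by default) equalizes intensities within tiles and
interpolates between them, spreading each region's histogram over the full
0–255 range. The clip limit prevents noise amplification in flat sediment
regions; both parameters are exposed on the CLI. Dimensions that are not
multiples of the tile grid are edge-replicated to the next multiple and
cropped back. Two properties of the underlying Zuiderveld algorithm are
worth knowing: a constant region maps to (nearly) itself rather than to
black or white, and repeated application is not idempotent — with a finite
clip limit each pass adds a bounded amount of contrast, so the package makes
no idempotence claim.

### Color normalization

One reference image is chosen — the one with the largest px/cm, i.e. taken
closest to the seafloor with the highest ground resolution (ties broken by
earliest acquisition) — and every image's channel histograms are matched to
it by the standard monotone CDF-inverse transport on exact 256-bin
histograms. Level $l$ maps to the lowest reference level whose CDF reaches
the input CDF at $l$; ties resolve to the lowest such intensity. The map is
monotone, so ranks within a channel are preserved.

A quantization fact governs what matching can achieve: a monotone intensity
map cannot split a histogram point mass. The residual sup-distance between
the matched and reference CDFs is therefore bounded by the largest
single-level mass of the input, and only for atom-free inputs (every level
≤ 1/256 of pixels) is the residual below 2/256 for any reference. The test
suite asserts exactly this pair of statements. In pipeline order the inputs
to matching are CLAHE outputs, whose histograms are nearly flat except for
saturated atoms at 0 and 255 produced by the ±3σ clip under dark nodules.

### Footprint standardization

All images are rescaled to the *median* of the per-image scales (bilinear,
anti-aliased when downscaling; output dimensions `round(dim × to/from)`),
which bounds the worst-case resampling factor and is robust to occasional
bad scale estimates. The common crop target is the elementwise per-axis
minimum of the rescaled dimensions — a minimum *area* alone does not
determine a rectangle, while per-axis minima guarantee the crop fits every
image and preserve a shared aspect ratio. Each image is then center-cropped
with floor offsets (top/left get the smaller margin when a margin is odd).
After this stage every image has identical pixel dimensions and identical
scale, so the across-image variance of the seafloor footprint is exactly
zero by construction; the footprint in m² is

$$ A = \frac{h}{s}\cdot\frac{w}{s}\cdot 10^{-4}. $$

For the published survey geometry — 2,240 × 3,360 px at 21.5 px/cm — this
gives 1.628 m², the "approximately 1.6 m²" standard footprint, and a 50%
per-axis center crop of the 30-megapixel 3:2 source frame (4,480 × 6,720)
yields exactly those dimensions. Where the survey documentation mentions
both a "median scale" and a "mean scale of 21.5 px/cm", this package follows
the median; for the tight altitude distributions of real deployments the two
nearly coincide, and the median is the better-behaved target.

## The synthetic scene generator

`generate_scene()` builds a scene as

```
clip( [textured sediment + dark elliptical nodules] × vignette × cast + noise, 0..255 )
```

then stamps three saturated red dots (R = 255, G = B = 0) in an equilateral
triangle centered mid-frame with side `laser_separation_cm × scale`. The
vignette is a multiplicative radial Gaussian falloff
$1 - \alpha\,(1 - e^{-(r/R)^2})$ with $R$ a fraction of the half-diagonal;
the scale model is pinhole proportionality, px/cm = base/altitude. All
randomness flows from one integer seed, and identical parameters give a
bit-identical raster.

Default conditions (chosen once, as a desk-scale emulation of a
nodule-field deployment):

| parameter | default | why |
|---|---|---|
| frame | 360 × 240 px | 3:2 like the survey camera, small enough for fast suites |
| base scale at 1 m | 30 px/cm | puts transect scales in the 10–30 px/cm working range |
| transect altitude | U(1, 3) m | a towed platform's realistic altitude band; spans a ≥2× scale ratio |
| laser separation | 5 cm | dots fit the frame at every altitude in the band |
| vignette | strength 0.6, radius 0.7 | visibly dark corners (~1/3 of center brightness at 0.8) |
| color cast | (0.55, 0.90, 1.00) | red attenuated most, the blue-green haze |
| brightness/cast jitter | ±25 / ±0.12 per image | the heterogeneous scene brightness colornorm must remove |
| nodules | 150 m⁻², radius 0.8–2.5 cm | dense dark coverage typical of nodule facies |
| noise | σ = 3 | visible sensor noise without drowning texture |
| capture | one frame / 10 s | the platform's 0.1 Hz still-image rate |

What the generator does *not* emulate: physically based light transport,
megafauna, motion blur, JPEG artifacts, and real nodule morphology. Passing
tests therefore demonstrate that the algorithms implement their contracts
(vignette removal, histogram transport, scale recovery, geometric
standardization) — not that the parameter defaults are optimal for any
particular real survey.

## Numerical choices and degenerate inputs

* Population (n-divisor) variance everywhere a variance crosses the API, so
  tests can be exact.
* Half-up rounding (`floor(x + 0.5)`) wherever intensities or dimensions are
  quantized; base R's round-half-to-even would make outputs depend on parity.
* z-score ε = 10⁻⁶ on the 0–255 scale: positions with batch σ below it
  output 0 instead of amplifying noise.
* Fewer than 2 images is an error for batching (a z-score is undefined);
  a single image is its own reference, median, and footprint.
* Even-count medians are the mean of the central pair, for scales,
  coverage coordinates, and intensity medians alike.
* Laser dot centroids are compared to sub-pixel ground truth; stamped disks
  recover centers to well under 1 px, and noise-free scale recovery is
  within 2% across the 10–50 px/cm range.
* Intermediates are always PNG. JPEG is allowed only for final export, and
  validation metrics are computed on in-memory buffers before encoding.

## Problem sizes

The test suite and the acceptance script use 100-image transects at
360 × 240 px (two light-cone batches of 50), 16 × 16 images for the
brute-force histogram-transport oracle, batches of ≤ 5 tiny rasters for the
direct z-score oracle, and a single full-size 4,480 × 6,720 frame for the
published crop geometry. These sizes exercise every code path, including
the batch remainder rule and both rescaling directions.

## Known limitations

* The light-cone model assumes the illumination pattern is static within a
  batch; a rig whose lights move relative to the camera violates this.
* CLAHE's clip limit trades contrast for noise; the 8×8/2.0 defaults are
  conventional, not calibrated to any particular camera.
* Histogram matching cannot split intensity atoms (see above); saturated
  regions stay saturated.
* The laser detector is a threshold-and-blob method. It assumes dots are
  the reddest compact objects in frame; red megafauna larger than
  `max_area` are rejected, but red objects in the dot-size range would be
  mistaken for dots.
* Footprint standardization requires every image's scale; images where both
  detection and metadata fail abort the run with the image named.
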