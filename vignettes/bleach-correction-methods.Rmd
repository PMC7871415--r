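---
title: "Photobleaching correction: models, assumptions and design choices"
author: "bleachr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Photobleaching correction: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bleachr)
```

## The problem

Excitation light irreversibly destroys a fraction of the fluorophores in
a sample at every exposure, so the intensity of a fluorescence time-lapse
decays even when the underlying biology is static. This photobleaching
degrades segmentation and biases any quantification of intensity
dynamics. When it cannot be suppressed at acquisition time, the sequence
can be restored computationally: estimate the per-time-point loss and
rescale (or redistribute) pixel values so the non-bleached condition is
recovered. `bleachr` implements three such corrections for single-channel
stacks of T time points, each a Z×Y×X volume (2D series have Z = 1),
always taking frame 0 as the reference.

## The three algorithms

**Simple ratio.** Assume the mean intensity would be constant without
bleaching, and that a constant background offset $I_b$ rides on the
signal. With per-time-point means $\bar I_i$ (pooled over all pixels of
the time point, in double precision), each pixel of frame $i$ becomes

$$I^c_i(x,y) = \frac{\bar I_0 - I_b}{\bar I_i - I_b}\,\bigl(I_i(x,y) - I_b\bigr).$$

The correction is defined only while $\bar I_i > I_b$. An algebraic
consequence worth knowing: in exact arithmetic the corrected frame mean
equals $\bar I_0 - I_b$ *whatever* value of $I_b$ is used — background
mis-estimation shows up in real (integer) images only through rounding
and clipping of negative intermediates, and through the historical
variant (`legacyNoSubtract = TRUE`) that multiplies raw pixels by the
ratio without subtracting $I_b$ from the pixel term. We implement the
subtracting equation as the default and keep the legacy variant for
comparability.

**Exponential fitting.** Model the mean series as a single-exponential
decay over a constant offset, $\bar I_i \approx a e^{-b i} + c$. The
offset estimate $c$ of a first fit is subtracted from every pixel, the
subtracted series is refitted giving $(a', b', c')$, and frame $i$ is
multiplied by the inverse bleach ratio $(a' + c') / (a' e^{-b' i} + c')$,
which is exactly 1 at $i = 0$. Frame-to-frame fluctuations about the
fitted decay pass through to the output rather than being flattened —
the method corrects the *trend*, not the frame. The index is the frame
number, not wall-clock time; non-uniform sampling is out of scope.

**Histogram matching.** Instead of rescaling by a summary statistic,
force every time point's pooled pixel-value histogram onto that of frame
0. With raw-count CDFs $\mathrm{CDF}_i(p) = \sum_{x \le p} H_i(x)$ over
the full dtype range (256 or 65536 bins, never rebinned), each source
value $p$ maps to

$$p' = \mathrm{CDF}_0^{-1}\bigl(\mathrm{CDF}_i(p)\bigr),$$

where the discrete inverse is taken as the *smallest* $q$ with
$\mathrm{CDF}_0(q) \ge \mathrm{CDF}_i(p)$. The map is monotone by
construction, outputs stay in the input dtype, no background estimate is
consumed, and applying the correction twice equals applying it once.
Equal pixel counts per time point are required (and enforced), so raw
counts are compared without normalization.

## Tunable parameters

* `background` (`correctSimpleRatio`): the offset $I_b$, in pixel units,
  spatially and temporally constant. Measure it from a non-fluorescent
  region with `measureBackgroundROI()` (the ROI is pooled over all
  frames and slices) or from a blank acquisition. Every frame's mean
  must exceed it.
* `legacyNoSubtract` (default `FALSE`): reproduce the historical
  multiply-raw behaviour instead of the subtracting equation.
* `zPerT` (`readStack`): pages per time point for plain multi-page
  TIFFs; ImageJ-hyperstack metadata takes precedence when present.
* `dtype` (`writeStack`): `"float"` writes 32-bit float TIFFs carrying
  the exact corrected values; `"preserve"` rounds half-to-even, clips to
  the source dtype range, and records per-frame clip counts in the
  report. Float is the default recommendation for quantification,
  preserve for viewers.

The exponential fit itself has no user-facing knobs: initialization is
deterministic (offset just below the series minimum, rate from a
log-linear slope with fallback $1/T$), and the profiled residual sum of
squares is minimized over the rate by a fixed 401-point grid plus Brent
refinement to tolerance $10^{-12}$, with amplitude and offset solved
exactly by linear least squares at each candidate rate (variable
projection). This recovers zero-residual input to machine precision,
where Gauss–Newton implementations abort. The rate is unconstrained: a
negative fitted rate converges but is flagged "not a decay", and a
(numerically) constant series is flagged degenerate, in which case the
second-pass correction factor is fixed at 1 (nothing to rescale).

## The synthetic generator

`bleachSimConfig()` describes a static scene of Gaussian blobs (uniform
seeded positions, separable profiles) replicated across T frames;
`applyBleach()` scales the *signal* by $e^{-b i}$ — never the background
offset, matching the additive-background model in which the offset is
fitted and subtracted, not rescaled — then adds the offset, additive
Gaussian noise (optionally Poisson), and rounds/clips into the dtype.
The standard fixture (`standardFixtureConfig()`) is T = 30, Z = 4,
64×64, 20 blobs, b = 0.08/frame, background 68, noise sd 1, seed 42.
Where the shape, decay, background, noise and seed were prescribed for
this fixture, the remaining values were chosen once for realism: 8-bit
depth with blob amplitude 120 and sigma 3 px, because a background of
68.3 ± 0.5 counts and the dynamic range of typical bleaching yeast
movies are consistent with an 8-bit acquisition with peaks near but
below saturation.

What the generator emulates: exponential signal decay over a constant
offset, static morphology, spatially uniform background, well-behaved
additive noise. What it does not: shape or localization changes
(receptor clustering, cell spreading), genuinely new fluorescence (GFP
synthesis), offset drift, detector nonlinearity, or model misfit such as
double-exponential bleaching. A green test on this fixture therefore
establishes correctness of the algorithms under their own assumptions,
not robustness to the biological scenarios that violate them.

## Numerical choices and degenerate inputs

* Means and all corrections are computed in double precision; corrected
  stacks are kept float until export.
* Negative intermediates (pixels below $I_b$, or below the fitted
  offset) are preserved in float mode — this is what makes the
  mean-conservation identity exact — and clamp to 0 only under the
  preserve policy.
* Half-to-even rounding avoids systematic bias on export.
* Ties in the discrete CDF inverse resolve to the smallest admissible
  reference value; equivalently, every source tie block lands on the
  value at its block-top rank. On histograms with very large tie blocks
  (low photon noise, few occupied bins) this convention biases matched
  frames slightly upward; see the limitations below.
* A simple-ratio background at or above any frame mean, a non-finite
  second-pass bleach ratio, unreadable/compressed/multi-channel TIFFs,
  and T < 2 all fail fast with the offending frame or pass named.

## Interpreting comparisons between the methods

Cross-method stability comparisons in the tests are made on
preserve-mode (integer) outputs of all three methods, mirroring how the
integer outputs of an image-processing plugin would be compared in
practice. In float mode the comparison is vacuous: the simple-ratio
corrected means are constant to machine precision by algebra.

Two idealized behaviours reported for real data do **not** reproduce in
this stated synthetic world, and the corresponding acceptance checks are
deliberately left failing rather than retuned:

* *Background-sensitivity drift.* On real sequences, under- and
  over-estimated backgrounds produce decreasing and increasing corrected
  trends. In the synthetic world the subtracting equation conserves the
  mean for any background (drift can only come from clamping, which
  yields a flat-to-slightly-positive trend for an underestimate), the
  legacy variant is algebraically increasing for every positive
  background, and a background of 72 exceeds the late-frame means of the
  standard fixture so the correction's own precondition fails there.
  The drift pattern seen on real data reflects properties absent from
  the simulator (offset bleaching, model misfit).
* *"Most stable" histogram matching.* With noise sd 1, the fixture's
  histograms are nearly degenerate (thousands of pixels per occupied
  bin) and the block-top tie convention drifts matched means upward by
  about 1 grey level per 10 frames, while the exponential model is exact
  (favouring the fit) and the true background is supplied exactly
  (favouring the ratio). The histogram-matching output was verified to
  equal an independent rank-matching oracle pixel for pixel, so this is
  the genuine behaviour of the specified algorithm under these
  conditions, not an implementation artifact.

## Known limitations

Single channel only; 8/16-bit unsigned input; no per-pixel fitting; no
double-exponential model; fixed reference frame 0 (no rolling
reference); histogram matching assumes a stable intensity distribution
and will force one onto data whose morphology genuinely changes.
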