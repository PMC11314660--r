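---
title: "Temporal-informed ultrasound thermometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal-informed ultrasound thermometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ustherm)
```

## The problem

During microwave hyperthermia, tissue in the treatment region is heated from
body temperature into the 41–45 °C range (mild hyperthermia) or the 46–65 °C
range (thermo-ablation). The therapeutic window is narrow, so the temperature
of the heated region must be monitored continuously, but the accurate sensors
(thermocouples, fiber probes) are invasive. B-mode ultrasound offers a
non-invasive alternative: temperature changes alter the speed of sound and the
scattering properties of tissue, which appear as drifts in image gray level
and texture. `ustherm` implements a complete estimation chain from B-mode
image sequences to per-second temperature estimates in the 25–65 °C regime.

The chain has four stages:

1. **Preprocessing** — fuse the 30 fps video down to the 1 Hz rate of the
   temperature trace by averaging non-overlapping frame blocks, suppress
   speckle with a small mean filter, and cut a 64×64 pixel region of interest
   around the temperature probe.
2. **Texture features** — per second, quantize the patch and its Sobel
   gradient-magnitude image and build the gray-level gradient co-occurrence
   matrix (GLGCM); extract the descriptor set whose members correlate most
   strongly with temperature.
3. **Period decomposition** — treat the multichannel feature series as a
   temporal signal, find its dominant periods by FFT, and reshape each
   1D window into a period × frequency 2D tensor.
4. **Regression** — a compact neural network whose blocks process the 2D
   tensors with a dual-branch attention module and emit one temperature per
   time step.

## Texture model

Let $f(i,j)$ be the filtered gray image and $g(i,j)$ its Sobel gradient
magnitude. Both are quantized by min–max scaling with floor-and-clip,

$$F(i,j) = \min\!\left(\left\lfloor \frac{f(i,j)-f_{\min}}{f_{\max}-f_{\min}}
N \right\rfloor,\, N-1\right), \qquad
G(i,j) = \min\!\left(\left\lfloor \frac{g(i,j)}{g_{\max}} M \right\rfloor,\,
M-1\right),$$

with $N = M = 16$ levels by default (configurable; 16 levels keep 64×64
patches from producing overly sparse matrices). A constant image maps to level
0. The GLGCM is the joint count
$h(x,y) = \#\{(i,j): F(i,j)=x,\ G(i,j)=y\}$, normalized to
$H = h / \sum h$. The default model channels are:

| channel | definition |
|---|---|
| average gray level | $\sum_x x \sum_y H(x,y)$ |
| gray-level entropy | $-\sum_x p_x \log p_x$, $p_x = \sum_y H(x,y)$ |
| gray-temperature gradient | $(T_{t+5}-T_t)/(\mathrm{AVGL}_{t+5}-\mathrm{AVGL}_t)$ |
| mixture entropy | $-\sum_{x,y} H \log H$ |
| inertia | $\sum_{x,y} (x-y)^2 H(x,y)$ |
| inverse difference moment | $\sum_{x,y} H(x,y) / (1+(x-y)^2)$ |

Entropies use the natural logarithm with $0 \log 0 := 0$. The remaining
standard second-order GLGCM descriptors are available behind
`all_features = TRUE` and are excluded from the default model input, since on
reference data their temperature correlations fall below the useful range.
`pearson_rank()` re-derives the ranking on any new dataset.

**The gray-temperature gradient and leakage.** This channel consumes the
*measured* temperature, which is the quantity being predicted. Feeding it to
the model at evaluation time leaks the target. The honest default
(`use_temp_grad = FALSE`) trains a 5-channel model without it; enabling it
reproduces protocols in which the probe trace is available at feature time,
and the flag is deliberately prominent.

## Period decomposition

For a length-$T$ multichannel window, each channel's DFT amplitude spectrum is
computed at frequency indices $1..\lfloor T/2 \rfloor$ (DC excluded so the
heating trend cannot consume the selection), normalized by its own maximum —
so a channel's physical scale does not privilege it — and averaged across
channels. The $k$ largest averaged amplitudes give frequencies
$f_1,\dots,f_k$ and periods $p_i = \lceil T/f_i \rceil$; ties break toward the
lower frequency. Each window is zero-padded to $p_i f_i$ and filled
column-major into a $p_i \times f_i$ tensor (consecutive samples run down a
column: rows index the position within a period, columns the period). The
inverse map truncates the padding exactly, and the round trip is the identity
for every admissible $(T, f)$.

The default is $k = 5$, the value at which test MSE is minimized on reference
data. Amplitude averaging runs over channels only.

## The network

Windows of 96 one-second samples (twice the longest default sub-period) are
embedded linearly to 16 channels plus a fixed sinusoidal positional encoding,
pass through 2 period blocks, and a linear head maps each time step to one
temperature. Each block:

1. selects the top-$k$ periods of its input (during batched training the
   spectra are averaged over the batch, the TimesNet convention; at inference
   selection is per forward call);
2. reshapes to the $k$ 2D tensors and applies a **dual-branch attention
   module** shared across periods:
   * *local branch* (half the channels): a depthwise 3×3 convolution over the
     period × frequency grid produces values and keys; a linear query is
     gated against the convolved key through a sigmoid, giving learned
     per-position attention weights that multiply the convolved values
     (attention-modulated convolution — high-frequency, local);
   * *global branch* (other half): multi-head scaled dot-product attention
     over all grid positions, with keys and values mean-pooled by a factor of
     4 along the token axis — the global branch targets low-frequency
     structure, so pooled keys/values lose little while cutting the quadratic
     attention cost;
   * branch outputs are concatenated and linearly fused;
3. inverts the reshape, aggregates the $k$ outputs with
   softmax-of-amplitude weights (recomputed per window), and adds the block
   input (residual).

The default configuration holds 1,505 trainable parameters — about 0.006 MB
in float32, two orders of magnitude under the 0.1 MB budget that makes the
model deployable on portable ultrasound hardware.

**Gradients.** Forward and backward passes are written directly (vectorized R
with two C++ kernels for the depthwise convolution and the batched
attention). All block gradients are exact against finite differences. The
FFT-derived aggregation weights are treated as constants during
backpropagation (detached); the discrete top-$k$ selection is not
differentiable anyway, and the detachment is the only approximation in the
gradient — visible as a small discrepancy in embedding-layer finite-difference
checks, and zero for parameters below every selection.

**Training.** Adam with initial learning rate 0.001 and weight decay $10^{-5}$
(applied to weights, not biases), MSE loss on z-scored targets, batches of 32
windows, up to 1000 epochs by default. Feature channels and targets are
z-scored with training-set statistics stored in the checkpoint. Since
synthetic data converges far sooner than the nominal epoch budget, early
stopping (patience 50 by default, on a held-out fifth of the training
experiments) is provided, and the scaled runs in the tests and the acceptance
script cap epochs at 150 with patience 15. Splits are at the experiment
level — windows within one heating run are strongly dependent, so pooled
time-step splits would leak.

## The synthetic-data generator

The reference experiments are not deposited, so the generator emulates the
study conditions: saturating heating curves 25→65 °C over 480 s
($T(t) = T_0 + (T_{\max}-T_0)(1-e^{-t/\tau})$, $\tau = 120$ s by default —
the single-exponential form matches the concave rise of measured curves and
keeps a closed form for tests), a 1 Hz thermocouple with 0.05 °C noise, and
30 fps B-mode imaging of a 64×64 patch. The echogenicity field couples
linearly to temperature (0.5 gray levels/°C, the order of magnitude implied
by reported °C-per-gray-level ratios near 2) and carries sinusoidal
sub-period modulations with default periods {6, 20, 48} s and amplitudes
{0.8, 1.0, 1.2} gray levels — the multi-component heating hypothesis: tissue
constituents with different dielectric constants heat at different rates,
nesting shorter temperature-elevation periods inside the long one. The
periods are well separated, all ≪ 480 s, and resolvable at 1 Hz.

Speckle is multiplicative unit-mean Rayleigh (the fully developed B-mode
approximation). A Rayleigh variable normalized to unit mean has a fixed
shape regardless of its scale parameter, so `speckle_scale` acts as a blend
weight in $[0,1]$ between the clean field and the fully speckled one rather
than as a raw scale.

Two modeling choices deserve emphasis:

* **Dynamic-range anchors.** Per-patch min–max quantization is invariant to
  any purely multiplicative image change, so a generator with only
  multiplicative speckle would erase the temperature signal from every
  GLGCM descriptor. Real B-mode scenes are anchored: specular interfaces
  saturate the display range and anechoic regions return no echo. The
  texture model therefore includes a static zero-sum mid-frequency pattern
  (so the GLGCM gradient bins are non-degenerate) plus a saturating bright
  band (gray level 255) and an anechoic inclusion (0 — nothing for speckle
  to multiply). With `pattern_amp = 0` all statics vanish and the patch
  mean equals the modeled field mean exactly.
* **What the generator does not emulate:** acoustic propagation, scan
  conversion, probe or tissue motion, protein-denaturation echogenicity
  changes above 60 °C, or spatially varying heating. Passing tests on this
  generator therefore demonstrates that the estimation chain recovers a
  known ground truth under the method's own assumptions — not that the
  printed accuracies on real tissue are reproduced.

## Numerical conventions and degenerate inputs

* Frame fusion averages `round(rate_in/rate_out)` frames and rounds half-up
  to 8 bits; a trailing partial block is dropped.
* The mean filter (default 3×3) uses replicate padding, avoiding dark-border
  bias in the average gray level; outputs stay floating point until
  quantization.
* The ROI convention is 0-based and half-open; an out-of-bounds ROI is an
  error, never clamped.
* A constant image quantizes to level 0; an all-zero gradient likewise. A
  constant series has no spectrum and `fft_period_select()` refuses it.
* The gray-temperature gradient carries its previous value (0 at the start)
  whenever the gray-level change falls below $10^{-9}$, and repeats its last
  value over the final `lag` samples so every channel shares the time axis.
* Zero-variance channels get Pearson $r = 0$ plus a warning flag rather
  than NaN.
* Training aborts with a diagnostic on a non-finite loss.

## Problem sizes in the tests and acceptance script

The packaged end-to-end checks synthesize 40 experiments at the full study
conditions (480 s, 30 fps, full speckle), split 7:3 by experiment (28/12),
and train with the scaled budget above; the ordering comparison against the
parameter-matched LSTM baseline uses a lighter budget (40 epochs, window
stride 48) applied identically to both models, since only the ranking is
asserted.
Smaller structural tests use a 4-channel toy configuration and a frame-free
feature simulator.

## Known limitations

* The gray-temperature-gradient channel is only meaningful when a measured
  trace exists; autoregressive feeding of prior predictions is not
  implemented.
* Period selection assumes integer-frequency structure is meaningful at the
  window length; periods that are incommensurate with the window leak across
  bins (handled, as in the reference architecture, by learned aggregation
  rather than by interpolation).
* The pseudocolor temperature map slides the ROI across the frame and
  predicts each tile independently; it inherits the single-point model's
  assumption that the tile contains the heated region's texture response.
* Uncompressed 8-bit AVI is the only video container read natively; other
  codecs should be exported to PNG frame directories first.
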