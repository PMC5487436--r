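---
title: "Training an event-driven classifier from spike-count histograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Training an event-driven classifier from spike-count histograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikehist)
```

## The problem

Spiking neural networks process address-event representation (AER) data:
each spike is a timestamped `(x, y, polarity)` tuple, produced either by
converting frame images to spike trains or recorded live from a dynamic
vision sensor (DVS). Networks trained in the frame domain and then mapped
to spikes tend to work well on synthetic Poisson inputs and degrade badly
on real DVS recordings, whose spike timing is nothing like Poisson.

`spikehist` implements an alternative: keep the spiking feature extractor
fixed, record how it actually responds to each training sample, and train
*only the classifier* on those recorded responses. Concretely, the
per-sample spike counts at the network's flatten stage are normalized into
analog "frames", a bias-free softmax classifier is trained on the frames by
mini-batch stochastic gradient descent, and the learned weights are
integer-scaled back onto spiking neurons. Because the frames are built from
the spiking network's own activity - including its leakage behavior - the
converted classifier sees at test time exactly the statistics it was
trained on, whatever the input encoding.

## The neuron model

All neurons are event-driven signed leaky integrate-and-fire units with
*linear* leakage and instantaneous (delta-dirac) synapses. Between events
the membrane \(V_m\) relaxes toward the resting level (0 throughout this
package) at a constant rate,

\[
\frac{dV_m}{dt} = -\frac{TH_+ - V_{rest}}{TL_+} \; (V_m > V_{rest}), \qquad
\frac{dV_m}{dt} = +\frac{V_{rest} - TH_-}{TL_-} \; (V_m < V_{rest}),
\]

clamped at rest: linear decay would otherwise oscillate through the resting
level, and the clamp matches the decay-to-rest behavior the model is meant
to have. On an input event the leak is applied first, then
\(V_m \mathrel{+}= s \cdot w\) where `s` is the presynaptic spike sign and
`w` the synaptic weight. Crossing \(TH_+\) (inclusive - chosen so that a
weight exactly equal to the threshold fires in one event) emits a `+1`
spike and resets; crossing \(TH_-\) resets and emits `-1` only if negative
output is enabled.

Two degenerate configurations matter:

* **convolution-layer neurons** use symmetric thresholds
  (\(TH_- = -TH_+\), equal leak constants) with negative *output* disabled:
  reaching \(TH_-\) resets silently. This bounds the membrane without
  injecting negative events downstream.
* **classifier neurons** are positive-only: \(TH_-\) is the numeric
  sentinel \(-2^{31}\), never reached in practice. When the sentinel is
  set, the below-rest leak slope uses the symmetric magnitude
  \((TH_+ - V_{rest})/TL_-\) - the sentinel's purpose is to disable
  negative spiking, not to define a leak slope of \(10^5\) units per
  microsecond.

Membranes and weights are integers held in R doubles; doubles are exact to
\(2^{53}\), far above the \(10^7\)-\(8 \times 10^8\) thresholds in use, so
this is integer arithmetic in effect. Timestamps are integer microseconds.
The event-driven update is validated against an independent 1 µs
clock-driven Euler integrator over \(10^4\) random event streams (agreement
within one membrane unit at every event).

## Network topology

The fixed topology is `source -> C1 -> S1 -> Flatten -> FC`:

* **C1**: 18 feature maps, one per Gabor kernel, valid convolution (no
  padding), so an \(n \times n\) input with \(k \times k\) kernels gives
  \((n-k+1)^2\) neurons per map. Each input event at \((x, y)\) updates the
  \(k^2\) neurons per map whose receptive field covers it, adding
  \(s \cdot K[y - y_o,\, x - x_o]\) (a correlation convention: the tap is
  addressed by the offset from the receptive field's top-left corner). In
  the no-leak, infinite-threshold limit the final membrane maps equal the
  dense cross-correlation of the signed event-count image with each kernel,
  exactly - the frame-equivalence property the tests verify.
* **S1**: subsampling pooling by address decimation,
  \((x, y) \to (\lfloor x/2 \rfloor, \lfloor y/2 \rfloor)\). This conserves
  events (a pure relabeling), which keeps the histogram counts
  interpretable; an `accumulate` mode (one output per `m` net inputs per
  block) is provided for comparison with summing pools.
* **Flatten**: the bijection \((fm, x, y) \to fm \cdot side^2 + y \cdot
  side + x\). For `n = 28, k = 7`: \(18 \times 11^2 = 2178\) indices.
* **FC**: one positive-only spiking neuron per class, fully connected to
  the flatten vector with the integer-scaled learned weights.

The Gabor bank follows the standard parameterization

\[
g(x,y) = \exp\!\left(-\frac{x'^2 + \gamma^2 y'^2}{2\sigma^2}\right)
\cos\!\left(\frac{2\pi x'}{\lambda} + \psi\right),
\quad x' = x\cos\theta + y\sin\theta,\; y' = -x\sin\theta + y\cos\theta,
\]

with 9 orientations (0° to 160° in 20° steps) x 2 phases (0 and 1.7 rad),
\(\sigma = 4\), \(\lambda = 8\), \(\gamma = 0.5\), on a 7x7 grid. Kernels
are quantized to integers (`round(tap * scale)`); the maximum per-tap error
is \(0.5/\text{scale}\).

```{r kernels, eval = FALSE}
autoplot(gabor_bank())
```

**Choosing the C1 threshold.** The ratio between the convolution threshold
and the kernel scale decides how much aligned evidence a feature-map neuron
needs before it fires. The defaults are `kernel_scale = 1e7` and
`c1_th_plus = 6e7`, i.e. a neuron fires after ~6 kernel-units: the positive
taps along one stripe of the default Gabor sum to ≈ 5.8, so one pass of a
well-aligned edge can fire a neuron while misaligned input cannot. Coarse
manual adjustment of this threshold on training-set pilots is part of the
method; it was not revisited afterwards.

## Input encodings

* **Intensity-to-latency**: one spike per nonzero pixel at
  \(t = \mathrm{round}((1 - I/255)\cdot T)\) over a \(T = 255\) µs window -
  brighter pixels spike earlier, maximum intensity at \(t = 0\).
  Zero-intensity pixels stay silent: the far end of the delay map is read
  as a limit, not as a command to fire every background pixel, which is
  what keeps this encoding's activity low (one spike per *active* pixel).
* **Poisson**: per-pixel rates proportional to intensity, shaped by a
  water-filling cap so no pixel *expects* more than 15 spikes, and exactly
  1,000 events in total, allocated by a single multinomial draw over the
  normalized capped rates with timestamps uniform in \([0, 255)\) µs.
  Drawing the budget in one multinomial is what guarantees the fixed total;
  independent Poisson draws cannot hit it exactly. On images with fewer
  than `total/cap` active pixels the capped rate shape saturates toward
  uniform and the full budget is still drawn.
* **DVS recordings** enter as they are; OFF-polarity events carry
  `sign = -1` into the signed network by default (a `rectify` option maps
  all polarities to `+1`; which of the two a given recording pipeline used
  is often undocumented, so both are supported).

## Training method

For each training sample the flatten spike record is tallied per index and
normalized by the window maximum, giving a frame \(x \in [0,1]^h\). The
classifier is bias-free softmax regression,

\[
Y_k(x, W) = \frac{e^{W_k x}}{\sum_j e^{W_j x}},
\qquad
C = -\frac{1}{|D|}\sum_{i \in D} \log Y_{L_i}(x_i, W),
\qquad
W \leftarrow W - \eta \nabla_W C,
\]

minimized by mini-batch SGD with a fixed learning rate (\(\eta = 0.1\)) and
a fixed epoch count. Weights start at zero: the problem is convex, and zero
initialization makes training deterministic given the shuffle seed.
Mini-batches are a fresh uniform shuffle each epoch. The analytic gradient
\(\nabla_W C = \frac{1}{|D|}\sum_i (Y(x_i) - \mathrm{onehot}(L_i))x_i^T\)
is checked against central finite differences in the test suite.

After training, `scale_weights()` maps \(W\) onto the spiking classifier:
\(W_{int} = \mathrm{round}(K \cdot W)\) with the classifier threshold set
equal to the scale, \(TH_{FC} = K = 10^7\). Since argmax is invariant to a
positive scale, the spiking layer implements the same decision rule up to
rounding (at most \(0.5/K\) per weight) and threshold discretization.

**Spiking readout.** The predicted class of a test window is the output
neuron with the most spikes; ties go to the earliest first spike; a window
with no output spikes is scored incorrect and tallied as "no decision".
(Count-based readout is the natural dual of the count-based training
frames; first-spike readout is the main alternative and is deliberately
not the default.)

## Presentation modes

* **SBS** (sample by sample): zero leakage, every sample starts from a
  fully reset network.
* **OP** (one pass): all samples form one continuous stream separated by
  `gap_us` of silence, and the configured leakage (e.g.
  \(TL = 1.2\times10^4\) µs) fades activity between samples. Histograms
  and readouts are windowed by the recorded sample boundaries. Training
  and testing must use the same leak setting, since leakage changes the
  histograms.

OP only works if the inter-sample time really lets membranes fade to rest.
The classifier neurons are the binding constraint: within a sample a
wrong class's membrane can integrate to the order of \(10^9\) (negative),
and at the default FC leak slope \(TH_{FC}/TL \approx 833\) units/µs that
takes several seconds to drain. The default `gap_us = 1e7` (10 s) absorbs
up to \(8\times10^9\) units and decouples consecutive samples; with a 1 s
gap residual charge measurably depressed the spiking accuracy on the
synthetic fixtures. With leakage disabled and explicit boundary resets, OP
is verified to reproduce SBS results sample for sample.

## The event-driven scheduler

The generic kernel (`netlist()`, `run_netlist()`) dispatches the globally
earliest *unprocessed* event (by its delivery timestamp; an event emitted
by a module with processing delay \(d\) at time \(t\) carries creation
time `pre_rqst = t` and is delivered at \(t + d\)). Ties between
simultaneous events are broken by node registration order, then FIFO - an
arbitrary but fixed total order, chosen because determinism is what makes
the simulation testable. A configurable event budget turns zero-delay
cyclic event generation into an error instead of a hang.

The ConvNet fast path (`run_convnet()`, in C++) processes input events in
time order and propagates each emission depth-first with zero module
delays. Registering nodes deepest-first makes the generic dispatcher drain
each cascade before the next simultaneous input, so the two paths produce
identical event streams - verified on random streams with leak on and off.

## Synthetic fixtures

The generators stand in for image and DVS benchmark data:

* `gen_bar_images()`: anti-aliased oriented bars (one class per
  orientation, matched to the Gabor bank angles) with positional and
  angular jitter and additive Gaussian noise clamped at a black level of
  10 gray levels - so the background stays mostly silent under latency
  encoding, as dark backgrounds do in digit images.
* `gen_dvs_stream()`: a bar sweeping along its normal (bouncing at the
  borders) watched by an idealized event camera: each pixel integrates its
  intensity change and emits one ON/OFF event per 40 gray levels, with
  uniform timestamp jitter within the 500 µs integration step, plus
  uniform background noise events. Event counts scale with swept path
  length; a symmetric bar yields balanced ON/OFF counts.

These fixtures reproduce the *structure* of the real data (oriented
features, signed edge events, timing-dependent activity) but not its
difficulty: classes are linearly separable by design, intra-class
variability is low, and real sensor artifacts (refractory effects,
hot pixels, correlated noise, scene clutter) are absent. Passing the
end-to-end tests therefore demonstrates that the pipeline is *correct* and
that conversion from frames to spikes loses almost nothing on data the
classifier can handle - it does not predict absolute accuracy on real
benchmarks.

## Numerical and design choices

* Coordinates are 0-based, `x` = column, `y` = row, origin top-left; time
  windows are half-open `[t_start, t_end)` (the final window of a record
  is closed at the top so end-of-stream spikes are kept).
* Stable sorting everywhere: equal timestamps keep input order.
* An all-empty spike record produces the zero frame; prediction on it
  falls to the tie rule (lowest class index) in the frame domain and to
  "no decision" in the spike domain.
* `(n - k + 1)` not divisible by the pooling factor is a configuration
  error - rejected at construction rather than silently cropped.
* Histograms are built once and cached; they are static given a fixed C1.
* The Wilson score interval backs the accuracy confidence intervals
  (well-behaved at the boundaries and for small DVS test sets); it is one
  function and can be swapped.

## Problem sizes

The shipped tests run the full method at reduced but representative sizes:
4 classes x 125 samples (400 train / 100 test) per experiment, 28x28
inputs, the full 18-kernel bank, 200 training epochs, five seeds, for four
input regimes (latency, Poisson, DVS-like SBS and OP). Unit tests use
smaller geometries where an independent oracle (dense convolution, clock
integration, scalar accumulation, manual cross-validation folds) is
feasible. `scripts/acceptance.R` re-runs the four experiments at the same
sizes for a single seed.

## Limitations

* One convolution layer with fixed, hand-programmed kernels; no kernel
  learning, no max pooling, no multi-layer backpropagation.
* The classifier has no biases, regularization, momentum or learning-rate
  schedule - fixed \(\eta\), fixed epochs, by design.
* Module processing delays default to zero; latency figures arise from
  neuron dynamics and input timing only. Hardware handshake timing and
  parameter variation are out of scope.
* The OP gap default assumes the package's leak constants; radically
  different \(TL\) values need a correspondingly scaled gap.
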