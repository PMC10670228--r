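---
title: "Methods: simulation, reconstruction and attention-ResNet grading of lung SD-OCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, reconstruction and attention-ResNet grading of lung SD-OCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octgrade)
```

## The problem

Intraoperative grading of early lung adenocarcinoma — distinguishing
invasive adenocarcinoma (IA), minimally invasive adenocarcinoma (MIA) and
normal parenchyma (NOR) on fresh specimens — decides how much lung is
resected. Spectral-domain optical coherence tomography (SD-OCT) images the
top 1–2 mm of tissue at micrometre depth resolution within seconds, and a
convolutional classifier over B-scans can grade those images on site. This
package implements that pipeline end to end and, because clinical OCT
volumes of graded lung tumours are not publicly available, pairs it with a
synthetic phantom generator so every stage is testable.

## The spectral forward model and its inverse

An A-line interferogram follows the standard SD-OCT model: with source
power envelope $S(k)$ at wavenumber $k = 2\pi/\lambda$, reference
reflectivity $R_{\mathrm{ref}}$ and scatterers of effective reflectivity
$R_n$ at depth $z_n$,

$$I(k) = S(k)\Big[R_{\mathrm{ref}} + \sum_n R_n
      + \sum_n 2\sqrt{R_{\mathrm{ref}}R_n}\cos(2kz_n + \phi_n)\Big] + \epsilon(k).$$

Scatterer–scatterer autocorrelation terms are neglected (they are
$O(R_n R_m)$ with $R_n \ll R_{\mathrm{ref}}$). The spectrometer samples
uniformly in *wavelength* (2048 pixels for the reference system; a grid
spanning 3.2 source FWHMs by default), which is exactly why reconstruction
needs k-linearization. Speckle is modelled as a multiplicative
complex-Gaussian field over the scatterers — exponentially distributed
intensities and uniform phases — frozen into the phantom, so noise-free
simulation is fully deterministic; detector noise is additive Gaussian.

Reconstruction inverts this in the usual order: cubic resampling onto a
uniform-$k$ grid (cubic is the standard accuracy/cost trade-off; the target
grid keeps the source grid's length and orientation so an already-linear
grid maps to the identity), subtraction of the background spectrum (the
mean line of the frame by default), apodization (Hann by default,
selectable; `"none"` keeps the Gaussian source envelope as the natural
window and is the right choice for point-spread-function measurements),
FFT, one-sided magnitude, and log compression referenced to the frame
maximum with a −60 dB floor to avoid `log(0)`. With $N$ samples and
uniform spacing $\delta k$, depth pixel $m$ sits at $z_m = m\pi/(N\delta k)$
(in air; no refractive-index correction is applied and all depths are
quoted in air). The image is cropped to the 1.4 mm depth of interest
before preprocessing.

Two closed forms are exposed alongside: scan timing
(B-scan duration = lines / A-line rate; volume duration = one slow-axis
period; at 20 kHz, 2000 lines and 0.025 Hz this gives 0.1 s per B-scan and
400 B-scans per 40 s volume) and sensitivity from an attenuated mirror
measurement (SNR plus ND attenuation, both in dB). The axial resolution of
a Gaussian source is $\delta z = C\,\lambda_c^2/\Delta\lambda$. The exact
Gaussian coherence prefactor is $2\ln 2/\pi \approx 0.4413$, but the OCT
literature conventionally quotes the rounded $C = 0.44$; `axial_resolution()`
defaults to the rounded convention (which reproduces the 6.06 µm quoted for
an 840 nm / 51.2 nm source) and accepts the exact constant through the
`prefactor` argument. The difference is 0.3%, well inside the 10% tolerance
used for the simulated-PSF cross-check.

## The tissue phantoms

Only qualitative texture descriptions are available for the three grades,
so the parameterization is this package's own design:

* **IA** — *interrupted attenuation with discontinuous reflection*: the
  lateral axis is cut into 3–5 segments at random boundaries; attenuation
  alternates between ≈0.9 and ≈3.2 mm⁻¹ and reflectivity between ≈0.65
  and ≈0.22 across boundaries.
* **MIA** — *formless homogeneity*: a single attenuation level with only a
  5% smooth lateral modulation, no jumps, no spots.
* **NOR** — *dense superficial spots*: ≈30 bright Gaussian blobs
  (radius ≈20 µm) confined above 25% of the imaging depth over an
  otherwise homogeneous background.

Amplitudes were fixed once so that the between-class differences exceed
the speckle-induced spread by well over 3× in two summary features
(superficial-spot density and the largest lateral jump in mean column
intensity, `phantom_features()`); a linear classifier on those two features
alone separates rendered phantoms almost perfectly, which is the designed
guarantee that the dataset is learnable before any deep model enters.
Every generator is a pure function of its seed. Per-patient texture
jitter (±10% on attenuation/reflectivity scales, ±20–30% on surface depth
and spot counts) makes patient-level splits meaningful.

Two rendering routes exist deliberately: the spectral route
(`simulate_interferogram()` → `reconstruct_bscan()`) is used for
physics-level validation, while `render_bscan()` evaluates the same
attenuation/reflectivity field directly on the pixel grid with fully
developed speckle — the inexpensive route used to build classifier-scale
datasets. What the phantoms do **not** model: multiple scattering,
polarization, dispersion mismatch, refraction at the surface, and the
full within-class histological variability of real tissue; a classifier
score on phantoms therefore certifies the pipeline, not clinical
performance.

## Preprocessing

Despeckling averages **seven adjacent B-scans after translational
registration** (integer-pixel cross-correlation, bounded at ±10% of the
image size; sub-pixel refinement is unnecessary because the seven-frame
average tolerates ±1 px). Volumes hold 400 frames, and reported
per-volume frame counts in the reference workflow exceed 400/7, implying
overlapping windows: the despeckle stride is therefore configurable with
stride 1 as the default reading. Frames are then resized bilinearly to
**128 (depth) × 218 (width)** and min–max rescaled to [0, 1] (a constant
image maps to zeros; resampling is skipped when the shape already
matches, making normalization exactly idempotent). Training-time
augmentation draws random width/height shifts, shear and zoom (shear and
zoom ratios fixed at the conservative 0.1; the shift fraction, not
specified anywhere, defaults to 0.1 as well) plus horizontal flips, as a
single bilinear affine resampling about the image centre.

## The classifier

The grader is an attention-gated residual network with **14 weight-bearing
layers and 6 residual blocks**. The counting convention — one input
convolution, two 3×3 convolutions per block, one final dense layer; 1×1
shortcut projections and attention gates counted as plumbing — is an
explicit design choice, as is the 16→32→64 filter progression over the
three stages. Attention gates sit at the 32- and 64-filter stages: the
gate computes a same-shape mask $M = \sigma(\mathrm{conv}_{1\times1}(F))$
and re-enters the main path as $F + \alpha\,(F \odot M)$ with a learnable
scalar $\alpha$ per gate, initialized at 0 so the un-gated network is the
starting point and attention can fade out if it never helps; with
$\alpha = 0$ the network is bitwise-equivalent to its attention-free twin,
which the tests assert. Activations are leaky ReLU (slope 0.01); the loss
is categorical cross-entropy plus an L2 penalty (weight 0.05) on all
convolution/dense kernels; optimization is minibatch SGD (batch 16,
learning rate 10⁻⁴, momentum 0.9) with early stopping after 15 epochs
without validation-loss improvement, returning the best-epoch weights.
Class probabilities are a softmax over (IA, MIA, NOR) and the prediction
is the argmax, ties broken in that fixed order.

Two implementation notes. First, model images arrive in [0, 1]; the
forward pass applies a fixed affine standardization $(x - 0.5)\times 4$ so
He-initialized layers see approximately zero-mean, unit-variance input —
without it the gradient scale at learning rate 10⁻⁴ makes convergence
needlessly slow. Second, no batch normalization is used: the layer count
convention above does not include normalization layers, and omitting them
keeps training exactly deterministic for a fixed seed under
single-threaded BLAS. The engine itself (im2col convolutions, max
pooling, the training loop) is part of the package, with gradients
verified against finite-difference oracles in the test suite.

## Explainability

Grad-CAM is taken at the last convolutional stage (the post-attention
feature maps): per-channel weights are the spatial mean of
$\partial(\text{class logit})/\partial F$, the map is the rectified
weighted sum, bilinearly upsampled to 128 × 218 and min–max normalized per
image — layer choice, upsampling and normalization are all conventions the
source material leaves open. t-SNE embeds the global-average-pooled
penultimate features (the layer feeding the dense head, the default
reading of an unspecified choice) of training and test images jointly in
one run — no out-of-sample projection — with perplexity 35, Gaussian input
affinities calibrated by per-point bisection, Student-t output
similarities and early exaggeration. The final 10% of iterations switch
to backtracking plain descent, which guarantees the recorded KL
divergence is non-increasing over that window; the implementation is
exact ($O(n^2)$), appropriate for the hundreds-to-thousands of points an
inspection session holds.

## Evaluation and the inspection session

Per-class sensitivity and specificity use the one-vs-rest decomposition of
the 3×3 confusion matrix; overall accuracy is the trace over the total;
undefined metrics (absent classes) surface as `NA` with a warning, never
as silent zeros. AUC uses the rank/concordance formula with midpoint tie
handling and is required (by test) to match trapezoidal integration of the
threshold-swept ROC curve. All evaluation helpers refuse splits that mix
one patient across train and test, and accuracy is reported both per
frame and per volume (majority vote), since either convention is
defensible. The inspection layer (`build_session()`, `lookup_point()`,
`export_session()`) joins every embedded point to its image, grad-CAM,
probability triple and placeholder patient metadata in a versioned,
diffable JSON bundle; the interface is headless and read-only, with the
interactive viewer a thin plotting shim on top.

## Problem sizes and numerical choices

The test suite runs the full-physics checks at 512 spectrometer pixels
(the PSF physics is resolution-independent; the acceptance checks use the
full 2048) and trains the end-to-end grader on 330 synthetic images per
class from 11 synthetic patients per class, split 3:1 by patient, for up
to 8 epochs — sizes chosen so a laptop-class single core completes the
whole suite comfortably while the statistics remain stable. FWHM
measurements interpolate half-maximum crossings on an 8× zero-padded
transform. Degenerate inputs fail loudly: reversed wavelength grids,
depths beyond the unambiguous range, single-pixel images, wrong despeckle
window sizes, perplexities too large for the point count, dangling ids in
session bundles.

## Known limitations

The phantom textures are stylized; no claim is made that classifier
accuracy on them transfers to patient data. One concrete divergence is
worth knowing: because preprocessing min–max normalizes every image, the
bright superficial spots that define the synthetic NOR class also set its
global intensity scale — NOR frames come out globally darker — and the
trained network exploits that, so its NOR saliency sits in the deep,
uniformly dark part of the image rather than on the spots (the clinical
observation it stylizes has saliency superficial). `grad_cam(..., stage =)`
exposes earlier, finer-grained stages for such inspections; the phantom
design itself is deliberately left as specified rather than re-tuned to
steer the saliency. Reconstruction omits
dispersion compensation and complex-conjugate suppression. The conv-net
engine is CPU-bound and single-threaded by design (determinism over
speed) and is not intended for datasets beyond the desk scale used here.
The theoretical shot-noise sensitivity of the reference instrument is not
computed because its inputs (exposure, responsivity, reference power) are
not part of the published system description.
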