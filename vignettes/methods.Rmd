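---
title: "Fall detection from global motion parameters: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fall detection from global motion parameters: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gloriafall)
```

## The model

A video frame is a multi-channel intensity field $L_c(x, y, t)$. If all
temporal change comes from scene deformation with velocity field
$v(x, y, t)$, brightness constancy gives

$$\frac{dL_c}{dt} = -\nabla L_c \cdot v.$$

Instead of reconstructing $v$ pixel by pixel (the classical optical-flow
problem, underdetermined along iso-intensity directions), the GLORIA approach
restricts $v$ to the global linear non-homogeneous group on the image plane,

$$v \equiv \sum_u A_u v^u,$$

with six generator fields: translations $(1,0)$, $(0,1)$; dilation $(x, y)$;
rotation $(y, -x)$; shear1 $(0, x)$; shear2 $(y, 0)$. Each generator defines a
differential operator $G_u = v^u_x \partial_x + v^u_y \partial_y$.
Substituting and minimizing the squared residual of the linearized constraint
over all interior pixels and channels yields a 6-dimensional normal system

$$S_{uv} = \sum_{\text{pix},c} (G_u L_c)(G_v L_c), \qquad
  H_u = -\sum_{\text{pix},c} \frac{dL_c}{dt}\, (G_u L_c), \qquad
  S A = H.$$

$S$ is the structural tensor generalized to the generator basis (a Gram
matrix, hence symmetric PSD); $H$ is the driving vector. One 6-vector $A$ is
produced per consecutive frame pair; 150 consecutive vectors form a
$6 \times 150$ motion window, the input of the fall classifier.

## The rank deficiency of the generator set, and the gauge we report

The six fields above are **linearly dependent**: as $2\times 2$ flow matrices,
rotation $= \begin{pmatrix}0&1\\-1&0\end{pmatrix}$ is exactly
shear2 $-$ shear1. The basis spans a 5-dimensional space, $S$ has a structural
null direction $(\text{rot}, \text{sh1}, \text{sh2}) = (1, 1, -1)$, and its
condition number is infinite for every input. Two consequences:

* A pure rotation of amplitude $A$ produces a flow *identical* to the flow of
  $(\text{sh1}, \text{sh2}) = (-A, +A)$. No estimator, of any kind, can tell
  these apart; only the 5-dimensional projection of the parameter vector is
  physically meaningful.
* `solve_motion()` therefore returns the **minimum-norm least-squares
  solution**, computed by symmetric eigendecomposition with eigenvalues below
  `reg_epsilon * trace(S) / 6` truncated. This equals the Moore–Penrose
  pseudo-inverse route (the test suite verifies agreement to `1e-8` against an
  independent SVD oracle) and is a deterministic, linear gauge fixing: a pure
  rotation is reported as $2/3$ rotation $\pm 1/3$ on each shear. Translations
  and dilation are unaffected and are recovered to within a few percent.

Ridge regularization of a full-rank but ill-conditioned system (the original
plan) is unworkable here — with the published basis the "ill-conditioned
branch" is taken always, and a ridge solution never agrees with a
pseudo-inverse oracle at tight tolerance.

For applications that need individually identifiable parameters,
`gloria_config(shear_pair = "symmetric")` replaces the shear pair by the
vorticity/strain completion $y\partial_x + x\partial_y$ and
$x\partial_x - y\partial_y$, which makes the six generators independent. The
default remains the published fields, and classification is insensitive to
the choice: the gauge fixing is a fixed linear map, and the classifier learns
on whatever consistent 6-channel representation it is given.

## Numerical choices

* **Coordinates.** Generator origin at the frame center, coordinates
  normalized by $\max(H, W)/2$. Centering makes dilation/rotation orthogonal
  to the translations over the symmetric pixel grid, improving the
  conditioning of the 5 informative dimensions. Translations are in
  pixels/frame; the other rates are per frame in normalized coordinates, so
  amplitude $A$ produces at most $\approx A$ pixels of displacement at the
  frame edge.
* **Gradients.** Both frames are Gaussian pre-smoothed (`smooth_sigma`,
  default 1 px); spatial gradients use the five-point fourth-order central
  difference of the two-frame average; the temporal derivative is the forward
  difference. The five-point stencil matters: with the three-point stencil
  the amplitude response of the solve has slope 1.08–1.12 instead of
  1.04–1.05, violating the package's own linearity requirement
  (slope $1 \pm 0.1$). A 2-pixel border is excluded from all sums.
* **Degeneracy.** `trace(S) ~ 0` (blank scene) returns zeros with
  `degenerate = TRUE` rather than an error: a structureless frame pair simply
  carries no motion evidence.
* **Warping (synthetic data).** Catmull-Rom cubic interpolation, reflect
  boundary. Bilinear interpolation was tried first and rejected: its
  first-order smoothing error leaves forward–backward warp round-trip errors
  of $\approx 2\times 10^{-2}$ on the default texture, above the $10^{-2}$
  tolerance the recovery harness requires; cubic meets it with margin and is
  exact on integer shifts and linear ramps.

## The synthetic world

No external video corpus is required anywhere in the build or tests. Two
seeded generators define the testable world:

* **Scenes** (`scene_spec()`/`render_sequence()`): Gaussian-blurred white
  noise (default sigma 2 px, giving a blurred-noise standard deviation of
  about 0.14 around mid-gray — smooth but gradient-rich, hence a well-behaved
  structural tensor), warped cumulatively by a known per-step parameter
  schedule. Sensor noise is added i.i.d. to each *emitted* frame, not into
  the warp chain, so the schedule remains the exact ground truth of the
  underlying motion.
* **Motion windows** (`motion_dataset_spec()`/`simulate_motion_dataset()`):
  background activity is temporally smooth noise (sd 0.02 per-frame units,
  correlation length 5 frames) on all six channels; a fall is one abrupt
  Hann-shaped transient of duration 8 frames and amplitude 10x the background
  sd hitting **all six channels simultaneously** with random per-channel
  signs — operationalizing the qualitative claim that a fall is a fast,
  abrupt whole-body event that registers on every element of the flow vector.
  Positive counts are exact (`round(n * fall_fraction)`); transients never
  straddle window boundaries, so the labeling rule has no ambiguous cases by
  construction (boundary-straddling labeling is the window module's
  configurable overlap rule, default 8 frames).

What a green test on this world establishes: the estimator recovers the
motions it models, the windowing bookkeeping is exact, and the classifiers
separate transient-vs-background time series essentially perfectly. What it
does **not** establish: performance on real falls — real scenes have
articulated bodies, backgrounds, lighting changes and camera noise that the
texture model does not emulate, and published benchmark accuracy on the
public fall corpora is out of this package's test scope.

## The classifiers

Input is a $6 \times 150$ window, standardized per channel with
*training-set* statistics (stored inside the trained model to prevent
train/serve skew).

The CNN treats the window as a 6-row image and convolves along time only
(kernels $1 \times k$), preserving the parameter-channel structure: block 1
(16 filters, kernel 7, max-pool 2), block 2 (32 filters, kernel 5, pool 2),
optional block 3 (64 filters, kernel 3, no pool), each with batch norm and
ReLU; then flatten, dense 64 + ReLU, dropout 0.5, dense 2, softmax. Training
follows the published regime exactly: Adam, learning rate 0.001, batch 32, up
to 16 epochs, L2 0.001, cross-entropy, stratified validation monitoring.
Kernel/filter/pool sizes and the dropout rate are not published; the defaults
above are ours.

The hybrid variant **adds** a bidirectional LSTM (64 units per direction)
that consumes the time axis of the final feature maps; its last hidden states
are concatenated with the flattened conv features before the dense head. The
additive reading (rather than replacing the flatten) follows the source's
framing of the LSTM as an *addition* to the existing network, and it
guarantees the hybrid has strictly more trainable parameters than the CNN at
equal convolutional configuration.

Everything — initialization, shuffling, dropout — runs off one seed; two runs
with the same seed produce identical parameters. The engine is written in
base R (im2col convolutions, BPTT for the LSTM) and is verified by
finite-difference gradient checks in the test suite; one caveat surfaced
there is worth recording: a convolution bias feeding batch norm has exactly
zero gradient, so those parameters are frozen by symmetry, which is standard
and harmless.

## Evaluation

Confusion counts with `fall` as the positive class; accuracy, sensitivity,
specificity, precision and F1 exactly as the printed formulas; undefined
ratios are reported as `NaN` with a warning, never silently zero. ROC sweeps
thresholds over every distinct score plus a $+\infty$ sentinel; AUC is
trapezoidal and is verified against brute-force Mann–Whitney pair counting.
Metrics are reported both as proportions and as percentages formatted to one
decimal.

## Pipeline conventions and limitations

* Video input is a PNG frame directory ([0,1] intensities, lexicographic
  order); AVI/MP4 decoding is not available in the target environment and is
  rejected with a clear error. Frame rate is a configuration value (the
  public fall corpora use 18/25/30 FPS), used only to attach timestamps to
  detection events.
* A detection event is a window whose fall probability reaches the threshold
  (default 0.5); with the default non-overlapping stride of 150 the detector
  answers once per 150-frame chunk, so responsiveness is limited to window
  granularity — smaller strides are supported but correlate adjacent
  decisions.
* The labeling rule for real annotations (a window is a fall iff it overlaps
  an annotated interval by at least 8 frames) is this package's convention;
  the source material does not state one.
* Window length 150 means 150 motion *vectors* from 151 frames; this
  preserves the stated $6 \times 150$ input shape exactly.
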