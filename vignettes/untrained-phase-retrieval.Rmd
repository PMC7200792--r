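---
title: "Untrained-network phase retrieval from a single diffraction pattern"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Untrained-network phase retrieval from a single diffraction pattern}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holophase)
```

## The problem

A thin transparent object — a cell, a tissue slice, an etched substrate —
delays the optical wavefront without absorbing it. Under coherent
plane-wave illumination the field immediately behind it is

$$U_0(x, y) = \exp[i\,\phi(x, y)],$$

unit modulus everywhere: all the information sits in the phase
$\phi$, which a camera cannot see directly. After free-space propagation
over a distance $d$ the field acquires intensity structure, and a lensless
in-line geometry records the diffraction pattern

$$I(x, y; d) = |U_d(x, y)|^2 = H(\phi),$$

where $H$ is the full forward map. Recovering $\phi$ from a single $I$ is a
classic ill-posed inverse problem: the measurement is blind to the global
phase offset (piston), and intensity alone under-determines the field.

`holophase` solves it with an *untrained* convolutional network. A randomly
initialized encoder–decoder $R_\theta$ takes the measured pattern as its
fixed input; its output is pushed through a differentiable implementation
of $H$, and $\theta$ is optimized so that the predicted pattern matches
the measured one:

$$\theta^\ast = \arg\min_\theta \| H(R_\theta(I)) - I \|^2,
\qquad \tilde\phi = R_{\theta^\ast}(I).$$

No training set and no ground-truth phases are involved anywhere: the
convolutional architecture itself supplies the image prior (the
deep-image-prior principle), and the physics supplies the data constraint.

## The forward model

Free-space propagation uses the exact angular-spectrum transfer function

$$G(f_x, f_y) = \exp\!\left[i k d \sqrt{1 - \lambda^2 f_x^2 - \lambda^2 f_y^2}\right],
\qquad k = 2\pi/\lambda,$$

applied in the DFT domain: $U_d = \mathrm{IDFT}[\mathrm{DFT}(U_0)\, G]$.
Conventions are fixed and tested: unshifted frequency layout (DC at array
index 1), forward transform with negative exponent, pixel-centered samples,
SI units internally. Where the radicand is negative (evanescent waves,
which decay over sub-wavelength distances) $G$ is set to zero, so
$|G| \in \{0, 1\}$ and propagation is unitary on the propagating band —
energy conservation, round-trip inversion and the semigroup property hold
to $10^{-10}$ relative error and are asserted against a brute-force DFT
summation oracle in the test suite.

The default `pad_factor = 1` keeps the implicit periodic boundary model
(the natural discrete counterpart of the continuous transform, and what
makes propagation exactly unitary); `pad_factor = 2` zero-pads before the
transform to suppress wraparound when simulating large distances for
non-periodic scenes.

The optimization needs $\partial \mathrm{loss}/\partial \phi$. Because
propagation is linear and diagonal in the Fourier domain, the adjoint of
the forward pipeline is the same pipeline with $\bar G$, i.e. propagation
over $-d$; the chain through $I = |U_d|^2$ and $U_0 = e^{i\phi}$ gives

$$\frac{\partial L}{\partial \phi}
  = 2\,\mathrm{Im}\!\left[\,\overline{U_0} \cdot
    P^{-d}\!\left(\frac{\partial L}{\partial I} \cdot U_d\right)\right],$$

implemented in `forward_intensity_grad()` and verified against finite
differences.

## The network and its optimization

The mapping $R_\theta$ is an encoder–decoder built from the four standard
block types: 3×3 convolution + batch normalization + leaky ReLU, 2×2 max
pooling on the way down, an up-convolution block (nearest-neighbor ×2
upsampling followed by the same 3×3 convolution block — a de-convolution
realization that avoids checkerboard artifacts) on the way up, and
channel-concatenation skip connections between matching scales. The output
layer is a 3×3 convolution followed by a bounded activation that makes
$\tilde\phi \ge 0$, anchoring the piston ambiguity at zero. Two choices
exist: the default scaled sigmoid ($2\pi\,\sigma(z)$, range $[0, 2\pi]$ —
the full unambiguous phase range — with nonzero gradients everywhere) and
a hard ReLU. The ReLU variant is faithful to the simplest formulation but
fragile in this single-image setting: pixels caught at the zero clamp
receive no gradient, and on our synthetic scenes the optimization then
reliably collapses to the flat zero-phase attractor (the loss plateaus
while the output goes constant). The sigmoid imposes the same
nonnegativity without dead gradients and is therefore the default. Every
forward/backward pass is hand-written (the 3×3 convolution hot path in
C++ via im2col + BLAS) and finite-difference-checked; normalization
layers run with the statistics of the current image in every pass,
including the final one (with a single fixed input there is no separate
inference distribution).

Tunable parameters, with defaults:

* `learning_rate = 0.01` (Adam), `epochs = 10000`: the reference recipe.
  Loss reduction is the pixel mean, so the learning rate is independent of
  image size.
* `noise_amplitude = 1/30`: uniform noise on $[0, 1/30]$ is added to the
  fixed input at every step — on the unit-mean normalized intensity scale
  this is a ~3% jitter that regularizes the optimization. The final
  reconstruction pass uses the clean input.
* `network_spec()`: 4 scales, 16 base channels doubling per scale, leaky
  slope 0.1, skips on. The architecture is deliberately configurable;
  smaller settings (3 scales, constant width) lose little on smooth scenes
  and run several times faster on a CPU.
* Normalization, two distinct scales. The *fidelity* compares predictions
  against the measurement divided by its mean — the forward model of a
  unit-amplitude object produces unit-mean intensity exactly, so data and
  prediction share one scale. The *network input* is the measurement
  min–max scaled to $[0, 1]$, the conventional image scale, on which the
  1/30 jitter is a small (~3%) perturbation of the signal. The distinction
  matters: conditioning the network on the unit-mean intensity makes the
  jitter large relative to the signal variation at small grid sizes, and
  the optimization then converges to flat, wrong phases.
* No early stopping by default (fixed epoch budget); an optional plateau
  criterion (`plateau_patience`, relative change below `plateau_tol`)
  exists for exploratory runs.
* Restarts (`n_restarts`, default 1 = off). The optimization is non-convex
  and, depending on the random initialization, occasionally stalls in a
  flat-phase local minimum. The stalled state is unambiguous from the data
  alone: its fidelity loss plateaus one to two orders of magnitude above a
  converging run's. With `n_restarts > 1` several initializations are
  probed for `restart_epochs` steps and the lowest-fidelity candidate
  (mean loss over its last 50 probe epochs) continues for the rest of the
  budget. The selection reads only the loss, never the ground truth, so
  objective purity is preserved; the probes count toward the total epoch
  budget.
* One master seed derives independent streams for phantom generation,
  parameter initialization and input jitter; results are bit-reproducible,
  and supplying or withholding the ground truth (which only feeds a
  diagnostic error trace) never changes the reconstruction.

With several measurements of the same object at different distances the
objective generalizes to $\sum_i \|H_i(R_\theta(I_1)) - I_i\|^2$
(`reconstruct_multi()`), with the first measurement as the network input;
a single-element list reduces exactly to the single-shot case.

## Baselines

*Gerchberg–Saxton* (`gs_retrieve()`): alternating projections with the
phase-only (unit-modulus) constraint on the object plane, cycling through
the measurement planes in ascending distance, one full cycle per
iteration. Deterministic zero-phase initialization by default. The global
phase offset is free, so the returned phase is mean-subtracted.

*Transport of intensity* (`tie_solve()`): solves
$-k\,\partial I/\partial z = \nabla \cdot (I \nabla \phi)$ from a
central-difference axial derivative over three planes, via FFT Poisson
inversion. The default `"uniform"` mode replaces $I$ by its mean — the
right simplification for phase-only objects under near-unit illumination;
a `"full"` variable-intensity mode (auxiliary-potential two-step) is
available. The DC division is Tikhonov-regularized
($\varepsilon = 10^{-9} \max q^2$) and the unobservable piston pinned to
zero.

*Regularization by denoising* (`red_reconstruct()`): adds the penalty
$\frac{\lambda}{2}\phi^{T}(\phi - D(\phi))$ with $\phi = R_\theta(I)$ to
the same Adam loop, with the standard RED surrogate gradient
$\lambda(\phi - D(\phi))$ (exact for fixed linear symmetric denoisers,
which is what the gradient test uses). The denoiser is pluggable —
identity, fixed Gaussian smoothing, or a smoothed-TV descent step are
built in; a learned denoiser can be passed as any
`function(phase) -> phase`. $\lambda$ defaults to 0.05 and
$\lambda = 0$ reduces bit-exactly to the plain reconstruction.

## Evaluation protocol

Intensity measurements are blind to piston and, for symmetric geometries,
to complex conjugation (the twin). `mse(a, b)` therefore rescales the
reconstruction affinely so its min/max match the ground-truth range,
evaluates both the direct and the sign-flipped branch, and reports the
smaller mean square error, flagging when the twin branch wins. The number
is labeled "rad" in reports, following the field's convention for phase
maps, although dimensionally it is a mean of squared radians. Scores are
computed over the full frame (no border crop).

## The synthetic test bed

`generate_phantom()` emulates smooth, thin, cell-like phase objects: the
default is a seeded sum of 5 Gaussian bumps with widths between 1/16 and
1/4 of the grid, normalized to the range $[0, 1]$ rad on a 256×256 grid at
8 µm pitch under 632.8 nm illumination — a sub-$2\pi$ smooth object of the
kind quantitative phase imaging targets. A low-pass-filtered noise kind
and a hard-edged binary kind exist for variety; the smooth kinds are
band-limited below half Nyquist (asserted spectrally), which keeps all
propagation tests within the regime where the discrete model is exact.
`simulate_measurement()` adds optional Gaussian or Poisson detector noise
(default: none, matching noise-free simulation studies).

What the phantoms deliberately do not emulate: absorption (real samples
are never perfectly transparent), illumination non-uniformity, partial
coherence, detector saturation and fixed-pattern noise, or sample drift
between multi-plane exposures. Passing the synthetic suite therefore
demonstrates the correctness of the method and its implementation, not
performance on any particular experimental data.

### Problem sizes used by the checks

The reference study conditions (256×256, 10,000 epochs) are sized for GPU
hardware. The package's acceptance checks run the identical pipeline at
the scale a single CPU core handles in minutes: 64×64 phantoms (same
pitch, wavelength and distances), 3,000-epoch budgets with three 750-epoch
restart probes, and a 3-scale, 8-channel network for the scaled runs —
settings recorded in `scripts/acceptance.R`. The classical baselines run at the same scale
with their reference settings (5-plane GS at 200 cycles; TIE at
$\pm 0.5$ mm).

## Numerical choices and edge cases

* DFT conventions as above; all fixed, none configurable.
* Evanescent cutoff: hard zero (keeps $|G|\in\{0,1\}$); the alternative
  exponential-decay form would make back-propagation amplify noise.
* Max-pooling ties break to the first window position in a fixed order —
  relevant only on exactly-tied values, but it keeps runs bit-reproducible.
* Batch-normalization variance floor $10^{-5}$; Adam
  $(\beta_1, \beta_2, \epsilon) = (0.9, 0.999, 10^{-8})$.
* Non-finite losses abort with the epoch and learning rate in the message
  rather than returning garbage.
* A constant reconstruction cannot be range-matched to a non-constant
  reference; `rescale_to_reference()` then returns the reference-minimum
  fill with a warning flag rather than dividing by zero.
* Phase modulation beyond $2\pi$ is a documented failure mode of the
  single-shot method (the exponential map wraps); the test bed asserts the
  degradation as a ratio against the sub-$2\pi$ case rather than hiding it.

## Worked example

```{r example, eval = FALSE}
spec  <- propagation_spec(632.8e-9, 8e-6, 10e-3)   # He-Ne, 8 um, 10 mm
truth <- generate_phantom(phantom_spec(size = 64, peak_phase = 1, seed = 11))
I     <- simulate_measurement(truth, spec)

fit <- reconstruct(I, spec,
                   network = network_spec(n_scales = 3, base_channels = 8),
                   config  = optim_config(epochs = 2000, seed = 5),
                   ground_truth = truth)
mse(fit$phase, truth)         # rescaled MSE, rad
smooth_trace(fit$loss_trace)  # convergence diagnostics
```

Baselines on the same scene use multiple planes, as they must:

```{r baselines, eval = FALSE}
planes <- lapply(c(10, 15, 20, 25, 30) * 1e-3, function(d) {
  s <- spec; s$distance <- d
  list(intensity = simulate_measurement(truth, s), distance = d)
})
phi_gs <- gs_retrieve(gs_config(planes, n_iterations = 200), spec)

dz <- 0.5e-3
at <- function(d) { s <- spec; s$distance <- d; simulate_measurement(truth, s) }
phi_tie <- tie_solve(tie_input(at(10e-3 - dz), at(10e-3), at(10e-3 + dz), dz), spec)
```

## Known limitations

* Single-shot recovery degrades sharply for phase ranges beyond $2\pi$ and
  for objects with strong high-frequency content (the convolutional prior
  favors smooth structure).
* The optimization is non-convex; different seeds give slightly different
  reconstructions. The seed is part of the result object for that reason.
* CPU runtime scales with `epochs * pixels * channels^2`; the reference
  256×256 configuration is feasible but slow in R — scale the network
  before scaling the image.
* The TIE solver assumes periodic boundaries; fields with strong structure
  at the frame edge leak across it.
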