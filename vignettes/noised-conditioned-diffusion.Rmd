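---
title: "Channel- and noised-conditioned diffusion for CBCT-to-sCT translation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Channel- and noised-conditioned diffusion for CBCT-to-sCT translation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbctdiff)
```

## The problem

In image-guided radiotherapy a planning CT (pCT) is acquired once, while
cone-beam CT (CBCT) images are acquired at every treatment fraction. CBCT
shows the patient's anatomy *of the day*, but its Hounsfield units (HU) are
unreliable — cupping bias, streaks, noise and a reduced field of view (FOV)
make it unsuitable for dose recalculation. `cbctdiff` implements a
conditional denoising diffusion probabilistic model (DDPM) that translates a
CBCT slice into a synthetic CT (sCT): an image that keeps the CBCT's anatomy
but restores CT-quality HU values.

## Model

The forward diffusion process destroys an image $x_0$ over $T$ steps,

$$q(x_t \mid x_{t-1}) = N\!\left(\sqrt{1-\beta_t}\,x_{t-1},\; \beta_t I\right),
\qquad
x_t = \sqrt{\bar\alpha_t}\,x_0 + \sqrt{1-\bar\alpha_t}\,\epsilon,$$

with $\alpha_t = 1-\beta_t$, $\bar\alpha_t = \prod_{i\le t}\alpha_i$ and
$\epsilon \sim N(0, I)$. A U-Net $\epsilon_\theta(x_t, y_0, t)$ is trained to
predict $\epsilon$; reverse sampling repeatedly applies

$$x_{t-1} = \tfrac{1}{\sqrt{\alpha_t}}\Big(x_t -
\tfrac{1-\alpha_t}{\sqrt{1-\bar\alpha_t}}\,\epsilon_\theta(x_t, y_0, t)\Big)
+ \sigma_t z, \qquad z \sim N(0, I) \text{ if } t > 1 \text{ else } 0.$$

Two conditioning mechanisms steer generation toward the guiding CBCT $y_0$:

* **Channel conditioning.** $y_0$ is concatenated with the noisy sample as a
  second input channel at every training and sampling step; the network has
  two input channels and one output channel.
* **Noised conditioning.** Instead of starting the reverse chain from pure
  noise $x_T$, the chain starts at a tunable timestep $t_{con}$ from the
  *noised CBCT* $x_{t_{con}} = \sqrt{\bar\alpha_{t_{con}}}\,y_0 +
  \sqrt{1-\bar\alpha_{t_{con}}}\,\epsilon$.

Noised conditioning relies on a latent-convergence property: if the pCT and
the CBCT are noised with the *same* $\epsilon$, their difference is exactly
$x_t - y_t = \sqrt{\bar\alpha_t}\,(x_0 - y_0)$, so the Euclidean distance
between their noisy versions shrinks as $\sqrt{\bar\alpha_t}$ and their cosine
similarity approaches 1 as the noise dominates. Starting from a noised CBCT
therefore places the chain close to where a noised CT would be — close enough
that the learned reverse process can finish the job, while the surviving
$\sqrt{\bar\alpha_{t_{con}}}\,y_0$ term keeps the anatomy of the day.
`latent_convergence_curve()` computes this curve, and the distance law is
asserted exactly (to $10^{-6}$ relative) in the test suite.

$t_{con}$ trades anatomy against quality: too large and the CBCT content is
destroyed (at $t_{con} = T$ sampling is effectively from pure noise); too
small and the network has too few iterations to remove the CBCT artifacts.

## Noise schedules

`make_schedule()` tabulates $\beta_t, \alpha_t, \bar\alpha_t, \sigma_t$ for
three schedules over $T$ steps with $\beta_t \in [10^{-4}, 0.02]$ and
$T = 1000$ as the reference configuration:

* **linear** — $\beta_t$ interpolates evenly between the bounds;
* **cosine** — defined in $\bar\alpha$ space,
  $\bar\alpha_t = \cos^2\big(\tfrac{t/T + s}{1 + s}\cdot\tfrac{\pi}{2}\big)$
  with offset $s = 0.008$, from which $\beta_t = 1 -
  \bar\alpha_t/\bar\alpha_{t-1}$ is derived and clipped to
  $[\beta_{min}, 0.999]$;
* **sigmoid** — a logistic ramp of $\beta_t$ between the bounds with
  steepness $k = 6$.

The $\bar\alpha$-based cosine construction was chosen (over a raised-cosine
$\beta$ ramp, which remains available via
`cosine_construction = "beta_ramp"`) because it is the standard form and it
reproduces the qualitative behaviour that motivates schedule choice here:
the cosine schedule retains far more signal late in the forward process —

```{r}
alpha_bar_at(make_schedule("cosine", 1000), 900)
alpha_bar_at(make_schedule("linear", 1000), 900)
```

— which is why noised-conditioned sampling with a cosine schedule can start
as late as $t_{con} \approx 0.8$–$0.9\,T$ and still see anatomy, while linear
and sigmoid schedules need earlier starts. Whether the printed $\beta$ bounds
should constrain the cosine schedule's *derived* $\beta_t$ is ambiguous; we
treat them as clip limits in the default construction and as exact endpoints
in the `beta_ramp` variant.

The reverse-step noise is fixed at $\sigma_t^2 = \beta_t$ (the simpler of the
two canonical choices; the posterior variant
$\tilde\beta_t = \beta_t(1-\bar\alpha_{t-1})/(1-\bar\alpha_t)$ is available
via `sigma = "beta_tilde"`). The variance is never learned: the network
predicts only $\epsilon$. Timesteps are 1-based with $\bar\alpha_0 = 1$
stored explicitly.

## Timestep samplers

Training draws $t$ from a distribution over $\{1..T\}$
(`timestep_distribution()`): uniform (the classic choice), exponential
(weights $\propto e^{-t/\tau}$, default $\tau = T/4$) or triangular (weights
$\propto T - t + 1$). The non-uniform samplers put more mass on low
timesteps, where the loss converges slowest because fine detail is being
formed. Losses are *not* reweighted under non-uniform sampling — the training
loop is followed literally. One subtlety: with $\tau = T/4$ the exponential
distribution stochastically dominates the triangular over the bulk of the
range but its relative tail mass near $T$ is slightly heavier, so the
three-way CDF ordering holds for $k \lesssim 0.9\,T$ rather than everywhere;
the property test asserts exactly that.

## The denoiser

`build_denoiser()` constructs a 2-channel-in / 1-channel-out U-Net with
ResNet blocks, group normalization, SiLU activations, sinusoidal timestep
embeddings injected per block, and single-head spatial self-attention at
configurable resolution levels (default: the bottleneck). Width doubles per
level, capped at 8x the base width. The network, its reverse-mode
differentiation and the Adam optimizer are implemented in the package (R with
small C++ kernels for the convolution gather/scatter, SiLU and group-norm
inner loops); every layer's gradient is verified against central finite
differences in the test suite.

The default configuration is a *toy scale* — depth 3, base width 16,
32 x 32 inputs, ~160k parameters — chosen to train on one CPU in minutes.
A publication-scale geometry (depth 6, two ResNet blocks per level,
256 x 256 inputs, ~$10^8$ parameters) is expressible with the same fields and
sized analytically by `count_denoiser_params()`, but is not exercised by the
tests. Unconditional sampling (`sample_original()`) keeps the two-channel
contract by passing an all-zeros conditioning channel. Attention output
projections start at zero and the prediction head starts near zero (small
random scale), so a fresh network predicts almost-zero noise while remaining
sensitive to its timestep and conditioning inputs.

## Synthetic paired data

Real paired pCT/CBCT data cannot ship with the package, so
`make_pair_dataset()` generates what the method assumes: registered pairs
where the CBCT differs from the pCT by known, seeded degradations.
`generate_phantom_ct()` draws piecewise-constant anatomy — air at
-1000 HU, an elliptical soft-tissue body at 40 HU, bone structures at
1000 HU, optional air cavities — mimicking rigid quality-assurance phantoms.
`degrade_to_cbct()` then applies, in a fixed order chosen so noise-free specs
are exactly invertible: body-contour rescale (default 2%, anatomy change
between scans), rigid shift (default 1 px), radial cupping bias (default
60 HU depression at the center, applied to non-air pixels), alternating-sign
streaks (default 4 lines at 150 HU), additive Gaussian noise (default
25 HU SD), and truncation to a circular FOV (default radius fraction 0.9,
outside filled with air). The default amplitudes were chosen once to give
CBCT-vs-pCT masked MAE in the range tens-to-low-hundreds of HU — the regime
reported for real head-and-neck CBCT — and are not tuned afterwards.

What the generator does **not** emulate: projection physics (no Radon/FDK
reconstruction), scatter, beam hardening spectra, deformable anatomy, or
texture inside tissue classes. Passing tests on these phantoms therefore
demonstrates that the *mechanism* works — conditioning, partial-noise starts,
HU restoration within a mask — not that clinical image quality is achieved on
real patients.

Preprocessing follows the standard chain: volumes can be resampled to
1 x 1 x 3 mm and center-cropped (`resample_and_crop()`); intensities are
clipped to [-1000, 3000] HU and mapped affinely to [-1, 1]
(`preprocess()`, exactly inverted by `to_hu()`). Images carry a unit tag so
HU-space metrics refuse normalized inputs.

## Evaluation

Metrics are computed inside a circular FOV mask (`fov_mask()`, default radius
fraction 0.9; a smaller mask, e.g. 0.7, mimics excluding phantom set-up
hardware): masked MAE in HU, masked PSNR with a *fixed* reference range of
4000 HU (the clipped window width, so scores are comparable across images;
identical images return a 100 dB cap instead of infinity), and zero-mean
normalized cross-correlation. The metric formulas themselves are the standard
definitions. HU difference maps and air-truncated HU histograms (lower limit
-950 HU) support visual assessment. `evaluate_pairs()` reports sCT-vs-pCT
and CBCT-vs-pCT side by side, per slice and aggregated as mean ± SD.

## Numerical choices

* Reverse sampling clamps the implied clean image
  $\hat x_0 = (x_t - \sqrt{1-\bar\alpha_t}\,\hat\epsilon)/\sqrt{\bar\alpha_t}$
  to $[-1, 1]$ by default (`clip_x0 = TRUE`) before applying the
  algebraically equivalent posterior-mean update — the standard safeguard
  against drift over long chains. Oracle-exactness tests disable it.
* With the exact-noise oracle denoiser and $z = 0$, both samplers recover
  their target to $\le 10^{-3}$ absolute per pixel over 1000 steps; the
  per-step residual contraction factor
  $\sqrt{\alpha_t}(1-\bar\alpha_{t-1})/(1-\bar\alpha_t)$ is asserted
  step-by-step.
* Group counts for normalization are reduced per layer to the largest divisor
  of the channel count not exceeding the configured value.
* $T = 1$ schedules degenerate to $\beta_1 = \beta_{min}$, avoiding a
  division by zero in the interpolants.
* All stochastic entry points take an explicit integer seed and restore the
  global RNG state; one experiment seed fans out into named sub-seeds (data,
  initialization, training, sampling) so components can be varied
  independently. Fixed seeds give bit-identical runs on one machine.
* Sampling at validation time uses stochastic $z$ (with $z = 0$ at $t = 1$)
  under a fixed seed; whether to use $z = 0$ throughout is exposed as
  `stochastic_z`.

## The scaled-down study

`run_experiment(experiment_config(seed = 1))` reproduces the method's
directional findings at desk scale. The conditions were fixed once: 200
paired 32 x 32 slices with 20 held out, cosine schedule with $T = 250$
(the $\bar\alpha$-based cosine is resolution-free in $t/T$, so a shorter
chain preserves the schedule's shape while keeping CPU sampling tractable),
2500 Adam steps at batch size 4 and learning rate $10^{-3}$, uniform
timestep sampling, and noised-conditioned sampling at
$t_{con} \in \{T, 0.8\,T\} = \{250, 200\}$. The expected qualitative
outcomes, asserted by the acceptance tests, are:

* the sCT sampled at $t_{con} = 0.8\,T$ has lower masked MAE than the CBCT
  it was generated from;
* it also has lower masked MAE than the sCT sampled from pure noise
  ($t_{con} = T$), the direction of the headline finding that noised
  conditioning is what makes few-shot conditional DDPMs work;
* early in training, the loss in the highest timestep decile sits below the
  lowest decile's (coarse structure is learned before fine detail).

The magnitudes are not comparable to a GPU-scale study on patients and are
not asserted.

## Limitations

* The phantom generator's degradations are additive/geometric surrogates, not
  physics; absolute metric values on it say nothing about clinical data.
* The toy denoiser underfits fine texture by construction; at 32 x 32 there
  is little texture to preserve.
* Only 2D slices are modelled; no 3D consistency across slices.
* No DDIM-style accelerated sampling; the only speedup is the $t_{con}$
  truncation itself, which is also its clinical appeal (fewer reverse steps
  per image).
* PSNR uses a fixed 4000 HU range; studies using per-image ranges will report
  different absolute dB values for the same images.
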