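---
title: "Methods: frequency-aware diffusion bridges for paired image translation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: frequency-aware diffusion bridges for paired image translation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of the model it implements, the
assumptions behind it, the parameters that matter, and the design decisions
taken where the design was genuinely open. It states no empirical result
that the test suite and `scripts/acceptance.R` do not themselves compute.

## The problem and the model

Given co-registered pairs of 2D grayscale images — a *source* modality
$X_T$ and a *target* modality $X_0$ of the same anatomy (think 1.5T vs 3T
MRI, or T1 vs T2 contrast) — we want a generative translator from source to
target that preserves fine structure. Instead of denoising from pure
Gaussian noise with the source only as guidance, the model walks a
*diffusion bridge* pinned at both endpoints. For paired endpoints the
bridge has an analytic Gaussian conditional:

$$q(X_t \mid X_0, X_T) = \mathcal{N}\!\left(\mu_t,\ \sigma_t^2\bar\sigma_t^2/(\sigma_t^2+\bar\sigma_t^2)\, I\right),
\qquad
\mu_t = \frac{\bar\sigma_t^2\,X_0 + \sigma_t^2\,X_T}{\sigma_t^2 + \bar\sigma_t^2},$$

where $\sigma_t^2$ accumulates the per-step variance $\beta$ from $0$ to
$t$ and $\bar\sigma_t^2$ from $t$ to $T$. The mean interpolates the
endpoints; the variance vanishes at both boundaries and peaks in the
middle. A denoiser $\epsilon_\theta$ is trained to regress the standardized
displacement $\epsilon = (X_t - X_0)/\sigma_t$; sampling starts at
$X_T = \text{source}$ and repeatedly forms $\hat X_0 = X_t - \sigma_t
\hat\epsilon$, then draws the analytic posterior of the sub-bridge pinned at
$(\hat X_0, X_t)$ at the previous time (`reverse_step()`). The final step
($t_{\text{prev}} = 0$) is deterministic.

Everything the denoiser sees lives in the *wavelet-packed domain*: each
image is decomposed by one level of the orthonormal Haar transform and its
four sub-bands are stacked along channels, quartering the spatial area. The
predicted noise is unpacked and inverse-transformed, and the reverse update
itself is applied in pixel space. Because the transform is an isometry, the
wavelet-domain mean-squared training loss equals the pixel-domain one
exactly (a property covered by a test).

### Conventions frozen in the wavelet kernel

- Orthonormal filters $(\pm 1/\sqrt2)$: energy is preserved, so Gaussian
  noise statistics are identical in both domains. With averaging (1/2)
  normalization the bridge variance would be distorted per sub-band.
- Detail sign: high-pass is *first minus second* sample; `lh` is high-pass
  along width, `hl` along height. The 2×2 image $[[1,2],[3,4]]$ maps to
  `ll` = 5, `lh` = −1, `hl` = −2, `hh` = 0, and a constant $c$ maps to
  `ll` $= 2c$.
- Packing order `(ll, lh, hl, hh)` in channel blocks; arbitrary but frozen
  and round-trip tested.
- Even dimensions are required at every level used; nothing is ever padded.
  Wavelet boundary extension creates boundary artifacts that compound over
  diffusion steps, so inputs that would need it are rejected instead.

## The denoiser

`faunet_config()` describes a U-Net over packed sub-bands with $M$
encoder/decoder levels:

- **Wavelet downsampling layers** replace strided convolution: per-channel
  Haar DWT, channel concatenation (4×), then a learned 1×1 projection. An
  extra wavelet shortcut maps the raw packed input onto the first
  downsampled pyramid level. The ablation baseline (`downsample =
  "strided"`) uses plain strided convolution and drops the shortcut.
- **High-frequency supervision (HFSM)** in the decoder: single-head
  cross-attention whose query is a 1×1 projection of the conditional
  image's summed detail bands $X_{lh}+X_{hl}+X_{hh}$ at the matching
  resolution, with keys and values projected from the decoder feature map.
  The attention output is *concatenated* with the skip connection rather
  than replacing it, so the plain skip path always survives. Level
  matching: the decoder level with spatial size $H/2^k$ consumes the
  level-$k$ detail bands of the conditional image's multi-level
  decomposition — resolution equality is the only consistent pairing.
  $d_k$ in the $1/\sqrt{d_k}$ attention scaling is the projected feature
  dimension.
- **Time conditioning**: interleaved sinusoidal embedding of $t$, a shared
  two-layer MLP, and a per-ResBlock learned projection added per channel.
- **Self-attention** at the bottleneck always, optionally at encoder levels.
- **Normalization**: channelwise RMS normalization with a learned gain,
  pre-activation in every ResBlock, before attention projections, and
  before the output head. The role is the one GroupNorm plays in this
  network family: without it, whether training leaves the
  zero-prediction plateau depends on the initialization draw (we observed
  both outcomes with different seeds); with it, feature scales stay bounded
  and training is stable across seeds.
- **Initialization**: He-style for convolutions, $\sqrt{1/\text{fan-in}}$
  for attention projections, and a *tiny* (sd $10^{-3}$) final output
  convolution. Exactly-zero final init is common for stabilizing early
  noise prediction, but it makes first-batch upstream gradients exactly
  zero; the tiny init keeps the stabilization while every parameter
  receives gradient from the first batch (a tested property).

The whole network, including backpropagation, is implemented on a small
reverse-mode tape over `(pixels, channels)` matrices (`R/tape.R`);
convolution is im2col plus matrix multiplication. Gradients are verified
against central finite differences across every branch type.

## Conditioning

The conditional image is a one-shot target-like estimate computed from the
source, used only to guide denoising — the bridge endpoint is always the
raw source, whatever the provider. At full scale this estimate comes from a
large pre-trained generative model; that is deliberately not reimplemented
here. The `condition_provider()` interface isolates it so such a model can
be slotted in, and two desk-scale providers ship:

- `"regression"` (default): a two-layer convolutional network fitted with a
  mean-absolute-error objective on the training split, deterministic once
  fitted. Its held-out conditioning error is required (by test) to be no
  worse than presenting the raw source.
- `"identity"`: the ablation baseline.

The conditional image is computed once per sample and held fixed across all
reverse steps.

## Synthetic phantoms

`make_phantom_pair()` draws a head-like outer ellipse, four inner tissue
ellipses and, with probability 0.5 per subject, a small lesion blob; it
renders the *same* geometry through two per-tissue contrast lookup tables
(the two "modalities") and adds independent Gaussian noise (sd 0.03) to
each, clipping to $[-1,1]$. Defaults are fixed so that the task is
non-trivial: the mean source–target gap inside the head is far above the
noise floor, and tissue intensity ranks swap between modalities, so no
monotone intensity remap solves the task. `make_dataset()` splits subjects
80/10/10 with no subject in two splits; slices within a subject share
geometry up to a small jitter, emulating adjacent slices. Lesions have
modality-dependent contrast (subtle in the source, bright in the target),
emulating lesion-focused evaluation.

What the phantoms do *not* emulate: scanner physics, bias fields,
k-space artifacts, registration error, realistic anatomy. Passing the
end-to-end tests therefore shows that the machinery — bridge algebra,
wavelet plumbing, conditioning, optimization — works and that the model
learns a non-trivial cross-contrast mapping at desk scale; it does not show
clinical-grade synthesis quality on real MRI.

Real volumes can be substituted through `load_volume_slices()` (NIfTI,
per-volume min–max normalization to $[-1,1]$, optional adjacent-slice
3-channel stacking, bilinear resize to a square grid). Registration is
assumed done upstream.

## Numerical and scale choices

- Discrete times $t = 0..T$; $\beta$ is a per-step variance increment, so
  the continuous-time integrals in the posterior become cumulative sums and
  both readings of the accumulated variances coincide.
- Default schedule: symmetric triangular with `beta_peak` normalized so
  $\sigma_T^2 = 1$ on the $[-1,1]$ intensity scale; a constant schedule is
  provided for analytic tests (with $\beta = 0.1$, $T = 10$: $\sigma_3^2 =
  0.3$, posterior weights $(0.7, 0.3)$, variance $0.21$).
- Desk-scale defaults, chosen once so a fit completes in a few minutes on
  one CPU and used by the verification suite: images 32×32, $T = 20$,
  2000 iterations, batch 2 (also the batch size used at full scale in this
  model family), AdamW with learning rate $2\times10^{-3}$, weight decay
  $10^{-4}$, channels (16, 32), validation every 100 iterations. The
  learning rate is larger than the $5\times10^{-5}$ used for GPU-scale
  training of this model family because the desk-scale budget is ~2000
  iterations rather than hundreds of thousands; both are reachable through
  `fadm()` arguments.
- The checkpoint with minimum validation loss is kept; ties break toward
  the later iteration.
- Validation losses are computed with a fixed per-evaluation seed, so the
  loss curve is comparable across evaluations and reruns are bit-identical.
- All randomness flows through explicit `rng_stream()` objects; nothing
  touches the global generator state visible to the user.
- Inference may stride the training steps uniformly
  (`n_infer_steps`); the default uses all steps. The final reverse step is
  deterministic, so output quality degrades gracefully with fewer steps.
- PSNR uses `data_range = 2`; identical images report `Inf`. SSIM uses the
  universal constants (Gaussian 11×11, $\sigma = 1.5$, $K_1 = 0.01$,
  $K_2 = 0.03$), valid-mode windows.

## Open choices and how they were resolved

- *Pixel- vs wavelet-space reverse update*: the literal sampling
  description (predict in the wavelet domain, inverse-transform the noise,
  then form $X_{t-1}$) is followed — the update happens in pixel space.
  Under an orthonormal transform the two readings give identical
  distributions for the linear update, so the tension is notational; the
  oracle-exactness test covers the composed pipeline.
- *HFSM augment vs replace*: augment (concatenate), because the module is
  described as an additional input to the upsampling block.
- *Distributional metrics* (pretrained-feature distances) are excluded: they
  require downloaded classifier weights. The report format keeps an
  optional column so a plug-in can add one.
- *Loss*: plain MSE on the packed noise prediction, the standard choice for
  this parameterization; the wavelet/pixel equivalence makes the domain
  choice immaterial.

## Known limitations

- The even-dimension requirement is strict; arbitrary sizes need upstream
  resizing.
- Training cost in pure R limits practical scale to small images and small
  nets; the architecture is faithful, the scale is not.
- The regression conditioning provider is far weaker than a pre-trained
  generative model; it exists to exercise the interface and the
  conditioning pathway at desk scale.
- Reproducibility is bit-exact under single-threaded BLAS; multi-threaded
  BLAS may reorder reductions.
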