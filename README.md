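# fadm — frequency-aware diffusion bridges for paired image translation

`fadm` translates images between two co-registered modalities of the same
anatomy — e.g. synthesizing a 3T-like MRI slice from a 1.5T scan, or a
T2-weighted contrast from T1 — for researchers who have paired 2D slices
and want a generative translator that preserves fine structure. It is a
complete, desk-scale implementation of a wavelet-domain Schrödinger-bridge
diffusion model: every component (bridge algebra, denoiser, training,
sampling, evaluation) runs in minutes on a single CPU on built-in synthetic
phantoms, and the same code accepts slices of user-supplied NIfTI volumes.

## The model

For paired endpoints — target $X_0$ and source $X_T$ — the diffusion bridge
pinned at both ends has an analytic Gaussian conditional

$$q(X_t \mid X_0, X_T)=\mathcal N\!\big(\mu_t,\ \tfrac{\sigma_t^2\bar\sigma_t^2}{\sigma_t^2+\bar\sigma_t^2} I\big),
\qquad
\mu_t=\frac{\bar\sigma_t^2 X_0+\sigma_t^2 X_T}{\sigma_t^2+\bar\sigma_t^2},$$

with $\sigma_t^2$, $\bar\sigma_t^2$ the variances accumulated from either
end of the schedule. A U-Net denoiser predicts the standardized
displacement $\epsilon=(X_t-X_0)/\sigma_t$; sampling starts from the source
image (not from pure noise) and repeatedly forms
$\hat X_0 = X_t-\sigma_t\hat\epsilon$, then draws the sub-bridge posterior
at the previous time.

The *frequency-aware* part: every denoiser evaluation happens on the four
orthonormal Haar sub-bands stacked as channels (quarter spatial area);
encoder downsampling is DWT + channel concatenation + learned projection
instead of strided convolution; and decoder levels apply cross-attention
whose queries come from the conditional image's high-frequency sub-bands
(the HFSM), sharpening detail recovery. A pluggable conditioning provider
supplies the conditional image — a one-shot target-like estimate; a small
fitted regression network by default, a pre-trained generative model if you
have one.

## Worked example

```r
library(fadm)

ds  <- make_dataset(n_subjects = 10, slices_per_subject = 4,
                    seed = 11, size = 32)   # 32 train / 4 val / 4 test
fit <- fadm(ds, seed = 11)                  # T = 20, 2000 iters, ~4 min
print(fit)
summary(fit, seed = 3)
```

```
Held-out evaluation (4 test images):
  generated vs target: PSNR 25.958 +- 0.650 dB, SSIM 0.7307 +- 0.0473
  source    vs target: PSNR 18.682 +- 0.272 dB, SSIM -0.0763 +- 0.0731
  PSNR gain 7.276 dB, SSIM gain 0.8069
```

The second line is the baseline of simply presenting the source modality;
the fitted bridge recovers the target contrast far more faithfully (here
about +7 dB PSNR on held-out subjects, with SSIM rising from about zero to
0.73). `predict(fit)` returns the generated images, `plot(fit)` draws a
source / conditional / generated / target panel, and
`simulate(fit, nsim = 3)` draws repeated stochastic translations.

Real data goes through the same interface:

```r
slices <- load_volume_slices("subject01_T1.nii.gz", plane = "axial",
                             stack_adjacent = TRUE, size = 256)
```

A thin command-line interface wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/fadm.R", package="fadm"))') \
    train --config cfg.yaml --out ckpt.rds --seed 1
```

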