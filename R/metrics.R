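# Image-quality metrics. PSNR uses the full data range of the [-1, 1]
# convention (data_range = 2) by default; SSIM uses the universal defaults:
# 11 x 11 Gaussian window with sigma 1.5, stabilizers K1 = 0.01, K2 = 0.03,
# valid-mode windows, mean over positions and channels.

#' Peak signal-to-noise ratio
#'
#' `10 * log10(data_range^2 / MSE)` in dB. Identical images have zero MSE
#' and are reported as `Inf` (the documented cap).
#'
#' @param a,b Images of identical shape.
#' @param data_range Intensity range; 2 for images in [-1, 1].
#' @return PSNR in dB.
#' @export
psnr <- function(a, b, data_range = 2) {
  a <- as_image(a); b <- as_image(b)
  if (!identical(dim(a), dim(b)))
    stop(sprintf("psnr: shapes differ: (%s) vs (%s)",
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  stopifnot(data_range > 0)
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

gaussian_kernel11 <- function(sigma = 1.5) {
  z <- seq(-5, 5)
  k <- exp(-z^2 / (2 * sigma^2))
  k <- k / sum(k)
  outer(k, k)
}

# valid-mode 2D filtering with an 11x11 kernel, via shifted accumulation
filter_valid11 <- function(m, kern) {
  d <- dim(m)
  out <- matrix(0, d[1] - 10L, d[2] - 10L)
  for (ki in 1:11) for (kj in 1:11) {
    out <- out + kern[ki, kj] *
      m[ki:(d[1] - 11L + ki), kj:(d[2] - 11L + kj)]
  }
  out
}

#' Structural similarity index
#'
#' Mean local SSIM over valid 11 x 11 Gaussian windows (sigma 1.5) with the
#' standard stabilizers `C1 = (0.01 * L)^2`, `C2 = (0.03 * L)^2`, averaged
#' over channels. Bounded in [-1, 1]; identical images score 1.
#'
#' @inheritParams psnr
#' @return SSIM value.
#' @export
ssim <- function(a, b, data_range = 2) {
  a <- as_image(a); b <- as_image(b)
  if (!identical(dim(a), dim(b)))
    stop(sprintf("ssim: shapes differ: (%s) vs (%s)",
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  d <- dim(a)
  if (d[1] < 11 || d[2] < 11)
    stop(sprintf("ssim: image %d x %d is smaller than the 11 x 11 window",
                 d[1], d[2]))
  kern <- gaussian_kernel11()
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  vals <- vapply(seq_len(d[3]), function(ch) {
    x <- a[, , ch]; y <- b[, , ch]
    mx <- filter_valid11(x, kern); my <- filter_valid11(y, kern)
    sxx <- filter_valid11(x * x, kern) - mx^2
    syy <- filter_valid11(y * y, kern) - my^2
    sxy <- filter_valid11(x * y, kern) - mx * my
    s <- ((2 * mx * my + C1) * (2 * sxy + C2)) /
         ((mx^2 + my^2 + C1) * (sxx + syy + C2))
    mean(s)
  }, numeric(1))
  mean(vals)
}

#' Evaluate a generated split against reference targets
#'
#' Computes per-image PSNR and SSIM plus split-level means and standard
#' deviations.
#'
#' @param generated,targets Equal-length lists of shape-matched images.
#' @param data_range Intensity range (2 for [-1, 1]).
#' @return Object of class `fadm_eval` with a per-image `table` and the
#'   summary fields `psnr_mean`, `psnr_sd`, `ssim_mean`, `ssim_sd`.
#' @export
evaluate_split <- function(generated, targets, data_range = 2) {
  if (length(generated) != length(targets))
    stop(sprintf("evaluate_split: %d generated images but %d targets",
                 length(generated), length(targets)))
  p <- mapply(psnr, generated, targets, MoreArgs = list(data_range = data_range))
  s <- mapply(ssim, generated, targets, MoreArgs = list(data_range = data_range))
  structure(list(
    table = data.frame(image = seq_along(p), psnr = p, ssim = s),
    psnr_mean = mean(p), psnr_sd = stats::sd(p),
    ssim_mean = mean(s), ssim_sd = stats::sd(s),
    data_range = data_range
  ), class = "fadm_eval")
}

#' @export
print.fadm_eval <- function(x, ...) {
  cat(sprintf("Evaluation over %d image(s) (data range %g):\n",
              nrow(x$table), x$data_range))
  cat(sprintf("  PSNR %.3f +- %.3f dB\n  SSIM %.4f +- %.4f\n",
              x$psnr_mean, x$psnr_sd, x$ssim_mean, x$ssim_sd))
  invisible(x)
}
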