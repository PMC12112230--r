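# Shared fixtures and independent oracles for the suite. Heavy artifacts
# (trained models) are built lazily once and shared across test files
# through this cache.

.cache <- new.env(parent = emptyenv())

rand_image <- function(h, w = h, c = 1L, seed = 1L) {
  r <- rng_stream(seed)
  array(rng_norm(r, h * w * c), dim = c(h, w, c))
}

# brute-force separable Haar filter-bank oracle: filters rows then columns
# with low = (1,1)/sqrt(2) and high = (first - second)/sqrt(2), independent
# of the production implementation's 2x2-block arithmetic
haar_oracle <- function(m) {
  H <- nrow(m); W <- ncol(m)
  lo <- function(v) (v[seq(1, length(v), 2)] + v[seq(2, length(v), 2)]) / sqrt(2)
  hi <- function(v) (v[seq(1, length(v), 2)] - v[seq(2, length(v), 2)]) / sqrt(2)
  rowf <- function(f) matrix(unlist(lapply(seq_len(H), function(i) f(m[i, ]))),
                             H, W / 2, byrow = TRUE)
  colf <- function(mm, f) matrix(unlist(lapply(seq_len(ncol(mm)),
                                               function(j) f(mm[, j]))),
                                 H / 2, ncol(mm))
  rl <- rowf(lo); rh <- rowf(hi)
  list(ll = colf(rl, lo), lh = colf(rh, lo), hl = colf(rl, hi), hh = colf(rh, hi))
}

# brute-force SSIM oracle: explicit loop over valid 11x11 windows
ssim_oracle <- function(a, b, data_range = 2) {
  a <- a[, , 1]; b <- b[, , 1]
  k <- local({
    z <- seq(-5, 5); g <- exp(-z^2 / (2 * 1.5^2)); g <- g / sum(g); outer(g, g)
  })
  C1 <- (0.01 * data_range)^2; C2 <- (0.03 * data_range)^2
  H <- nrow(a); W <- ncol(a)
  vals <- c()
  for (i in 1:(H - 10)) for (j in 1:(W - 10)) {
    wa <- a[i:(i + 10), j:(j + 10)]; wb <- b[i:(i + 10), j:(j + 10)]
    mx <- sum(k * wa); my <- sum(k * wb)
    sxx <- sum(k * wa * wa) - mx^2
    syy <- sum(k * wb * wb) - my^2
    sxy <- sum(k * wa * wb) - mx * my
    vals <- c(vals, ((2 * mx * my + C1) * (2 * sxy + C2)) /
                      ((mx^2 + my^2 + C1) * (sxx + syy + C2)))
  }
  mean(vals)
}

tiny_config <- function(...) {
  faunet_config(levels = 2L, base_channels = 4L, time_embed_dim = 8L, ...)
}

# the study-condition dataset and fitted model shared by the end-to-end
# checks: 10 subjects x 4 slices at 32 x 32, T = 20, 2000 iterations
study_dataset <- function() {
  if (is.null(.cache$ds)) .cache$ds <- make_dataset(10, 4, seed = 11, size = 32)
  .cache$ds
}

study_fit <- function() {
  if (is.null(.cache$fit))
    .cache$fit <- fadm(study_dataset(), seed = 11, verbose = FALSE)
  .cache$fit
}

study_summary <- function() {
  if (is.null(.cache$summary)) .cache$summary <- summary(study_fit(), seed = 3)
  .cache$summary
}
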