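# Analytic Schroedinger-bridge posterior between paired endpoints.
#
# With x0 the target-modality image and xT the source-modality image, the
# bridge pinned at both ends has the Gaussian conditional
#     q(x_t | x0, xT) = N(mu_t, var_t I),
#     mu_t  = (sbar2_t x0 + s2_t xT) / (s2_t + sbar2_t),
#     var_t = s2_t sbar2_t / (s2_t + sbar2_t),
# where s2_t accumulates the per-step beta from 0 to t and sbar2_t from t to
# T. The variance vanishes at both boundaries and peaks inside, and the mean
# interpolates the endpoints. Discrete indices t = 0..T are used throughout;
# beta is a per-step variance increment, so the continuous-time integrals
# become cumulative sums.

#' Construct a bridge noise schedule
#'
#' Builds the per-step `beta` sequence and the two accumulated variances
#' `sigma2_fwd` (from 0) and `sigma2_bwd` (from T), which satisfy
#' `sigma2_fwd[t] + sigma2_bwd[t] = sigma2_fwd[T]` for all t.
#'
#' @param n_steps Number of diffusion steps T (>= 2).
#' @param beta_peak Peak per-step variance. If `NULL`, it is set so that the
#'   total accumulated variance `sigma_T^2` equals 1 on the normalized
#'   intensity scale.
#' @param shape `"symmetric_triangular"` (beta rises linearly to the midpoint
#'   then falls, the usual bridge convention) or `"constant"`.
#' @return An object of class `noise_schedule` with fields `n_steps`, `beta`
#'   (length T), `sigma2_fwd` and `sigma2_bwd` (length T + 1, indexed t = 0..T
#'   via `[t + 1]`).
#' @examples
#' s <- make_schedule(10, beta_peak = 0.1, shape = "constant")
#' s$sigma2_fwd[11]  # = 1
#' @export
make_schedule <- function(n_steps,
                          beta_peak = NULL,
                          shape = c("symmetric_triangular", "constant")) {
  shape <- match.arg(shape)
  if (length(n_steps) != 1 || n_steps < 2 || n_steps != round(n_steps))
    stop("make_schedule: n_steps must be an integer >= 2")
  n_steps <- as.integer(n_steps)
  w <- switch(shape,
    constant = rep(1, n_steps),
    symmetric_triangular = {
      tt <- seq_len(n_steps)
      pmin(tt, n_steps + 1L - tt)
    })
  w <- w / max(w)
  if (is.null(beta_peak)) beta_peak <- 1 / sum(w)
  if (length(beta_peak) != 1 || !is.finite(beta_peak) || beta_peak <= 0)
    stop("make_schedule: beta_peak must be a positive real")
  beta <- beta_peak * w
  s2 <- c(0, cumsum(beta))
  structure(list(
    n_steps = n_steps,
    beta = beta,
    sigma2_fwd = s2,
    sigma2_bwd = s2[n_steps + 1L] - s2,
    shape = shape,
    beta_peak = beta_peak
  ), class = "noise_schedule")
}

#' @export
print.noise_schedule <- function(x, ...) {
  cat(sprintf("Bridge noise schedule: T = %d, shape = %s, total sigma_T^2 = %.4g\n",
              x$n_steps, x$shape, x$sigma2_fwd[x$n_steps + 1L]))
  invisible(x)
}

check_t <- function(t, sched, lo = 0L) {
  if (length(t) != 1 || t != round(t) || t < lo || t > sched$n_steps)
    stop(sprintf("time index t = %s out of range [%d, %d]",
                 format(t), lo, sched$n_steps))
  as.integer(t)
}

#' Bridge posterior mean and variance
#'
#' Evaluates the analytic Gaussian posterior q(x_t | x0, xT): the mean is a
#' convex combination of the endpoints with weights proportional to the
#' variance accumulated from the opposite end, and the variance is the
#' harmonic-style product `s2 * sbar2 / (s2 + sbar2)` (isotropic).
#'
#' @param x0 Target endpoint (image array or numeric).
#' @param xT Source endpoint, same shape as `x0`.
#' @param t Integer time index in `[0, T]`.
#' @param sched A [make_schedule()] object.
#' @return List with `mu` (same shape as `x0`) and scalar `var`.
#' @export
posterior_params <- function(x0, xT, t, sched) {
  stopifnot(inherits(sched, "noise_schedule"))
  if (!identical(dim(x0), dim(xT)) || length(x0) != length(xT))
    stop("posterior_params: x0 and xT must have identical shape")
  t <- check_t(t, sched)
  s2 <- sched$sigma2_fwd[t + 1L]
  sb2 <- sched$sigma2_bwd[t + 1L]
  tot <- s2 + sb2
  list(mu = (sb2 * x0 + s2 * xT) / tot, var = s2 * sb2 / tot)
}

#' Draw an intermediate bridge state
#'
#' Samples `x_t = mu_t + sqrt(var_t) z` with elementwise standard Gaussian z.
#' At t = 0 or t = T the variance is zero and the endpoint is returned
#' exactly.
#'
#' @inheritParams posterior_params
#' @param rng A [rng_stream()].
#' @return Same shape as `x0`.
#' @export
sample_xt <- function(x0, xT, t, sched, rng) {
  pp <- posterior_params(x0, xT, t, sched)
  if (pp$var == 0) return(pp$mu)
  pp$mu + sqrt(pp$var) * array(rng_norm(rng, length(pp$mu)), dim = dim(pp$mu) %||% length(pp$mu))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Noise-prediction training target
#'
#' The denoiser regresses the standardized displacement
#' `eps = (x_t - x0) / sigma_t`; predicting `eps` and forming
#' `x0_hat = x_t - sigma_t * eps_hat` inverts it exactly.
#'
#' @inheritParams posterior_params
#' @param xt Bridge state at time `t`.
#' @export
epsilon_target <- function(x0, xt, t, sched) {
  stopifnot(inherits(sched, "noise_schedule"))
  t <- check_t(t, sched, lo = 1L)
  (xt - x0) / sqrt(sched$sigma2_fwd[t + 1L])
}

#' One ancestral reverse step of the bridge sampler
#'
#' Forms the clean-image estimate `x0_hat = x_t - sigma_t * eps_hat`, then
#' samples the analytic posterior of the sub-bridge pinned at (x0_hat, x_t) on
#' the interval `[0, t]`, evaluated at `t_prev` (variances accumulated on
#' `[0, t_prev]` and `[t_prev, t]`). When `t_prev = 0` the step is
#' deterministic and returns `x0_hat`.
#'
#' @param xt Current state at time `t`.
#' @param eps_hat Predicted noise, same shape as `xt`.
#' @param t,t_prev Integer times with `0 <= t_prev < t <= T`.
#' @param sched A [make_schedule()] object.
#' @param rng A [rng_stream()]; unused when `t_prev = 0`.
#' @export
reverse_step <- function(xt, eps_hat, t, t_prev, sched, rng) {
  stopifnot(inherits(sched, "noise_schedule"))
  t <- check_t(t, sched, lo = 1L)
  if (length(t_prev) != 1 || t_prev != round(t_prev) || t_prev < 0 || t_prev >= t)
    stop(sprintf("reverse_step: need 0 <= t_prev < t, got t_prev = %s, t = %d",
                 format(t_prev), t))
  t_prev <- as.integer(t_prev)
  if (!identical(dim(xt), dim(eps_hat)) || length(xt) != length(eps_hat))
    stop("reverse_step: xt and eps_hat must have identical shape")
  x0_hat <- xt - sqrt(sched$sigma2_fwd[t + 1L]) * eps_hat
  if (t_prev == 0L) return(x0_hat)
  s2 <- sched$sigma2_fwd[t_prev + 1L]
  sb2 <- sched$sigma2_fwd[t + 1L] - sched$sigma2_fwd[t_prev + 1L]
  tot <- s2 + sb2
  mu <- (sb2 * x0_hat + s2 * xt) / tot
  v <- s2 * sb2 / tot
  mu + sqrt(v) * array(rng_norm(rng, length(mu)), dim = dim(mu) %||% length(mu))
}
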