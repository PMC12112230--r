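# Iterative sampling: start from the source image at t = T and walk the
# reverse bridge. Every network evaluation happens in the wavelet-packed
# domain; the predicted noise is unpacked and inverse-transformed back to
# pixel space, where the ancestral reverse step is applied. The conditional
# image is computed once per sample and held fixed across steps.

#' Translate a source image with the trained (or an oracle) denoiser
#'
#' Sets `X_T = source`; for each step the current state and the conditional
#' image are Haar-transformed and channel-packed, the denoiser predicts
#' wavelet-domain noise, the prediction is unpacked and inverse-transformed,
#' and [reverse_step()] produces the next state. The final state (the t = 0
#' estimate) is clipped to [-1, 1].
#'
#' @param source Source-modality image (H, W[, C]) in [-1, 1].
#' @param provider A `condition_provider` function.
#' @param net A [faunet_init()] object, or a function
#'   `(xt_packed, y_packed, cond_image, t) -> packed noise` (used by the
#'   oracle-exactness tests).
#' @param sched A [make_schedule()] object.
#' @param n_infer_steps Number of reverse steps; `NULL` uses all `T` steps,
#'   otherwise a uniform stride over the training steps is taken.
#' @param rng A [rng_stream()] for the stochastic intermediate steps.
#' @return (H, W, C) array, the target-modality estimate.
#' @export
fadm_sample <- function(source, provider, net, sched, n_infer_steps = NULL,
                        rng = rng_stream(0L)) {
  src <- as_image(source)
  Tn <- sched$n_steps
  if (is.null(n_infer_steps)) n_infer_steps <- Tn
  if (n_infer_steps < 1 || n_infer_steps > Tn)
    stop("fadm_sample: n_infer_steps must be in [1, T]")
  ts <- unique(round(seq(Tn, 0, length.out = n_infer_steps + 1L)))
  cond <- provider(src)
  yp <- pack_subbands(dwt2(cond))
  predict_eps <- if (inherits(net, "faunet")) {
    function(xp, t) faunet_forward(net, xp, yp, cond, t)
  } else if (is.function(net)) {
    function(xp, t) net(xp, yp, cond, t)
  } else stop("fadm_sample: net must be a faunet object or a function")
  x <- src
  for (k in seq_len(length(ts) - 1L)) {
    t <- ts[k]; t_prev <- ts[k + 1L]
    xp <- pack_subbands(dwt2(x))
    eps_hat <- idwt2(unpack_subbands(predict_eps(xp, t)))
    x <- reverse_step(x, eps_hat, t, t_prev, sched, rng)
  }
  array(pmin(pmax(x, -1), 1), dim = dim(src))
}

#' Exact noise oracle for a known target
#'
#' Returns a drop-in replacement for the denoiser that computes the true
#' `epsilon` from the known target image. With this oracle the reverse
#' trajectory must recover the target exactly (up to float tolerance), which
#' jointly verifies the posterior algebra, the packing convention and the
#' wavelet isometry; used by the correctness checks.
#'
#' @param target The known target image.
#' @param sched A [make_schedule()] object.
#' @return A function usable as the `net` argument of [fadm_sample()].
#' @export
oracle_denoiser <- function(target, sched) {
  tgt <- as_image(target)
  function(xt_packed, y_packed, cond_image, t) {
    xt <- idwt2(unpack_subbands(xt_packed))
    pack_subbands(dwt2(epsilon_target(tgt, xt, t, sched)))
  }
}
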