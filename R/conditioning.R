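# Pluggable providers of the "conditional image": a one-shot, target-like
# estimate computed from the source image, used purely to guide denoising.
# The bridge endpoints never change with the provider -- X_T is always the
# raw source. At full scale this role is played by a large pre-trained
# generative model; here the interface isolates it behind a function so such
# a model can be slotted in, and two desk-scale providers ship by default.

#' Identity conditioning provider
#'
#' Returns the source unchanged; the ablation baseline for conditioning.
#' Called with no arguments it returns the provider function itself, so both
#' `identity_provider(x)` and `provider <- identity_provider()` work.
#'
#' @param source An image, or missing to obtain the provider object.
#' @return The source image, or a `condition_provider` function.
#' @export
identity_provider <- function(source) {
  f <- structure(function(source) as_image(source),
                 name = "identity", class = c("condition_provider", "function"))
  if (missing(source)) return(f)
  f(source)
}

#' Fit the regression conditioning provider
#'
#' A small convolutional network (`depth` 3x3 convolutions with SiLU between
#' them) fitted with a mean-absolute-error objective to map source images to
#' targets in one pass. The result is used only as conditioning -- it is
#' never evaluated as the final output -- and is deterministic once fitted.
#' The default depth of 3 gives the network two nonlinearities, enough to
#' represent a non-monotone intensity lookup with local context.
#'
#' @param pairs List of `phantom_pair`s (or any objects with `source` and
#'   `target` images) to fit on; use the training split only.
#' @param hidden Hidden channel count.
#' @param depth Number of convolution layers (>= 2).
#' @param iterations Optimization steps.
#' @param learning_rate AdamW learning rate.
#' @param seed Integer seed.
#' @param verbose Print progress.
#' @return A `condition_provider` function mapping a source image to a
#'   conditional image of the same shape, values in [-1, 1].
#' @export
fit_regression_provider <- function(pairs, hidden = 32L, depth = 3L,
                                    iterations = 2500L,
                                    learning_rate = 5e-3, seed = 1L,
                                    verbose = FALSE) {
  stopifnot(length(pairs) >= 1, depth >= 2)
  rng <- rng_stream(seed)
  src0 <- as_image(pairs[[1]]$source)
  C <- dim(src0)[3]
  chs <- c(C, rep(hidden, depth - 1L), C)
  params <- list()
  for (k in seq_len(depth)) {
    params[[paste0("W", k)]] <- mat_init(rng, 9L * chs[k], chs[k + 1L],
                                         sqrt(2 / (9 * chs[k])))
    params[[paste0("b", k)]] <- zeros(1L, chs[k + 1L])
  }
  fwd <- function(pn, tp, x_mat, h, w) {
    cur <- td_leaf(tp, x_mat)
    for (k in seq_len(depth)) {
      cur <- td_addbias(tp, td_mm(tp,
               td_im2col3(tp, cur, conv3_idx(h, w), h * w),
               pn[[paste0("W", k)]]), pn[[paste0("b", k)]])
      if (k < depth) cur <- td_silu(tp, cur)
    }
    cur
  }
  opt <- adamw_init(params)
  for (it in seq_len(iterations)) {
    k <- rng_int(rng, 1L, length(pairs))
    src <- as_image(pairs[[k]]$source); tgt <- as_image(pairs[[k]]$target)
    d <- dim(src)
    tp <- new_tape()
    pn <- lapply(params, function(v) td_leaf(tp, v, requires_grad = TRUE))
    out <- fwd(pn, tp, matrix(src, ncol = d[3]), d[1], d[2])
    loss <- td_mean_abs_diff(tp, out, matrix(tgt, ncol = d[3]))
    td_backward(tp, loss)
    grads <- lapply(pn, function(nd) if (is.null(nd$grad)) 0 * nd$value else nd$grad)
    upd <- adamw_step(params, grads, opt, lr = learning_rate)
    params <- upd$params; opt <- upd$state
    if (verbose && it %% 100L == 0L)
      message(sprintf("regression provider iter %d loss %.4f", it, loss$value))
  }
  force(params)
  f <- structure(function(source) {
    x <- as_image(source)
    d <- dim(x)
    tp <- new_tape()
    pn <- lapply(params, function(v) td_leaf(tp, v))
    out <- fwd(pn, tp, matrix(x, ncol = d[3]), d[1], d[2])
    array(pmin(pmax(out$value, -1), 1), dim = d)
  }, name = "regression", class = c("condition_provider", "function"))
  f
}

#' Resolve a conditioning provider by name or function
#'
#' @param provider `"identity"`, `"regression"`, or a function mapping an
#'   image to an image of the same shape.
#' @param train_pairs Training pairs, required to fit `"regression"`.
#' @param seed Seed for provider fitting.
#' @param ... Passed to [fit_regression_provider()].
#' @return A `condition_provider` function.
#' @export
condition_provider <- function(provider, train_pairs = NULL, seed = 1L, ...) {
  if (is.function(provider)) {
    if (!inherits(provider, "condition_provider"))
      provider <- structure(provider, name = "custom",
                            class = c("condition_provider", "function"))
    return(provider)
  }
  switch(match.arg(provider, c("regression", "identity")),
    identity = identity_provider(),
    regression = {
      if (is.null(train_pairs))
        stop("condition_provider: the regression provider must be fitted; supply train_pairs")
      fit_regression_provider(train_pairs, seed = seed, ...)
    })
}

#' @export
print.condition_provider <- function(x, ...) {
  cat(sprintf("Condition provider: %s\n", attr(x, "name") %||% "custom"))
  invisible(x)
}
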