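# Training: wavelet-domain noise-prediction loss with decoupled-weight-decay
# Adam. For each draw, a time index t is sampled uniformly in 1..T, the
# bridge state x_t is drawn from the analytic posterior, the regression
# target eps = (x_t - x0)/sigma_t is formed in pixel space, and x_t, the
# conditional image and eps are all moved to the wavelet-packed domain where
# the network predicts and the squared error is taken. Under the orthonormal
# Haar transform this loss equals the pixel-domain MSE exactly (isometry),
# which is covered by a test.

adamw_init <- function(params) {
  list(m = lapply(params, function(v) 0 * v),
       v = lapply(params, function(v) 0 * v),
       step = 0L)
}

adamw_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       weight_decay = 1e-4) {
  state$step <- state$step + 1L
  b1c <- 1 - beta1^state$step
  b2c <- 1 - beta2^state$step
  for (k in names(params)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    mhat <- state$m[[k]] / b1c
    vhat <- state$v[[k]] / b2c
    params[[k]] <- params[[k]] - lr * (mhat / (sqrt(vhat) + eps) +
                                       weight_decay * params[[k]])
  }
  list(params = params, state = state)
}

# precompute the per-pair quantities that do not change during training
prep_pair <- function(pair, provider, levels) {
  src <- as_image(pair$source); tgt <- as_image(pair$target)
  cond <- provider(src)
  yp <- pack_subbands(dwt2(cond))
  list(source = src, target = tgt, cond = cond,
       y_mat = matrix(yp, ncol = dim(yp)[3]),
       s_mats = cond_detail_mats(cond, levels))
}

# loss and parameter gradients for one prepared pair at time t
pair_loss_grads <- function(prep, params, cfg, sched, t, rng, want_grads = TRUE) {
  xt <- sample_xt(prep$target, prep$source, t, sched, rng)
  eps <- epsilon_target(prep$target, xt, t, sched)
  xp <- pack_subbands(dwt2(xt))
  ep <- pack_subbands(dwt2(eps))
  d <- dim(xp)
  x_in <- cbind(matrix(xp, ncol = d[3]), prep$y_mat)
  faunet_run(params, cfg, x_in, prep$s_mats, t, d[1], d[2],
             target = matrix(ep, ncol = d[3]), want_grads = want_grads)
}

#' One optimization step of the denoiser
#'
#' Samples a uniform time index per batch element, draws the bridge state,
#' forms the wavelet-packed noise target, runs the network, and applies one
#' AdamW update on the mean squared error averaged over the batch.
#'
#' @param batch List of `phantom_pair`s.
#' @param provider A `condition_provider` function.
#' @param net A [faunet_init()] object.
#' @param sched A [make_schedule()] object.
#' @param rng A [rng_stream()].
#' @param opt_state AdamW state (`NULL` to initialize).
#' @param learning_rate,weight_decay Optimizer settings.
#' @return List with `loss` (scalar batch loss), updated `net` and
#'   `opt_state`.
#' @export
training_step <- function(batch, provider, net, sched, rng, opt_state = NULL,
                          learning_rate = 2e-3, weight_decay = 1e-4) {
  stopifnot(inherits(net, "faunet"))
  cfg <- net$config
  if (is.null(opt_state)) opt_state <- adamw_init(net$params)
  total <- 0
  grads <- NULL
  ts <- rng_int(rng, length(batch), sched$n_steps)
  for (i in seq_along(batch)) {
    prep <- if (!is.null(batch[[i]]$y_mat)) batch[[i]]
            else prep_pair(batch[[i]], provider, cfg$levels)
    res <- pair_loss_grads(prep, net$params, cfg, sched, ts[i], rng)
    if (!is.finite(res$loss))
      stop(sprintf("training_step: non-finite loss at t = %d (batch element %d)",
                   ts[i], i))
    total <- total + res$loss
    grads <- if (is.null(grads)) res$grads
             else Map(`+`, grads, res$grads)
  }
  grads <- lapply(grads, function(g) g / length(batch))
  upd <- adamw_step(net$params, grads, opt_state, lr = learning_rate,
                    weight_decay = weight_decay)
  net$params <- upd$params
  list(loss = total / length(batch), net = net, opt_state = upd$state)
}

# deterministic validation loss: fixed time strata and a per-call seed
validation_loss <- function(preps, params, cfg, sched, seed) {
  rng <- rng_stream(seed)
  ts <- rng_int(rng, length(preps), sched$n_steps)
  tot <- 0
  for (i in seq_along(preps)) {
    res <- pair_loss_grads(preps[[i]], params, cfg, sched, ts[i], rng,
                           want_grads = FALSE)
    tot <- tot + res$loss
  }
  tot / length(preps)
}

#' Select the best checkpoint from a validation history
#'
#' Returns the index of the minimum validation loss; ties break toward the
#' later iteration (the longer-trained model).
#'
#' @param history Numeric vector of validation losses, in iteration order.
#' @return 1-based index of the chosen checkpoint.
#' @export
checkpoint_select <- function(history) {
  if (length(history) < 1) stop("checkpoint_select: empty validation history")
  max(which(history == min(history)))
}

# main training loop; returns the best-validation network plus history
fadm_train <- function(data, net, sched, provider,
                       iterations = 2000L, batch_size = 4L,
                       learning_rate = 2e-3, weight_decay = 1e-4,
                       validation_interval = 100L, seed = 1L,
                       verbose = TRUE) {
  cfg <- net$config
  preps <- lapply(data$train, prep_pair, provider = provider, levels = cfg$levels)
  vpreps <- lapply(data$val, prep_pair, provider = provider, levels = cfg$levels)
  rng <- rng_stream(seed)
  opt <- adamw_init(net$params)
  history <- data.frame(iteration = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best <- list(loss = Inf, params = net$params, iteration = 0L)
  run_mean <- NULL
  for (it in seq_len(iterations)) {
    idx <- rng_int(rng, batch_size, length(preps))
    st <- training_step(preps[idx], provider, net, sched, rng, opt,
                        learning_rate = learning_rate,
                        weight_decay = weight_decay)
    net <- st$net; opt <- st$opt_state
    run_mean <- if (is.null(run_mean)) st$loss else 0.98 * run_mean + 0.02 * st$loss
    if (it %% validation_interval == 0L || it == iterations) {
      vl <- if (length(vpreps))
        validation_loss(vpreps, net$params, cfg, sched,
                        seed = (as.double(seed) * 31 + it) %% 2147483647)
      else run_mean
      history <- rbind(history, data.frame(iteration = it, train_loss = run_mean,
                                           val_loss = vl))
      if (vl <= best$loss) best <- list(loss = vl, params = net$params,
                                        iteration = it)
      if (verbose)
        message(sprintf("iter %5d  train %.5f  val %.5f", it, run_mean, vl))
    }
  }
  sel <- checkpoint_select(history$val_loss)
  net$params <- best$params
  list(net = net, history = history, best_iteration = history$iteration[sel],
       best_val_loss = history$val_loss[sel])
}

#' Save / load a training checkpoint
#'
#' The checkpoint bundles the parameter tree, the architecture config, the
#' noise schedule and the seed, so sampling can resume exactly.
#'
#' @param net A [faunet_init()] object.
#' @param sched A [make_schedule()] object.
#' @param path Destination file (RDS).
#' @param extra Optional named list stored alongside (e.g. provider info).
#' @export
save_checkpoint <- function(net, sched, path, extra = list()) {
  saveRDS(c(list(params = net$params, config = unclass(net$config),
                 schedule = unclass(sched)), extra), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  v <- readRDS(path)
  cfg <- structure(v$config, class = "faunet_config")
  list(net = structure(list(params = v$params, config = cfg), class = "faunet"),
       sched = structure(v$schedule, class = "noise_schedule"),
       extra = v[setdiff(names(v), c("params", "config", "schedule"))])
}
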