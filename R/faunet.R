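# Frequency-aware U-Net denoiser (FAUnet).
#
# The network predicts bridge noise in the wavelet-packed domain. Encoder
# levels downsample with a wavelet downsampling layer (Haar DWT -> channel
# concatenation -> learned 1x1 projection) instead of strided convolution,
# with an extra wavelet shortcut mapping the raw input onto the first
# downsampled pyramid level. The bottleneck applies residual blocks and
# single-head self-attention. Decoder levels upsample, concatenate the
# encoder skip, and (optionally) a high-frequency supervision module (HFSM):
# cross-attention whose queries are a 1x1 projection of the conditional
# image's summed detail sub-bands at the matching resolution and whose
# keys/values come from the decoder feature map. The HFSM output augments
# (is concatenated with) the skip, never substituted for it.
#
# A sinusoidal time embedding passed through a two-layer MLP is injected
# into every residual block via a learned per-block projection. Residual
# blocks, attention and the output head are pre-activation normalized
# (channelwise RMS norm with learned gain) so feature scales stay bounded
# through training.

#' Denoiser architecture description
#'
#' @param image_channels Channels C of the pixel-domain images (1 for
#'   grayscale slices, 3 for adjacent-slice stacks).
#' @param levels Encoder/decoder depth M (>= 1).
#' @param base_channels Channels at the first level.
#' @param channel_multipliers Length-`levels` positive integers; level l has
#'   `base_channels * channel_multipliers[l]` channels. Default doubles per
#'   level.
#' @param attn_levels Levels (subset of `1:levels`) with self-attention after
#'   the encoder residual block; the bottleneck always has self-attention.
#' @param hfsm_levels Decoder levels with an HFSM block. Default: all.
#' @param time_embed_dim Even positive integer, dimension of the sinusoidal
#'   time embedding.
#' @param downsample `"wavelet"` (the frequency-aware layer) or `"strided"`
#'   (plain strided convolution, the ablation baseline; disables the wavelet
#'   input shortcut).
#' @param n_condition_images Number of wavelet-packed conditioning images
#'   concatenated to the input (1: the conditional image).
#' @return An object of class `faunet_config`.
#' @export
faunet_config <- function(image_channels = 1L,
                          levels = 2L,
                          base_channels = 16L,
                          channel_multipliers = NULL,
                          attn_levels = integer(0),
                          hfsm_levels = seq_len(levels),
                          time_embed_dim = 32L,
                          downsample = c("wavelet", "strided"),
                          n_condition_images = 1L) {
  downsample <- match.arg(downsample)
  if (levels < 1 || levels != round(levels)) stop("levels must be a positive integer")
  levels <- as.integer(levels)
  if (is.null(channel_multipliers)) channel_multipliers <- 2L^(seq_len(levels) - 1L)
  if (length(channel_multipliers) != levels || any(channel_multipliers < 1))
    stop("channel_multipliers must be a length-`levels` vector of positive integers")
  if (length(attn_levels) && !all(attn_levels %in% seq_len(levels)))
    stop("attn_levels must be a subset of 1:levels")
  if (length(hfsm_levels) && !all(hfsm_levels %in% seq_len(levels)))
    stop("hfsm_levels must be a subset of 1:levels")
  if (time_embed_dim < 2 || time_embed_dim %% 2 != 0)
    stop("time_embed_dim must be an even positive integer")
  C <- as.integer(image_channels)
  structure(list(
    image_channels = C,
    levels = levels,
    base_channels = as.integer(base_channels),
    channel_multipliers = as.integer(channel_multipliers),
    attn_levels = as.integer(attn_levels),
    hfsm_levels = as.integer(sort(hfsm_levels)),
    time_embed_dim = as.integer(time_embed_dim),
    downsample = downsample,
    n_condition_images = as.integer(n_condition_images),
    in_channels = 4L * C * (1L + as.integer(n_condition_images)),
    out_channels = 4L * C
  ), class = "faunet_config")
}

#' @export
print.faunet_config <- function(x, ...) {
  cat(sprintf(
    "FAUnet config: %d level(s), channels %s, %s downsampling, HFSM at {%s}, in/out %d/%d\n",
    x$levels,
    paste(x$base_channels * x$channel_multipliers, collapse = "/"),
    x$downsample,
    paste(x$hfsm_levels, collapse = ","),
    x$in_channels, x$out_channels))
  invisible(x)
}

# per-level channel counts; bottleneck keeps the deepest level's width
cfg_channels <- function(cfg) {
  ch <- cfg$base_channels * cfg$channel_multipliers
  list(ch = ch, bot = ch[cfg$levels])
}

#' Sinusoidal time-step embedding
#'
#' Interleaved sine/cosine embedding: odd positions carry
#' `sin(t * f_i)`, even positions `cos(t * f_i)` with geometrically spaced
#' frequencies, so t = 0 maps to the alternating 0/1 pattern.
#'
#' @param t Non-negative time index.
#' @param dim Even embedding dimension.
#' @return Numeric vector of length `dim`.
#' @export
time_embedding <- function(t, dim) {
  if (length(dim) != 1 || dim < 2 || dim %% 2 != 0)
    stop("time_embedding: dim must be an even positive integer")
  if (length(t) != 1 || t < 0) stop("time_embedding: t must be a single value >= 0")
  half <- dim %/% 2L
  expo <- if (half > 1L) (seq_len(half) - 1L) / (half - 1L) else 0
  freq <- 10000^(-expo)
  out <- numeric(dim)
  out[seq(1L, dim, 2L)] <- sin(t * freq)
  out[seq(2L, dim, 2L)] <- cos(t * freq)
  out
}

# ---- parameter initialization ----

mat_init <- function(rng, nr, nc, sd) matrix(rng_norm(rng, nr * nc) * sd, nr, nc)
zeros <- function(nr, nc) matrix(0, nr, nc)

#' Initialize FAUnet parameters
#'
#' Convolution weights use He-style normal initialization
#' (sd = sqrt(2 / fan_in)); attention and HFSM projections use
#' sd = sqrt(1 / fan_in); the final output convolution starts at tiny scale
#' (sd = 1e-3) so early noise predictions are near zero while gradients still
#' reach every upstream branch.
#'
#' @param config A [faunet_config()].
#' @param seed Integer seed for the initialization stream.
#' @return An object of class `faunet`: list with `params` (named list of
#'   matrices) and `config`.
#' @export
faunet_init <- function(config, seed = 1L) {
  stopifnot(inherits(config, "faunet_config"))
  rng <- rng_stream(seed)
  chs <- cfg_channels(config)
  ch <- chs$ch; bot <- chs$bot
  M <- config$levels
  D <- config$time_embed_dim
  p <- list()
  conv <- function(cin, cout) mat_init(rng, 9L * cin, cout, sqrt(2 / (9 * cin)))
  lin <- function(cin, cout, sd = sqrt(2 / cin)) mat_init(rng, cin, cout, sd)
  add_rb <- function(name, cin, cout) {
    p[[paste0(name, ".g1")]] <<- matrix(1, 1L, cin)
    p[[paste0(name, ".g2")]] <<- matrix(1, 1L, cout)
    p[[paste0(name, ".W1")]] <<- conv(cin, cout)
    p[[paste0(name, ".b1")]] <<- zeros(1L, cout)
    p[[paste0(name, ".Wt")]] <<- lin(D, cout)
    p[[paste0(name, ".bt")]] <<- zeros(1L, cout)
    p[[paste0(name, ".W2")]] <<- conv(cout, cout)
    p[[paste0(name, ".b2")]] <<- zeros(1L, cout)
    if (cin != cout) p[[paste0(name, ".Wskip")]] <<- lin(cin, cout, sqrt(1 / cin))
  }
  add_attn <- function(name, c0) {
    p[[paste0(name, ".g")]] <<- matrix(1, 1L, c0)
    for (w in c("Wq", "Wk", "Wv", "Wo"))
      p[[paste0(name, ".", w)]] <<- lin(c0, c0, sqrt(1 / c0))
    p[[paste0(name, ".bo")]] <<- zeros(1L, c0)
  }
  p[["temb.W1"]] <- lin(D, D); p[["temb.b1"]] <- zeros(1L, D)
  p[["temb.W2"]] <- lin(D, D); p[["temb.b2"]] <- zeros(1L, D)
  p[["stem.W"]] <- conv(config$in_channels, ch[1]); p[["stem.b"]] <- zeros(1L, ch[1])
  for (l in seq_len(M)) {
    add_rb(sprintf("enc%d", l), ch[l], ch[l])
    if (l %in% config$attn_levels) add_attn(sprintf("attn.enc%d", l), ch[l])
    cnext <- if (l < M) ch[l + 1L] else bot
    if (config$downsample == "wavelet") {
      p[[sprintf("down%d.W", l)]] <- lin(4L * ch[l], cnext, sqrt(2 / (4 * ch[l])))
    } else {
      p[[sprintf("down%d.W", l)]] <- conv(ch[l], cnext)
    }
    p[[sprintf("down%d.b", l)]] <- zeros(1L, cnext)
  }
  if (config$downsample == "wavelet") {
    ctgt <- if (M >= 2L) ch[2] else bot
    p[["shortcut.W"]] <- lin(4L * config$in_channels, ctgt,
                             sqrt(2 / (4 * config$in_channels)))
    p[["shortcut.b"]] <- zeros(1L, ctgt)
  }
  add_rb("bot1", bot, bot)
  add_attn("attn.bot", bot)
  add_rb("bot2", bot, bot)
  for (l in rev(seq_len(M))) {
    cfrom <- if (l == M) bot else ch[l + 1L]
    p[[sprintf("up%d.W", l)]] <- conv(cfrom, ch[l])
    p[[sprintf("up%d.b", l)]] <- zeros(1L, ch[l])
    nin <- 2L * ch[l]
    if (l %in% config$hfsm_levels) {
      p[[sprintf("hfsm%d.Wq", l)]] <- lin(config$image_channels, ch[l],
                                          sqrt(1 / config$image_channels))
      p[[sprintf("hfsm%d.bq", l)]] <- zeros(1L, ch[l])
      p[[sprintf("hfsm%d.Wk", l)]] <- lin(ch[l], ch[l], sqrt(1 / ch[l]))
      p[[sprintf("hfsm%d.bk", l)]] <- zeros(1L, ch[l])
      p[[sprintf("hfsm%d.Wv", l)]] <- lin(ch[l], ch[l], sqrt(1 / ch[l]))
      p[[sprintf("hfsm%d.bv", l)]] <- zeros(1L, ch[l])
      nin <- nin + ch[l]
    }
    add_rb(sprintf("dec%d", l), nin, ch[l])
  }
  p[["out.g"]] <- matrix(1, 1L, ch[1])
  p[["out.W"]] <- mat_init(rng, 9L * ch[1], config$out_channels, 1e-3)
  p[["out.b"]] <- zeros(1L, config$out_channels)
  structure(list(params = p, config = config), class = "faunet")
}

#' @export
print.faunet <- function(x, ...) {
  n <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("FAUnet denoiser: %d parameters\n", n))
  print(x$config)
  invisible(x)
}

# ---- tape-level building blocks ----

td_conv3 <- function(tp, x, Wn, bn, h, w)
  td_addbias(tp, td_mm(tp, td_im2col3(tp, x, conv3_idx(h, w), h * w), Wn), bn)

td_resblock <- function(tp, x, temb_s, pn, name, h, w) {
  g <- function(s) pn[[paste0(name, ".", s)]]
  h1 <- td_conv3(tp, td_silu(tp, td_rmsnorm(tp, x, g("g1"))), g("W1"), g("b1"), h, w)
  tproj <- td_addbias(tp, td_mm(tp, temb_s, g("Wt")), g("bt"))
  h1 <- td_addrow(tp, h1, tproj)
  h2 <- td_conv3(tp, td_silu(tp, td_rmsnorm(tp, h1, g("g2"))), g("W2"), g("b2"), h, w)
  skip <- if (!is.null(g("Wskip"))) td_mm(tp, x, g("Wskip")) else x
  td_add(tp, h2, skip)
}

td_self_attn <- function(tp, x, pn, name) {
  g <- function(s) pn[[paste0(name, ".", s)]]
  dk <- ncol(x$value)
  xn <- td_rmsnorm(tp, x, g("g"))
  q <- td_mm(tp, xn, g("Wq")); k <- td_mm(tp, xn, g("Wk")); v <- td_mm(tp, xn, g("Wv"))
  A <- td_softmax_rows(tp, td_scale(tp, td_mmT(tp, q, k), 1 / sqrt(dk)))
  o <- td_addbias(tp, td_mm(tp, td_mm(tp, A, v), g("Wo")), g("bo"))
  td_add(tp, x, o)
}

td_hfsm <- function(tp, m, s_const, pn, name) {
  g <- function(s) pn[[paste0(name, ".", s)]]
  S <- td_leaf(tp, s_const)
  Q <- td_addbias(tp, td_mm(tp, S, g("Wq")), g("bq"))
  K <- td_addbias(tp, td_mm(tp, m, g("Wk")), g("bk"))
  V <- td_addbias(tp, td_mm(tp, m, g("Wv")), g("bv"))
  A <- td_softmax_rows(tp, td_scale(tp, td_mmT(tp, Q, K), 1 / sqrt(ncol(Q$value))))
  td_mm(tp, A, V)
}

# Full forward pass on a tape. x_in_mat: (Ph*Pw, in_channels) packed input;
# s_mats: list indexed by decoder level of summed detail-band matrices (or
# NULL); geometry (Ph, Pw) is the packed spatial size.
faunet_run <- function(params, cfg, x_in_mat, s_mats, t, Ph, Pw,
                       target = NULL, want_grads = FALSE) {
  tp <- new_tape()
  pn <- lapply(params, function(v) td_leaf(tp, v, requires_grad = want_grads))
  M <- cfg$levels
  chs <- cfg_channels(cfg)
  temb0 <- td_leaf(tp, matrix(time_embedding(t, cfg$time_embed_dim), 1L))
  th <- td_silu(tp, td_addbias(tp, td_mm(tp, temb0, pn[["temb.W1"]]), pn[["temb.b1"]]))
  temb_s <- td_silu(tp, td_addbias(tp, td_mm(tp, th, pn[["temb.W2"]]), pn[["temb.b2"]]))
  x_in <- td_leaf(tp, x_in_mat)
  hh <- Ph; ww <- Pw
  cur <- td_conv3(tp, x_in, pn[["stem.W"]], pn[["stem.b"]], hh, ww)
  cur <- td_resblock(tp, cur, temb_s, pn, "enc1", hh, ww)
  if (1L %in% cfg$attn_levels) cur <- td_self_attn(tp, cur, pn, "attn.enc1")
  feats <- vector("list", M)
  dims <- vector("list", M)
  feats[[1]] <- cur; dims[[1]] <- c(hh, ww)
  for (l in seq_len(M)) {
    if (cfg$downsample == "wavelet") {
      d <- td_addbias(tp, td_mm(tp, td_dwt_pack(tp, cur, haar_phase_idx(hh, ww)),
                                pn[[sprintf("down%d.W", l)]]),
                      pn[[sprintf("down%d.b", l)]])
    } else {
      full <- td_conv3(tp, cur, pn[[sprintf("down%d.W", l)]],
                       pn[[sprintf("down%d.b", l)]], hh, ww)
      d <- td_gather0(tp, full, stride2_idx(hh, ww))
    }
    if (l == 1L && !is.null(pn[["shortcut.W"]])) {
      sc <- td_addbias(tp, td_mm(tp, td_dwt_pack(tp, x_in, haar_phase_idx(Ph, Pw)),
                                 pn[["shortcut.W"]]), pn[["shortcut.b"]])
      d <- td_add(tp, d, sc)
    }
    hh <- hh %/% 2L; ww <- ww %/% 2L
    if (l < M) {
      cur <- td_resblock(tp, d, temb_s, pn, sprintf("enc%d", l + 1L), hh, ww)
      if ((l + 1L) %in% cfg$attn_levels)
        cur <- td_self_attn(tp, cur, pn, sprintf("attn.enc%d", l + 1L))
      feats[[l + 1L]] <- cur; dims[[l + 1L]] <- c(hh, ww)
    } else {
      cur <- d
    }
  }
  cur <- td_resblock(tp, cur, temb_s, pn, "bot1", hh, ww)
  cur <- td_self_attn(tp, cur, pn, "attn.bot")
  cur <- td_resblock(tp, cur, temb_s, pn, "bot2", hh, ww)
  for (l in rev(seq_len(M))) {
    up <- td_gather0(tp, cur, upsample2_idx(hh, ww))
    hh <- hh * 2L; ww <- ww * 2L
    x_up <- td_conv3(tp, up, pn[[sprintf("up%d.W", l)]],
                     pn[[sprintf("up%d.b", l)]], hh, ww)
    parts <- list(x_up, feats[[l]])
    if (l %in% cfg$hfsm_levels)
      parts <- c(parts, list(td_hfsm(tp, x_up, s_mats[[l]], pn, sprintf("hfsm%d", l))))
    cur <- td_resblock(tp, td_cbind(tp, parts), temb_s, pn, sprintf("dec%d", l), hh, ww)
  }
  out <- td_conv3(tp, td_silu(tp, td_rmsnorm(tp, cur, pn[["out.g"]])),
                  pn[["out.W"]], pn[["out.b"]], hh, ww)
  res <- list(out = out$value)
  if (!is.null(target)) {
    loss <- td_mean_sq_diff(tp, out, target)
    res$loss <- loss$value
    if (want_grads) {
      td_backward(tp, loss)
      res$grads <- lapply(pn, function(nd) {
        if (is.null(nd$grad)) 0 * nd$value else nd$grad
      })
    }
  }
  res
}

# summed detail-band matrices of the conditional image, one per level
cond_detail_mats <- function(cond_image, levels) {
  if (is.null(cond_image)) return(NULL)
  stacks <- dwt_multilevel(cond_image, levels)
  lapply(stacks, function(s) {
    v <- s$lh + s$hl + s$hh
    matrix(v, ncol = dim(v)[3])
  })
}

#' Run the denoiser forward
#'
#' Predicts wavelet-packed noise for a packed bridge state, conditioned on a
#' packed conditional image (channel-concatenated at the input) and on the
#' conditional image's high-frequency sub-bands (through the HFSM path).
#' Deterministic given parameters and inputs.
#'
#' @param net A [faunet_init()] object.
#' @param xt_packed (h, w, 4C) wavelet-packed bridge state.
#' @param y_packed (h, w, 4C) wavelet-packed conditional image; must match
#'   `xt_packed` spatially.
#' @param cond_image Pixel-domain conditional image (2h, 2w, C); required
#'   when the config has HFSM levels, otherwise may be `NULL`.
#' @param t Integer time index.
#' @return (h, w, 4C) array of predicted noise.
#' @export
faunet_forward <- function(net, xt_packed, y_packed, cond_image, t) {
  stopifnot(inherits(net, "faunet"))
  cfg <- net$config
  xt_packed <- as_image(xt_packed); y_packed <- as_image(y_packed)
  dx <- dim(xt_packed); dy <- dim(y_packed)
  if (!identical(dx, dy))
    stop(sprintf("faunet_forward: xt_packed (%s) and y_packed (%s) shapes differ",
                 paste(dx, collapse = "x"), paste(dy, collapse = "x")))
  if (dx[3] + dy[3] * cfg$n_condition_images != cfg$in_channels)
    stop(sprintf(
      "faunet_forward: packed inputs provide %d channels but the config expects %d",
      dx[3] + dy[3] * cfg$n_condition_images, cfg$in_channels))
  s_mats <- NULL
  if (length(cfg$hfsm_levels)) {
    if (is.null(cond_image))
      stop("faunet_forward: cond_image is required when the config has HFSM levels")
    s_mats <- cond_detail_mats(as_image(cond_image), cfg$levels)
  }
  x_in <- cbind(matrix(xt_packed, ncol = dx[3]), matrix(y_packed, ncol = dy[3]))
  res <- faunet_run(net$params, cfg, x_in, s_mats, t, dx[1], dx[2])
  array(res$out, dim = c(dx[1], dx[2], cfg$out_channels))
}

#' Wavelet downsampling layer (standalone)
#'
#' One encoder downsampling stage: per-channel single-level Haar DWT, channel
#' concatenation of the four sub-bands (4x channels, half spatial size), and
#' a learned 1x1 projection to `target_channels`. Exposed standalone for
#' inspection and testing; the network uses the same arithmetic internally.
#'
#' @param features (h, w, c) array with even h, w.
#' @param weights List with `W` (a 4c x k projection matrix) and optional
#'   `b` (length-k bias).
#' @return (h/2, w/2, k) array.
#' @export
wavelet_downsample_layer <- function(features, weights) {
  x <- as_image(features)
  d <- dim(x)
  check_even(d[1], d[2], "wavelet_downsample_layer")
  packed <- pack_subbands(dwt2(x))
  m <- matrix(packed, ncol = 4L * d[3])
  W <- weights$W
  if (nrow(W) != 4L * d[3])
    stop(sprintf("wavelet_downsample_layer: W has %d rows, expected %d",
                 nrow(W), 4L * d[3]))
  out <- m %*% W
  if (!is.null(weights$b)) out <- sweep(out, 2L, as.numeric(weights$b), "+")
  array(out, dim = c(d[1] %/% 2L, d[2] %/% 2L, ncol(W)))
}

#' High-frequency supervision module (standalone)
#'
#' Cross-attention in which the query comes from the conditional image's
#' summed detail sub-bands (`lh + hl + hh`) through a 1x1 projection, and
#' keys/values are 1x1 projections of the feature map `m`. Attention is
#' single-head over flattened spatial positions with scaling `1/sqrt(d_k)`,
#' `d_k` the projected feature dimension.
#'
#' @param m (h, w, ch) feature map.
#' @param cond_subbands A `subband_stack` whose detail bands are (h, w, C).
#' @param weights List with `Wq` (C x ch), `Wk`, `Wv` (ch x ch) and optional
#'   biases `bq`, `bk`, `bv`. Default: identity projections (requires
#'   C == ch).
#' @return List with `output` ((h, w, ch) array, same shape as `m`) and
#'   `attention` (the (hw x hw) row-stochastic attention matrix).
#' @export
hfsm <- function(m, cond_subbands, weights = NULL) {
  m <- as_image(m)
  b <- check_stack(cond_subbands)
  dm <- dim(m); db <- dim(b$lh)
  if (!identical(dm[1:2], db[1:2]))
    stop(sprintf("hfsm: feature map is %s but detail bands are %s",
                 paste(dm[1:2], collapse = "x"), paste(db[1:2], collapse = "x")))
  ch <- dm[3]; C <- db[3]
  if (is.null(weights)) {
    if (C != ch)
      stop("hfsm: default identity projections need matching channel counts")
    weights <- list(Wq = diag(ch), Wk = diag(ch), Wv = diag(ch))
  }
  S <- matrix(b$lh + b$hl + b$hh, ncol = C)
  Mm <- matrix(m, ncol = ch)
  lin1 <- function(x, W, bias) {
    out <- x %*% W
    if (!is.null(bias)) out <- sweep(out, 2L, as.numeric(bias), "+")
    out
  }
  Q <- lin1(S, weights$Wq, weights$bq)
  K <- lin1(Mm, weights$Wk, weights$bk)
  V <- lin1(Mm, weights$Wv, weights$bv)
  logits <- tcrossprod(Q, K) / sqrt(ncol(Q))
  e <- exp(logits - apply(logits, 1L, max))
  A <- e / rowSums(e)
  list(output = array(A %*% V, dim = dm), attention = A)
}

#' Serialize / restore a denoiser config
#'
#' @param config A [faunet_config()].
#' @param path File path for the YAML description.
#' @export
write_faunet_config <- function(config, path) {
  stopifnot(inherits(config, "faunet_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_faunet_config
#' @export
read_faunet_config <- function(path) {
  v <- yaml::read_yaml(path)
  faunet_config(
    image_channels = v$image_channels, levels = v$levels,
    base_channels = v$base_channels, channel_multipliers = v$channel_multipliers,
    attn_levels = as.integer(unlist(v$attn_levels)),
    hfsm_levels = as.integer(unlist(v$hfsm_levels)),
    time_embed_dim = v$time_embed_dim, downsample = v$downsample,
    n_condition_images = v$n_condition_images)
}
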