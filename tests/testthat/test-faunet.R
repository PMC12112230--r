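test_that("time embedding has the closed form at t = 0 and separates time points", {
  e0 <- time_embedding(0, 16)
  expect_equal(e0[seq(1, 16, 2)], rep(0, 8))  # sines
  expect_equal(e0[seq(2, 16, 2)], rep(1, 8))  # cosines
  embs <- vapply(0:20, time_embedding, numeric(16), dim = 16)
  expect_equal(anyDuplicated(t(embs)), 0)
  expect_true(all(is.finite(time_embedding(1e4, 32))))
  expect_lte(max(abs(time_embedding(1e4, 32))), 1)
  expect_error(time_embedding(3, 7), "even")
})

test_that("forward pass honors the shape contract across configs and is deterministic", {
  for (M in c(2L, 3L)) for (C in c(1L, 3L)) {
    cfg <- faunet_config(image_channels = C, levels = M, base_channels = 4L,
                         time_embed_dim = 8L)
    net <- faunet_init(cfg, seed = M * 10L + C)
    n <- 2L^(M + 2L)  # pixel size supporting M levels below the packed domain
    img <- rand_image(n, c = C, seed = 1)
    xp <- pack_subbands(dwt2(rand_image(n, c = C, seed = 2)))
    yp <- pack_subbands(dwt2(rand_image(n, c = C, seed = 3)))
    out <- faunet_forward(net, xp, yp, img, 3)
    expect_equal(dim(out), dim(xp))
    expect_identical(out, faunet_forward(net, xp, yp, img, 3))
    # the time embedding is live
    expect_gt(max(abs(out - faunet_forward(net, xp, yp, img, 9))), 0)
  }
})

test_that("shape mismatches between state and conditioning are rejected", {
  cfg <- tiny_config()
  net <- faunet_init(cfg, seed = 1)
  xp <- pack_subbands(dwt2(rand_image(16, seed = 1)))
  yp_bad <- pack_subbands(dwt2(rand_image(32, seed = 2)))
  expect_error(faunet_forward(net, xp, yp_bad, rand_image(16, seed = 1), 1),
               "shapes differ")
})

test_that("wavelet downsampling layer contracts space, expands channels, kills constant detail", {
  set.seed(4)
  f <- rand_image(8, c = 3, seed = 7)
  W <- matrix(rnorm(12 * 5), 12, 5)
  out <- wavelet_downsample_layer(f, list(W = W))
  expect_equal(dim(out), c(4, 4, 5))
  # constant input: only the ll block feeds the projection
  fc <- array(0.5, dim = c(8, 8, 3))
  outc <- wavelet_downsample_layer(fc, list(W = W))
  expect_equal(as.numeric(outc),
               as.numeric(wavelet_downsample_layer(fc, list(W = rbind(W[1:3, ], matrix(0, 9, 5))))),
               tolerance = 1e-12)
  # the transform stage itself preserves energy (orthonormality)
  pk <- pack_subbands(dwt2(f))
  expect_equal(sum(pk^2), sum(f^2), tolerance = 1e-10)
  expect_error(wavelet_downsample_layer(rand_image(7, 8, seed = 1), list(W = W)),
               "height")
})

test_that("HFSM cross-attention matches brute-force matrix arithmetic", {
  # 2x2 toy feature map, identity projections, hand-computed attention
  m <- array(c(1, 0.5, -0.5, 0.25), dim = c(2, 2, 1))
  stack <- dwt2(rand_image(4, seed = 8))
  res <- hfsm(m, stack)
  S <- matrix(stack$lh + stack$hl + stack$hh, ncol = 1)
  Mm <- matrix(m, ncol = 1)
  logits <- (S %*% t(Mm)) / sqrt(1)
  A_ref <- t(apply(logits, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  expect_equal(res$attention, A_ref, tolerance = 1e-6)
  expect_equal(as.numeric(res$output), as.numeric(A_ref %*% Mm), tolerance = 1e-6)
  # rows of the attention matrix sum to one
  expect_lt(max(abs(rowSums(res$attention) - 1)), 1e-6)
  # output shape equals the feature map's shape
  expect_equal(dim(res$output), dim(m))
  # constant K: every output row is the mean of V's rows
  mk <- array(1, dim = c(2, 2, 1))
  res2 <- hfsm(mk, stack)
  expect_equal(as.numeric(res2$output), rep(mean(mk), 4), tolerance = 1e-10)
  # learned projections with larger channel counts
  set.seed(11)
  m8 <- rand_image(4, c = 6, seed = 9)
  st8 <- dwt2(rand_image(8, c = 2, seed = 10))
  w <- list(Wq = matrix(rnorm(12), 2, 6), Wk = diag(6), Wv = diag(6))
  r8 <- hfsm(m8, st8, w)
  expect_equal(dim(r8$output), dim(m8))
  expect_lt(max(abs(rowSums(r8$attention) - 1)), 1e-6)
  expect_error(hfsm(m8, dwt2(rand_image(16, seed = 1))), "feature map")
})

test_that("every parameter receives gradient and gradients match finite differences", {
  cfg <- faunet_config(levels = 2L, base_channels = 4L, time_embed_dim = 8L,
                       attn_levels = 1L)
  net <- faunet_init(cfg, seed = 3)
  sch <- make_schedule(10)
  pair <- make_phantom_pair(21, 16)
  prep <- fadm:::prep_pair(pair, identity_provider(), cfg$levels)
  res <- fadm:::pair_loss_grads(prep, net$params, cfg, sch, 4, rng_stream(5))
  expect_true(is.finite(res$loss))
  nonzero <- vapply(res$grads, function(g) any(g != 0), logical(1))
  expect_true(all(nonzero))
  # finite-difference spot checks across branch types
  res0 <- fadm:::pair_loss_grads(prep, net$params, cfg, sch, 4, rng_stream(42))
  for (pn in c("stem.W", "shortcut.W", "hfsm1.Wq", "attn.enc1.Wk",
               "attn.bot.Wv", "temb.W2", "dec2.Wskip", "out.W")) {
    h <- 1e-5
    p2 <- net$params
    p2[[pn]][1] <- p2[[pn]][1] + h
    lp <- fadm:::pair_loss_grads(prep, p2, cfg, sch, 4, rng_stream(42),
                                 want_grads = FALSE)$loss
    p2[[pn]][1] <- p2[[pn]][1] - 2 * h
    lm <- fadm:::pair_loss_grads(prep, p2, cfg, sch, 4, rng_stream(42),
                                 want_grads = FALSE)$loss
    fd <- (lp - lm) / (2 * h)
    expect_equal(res0$grads[[pn]][1], fd, tolerance = 1e-4)
  }
})

test_that("the strided ablation variant runs without wavelet shortcut or HFSM", {
  cfg <- faunet_config(levels = 2L, base_channels = 4L, time_embed_dim = 8L,
                       hfsm_levels = integer(0), downsample = "strided")
  net <- faunet_init(cfg, seed = 5)
  expect_false("shortcut.W" %in% names(net$params))
  expect_false(any(grepl("^hfsm", names(net$params))))
  xp <- pack_subbands(dwt2(rand_image(16, seed = 1)))
  out <- faunet_forward(net, xp, xp, NULL, 2)
  expect_equal(dim(out), dim(xp))
})

test_that("config serializes to YAML and back", {
  cfg <- faunet_config(levels = 3L, base_channels = 8L, attn_levels = 2L,
                       hfsm_levels = c(1L, 3L), time_embed_dim = 16L)
  f <- tempfile(fileext = ".yaml")
  write_faunet_config(cfg, f)
  cfg2 <- read_faunet_config(f)
  expect_equal(cfg2, cfg)
  expect_error(faunet_config(levels = 2, hfsm_levels = 5), "subset")
})
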