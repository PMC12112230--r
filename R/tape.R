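# Minimal reverse-mode autodiff on matrices, used internally by the denoiser.
#
# Feature maps are (n_pixels, channels) matrices, pixel order column-major in
# (H, W). Each op pushes a node holding its value and a backward closure that
# accumulates gradients into its parents; backprop walks nodes in reverse
# creation order. Only the ops the network needs are provided -- this is
# plumbing, not a general framework.

new_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 512L)
  e$n <- 0L
  e
}

tp_push <- function(tp, nd) {
  n <- tp$n + 1L
  if (n > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  tp$nodes[[n]] <- nd
  tp$n <- n
  nd
}

td_leaf <- function(tp, value, requires_grad = FALSE) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$back <- NULL
  nd$requires_grad <- requires_grad
  tp_push(tp, nd)
}

td_op <- function(tp, value, back) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$back <- back
  tp_push(tp, nd)
}

td_acc <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

td_backward <- function(tp, loss) {
  loss$grad <- 1
  for (i in seq.int(tp$n, 1L)) {
    nd <- tp$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$back)) nd$back(nd$grad)
  }
  invisible(NULL)
}

# ---- arithmetic ----

td_add <- function(tp, a, b)
  td_op(tp, a$value + b$value, function(g) { td_acc(a, g); td_acc(b, g) })

td_sub <- function(tp, a, b)
  td_op(tp, a$value - b$value, function(g) { td_acc(a, g); td_acc(b, -g) })

td_scale <- function(tp, a, s)
  td_op(tp, a$value * s, function(g) td_acc(a, g * s))

td_mm <- function(tp, a, b)
  td_op(tp, a$value %*% b$value, function(g) {
    td_acc(a, tcrossprod(g, b$value))
    td_acc(b, crossprod(a$value, g))
  })

# a %*% t(b)
td_mmT <- function(tp, a, b)
  td_op(tp, tcrossprod(a$value, b$value), function(g) {
    td_acc(a, g %*% b$value)
    td_acc(b, crossprod(g, a$value))
  })

# add per-column bias vector (parameter node b, length = ncol(a))
td_addbias <- function(tp, a, b) {
  av <- a$value
  td_op(tp, av + rep(as.numeric(b$value), each = nrow(av)), function(g) {
    td_acc(a, g)
    td_acc(b, matrix(colSums(g), nrow(b$value), ncol(b$value)))
  })
}

# add a (1 x k) row node to every row of a
td_addrow <- function(tp, a, r) {
  av <- a$value
  td_op(tp, av + rep(as.numeric(r$value), each = nrow(av)), function(g) {
    td_acc(a, g)
    td_acc(r, matrix(colSums(g), 1L))
  })
}

# ---- nonlinearities ----

td_silu <- function(tp, a) {
  x <- a$value
  s <- 1 / (1 + exp(-x))
  td_op(tp, x * s, function(g) td_acc(a, g * (s * (1 + x * (1 - s)))))
}

# channelwise RMS normalization per spatial position with a learned
# per-channel gain; keeps feature scales bounded so training does not depend
# on initialization luck (the role GroupNorm plays in this network family)
td_rmsnorm <- function(tp, x, gamma) {
  xv <- x$value
  C <- ncol(xv)
  r <- 1 / sqrt(rowMeans(xv * xv) + 1e-6)
  u <- xv * r
  gv <- as.numeric(gamma$value)
  td_op(tp, u * rep(gv, each = nrow(xv)), function(g) {
    g_u <- g * rep(gv, each = nrow(xv))
    td_acc(gamma, matrix(colSums(g * u), 1L))
    s <- rowSums(g_u * xv)
    td_acc(x, r * g_u - (r^3 / C) * xv * s)
  })
}

td_softmax_rows <- function(tp, a) {
  x <- a$value
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  p <- e / rowSums(e)
  td_op(tp, p, function(g) td_acc(a, p * (g - rowSums(g * p))))
}

# ---- structural ops ----

# gather rows by index; idx == 0 yields a zero row (used for conv padding)
td_gather0 <- function(tp, a, idx) {
  av <- a$value
  C <- ncol(av)
  pos <- idx > 0L
  v <- matrix(0, length(idx), C)
  v[pos, ] <- av[idx[pos], , drop = FALSE]
  td_op(tp, v, function(g) {
    rs <- rowsum(g[pos, , drop = FALSE], idx[pos])
    G <- matrix(0, nrow(av), C)
    G[as.integer(rownames(rs)), ] <- rs
    td_acc(a, G)
  })
}

td_cbind <- function(tp, nodes) {
  vals <- lapply(nodes, function(nd) nd$value)
  ncols <- vapply(vals, ncol, integer(1))
  v <- do.call(cbind, vals)
  ends <- cumsum(ncols)
  starts <- c(1L, head(ends, -1L) + 1L)
  td_op(tp, v, function(g) {
    for (k in seq_along(nodes))
      td_acc(nodes[[k]], g[, starts[k]:ends[k], drop = FALSE])
  })
}

# 3x3 "same" convolution as one im2col gather + matmul. idx_all is the
# concatenation of the 9 per-offset index vectors with out-of-bounds
# positions mapped to the sentinel row npix + 1 (a zero row appended to the
# input); the (9*npix, C) gather is re-dimmed to (npix, 9C) so weight rows
# are ordered offset-fastest within each input channel.
td_im2col3 <- function(tp, x, idx_all, npix) {
  xv <- x$value
  C <- ncol(xv)
  big <- rbind(xv, 0)[idx_all, , drop = FALSE]
  dim(big) <- c(npix, 9L * C)
  pos <- idx_all <= npix
  td_op(tp, big, function(g) {
    dim(g) <- c(9L * npix, C)
    rs <- rowsum(g[pos, , drop = FALSE], idx_all[pos])
    G <- matrix(0, npix, C)
    G[as.integer(rownames(rs)), ] <- rs
    td_acc(x, G)
  })
}

# one-level Haar DWT + channel packing on an (npix, C) feature matrix, in a
# single linear node. ip/iq/ir/is_ index the four phases of each 2x2 block
# (top-left, top-right, bottom-left, bottom-right) in the parent grid.
td_dwt_pack <- function(tp, x, ph) {
  xv <- x$value
  C <- ncol(xv)
  A <- xv[ph$p, , drop = FALSE]; B <- xv[ph$q, , drop = FALSE]
  Cc <- xv[ph$r, , drop = FALSE]; D <- xv[ph$s, , drop = FALSE]
  v <- cbind(A + B + Cc + D, A - B + Cc - D, A + B - Cc - D, A - B - Cc + D) * 0.5
  td_op(tp, v, function(g) {
    j <- seq_len(C)
    g1 <- g[, j, drop = FALSE];          g2 <- g[, C + j, drop = FALSE]
    g3 <- g[, 2L * C + j, drop = FALSE]; g4 <- g[, 3L * C + j, drop = FALSE]
    G <- matrix(0, nrow(xv), C)
    G[ph$p, ] <- 0.5 * (g1 + g2 + g3 + g4)
    G[ph$q, ] <- 0.5 * (g1 - g2 + g3 - g4)
    G[ph$r, ] <- 0.5 * (g1 + g2 - g3 - g4)
    G[ph$s, ] <- 0.5 * (g1 - g2 - g3 + g4)
    td_acc(x, G)
  })
}

# ---- losses ----

td_mean_sq_diff <- function(tp, a, target) {
  d <- a$value - target
  n <- length(d)
  td_op(tp, sum(d * d) / n, function(g) td_acc(a, (2 * g / n) * d))
}

td_mean_abs_diff <- function(tp, a, target) {
  d <- a$value - target
  n <- length(d)
  td_op(tp, sum(abs(d)) / n, function(g) td_acc(a, (g / n) * sign(d)))
}

# ---- cached index sets (per spatial geometry) ----

.geom_cache <- new.env(parent = emptyenv())

# 9 stacked offset-index vectors for 3x3 same-padding conv on (h, w),
# column-major pixel order; out-of-bounds positions point at the sentinel
# zero row h*w + 1 consumed by td_im2col3.
conv3_idx <- function(h, w) {
  key <- sprintf("c3_%d_%d", h, w)
  got <- .geom_cache[[key]]
  if (!is.null(got)) return(got)
  i <- rep.int(seq_len(h), w)
  j <- rep(seq_len(w), each = h)
  out <- integer(0)
  for (dx in -1:1) for (dy in -1:1) {
    ii <- i + dy; jj <- j + dx
    ok <- ii >= 1L & ii <= h & jj >= 1L & jj <= w
    idx <- ifelse(ok, ii + (jj - 1L) * h, h * w + 1L)
    out <- c(out, idx)
  }
  .geom_cache[[key]] <- as.integer(out)
  out
}

# four phase-index vectors of the 2x2 blocks of an (h, w) grid, ordered
# column-major over the (h/2, w/2) half grid
haar_phase_idx <- function(h, w) {
  key <- sprintf("ph_%d_%d", h, w)
  got <- .geom_cache[[key]]
  if (!is.null(got)) return(got)
  hi <- rep.int(seq_len(h %/% 2L), w %/% 2L)
  hj <- rep(seq_len(w %/% 2L), each = h %/% 2L)
  at <- function(di, dj) (2L * hi - 1L + di) + (2L * hj - 2L + dj) * h
  out <- list(p = at(0L, 0L), q = at(0L, 1L), r = at(1L, 0L), s = at(1L, 1L))
  .geom_cache[[key]] <- out
  out
}

# nearest-neighbour 2x upsample indices: target (2h, 2w) -> source (h, w)
upsample2_idx <- function(h, w) {
  key <- sprintf("up_%d_%d", h, w)
  got <- .geom_cache[[key]]
  if (!is.null(got)) return(got)
  ti <- rep.int(seq_len(2L * h), 2L * w)
  tj <- rep(seq_len(2L * w), each = 2L * h)
  out <- ((ti + 1L) %/% 2L) + (((tj + 1L) %/% 2L) - 1L) * h
  .geom_cache[[key]] <- out
  out
}

# stride-2 subsample indices (top-left of each 2x2 block), for the plain
# strided-downsampling ablation variant
stride2_idx <- function(h, w) {
  key <- sprintf("s2_%d_%d", h, w)
  got <- .geom_cache[[key]]
  if (!is.null(got)) return(got)
  hi <- rep.int(seq_len(h %/% 2L), w %/% 2L)
  hj <- rep(seq_len(w %/% 2L), each = h %/% 2L)
  out <- (2L * hi - 1L) + (2L * hj - 2L) * h
  .geom_cache[[key]] <- out
  out
}
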