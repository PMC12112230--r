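# Orthonormal single- and multi-level 2D Haar transform. This is the numeric
# kernel every other module builds on: the diffusion runs its denoiser on
# wavelet-packed images, the encoder's downsampling layers reuse the same
# filter bank, and the high-frequency conditioning consumes detail sub-bands.
#
# Conventions (frozen, covered by tests):
#   * filters: low = (1, 1)/sqrt(2), high = (first - second)/sqrt(2), so the
#     transform is an isometry (energy preserving) and a constant image of
#     value c has ll = 2c after one level;
#   * sub-band names: `lh` is high-pass along width (columns), `hl` is
#     high-pass along height (rows), `hh` along both;
#   * images must have even dimensions at every level used -- no padding or
#     boundary extension mode is ever exercised; offending inputs are rejected.

# Coerce to (H, W, C) array; matrices become single-channel.
as_image <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (!(is.array(x) && length(dim(x)) == 3L))
    stop("image must be an (H, W) matrix or (H, W, C) array")
  if (!all(is.finite(x))) stop("image contains non-finite values")
  x
}

check_even <- function(h, w, what = "dwt2") {
  if (h %% 2L != 0L)
    stop(sprintf("%s: height (%d) must be even", what, h))
  if (w %% 2L != 0L)
    stop(sprintf("%s: width (%d) must be even", what, w))
}

#' Single-level orthonormal 2D Haar decomposition
#'
#' Splits an image into the four Haar sub-bands `ll`, `lh`, `hl`, `hh`, each
#' with one quarter of the spatial area. The transform uses orthonormal
#' filter taps (+-1/sqrt(2)) and is therefore an isometry: the total energy
#' (sum of squares) of the four sub-bands equals that of the input.
#'
#' @param image An (H, W) matrix or (H, W, C) array with H, W even.
#' @return An object of class `subband_stack`: a list with components
#'   `ll`, `lh`, `hl`, `hh`, each an (H/2, W/2, C) array.
#' @examples
#' s <- dwt2(matrix(1:16, 4, 4))
#' max(abs(idwt2(s) - matrix(1:16, 4, 4)))
#' @seealso [idwt2()], [dwt_multilevel()], [pack_subbands()]
#' @export
dwt2 <- function(image) {
  x <- as_image(image)
  d <- dim(x)
  check_even(d[1], d[2], "dwt2")
  io <- seq(1L, d[1], 2L); jo <- seq(1L, d[2], 2L)
  p <- x[io, jo, , drop = FALSE]       # top-left of each 2x2 block
  q <- x[io, jo + 1L, , drop = FALSE]  # top-right
  r <- x[io + 1L, jo, , drop = FALSE]  # bottom-left
  s <- x[io + 1L, jo + 1L, , drop = FALSE]
  structure(list(
    ll = (p + q + r + s) / 2,
    lh = (p - q + r - s) / 2,
    hl = (p + q - r - s) / 2,
    hh = (p - q - r + s) / 2
  ), class = "subband_stack")
}

check_stack <- function(stack) {
  if (!inherits(stack, "subband_stack") &&
      !(is.list(stack) && all(c("ll", "lh", "hl", "hh") %in% names(stack))))
    stop("expected a subband_stack (list with ll, lh, hl, hh)")
  dims <- lapply(stack[c("ll", "lh", "hl", "hh")], function(b) dim(as_image(b)))
  if (!all(vapply(dims, function(d) identical(d, dims[[1]]), logical(1))))
    stop(sprintf(
      "sub-band shapes differ: ll is (%s) but another band is not",
      paste(dims[[1]], collapse = ", ")))
  lapply(stack[c("ll", "lh", "hl", "hh")], as_image)
}

#' Inverse single-level Haar transform
#'
#' Exact inverse of [dwt2()] up to floating-point tolerance.
#'
#' @param stack A `subband_stack` with four equally shaped sub-bands.
#' @return An (H, W, C) array.
#' @export
idwt2 <- function(stack) {
  b <- check_stack(stack)
  d <- dim(b$ll)
  out <- array(0, dim = c(2L * d[1], 2L * d[2], d[3]))
  io <- seq(1L, 2L * d[1], 2L); jo <- seq(1L, 2L * d[2], 2L)
  out[io, jo, ]           <- (b$ll + b$lh + b$hl + b$hh) / 2
  out[io, jo + 1L, ]      <- (b$ll - b$lh + b$hl - b$hh) / 2
  out[io + 1L, jo, ]      <- (b$ll + b$lh - b$hl - b$hh) / 2
  out[io + 1L, jo + 1L, ] <- (b$ll - b$lh - b$hl + b$hh) / 2
  out
}

#' Multi-level Haar decomposition
#'
#' Level k + 1 decomposes level k's `ll` band, so level k sub-bands have
#' spatial shape (H/2^k, W/2^k). Used to match conditional-image detail bands
#' to decoder resolutions in the denoiser.
#'
#' @param image An (H, W) matrix or (H, W, C) array.
#' @param levels Positive integer decomposition depth; H and W must be
#'   divisible by `2^levels`.
#' @return A list of `subband_stack`s, one per level (finest first).
#' @export
dwt_multilevel <- function(image, levels) {
  x <- as_image(image)
  stopifnot(length(levels) == 1, levels >= 1, levels == round(levels))
  d <- dim(x)
  feasible <- function(n) {
    k <- 0L
    while (n %% 2L == 0L && n > 0L) { n <- n %/% 2L; k <- k + 1L }
    k
  }
  max_depth <- min(feasible(d[1]), feasible(d[2]))
  if (levels > max_depth)
    stop(sprintf(
      "dwt_multilevel: image of size %d x %d supports at most %d level(s), not %d",
      d[1], d[2], max_depth, levels))
  out <- vector("list", levels)
  cur <- x
  for (k in seq_len(levels)) {
    out[[k]] <- dwt2(cur)
    cur <- out[[k]]$ll
  }
  out
}

#' Pack Haar sub-bands along the channel axis
#'
#' Stacks the four sub-bands of a decomposition into a single image of shape
#' (H/2, W/2, 4C), channel blocks ordered (ll, lh, hl, hh). This is the
#' representation the denoiser consumes; [unpack_subbands()] is its exact
#' inverse.
#'
#' @param stack A `subband_stack`.
#' @return An (H/2, W/2, 4C) array.
#' @export
pack_subbands <- function(stack) {
  b <- check_stack(stack)
  d <- dim(b$ll)
  array(c(b$ll, b$lh, b$hl, b$hh), dim = c(d[1], d[2], 4L * d[3]))
}

#' @rdname pack_subbands
#' @param packed An (h, w, 4C) array produced by [pack_subbands()].
#' @export
unpack_subbands <- function(packed) {
  x <- as_image(packed)
  d <- dim(x)
  if (d[3] %% 4L != 0L)
    stop(sprintf("unpack_subbands: channel count %d is not a multiple of 4", d[3]))
  C <- d[3] %/% 4L
  band <- function(k) x[, , (k - 1L) * C + seq_len(C), drop = FALSE]
  structure(list(ll = band(1), lh = band(2), hl = band(3), hh = band(4)),
            class = "subband_stack")
}

#' @export
print.subband_stack <- function(x, ...) {
  d <- dim(as_image(x$ll))
  cat(sprintf("Haar subband stack: 4 bands of %d x %d x %d\n", d[1], d[2], d[3]))
  invisible(x)
}
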