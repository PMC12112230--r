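# Synthetic paired phantoms: the default desk-scale test bed. A pair shares
# one tissue geometry (head ellipse, K inner tissue ellipses, optionally a
# small lesion blob) rendered through two distinct per-tissue contrast
# lookup tables -- the two "modalities" -- with independent additive
# Gaussian noise. This emulates co-registered same-geometry /
# different-contrast image pairs; it does not emulate scanner physics,
# bias fields, or registration error.

#' Phantom generation parameters
#'
#' The default contrast tables are fixed so that the translation task is
#' non-trivial: the mean absolute source-target difference inside the head
#' mask is far above the noise floor, and the source-to-target intensity
#' mapping is not monotone (tissue ranks swap between modalities).
#'
#' @param n_tissues Number of inner tissue ellipses.
#' @param lesion_prob Probability that a pair (or subject) carries a lesion
#'   blob with modality-dependent contrast.
#' @param noise_sigma Additive Gaussian noise sd per modality.
#' @param contrast_source,contrast_target Named lists with `background`,
#'   `head`, `tissues` (length `n_tissues`) and `lesion` intensities in
#'   [-1, 1].
#' @return List of class `phantom_params`.
#' @export
phantom_params <- function(n_tissues = 4L,
                           lesion_prob = 0.5,
                           noise_sigma = 0.03,
                           contrast_source = list(
                             background = -0.95, head = 0.10,
                             tissues = c(0.45, -0.25, 0.70, 0.30),
                             lesion = 0.25),
                           contrast_target = list(
                             background = -0.95, head = -0.15,
                             tissues = c(-0.05, 0.40, 0.15, 0.75),
                             lesion = 0.85)) {
  stopifnot(n_tissues >= 1, lesion_prob >= 0, lesion_prob <= 1, noise_sigma >= 0)
  for (tb in list(contrast_source, contrast_target)) {
    if (length(tb$tissues) != n_tissues)
      stop("phantom_params: contrast tables must list one intensity per tissue")
    if (any(abs(unlist(tb)) > 1)) stop("phantom_params: intensities must lie in [-1, 1]")
  }
  structure(list(n_tissues = as.integer(n_tissues), lesion_prob = lesion_prob,
                 noise_sigma = noise_sigma, contrast_source = contrast_source,
                 contrast_target = contrast_target),
            class = "phantom_params")
}

# ellipse geometry in normalized [0,1]^2 coordinates: c(cx, cy, ax, ay, theta)
draw_geometry <- function(rng, n_tissues, lesion) {
  u <- function(lo, hi, n = 1L) lo + (hi - lo) * rng_unif(rng, n)
  head <- c(u(0.47, 0.53), u(0.47, 0.53), u(0.38, 0.44), u(0.33, 0.39), u(0, pi))
  tissues <- t(vapply(seq_len(n_tissues), function(k)
    c(u(0.3, 0.7), u(0.3, 0.7), u(0.06, 0.17), u(0.05, 0.15), u(0, pi)),
    numeric(5)))
  les <- if (lesion) c(u(0.35, 0.65), u(0.35, 0.65), u(0.05, 0.09), u(0.04, 0.08), u(0, pi))
         else NULL
  list(head = head, tissues = tissues, lesion = les)
}

jitter_geometry <- function(geom, rng, sd = 0.012) {
  jit <- function(e) {
    e[1:4] <- e[1:4] + sd * rng_norm(rng, 4L)
    e[3:4] <- pmax(e[3:4], 0.02)
    e
  }
  geom$head <- jit(geom$head)
  geom$tissues <- t(apply(geom$tissues, 1L, jit))
  if (!is.null(geom$lesion)) geom$lesion <- jit(geom$lesion)
  geom
}

inside_ellipse <- function(px, py, e) {
  dx <- px - e[1]; dy <- py - e[2]
  ct <- cos(e[5]); st <- sin(e[5])
  xr <- ct * dx + st * dy
  yr <- -st * dx + ct * dy
  (xr / e[3])^2 + (yr / e[4])^2 <= 1
}

#' Tissue label mask of a phantom geometry
#'
#' Deterministically re-renders the integer label mask (0 background, 1 head,
#' 2..K+1 tissues, K+2 lesion) from stored generation metadata; used to check
#' that both modalities of a pair share identical geometry.
#'
#' @param meta The `meta` field of a [make_phantom_pair()] result (or a list
#'   with `geometry` and `size`).
#' @return Integer label matrix.
#' @export
phantom_masks <- function(meta) {
  g <- meta$geometry; n <- meta$size
  cc <- (seq_len(n) - 0.5) / n
  px <- matrix(cc, n, n)        # row coordinate (vertical)
  py <- matrix(cc, n, n, byrow = TRUE)
  mask <- matrix(0L, n, n)
  head_in <- inside_ellipse(px, py, g$head)
  mask[head_in] <- 1L
  for (k in seq_len(nrow(g$tissues))) {
    hit <- inside_ellipse(px, py, g$tissues[k, ]) & head_in
    mask[hit] <- k + 1L
  }
  if (!is.null(g$lesion)) {
    hit <- inside_ellipse(px, py, g$lesion) & head_in
    mask[hit] <- nrow(g$tissues) + 2L
  }
  mask
}

render_modality <- function(mask, table, sigma, rng) {
  lut <- c(table$background, table$head, table$tissues, table$lesion)
  img <- matrix(lut[mask + 1L], nrow(mask), ncol(mask))
  if (sigma > 0) img <- img + sigma * matrix(rng_norm(rng, length(img)), nrow(mask))
  array(pmin(pmax(img, -1), 1), dim = c(nrow(mask), ncol(mask), 1L))
}

#' Generate one synthetic phantom pair
#'
#' Draws a head-like outer ellipse, `n_tissues` inner tissue ellipses and
#' (with probability `lesion_prob`) one small high-contrast lesion blob,
#' renders the same geometry through the source and target contrast tables,
#' and adds independent Gaussian noise to each modality. Fully reproducible
#' from the seed.
#'
#' @param seed Integer seed.
#' @param size Even image side length >= 16.
#' @param params A [phantom_params()] object.
#' @param geometry Optional pre-drawn geometry (used for slice jitter within
#'   a subject); when supplied only rendering noise is drawn from the seed.
#' @return Object of class `phantom_pair`: list with `source`, `target`
#'   ((size, size, 1) arrays in [-1, 1]), `seed` and `meta`.
#' @export
make_phantom_pair <- function(seed, size = 32L, params = phantom_params(),
                              geometry = NULL) {
  if (length(size) != 1 || size < 16 || size %% 2 != 0)
    stop("make_phantom_pair: size must be an even integer >= 16")
  size <- as.integer(size)
  rng <- rng_stream(seed)
  if (is.null(geometry)) {
    lesion <- rng_unif(rng, 1L) < params$lesion_prob
    geometry <- draw_geometry(rng, params$n_tissues, lesion)
  }
  meta <- list(size = size, geometry = geometry, params = params,
               lesion = !is.null(geometry$lesion), seed = seed)
  mask <- phantom_masks(meta)
  source <- render_modality(mask, params$contrast_source, params$noise_sigma, rng)
  target <- render_modality(mask, params$contrast_target, params$noise_sigma, rng)
  structure(list(source = source, target = target, seed = seed, meta = meta),
            class = "phantom_pair")
}

#' @export
print.phantom_pair <- function(x, ...) {
  cat(sprintf("Phantom pair: %d x %d, %d tissues, lesion: %s, seed %d\n",
              x$meta$size, x$meta$size, x$meta$params$n_tissues,
              if (x$meta$lesion) "yes" else "no", x$seed))
  invisible(x)
}

#' Generate a subject-split synthetic dataset
#'
#' Subjects are split 80/10/10 into train/validation/test with no subject in
#' two splits. Slices of one subject share the subject's tissue geometry up
#' to a small jitter, emulating adjacent slices; lesion presence is decided
#' per subject.
#'
#' @param n_subjects Number of subjects (>= 10, so each split is non-empty).
#' @param slices_per_subject Paired slices per subject.
#' @param seed Integer seed; the whole dataset is a pure function of
#'   `(seed, params, size)`.
#' @param params A [phantom_params()].
#' @param size Image side length.
#' @return Object of class `fadm_dataset`: lists `train`, `val`, `test` of
#'   `phantom_pair`s plus a `manifest` data frame (subject_id, split, slice).
#' @export
make_dataset <- function(n_subjects = 10L, slices_per_subject = 4L, seed = 1L,
                         params = phantom_params(), size = 32L) {
  if (n_subjects < 10)
    stop("make_dataset: need n_subjects >= 10 for a non-empty 80-10-10 split")
  n_subjects <- as.integer(n_subjects)
  rng <- rng_stream(seed)
  n_val <- max(1L, round(0.1 * n_subjects))
  n_test <- max(1L, round(0.1 * n_subjects))
  ord <- rng_eval(rng, sample.int(n_subjects))
  split <- rep("train", n_subjects)
  split[ord[seq_len(n_val)]] <- "val"
  split[ord[n_val + seq_len(n_test)]] <- "test"
  sets <- list(train = list(), val = list(), test = list())
  manifest <- data.frame(subject_id = character(0), split = character(0),
                         slice = integer(0))
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("S%03d", s)
    srng <- rng_child(rng, s)
    lesion <- rng_unif(srng, 1L) < params$lesion_prob
    base_geom <- draw_geometry(srng, params$n_tissues, lesion)
    for (k in seq_len(slices_per_subject)) {
      geom <- jitter_geometry(base_geom, srng)
      pair_seed <- (as.double(seed) * 7919 + s * 104729 + k * 131) %% 2147483647
      pair <- make_phantom_pair(pair_seed, size = size, params = params,
                                geometry = geom)
      pair$meta$subject_id <- sid
      pair$meta$slice <- k
      sets[[split[s]]] <- c(sets[[split[s]]], list(pair))
      manifest <- rbind(manifest, data.frame(subject_id = sid, split = split[s],
                                             slice = k))
    }
  }
  structure(c(sets, list(manifest = manifest, params = params, size = size,
                         seed = as.integer(seed))),
            class = "fadm_dataset")
}

#' @export
print.fadm_dataset <- function(x, ...) {
  cat(sprintf(
    "Paired phantom dataset: %d train / %d val / %d test slices (%d x %d), seed %d\n",
    length(x$train), length(x$val), length(x$test), x$size, x$size, x$seed))
  invisible(x)
}

#' Write a dataset manifest as a plain-text table
#'
#' @param dataset A [make_dataset()] object.
#' @param path Output TSV path.
#' @export
write_manifest <- function(dataset, path) {
  utils::write.table(dataset$manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# bilinear resize of one (H, W) matrix to (n, n)
resize_bilinear <- function(m, n) {
  d <- dim(m)
  if (all(d == n)) return(m)
  sx <- (seq_len(n) - 0.5) * d[1] / n + 0.5
  sy <- (seq_len(n) - 0.5) * d[2] / n + 0.5
  i0 <- pmin(pmax(floor(sx), 1L), d[1]); i1 <- pmin(i0 + 1L, d[1])
  j0 <- pmin(pmax(floor(sy), 1L), d[2]); j1 <- pmin(j0 + 1L, d[2])
  fx <- pmin(pmax(sx - i0, 0), 1); fy <- pmin(pmax(sy - j0, 0), 1)
  a <- m[i0, j0, drop = FALSE] * outer(1 - fx, 1 - fy) +
       m[i1, j0, drop = FALSE] * outer(fx, 1 - fy) +
       m[i0, j1, drop = FALSE] * outer(1 - fx, fy) +
       m[i1, j1, drop = FALSE] * outer(fx, fy)
  a
}

#' Extract 2D slices from a co-registered NIfTI volume
#'
#' Slices a 3D volume along the requested plane, optionally stacking each
#' slice with its two neighbours as channels (edge slices replicate their
#' single neighbour), resizes to a square grid, and rescales intensities to
#' [-1, 1] by the per-volume min-max. Cross-modal registration is assumed
#' already done; only shapes are validated.
#'
#' @param path Path to a NIfTI file (requires the RNifti package).
#' @param plane `"axial"`, `"coronal"` or `"sagittal"` (3rd, 2nd, 1st axis).
#' @param stack_adjacent If `TRUE`, return 3-channel slices
#'   (index - 1, index, index + 1).
#' @param size Output side length (even); `NULL` keeps the native in-plane
#'   size when square.
#' @return List of `slice_record`s: `image` ((size, size, 1 or 3) array),
#'   `subject_id`, `plane`, `index`.
#' @export
load_volume_slices <- function(path, plane = c("axial", "coronal", "sagittal"),
                               stack_adjacent = FALSE, size = NULL) {
  plane <- match.arg(plane)
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("load_volume_slices requires the RNifti package")
  vol <- tryCatch(as.array(RNifti::readNifti(path)),
                  error = function(e) stop(sprintf("cannot read volume '%s': %s",
                                                   path, conditionMessage(e))))
  if (length(dim(vol)) == 4L && dim(vol)[4] == 1L) vol <- vol[, , , 1L]
  if (length(dim(vol)) != 3L)
    stop(sprintf("load_volume_slices: expected a 3D volume, got %d dims",
                 length(dim(vol))))
  rngv <- range(vol, finite = TRUE)
  vol <- if (diff(rngv) > 0) 2 * (vol - rngv[1]) / diff(rngv) - 1 else vol * 0
  axis <- switch(plane, sagittal = 1L, coronal = 2L, axial = 3L)
  D <- dim(vol)[axis]
  grab <- function(i) {
    i <- min(max(i, 1L), D)
    m <- switch(plane,
      sagittal = vol[i, , ],
      coronal = vol[, i, ],
      axial = vol[, , i])
    if (!is.null(size)) m <- resize_bilinear(m, size)
    m
  }
  sid <- sub("\\.nii(\\.gz)?$", "", basename(path))
  lapply(seq_len(D), function(i) {
    img <- if (stack_adjacent) {
      slabs <- lapply(c(i - 1L, i, i + 1L), grab)
      array(unlist(slabs), dim = c(dim(slabs[[1]]), 3L))
    } else {
      array(grab(i), dim = c(dim(grab(i)), 1L))
    }
    structure(list(image = img, subject_id = sid, plane = plane, index = i),
              class = "slice_record")
  })
}

#' Write an image (or side-by-side panel) as PNG
#'
#' Intensities in [-1, 1] are mapped to [0, 1] gray. Requires the png
#' package.
#'
#' @param images A single image or list of images of equal height.
#' @param path Output path.
#' @export
write_image_png <- function(images, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("write_image_png requires the png package")
  if (!is.list(images)) images <- list(images)
  mats <- lapply(images, function(im) {
    x <- as_image(im)
    (pmin(pmax(x[, , 1], -1), 1) + 1) / 2
  })
  png::writePNG(do.call(cbind, mats), path)
  invisible(path)
}
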