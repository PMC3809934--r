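#' Synthetic textured phantoms of known roughness
#'
#' Fractional Brownian motion (fBm) surfaces provide textures whose
#' theoretical fractal dimension is known exactly: a surface with Hurst
#' exponent H has dimension 3 - H. Classes of phantom volumes that differ
#' in H and in intensity statistics stand in for multi-class clinical
#' texture data, so every stage of the pipeline can be exercised and
#' validated without patient images.
#'
#' @name phantoms
#' @keywords internal
NULL

fft_freqs <- function(n) {
  c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
}

# fBm surface via spectral synthesis using the current RNG stream:
# amplitude ~ f^-(H+1), i.e. power ~ f^-(2H+2). Returns an unscaled field.
fbm_field <- function(hurst, size) {
  f <- fft_freqs(size)
  fr <- sqrt(outer(f^2, f^2, `+`))
  amp <- matrix(0, size, size)
  amp[fr > 0] <- fr[fr > 0]^(-(hurst + 1))
  noise <- matrix(rnorm(size * size), size, size)
  Re(fft(fft(noise) * amp, inverse = TRUE)) / (size * size)
}

#' Generate a fractional Brownian surface image
#'
#' Spectral synthesis: white Gaussian noise is filtered in the frequency
#' domain so the power spectrum falls off as `f^-(2H+2)`, then the field is
#' rescaled linearly to `[0, 255]`. Deterministic given `seed`. The
#' resulting surface has theoretical fractal dimension `3 - hurst`.
#'
#' @param hurst Hurst exponent, strictly inside (0, 1); smaller is rougher.
#' @param size image side (>= 16).
#' @param seed integer seed.
#' @return a `size` x `size` matrix with values in `[0, 255]`.
#' @export
#' @examples
#' img <- generate_fbm_image(0.5, 64, seed = 1)
#' range(img)
generate_fbm_image <- function(hurst, size, seed) {
  if (hurst <= 0 || hurst >= 1) stop("`hurst` must be in (0, 1)",
                                     call. = FALSE)
  if (size < 16) stop("`size` must be >= 16", call. = FALSE)
  with_seed(seed, rescale_gray(fbm_field(hurst, size)))
}

ellipsoid_mask <- function(shape, semi_axes = c(0.42, 0.42, 0.42)) {
  ctr <- (shape + 1) / 2
  ax <- semi_axes * shape
  ii <- (seq_len(shape[1]) - ctr[1]) / ax[1]
  jj <- (seq_len(shape[2]) - ctr[2]) / ax[2]
  kk <- (seq_len(shape[3]) - ctr[3]) / ax[3]
  d2 <- outer(outer(ii^2, jj^2, `+`), kk^2, `+`)
  d2 <= 1
}

#' Generate one phantom volume of a texture class
#'
#' Each slice is an fBm texture at the class's Hurst exponent, blended with
#' a shared low-frequency base field so slices are correlated as in real
#' stacks; the volume is then standardized and mapped to the class's
#' intensity mean and spread (clamped to `[0, 255]`), and an ellipsoidal
#' region-of-interest mask is applied (voxels outside are 0).
#'
#' @param hurst class roughness, in (0, 1).
#' @param mean_intensity,intensity_sd target in-mask intensity moments.
#' @param shape volume dimensions (rows, cols, slices).
#' @param seed integer seed; fully deterministic.
#' @param base_weight weight of the shared smooth base field (default 0.3).
#' @param mask_axes ellipsoid semi-axes as fractions of each dimension.
#' @return a [gray_volume()] with mask.
#' @export
generate_phantom_volume <- function(hurst, mean_intensity = 120,
                                    intensity_sd = 20,
                                    shape = c(64, 64, 10), seed = 1L,
                                    base_weight = 0.3,
                                    mask_axes = c(0.42, 0.42, 0.42)) {
  if (hurst <= 0 || hurst >= 1) stop("`hurst` must be in (0, 1)",
                                     call. = FALSE)
  shape <- as.integer(shape)
  side <- max(shape[1], shape[2])
  with_seed(seed, {
    base <- fbm_field(0.9, side)[seq_len(shape[1]), seq_len(shape[2])]
    base <- base / sd(base)
    vox <- array(0, dim = shape)
    for (s in seq_len(shape[3])) {
      sl <- fbm_field(hurst, side)[seq_len(shape[1]), seq_len(shape[2])]
      vox[, , s] <- base_weight * base + (1 - base_weight) * sl / sd(sl)
    }
    z <- (vox - mean(vox)) / sd(vox)
    vox <- pmin(pmax(mean_intensity + intensity_sd * z, 0), 255)
    mask <- ellipsoid_mask(shape, mask_axes)
    vox[!mask] <- 0
    gray_volume(vox, mask = mask)
  })
}

#' Specification of a multi-class phantom dataset
#'
#' The default templates define four texture classes over two Hurst levels
#' and two intensity levels, mirroring a 4-way clinical split: `normal`
#' (H = 0.7, mean 100) and `cirrhosis` (H = 0.5, mean 100) differ only in
#' roughness; `cirrhosis` and `hydatoncus` (H = 0.5, mean 150) only in
#' intensity; `cancer` (H = 0.3, mean 150) and `hydatoncus` only in
#' roughness.
#'
#' @param classes tibble with columns `label`, `hurst`, `mean_intensity`,
#'   `intensity_sd`, `n_volumes`; defaults to the four templates with 5
#'   volumes each.
#' @param volume_shape volume dimensions (default `c(64, 64, 10)`, a
#'   desk-scale stand-in for full 512 x 512 x 50 stacks).
#' @param mask_axes ellipsoid semi-axes fractions.
#' @param seed master seed; per-volume seeds are derived from it.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(classes = NULL, volume_shape = c(64, 64, 10),
                         mask_axes = c(0.42, 0.42, 0.42), seed = 1L) {
  if (is.null(classes)) {
    classes <- tibble::tibble(
      label = c("normal", "cirrhosis", "cancer", "hydatoncus"),
      hurst = c(0.7, 0.5, 0.3, 0.5),
      mean_intensity = c(100, 100, 150, 150),
      intensity_sd = c(20, 20, 20, 20),
      n_volumes = 5L)
  }
  stopifnot(all(c("label", "hurst", "mean_intensity", "intensity_sd",
                  "n_volumes") %in% names(classes)))
  if (any(classes$hurst <= 0 | classes$hurst >= 1))
    stop("`hurst` must be strictly inside (0, 1)", call. = FALSE)
  if (any(classes$n_volumes < 1))
    stop("`n_volumes` must be >= 1 per class", call. = FALSE)
  structure(list(classes = classes, volume_shape = as.integer(volume_shape),
                 mask_axes = mask_axes, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a labelled phantom dataset
#'
#' Generates every class's volumes with per-volume seeds derived from the
#' master seed (`seed + running index`), so the dataset is byte-identical
#' across runs.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `phantom_dataset`: list with `volumes` (list
#'   of [gray_volume()]), `labels`, `manifest` (tibble: sample_id, label,
#'   seed) and `spec`.
#' @export
generate_dataset <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  volumes <- list()
  labels <- character(0)
  rows <- list()
  idx <- 0L
  for (ci in seq_len(nrow(spec$classes))) {
    cl <- spec$classes[ci, ]
    for (v in seq_len(cl$n_volumes)) {
      idx <- idx + 1L
      vol_seed <- spec$seed + idx
      volumes[[idx]] <- generate_phantom_volume(
        cl$hurst, cl$mean_intensity, cl$intensity_sd,
        shape = spec$volume_shape, seed = vol_seed,
        mask_axes = spec$mask_axes)
      labels[idx] <- cl$label
      rows[[idx]] <- tibble::tibble(
        sample_id = sprintf("%s_%02d", cl$label, v),
        label = cl$label, seed = vol_seed)
    }
  }
  structure(list(volumes = volumes, labels = labels,
                 manifest = dplyr::bind_rows(rows), spec = spec),
            class = "phantom_dataset")
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat("Phantom dataset:", length(x$volumes), "volumes of",
      paste(x$spec$volume_shape, collapse = " x "), "\n")
  print(table(x$labels))
  invisible(x)
}

#' Deterministic stratified half/half train-test split
#'
#' Splits sample indices per class (default half and half, odd counts give
#' the extra sample to the training side), deterministically for a given
#' seed; the two sides are disjoint and cover all samples.
#'
#' @param labels class labels (or a `phantom_dataset`).
#' @param train_fraction fraction per class assigned to training
#'   (default 0.5).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
split_dataset <- function(labels, train_fraction = 0.5, seed = 1L) {
  if (inherits(labels, "phantom_dataset")) labels <- labels$labels
  labels <- as.character(labels)
  with_seed(seed, {
    train <- integer(0)
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      n_tr <- ceiling(length(idx) * train_fraction)
      train <- c(train, idx[seq_len(n_tr)])
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(labels), train))
  })
}
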