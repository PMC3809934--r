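#' Gray-level volume container
#'
#' A thin container for a 3-D intensity array with an optional binary
#' region-of-interest mask and voxel spacing metadata.
#'
#' @param voxels 3-D numeric array (rows x cols x slices), finite values.
#' @param mask optional logical/0-1 array of the same shape; `TRUE` marks
#'   voxels inside the region of interest.
#' @param spacing numeric length-3 voxel size in mm (metadata only).
#' @return an object of class `gray_volume`.
#' @export
gray_volume <- function(voxels, mask = NULL, spacing = c(1, 1, 1)) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3)
  if (!all(is.finite(voxels))) stop("voxels must be finite", call. = FALSE)
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), dim(voxels)))
    mask <- array(as.logical(mask), dim = dim(mask))
  }
  structure(list(voxels = voxels, mask = mask, spacing = spacing),
            class = "gray_volume")
}

#' @export
print.gray_volume <- function(x, ...) {
  cat("Gray volume", paste(dim(x$voxels), collapse = " x "),
      if (!is.null(x$mask)) sprintf("(mask covers %.1f%%)",
                                    100 * mean(x$mask)) else "(no mask)",
      "\n")
  invisible(x)
}

as_voxel_array <- function(volume) {
  if (inherits(volume, "gray_volume")) return(volume$voxels)
  stopifnot(is.array(volume), length(dim(volume)) == 3)
  volume
}

#' Mode-n unfolding of a tensor
#'
#' Flattens an order-N array into the matrix whose row r enumerates all
#' entries with index of mode `mode` fixed at r; the remaining modes vary in
#' the cyclic order (mode+1, ..., N, 1, ..., mode-1), fastest first.
#' [mode_fold()] is the exact inverse.
#'
#' @param x order-N numeric array.
#' @param mode mode to bring to the rows (1..N).
#' @return a matrix of shape `dim(x)[mode]` x `prod(dim(x)[-mode])`.
#' @export
#' @examples
#' x <- array(1:24, c(2, 3, 4))
#' dim(mode_unfold(x, 2))  # 3 x 8
mode_unfold <- function(x, mode) {
  d <- dim(x)
  n <- length(d)
  if (mode < 1 || mode > n) stop("`mode` out of range", call. = FALSE)
  perm <- c(mode, if (n > 1) ((seq_len(n - 1) + mode - 1) %% n) + 1)
  y <- aperm(x, perm)
  dim(y) <- c(d[mode], prod(d[-mode]))
  y
}

#' Fold a mode-n unfolding back into a tensor
#'
#' @param m matrix produced by [mode_unfold()] (possibly with a different
#'   row count, e.g. after a mode product).
#' @param mode the unfolded mode.
#' @param dims the target tensor dimensions (with `dims[mode] == nrow(m)`).
#' @return an order-N array of dimension `dims`.
#' @export
mode_fold <- function(m, mode, dims) {
  n <- length(dims)
  if (mode < 1 || mode > n) stop("`mode` out of range", call. = FALSE)
  if (nrow(m) != dims[mode]) stop("row count does not match `dims`",
                                  call. = FALSE)
  perm <- c(mode, if (n > 1) ((seq_len(n - 1) + mode - 1) %% n) + 1)
  dim(m) <- dims[perm]
  aperm(m, order(perm))
}

#' Mode-n product of a tensor with a matrix
#'
#' Contracts mode `mode` of `x` (size I_n) with the columns of `u`
#' (J x I_n), resizing that mode to J:
#' `(x ×_n u)[..., j, ...] = sum_i x[..., i, ...] * u[j, i]`.
#'
#' @param x order-N numeric array.
#' @param u numeric matrix with `ncol(u) == dim(x)[mode]`.
#' @param mode the contracted mode.
#' @return an order-N array with mode `mode` resized to `nrow(u)`.
#' @export
mode_product <- function(x, u, mode) {
  d <- dim(x)
  if (ncol(u) != d[mode]) stop("matrix columns must match the mode size",
                               call. = FALSE)
  d2 <- d
  d2[mode] <- nrow(u)
  mode_fold(u %*% mode_unfold(x, mode), mode, d2)
}

#' Assemble the order-4 feature tensor of a volume
#'
#' Channel 1 holds gray intensities rescaled to `[0, 1]`; channels 2-5 hold
#' the per-voxel fractal maps d1..d4 divided by 3 (so a dimension in
#' `[2, 3]` lands in `[2/3, 1]`). Voxels outside the mask are zeroed in all
#' channels.
#'
#' @param volume 3-D array or [gray_volume()]; intensities in
#'   `[0, gray_levels - 1]`.
#' @param window_d1,window_box sliding-window sides for the fractal maps.
#' @param max_epsilon blanket scales for the d1 map.
#' @param gray_levels number of gray levels (default 256).
#' @return an object of class `feature_tensor`: the order-4 array with
#'   attributes `channel_names` and `channel_kinds` (`"gray"`/`"fractal"`).
#' @export
build_feature_tensor <- function(volume, window_d1 = 33L, window_box = 32L,
                                 max_epsilon = 8L, gray_levels = 256) {
  vox <- as_voxel_array(volume)
  mask <- if (inherits(volume, "gray_volume")) volume$mask else NULL
  d <- dim(vox)
  out <- array(0, dim = c(d, 5L))
  out[, , , 1] <- vox / (gray_levels - 1)
  feats <- c("d1", "d2", "d3", "d4")
  for (ch in seq_along(feats)) {
    w <- if (feats[ch] == "d1") window_d1 else window_box
    out[, , , ch + 1L] <-
      local_fractal_map(vox, feats[ch], window = w,
                        max_epsilon = max_epsilon,
                        gray_levels = gray_levels, mask = mask) / 3
  }
  if (!is.null(mask)) {
    m4 <- array(rep(as.numeric(mask), 5L), dim = c(d, 5L))
    out <- out * m4
  }
  structure(out,
            channel_names = c("gray", feats),
            channel_kinds = c("gray", rep("fractal", 4L)),
            class = c("feature_tensor", "array"))
}

#' Channel tags of a feature tensor
#' @param x a `feature_tensor`.
#' @return character vector of per-channel kinds (`"gray"`/`"fractal"`).
#' @export
channel_kinds <- function(x) attr(x, "channel_kinds")

sample_list <- function(samples) {
  if (!is.list(samples)) samples <- list(samples)
  samples <- lapply(samples, function(s) {
    if (inherits(s, "gray_volume")) s$voxels else unclass(s)
  })
  d <- dim(samples[[1]])
  ok <- vapply(samples, function(s) identical(dim(s), d), logical(1))
  if (!all(ok)) stop("samples must all have the same shape", call. = FALSE)
  samples
}

#' Fit a generalized N-dimensional PCA (shared Tucker bases) model
#'
#' Learns one orthonormal basis per tensor mode, shared across a sample of
#' equally-shaped order-N tensors, by maximizing the total projected energy
#' C' = sum_i ||A_i x_1 U1' x_2 ... x_N UN'||^2 over the centred samples.
#' Bases are initialized from the leading eigenvectors of each mode's
#' scatter matrix (a truncated higher-order SVD start) and refined by
#' alternating eigen-updates: cycling over modes, each basis is replaced by
#' the leading `core_dims[n]` eigenvectors of the scatter of the samples
#' projected on all *other* modes. Two full cycles suffice in practice; the
#' cost trace is recorded after every mode update and is non-decreasing.
#'
#' Bases are stored as I_n x J_n matrices with orthonormal columns, so
#' projection contracts with `t(U)` and reconstruction with `U`.
#'
#' @param samples list of equally-shaped numeric arrays (e.g.
#'   `feature_tensor`s, raw 3-D volumes, or any order-N arrays).
#' @param core_dims integer vector of mode-subspace dimensions J_n,
#'   elementwise `<= dim`.
#' @param iterations number of full alternating cycles (default 2);
#'   `iterations = 0` returns the model at its truncated-HOSVD start.
#' @param tol optional relative cost-change tolerance; when supplied,
#'   iteration stops early once the relative increase of C' over a full
#'   cycle drops below `tol` (at most `iterations` cycles).
#' @param center subtract the voxelwise sample mean before fitting
#'   (default: yes whenever more than one sample is supplied; a single
#'   sample is fitted uncentred, where the model coincides with its
#'   truncated higher-order SVD).
#' @return an object of class `gnd_pca` with fields `mean`, `bases`,
#'   `core_dims`, `dims` and `fit_history` (a tibble with one row per mode
#'   update: `iteration`, `mode`, `cost`).
#' @seealso [project()], [reconstruct()], [normalized_correlation()]
#' @export
fit_gnd_pca <- function(samples, core_dims, iterations = 2L, tol = NULL,
                        center = NULL) {
  samples <- sample_list(samples)
  d <- dim(samples[[1]])
  n_modes <- length(d)
  core_dims <- as.integer(core_dims)
  if (length(core_dims) != n_modes)
    stop("`core_dims` must have one entry per mode", call. = FALSE)
  if (any(core_dims < 1L) || any(core_dims > d))
    stop("`core_dims` must satisfy 1 <= J_n <= I_n", call. = FALSE)

  if (is.null(center)) center <- length(samples) > 1
  mean_tensor <- if (center) {
    Reduce(`+`, samples) / length(samples)
  } else {
    array(0, dim = d)
  }
  centred <- lapply(samples, function(s) s - mean_tensor)

  lead_eigvecs <- function(scatter, j) {
    ev <- eigen(scatter, symmetric = TRUE)
    ev$vectors[, seq_len(j), drop = FALSE]
  }
  mode_scatter <- function(tensors, mode) {
    s <- 0
    for (a in tensors) {
      m <- mode_unfold(a, mode)
      s <- s + tcrossprod(m)
    }
    s
  }

  bases <- lapply(seq_len(n_modes), function(n)
    lead_eigvecs(mode_scatter(centred, n), core_dims[n]))

  project_all <- function(a, skip = 0L) {
    for (n in seq_len(n_modes)) {
      if (n == skip) next
      a <- mode_product(a, t(bases[[n]]), n)
    }
    a
  }
  cost <- function() sum(vapply(centred, function(a)
    sum(project_all(a)^2), numeric(1)))

  history <- list(tibble::tibble(iteration = 0L, mode = 0L, cost = cost()))
  prev_cost <- NA_real_
  for (it in seq_len(iterations)) {
    for (n in seq_len(n_modes)) {
      partial <- lapply(centred, project_all, skip = n)
      bases[[n]] <- lead_eigvecs(mode_scatter(partial, n), core_dims[n])
      history[[length(history) + 1L]] <-
        tibble::tibble(iteration = it, mode = n, cost = cost())
    }
    cyc <- history[[length(history)]]$cost
    if (!is.null(tol) && !is.na(prev_cost) &&
        (cyc - prev_cost) <= tol * abs(prev_cost)) {
      prev_cost <- cyc
      break
    }
    prev_cost <- cyc
  }

  structure(list(mean = mean_tensor, bases = bases, core_dims = core_dims,
                 dims = d, fit_history = dplyr::bind_rows(history),
                 n_samples = length(samples)),
            class = "gnd_pca")
}

#' @export
print.gnd_pca <- function(x, ...) {
  cat("GND-PCA model:", paste(x$dims, collapse = " x "), "->",
      paste(x$core_dims, collapse = " x "),
      sprintf("(%d samples, final C' = %.4g)\n", x$n_samples,
              max(x$fit_history$cost)))
  invisible(x)
}

#' Project a sample into the learned mode subspaces
#'
#' Centres the sample by the model mean and contracts every mode with the
#' transposed basis, yielding the core tensor B = (A - mean) x_1 U1' x_2 ...
#'
#' @param model a fitted model ([fit_gnd_pca()] or [fit_eigenface_pca()]).
#' @param sample array (or vector, for the eigenface baseline) matching the
#'   training shape.
#' @param ... unused.
#' @return the core tensor (array of shape `core_dims`) or coefficient
#'   vector.
#' @export
project <- function(model, sample, ...) UseMethod("project")

#' @rdname project
#' @export
project.gnd_pca <- function(model, sample, ...) {
  sample <- if (inherits(sample, "gray_volume")) sample$voxels
            else unclass(sample)
  if (!identical(dim(sample), model$dims))
    stop("sample shape does not match the model", call. = FALSE)
  a <- sample - model$mean
  for (n in seq_along(model$bases))
    a <- mode_product(a, t(model$bases[[n]]), n)
  a
}

#' Reconstruct a sample from its core tensor
#'
#' Applies the Tucker synthesis A* = B x_1 U1 x_2 ... x_N UN and adds the
#' model mean back.
#'
#' @inheritParams project
#' @param core core tensor of shape `core_dims` (or coefficient vector for
#'   the eigenface baseline).
#' @return array of the training shape.
#' @export
reconstruct <- function(model, core, ...) UseMethod("reconstruct")

#' @rdname reconstruct
#' @export
reconstruct.gnd_pca <- function(model, core, ...) {
  if (!identical(as.integer(dim(core)), as.integer(model$core_dims)))
    stop("core shape does not match the model", call. = FALSE)
  a <- core
  for (n in seq_along(model$bases))
    a <- mode_product(a, model$bases[[n]], n)
  a + model$mean
}

#' Normalized correlation between two tensors
#'
#' The cosine similarity sum(I * I*) / sqrt(sum(I^2) * sum(I*^2)); equal to
#' 1 when the reconstruction matches the original up to positive scale.
#'
#' @param original,reconstructed equally-shaped numeric arrays, neither
#'   all-zero.
#' @return a scalar in `[-1, 1]`.
#' @export
normalized_correlation <- function(original, reconstructed) {
  original <- unclass(original); reconstructed <- unclass(reconstructed)
  if (!identical(dim(original), dim(reconstructed)))
    stop("shapes differ", call. = FALSE)
  s1 <- sum(original^2); s2 <- sum(reconstructed^2)
  if (s1 == 0 || s2 == 0) stop("all-zero input", call. = FALSE)
  sum(original * reconstructed) / sqrt(s1 * s2)
}

#' Compression rate of a mode-subspace model
#'
#' 100 * prod(J_n) / prod(I_n) over the spatial modes. When a trailing
#' channel mode is kept full it contributes a factor of one either way; a
#' core/full pair of unequal length is an error.
#'
#' @param core_dims,full_dims positive integer vectors of equal length,
#'   elementwise `core_dims <= full_dims`.
#' @return the compression rate as a percentage (unrounded; round to 4
#'   decimals for display).
#' @export
#' @examples
#' round(compression_rate(c(100, 100, 10), c(512, 512, 50)), 4)  # 0.7629
compression_rate <- function(core_dims, full_dims) {
  if (length(core_dims) != length(full_dims))
    stop("dimension mismatch", call. = FALSE)
  if (any(core_dims < 1) || any(full_dims < 1) || any(core_dims > full_dims))
    stop("need 1 <= core_dims <= full_dims", call. = FALSE)
  100 * prod(core_dims / full_dims)
}

#' Eigenface PCA baseline on vectorized tensors
#'
#' Classical principal component analysis on vectorized samples, computed
#' through the M x M Gram matrix of the centred sample vectors (M samples
#' are far fewer than voxels). Serves as the flattening baseline that the
#' multilinear model is compared against.
#'
#' @param samples list of equally-shaped numeric arrays.
#' @param n_components number of principal axes (at most M - 1).
#' @return an object of class `eigenface_pca` with fields `mean`,
#'   `components` (columns are unit-norm axes), `eigenvalues` (all M - 1
#'   Gram eigenvalues) and `dims`.
#' @export
fit_eigenface_pca <- function(samples, n_components) {
  samples <- sample_list(samples)
  m <- length(samples)
  if (m < 2) stop("need at least 2 samples", call. = FALSE)
  d <- dim(samples[[1]])
  x <- vapply(samples, as.vector, numeric(prod(d)))  # voxels x M
  mu <- rowMeans(x)
  xc <- x - mu
  gram <- crossprod(xc)                              # M x M
  ev <- eigen(gram, symmetric = TRUE)
  pos <- ev$values > max(ev$values) * 1e-12
  rank <- sum(pos)
  if (n_components > rank)
    stop("`n_components` exceeds the available rank (", rank, ")",
         call. = FALSE)
  comp <- xc %*% ev$vectors[, seq_len(n_components), drop = FALSE]
  comp <- sweep(comp, 2, sqrt(ev$values[seq_len(n_components)]), `/`)
  structure(list(mean = mu, components = comp,
                 eigenvalues = ev$values, n_components = n_components,
                 dims = d),
            class = "eigenface_pca")
}

#' @rdname project
#' @export
project.eigenface_pca <- function(model, sample, ...) {
  v <- as.vector(if (inherits(sample, "gray_volume")) sample$voxels
                 else unclass(sample))
  drop(crossprod(model$components, v - model$mean))
}

#' @rdname reconstruct
#' @export
reconstruct.eigenface_pca <- function(model, core, ...) {
  array(model$mean + model$components %*% core, dim = model$dims)
}

#' @rdname tidy.gnd_pca
#' @method glance gnd_pca
#' @export
glance.gnd_pca <- function(x, ...) {
  tibble::tibble(
    n_samples = x$n_samples,
    n_modes = length(x$dims),
    compression = compression_rate(x$core_dims, x$dims),
    final_cost = max(x$fit_history$cost),
    n_updates = nrow(x$fit_history))
}

#' Tidy the fit trace of a GND-PCA model
#'
#' `tidy()` returns the alternating-update cost trace (one row per mode
#' update); `glance()` a one-row model summary; `autoplot()` draws the
#' trace.
#'
#' @param x a `gnd_pca` model.
#' @param ... unused.
#' @return a tibble (`tidy`, `glance`) or a ggplot (`autoplot`).
#' @method tidy gnd_pca
#' @export
tidy.gnd_pca <- function(x, ...) x$fit_history

#' @rdname tidy.gnd_pca
#' @param object a `gnd_pca` model.
#' @method autoplot gnd_pca
#' @export
autoplot.gnd_pca <- function(object, ...) {
  df <- dplyr::mutate(object$fit_history,
                      update = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$update, y = .data$cost)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$iteration))) +
    ggplot2::labs(x = "mode update", y = "projected energy C'",
                  colour = "cycle",
                  title = "Alternating eigen-update convergence") +
    ggplot2::theme_minimal()
}
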