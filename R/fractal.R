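#' Fractal dimension estimation for gray-level images
#'
#' A gray-level image is treated as a height surface z = g(i, j): a flat
#' surface has fractal dimension 2, a space-filling rough one approaches 3.
#' Two classical estimators are provided. The *blanket* (covering) method
#' grows an upper and a lower envelope around the surface and reads the
#' dimension off the power law A(eps) = F * eps^(2 - D) relating estimated
#' surface area to scale. The *differential box-counting* method partitions
#' the image plane into grid cells, stacks gray-level boxes between each
#' cell's minimum and maximum intensity, and reads the dimension off
#' D_B = log N_delta / log(1/delta).
#'
#' @name fractal-dimension
#' @keywords internal
NULL

validate_gray <- function(pixels, min_side = 3L) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (nrow(pixels) < min_side || ncol(pixels) < min_side)
    stop("image must be at least ", min_side, "x", min_side, call. = FALSE)
  if (!all(is.finite(pixels)) || any(pixels < 0))
    stop("pixel values must be finite and non-negative", call. = FALSE)
  invisible(pixels)
}

#' Rescale intensities linearly onto the gray-level range
#'
#' Maps an arbitrary finite-valued array linearly onto `[0, gray_levels - 1]`.
#' Constant inputs map to 0. Float-valued images should pass through this
#' before fractal feature extraction so that gray levels and box heights are
#' commensurate.
#'
#' @param x numeric vector, matrix or array.
#' @param gray_levels number of gray levels G (default 256).
#' @return `x` rescaled onto `[0, gray_levels - 1]`, same shape.
#' @export
#' @examples
#' rescale_gray(matrix(rnorm(9), 3))
rescale_gray <- function(x, gray_levels = 256) {
  r <- range(x, finite = TRUE)
  if (r[1] == r[2]) return(array(0, dim = dim(x) %||% length(x)))
  out <- (x - r[1]) / (r[2] - r[1]) * (gray_levels - 1)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Create a blanket state from a gray image
#'
#' At scale eps = 0 both blanket surfaces coincide with the image:
#' u_0 = b_0 = g.
#'
#' @param pixels numeric matrix of gray levels (finite, non-negative, at
#'   least 3x3).
#' @return an object of class `blanket_state` with fields `upper`, `lower`
#'   and `epsilon`.
#' @seealso [dilate_blanket()], [blanket_dimension()]
#' @export
blanket_state <- function(pixels) {
  validate_gray(pixels)
  structure(list(upper = pixels, lower = pixels, epsilon = 0L),
            class = "blanket_state")
}

#' Grow the blanket by one scale step
#'
#' Advances the covering blanket from scale eps to eps + 1:
#' the upper surface becomes the maximum of itself plus one and its
#' 8-connected neighbourhood; the lower surface the minimum of itself minus
#' one and its neighbourhood. Border pixels use the neighbourhood clipped to
#' the image. The blanket thickness `upper - lower` therefore grows by at
#' least 2 everywhere per step.
#'
#' @param state a `blanket_state`.
#' @return a `blanket_state` at `epsilon + 1`.
#' @export
#' @examples
#' s <- blanket_state(matrix(5, 4, 4))
#' s1 <- dilate_blanket(s)
#' all(s1$upper == 6) && all(s1$lower == 4)
dilate_blanket <- function(state) {
  stopifnot(inherits(state, "blanket_state"))
  d <- cpp_dilate_blanket(state$upper, state$lower)
  structure(list(upper = d$upper, lower = d$lower,
                 epsilon = state$epsilon + 1L),
            class = "blanket_state")
}

#' Blanket volume at the current scale
#'
#' v_eps = sum over pixels of (u_eps - b_eps); zero at eps = 0.
#'
#' @param state a `blanket_state`.
#' @return the non-negative blanket volume.
#' @export
blanket_volume <- function(state) {
  stopifnot(inherits(state, "blanket_state"))
  sum(state$upper - state$lower)
}

#' Estimate the blanket fractal dimension of a gray image
#'
#' Iterates the blanket dilation for eps = 1..`max_epsilon`, computes the
#' surface area estimate A(eps) = (v_eps - v_(eps-1)) / 2, and fits the
#' power law A(eps) = F * eps^(2 - D). The default estimator regresses
#' log A(eps) on log eps by ordinary least squares (eps = 1 enters at
#' abscissa 0 and anchors the intercept log F); `method = "single"` instead
#' evaluates the closed form D = 2 - log(A(max)/F) / log(max) with F taken
#' from A(1), a one-scale approximation of the same law.
#'
#' @param pixels numeric matrix of gray levels.
#' @param max_epsilon largest blanket scale (integer >= 2, default 8).
#' @param method `"ols"` (default) or `"single"`.
#' @return an object of class `blanket_fit` with fields `epsilons`, `areas`,
#'   `volumes`, `dimension` (D1), and `scale_const` (F).
#' @export
#' @examples
#' fit <- blanket_dimension(matrix(7, 16, 16))
#' fit$dimension  # a flat surface has dimension 2
blanket_dimension <- function(pixels, max_epsilon = 8L,
                              method = c("ols", "single")) {
  validate_gray(pixels)
  method <- match.arg(method)
  max_epsilon <- as.integer(max_epsilon)
  if (max_epsilon < 2L) stop("`max_epsilon` must be >= 2", call. = FALSE)
  areas <- cpp_blanket_areas(pixels, max_epsilon)
  if (any(areas <= 0))
    stop("non-positive blanket area: blanket state is broken", call. = FALSE)
  eps <- seq_len(max_epsilon)
  lx <- log(eps)
  ly <- log(areas)
  if (method == "ols") {
    slope <- sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
    dimension <- 2 - slope
    scale_const <- exp(mean(ly) - slope * mean(lx))
  } else {
    scale_const <- areas[1]
    dimension <- 2 - (ly[max_epsilon] - log(scale_const)) / lx[max_epsilon]
  }
  structure(list(epsilons = eps, areas = areas,
                 volumes = cumsum(2 * areas), dimension = dimension,
                 scale_const = scale_const, method = method),
            class = "blanket_fit")
}

#' @export
print.blanket_fit <- function(x, ...) {
  cat("Blanket fractal fit: D1 =", format(x$dimension, digits = 5),
      "over eps = 1..", max(x$epsilons), "\n")
  invisible(x)
}

#' Differential box count of a gray image
#'
#' Partitions an R x R image into a `cells_per_side` x `cells_per_side` grid
#' of cells of side S = R / cells_per_side, stacks boxes of height
#' h = G * S / R along the gray axis (so the gray axis holds R/S boxes), and
#' counts for each cell n_delta = l - k + 1 where k and l index the boxes
#' containing the cell's minimum and maximum gray level. The single-scale
#' dimension is D_B = log N_delta / log(1/delta) with delta = S/R.
#'
#' Non-square or non-divisible images are cropped to the largest centred
#' square region divisible by the grid (the default policy); with
#' `crop = FALSE` such inputs raise an error.
#'
#' @param pixels numeric matrix with values in `[0, gray_levels - 1]`.
#' @param cells_per_side grid cells per side (positive integer).
#' @param gray_levels number of gray levels G (default 256).
#' @param crop crop to a centred divisible square (default TRUE).
#' @return an object of class `box_count_result` with fields
#'   `grid_cells_per_side`, `box_scale` (delta), `total_count` (N_delta) and
#'   `dimension` (D_B).
#' @export
#' @examples
#' box_count(matrix(10, 16, 16), 4)$dimension  # exactly 2 for a flat image
box_count <- function(pixels, cells_per_side, gray_levels = 256,
                      crop = TRUE) {
  validate_gray(pixels)
  cells_per_side <- as.integer(cells_per_side)
  if (cells_per_side < 1L) stop("`cells_per_side` must be positive")
  if (max(pixels) > gray_levels - 1)
    stop("pixel values exceed gray_levels - 1; rescale_gray() first",
         call. = FALSE)
  nr <- nrow(pixels); nc <- ncol(pixels)
  if (nr != nc || nr %% cells_per_side != 0L) {
    if (!crop)
      stop("image side not square/divisible by the grid and crop = FALSE",
           call. = FALSE)
    side <- cells_per_side * (min(nr, nc) %/% cells_per_side)
    if (side < cells_per_side)
      stop("`cells_per_side` larger than the image side", call. = FALSE)
    r0 <- (nr - side) %/% 2L
    c0 <- (nc - side) %/% 2L
    pixels <- pixels[r0 + seq_len(side), c0 + seq_len(side), drop = FALSE]
    nr <- side
  }
  if (cells_per_side > nr)
    stop("`cells_per_side` larger than the image side", call. = FALSE)
  total <- cpp_box_total(pixels, cells_per_side, gray_levels)
  delta <- (nr / cells_per_side) / nr
  structure(list(grid_cells_per_side = cells_per_side,
                 box_scale = delta,
                 total_count = total,
                 dimension = log(total) / log(1 / delta)),
            class = "box_count_result")
}

#' Global fractal feature vector of a gray image
#'
#' D1 is the blanket dimension; D2, D3, D4 are single-scale box-counting
#' dimensions on grids of 4, 8 and 16 cells per side (by default).
#'
#' @param pixels numeric matrix with values in `[0, gray_levels - 1]`.
#' @param max_epsilon blanket scales for D1 (default 8).
#' @param grids grid cells per side for the box features (default 4, 8, 16).
#' @param gray_levels number of gray levels (default 256).
#' @return a one-row tibble with columns `d1`, `d2`, `d3`, `d4` (one `d`
#'   column per grid).
#' @export
#' @examples
#' fractal_features(matrix(3, 32, 32))  # (2, 2, 2, 2) for a flat image
fractal_features <- function(pixels, max_epsilon = 8L, grids = c(4L, 8L, 16L),
                             gray_levels = 256) {
  d1 <- blanket_dimension(pixels, max_epsilon)$dimension
  dbox <- vapply(grids, function(g)
    box_count(pixels, g, gray_levels)$dimension, numeric(1))
  out <- c(d1, dbox)
  names(out) <- paste0("d", seq_along(out))
  tibble::as_tibble(as.list(out))
}

#' Per-slice fractal feature table for a volume
#'
#' Applies [fractal_features()] to every slice of a volume and binds the
#' rows, giving the flat feature table used for CSV export.
#'
#' @param volume 3-D numeric array or [gray_volume()].
#' @param sample_id identifier recorded in the first column.
#' @inheritParams fractal_features
#' @return a tibble with columns `sample_id`, `slice`, `d1`..`d4`.
#' @export
fractal_feature_table <- function(volume, sample_id = "sample",
                                  max_epsilon = 8L, grids = c(4L, 8L, 16L),
                                  gray_levels = 256) {
  vox <- as_voxel_array(volume)
  purrr::map_dfr(seq_len(dim(vox)[3]), function(s) {
    dplyr::bind_cols(
      tibble::tibble(sample_id = sample_id, slice = s),
      fractal_features(vox[, , s], max_epsilon, grids, gray_levels))
  })
}

#' Per-voxel sliding-window fractal map
#'
#' For every voxel, computes the chosen fractal feature on the
#' `window` x `window` patch of that voxel's slice centred at the voxel
#' (edges use symmetric reflection padding), producing a roughness map
#' aligned voxel-for-voxel with the input. Slices are processed in 2-D
#' because both estimators are defined on 2-D gray surfaces.
#'
#' The blanket feature `d1` requires an odd window (>= 9). Box features use
#' grids of 4 (`d2`), 8 (`d3`) and 16 (`d4`) cells per side and require the
#' window to be divisible by the grid; the default box window 32 is even, so
#' its patch extends one pixel less on the trailing side.
#'
#' @param volume 3-D numeric array or [gray_volume()].
#' @param feature one of `"d1"`, `"d2"`, `"d3"`, `"d4"`.
#' @param window patch side in pixels; defaults to 33 for `d1`, 32 otherwise.
#' @param max_epsilon blanket scales for `d1` (default 8).
#' @param gray_levels number of gray levels (default 256).
#' @param mask optional logical array of the volume's shape; voxels outside
#'   it are skipped (their map value is 0). Patches still read the full
#'   slice, so values near the mask boundary are unaffected.
#' @return numeric array with the spatial shape of `volume`.
#' @export
local_fractal_map <- function(volume, feature = c("d1", "d2", "d3", "d4"),
                              window = NULL, max_epsilon = 8L,
                              gray_levels = 256, mask = NULL) {
  feature <- match.arg(feature)
  vox <- as_voxel_array(volume)
  if (!is.null(mask) && !identical(dim(mask), dim(vox)))
    stop("`mask` must match the volume shape", call. = FALSE)
  window <- as.integer(window %||% if (feature == "d1") 33L else 32L)
  if (window > min(dim(vox)[1:2]))
    stop("`window` larger than the slice side", call. = FALSE)
  if (feature == "d1") {
    if (window < 9L || window %% 2L == 0L)
      stop("`window` must be odd and >= 9 for d1", call. = FALSE)
  } else {
    cells <- c(d2 = 4L, d3 = 8L, d4 = 16L)[[feature]]
    if (window %% cells != 0L)
      stop("`window` must be divisible by the box grid (", cells, ")",
           call. = FALSE)
  }
  out <- array(0, dim = dim(vox))
  for (s in seq_len(dim(vox)[3])) {
    sl <- vox[, , s]
    validate_gray(sl)
    msl <- if (is.null(mask)) {
      matrix(TRUE, nrow(sl), ncol(sl))
    } else {
      matrix(as.logical(mask[, , s]), nrow(sl), ncol(sl))
    }
    out[, , s] <- if (feature == "d1") {
      cpp_local_blanket_map(sl, window, as.integer(max_epsilon), msl)
    } else {
      cpp_local_box_map(sl, window, cells, as.integer(gray_levels), msl)
    }
  }
  out
}
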