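# Shared small fixtures, all generated in code.

# Random integer-valued gray image in [0, gmax].
rand_gray <- function(nr, nc = nr, gmax = 255, seed = 1) {
  set.seed(seed)
  matrix(sample(0:gmax, nr * nc, replace = TRUE), nr, nc)
}

# Gaussian blobs on a circle: k classes, n points each, first two dims carry
# the class structure.
make_blobs <- function(k, n, d = 2, sep = 4, noise = 0.5, seed = 1) {
  set.seed(seed)
  ang <- 2 * pi * (seq_len(k) - 1) / k
  centers <- cbind(sep * cos(ang), sep * sin(ang),
                   matrix(0, k, max(0, d - 2)))[, seq_len(d), drop = FALSE]
  x <- do.call(rbind, lapply(seq_len(k), function(i)
    matrix(rnorm(n * d, sd = noise), n, d) +
      matrix(centers[i, ], n, d, byrow = TRUE)))
  list(x = x, y = rep(paste0("class", letters[seq_len(k)]), each = n))
}

# Small phantom dataset for pipeline tests (desk-scale shape and windows).
small_phantom_config <- function(...) {
  validate_config(modifyList(list(
    volume_shape = c(32L, 32L, 6L), window_d1 = 9L, window_box = 16L,
    core_dims = c(2L, 2L, 2L, 5L), n_ants = 4L, max_cycles = 3L),
    list(...)))
}

small_phantom_dataset <- function(n_volumes = 3L, shape = c(32, 32, 6),
                                  seed = 7) {
  cl <- tibble::tibble(
    label = c("normal", "cirrhosis", "cancer", "hydatoncus"),
    hurst = c(0.7, 0.5, 0.3, 0.5),
    mean_intensity = c(100, 100, 150, 150),
    intensity_sd = 20,
    n_volumes = as.integer(n_volumes))
  generate_dataset(phantom_spec(cl, volume_shape = shape, seed = seed))
}
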