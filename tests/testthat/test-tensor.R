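test_that("mode unfolding is a bijective rearrangement and folding inverts it", {
  x <- array(1:8, c(2, 2, 2))
  for (n in 1:3)
    expect_setequal(as.vector(mode_unfold(x, n)), 1:8)

  set.seed(1)
  y <- array(rnorm(60), c(3, 4, 5))
  for (n in 1:3)
    expect_equal(mode_fold(mode_unfold(y, n), n, dim(y)), y)

  # rank-1 tensor unfolds to a rank-1 matrix
  a <- rnorm(3); b <- rnorm(4); c <- rnorm(5)
  r1 <- outer(outer(a, b), c)
  sv <- svd(mode_unfold(r1, 1))$d
  expect_lt(sv[2] / sv[1], 1e-12)

  expect_error(mode_unfold(y, 4), "out of range")
})

test_that("mode products match identity, scaling and the loop oracle", {
  set.seed(2)
  x <- array(rnorm(24), c(2, 3, 4))
  expect_equal(mode_product(x, diag(3), 2), x)
  expect_equal(mode_product(x, 2.5 * diag(4), 3), 2.5 * x)
  expect_error(mode_product(x, matrix(1, 2, 5), 2), "match the mode")

  for (seed in 1:50) {
    set.seed(seed)
    d <- sample(2:4, 3, replace = TRUE)
    x <- array(rnorm(prod(d)), d)
    n <- sample(1:3, 1)
    u <- matrix(rnorm(2 * d[n]), 2, d[n])
    expect_equal(mode_product(x, u, n), oracle_mode_product(x, u, n))
  }
  # and once on an order-4 tensor
  set.seed(99)
  x4 <- array(rnorm(16 * 3), c(2, 2, 4, 3))
  u <- matrix(rnorm(8), 2, 4)
  expect_equal(mode_product(x4, u, 3), oracle_mode_product(x4, u, 3))
})

test_that("a single-sample model starts at the truncated higher-order SVD and refines upward", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- array(rnorm(6 * 5 * 4 * 3), c(6, 5, 4, 3))
    core <- c(3, 3, 2, 2)
    fit0 <- fit_gnd_pca(list(x), core, iterations = 0, center = FALSE)
    for (n in 1:4) {
      ref <- oracle_hosvd_basis(x, n, core[n])
      expect_lt(principal_angle_max(fit0$bases[[n]], ref), 1e-6)
    }
    # projected energy at the start equals the truncated HOSVD core norm
    b <- x
    for (n in 1:4) b <- oracle_mode_product(
      b, t(oracle_hosvd_basis(x, n, core[n])), n)
    expect_equal(max(fit0$fit_history$cost), sum(b^2), tolerance = 1e-8)
    # alternating refinement can only improve on the HOSVD objective
    fit2 <- fit_gnd_pca(list(x), core, iterations = 2, center = FALSE)
    expect_gte(max(fit2$fit_history$cost), sum(b^2) - 1e-10)
  }
})

test_that("full-dimension subspaces reconstruct training samples exactly", {
  set.seed(3)
  samples <- lapply(1:4, function(i) array(rnorm(120), c(6, 5, 4)))
  fit <- fit_gnd_pca(samples, c(6, 5, 4))
  for (s in samples) {
    rec <- reconstruct(fit, project(fit, s))
    expect_equal(rec, s, tolerance = 1e-6)
    expect_equal(normalized_correlation(s, rec), 1, tolerance = 1e-9)
  }
})

test_that("rank-one variation around the mean is captured by unit core dims", {
  set.seed(4)
  r1 <- outer(outer(rnorm(5), rnorm(4)), rnorm(3))
  mean_t <- array(rnorm(60), c(5, 4, 3))
  samples <- lapply(c(-2, -0.5, 1, 3), function(s) mean_t + s * r1)
  fit <- fit_gnd_pca(samples, c(1, 1, 1))
  for (s in samples)
    expect_equal(normalized_correlation(
      s, reconstruct(fit, project(fit, s))), 1, tolerance = 1e-9)
})

test_that("alternating eigen-updates keep bases orthonormal and the cost non-decreasing", {
  set.seed(5)
  samples <- lapply(1:6, function(i) array(rnorm(6 * 5 * 4), c(6, 5, 4)))
  fit <- fit_gnd_pca(samples, c(3, 2, 2), iterations = 3)
  for (u in fit$bases)
    expect_equal(crossprod(u), diag(ncol(u)), tolerance = 1e-8)
  expect_false(is.unsorted(fit$fit_history$cost))
  expect_equal(nrow(fit$fit_history), 10)  # HOSVD start + 3 modes x 3 cycles

  expect_error(fit_gnd_pca(samples, c(7, 2, 2)), "J_n")
  expect_error(fit_gnd_pca(list(samples[[1]],
                                array(0, c(2, 2, 2))), c(2, 2, 2)),
               "same shape")
})

test_that("projection geometry: centring, Bessel, idempotence and Pythagoras", {
  set.seed(6)
  samples <- lapply(1:5, function(i) array(rnorm(6 * 5 * 4), c(6, 5, 4)))
  fit <- fit_gnd_pca(samples, c(3, 3, 2))

  expect_equal(max(abs(project(fit, fit$mean))), 0, tolerance = 1e-10)
  expect_equal(reconstruct(fit, array(0, c(3, 3, 2))), fit$mean)

  for (s in samples) {
    core <- project(fit, s)
    expect_lte(sum(core^2), sum((s - fit$mean)^2) + 1e-10)
    again <- project(fit, reconstruct(fit, core))
    expect_equal(again, core, tolerance = 1e-8)
  }

  resid <- sum(vapply(samples, function(s)
    sum((s - reconstruct(fit, project(fit, s)))^2), numeric(1)))
  total <- sum(vapply(samples, function(s)
    sum((s - fit$mean)^2), numeric(1)))
  expect_equal(resid, total - max(fit$fit_history$cost), tolerance = 1e-8)
})

test_that("normalized correlation behaves like a cosine similarity", {
  set.seed(7)
  x <- array(rnorm(24), c(2, 3, 4))
  expect_equal(normalized_correlation(x, x), 1)
  expect_equal(normalized_correlation(x, 3 * x), 1)
  y <- array(0, c(2, 3, 4)); y[1, 1, 1] <- 1
  z <- array(0, c(2, 3, 4)); z[2, 3, 4] <- 1
  expect_equal(normalized_correlation(y, z), 0)
  expect_error(normalized_correlation(x, array(0, c(2, 3, 4))), "zero")
  expect_error(normalized_correlation(x, array(1, c(2, 3, 5))), "differ")
})

test_that("compression rate is the mode-subspace volume ratio", {
  expect_equal(compression_rate(c(4, 4, 4), c(4, 4, 4)), 100)
  expect_equal(compression_rate(c(1, 1), c(10, 10)), 1)
  expect_error(compression_rate(c(2, 2), c(4, 4, 4)), "mismatch")
  expect_error(compression_rate(c(5, 2), c(4, 4)), "core_dims")
})

test_that("eigenface baseline reproduces classical PCA identities", {
  set.seed(8)
  samples <- lapply(1:6, function(i) array(rnorm(60), c(5, 4, 3)))
  fit <- fit_eigenface_pca(samples, 5)

  # M - 1 components span the centred samples exactly
  for (s in samples)
    expect_equal(reconstruct(fit, project(fit, s)), s, tolerance = 1e-6)

  # the mean projects to the origin
  mean_s <- array(fit$mean, c(5, 4, 3))
  expect_equal(max(abs(project(fit, mean_s))), 0, tolerance = 1e-8)

  # residual energy equals the discarded Gram eigenvalues
  fit2 <- fit_eigenface_pca(samples, 2)
  resid <- sum(vapply(samples, function(s)
    sum((s - reconstruct(fit2, project(fit2, s)))^2), numeric(1)))
  expect_equal(resid, sum(fit2$eigenvalues[3:6]), tolerance = 1e-6)

  expect_error(fit_eigenface_pca(samples, 6), "rank")
  expect_error(fit_eigenface_pca(samples[1], 1), "2 samples")
})

test_that("feature tensors stack gray and fractal channels with mask zeroing", {
  vol <- gray_volume(array(100, dim = c(24, 24, 2)),
                     mask = array(rep(c(TRUE, FALSE), each = 12 * 24 * 2),
                                  c(24, 24, 2)))
  ft <- build_feature_tensor(vol, window_d1 = 9L, window_box = 16L,
                             max_epsilon = 4L)
  expect_equal(dim(ft), c(24, 24, 2, 5))
  expect_equal(channel_kinds(ft), c("gray", rep("fractal", 4)))
  inside <- vol$mask
  expect_true(all(abs(ft[, , , 1][inside] - 100 / 255) < 1e-12))
  for (ch in 2:5) {
    expect_true(all(abs(ft[, , , ch][inside] - 2 / 3) < 1e-12))
    expect_true(all(ft[, , , ch][!inside] == 0))
  }
  expect_true(all(ft[, , , 1][!inside] == 0))
})

test_that("model tidiers summarise the fit trace", {
  set.seed(9)
  samples <- lapply(1:3, function(i) array(rnorm(36), c(4, 3, 3)))
  fit <- fit_gnd_pca(samples, c(2, 2, 2))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("iteration", "mode", "cost"))
  gl <- glance(fit)
  expect_equal(gl$n_samples, 3)
  expect_equal(gl$final_cost, max(td$cost))
  expect_s3_class(autoplot(fit), "ggplot")
})
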