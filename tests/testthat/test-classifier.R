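test_that("core vectorization tags gray and fractal entries by channel", {
  kinds <- c("gray", rep("fractal", 4))
  v <- vectorize_core(array(seq_len(40), c(2, 2, 2, 5)), kinds)
  expect_length(v$values, 40)
  expect_equal(sum(v$kinds == "gray"), 8)
  expect_equal(sum(v$kinds == "fractal"), 32)
  # flatten-then-reshape is the identity
  expect_equal(array(v$values, c(2, 2, 2, 5)),
               array(seq_len(40), c(2, 2, 2, 5)))
  # tags partition the index set
  expect_true(all(v$kinds %in% c("gray", "fractal")))
  # order-3 cores take a single tag
  v3 <- vectorize_core(array(1, c(2, 2, 2)), "gray")
  expect_true(all(v3$kinds == "gray"))
  expect_error(vectorize_core(array(1, c(2, 2, 3)), kinds), "per channel")
})

test_that("feature weighting scales tagged entries exactly", {
  kinds <- c("gray", rep("fractal", 4))
  v <- vectorize_core(array(rep(1, 40), c(2, 2, 2, 5)), kinds)
  expect_equal(apply_weights(v, 1, 1)$values, v$values)
  expect_equal(apply_weights(v, 0, 0)$values, rep(0, 40))
  w <- apply_weights(v)
  expect_equal(w$values[v$kinds == "fractal"], rep(0.6, 32))
  expect_equal(w$values[v$kinds == "gray"], rep(0.4, 8))
  expect_equal(w$weights_applied, c(fractal = 0.6, gray = 0.4))
})

test_that("feature scaler standardizes columns on training statistics", {
  set.seed(1)
  x <- cbind(rnorm(30, 5, 2), rnorm(30, -1, 0.1), rep(7, 30))
  sc <- fit_feature_scaler(x)
  xs <- scale_features(x, sc)
  expect_equal(colMeans(xs), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(apply(xs[, 1:2], 2, sd), c(1, 1), tolerance = 1e-12)
  expect_true(all(xs[, 3] == 0))  # constant column survives with scale 1
})

test_that("the decimal digit grid spans the documented parameter ranges", {
  nines <- decode_params(rep(9L, 10))
  expect_equal(nines$C, 999.99)
  expect_equal(nines$sigma, 9.9999)
  zeros <- decode_params(rep(0L, 10))
  expect_equal(zeros$C, 0)
  expect_equal(zeros$sigma, 0)
  expect_error(decode_params(rep(10L, 10)), "0..9")
  expect_error(encode_params(1000, 1), "999.99")
  expect_error(encode_params(1, 10), "9.9999")

  # encode/decode round-trip on 1000 random grid points
  set.seed(42)
  for (i in 1:1000) {
    digits <- sample(0:9, 10, replace = TRUE)
    p <- decode_params(digits)
    expect_identical(encode_params(p$C, p$sigma), as.integer(digits))
  }
})

test_that("one ant colony cycle reproduces a hand-stepped pheromone trace", {
  res <- aco_optimize(fitness = function(C, sigma) 0.8,
                      n_ants = 2L, max_cycles = 1L, rho = 0.1, tau0 = 0.5,
                      Q = 1, seed = 42L)
  o <- oracle_aco_one_cycle(2L, 0.1, 0.5, 1, 0.8, 42L)
  expect_equal(res$pheromone, o$tau, tolerance = 1e-12)
  expect_identical(res$digits, o$digits)
  expect_equal(res$accuracy, 0.8)
  p <- decode_params(o$digits)
  expect_equal(res$C, max(p$C, 0.01))
  expect_equal(res$sigma, max(p$sigma, 1e-4))
  expect_true(all(res$pheromone > 0))
})

test_that("a flat fitness landscape still yields a valid decoded path", {
  res <- aco_optimize(fitness = function(C, sigma) 0.5,
                      n_ants = 5L, max_cycles = 3L, seed = 7L)
  expect_equal(res$accuracy, 0.5)
  expect_length(res$digits, 10)
  expect_true(all(res$digits %in% 0:9))
  d <- decode_params(res$digits)
  expect_equal(res$C, max(d$C, 0.01))
  expect_true(all(res$pheromone > 0))
})

test_that("the search is reproducible and its best-so-far trace never decreases", {
  # deterministic bumpy fitness keeps the search running all cycles
  fit_fun <- function(C, sigma) 0.4 + 0.3 * abs(sin(C / 50)) +
    0.2 * abs(cos(sigma))
  a1 <- aco_optimize(fitness = fit_fun, n_ants = 6L, max_cycles = 8L,
                     seed = 11L)
  a2 <- aco_optimize(fitness = fit_fun, n_ants = 6L, max_cycles = 8L,
                     seed = 11L)
  expect_identical(a1$C, a2$C)
  expect_identical(a1$sigma, a2$sigma)
  expect_identical(a1$history, a2$history)
  expect_false(is.unsorted(a1$history$best_so_far))
  expect_equal(nrow(a1$history), 8)
})

test_that("the colony finds near-perfect parameters for separated blobs", {
  blobs <- make_blobs(2, 60, d = 5, sep = 1.5, noise = 0.5, seed = 0)
  res <- aco_optimize(blobs$x, blobs$y, cv_folds = 5L, n_ants = 10L,
                      max_cycles = 10L, seed = 1L)
  expect_gte(res$accuracy, 0.95)
  expect_error(aco_optimize(blobs$x, rep("a", 120), seed = 1), "2 classes")
})

test_that("DAG training builds k(k-1)/2 pairwise nodes and classifies blobs", {
  for (k in 2:6) {
    blobs <- make_blobs(k, 8, sep = 6, noise = 0.3, seed = k)
    dag <- train_dag_svm(blobs$x, blobs$y, C = 10, sigma = 1)
    expect_length(dag$nodes, k * (k - 1) / 2)
    expect_gte(mean(classify(dag, blobs$x) == blobs$y), 0.95)
  }
  blobs <- make_blobs(3, 6, sep = 6, seed = 1)
  expect_error(train_dag_svm(blobs$x[-(1:5), ], blobs$y[-(1:5)], 1, 1),
               "2 samples")
  expect_error(train_dag_svm(blobs$x, rep("z", 18), 1, 1), "2 classes")
})

test_that("DAG predictions are deterministic under sample permutation", {
  blobs <- make_blobs(4, 10, sep = 5, noise = 0.6, seed = 3)
  dag <- train_dag_svm(blobs$x, blobs$y, C = 10, sigma = 1)
  pred <- classify(dag, blobs$x)
  perm <- sample(seq_along(blobs$y))
  expect_identical(classify(dag, blobs$x[perm, ]), pred[perm])
})

test_that("DAG evaluation reports overall, per-node and confusion summaries", {
  blobs <- make_blobs(4, 10, sep = 6, noise = 0.3, seed = 5)
  dag <- train_dag_svm(blobs$x, blobs$y, C = 10, sigma = 1)
  ev <- evaluate_dag(dag, blobs$x, blobs$y)
  expect_equal(ev$accuracy, 1.0)
  expect_equal(nrow(ev$nodes), 6)
  expect_true(all(rowSums(ev$confusion) == 10))
  # the root node is visited by every sample
  root <- paste(dag$labels[1], dag$labels[4], sep = "|")
  expect_equal(ev$nodes$n_reaching[ev$nodes$node == root], 40L)
  expect_equal(glance(ev)$n_nodes, 6)
  expect_named(tidy(ev),
               c("node", "label_a", "label_b", "n_reaching", "n_scored",
                 "accuracy"))
})

test_that("weighted fractal features separate a roughness pair at least as well as gray-only", {
  # two classes identical in intensity, different in roughness; cores of a
  # small multilinear model feed the pairwise SVM
  ds <- small_phantom_dataset(n_volumes = 4)
  sel <- which(ds$labels %in% c("normal", "cirrhosis"))
  cfg <- small_phantom_config()
  tensors <- lapply(ds$volumes[sel], build_feature_tensor,
                    window_d1 = cfg$window_d1, window_box = cfg$window_box)
  kinds <- channel_kinds(tensors[[1]])
  split <- split_dataset(ds$labels[sel], 0.5, seed = 1)
  model <- fit_gnd_pca(tensors[split$train], cfg$core_dims)
  xall <- do.call(rbind, lapply(tensors, function(tn)
    vectorize_core(project(model, tn), kinds)$values))
  tags <- vectorize_core(project(model, tensors[[1]]), kinds)$kinds
  sc <- fit_feature_scaler(xall[split$train, , drop = FALSE])
  xs <- scale_features(xall, sc)
  y <- ds$labels[sel]
  acc_of <- function(x) {
    dag <- train_dag_svm(x[split$train, , drop = FALSE], y[split$train],
                         C = 10, sigma = 2)
    mean(classify(dag, x[split$test, , drop = FALSE]) == y[split$test])
  }
  xw <- sweep(xs, 2, ifelse(tags == "fractal", 0.6, 0.4), `*`)
  expect_gte(acc_of(xw), acc_of(xs[, tags == "gray", drop = FALSE]))
})
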