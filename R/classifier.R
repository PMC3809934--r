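#' Flatten a core tensor into a tagged feature vector
#'
#' Flattens in R's native column-major order (mode 1 fastest, the trailing
#' channel mode slowest) and tags every entry as `"gray"` or `"fractal"`
#' according to its channel-mode index, so that channel-aware weighting can
#' be applied downstream.
#'
#' @param core numeric array (a projected core tensor). For an order-4 core
#'   the last mode is the channel mode.
#' @param channel_kinds character vector of per-channel tags, one per entry
#'   of the last mode (recycled over the flattened vector), or a single tag
#'   for order-3 per-channel models.
#' @return an object of class `core_vector`: list with `values`, `kinds`
#'   (per-entry tag) and `weights_applied`.
#' @export
#' @examples
#' v <- vectorize_core(array(1, c(2, 2, 2, 5)),
#'                     c("gray", rep("fractal", 4)))
#' table(v$kinds)  # 8 gray, 32 fractal
vectorize_core <- function(core, channel_kinds = "gray") {
  core <- unclass(core)
  d <- dim(core) %||% length(core)
  if (length(channel_kinds) > 1L) {
    if (length(channel_kinds) != d[length(d)])
      stop("`channel_kinds` must have one tag per channel", call. = FALSE)
    kinds <- rep(channel_kinds, each = prod(d[-length(d)]))
  } else {
    kinds <- rep(channel_kinds, prod(d))
  }
  structure(list(values = as.vector(core), kinds = kinds,
                 weights_applied = c(fractal = 1, gray = 1)),
            class = "core_vector")
}

#' Weight fractal and gray entries of a feature vector
#'
#' Multiplies fractal-tagged entries by `w_fractal` and gray-tagged entries
#' by `w_gray`. Weighting is meaningful on commensurate scales, so in the
#' classification pipeline per-dimension standardization (training-set
#' statistics, see [fit_feature_scaler()]) is applied first; this function
#' itself only applies the weights.
#'
#' @param vec a `core_vector` from [vectorize_core()].
#' @param w_fractal,w_gray non-negative weights (defaults 0.6 and 0.4, the
#'   values found to discriminate best when fractal channels are fewer than
#'   gray ones).
#' @return the weighted `core_vector`.
#' @export
apply_weights <- function(vec, w_fractal = 0.6, w_gray = 0.4) {
  stopifnot(inherits(vec, "core_vector"), w_fractal >= 0, w_gray >= 0)
  w <- ifelse(vec$kinds == "fractal", w_fractal, w_gray)
  vec$values <- vec$values * w
  vec$weights_applied <- c(fractal = w_fractal, gray = w_gray)
  vec
}

#' Per-dimension standardization fitted on a training matrix
#'
#' @param x numeric matrix, rows are samples.
#' @return a `feature_scaler`: list with `center` and `scale` (zero-variance
#'   columns get scale 1).
#' @export
fit_feature_scaler <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  structure(list(center = ctr, scale = scl), class = "feature_scaler")
}

#' @rdname fit_feature_scaler
#' @param scaler a fitted `feature_scaler`.
#' @return `scale_features()`: the standardized matrix.
#' @export
scale_features <- function(x, scaler) {
  sweep(sweep(x, 2, scaler$center), 2, scaler$scale, `/`)
}

#' Decimal-digit encoding of SVM hyperparameters
#'
#' The penalty C and the kernel width sigma are discretized to five decimal
#' digits each for the ant-colony search: C's top digit is the hundreds
#' place (range 0 to 999.99, grid step 0.01), sigma's top digit is the ones
#' place (range 0 to 9.9999, grid step 0.0001). `encode_params()` rounds to
#' the grid and returns the 10 digits (C first); `decode_params()` is its
#' exact inverse on the grid.
#'
#' @param C penalty in `[0, 999.99]`.
#' @param sigma kernel width in `[0, 9.9999]`.
#' @return `encode_params()`: integer vector of 10 digits in 0..9.
#' @export
#' @examples
#' decode_params(rep(9L, 10))  # C = 999.99, sigma = 9.9999
encode_params <- function(C, sigma) {
  if (C < 0 || C > 999.99) stop("C out of [0, 999.99]", call. = FALSE)
  if (sigma < 0 || sigma > 9.9999) stop("sigma out of [0, 9.9999]",
                                        call. = FALSE)
  to_digits <- function(n) (n %/% 10^(4:0)) %% 10
  as.integer(c(to_digits(round(C * 100)), to_digits(round(sigma * 10000))))
}

#' @rdname encode_params
#' @param digits integer vector of 10 digits in 0..9.
#' @return `decode_params()`: list with elements `C` and `sigma`.
#' @export
decode_params <- function(digits) {
  digits <- as.integer(digits)
  if (length(digits) != 10L || any(digits < 0L) || any(digits > 9L))
    stop("`digits` must be 10 values in 0..9", call. = FALSE)
  list(C = sum(digits[1:5] * c(100, 10, 1, 0.1, 0.01)),
       sigma = sum(digits[6:10] * c(1, 0.1, 0.01, 0.001, 0.0001)))
}

# Binary RBF-SVM with the width convention exp(-||x-y||^2 / (2 sigma^2)).
svm_rbf <- function(x, y, C, sigma) {
  e1071::svm(x = x, y = factor(y), type = "C-classification",
             kernel = "radial", gamma = 1 / (2 * sigma^2), cost = C,
             scale = FALSE)
}

clamp_params <- function(p) {
  list(C = max(p$C, 0.01), sigma = max(p$sigma, 1e-4))
}

#' Train a DAG-arranged multiclass RBF-SVM
#'
#' Trains one binary RBF-SVM per unordered pair of class labels, all
#' sharing the penalty `C` and kernel width `sigma`, and arranges them as a
#' directed acyclic decision graph: labels are sorted lexicographically,
#' the root node compares the first against the last label, and every node
#' eliminates one label until a single one remains (k - 1 decisions for k
#' classes).
#'
#' @param x numeric matrix of features, rows are samples.
#' @param y class labels (coerced to character), at least 2 classes with at
#'   least 2 samples each.
#' @param C penalty factor (> 0).
#' @param sigma RBF kernel width (> 0); the kernel is
#'   `exp(-||x - y||^2 / (2 sigma^2))`.
#' @return an object of class `dag_svm` with fields `labels`, `nodes`
#'   (named list of `k(k-1)/2` binary SVMs), `C`, `sigma`.
#' @export
train_dag_svm <- function(x, y, C, sigma) {
  x <- as.matrix(x)
  y <- as.character(y)
  labels <- sort(unique(y))
  k <- length(labels)
  if (k < 2) stop("need at least 2 classes", call. = FALSE)
  counts <- table(y)
  if (any(counts < 2))
    stop("every class needs at least 2 samples", call. = FALSE)
  nodes <- list()
  for (a in seq_len(k - 1)) for (b in seq((a + 1), k)) {
    sel <- y %in% labels[c(a, b)]
    nodes[[paste(labels[a], labels[b], sep = "|")]] <-
      svm_rbf(x[sel, , drop = FALSE], y[sel], C, sigma)
  }
  structure(list(labels = labels, nodes = nodes, C = C, sigma = sigma),
            class = "dag_svm")
}

#' @export
print.dag_svm <- function(x, ...) {
  cat(sprintf("DAG-SVM: %d classes, %d binary nodes (C = %g, sigma = %g)\n",
              length(x$labels), length(x$nodes), x$C, x$sigma))
  invisible(x)
}

dag_traverse <- function(model, xrow) {
  labels <- model$labels
  l <- 1L; r <- length(labels)
  path <- character(0)
  while (l < r) {
    key <- paste(labels[l], labels[r], sep = "|")
    pred <- as.character(predict(model$nodes[[key]],
                                 matrix(xrow, nrow = 1)))
    path <- c(path, key)
    if (pred == labels[l]) r <- r - 1L else l <- l + 1L
  }
  list(label = labels[l], path = path)
}

#' Classify samples with a DAG-SVM
#'
#' Deterministic traversal of the decision graph: each internal node's
#' binary SVM eliminates one candidate label; the surviving label is
#' returned after k - 1 decisions.
#'
#' @param model a `dag_svm`.
#' @param x numeric matrix (rows are samples) or a single feature vector.
#' @return character vector of predicted labels.
#' @export
classify <- function(model, x) {
  stopifnot(inherits(model, "dag_svm"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  vapply(seq_len(nrow(x)),
         function(i) dag_traverse(model, x[i, ])$label, character(1))
}

#' Evaluate a DAG-SVM on labelled data
#'
#' Reports overall accuracy, the confusion matrix, and for every binary
#' node the accuracy over the samples that reached it during traversal and
#' whose true label belongs to that node's pair.
#'
#' @param model a `dag_svm`.
#' @param x numeric matrix of features.
#' @param y true labels.
#' @return an object of class `dag_evaluation`: list with `accuracy`,
#'   `confusion` (table) and `nodes` (tibble: node, label_a, label_b,
#'   n_reaching, n_scored, accuracy).
#' @export
evaluate_dag <- function(model, x, y) {
  x <- as.matrix(x)
  y <- as.character(y)
  trav <- lapply(seq_len(nrow(x)), function(i) dag_traverse(model, x[i, ]))
  pred <- vapply(trav, `[[`, character(1), "label")
  keys <- names(model$nodes)
  node_stats <- purrr::map_dfr(keys, function(key) {
    pair <- strsplit(key, "|", fixed = TRUE)[[1]]
    reached <- vapply(trav, function(t) key %in% t$path, logical(1))
    scored <- reached & y %in% pair
    acc <- if (any(scored)) {
      hits <- vapply(which(scored), function(i) {
        as.character(predict(model$nodes[[key]],
                             matrix(x[i, ], nrow = 1))) == y[i]
      }, logical(1))
      mean(hits)
    } else NA_real_
    tibble::tibble(node = key, label_a = pair[1], label_b = pair[2],
                   n_reaching = sum(reached), n_scored = sum(scored),
                   accuracy = acc)
  })
  structure(list(accuracy = mean(pred == y),
                 confusion = table(truth = factor(y, model$labels),
                                   prediction = factor(pred, model$labels)),
                 nodes = node_stats,
                 predictions = tibble::tibble(truth = y, prediction = pred)),
            class = "dag_evaluation")
}

#' @export
print.dag_evaluation <- function(x, ...) {
  cat(sprintf("DAG-SVM evaluation: accuracy %.3f over %d samples\n",
              x$accuracy, nrow(x$predictions)))
  print(x$confusion)
  invisible(x)
}

#' @rdname evaluate_dag
#' @method tidy dag_evaluation
#' @export
tidy.dag_evaluation <- function(x, ...) x$nodes

#' @rdname evaluate_dag
#' @method glance dag_evaluation
#' @export
glance.dag_evaluation <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy,
                 n = nrow(x$predictions),
                 n_nodes = nrow(x$nodes))
}

# Deterministic stratified k-fold assignment (uses the current RNG stream).
stratified_folds <- function(y, k) {
  y <- as.character(y)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Cross-validated DAG-SVM accuracy as the ACO fitness; folds are drawn once
# so every candidate is scored on the same partition.
make_cv_fitness <- function(x, y, cv_folds) {
  y <- as.character(y)
  if (cv_folds > min(table(y)))
    stop("cv_folds exceeds the smallest class count; folds would lose a ",
         "class", call. = FALSE)
  fold <- stratified_folds(y, cv_folds)
  function(C, sigma) {
    hits <- 0L
    for (f in seq_len(cv_folds)) {
      tr <- fold != f
      model <- train_dag_svm(x[tr, , drop = FALSE], y[tr], C, sigma)
      pred <- classify(model, x[!tr, , drop = FALSE])
      hits <- hits + sum(pred == y[!tr])
    }
    hits / length(y)
  }
}

#' Ant colony optimization of SVM hyperparameters
#'
#' Searches the 10-column decimal-digit graph (five digits for C, five for
#' sigma) with an ant colony: in the first cycle ants pick digits uniformly
#' at random; afterwards they follow the Ant Colony System
#' pseudo-random-proportional rule (with probability `q0` the highest-
#' pheromone digit, otherwise sampling proportional to pheromone; the
#' heuristic term is identically 1). After every move the chosen cell is
#' locally evaporated towards `tau0` (`tau <- (1 - rho) tau + rho tau0`);
#' after each cycle the best ant's path is reinforced by `Q * Acc`, where
#' Acc is that cycle's best fitness. The default fitness is stratified
#' `cv_folds`-fold cross-validated accuracy of the (DAG-)SVM on the
#' training set. Decoded parameters of 0 are clamped to the smallest
#' positive grid values (0.01, 0.0001) before training.
#'
#' @param x feature matrix (rows are samples); ignored when `fitness` is
#'   supplied.
#' @param y class labels; ignored when `fitness` is supplied.
#' @param fitness optional function `(C, sigma) -> accuracy in [0, 1]`
#'   replacing the cross-validation fitness.
#' @param cv_folds stratified folds for the default fitness (default 5).
#' @param n_ants ants per cycle (default 20).
#' @param max_cycles cycle budget (default 50).
#' @param rho local evaporation rate in (0, 1) (default 0.1).
#' @param q0 exploitation probability (default 0.9).
#' @param tau0 local-update pheromone level (default 1; pheromone is also
#'   initialized at 1).
#' @param Q pheromone intensity of the global update (default 1).
#' @param target_acc stop early once the best accuracy reaches this
#'   (default 1).
#' @param seed integer seed; the search is exactly reproducible given it.
#' @return an object of class `aco_result`: list with `C`, `sigma`,
#'   `accuracy`, `digits`, `pheromone` (10 x 10 matrix, rows digits 0-9,
#'   columns positions), `history` (tibble per cycle) and `config`.
#' @export
aco_optimize <- function(x = NULL, y = NULL, fitness = NULL, cv_folds = 5L,
                         n_ants = 20L, max_cycles = 50L, rho = 0.1,
                         q0 = 0.9, tau0 = 1, Q = 1, target_acc = 1,
                         seed = 1L) {
  stopifnot(n_ants >= 1, max_cycles >= 1, rho > 0, rho < 1, Q > 0)
  if (is.null(fitness)) {
    if (is.null(x) || is.null(y))
      stop("supply `x` and `y`, or a `fitness` function", call. = FALSE)
    if (length(unique(as.character(y))) < 2)
      stop("need at least 2 classes", call. = FALSE)
  }
  with_seed(seed, {
    if (is.null(fitness)) fitness <- make_cv_fitness(as.matrix(x), y,
                                                     cv_folds)
    tau <- matrix(1, nrow = 10, ncol = 10)  # rows: digits 0-9
    best <- list(acc = -Inf, digits = NULL, C = NA, sigma = NA)
    history <- list()
    for (cycle in seq_len(max_cycles)) {
      paths <- matrix(0L, nrow = n_ants, ncol = 10)
      accs <- numeric(n_ants)
      for (ant in seq_len(n_ants)) {
        for (col in 1:10) {
          d <- if (cycle == 1L) {
            sample.int(10L, 1L) - 1L
          } else if (runif(1) < q0) {
            which.max(tau[, col]) - 1L
          } else {
            sample.int(10L, 1L, prob = tau[, col]) - 1L
          }
          paths[ant, col] <- d
          tau[d + 1L, col] <- (1 - rho) * tau[d + 1L, col] + rho * tau0
        }
        p <- clamp_params(decode_params(paths[ant, ]))
        accs[ant] <- fitness(p$C, p$sigma)
      }
      top <- which.max(accs)
      for (col in 1:10)
        tau[paths[top, col] + 1L, col] <-
          tau[paths[top, col] + 1L, col] + Q * accs[top]
      if (accs[top] > best$acc) {
        p <- clamp_params(decode_params(paths[top, ]))
        best <- list(acc = accs[top], digits = paths[top, ],
                     C = p$C, sigma = p$sigma)
      }
      history[[cycle]] <- tibble::tibble(
        cycle = cycle, cycle_best = accs[top], best_so_far = best$acc,
        C = best$C, sigma = best$sigma)
      if (best$acc >= target_acc) break
    }
    structure(list(C = best$C, sigma = best$sigma, accuracy = best$acc,
                   digits = best$digits, pheromone = tau,
                   history = dplyr::bind_rows(history),
                   config = list(n_ants = n_ants, max_cycles = max_cycles,
                                 rho = rho, q0 = q0, tau0 = tau0, Q = Q,
                                 target_acc = target_acc, seed = seed)),
              class = "aco_result")
  })
}

#' @export
print.aco_result <- function(x, ...) {
  cat(sprintf(
    "ACO-SVM search: best C = %g, sigma = %g, accuracy = %.4f (%d cycles)\n",
    x$C, x$sigma, x$accuracy, nrow(x$history)))
  invisible(x)
}

#' Tidiers and plot for an ACO search
#'
#' `tidy()` returns the per-cycle search history, `glance()` a one-row
#' summary, `autoplot()` the best-so-far accuracy trace.
#'
#' @param x,object an `aco_result`.
#' @param ... unused.
#' @method tidy aco_result
#' @export
tidy.aco_result <- function(x, ...) x$history

#' @rdname tidy.aco_result
#' @method glance aco_result
#' @export
glance.aco_result <- function(x, ...) {
  tibble::tibble(C = x$C, sigma = x$sigma, accuracy = x$accuracy,
                 cycles = nrow(x$history))
}

#' @rdname tidy.aco_result
#' @method autoplot aco_result
#' @export
autoplot.aco_result <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$cycle)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$best_so_far)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$cycle_best), alpha = 0.6) +
    ggplot2::labs(y = "cross-validated accuracy",
                  title = "Ant colony search progress") +
    ggplot2::theme_minimal()
}
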