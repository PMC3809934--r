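#' Validate and normalize a pipeline run configuration
#'
#' Fills defaults (feature weights 0.6/0.4, two alternating cycles, box
#' grids 4/8/16, blanket scales up to 8, windows 33/32, volume shape
#' 64 x 64 x 10, core dims 2 x 2 x 2 with the channel mode kept full —
#' compact enough that the sigma grid of the ant-colony search can reach
#' typical distances between standardized core vectors),
#' checks ranges, and verifies any referenced paths exist.
#'
#' @param config named list of overrides (may be empty).
#' @return the normalized config (class `run_config`).
#' @export
#' @examples
#' validate_config(list())$w_fractal  # 0.6
validate_config <- function(config = list()) {
  defaults <- list(
    volume_shape = c(64L, 64L, 10L),
    n_channels = 5L,
    core_dims = NULL,          # filled below: c(2, 2, 2, n_channels)
    iterations = 2L,
    max_epsilon = 8L,
    grids = c(4L, 8L, 16L),
    window_d1 = 33L,
    window_box = 32L,
    gray_levels = 256,
    w_fractal = 0.6,
    w_gray = 0.4,
    n_ants = 10L,
    max_cycles = 10L,
    rho = 0.1,
    q0 = 0.9,
    tau0 = 1,
    Q = 1,
    target_acc = 1,
    cv_folds = 5L,
    split_seed = 1L,
    aco_seed = 1L,
    train_fraction = 0.5,
    paths = list(),
    out_dir = NULL)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config entries: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- modifyList(defaults, config)
  # modifyList drops unnamed list members, so pass `paths` through directly
  if ("paths" %in% names(config)) cfg$paths <- config$paths
  if (is.null(cfg$core_dims))
    cfg$core_dims <- c(2L, 2L, 2L, cfg$n_channels)
  if (cfg$w_fractal < 0 || cfg$w_gray < 0)
    stop("feature weights must be non-negative", call. = FALSE)
  if (cfg$iterations < 1) stop("`iterations` must be >= 1", call. = FALSE)
  if (cfg$max_epsilon < 2) stop("`max_epsilon` must be >= 2", call. = FALSE)
  if (length(cfg$core_dims) != 4L)
    stop("`core_dims` must have 4 entries (rows, cols, slices, channels)",
         call. = FALSE)
  full <- c(cfg$volume_shape, cfg$n_channels)
  if (any(cfg$core_dims < 1) || any(cfg$core_dims > full))
    stop("`core_dims` must satisfy 1 <= J_n <= volume dimension",
         call. = FALSE)
  if (cfg$train_fraction <= 0 || cfg$train_fraction >= 1)
    stop("`train_fraction` must be inside (0, 1)", call. = FALSE)
  for (p in unlist(cfg$paths))
    if (!file.exists(p)) stop("path does not exist: ", p, call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Leave-one-out reconstruction study over a core-dimension ladder
#'
#' For each core size: fits the multilinear model on all volumes but one,
#' reconstructs the held-out volume through project + reconstruct (using
#' the training mean only), and records its normalized correlation; also
#' records the mean training-reconstruction NC of a model fitted on all
#' volumes, the compression rate, and an eigenface PCA baseline at a
#' matched coefficient budget (principal axes capped by the training rank).
#'
#' @param volumes list of 3-D arrays or [gray_volume()]s (at least 2), all
#'   the same shape.
#' @param core_ladder list of length-3 integer vectors of mode-subspace
#'   dimensions, e.g. `list(c(5, 5, 3), c(16, 16, 5))`.
#' @param iterations alternating cycles per fit (default 2).
#' @param baseline include the eigenface PCA baseline (default TRUE).
#' @return an object of class `reconstruction_report`: tibble with one row
#'   per core size (`core`, `compression`, `nc_train`, `nc_loo`,
#'   `nc_pca_loo`) plus the last fit's cost trace in
#'   `attr(, "fit_history")`.
#' @export
run_reconstruction_study <- function(volumes, core_ladder,
                                     iterations = 2L, baseline = TRUE) {
  vols <- lapply(volumes, as_voxel_array)
  m <- length(vols)
  if (m < 2) stop("need at least 2 volumes", call. = FALSE)
  d <- dim(vols[[1]])
  fit_history <- NULL
  rows <- purrr::map_dfr(core_ladder, function(core) {
    core <- as.integer(core)
    full_fit <- fit_gnd_pca(vols, core, iterations = iterations)
    fit_history <<- full_fit$fit_history
    nc_train <- mean(vapply(vols, function(v)
      normalized_correlation(v, reconstruct(full_fit,
                                            project(full_fit, v))),
      numeric(1)))
    nc_loo <- mean(vapply(seq_len(m), function(i) {
      fit <- fit_gnd_pca(vols[-i], core, iterations = iterations)
      normalized_correlation(vols[[i]],
                             reconstruct(fit, project(fit, vols[[i]])))
    }, numeric(1)))
    nc_pca <- NA_real_
    if (baseline && m >= 3) {
      budget <- min(m - 2L, prod(core))
      nc_pca <- mean(vapply(seq_len(m), function(i) {
        fit <- fit_eigenface_pca(vols[-i], budget)
        normalized_correlation(vols[[i]],
                               reconstruct(fit, project(fit, vols[[i]])))
      }, numeric(1)))
    }
    comp <- compression_rate(core, d)
    label <- paste(core, collapse = "x")
    js <- core
    tibble::tibble(core = label,
                   j1 = js[1], j2 = js[2], j3 = js[3],
                   compression = comp,
                   nc_train = nc_train, nc_loo = nc_loo,
                   nc_pca_loo = nc_pca)
  })
  structure(rows, fit_history = fit_history,
            class = c("reconstruction_report", class(rows)))
}

#' @rdname run_reconstruction_study
#' @param object a `reconstruction_report`.
#' @param ... unused.
#' @method autoplot reconstruction_report
#' @export
autoplot.reconstruction_report <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            dplyr::any_of(c("nc_train", "nc_loo",
                                            "nc_pca_loo")),
                            names_to = "measure", values_to = "nc")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$compression, y = .data$nc,
                                   colour = .data$measure)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "compression rate (%)",
                  y = "normalized correlation",
                  title = "Reconstruction quality vs mode-subspace size") +
    ggplot2::theme_minimal()
}

# Features -> core vectors for a set of volumes under a fitted model.
core_feature_matrix <- function(model, tensors, kinds) {
  vecs <- lapply(tensors, function(tn) vectorize_core(project(model, tn),
                                                      kinds))
  list(x = do.call(rbind, lapply(vecs, `[[`, "values")),
       kinds = vecs[[1]]$kinds)
}

weight_columns <- function(x, kinds, w_fractal, w_gray) {
  w <- ifelse(kinds == "fractal", w_fractal, w_gray)
  sweep(x, 2, w, `*`)
}

#' End-to-end classification study on a labelled volume dataset
#'
#' Runs the full pipeline at one go: stratified train/test split; order-4
#' feature tensors (gray + 4 fractal channels); GND-PCA fitted on the
#' training tensors; core tensors flattened, standardized and weighted;
#' then three classifiers are trained on the training half and scored on
#' the held-out half:
#' `wf_aco_svm` (fractal/gray weighting + ant-colony-tuned DAG-SVM),
#' `aco_svm` (unweighted features, ant-colony-tuned), and
#' `default_svm` (unweighted, fixed C = 1, sigma = 1).
#'
#' @param dataset a `phantom_dataset` or list with `volumes` and `labels`.
#' @param config a [validate_config()] list (defaults used when omitted).
#' @return an object of class `classification_report`: list with `methods`
#'   (tibble: method, accuracy), `nodes` (per-binary-node accuracies of the
#'   weighted classifier), `confusion`, `params` (tibble of tuned C, sigma
#'   per method), `split`, `fit_history` and `aco_history`.
#' @export
run_classification_study <- function(dataset, config = validate_config()) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  labels <- dataset$labels
  split <- split_dataset(labels, config$train_fraction, config$split_seed)
  tensors <- lapply(dataset$volumes, build_feature_tensor,
                    window_d1 = config$window_d1,
                    window_box = config$window_box,
                    max_epsilon = config$max_epsilon,
                    gray_levels = config$gray_levels)
  kinds4 <- channel_kinds(tensors[[1]])
  model <- fit_gnd_pca(tensors[split$train], config$core_dims,
                       iterations = config$iterations)
  train <- core_feature_matrix(model, tensors[split$train], kinds4)
  test <- core_feature_matrix(model, tensors[split$test], kinds4)
  y_train <- labels[split$train]
  y_test <- labels[split$test]
  scaler <- fit_feature_scaler(train$x)
  xs_train <- scale_features(train$x, scaler)
  xs_test <- scale_features(test$x, scaler)
  xw_train <- weight_columns(xs_train, train$kinds, config$w_fractal,
                             config$w_gray)
  xw_test <- weight_columns(xs_test, test$kinds, config$w_fractal,
                            config$w_gray)
  folds <- min(config$cv_folds, min(table(y_train)))

  run_aco <- function(xtr) aco_optimize(
    xtr, y_train, cv_folds = folds, n_ants = config$n_ants,
    max_cycles = config$max_cycles, rho = config$rho, q0 = config$q0,
    tau0 = config$tau0, Q = config$Q, target_acc = config$target_acc,
    seed = config$aco_seed)

  aco_w <- run_aco(xw_train)
  dag_w <- train_dag_svm(xw_train, y_train, aco_w$C, aco_w$sigma)
  eval_w <- evaluate_dag(dag_w, xw_test, y_test)

  aco_u <- run_aco(xs_train)
  dag_u <- train_dag_svm(xs_train, y_train, aco_u$C, aco_u$sigma)
  eval_u <- evaluate_dag(dag_u, xs_test, y_test)

  dag_d <- train_dag_svm(xs_train, y_train, C = 1, sigma = 1)
  eval_d <- evaluate_dag(dag_d, xs_test, y_test)

  structure(list(
    methods = tibble::tibble(
      method = c("wf_aco_svm", "aco_svm", "default_svm"),
      accuracy = c(eval_w$accuracy, eval_u$accuracy, eval_d$accuracy)),
    nodes = eval_w$nodes,
    confusion = eval_w$confusion,
    params = tibble::tibble(
      method = c("wf_aco_svm", "aco_svm", "default_svm"),
      C = c(aco_w$C, aco_u$C, 1),
      sigma = c(aco_w$sigma, aco_u$sigma, 1),
      cv_accuracy = c(aco_w$accuracy, aco_u$accuracy, NA)),
    split = split,
    fit_history = model$fit_history,
    aco_history = aco_w$history,
    config = config), class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("Held-out classification accuracy:\n")
  print(as.data.frame(x$methods), row.names = FALSE)
  cat("\nConfusion matrix (weighted fractal ACO-SVM):\n")
  print(x$confusion)
  invisible(x)
}

#' @rdname run_classification_study
#' @param x a `classification_report`.
#' @param ... unused.
#' @method tidy classification_report
#' @export
tidy.classification_report <- function(x, ...) x$methods

#' @rdname run_classification_study
#' @method glance classification_report
#' @export
glance.classification_report <- function(x, ...) {
  tibble::tibble(
    best_method = x$methods$method[which.max(x$methods$accuracy)],
    best_accuracy = max(x$methods$accuracy),
    n_train = length(x$split$train),
    n_test = length(x$split$test))
}

#' @rdname run_classification_study
#' @param object a `classification_report`.
#' @method autoplot classification_report
#' @export
autoplot.classification_report <- function(object, ...) {
  ggplot2::ggplot(object$methods,
                  ggplot2::aes(x = stats::reorder(.data$method,
                                                  .data$accuracy),
                               y = .data$accuracy)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "held-out accuracy",
                  title = "Classifier comparison") +
    ggplot2::theme_minimal()
}
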