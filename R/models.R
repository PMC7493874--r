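#' Specification of a convolutional fingerprint classifier
#'
#' Describes one network in the family used throughout the package: four
#' convolutional layers with ReLU activations, each followed by max pooling,
#' then a dense head of 1024/512/256 ReLU units and a single sigmoid output.
#' One-dimensional networks read a single signed fingerprint (length
#' `n_bits`); two-dimensional networks read a k x `n_bits` stack of distinct
#' fingerprint types and differ only in their kernel shape. Pooling is 2
#' along the bit axis and 2 along the row axis while rows remain (the row
#' axis stops being pooled once it reaches 1).
#'
#' @param dimensionality `"1d"` or `"2d"`.
#' @param conv_filters Four filter counts, one per convolutional layer.
#'   Direct classifiers default to 128/64/32/16; the stacked-ensemble member
#'   networks use 512/256/128/64.
#' @param kernel Kernel size: a single integer for 1D (one of 2/3/4 in the
#'   tuning grid); for 2D a pair `(length along bits, extent across rows)`,
#'   e.g. `c(3, 2)`.
#' @param padding `"same"` or `"valid"`.
#' @param dropout Dropout probability applied after each dense hidden layer
#'   during training (0 disables it; the tuning grid spans 0.2–0.9).
#' @param learning_rate Optimizer step size.
#' @param optimizer One of `"adam"`, `"adamax"`, `"sgd"`.
#' @param batch_size Minibatch size.
#' @param head_units Dense hidden layer sizes.
#' @param n_bits Fingerprint width.
#' @param seed Seed controlling weight initialization.
#' @return A `cnn_spec` object.
#' @export
cnn_spec <- function(dimensionality = c("1d", "2d"),
                     conv_filters = c(128, 64, 32, 16),
                     kernel = NULL,
                     padding = c("same", "valid"),
                     dropout = 0.5,
                     learning_rate = 1e-3,
                     optimizer = c("adam", "adamax", "sgd"),
                     batch_size = 32,
                     head_units = c(1024, 512, 256),
                     n_bits = 1024,
                     seed = 1) {
  dimensionality <- match.arg(dimensionality)
  padding <- match.arg(padding)
  optimizer <- match.arg(optimizer)
  if (length(conv_filters) != 4 || any(conv_filters < 1)) {
    stop_fpscreen("conv_filters must give four positive filter counts",
                  "fpscreen_validation_error")
  }
  if (is.null(kernel)) {
    kernel <- if (dimensionality == "1d") 3L else c(3L, 2L)
  }
  if (dimensionality == "1d" && length(kernel) != 1) {
    stop_fpscreen("1d networks take a single kernel size",
                  "fpscreen_validation_error")
  }
  if (dimensionality == "2d" && length(kernel) != 2) {
    stop_fpscreen("2d networks take a kernel pair (bits extent, row extent)",
                  "fpscreen_validation_error")
  }
  if (dropout < 0 || dropout > 0.9) {
    stop_fpscreen("dropout must lie in [0, 0.9]", "fpscreen_validation_error")
  }
  if (learning_rate <= 0) {
    stop_fpscreen("learning_rate must be positive",
                  "fpscreen_validation_error")
  }
  structure(
    list(dimensionality = dimensionality,
         conv_filters = as.integer(conv_filters),
         kernel = as.integer(kernel), padding = padding, dropout = dropout,
         learning_rate = learning_rate, optimizer = optimizer,
         batch_size = as.integer(batch_size),
         head_units = as.integer(head_units), n_bits = as.integer(n_bits),
         seed = as.integer(seed)),
    class = "cnn_spec"
  )
}

# the flat list the C++ engine consumes
engine_spec <- function(spec, k_rows) {
  if (spec$dimensionality == "1d") {
    kh <- 1L
    kw <- spec$kernel[1]
  } else {
    kw <- spec$kernel[1]   # along the bit axis
    kh <- spec$kernel[2]   # across fingerprint rows
  }
  list(in_rows = as.integer(k_rows), in_cols = spec$n_bits,
       conv_filters = spec$conv_filters, kh = kh, kw = kw,
       pad_same = spec$padding == "same", head_units = spec$head_units)
}

new_cnn_model <- function(spec, k_rows) {
  es <- engine_spec(spec, k_rows)
  dims <- .cnn_dims(es)                      # validates kernel vs shape
  weights <- .cnn_init(es, spec$seed)
  structure(
    list(spec = spec, k_rows = as.integer(k_rows), engine_spec = es,
         dims = dims, weights = weights,
         n_params = sum(vapply(weights, length, numeric(1)))),
    class = "cnn_model"
  )
}

#' Build an untrained 1D convolutional classifier
#'
#' @param spec A [cnn_spec()] with `dimensionality = "1d"`.
#' @return A `cnn_model` with freshly initialized weights (deterministic in
#'   `spec$seed`) and a `n_params` field.
#' @export
build_cnn1d <- function(spec = cnn_spec("1d")) {
  stopifnot(inherits(spec, "cnn_spec"))
  if (spec$dimensionality != "1d") {
    stop_fpscreen("spec is not one-dimensional", "fpscreen_validation_error")
  }
  new_cnn_model(spec, k_rows = 1L)
}

#' Build an untrained 2D convolutional classifier
#'
#' @param spec A [cnn_spec()] with `dimensionality = "2d"`.
#' @param k_rows Number of stacked fingerprint types (2–7). The kernel's row
#'   extent must not exceed `k_rows`.
#' @return A `cnn_model`.
#' @export
build_cnn2d <- function(spec = cnn_spec("2d"), k_rows) {
  stopifnot(inherits(spec, "cnn_spec"))
  if (spec$dimensionality != "2d") {
    stop_fpscreen("spec is not two-dimensional", "fpscreen_validation_error")
  }
  if (k_rows < 2 || k_rows > 7) {
    stop_fpscreen("k_rows must be between 2 and 7",
                  "fpscreen_validation_error")
  }
  tryCatch(
    new_cnn_model(spec, k_rows = k_rows),
    error = function(e) {
      stop_fpscreen(conditionMessage(e), "fpscreen_shape_error")
    }
  )
}

#' @export
print.cnn_model <- function(x, ...) {
  s <- x$spec
  cat(sprintf("%s CNN (%s input, %s)\n", toupper(s$dimensionality),
              paste0(x$k_rows, "x", s$n_bits),
              if (inherits(x, "trained_cnn")) "trained" else "untrained"))
  cat(sprintf("  conv filters %s, kernel %s, %s padding; head %s -> sigmoid\n",
              paste(s$conv_filters, collapse = "/"),
              paste(s$kernel, collapse = "x"), s$padding,
              paste(s$head_units, collapse = "/")))
  cat(sprintf("  %s parameters\n", format(x$n_params, big.mark = ",")))
  invisible(x)
}

check_input_matrix <- function(model, x) {
  expected <- model$k_rows * model$spec$n_bits
  if (!is.matrix(x)) x <- as.matrix(x)
  if (ncol(x) != expected) {
    stop_fpscreen(
      sprintf("input has %d features per compound; the model expects %d (%d x %d)",
              ncol(x), expected, model$k_rows, model$spec$n_bits),
      "fpscreen_shape_error"
    )
  }
  storage.mode(x) <- "double"
  x
}

#' Train a convolutional classifier
#'
#' Minimizes binary cross-entropy by minibatch gradient descent with the
#' spec's optimizer, evaluating the validation loss after every epoch. Early
#' stopping halts training after `patience` epochs without improvement, and
#' the returned weights are the checkpoint with the best validation loss,
#' not the last epoch. Training is deterministic given `seed` (single
#' threaded).
#'
#' @param model An untrained `cnn_model` (or a `trained_cnn` to continue).
#' @param x_train,x_val Input matrices from [fp_input()] (rows = compounds).
#' @param y_train,y_val Binary labels (0/1, logical, or active/inactive).
#' @param max_epochs Epoch cap.
#' @param patience Early-stopping patience in epochs (0 stops one epoch
#'   after the best).
#' @param monitor Validation quantity that drives checkpointing and early
#'   stopping: `"val_loss"` (default) or `"val_bacc"` (the discrimination
#'   metric itself).
#' @param seed Seed for shuffling and dropout.
#' @param verbose Print per-epoch progress.
#' @return A `trained_cnn`: the model plus a `history` tibble (epoch,
#'   train_loss, val_loss, val_bacc), `best_epoch` and `best_val_loss`.
#' @export
train_cnn <- function(model, x_train, y_train, x_val, y_val,
                      max_epochs = 100, patience = 10,
                      monitor = c("val_loss", "val_bacc"),
                      seed = model$spec$seed, verbose = FALSE) {
  monitor <- match.arg(monitor)
  stopifnot(inherits(model, "cnn_model"))
  x_train <- check_input_matrix(model, x_train)
  x_val <- check_input_matrix(model, x_val)
  y_train <- as_binary_labels(y_train, "y_train")
  y_val <- as_binary_labels(y_val, "y_val")
  stopifnot(length(y_train) == nrow(x_train), length(y_val) == nrow(x_val))
  if (length(unique(y_train)) < 2) {
    stop_fpscreen("training set contains a single class",
                  "fpscreen_validation_error")
  }
  res <- .cnn_train(model$weights, model$engine_spec, x_train, y_train,
                    x_val, y_val, as.integer(max_epochs),
                    as.integer(patience), model$spec$batch_size,
                    model$spec$learning_rate, model$spec$optimizer,
                    model$spec$dropout, as.integer(seed),
                    monitor == "val_bacc", isTRUE(verbose))
  out <- model
  out$weights <- res$weights
  out$history <- tibble(
    epoch = seq_along(res$train_loss),
    train_loss = res$train_loss,
    val_loss = res$val_loss,
    val_bacc = res$val_bacc
  )
  out$best_epoch <- res$best_epoch
  out$best_val_loss <- res$best_val_loss
  class(out) <- c("trained_cnn", class(model))
  out
}

#' Predict activity probabilities
#'
#' @param object A `cnn_model` or `trained_cnn`.
#' @param x Input matrix with the shape the model was built for.
#' @param ... Unused.
#' @return Numeric vector of probabilities in `[0, 1]`, one per row of `x`,
#'   in input order.
#' @export
predict.cnn_model <- function(object, x, ...) {
  x <- check_input_matrix(object, x)
  if (nrow(x) == 0) return(numeric(0))
  as.numeric(.cnn_predict(object$weights, object$engine_spec, x))
}

#' @rdname predict.cnn_model
#' @param model A model accepted by `predict()` (CNN, ensemble or baseline).
#' @export
predict_scores <- function(model, x, ...) {
  predict(model, x, ...)
}

#' @export
tidy.trained_cnn <- function(x, ...) x$history

#' @export
glance.trained_cnn <- function(x, ...) {
  tibble(
    dimensionality = x$spec$dimensionality,
    n_params = x$n_params,
    epochs_run = nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_loss = x$best_val_loss,
    best_val_bacc = x$history$val_bacc[x$best_epoch]
  )
}

#' @export
autoplot.trained_cnn <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                           names_to = "series", values_to = "loss")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2) +
    ggplot2::labs(title = "Training history",
                  subtitle = "dashed line: best checkpoint") +
    ggplot2::theme_minimal()
}

#' The hyperparameter grid
#'
#' Enumerates candidate specs over the tuning grid: first-layer filter
#' counts (subsequent layers halve, with a floor of 1), learning-rate decade
#' ladders over `[1e-6, 1]` and `[2e-5, 0.2]`, dropout 0.2–0.9 in steps of
#' 0.1, both padding modes, kernel sizes 2/3/4 (1D) or the ten 2D pairs,
#' batch sizes 8–128 in doublings, and all supported optimizers. The full
#' cartesian grid is large; [grid_search()] takes a `budget` to evaluate a
#' prefix of it.
#'
#' @param dimensionality `"1d"` or `"2d"`.
#' @param filters1,learning_rate,dropout,padding,batch_size,optimizer,kernels
#'   Grid axes; defaults follow the tuning protocol above.
#' @return A tibble with one row per candidate spec (`kernel` is a list
#'   column).
#' @export
grid_space <- function(dimensionality = c("1d", "2d"),
                       filters1 = c(1024, 512, 256, 128, 64, 32, 16),
                       learning_rate = sort(unique(c(10^(-6:0), 2 * 10^(-5:-1)))),
                       dropout = seq(0.2, 0.9, by = 0.1),
                       padding = c("same", "valid"),
                       batch_size = c(8, 16, 32, 64, 128),
                       optimizer = c("adam", "adamax", "sgd"),
                       kernels = NULL) {
  dimensionality <- match.arg(dimensionality)
  if (is.null(kernels)) {
    kernels <- if (dimensionality == "1d") {
      list(2L, 3L, 4L)
    } else {
      list(c(20L, 2L), c(20L, 1L), c(15L, 2L), c(15L, 1L), c(5L, 2L),
           c(5L, 1L), c(4L, 2L), c(4L, 1L), c(3L, 2L), c(3L, 1L))
    }
  }
  grid <- tidyr::expand_grid(
    filters1 = filters1, kernel = kernels, padding = padding,
    dropout = dropout, learning_rate = learning_rate,
    batch_size = batch_size, optimizer = optimizer
  )
  grid$dimensionality <- dimensionality
  grid
}

grid_row_spec <- function(row, head_units, n_bits, seed) {
  f1 <- row$filters1
  filters <- pmax(1, f1 / c(1, 2, 4, 8))
  cnn_spec(row$dimensionality, conv_filters = filters,
           kernel = row$kernel[[1]], padding = row$padding,
           dropout = row$dropout, learning_rate = row$learning_rate,
           optimizer = row$optimizer, batch_size = row$batch_size,
           head_units = head_units, n_bits = n_bits, seed = seed)
}

#' Grid search by cross-validated objective
#'
#' Evaluates candidate specs (the first `budget` rows of `space`) by k-fold
#' cross-validation on the training data, scoring each spec by the mean of
#' the chosen objective over folds: balanced accuracy for the discrimination
#' task, sensitivity for active-only early screening. Returns the full
#' leaderboard sorted by the objective.
#'
#' @param space A tibble from [grid_space()] (or any tibble with the same
#'   columns).
#' @param x Input matrix from [fp_input()].
#' @param y Binary labels.
#' @param objective `"bacc"` or `"sensitivity"`.
#' @param k Number of cross-validation folds.
#' @param budget Maximum number of specs to evaluate.
#' @param max_epochs,patience Per-fit training caps.
#' @param head_units Dense head sizes for every candidate.
#' @param seed Seed controlling fold assignment and training.
#' @param verbose Print progress.
#' @return A tibble: the evaluated rows of `space` plus `order_evaluated`,
#'   `mean_objective`, `sd_objective` and `rank`, sorted by rank.
#' @export
grid_search <- function(space, x, y, objective = c("bacc", "sensitivity"),
                        k = 10, budget = Inf, max_epochs = 20, patience = 3,
                        head_units = c(1024, 512, 256), seed = 1,
                        verbose = FALSE) {
  objective <- match.arg(objective)
  if (nrow(space) == 0) {
    stop_fpscreen("empty search space", "fpscreen_validation_error")
  }
  if (budget < 1) {
    stop_fpscreen("budget must be at least 1", "fpscreen_validation_error")
  }
  y <- as_binary_labels(y)
  k_rows <- attr(x, "k_rows") %||% 1L
  n_eval <- min(nrow(space), budget)
  space <- as_tibble(space)[seq_len(n_eval), , drop = FALSE]
  folds <- make_folds(tibble(compound_id = as.character(seq_len(nrow(x))),
                             label = y),
                      k = k, seed = seed)$fold
  scores <- matrix(NA_real_, nrow = n_eval, ncol = k)
  for (i in seq_len(n_eval)) {
    spec <- grid_row_spec(space[i, ], head_units, ncol(x) / k_rows, seed)
    for (f in seq_len(k)) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2) next
      model <- if (spec$dimensionality == "1d") {
        build_cnn1d(spec)
      } else {
        build_cnn2d(spec, k_rows = k_rows)
      }
      fit <- train_cnn(model, x[tr, , drop = FALSE], y[tr],
                       x[!tr, , drop = FALSE], y[!tr],
                       max_epochs = max_epochs, patience = patience,
                       seed = seed + f)
      p <- predict(fit, x[!tr, , drop = FALSE])
      cm <- confusion(y[!tr], as.numeric(p > 0.5))
      scores[i, f] <- if (objective == "bacc") {
        balanced_accuracy(cm)
      } else {
        sensitivity(cm)
      }
    }
    if (verbose) {
      inform(sprintf("spec %d/%d: mean %s = %.4f", i, n_eval, objective,
                     mean(scores[i, ], na.rm = TRUE)))
    }
  }
  out <- space
  out$order_evaluated <- seq_len(n_eval)
  out$mean_objective <- rowMeans(scores, na.rm = TRUE)
  out$sd_objective <- apply(scores, 1, stats::sd, na.rm = TRUE)
  out <- dplyr::arrange(out, dplyr::desc(.data$mean_objective))
  out$rank <- seq_len(nrow(out))
  attr(out, "objective") <- objective
  out
}
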