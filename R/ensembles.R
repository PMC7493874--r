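# Ensemble architectures over the per-fingerprint 1D CNNs: a hard-majority
# voting scheme and a stacked model whose MLP head reads the seven member
# output probabilities.

#' Majority vote over seven member labels
#'
#' @param labels A vector of exactly 7 binary labels, or a matrix with 7
#'   columns (one row per compound).
#' @return The label(s) held by at least 4 of the 7 members (0/1 integers).
#'   Membership is odd, so the vote never ties.
#' @export
majority_vote <- function(labels) {
  if (is.matrix(labels) || is.data.frame(labels)) {
    m <- as.matrix(labels)
    if (ncol(m) != 7) {
      stop_fpscreen("majority_vote expects exactly 7 member labels",
                    "fpscreen_validation_error")
    }
    votes <- rowSums(matrix(as_binary_labels(c(m)), nrow = nrow(m)))
    return(as.integer(votes >= 4))
  }
  v <- as_binary_labels(labels, "labels")
  if (length(v) != 7) {
    stop_fpscreen("majority_vote expects exactly 7 member labels",
                  "fpscreen_validation_error")
  }
  as.integer(sum(v) >= 4)
}

#' Head configuration of the stacked ensemble, per task
#'
#' The stacked ensemble's output head is a single hidden MLP layer over the
#' seven member probabilities. Its tuned settings differ by task: the
#' discrimination head uses 3 ReLU units with Adam at learning rate 1e-3;
#' the active-only (early screening) head uses 5 units with Adamax at 1e-4.
#'
#' @param task `"discrimination"` or `"active_only"`.
#' @return A `tmo_config` list: `task`, `hidden_units`, `learning_rate`,
#'   `optimizer`.
#' @export
tuned_mlp_out_config <- function(task = c("discrimination", "active_only")) {
  task <- match.arg(task)
  cfg <- if (task == "discrimination") {
    list(task = task, hidden_units = 3L, learning_rate = 1e-3,
         optimizer = "adam")
  } else {
    list(task = task, hidden_units = 5L, learning_rate = 1e-4,
         optimizer = "adamax")
  }
  structure(cfg, class = "tmo_config")
}

#' @rdname tuned_mlp_out_config
#' @param path JSON file path.
#' @export
write_tmo_config <- function(task, path) {
  cfg <- if (inherits(task, "tmo_config")) task else tuned_mlp_out_config(task)
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname tuned_mlp_out_config
#' @export
read_tmo_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$hidden_units <- as.integer(cfg$hidden_units)
  structure(cfg, class = "tmo_config")
}

# ---- small dense head (input 7 -> hidden ReLU -> sigmoid), trained in R ----

mlp_head_init <- function(n_in, n_hidden, seed) {
  set.seed(seed)
  lim1 <- sqrt(6 / (n_in + n_hidden))
  lim2 <- sqrt(6 / (n_hidden + 1))
  list(
    W1 = matrix(runif(n_hidden * n_in, -lim1, lim1), n_hidden, n_in),
    b1 = numeric(n_hidden),
    w2 = matrix(runif(n_hidden, -lim2, lim2), 1, n_hidden),
    b2 = 0
  )
}

mlp_head_forward <- function(w, X) {
  # X: n x n_in
  H <- pmax(X %*% t(w$W1) + matrix(w$b1, nrow(X), length(w$b1), byrow = TRUE),
            0)
  z <- drop(H %*% t(w$w2)) + w$b2
  list(H = H, p = 1 / (1 + exp(-z)))
}

mlp_head_train <- function(X, y, Xv, yv, config, seed = 1, max_epochs = 500,
                           patience = 50) {
  stopifnot(ncol(X) == 7)
  w <- mlp_head_init(ncol(X), config$hidden_units, seed)
  state <- lapply(w, function(x) list(m = x * 0, v = x * 0))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-7
  lr <- config$learning_rate
  t <- 0
  best <- list(val = Inf, w = w, epoch = 0)
  wait <- 0
  history <- numeric(0)
  n <- nrow(X)
  for (e in seq_len(max_epochs)) {
    fw <- mlp_head_forward(w, X)
    dz <- (fw$p - y) / n
    gH <- outer(dz, drop(w$w2)) * (fw$H > 0)
    g <- list(W1 = t(gH) %*% X, b1 = colSums(gH),
              w2 = matrix(colSums(fw$H * dz), 1), b2 = sum(dz))
    t <- t + 1
    for (nm in names(w)) {
      state[[nm]]$m <- b1 * state[[nm]]$m + (1 - b1) * g[[nm]]
      if (config$optimizer == "adamax") {
        state[[nm]]$v <- pmax(b2 * state[[nm]]$v, abs(g[[nm]]))
        w[[nm]] <- w[[nm]] - (lr / (1 - b1^t)) *
          state[[nm]]$m / (state[[nm]]$v + eps)
      } else if (config$optimizer == "adam") {
        state[[nm]]$v <- b2 * state[[nm]]$v + (1 - b2) * g[[nm]]^2
        w[[nm]] <- w[[nm]] - lr * (state[[nm]]$m / (1 - b1^t)) /
          (sqrt(state[[nm]]$v / (1 - b2^t)) + eps)
      } else {
        w[[nm]] <- w[[nm]] - lr * g[[nm]]
      }
    }
    vp <- mlp_head_forward(w, Xv)$p
    vloss <- bce_loss(vp, yv)
    history <- c(history, vloss)
    if (vloss < best$val) {
      best <- list(val = vloss, w = w, epoch = e)
      wait <- 0
    } else {
      wait <- wait + 1
      if (wait > patience) break
    }
  }
  list(weights = best$w, best_epoch = best$epoch, best_val_loss = best$val,
       val_loss = history, config = config)
}

check_member_inputs <- function(x_list) {
  if (is.null(names(x_list)) || !setequal(names(x_list), fp_types())) {
    stop_fpscreen(
      sprintf("inputs must be a named list covering all 7 fingerprint types (%s)",
              paste(setdiff(fp_types(), names(x_list)), collapse = ", ")),
      "fpscreen_validation_error"
    )
  }
  x_list[fp_types()]
}

member_probabilities <- function(members, x_list) {
  x_list <- check_member_inputs(x_list)
  P <- vapply(fp_types(), function(tt) predict(members[[tt]], x_list[[tt]]),
              numeric(nrow(x_list[[1]])))
  matrix(P, nrow = nrow(x_list[[1]]), ncol = 7,
         dimnames = list(NULL, fp_types()))
}

#' Train the stacked ensemble (Tuned-MLP-Out)
#'
#' Two-phase training of the stacked architecture. Phase 1 trains seven 1D
#' CNN members from scratch, one per fingerprint type, with 512/256/128/64
#' filters per layer (higher capacity than the direct classifiers). Phase 2
#' freezes the members and trains a one-hidden-layer MLP head on the seven
#' member output probabilities, with the per-task settings of
#' [tuned_mlp_out_config()].
#'
#' @param x_list Named list of training input matrices, one per fingerprint
#'   type in [fp_types()] (same compounds and order in each).
#' @param y Binary training labels shared by all members.
#' @param xv_list,yv Validation inputs and labels (same structure).
#' @param task `"discrimination"` or `"active_only"`.
#' @param member_spec [cnn_spec()] for the members; the default uses
#'   512/256/128/64 filters and kernel 2.
#' @param max_epochs,patience Member training caps.
#' @param head_epochs,head_patience Head training caps.
#' @param seed Root seed; member i trains with `seed + i`.
#' @param verbose Print progress.
#' @return A `tuned_mlp_out` model: `members` (list of `trained_cnn`),
#'   `head`, `config`, `task`.
#' @export
train_stacked <- function(x_list, y, xv_list, yv,
                          task = c("discrimination", "active_only"),
                          member_spec = NULL, max_epochs = 30, patience = 5,
                          monitor = "val_loss",
                          head_epochs = 500, head_patience = 50, seed = 1,
                          verbose = FALSE) {
  task <- match.arg(task)
  x_list <- check_member_inputs(x_list)
  xv_list <- check_member_inputs(xv_list)
  y <- as_binary_labels(y)
  yv <- as_binary_labels(yv)
  config <- tuned_mlp_out_config(task)
  if (is.null(member_spec)) {
    member_spec <- cnn_spec("1d", conv_filters = c(512, 256, 128, 64),
                            kernel = 2, dropout = 0.2, batch_size = 16,
                            n_bits = ncol(x_list[[1]]), seed = seed)
  }
  members <- list()
  for (i in seq_along(fp_types())) {
    tt <- fp_types()[i]
    if (verbose) inform(sprintf("training member %d/7 (%s)", i, tt))
    spec_i <- member_spec
    spec_i$seed <- as.integer(seed + i)
    model <- build_cnn1d(spec_i)
    members[[tt]] <- train_cnn(model, x_list[[tt]], y, xv_list[[tt]], yv,
                               max_epochs = max_epochs, patience = patience,
                               monitor = monitor, seed = seed + i,
                               verbose = verbose)
  }
  P <- member_probabilities(members, x_list)
  Pv <- member_probabilities(members, xv_list)
  head <- mlp_head_train(P, y, Pv, yv, config, seed = seed,
                         max_epochs = head_epochs, patience = head_patience)
  structure(list(members = members, head = head, config = config,
                 task = task),
            class = "tuned_mlp_out")
}

#' @export
predict.tuned_mlp_out <- function(object, x_list, ...) {
  P <- member_probabilities(object$members, x_list)
  as.numeric(mlp_head_forward(object$head$weights, P)$p)
}

#' @export
print.tuned_mlp_out <- function(x, ...) {
  cat(sprintf("stacked ensemble (Tuned-MLP-Out), task = %s\n", x$task))
  cat(sprintf("  7 member 1D CNNs (%s filters), head: %d ReLU units, %s @ lr %g\n",
              paste(x$members[[1]]$spec$conv_filters, collapse = "/"),
              x$config$hidden_units, x$config$optimizer,
              x$config$learning_rate))
  invisible(x)
}

#' @export
glance.tuned_mlp_out <- function(x, ...) {
  tibble(task = x$task, hidden_units = x$config$hidden_units,
         optimizer = x$config$optimizer,
         learning_rate = x$config$learning_rate,
         head_best_epoch = x$head$best_epoch,
         head_val_loss = x$head$best_val_loss)
}

#' Hard-majority voting ensemble over per-type 1D CNNs
#'
#' Collects the binary labels emitted by the best 1D CNN for each fingerprint
#' type (each thresholded at 0.5) and returns the majority label. With seven
#' members the vote never abstains.
#'
#' @param members Named list of seven `trained_cnn` models, one per
#'   fingerprint type.
#' @return A `voting_ensemble`.
#' @export
voting_ensemble <- function(members) {
  if (!setequal(names(members), fp_types())) {
    stop_fpscreen("voting ensemble needs one member per fingerprint type",
                  "fpscreen_validation_error")
  }
  structure(list(members = members[fp_types()]), class = "voting_ensemble")
}

#' @export
predict.voting_ensemble <- function(object, x_list, threshold = 0.5, ...) {
  P <- member_probabilities(object$members, x_list)
  majority_vote(P > threshold)
}
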