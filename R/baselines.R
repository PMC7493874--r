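# Shallow reference models: an RBF-kernel SVM and a random forest, at the
# grid-search winners' hyperparameters for each training scheme. Both consume
# the same signed fingerprint matrices as the CNNs.

#' Baseline model specification
#'
#' Hyperparameter defaults follow the tuned values per training scheme:
#' scheme 1 uses an RBF SVM with C = 5, gamma = 1 and a 100-tree Gini random
#' forest; scheme 2 uses C = 1, gamma = 0.1 and a 2-tree forest. FeatMorgan
#' is the default fingerprint type (the best-performing one for both
#' baselines).
#'
#' @param kind `"svm_rbf"` or `"random_forest"`.
#' @param scheme `"scheme1"` or `"scheme2"` (sets the defaults below).
#' @param fp_type Fingerprint type the baseline is trained on.
#' @param cost,gamma SVM hyperparameters (ignored for the forest).
#' @param n_estimators Number of trees (ignored for the SVM).
#' @param seed Integer seed.
#' @return A `baseline_spec`.
#' @export
baseline_spec <- function(kind = c("svm_rbf", "random_forest"),
                          scheme = c("scheme1", "scheme2"),
                          fp_type = "featmorgan",
                          cost = NULL, gamma = NULL, n_estimators = NULL,
                          seed = 1) {
  kind <- match.arg(kind)
  scheme <- match.arg(scheme)
  fp_type <- validate_fp_types(fp_type, "fp_type")
  if (kind == "svm_rbf") {
    cost <- cost %||% if (scheme == "scheme1") 5 else 1
    gamma <- gamma %||% if (scheme == "scheme1") 1 else 0.1
    n_estimators <- NULL
  } else {
    n_estimators <- n_estimators %||% if (scheme == "scheme1") 100L else 2L
    cost <- NULL
    gamma <- NULL
  }
  structure(
    list(kind = kind, scheme = scheme, fp_type = fp_type, cost = cost,
         gamma = gamma, n_estimators = n_estimators, criterion = "gini",
         seed = as.integer(seed)),
    class = "baseline_spec"
  )
}

#' Train a baseline classifier
#'
#' @param spec A [baseline_spec()].
#' @param x Signed fingerprint matrix of the spec's fingerprint type
#'   (rows = compounds).
#' @param y Binary labels.
#' @return A `baseline_model` wrapping the fitted e1071 SVM or randomForest.
#' @export
train_baseline <- function(spec, x, y) {
  stopifnot(inherits(spec, "baseline_spec"))
  y <- as_binary_labels(y)
  if (length(unique(y)) < 2) {
    stop_fpscreen("both classes are required to train a baseline",
                  "fpscreen_validation_error")
  }
  x <- as.matrix(x)
  yf <- factor(y, levels = c(0, 1))
  set.seed(spec$seed)
  fit <- if (spec$kind == "svm_rbf") {
    e1071::svm(x, yf, kernel = "radial", cost = spec$cost,
               gamma = spec$gamma, probability = TRUE, scale = FALSE)
  } else {
    randomForest::randomForest(x, yf, ntree = spec$n_estimators)
  }
  structure(list(spec = spec, fit = fit), class = "baseline_model")
}

#' @export
predict.baseline_model <- function(object, x, ...) {
  x <- as.matrix(x)
  if (nrow(x) == 0) return(numeric(0))
  if (object$spec$kind == "svm_rbf") {
    pr <- predict(object$fit, x, probability = TRUE)
    as.numeric(attr(pr, "probabilities")[, "1"])
  } else {
    as.numeric(predict(object$fit, x, type = "prob")[, "1"])
  }
}

#' @rdname predict.baseline_model
#' @param model A `baseline_model`.
#' @export
predict_baseline <- function(model, x) {
  stopifnot(inherits(model, "baseline_model"))
  predict(model, x)
}

#' @export
print.baseline_model <- function(x, ...) {
  s <- x$spec
  if (s$kind == "svm_rbf") {
    cat(sprintf("RBF SVM baseline (%s): C = %g, gamma = %g, fp = %s\n",
                s$scheme, s$cost, s$gamma, s$fp_type))
  } else {
    cat(sprintf("random forest baseline (%s): %d trees (Gini), fp = %s\n",
                s$scheme, s$n_estimators, s$fp_type))
  }
  invisible(x)
}
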