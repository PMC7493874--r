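#' Confusion matrix for binary predictions
#'
#' @param truth,pred Binary vectors of equal length (0/1, logical, or
#'   active/inactive).
#' @return A `confusion_matrix` with fields `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(truth, pred) {
  truth <- as_binary_labels(truth, "truth")
  pred <- as_binary_labels(pred, "pred")
  if (length(truth) != length(pred)) {
    stop_fpscreen("truth and pred differ in length",
                  "fpscreen_validation_error")
  }
  structure(
    list(tp = sum(truth == 1 & pred == 1),
         fp = sum(truth == 0 & pred == 1),
         tn = sum(truth == 0 & pred == 0),
         fn = sum(truth == 1 & pred == 0)),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("confusion matrix: TP=%d FP=%d TN=%d FN=%d\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' @export
tidy.confusion_matrix <- function(x, ...) {
  tibble(tp = x$tp, fp = x$fp, tn = x$tn, fn = x$fn,
         p = x$tp + x$fn, n = x$tn + x$fp)
}

check_cm <- function(cm) {
  if (!inherits(cm, "confusion_matrix")) {
    stop_fpscreen("expected a confusion_matrix", "fpscreen_validation_error")
  }
  cm
}

#' Scalar classification metrics
#'
#' Balanced accuracy is the mean of sensitivity (TP/P) and specificity
#' (TN/N), robust to class imbalance. The Matthews correlation coefficient
#' satisfies `|MCC| = sqrt(chi^2 / n)` for the 2x2 table; degenerate margins
#' yield 0 with a warning. F1 is the harmonic mean of precision and recall.
#'
#' @param cm A [confusion()] matrix.
#' @return A number: bACC, sensitivity, specificity and F1 in `[0, 1]`; MCC
#'   in `[-1, 1]`.
#' @export
balanced_accuracy <- function(cm) {
  cm <- check_cm(cm)
  p <- cm$tp + cm$fn
  n <- cm$tn + cm$fp
  if (p == 0 || n == 0) {
    stop_fpscreen("balanced accuracy undefined: a class is empty",
                  "fpscreen_metric_error")
  }
  (cm$tp / p + cm$tn / n) / 2
}

#' @rdname balanced_accuracy
#' @export
sensitivity <- function(cm) {
  cm <- check_cm(cm)
  p <- cm$tp + cm$fn
  if (p == 0) {
    stop_fpscreen("sensitivity undefined: no positives",
                  "fpscreen_metric_error")
  }
  cm$tp / p
}

#' @rdname balanced_accuracy
#' @export
specificity <- function(cm) {
  cm <- check_cm(cm)
  n <- cm$tn + cm$fp
  if (n == 0) {
    stop_fpscreen("specificity undefined: no negatives",
                  "fpscreen_metric_error")
  }
  cm$tn / n
}

#' @rdname balanced_accuracy
#' @export
f1 <- function(cm) {
  cm <- check_cm(cm)
  denom <- 2 * cm$tp + cm$fp + cm$fn
  if (denom == 0) {
    stop_fpscreen("F1 undefined: no positives predicted or labeled",
                  "fpscreen_metric_error")
  }
  2 * cm$tp / denom
}

#' @rdname balanced_accuracy
#' @export
mcc <- function(cm) {
  cm <- check_cm(cm)
  tp <- as.numeric(cm$tp); fp <- as.numeric(cm$fp)
  tn <- as.numeric(cm$tn); fn <- as.numeric(cm$fn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) {
    warn("MCC degenerate (a margin is zero); returning 0")
    return(0)
  }
  (tp * tn - fp * fn) / sqrt(den)
}

#' Binary cross-entropy of predicted probabilities
#'
#' Probabilities are clipped to `[clip, 1 - clip]` before taking logs so
#' perfectly confident predictions do not produce infinities.
#'
#' @param scores Predicted probabilities in `[0, 1]`.
#' @param labels Binary labels.
#' @param clip Clipping bound.
#' @return Mean binary cross-entropy.
#' @export
bce_loss <- function(scores, labels, clip = 1e-7) {
  labels <- as_binary_labels(labels)
  stopifnot(length(scores) == length(labels))
  p <- pmin(pmax(as.numeric(scores), clip), 1 - clip)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

#' Area under the ROC curve
#'
#' The probability that a randomly chosen active outranks a randomly chosen
#' inactive, with ties counting one half (the rank-statistic formulation, so
#' the value is invariant under any strictly monotone transform of the
#' scores).
#'
#' @param scores Numeric scores, larger = more active.
#' @param labels Binary labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop_fpscreen("AUC undefined: both classes must be present",
                  "fpscreen_metric_error")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Rank compounds for screening
#'
#' Orders compounds by decreasing predicted activity score (stable on ties,
#' so equal scores keep their input order) — the structure on which the
#' enrichment factor is computed.
#'
#' @param data Data frame with score and label columns.
#' @param score_col,label_col,id_col Column names.
#' @return A `ranked_screen` tibble with columns `compound_id`, `score`,
#'   `is_active`, sorted by descending score.
#' @export
ranked_screen <- function(data, score_col = "score", label_col = "label",
                          id_col = "compound_id") {
  stopifnot(is.data.frame(data))
  score <- as.numeric(data[[score_col]])
  is_active <- as_binary_labels(data[[label_col]], label_col) == 1
  ids <- if (id_col %in% names(data)) {
    as.character(data[[id_col]])
  } else {
    sprintf("compound_%d", seq_along(score))
  }
  ord <- order(-score)   # stable: ties keep input order
  out <- tibble(compound_id = ids[ord], score = score[ord],
                is_active = is_active[ord])
  class(out) <- c("ranked_screen", class(out))
  out
}

#' Enrichment factor of a ranked screen
#'
#' For each percentage p, counts the true actives among the top
#' `floor(p * n / 100)` ranked compounds. The reported percentage divides the
#' hit count by the best attainable count in that window,
#' `min(window, total actives)`, so a perfect ranking always scores 100%.
#' This is the headline early-recognition metric of a virtual screen: a good
#' model concentrates the actives at the very top so that only a small
#' fraction of candidates needs testing.
#'
#' @param screen A [ranked_screen()].
#' @param p Percentages of the screen to inspect (each in `(0, 100]`).
#' @return An `ef_table` tibble with columns `p_percent`, `window`, `hits`
#'   and `percent`.
#' @export
enrichment_factor <- function(screen, p = c(1, 2, 5, 10)) {
  stopifnot(inherits(screen, "ranked_screen") || is.data.frame(screen))
  n <- nrow(screen)
  if (n == 0) {
    stop_fpscreen("empty screen", "fpscreen_validation_error")
  }
  if (any(p <= 0 | p > 100)) {
    stop_fpscreen("p must lie in (0, 100]", "fpscreen_validation_error")
  }
  n_active <- sum(screen$is_active)
  rows <- lapply(p, function(pp) {
    window <- floor(pp * n / 100)
    if (window == 0) {
      stop_fpscreen(
        sprintf("EF window is empty at p = %g%% with n = %d; use a larger p or screen",
                pp, n),
        "fpscreen_validation_error"
      )
    }
    hits <- sum(screen$is_active[seq_len(window)])
    tibble(p_percent = pp, window = window, hits = hits,
           percent = 100 * hits / min(window, n_active))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "n") <- n
  attr(out, "n_active") <- n_active
  class(out) <- c("ef_table", class(out))
  out
}

#' @export
autoplot.ef_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$p_percent,
                                       y = .data$percent)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "top fraction of the screen (%)",
                  y = "recovered actives (% of attainable)",
                  title = "Enrichment factor") +
    ggplot2::theme_minimal()
}

#' One-row evaluation report for a scored test set
#'
#' Computes the full metric suite (balanced accuracy, sensitivity,
#' specificity, F1, MCC, AUC and log-loss) for predicted probabilities
#' against true labels, thresholding at `threshold` for the count-based
#' metrics.
#'
#' @param truth Binary labels.
#' @param scores Predicted probabilities.
#' @param threshold Decision threshold for the hard labels.
#' @return A one-row tibble.
#' @export
evaluate_scores <- function(truth, scores, threshold = 0.5) {
  truth <- as_binary_labels(truth, "truth")
  pred <- as.numeric(as.numeric(scores) > threshold)
  cm <- confusion(truth, pred)
  tibble(
    bacc = balanced_accuracy(cm),
    sensitivity = sensitivity(cm),
    specificity = specificity(cm),
    f1 = f1(cm),
    mcc = mcc(cm),
    auc = auc(scores, truth),
    loss = bce_loss(scores, truth),
    n = length(truth),
    n_active = cm$tp + cm$fn
  )
}
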