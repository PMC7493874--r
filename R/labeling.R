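#' Within-cluster sum of squares curve for the elbow method
#'
#' Runs one-dimensional K-means on the IC50 values for k = 1..`k_max` and
#' records the best within-cluster sum of squares (WCSS) over `nstart`
#' restarts at each k. Plotting WCSS against k (see [autoplot.elbow_curve()])
#' is the standard elbow diagnostic for choosing the cluster count; on
#' bioactivity data with a clear potent/weak separation the elbow sits at
#' k = 2.
#'
#' @param data Data frame of activity records.
#' @param ic50_col Column holding IC50 values in micromolar; missing values
#'   are dropped.
#' @param k_max Largest cluster count to evaluate.
#' @param seed Random seed for the K-means restarts.
#' @param nstart Restarts per k; the best solution is kept.
#' @return A tibble of class `elbow_curve` with columns `k` and `wcss`.
#' @export
wcss_curve <- function(data, ic50_col = "ic50_um", k_max = 10, seed = 1,
                       nstart = 10) {
  values <- ic50_values(data, ic50_col)
  if (length(values) == 0) {
    stop_fpscreen("no IC50 values to cluster", "fpscreen_validation_error")
  }
  if (k_max < 2) {
    stop_fpscreen("k_max must be at least 2", "fpscreen_validation_error")
  }
  if (length(values) < k_max) {
    stop_fpscreen("need at least k_max IC50 values", "fpscreen_validation_error")
  }
  n_distinct <- length(unique(values))
  set.seed(seed)
  wcss <- vapply(seq_len(k_max), function(k) {
    if (k == 1) return(sum((values - mean(values))^2))
    if (k >= n_distinct) return(0)
    stats::kmeans(values, centers = k, nstart = nstart,
                  iter.max = 100)$tot.withinss
  }, numeric(1))
  out <- tibble(k = seq_len(k_max), wcss = wcss)
  class(out) <- c("elbow_curve", class(out))
  out
}

ic50_values <- function(data, ic50_col) {
  stopifnot(is.data.frame(data))
  if (!ic50_col %in% names(data)) {
    stop_fpscreen(sprintf("column '%s' not found", ic50_col),
                  "fpscreen_validation_error")
  }
  v <- as.numeric(data[[ic50_col]])
  v <- v[is.finite(v)]
  if (any(v <= 0)) {
    stop_fpscreen("IC50 values must be positive", "fpscreen_validation_error")
  }
  v
}

#' Derive the active/inactive IC50 threshold by two-cluster K-means
#'
#' Clusters the raw IC50 values (micromolar) into two groups with K-means
#' (multiple restarts, run to convergence) and sets the activity threshold
#' at the mean of the two cluster centroids. The model also records the
#' upper bound of the active (low-IC50) cluster and the lower bound of the
#' inactive cluster. The threshold is a property of the dataset it was
#' fitted on and should be persisted with it ([write_threshold()]).
#'
#' @inheritParams wcss_curve
#' @param nstart Number of K-means restarts.
#' @return An object of class `threshold_model` with fields
#'   `centroid_active`, `centroid_inactive`, `threshold`,
#'   `upper_bound_active`, `lower_bound_inactive`, `n`, `seed`.
#' @export
fit_threshold <- function(data, ic50_col = "ic50_um", seed = 1, nstart = 25) {
  values <- ic50_values(data, ic50_col)
  if (length(unique(values)) < 2) {
    stop_fpscreen("all IC50 values identical: two clusters are degenerate",
                  "fpscreen_degenerate_error")
  }
  set.seed(seed)
  km <- stats::kmeans(values, centers = 2, nstart = nstart, iter.max = 100)
  lo <- which.min(km$centers)
  hi <- which.max(km$centers)
  model <- structure(
    list(
      centroid_active = unname(km$centers[lo]),
      centroid_inactive = unname(km$centers[hi]),
      threshold = unname(mean(km$centers)),
      upper_bound_active = max(values[km$cluster == lo]),
      lower_bound_inactive = min(values[km$cluster == hi]),
      n = length(values),
      seed = seed
    ),
    class = "threshold_model"
  )
  model
}

#' @export
print.threshold_model <- function(x, ...) {
  cat("IC50 activity threshold model (two-cluster K-means)\n")
  cat(sprintf("  active centroid:   %.5f uM (cluster upper bound %.3f)\n",
              x$centroid_active, x$upper_bound_active))
  cat(sprintf("  inactive centroid: %.5f uM (cluster lower bound %.3f)\n",
              x$centroid_inactive, x$lower_bound_inactive))
  cat(sprintf("  threshold:         %.5f uM (centroid average), n = %d\n",
              x$threshold, x$n))
  invisible(x)
}

#' @export
tidy.threshold_model <- function(x, ...) {
  tibble(
    centroid_active = x$centroid_active,
    centroid_inactive = x$centroid_inactive,
    threshold = x$threshold,
    upper_bound_active = x$upper_bound_active,
    lower_bound_inactive = x$lower_bound_inactive,
    n = x$n
  )
}

#' Persist or restore a threshold model as JSON
#'
#' @param model A `threshold_model`.
#' @param path File path.
#' @return `write_threshold()` returns `path` invisibly; `read_threshold()`
#'   returns a `threshold_model`.
#' @export
write_threshold <- function(model, path) {
  stopifnot(inherits(model, "threshold_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_threshold
#' @export
read_threshold <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "threshold_model")
}

#' Assign binary activity labels from an IC50 threshold
#'
#' A compound is labeled `active` when its IC50 is less than or equal to the
#' threshold (boundary inclusive) and `inactive` otherwise. Records with a
#' missing IC50 are dropped with a message; the number removed is recorded in
#' the `n_dropped` attribute. Compounds listed in `inactive_ids` are labeled
#' inactive regardless of their IC50 — the mechanism for off-target expansion
#' sets that are inactive on the screened target by construction.
#'
#' @param data Data frame of activity records.
#' @param threshold A `threshold_model` or a positive number (micromolar).
#' @param ic50_col Column with IC50 values in micromolar.
#' @param id_col Column with compound ids (used for `inactive_ids`).
#' @param inactive_ids Optional ids labeled inactive bypassing the threshold.
#' @return The input tibble with a `label` factor column
#'   (levels `active`, `inactive`), missing-IC50 rows removed.
#' @export
assign_labels <- function(data, threshold, ic50_col = "ic50_um",
                          id_col = "compound_id", inactive_ids = NULL) {
  stopifnot(is.data.frame(data))
  if (inherits(threshold, "threshold_model")) threshold <- threshold$threshold
  threshold <- as.numeric(threshold)
  if (!is.finite(threshold) || threshold <= 0) {
    stop_fpscreen("threshold must be a positive number",
                  "fpscreen_validation_error")
  }
  ic50 <- as.numeric(data[[ic50_col]])
  keep <- is.finite(ic50)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    inform(sprintf("dropped %d record(s) with missing IC50", n_dropped))
  }
  out <- as_tibble(data[keep, , drop = FALSE])
  lab <- ifelse(ic50[keep] <= threshold, "active", "inactive")
  if (!is.null(inactive_ids) && id_col %in% names(out)) {
    lab[out[[id_col]] %in% inactive_ids] <- "inactive"
  }
  out$label <- factor(lab, levels = c("active", "inactive"))
  attr(out, "n_dropped") <- n_dropped
  attr(out, "threshold") <- threshold
  out
}

#' @export
autoplot.elbow_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$wcss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "number of clusters k",
                  y = "within-cluster sum of squares",
                  title = "Elbow diagnostic for the IC50 clustering") +
    ggplot2::theme_minimal()
}
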