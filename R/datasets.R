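# Train/validation/test splitting for the two training regimes, fold
# construction for cross-validation, and class-ratio stress resampling.

check_labeled <- function(data, label_col, id_col) {
  stopifnot(is.data.frame(data))
  for (col in c(label_col, id_col)) {
    if (!col %in% names(data)) {
      stop_fpscreen(sprintf("column '%s' not found", col),
                    "fpscreen_validation_error")
    }
  }
  y <- as_binary_labels(data[[label_col]], label_col)
  if (length(unique(y)) < 2) {
    stop_fpscreen("both classes must be present", "fpscreen_validation_error")
  }
  y
}

# largest-remainder allocation of n items to the given fractions; exact sum
quota_counts <- function(n, fractions) {
  diff(round(cumsum(c(0, fractions)) * n))
}

new_dataset_split <- function(tbl, scheme, seed, extra = list()) {
  tbl <- as_tibble(tbl)
  attr(tbl, "scheme") <- scheme
  attr(tbl, "seed") <- seed
  counts <- table(tbl$partition, tbl$label)
  attr(tbl, "class_counts") <- counts
  for (nm in names(extra)) attr(tbl, nm) <- extra[[nm]]
  class(tbl) <- c("dataset_split", class(tbl))
  tbl
}

#' Scheme-1 split: stratified 80/10/10 for precise discrimination
#'
#' Splits the labeled compounds into training, validation and test partitions
#' (default 80%:10%:10%) with per-class stratification, so the global
#' active/inactive ratio is preserved in every partition to within one
#' sample. Training compounds additionally receive a stratified fold
#' assignment for k-fold cross-validation. This is the regime for maximizing
#' discriminative power: most data goes to training and the class balance is
#' left untouched.
#'
#' @param data Data frame with label and id columns.
#' @param seed Integer seed; the split is reproducible bit-for-bit.
#' @param fractions Named fractions for train/validation/test, summing to 1.
#' @param label_col,id_col Column names.
#' @param k Number of cross-validation folds on the training partition.
#' @return A `dataset_split` tibble with columns `compound_id`, `label`,
#'   `partition` and `fold` (NA outside training), plus bookkeeping
#'   attributes (`scheme`, `seed`, `class_counts`).
#' @export
scheme1_split <- function(data, seed = 1,
                          fractions = c(train = 0.8, validation = 0.1,
                                        test = 0.1),
                          label_col = "label", id_col = "compound_id",
                          k = 10) {
  y <- check_labeled(data, label_col, id_col)
  if (abs(sum(fractions) - 1) > 1e-8 || any(fractions <= 0)) {
    stop_fpscreen("fractions must be positive and sum to 1",
                  "fpscreen_validation_error")
  }
  if (min(table(y)) < 10) {
    stop_fpscreen("each class needs at least 10 members for stratification",
                  "fpscreen_stratification_error")
  }
  ids <- as.character(data[[id_col]])
  set.seed(seed)
  partition <- character(length(ids))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    counts <- quota_counts(length(idx), fractions)
    partition[idx] <- rep(names(fractions), counts)
  }
  out <- tibble(
    compound_id = ids,
    label = factor(ifelse(y == 1, "active", "inactive"),
                   levels = c("active", "inactive")),
    partition = factor(partition, levels = names(fractions))
  )
  out$fold <- NA_integer_
  train_idx <- which(out$partition == "train")
  folds <- make_folds(out[train_idx, ], k = min(k, length(train_idx)),
                      seed = seed)
  out$fold[train_idx] <- folds$fold[match(out$compound_id[train_idx],
                                          folds$compound_id)]
  new_dataset_split(out, "scheme1", seed)
}

#' Scheme-2 split: active-enriched training for early screening
#'
#' Splits the dataset into two almost equal parts (default 48% training,
#' 52% test) with the training side deliberately enriched in actives
#' (default: 90% of all actives go to training), leaving the test set scarce
#' in actives as a realistic screening population. The training side is
#' further split 90%:10% into train and validation, stratified. Defaults
#' reproduce the study proportions: on a dataset of 800 actives and 6360
#' inactives they give a 3440-compound training side with 720 actives and a
#' 3720-compound test set with 80 actives.
#'
#' @inheritParams scheme1_split
#' @param train_frac Fraction of all compounds on the training side.
#' @param train_active_frac Fraction of all actives sent to training.
#' @param val_frac Fraction of the training side held out for validation.
#' @return A `dataset_split` tibble (see [scheme1_split()]); the attribute
#'   `quota` records the achieved counts.
#' @export
scheme2_split <- function(data, seed = 1, train_frac = 3440 / 7160,
                          train_active_frac = 0.9, val_frac = 0.1,
                          label_col = "label", id_col = "compound_id",
                          k = 10) {
  y <- check_labeled(data, label_col, id_col)
  n <- length(y)
  n_act <- sum(y == 1)
  n_train <- round(train_frac * n)
  train_act <- round(train_active_frac * n_act)
  train_inact <- n_train - train_act
  if (train_act < 1 || train_act > n_act) {
    stop_fpscreen("not enough active compounds to enrich the training set",
                  "fpscreen_stratification_error")
  }
  if (train_inact < 1 || train_inact > sum(y == 0)) {
    stop_fpscreen("not enough inactive compounds for the requested split",
                  "fpscreen_stratification_error")
  }
  ids <- as.character(data[[id_col]])
  set.seed(seed)
  act_idx <- sample(which(y == 1))
  inact_idx <- sample(which(y == 0))
  train_idx <- c(act_idx[seq_len(train_act)], inact_idx[seq_len(train_inact)])
  partition <- rep("test", n)
  partition[train_idx] <- "train"
  # stratified validation carve-out inside the training side
  val <- integer(0)
  for (cls in c(1, 0)) {
    cls_train <- intersect(train_idx, which(y == cls))
    n_val <- round(val_frac * length(cls_train))
    val <- c(val, sample(cls_train, n_val))
  }
  partition[val] <- "validation"
  out <- tibble(
    compound_id = ids,
    label = factor(ifelse(y == 1, "active", "inactive"),
                   levels = c("active", "inactive")),
    partition = factor(partition, levels = c("train", "validation", "test"))
  )
  out$fold <- NA_integer_
  tr <- which(out$partition == "train")
  folds <- make_folds(out[tr, ], k = min(k, length(tr)), seed = seed)
  out$fold[tr] <- folds$fold[match(out$compound_id[tr], folds$compound_id)]
  quota <- list(train_total = n_train, train_active = train_act,
                test_total = n - n_train, test_active = n_act - train_act)
  new_dataset_split(out, "scheme2", seed, extra = list(quota = quota))
}

#' Stratified cross-validation folds
#'
#' Assigns each compound to one of `k` folds so that fold sizes differ by at
#' most one and each class is spread evenly across folds.
#'
#' @param data Data frame with id and (optionally) label columns.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @param label_col,id_col Column names; if `label_col` is missing from the
#'   data the folds are unstratified.
#' @return Tibble with columns `compound_id` and `fold`.
#' @export
make_folds <- function(data, k = 10, seed = 1, label_col = "label",
                       id_col = "compound_id") {
  stopifnot(is.data.frame(data))
  n <- nrow(data)
  if (k > n) {
    stop_fpscreen("k exceeds the number of compounds",
                  "fpscreen_validation_error")
  }
  ids <- as.character(data[[id_col]])
  set.seed(seed)
  strata <- if (label_col %in% names(data)) {
    as.character(data[[label_col]])
  } else {
    rep("all", n)
  }
  fold <- integer(n)
  fold_order <- sample(k)   # random fold rotation
  counter <- 0L
  for (cls in unique(strata)) {
    idx <- sample(which(strata == cls))
    # round-robin continuing across strata keeps global sizes within 1
    fold[idx] <- fold_order[((counter + seq_along(idx) - 1L) %% k) + 1L]
    counter <- counter + length(idx)
  }
  tibble(compound_id = ids, fold = fold)
}

#' Resample a dataset to a target active/inactive ratio
#'
#' Builds the class-imbalance stress sets: given a ratio 1:r, actives are
#' subsampled (keeping every inactive) until one active remains per r
#' inactives. When the inactive pool is itself too small to support the
#' requested ratio for all available actives, all actives are kept and
#' inactives are subsampled to `r` per active instead. A 1:1 ratio on
#' balanced input is the identity.
#'
#' @param data Labeled data frame.
#' @param ratio The r in the 1:r active:inactive target.
#' @param seed Integer seed.
#' @param label_col Column with the labels.
#' @return The resampled tibble (original row order preserved).
#' @export
resample_ratio <- function(data, ratio, seed = 1, label_col = "label") {
  stopifnot(is.data.frame(data), ratio >= 1)
  y <- as_binary_labels(data[[label_col]], label_col)
  n_act <- sum(y == 1)
  n_inact <- sum(y == 0)
  set.seed(seed)
  if (n_inact <= ratio * n_act) {
    keep_act <- round(n_inact / ratio)
    if (keep_act < 1) {
      stop_fpscreen(
        "inactive class too small: no actives can be retained at this ratio",
        "fpscreen_validation_error"
      )
    }
    keep <- sort(c(sample(which(y == 1), keep_act), which(y == 0)))
  } else {
    keep_inact <- ratio * n_act
    if (keep_inact < 1 || n_act < 1) {
      stop_fpscreen("active class too small for the requested ratio",
                    "fpscreen_validation_error")
    }
    keep <- sort(c(which(y == 1), sample(which(y == 0), keep_inact)))
  }
  as_tibble(data[keep, , drop = FALSE])
}

#' Persist a dataset split as a JSON manifest
#'
#' @param split A `dataset_split`.
#' @param path Output path.
#' @return `path`, invisibly; `read_split_manifest()` returns the split.
#' @export
write_split_manifest <- function(split, path) {
  stopifnot(inherits(split, "dataset_split"))
  payload <- list(
    scheme = attr(split, "scheme"),
    seed = attr(split, "seed"),
    partitions = split(as.character(split$compound_id), split$partition),
    folds = stats::setNames(as.list(split$fold[!is.na(split$fold)]),
                            split$compound_id[!is.na(split$fold)]),
    labels = stats::setNames(as.list(as.character(split$label)),
                             split$compound_id)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_split_manifest
#' @export
read_split_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  ids <- unlist(m$partitions, use.names = FALSE)
  partition <- rep(names(m$partitions), vapply(m$partitions, length, 1L))
  out <- tibble(
    compound_id = ids,
    label = factor(unlist(m$labels[ids]), levels = c("active", "inactive")),
    partition = factor(partition,
                       levels = c("train", "validation", "test")),
    fold = vapply(ids, function(i) {
      f <- m$folds[[i]]
      if (is.null(f)) NA_integer_ else as.integer(f)
    }, integer(1), USE.NAMES = FALSE)
  )
  new_dataset_split(out, m$scheme, m$seed)
}
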