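#' The seven supported fingerprint types
#'
#' Canonical ordering of the fingerprint types used throughout the package:
#' wherever several fingerprints of one compound are stacked into a matrix,
#' rows follow this order.
#'
#' @return Character vector of length 7.
#' @export
#' @examples
#' fp_types()
fp_types <- function() {
  c("rdkit", "morgan", "atompair", "torsion", "layered", "featmorgan", "ecfp4")
}

validate_fp_types <- function(types, arg = "fp_types") {
  types <- tolower(as.character(types))
  bad <- setdiff(types, fp_types())
  if (length(bad) > 0) {
    stop_fpscreen(
      sprintf("unknown fingerprint type(s) for `%s`: %s", arg,
              paste(bad, collapse = ", ")),
      "fpscreen_config_error"
    )
  }
  types
}

fp_type_factor <- function(types) factor(types, levels = fp_types())

#' Compute molecular fingerprints for a table of compounds
#'
#' Computes 1024-bit (by default) binary fingerprints of one or more types
#' for every compound in `data`. Fingerprinting is delegated to RDKit through
#' the `python` interpreter on the PATH (see Details); the seven supported
#' types are circular (`morgan`, `featmorgan`, `ecfp4`), path/subgraph-based
#' (`rdkit`, `layered`), and pairwise-topology based (`atompair`, `torsion`).
#'
#' `morgan` and `ecfp4` are both radius-2 circular fingerprints; they are
#' computed with different generator settings (`ecfp4` additionally hashes
#' redundant atom environments) so the two descriptors are distinct.
#'
#' When `standardize = TRUE` (the default) multi-fragment inputs (salts,
#' mixtures) are reduced to their largest fragment before fingerprinting.
#'
#' @param data Data frame with one row per compound.
#' @param fp_types Character vector of fingerprint types, a subset of
#'   [fp_types()].
#' @param smiles_col,id_col Column names holding SMILES strings and compound
#'   identifiers. If `id_col` is absent, sequential ids are generated.
#' @param n_bits Fingerprint width; 1024 is used throughout the package and
#'   is the only width exercised by its tests.
#' @param standardize Keep only the largest fragment before fingerprinting.
#' @param python Path to the python interpreter with RDKit available.
#' @return A tibble with columns `compound_id`, `fp_type` (factor in
#'   canonical order), `n_bits`, and `bits` (list column of 0/1 integer
#'   vectors).
#' @export
compute_fingerprints <- function(data,
                                 fp_types = fpscreen::fp_types(),
                                 smiles_col = "smiles",
                                 id_col = "compound_id",
                                 n_bits = 1024,
                                 standardize = TRUE,
                                 python = getOption("fpscreen.python", "python")) {
  stopifnot(is.data.frame(data))
  if (!smiles_col %in% names(data)) {
    stop_fpscreen(sprintf("column '%s' not found in `data`", smiles_col),
                  "fpscreen_validation_error")
  }
  if (n_bits < 64) {
    stop_fpscreen("n_bits must be at least 64", "fpscreen_validation_error")
  }
  fp_types <- validate_fp_types(fp_types)
  smiles <- as.character(data[[smiles_col]])
  ids <- if (id_col %in% names(data)) {
    as.character(data[[id_col]])
  } else {
    sprintf("compound_%d", seq_along(smiles))
  }
  rdkit_fingerprints(smiles, ids, fp_types, n_bits, standardize, python)
}

#' Compute a single fingerprint
#'
#' Convenience wrapper around [compute_fingerprints()] for one SMILES string
#' and one fingerprint type.
#'
#' @param smiles A single SMILES string.
#' @param fp_type One of [fp_types()].
#' @param n_bits Fingerprint width (>= 64).
#' @inheritParams compute_fingerprints
#' @return A one-row fingerprint tibble (see [compute_fingerprints()]).
#' @export
compute_fingerprint <- function(smiles, fp_type, n_bits = 1024,
                                standardize = TRUE,
                                python = getOption("fpscreen.python", "python")) {
  stopifnot(length(smiles) == 1, length(fp_type) == 1)
  compute_fingerprints(
    tibble(compound_id = "compound_1", smiles = smiles),
    fp_types = fp_type, n_bits = n_bits, standardize = standardize,
    python = python
  )
}

rdkit_fingerprints <- function(smiles, ids, types, n_bits, standardize,
                               python) {
  script <- system.file("python", "rdkit_fps.py", package = "fpscreen")
  if (script == "") {
    stop_fpscreen("bundled rdkit_fps.py not found; is fpscreen installed?",
                  "fpscreen_config_error")
  }
  infile <- tempfile(fileext = ".tsv")
  on.exit(unlink(infile), add = TRUE)
  writeLines(paste(ids, smiles, sep = "\t"), infile)
  res <- suppressWarnings(system2(
    python,
    c(shQuote(script), shQuote(infile), paste(types, collapse = ","),
      n_bits, if (standardize) "1" else "0"),
    stdout = TRUE, stderr = TRUE
  ))
  status <- attr(res, "status") %||% 0L
  if (status != 0) {
    stop_fpscreen(
      c("fingerprint backend failed", utils::tail(res, 3)),
      "fpscreen_config_error"
    )
  }
  parts <- strsplit(res, "\t", fixed = TRUE)
  parts <- parts[lengths(parts) >= 2]
  type_col <- vapply(parts, `[[`, "", 2)
  bad <- which(type_col == "__parse_error__")
  if (length(bad) > 0) {
    offending <- vapply(parts[bad], function(p) p[[3]] %||% "", "")
    stop_fpscreen(
      c(sprintf("%d SMILES string(s) could not be parsed", length(bad)),
        utils::head(offending, 5)),
      "fpscreen_parse_error", smiles = offending
    )
  }
  bits <- lapply(parts, function(p) {
    v <- integer(n_bits)
    if (length(p) >= 3 && nzchar(p[[3]])) {
      v[as.integer(strsplit(p[[3]], " ", fixed = TRUE)[[1]]) + 1L] <- 1L
    }
    v
  })
  out <- tibble(
    compound_id = vapply(parts, `[[`, "", 1),
    fp_type = fp_type_factor(type_col),
    n_bits = n_bits,
    bits = bits
  )
  dplyr::arrange(out, match(.data$compound_id, ids), .data$fp_type)
}

#' Recode binary fingerprints as signed vectors
#'
#' Maps every 0 bit to -1 and every 1 bit to +1 (`values = 2 * bits - 1`).
#' The signed form is what the classifiers consume: it keeps the binary
#' information while avoiding near-zero inputs to the convolutional units on
#' these very sparse vectors. The recoding is lossless; [to_bits()] inverts
#' it.
#'
#' @param data A fingerprint tibble with a `bits` list column (from
#'   [compute_fingerprints()]).
#' @return The same tibble with `bits` replaced by a `values` list column of
#'   -1/+1 integer vectors.
#' @export
to_signed <- function(data) {
  stopifnot(is.data.frame(data), "bits" %in% names(data))
  out <- data
  out$values <- lapply(out$bits, function(b) 2L * as.integer(b) - 1L)
  out$bits <- NULL
  as_tibble(out)
}

#' @rdname to_signed
#' @export
to_bits <- function(data) {
  stopifnot(is.data.frame(data), "values" %in% names(data))
  out <- data
  out$bits <- lapply(out$values, function(v) as.integer((as.integer(v) + 1L) %/% 2L))
  out$values <- NULL
  as_tibble(out)
}

#' Stack several fingerprints of one compound into a signed matrix
#'
#' Builds the k x n_bits signed {-1,+1} matrix that the 2D classifiers take
#' as input. Rows are ordered canonically (see [fp_types()]) regardless of
#' input order.
#'
#' @param data A fingerprint tibble for a single compound with at least two
#'   rows of pairwise-distinct `fp_type`; either a `bits` or a `values`
#'   column is accepted.
#' @return An integer matrix of -1/+1 values with one row per fingerprint
#'   type (rownames = types), of class `fp_matrix`.
#' @export
fp_stack <- function(data) {
  stopifnot(is.data.frame(data))
  if ("bits" %in% names(data)) data <- to_signed(data)
  stopifnot("values" %in% names(data))
  if (nrow(data) < 2) {
    stop_fpscreen("at least two fingerprints are required to stack",
                  "fpscreen_validation_error")
  }
  if (length(unique(data$compound_id)) != 1) {
    stop_fpscreen("all stacked fingerprints must belong to one compound",
                  "fpscreen_validation_error")
  }
  types <- as.character(data$fp_type)
  if (anyDuplicated(types)) {
    stop_fpscreen("duplicate fingerprint types cannot be stacked",
                  "fpscreen_validation_error")
  }
  ord <- order(match(types, fp_types()))
  m <- do.call(rbind, data$values[ord])
  rownames(m) <- types[ord]
  class(m) <- c("fp_matrix", class(m))
  m
}

#' Enumerate fingerprint-type combinations
#'
#' All subsets of size >= 2 of the given types, each returned in canonical
#' order. With all seven types this yields 120 combinations (2^7 - 7 - 1),
#' covering everything from pairs up to the full 7-row stack.
#'
#' @param types Fingerprint types to combine (>= 2 of them).
#' @return List of character vectors.
#' @export
fp_combinations <- function(types = fp_types()) {
  types <- validate_fp_types(types, "types")
  types <- unique(types)
  if (length(types) < 2) {
    stop_fpscreen("at least two fingerprint types are required",
                  "fpscreen_validation_error")
  }
  types <- types[order(match(types, fp_types()))]
  out <- list()
  for (k in 2:length(types)) {
    cmb <- utils::combn(types, k, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

#' Build a model input matrix from fingerprints
#'
#' Assembles the numeric matrix the classifiers consume: one row per
#' compound, `k * n_bits` columns where `k` is the number of fingerprint
#' types, interleaved so that each compound's features form its k x n_bits
#' stacked matrix in column-major order. The returned matrix carries a
#' `k_rows` attribute used by [build_cnn2d()] inputs.
#'
#' @param x A fingerprint tibble ([compute_fingerprints()]) or a synthetic
#'   dataset ([generate_dataset()]).
#' @param types Fingerprint types to include, in canonical order.
#' @param ... Passed to methods.
#' @param signed Emit -1/+1 values (the default) rather than 0/1 bits.
#' @return Numeric matrix with rownames = compound ids and attributes
#'   `k_rows` and `fp_types`.
#' @export
fp_input <- function(x, types, ..., signed = TRUE) {
  UseMethod("fp_input")
}

fp_input_assemble <- function(mats, ids, types, signed) {
  k <- length(mats)
  n_bits <- ncol(mats[[1]])
  X <- matrix(0, nrow = nrow(mats[[1]]), ncol = k * n_bits)
  for (h in seq_len(k)) {
    m <- mats[[h]]
    if (signed) m <- 2 * m - 1
    X[, h + k * (seq_len(n_bits) - 1L)] <- m
  }
  rownames(X) <- ids
  attr(X, "k_rows") <- k
  attr(X, "fp_types") <- types
  X
}

#' @rdname fp_input
#' @export
fp_input.data.frame <- function(x, types = levels(droplevels(x$fp_type)),
                                ..., signed = TRUE) {
  types <- validate_fp_types(types, "types")
  types <- types[order(match(types, fp_types()))]
  if ("values" %in% names(x)) x <- to_bits(x)
  ids <- unique(x$compound_id)
  mats <- lapply(types, function(tt) {
    sub <- x[as.character(x$fp_type) == tt, , drop = FALSE]
    if (!setequal(sub$compound_id, ids)) {
      stop_fpscreen(
        sprintf("fingerprint type '%s' is missing for some compounds", tt),
        "fpscreen_validation_error"
      )
    }
    sub <- sub[match(ids, sub$compound_id), , drop = FALSE]
    do.call(rbind, sub$bits)
  })
  fp_input_assemble(mats, ids, types, signed)
}
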