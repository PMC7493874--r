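# Readers and writers for the formats the workbench exchanges: SMILES lists,
# compound CSVs, SDF (via ChemmineR when available), wide fingerprint CSVs
# and a compact binary fingerprint container with a JSON sidecar.

#' Read compounds from a SMILES file
#'
#' One SMILES per line; an optional second tab-separated field is taken as
#' the compound id. Blank lines and lines starting with `#` are skipped.
#'
#' @param path File path.
#' @return Tibble with columns `compound_id`, `smiles`.
#' @export
read_smiles <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  smiles <- vapply(parts, `[[`, "", 1)
  ids <- vapply(seq_along(parts), function(i) {
    if (length(parts[[i]]) >= 2 && nzchar(parts[[i]][[2]])) {
      parts[[i]][[2]]
    } else {
      sprintf("compound_%d", i)
    }
  }, "")
  tibble(compound_id = ids, smiles = smiles)
}

#' Read compounds from a CSV file
#'
#' @param path File path.
#' @param smiles_col,id_col,ic50_col Column names in the file; `ic50_col` is
#'   optional (set to `NULL` to skip).
#' @return Tibble with columns `compound_id`, `smiles` and, when present,
#'   `ic50_um`.
#' @export
read_compounds_csv <- function(path, smiles_col = "smiles",
                               id_col = "compound_id",
                               ic50_col = "ic50_um") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!smiles_col %in% names(df)) {
    stop_fpscreen(sprintf("column '%s' not found in %s", smiles_col, path),
                  "fpscreen_io_error")
  }
  out <- tibble(
    compound_id = if (id_col %in% names(df)) {
      as.character(df[[id_col]])
    } else {
      sprintf("compound_%d", seq_len(nrow(df)))
    },
    smiles = as.character(df[[smiles_col]])
  )
  if (!is.null(ic50_col) && ic50_col %in% names(df)) {
    out$ic50_um <- as.numeric(df[[ic50_col]])
  }
  out
}

#' Read compounds from an SDF file
#'
#' Requires the ChemmineR package. Molecules are converted to SMILES; an
#' SD-tag holding the IC50 (default `IC50_uM`) is carried over when present.
#'
#' @param path File path.
#' @param ic50_tag SD data tag with the IC50 in micromolar.
#' @return Tibble with columns `compound_id`, `smiles` and optionally
#'   `ic50_um`.
#' @export
read_sdf <- function(path, ic50_tag = "IC50_uM") {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    stop_fpscreen("reading SDF requires the ChemmineR package",
                  "fpscreen_config_error")
  }
  sdf <- ChemmineR::read.SDFset(path)
  smiles <- as.character(ChemmineR::sdf2smiles(sdf))
  ids <- ChemmineR::sdfid(sdf)
  out <- tibble(compound_id = as.character(ids), smiles = smiles)
  blocks <- ChemmineR::datablock(sdf)
  ic50 <- vapply(blocks, function(b) {
    v <- suppressWarnings(as.numeric(b[ic50_tag]))
    if (length(v) == 0) NA_real_ else v
  }, numeric(1))
  if (any(is.finite(ic50))) out$ic50_um <- ic50
  out
}

#' Write and read fingerprints as wide CSV
#'
#' One row per (compound, type) with the 1024 bit columns `b1..b1024`.
#'
#' @param data Fingerprint tibble with a `bits` list column.
#' @param path File path.
#' @return `path` invisibly; the reader returns a fingerprint tibble.
#' @export
write_fingerprints_csv <- function(data, path) {
  stopifnot(is.data.frame(data), "bits" %in% names(data))
  m <- do.call(rbind, data$bits)
  colnames(m) <- sprintf("b%d", seq_len(ncol(m)))
  wide <- cbind(
    data.frame(compound_id = data$compound_id,
               fp_type = as.character(data$fp_type)),
    as.data.frame(m)
  )
  utils::write.csv(wide, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fingerprints_csv
#' @export
read_fingerprints_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  bit_cols <- grep("^b[0-9]+$", names(df))
  m <- as.matrix(df[, bit_cols])
  tibble(
    compound_id = as.character(df$compound_id),
    fp_type = fp_type_factor(df$fp_type),
    n_bits = length(bit_cols),
    bits = lapply(seq_len(nrow(m)), function(i) as.integer(m[i, ]))
  )
}

#' Write and read fingerprints as a packed binary container
#'
#' Bits are packed 8-per-byte in a raw binary file, described by a JSON
#' sidecar (`<path>.json`) recording the shape, compound ids, type order and
#' encoding, so the container is self-describing.
#'
#' @param data Fingerprint tibble.
#' @param path Output path for the binary payload.
#' @return `path` invisibly; the reader returns a fingerprint tibble.
#' @export
write_fp_bin <- function(data, path) {
  stopifnot(is.data.frame(data), "bits" %in% names(data))
  n_bits <- length(data$bits[[1]])
  bits <- unlist(data$bits, use.names = FALSE)
  payload <- packBits(as.logical(c(bits, rep(0L, (8 - length(bits) %% 8) %% 8))),
                      type = "raw")
  writeBin(payload, path)
  sidecar <- list(
    n_rows = nrow(data), n_bits = n_bits,
    compound_id = data$compound_id, fp_type = as.character(data$fp_type),
    encoding = "bit-packed, row-major, LSB-first within each byte"
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_fp_bin
#' @export
read_fp_bin <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  payload <- readBin(path, "raw",
                     n = ceiling(sidecar$n_rows * sidecar$n_bits / 8))
  bits <- as.integer(rawToBits(payload))[seq_len(sidecar$n_rows * sidecar$n_bits)]
  m <- matrix(bits, nrow = sidecar$n_rows, ncol = sidecar$n_bits, byrow = TRUE)
  tibble(
    compound_id = sidecar$compound_id,
    fp_type = fp_type_factor(sidecar$fp_type),
    n_bits = sidecar$n_bits,
    bits = lapply(seq_len(nrow(m)), function(i) m[i, ])
  )
}
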