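# Synthetic fingerprint data with the statistical structure the classifiers
# assume: compounds are abstract pattern sets, each pattern hashes to 4-5 bit
# positions per pseudo-type, and a compound's fingerprint is the bitwise OR
# of its patterns' position sets (collisions included). Activity is planted
# through a small set of motif patterns — an active's signature is a PAIR of
# distinct motifs, while structured noise puts single stray motifs in some
# inactives — and IC50 values are drawn from a bimodal lognormal mixture
# straddling the activity threshold.

#' Build a synthetic pattern-hashing library
#'
#' Creates the hash maps behind the synthetic fingerprints: each pattern maps
#' to exactly `bits_per_pattern` positions in `[1, n_bits]` per pseudo-type,
#' with independent maps (distinct hash seeds) across the pseudo-types.
#' Collisions — several patterns claiming a position — are expected and
#' retained; their rate is recorded.
#'
#' @param n_patterns Number of patterns in the universe.
#' @param n_bits Fingerprint width.
#' @param bits_per_pattern Positions per pattern, 4 or 5.
#' @param n_pseudotypes Number of independent hash maps; with the default 7
#'   they are named after [fp_types()] so synthetic data flows through the
#'   same pipeline as real fingerprints.
#' @param seed Integer seed.
#' @return A `pattern_library`: per-type position matrices
#'   (`n_patterns` x `bits_per_pattern`, 1-based), plus bookkeeping.
#' @export
build_library <- function(n_patterns, n_bits = 1024, bits_per_pattern = 4,
                          n_pseudotypes = 7, seed = 1) {
  if (!bits_per_pattern %in% c(4, 5)) {
    stop_fpscreen("bits_per_pattern must be 4 or 5",
                  "fpscreen_validation_error")
  }
  stopifnot(n_patterns >= 1, n_bits >= 64)
  types <- if (n_pseudotypes == 7) {
    fp_types()
  } else {
    sprintf("pseudo%d", seq_len(n_pseudotypes))
  }
  set.seed(seed)
  positions <- lapply(types, function(tt) {
    t(vapply(seq_len(n_patterns),
             function(i) sample.int(n_bits, bits_per_pattern),
             integer(bits_per_pattern)))
  })
  names(positions) <- types
  lib <- structure(
    list(positions = positions, n_patterns = n_patterns, n_bits = n_bits,
         bits_per_pattern = bits_per_pattern, seed = seed),
    class = "pattern_library"
  )
  lib
}

#' Collision provenance of a pattern library
#'
#' Lists, for one pseudo-type, every bit position claimed by more than one
#' pattern — the ground truth needed to audit the absence guarantee (a
#' pattern not in a compound can only appear fully set if each of its
#' positions collides with a present pattern).
#'
#' @param library A [build_library()] object.
#' @param pseudo_type One of the library's pseudo-types.
#' @return Tibble with columns `bit`, `n_patterns`, `patterns` (list).
#' @export
pattern_collisions <- function(library, pseudo_type) {
  stopifnot(inherits(library, "pattern_library"))
  pos <- library$positions[[pseudo_type]]
  if (is.null(pos)) {
    stop_fpscreen(sprintf("unknown pseudo-type '%s'", pseudo_type),
                  "fpscreen_validation_error")
  }
  owners <- split(rep(seq_len(nrow(pos)), ncol(pos)), c(pos))
  multi <- owners[lengths(owners) > 1]
  tibble(
    bit = as.integer(names(multi)),
    n_patterns = lengths(multi),
    patterns = unname(multi)
  )
}

#' Render a compound's synthetic fingerprint
#'
#' ORs together the position sets of all the compound's patterns under one
#' pseudo-type's hash map. Monotone: a superset of patterns can only set a
#' superset of bits.
#'
#' @param pattern_ids Integer pattern ids present in the compound.
#' @param pseudo_type One of the library's pseudo-types.
#' @param library A [build_library()] object.
#' @return Integer 0/1 vector of length `n_bits`.
#' @export
render_fingerprint <- function(pattern_ids, pseudo_type, library) {
  stopifnot(inherits(library, "pattern_library"))
  pos <- library$positions[[pseudo_type]]
  if (is.null(pos)) {
    stop_fpscreen(sprintf("unknown pseudo-type '%s'", pseudo_type),
                  "fpscreen_validation_error")
  }
  pattern_ids <- as.integer(pattern_ids)
  if (length(pattern_ids) > 0 &&
      (min(pattern_ids) < 1 || max(pattern_ids) > library$n_patterns)) {
    stop_fpscreen("pattern id outside the library",
                  "fpscreen_validation_error")
  }
  v <- integer(library$n_bits)
  if (length(pattern_ids) > 0) v[c(pos[pattern_ids, , drop = FALSE])] <- 1L
  v
}

#' Generate a synthetic screening dataset
#'
#' Emulates the structure the classifiers are built for, with a planted,
#' recoverable signal. Compounds are random pattern sets over a shared
#' universe; a small group of motif patterns carries the activity signal:
#' with probability `q_signal` an active carries the activity signature — a
#' pair of distinct motif patterns — while with probability `noise_rate` an
#' inactive picks up a single stray motif (structured noise: motif presence
#' alone does not separate the classes, the two-motif signature does). Every
#' compound gets 7 pseudo-type fingerprints (same pattern set, independently
#' hashed) and an IC50 drawn from the lognormal component matching its class
#' — medians 0.92 uM (active) and 13.9 uM (inactive) by default, with
#' spreads chosen so well under 2% of the mass crosses the 7.414 uM boundary
#' and two-cluster K-means on the raw values recovers the component
#' boundary, keeping derived labels nearly noiseless while still exercising
#' the threshold clustering.
#'
#' @param n_active,n_inactive Class sizes.
#' @param q_signal Probability an active carries a motif (in `(0.5, 1]`).
#' @param noise_rate Probability an inactive carries a motif (in `[0, 0.2]`).
#' @param n_patterns Background pattern universe size.
#' @param n_motifs Number of active-motif patterns.
#' @param patterns_per_compound Background patterns per compound.
#' @param bits_per_pattern Hash positions per pattern (4 or 5).
#' @param ic50_params List with `median_active`, `median_inactive` (uM) and
#'   `sdlog_active`, `sdlog_inactive` (log-scale standard deviations).
#' @param n_bits Fingerprint width.
#' @param seed Integer seed; the dataset is fully reproducible.
#' @return A `synth_screen`: `compounds` tibble (`compound_id`, `is_active`,
#'   `ic50_um`), `fingerprints` (named list of n x n_bits 0/1 integer
#'   matrices, one per pseudo-type), `library`, and `truth` (motif ids and
#'   per-compound pattern sets).
#' @export
generate_dataset <- function(n_active = 500, n_inactive = 5000,
                             q_signal = 0.9, noise_rate = 0.05,
                             n_patterns = 200, n_motifs = 8,
                             patterns_per_compound = 20,
                             bits_per_pattern = 4,
                             ic50_params = list(median_active = 0.92,
                                                median_inactive = 13.9,
                                                sdlog_active = 0.55,
                                                sdlog_inactive = 0.18),
                             n_bits = 1024, seed = 1) {
  if (n_active < 1 || n_inactive < 1) {
    stop_fpscreen("both classes need at least one compound",
                  "fpscreen_validation_error")
  }
  if (q_signal <= 0.5 || q_signal > 1) {
    stop_fpscreen("q_signal must lie in (0.5, 1]",
                  "fpscreen_validation_error")
  }
  if (noise_rate < 0 || noise_rate > 0.2) {
    stop_fpscreen("noise_rate must lie in [0, 0.2]",
                  "fpscreen_validation_error")
  }
  library <- build_library(n_patterns + n_motifs, n_bits = n_bits,
                           bits_per_pattern = bits_per_pattern,
                           seed = seed)
  motif_ids <- seq_len(n_motifs)
  background <- n_motifs + seq_len(n_patterns)
  n <- n_active + n_inactive
  is_active <- rep(c(TRUE, FALSE), c(n_active, n_inactive))
  set.seed(seed + 1)
  pattern_sets <- vector("list", n)
  for (i in seq_len(n)) {
    ps <- sample(background, min(patterns_per_compound, n_patterns))
    if (is_active[i]) {
      # the activity signature: a pair of distinct motifs, present at rate q
      if (runif(1) < q_signal) ps <- c(sample(motif_ids, 2), ps)
    } else if (runif(1) < noise_rate) {
      # structured noise: a single stray motif
      ps <- c(sample(motif_ids, 1), ps)
    }
    pattern_sets[[i]] <- ps
  }
  ids <- sprintf("synth_%05d", seq_len(n))
  ic50 <- ifelse(
    is_active,
    rlnorm(n, log(ic50_params$median_active), ic50_params$sdlog_active),
    rlnorm(n, log(ic50_params$median_inactive), ic50_params$sdlog_inactive)
  )
  fingerprints <- lapply(library$positions, function(pos) {
    m <- matrix(0L, nrow = n, ncol = n_bits,
                dimnames = list(ids, NULL))
    rows <- rep(seq_len(n), lengths(pattern_sets))
    cols <- c(pos[unlist(pattern_sets), , drop = FALSE])
    m[cbind(rep(rows, library$bits_per_pattern), cols)] <- 1L
    m
  })
  structure(
    list(
      compounds = tibble(compound_id = ids, is_active = is_active,
                         ic50_um = ic50),
      fingerprints = fingerprints,
      library = library,
      truth = list(motif_ids = motif_ids, pattern_sets = pattern_sets,
                   seed = seed,
                   params = list(n_active = n_active,
                                 n_inactive = n_inactive,
                                 q_signal = q_signal,
                                 noise_rate = noise_rate,
                                 ic50_params = ic50_params))
    ),
    class = "synth_screen"
  )
}

#' @export
print.synth_screen <- function(x, ...) {
  p <- x$truth$params
  cat(sprintf("synthetic screen: %d actives / %d inactives, %d pseudo-types x %d bits\n",
              p$n_active, p$n_inactive, length(x$fingerprints),
              x$library$n_bits))
  cat(sprintf("  motif signal q = %g, inactive noise = %g, %d motif patterns\n",
              p$q_signal, p$noise_rate, length(x$truth$motif_ids)))
  invisible(x)
}

#' @rdname fp_input
#' @export
fp_input.synth_screen <- function(x, types = names(x$fingerprints), ...,
                                  signed = TRUE) {
  types <- types[order(match(types, names(x$fingerprints)))]
  mats <- lapply(types, function(tt) {
    m <- x$fingerprints[[tt]]
    if (is.null(m)) {
      stop_fpscreen(sprintf("pseudo-type '%s' not in this dataset", tt),
                    "fpscreen_validation_error")
    }
    m
  })
  fp_input_assemble(mats, rownames(mats[[1]]), types, signed)
}

#' Convert a synthetic screen to a long fingerprint tibble
#'
#' Gives synthetic data the exact shape [compute_fingerprints()] emits so it
#' can flow through the same writers and stackers.
#'
#' @param x A `synth_screen`.
#' @param types Pseudo-types to include.
#' @return Fingerprint tibble with `compound_id`, `fp_type`, `n_bits`,
#'   `bits`.
#' @export
synth_fingerprint_tbl <- function(x, types = names(x$fingerprints)) {
  stopifnot(inherits(x, "synth_screen"))
  rows <- lapply(types, function(tt) {
    m <- x$fingerprints[[tt]]
    tibble(
      compound_id = rownames(m),
      fp_type = fp_type_factor(tt),
      n_bits = ncol(m),
      bits = lapply(seq_len(nrow(m)), function(i) m[i, ])
    )
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$compound_id, .data$fp_type)
}
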