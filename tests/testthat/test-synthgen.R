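test_that("pattern libraries hash reproducibly with the stated geometry", {
  lib <- build_library(50, bits_per_pattern = 4, seed = 2)
  expect_named(lib$positions, fp_types())
  for (pos in lib$positions) {
    expect_equal(dim(pos), c(50, 4))
    expect_true(all(pos >= 1 & pos <= 1024))
    # a pattern's positions are distinct within itself
    expect_true(all(apply(pos, 1, anyDuplicated) == 0))
  }
  lib2 <- build_library(50, bits_per_pattern = 4, seed = 2)
  expect_identical(lib$positions, lib2$positions)
  # maps differ across pseudo-types
  expect_false(identical(lib$positions[[1]], lib$positions[[2]]))
  expect_error(build_library(10, bits_per_pattern = 3),
               class = "fpscreen_validation_error")
})

test_that("rendering ORs pattern positions and honors set semantics", {
  lib <- build_library(10, bits_per_pattern = 4, seed = 5)
  one <- render_fingerprint(1, "morgan", lib)
  expect_equal(sum(one), 4)   # a single 4-bit pattern sets exactly 4 bits
  expect_equal(which(one == 1), sort(lib$positions$morgan[1, ]))
  # two patterns: popcount equals the size of the union of their positions
  two <- render_fingerprint(c(1, 2), "morgan", lib)
  expect_equal(sum(two), length(union(lib$positions$morgan[1, ],
                                      lib$positions$morgan[2, ])))
  expect_equal(sum(render_fingerprint(integer(0), "morgan", lib)), 0)
  expect_error(render_fingerprint(99, "morgan", lib),
               class = "fpscreen_validation_error")
  expect_error(render_fingerprint(1, "nosuch", lib),
               class = "fpscreen_validation_error")
})

test_that("rendering is monotone: more patterns can only set more bits", {
  lib <- build_library(60, bits_per_pattern = 5, seed = 7)
  set.seed(7)
  for (i in 1:50) {
    small <- sample(60, sample(3:10, 1))
    big <- union(small, sample(60, sample(1:10, 1)))
    a <- render_fingerprint(small, "torsion", lib)
    b <- render_fingerprint(big, "torsion", lib)
    expect_true(all(b[a == 1] == 1))
  }
})

test_that("hash collisions match the birthday-bound expectation", {
  # m patterns x k bits thrown into B positions: E[distinct] = B(1-(1-1/B)^mk)
  lib <- build_library(500, bits_per_pattern = 5, seed = 11)
  B <- 1024; mk <- 500 * 5
  expected_distinct <- B * (1 - (1 - 1 / B)^mk)
  distinct <- vapply(lib$positions, function(pos) length(unique(c(pos))), 0)
  # each pseudo-type is one Monte-Carlo draw; sd of distinct count is ~ sqrt(B*p*(1-p))
  expect_true(all(abs(distinct - expected_distinct) < 40))
  # collision provenance is queryable and consistent
  coll <- pattern_collisions(lib, "rdkit")
  expect_true(all(coll$n_patterns > 1))
  expect_equal(1024 - sum(tabulate(c(lib$positions$rdkit), 1024) == 0),
               distinct[["rdkit"]])
})

test_that("the absence guarantee holds up to recorded collisions", {
  ds <- generate_dataset(n_active = 30, n_inactive = 30, n_patterns = 40,
                         seed = 3)
  lib <- ds$library
  collided_bits <- pattern_collisions(lib, "morgan")$bit
  pos <- lib$positions$morgan
  # an absent pattern may only appear fully lit if every one of its
  # positions collides with some other pattern; count violations directly
  violations <- 0
  for (i in seq_len(30)) {
    present <- ds$truth$pattern_sets[[i]]
    absent <- setdiff(seq_len(lib$n_patterns), present)
    fp <- ds$fingerprints$morgan[i, ]
    for (a in absent) {
      bits_a <- pos[a, ]
      if (all(fp[bits_a] == 1) && !all(bits_a %in% collided_bits)) {
        violations <- violations + 1
      }
    }
  }
  expect_equal(violations, 0)
})

test_that("a noiseless generator yields a perfectly separable motif rule", {
  ds <- generate_dataset(n_active = 40, n_inactive = 200, q_signal = 1,
                         noise_rate = 0, seed = 9)
  # single rule: count motif bits; actives carry a two-motif signature
  score <- Reduce(`+`, lapply(names(ds$fingerprints), function(tt) {
    mb <- unique(c(ds$library$positions[[tt]][ds$truth$motif_ids, ]))
    rowSums(ds$fingerprints[[tt]][, mb])
  }))
  thr <- min(score[ds$compounds$is_active]) - 0.5
  pred <- as.numeric(score > thr)
  cm <- confusion(ds$compounds$is_active, pred)
  expect_equal(balanced_accuracy(cm), 1)
})

test_that("default generation plants a strong linear signal and bimodal IC50s", {
  ds <- generate_dataset(n_active = 150, n_inactive = 1500, seed = 4)
  score <- Reduce(`+`, lapply(names(ds$fingerprints), function(tt) {
    mb <- unique(c(ds$library$positions[[tt]][ds$truth$motif_ids, ]))
    rowSums(ds$fingerprints[[tt]][, mb])
  }))
  expect_gte(auc(score, ds$compounds$is_active), 0.9)
  # threshold recovery between the two component medians
  m <- fit_threshold(ds$compounds, seed = 4)
  expect_gt(m$threshold, 0.92)
  expect_lt(m$threshold, 13.9)
  # labels derived from the recovered threshold agree with ground truth
  lab <- assign_labels(ds$compounds, m)
  expect_gte(mean((lab$label == "active") == lab$is_active), 0.98)
  # reproducibility
  ds2 <- generate_dataset(n_active = 150, n_inactive = 1500, seed = 4)
  expect_identical(ds$fingerprints$ecfp4, ds2$fingerprints$ecfp4)
  expect_equal(ds$compounds$ic50_um, ds2$compounds$ic50_um)
})

test_that("generator validates its rates and sizes", {
  expect_error(generate_dataset(0, 10), class = "fpscreen_validation_error")
  expect_error(generate_dataset(10, 10, q_signal = 0.4),
               class = "fpscreen_validation_error")
  expect_error(generate_dataset(10, 10, noise_rate = 0.5),
               class = "fpscreen_validation_error")
})

test_that("synthetic data flows through the standard fingerprint containers", {
  ds <- generate_dataset(n_active = 10, n_inactive = 20, seed = 8)
  tbl <- synth_fingerprint_tbl(ds, types = c("rdkit", "morgan"))
  expect_equal(nrow(tbl), 60)
  X <- fp_input(ds, types = c("rdkit", "morgan"))
  expect_equal(dim(X), c(30, 2048))
  expect_equal(attr(X, "k_rows"), 2)
  expect_true(all(X %in% c(-1, 1)))
  # the tibble path and the matrix path agree
  X2 <- fp_input(tbl)
  expect_equal(unname(X2), unname(X[rownames(X2), ]), ignore_attr = TRUE)
})
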