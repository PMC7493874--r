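test_that("majority vote equals exhaustive counting on all 128 label vectors", {
  grid <- as.matrix(expand.grid(rep(list(0:1), 7)))
  for (i in seq_len(nrow(grid))) {
    expect_equal(majority_vote(grid[i, ]), oracle_majority(grid[i, ]))
  }
  # matrix form votes row-wise
  expect_equal(majority_vote(grid), apply(grid, 1, oracle_majority))
  expect_equal(majority_vote(c(1, 1, 1, 1, 0, 0, 0)), 1L)
  expect_equal(majority_vote(rep(0, 7)), 0L)
  expect_error(majority_vote(rep(1, 5)), class = "fpscreen_validation_error")
})

test_that("per-task head configurations carry the tuned settings", {
  d <- tuned_mlp_out_config("discrimination")
  expect_equal(d$hidden_units, 3L)
  expect_equal(d$learning_rate, 1e-3)
  expect_equal(d$optimizer, "adam")
  a <- tuned_mlp_out_config("active_only")
  expect_equal(a$hidden_units, 5L)
  expect_equal(a$learning_rate, 1e-4)
  expect_equal(a$optimizer, "adamax")
  expect_error(tuned_mlp_out_config("other"))
  path <- tempfile(fileext = ".json")
  write_tmo_config("active_only", path)
  back <- read_tmo_config(path)
  expect_equal(back$hidden_units, a$hidden_units)
  expect_equal(back$learning_rate, a$learning_rate)
  expect_equal(back$optimizer, a$optimizer)
})

test_that("a head trained on uninformative constant members stays at chance", {
  set.seed(1)
  P <- matrix(0.5, 200, 7)
  y <- rep(c(1, 0), 100)
  head <- fpscreen:::mlp_head_train(P, y, P[1:50, ], y[1:50],
                                    tuned_mlp_out_config("discrimination"),
                                    seed = 1, max_epochs = 100)
  p <- fpscreen:::mlp_head_forward(head$weights, P)$p
  cm <- confusion(y, as.numeric(p > 0.5))
  expect_lt(abs(balanced_accuracy(cm) - 0.5), 0.05)
})

test_that("permuting members with matching head weights leaves predictions fixed", {
  set.seed(2)
  P <- matrix(runif(140), 20, 7)
  y <- rep(c(1, 0), 10)
  head <- fpscreen:::mlp_head_train(P, y, P, y,
                                    tuned_mlp_out_config("discrimination"),
                                    seed = 3, max_epochs = 50)
  perm <- sample(7)
  w2 <- head$weights
  w2$W1 <- w2$W1[, perm]
  p1 <- fpscreen:::mlp_head_forward(head$weights, P)$p
  p2 <- fpscreen:::mlp_head_forward(w2, P[, perm])$p
  expect_equal(p1, p2)
})

# one small stacked fit shared by the remaining assertions
small_member_spec <- cnn_spec("1d", conv_filters = c(16, 8, 8, 4), kernel = 2,
                              dropout = 0.2, head_units = c(32, 16, 8),
                              n_bits = 64, batch_size = 16, seed = 1)

stacked_fixture <- local({
  set.seed(31)
  n <- 260; nb <- 64
  y <- rep(c(1, 0), length.out = n)
  x_all <- lapply(stats::setNames(fp_types(), fp_types()), function(tt) {
    X <- matrix(sample(c(-1, 1), n * nb, replace = TRUE), n)
    X[y == 1, 1:5] <- 1           # same signal, independently noisy per type
    X
  })
  tr <- 1:200; va <- 201:260
  list(
    x = lapply(x_all, function(X) X[tr, ]),
    xv = lapply(x_all, function(X) X[va, ]),
    y = y[tr], yv = y[va]
  )
})

test_that("the stacked ensemble trains, stays in [0,1], and tracks its members", {
  tmo <- train_stacked(stacked_fixture$x, stacked_fixture$y,
                       stacked_fixture$xv, stacked_fixture$yv,
                       task = "discrimination",
                       member_spec = small_member_spec,
                       max_epochs = 8, patience = 8, seed = 31)
  p <- predict(tmo, stacked_fixture$xv)
  expect_true(all(p >= 0 & p <= 1))
  cm <- confusion(stacked_fixture$yv, as.numeric(p > 0.5))
  stacked_bacc <- balanced_accuracy(cm)
  member_bacc <- vapply(fp_types(), function(tt) {
    pm <- predict(tmo$members[[tt]], stacked_fixture$xv[[tt]])
    balanced_accuracy(confusion(stacked_fixture$yv, as.numeric(pm > 0.5)))
  }, 0)
  # stacking does not fall behind its best member
  expect_gte(stacked_bacc, max(member_bacc) - 0.02)
  # determinism end to end
  tmo2 <- train_stacked(stacked_fixture$x, stacked_fixture$y,
                        stacked_fixture$xv, stacked_fixture$yv,
                        task = "discrimination",
                        member_spec = small_member_spec,
                        max_epochs = 8, patience = 8, seed = 31)
  expect_identical(tmo$head$weights, tmo2$head$weights)
  expect_equal(predict(tmo2, stacked_fixture$xv), p)
})

test_that("ensembles demand all seven fingerprint types", {
  bad <- stacked_fixture$x[1:6]
  expect_error(
    train_stacked(bad, stacked_fixture$y, stacked_fixture$xv,
                  stacked_fixture$yv, member_spec = small_member_spec,
                  max_epochs = 1),
    class = "fpscreen_validation_error"
  )
})

test_that("the voting ensemble emits hard majority labels and never abstains", {
  tmo <- train_stacked(stacked_fixture$x, stacked_fixture$y,
                       stacked_fixture$xv, stacked_fixture$yv,
                       member_spec = small_member_spec,
                       max_epochs = 4, patience = 4, seed = 31)
  voter <- voting_ensemble(tmo$members)
  labels <- predict(voter, stacked_fixture$xv)
  expect_true(all(labels %in% c(0L, 1L)))
  expect_length(labels, length(stacked_fixture$yv))
  # members that agree unanimously fix the vote
  P <- fpscreen:::member_probabilities(tmo$members, stacked_fixture$xv)
  unanimous <- rowSums(P > 0.5) %in% c(0, 7)
  if (any(unanimous)) {
    expect_equal(labels[unanimous],
                 as.integer(rowSums(P[unanimous, , drop = FALSE] > 0.5) == 7))
  }
  expect_error(voting_ensemble(tmo$members[1:3]),
               class = "fpscreen_validation_error")
})
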