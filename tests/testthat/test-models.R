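# Small specs keep these fast: the architecture family is the same as the
# full-width networks, only narrower.
small_spec_1d <- function(seed = 7) {
  cnn_spec("1d", conv_filters = c(16, 8, 8, 4), kernel = 3, dropout = 0.2,
           head_units = c(32, 16, 8), n_bits = 128, batch_size = 16,
           seed = seed)
}

test_that("parameter counts equal independent shape arithmetic", {
  # default 1D classifier: 128/64/32/16 filters, kernel 3, same padding,
  # 1024 bits, head 1024/512/256
  m <- build_cnn1d(cnn_spec("1d"))
  conv_params <- 128 * (1 * 3) + 128 +
    64 * (128 * 3) + 64 +
    32 * (64 * 3) + 32 +
    16 * (32 * 3) + 16
  flat <- 16 * (1024 / 2^4)            # 16 channels x 64 pooled positions
  dense_params <- 1024 * flat + 1024 +
    512 * 1024 + 512 +
    256 * 512 + 256 +
    1 * 256 + 1
  expect_equal(m$n_params, conv_params + dense_params)
  # a 2D stack: 3 rows, kernel (5,2): rows pool 3 -> 1 after layer 1
  m2 <- build_cnn2d(cnn_spec("2d", conv_filters = c(8, 8, 8, 4),
                             kernel = c(5, 2), head_units = c(16, 8, 8),
                             n_bits = 128), k_rows = 3)
  conv2 <- 8 * (1 * 2 * 5) + 8 +
    8 * (8 * 2 * 5) + 8 +
    8 * (8 * 2 * 5) + 8 +
    4 * (8 * 2 * 5) + 4
  flat2 <- 4 * 1 * (128 / 2^4)
  dense2 <- 16 * flat2 + 16 + 8 * 16 + 8 + 8 * 8 + 8 + 1 * 8 + 1
  expect_equal(m2$n_params, conv2 + dense2)
})

test_that("builds are deterministic in the seed and outputs are probabilities", {
  a <- build_cnn1d(small_spec_1d())
  b <- build_cnn1d(small_spec_1d())
  expect_identical(a$weights, b$weights)
  c2 <- build_cnn1d(small_spec_1d(seed = 8))
  expect_false(identical(a$weights, c2$weights))
  x_neg <- matrix(-1, 3, 128)
  p <- predict(a, x_neg)
  expect_true(all(p > 0 & p < 1))
})

test_that("the engine forward matches an exact double-precision reference", {
  # degenerate 1x1-kernel network: every layer reproducible in plain R
  spec <- cnn_spec("2d", conv_filters = c(1, 1, 1, 1), kernel = c(1, 1),
                   dropout = 0, head_units = c(3, 2, 2), n_bits = 64,
                   seed = 5)
  m <- build_cnn2d(spec, k_rows = 2)
  set.seed(3)
  X <- matrix(sample(c(-1, 1), 8 * 2 * 64, replace = TRUE), 8)
  expect_equal(predict(m, X), reference_forward_1x1(m$weights, X, 2),
               tolerance = 1e-6)
})

test_that("prediction is empty-safe, order-preserving and batch-consistent", {
  m <- build_cnn1d(small_spec_1d())
  expect_length(predict(m, matrix(0, 0, 128)), 0)
  set.seed(2)
  X <- matrix(sample(c(-1, 1), 9 * 128, replace = TRUE), 9)
  batch <- predict(m, X)
  single <- vapply(1:9, function(i) predict(m, X[i, , drop = FALSE]), 0)
  expect_equal(batch, single, tolerance = 1e-6)
  expect_error(predict(m, matrix(0, 2, 64)), class = "fpscreen_shape_error")
})

test_that("2D kernels cannot span more rows than the stack provides", {
  spec <- cnn_spec("2d", conv_filters = c(8, 8, 8, 4), kernel = c(20, 3),
                   head_units = c(16, 8, 8), n_bits = 128)
  expect_error(build_cnn2d(spec, k_rows = 2), class = "fpscreen_shape_error")
  ok <- build_cnn2d(cnn_spec("2d", conv_filters = c(8, 8, 8, 4),
                             kernel = c(20, 2), head_units = c(16, 8, 8),
                             n_bits = 128), k_rows = 2)
  expect_s3_class(ok, "cnn_model")
  expect_error(build_cnn2d(cnn_spec("2d"), k_rows = 9),
               class = "fpscreen_validation_error")
})

test_that("training learns a planted linearly separable signal", {
  d <- planted_data(300, 128, seed = 42)
  tr <- 1:240; va <- 241:300
  fit <- train_cnn(build_cnn1d(small_spec_1d()), d$x[tr, ], d$y[tr],
                   d$x[va, ], d$y[va], max_epochs = 20, patience = 5,
                   seed = 7)
  p <- predict(fit, d$x[va, ])
  cm <- confusion(d$y[va], as.numeric(p > 0.5))
  expect_gte(balanced_accuracy(cm), 0.9)
  # majority-class baseline is 0.5 by construction; the CNN must beat it
  expect_gte(balanced_accuracy(cm) - 0.5, 0.3)
})

test_that("a 2D stack also learns the planted signal", {
  set.seed(12)
  n <- 240; nb <- 64; k <- 3
  X <- matrix(sample(c(-1, 1), n * k * nb, replace = TRUE), n)
  y <- rep(c(1, 0), length.out = n)
  X[y == 1, c(1:4, (nb * k - 3):(nb * k))] <- 1
  spec <- cnn_spec("2d", conv_filters = c(8, 8, 8, 4), kernel = c(3, 2),
                   dropout = 0.2, head_units = c(16, 8, 8), n_bits = nb,
                   batch_size = 16, seed = 3)
  fit <- train_cnn(build_cnn2d(spec, k_rows = k), X[1:180, ], y[1:180],
                   X[181:240, ], y[181:240], max_epochs = 25, patience = 25,
                   monitor = "val_bacc", seed = 3)
  cm <- confusion(y[181:240],
                  as.numeric(predict(fit, X[181:240, ]) > 0.5))
  expect_gte(balanced_accuracy(cm) - 0.5, 0.3)
})

test_that("training is seed-reproducible and honors the early-stopping contract", {
  d <- planted_data(160, 128, seed = 5)
  m <- build_cnn1d(small_spec_1d())
  args <- list(m, d$x[1:120, ], d$y[1:120], d$x[121:160, ], d$y[121:160])
  f1 <- do.call(train_cnn, c(args, max_epochs = 6, patience = 2, seed = 9))
  f2 <- do.call(train_cnn, c(args, max_epochs = 6, patience = 2, seed = 9))
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$history, f2$history)
  # patience 0: training stops exactly one epoch after the best
  f0 <- do.call(train_cnn, c(args, max_epochs = 30, patience = 0, seed = 9))
  expect_equal(nrow(f0$history), f0$best_epoch + 1)
})

test_that("shuffled labels yield chance-level validation accuracy", {
  d <- planted_data(400, 128, seed = 21)
  set.seed(99)
  y_shuf <- sample(d$y[1:300])
  fit <- train_cnn(build_cnn1d(small_spec_1d()), d$x[1:300, ], y_shuf,
                   d$x[301:400, ], d$y[301:400], max_epochs = 8,
                   patience = 8, seed = 21)
  p <- predict(fit, d$x[301:400, ])
  cm <- confusion(d$y[301:400], as.numeric(p > 0.5))
  expect_lt(abs(balanced_accuracy(cm) - 0.5), 0.1)
})

test_that("single-class training sets are rejected", {
  d <- planted_data(40, 128)
  expect_error(
    train_cnn(build_cnn1d(small_spec_1d()), d$x[d$y == 1, ],
              d$y[d$y == 1], d$x, d$y),
    class = "fpscreen_validation_error"
  )
})

test_that("the grid enumerates the tuning axes and respects its budget", {
  space <- grid_space("1d")
  expect_equal(nrow(space),
               7 * 3 * 2 * 8 * length(unique(c(10^(-6:0), 2 * 10^(-5:-1)))) *
                 5 * 3)
  space2d <- grid_space("2d", filters1 = 32, learning_rate = 1e-3,
                        dropout = 0.2, padding = "same", batch_size = 16,
                        optimizer = "adam")
  expect_equal(nrow(space2d), 10)   # the ten 2D kernel shapes
  expect_error(grid_search(space[0, ], matrix(0, 4, 8), c(0, 1, 0, 1)),
               class = "fpscreen_validation_error")
})

test_that("grid search ranks an intact spec above a label-permuted control", {
  d <- planted_data(200, 64, signal_cols = 1:12, seed = 33)
  # one candidate spec scored on the true labels and, as a permutation
  # control, on shuffled labels
  space <- grid_space("1d", filters1 = 16, learning_rate = 1e-3,
                      dropout = 0.2, padding = "same", batch_size = 16,
                      optimizer = "adam", kernels = list(3L))
  lb <- grid_search(space, d$x, d$y, objective = "bacc", k = 2,
                    max_epochs = 8, patience = 8,
                    head_units = c(16, 8, 8), seed = 1)
  expect_equal(nrow(lb), 1)
  expect_equal(lb$rank, 1)
  set.seed(44)
  lb_null <- grid_search(space, d$x, sample(d$y), objective = "bacc", k = 2,
                         max_epochs = 8, patience = 8,
                         head_units = c(16, 8, 8), seed = 1)
  expect_gt(lb$mean_objective, lb_null$mean_objective)
  # budget truncates and logs evaluation order
  space3 <- grid_space("1d", filters1 = c(8, 16, 32), learning_rate = 1e-3,
                       dropout = 0.2, padding = "same", batch_size = 16,
                       optimizer = "adam", kernels = list(3L))
  lb2 <- grid_search(space3, d$x, d$y, objective = "sensitivity", k = 2,
                     budget = 2, max_epochs = 2, patience = 2,
                     head_units = c(16, 8, 8), seed = 1)
  expect_equal(nrow(lb2), 2)
  expect_setequal(lb2$order_evaluated, 1:2)
})
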