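test_that("confusion counts partition the inputs and match direct counting", {
  cm <- confusion(rep(c(1, 0), c(10, 90)), rep(c(1, 0), c(10, 90)))
  expect_equal(c(cm$tp, cm$tn, cm$fp, cm$fn), c(10, 90, 0, 0))
  inv <- confusion(rep(c(1, 0), c(10, 90)), rep(c(0, 1), c(10, 90)))
  expect_equal(c(inv$tp, inv$tn), c(0, 0))
  set.seed(42)
  for (i in 1:20) {
    truth <- sample(0:1, 50, replace = TRUE)
    pred <- sample(0:1, 50, replace = TRUE)
    cm <- confusion(truth, pred)
    expect_equal(cm$tp, sum(truth & pred))
    expect_equal(cm$fp, sum(!truth & pred))
    expect_equal(cm$tn, sum(!truth & !pred))
    expect_equal(cm$fn, sum(truth & !pred))
    expect_equal(cm$tp + cm$fp + cm$tn + cm$fn, 50)
  }
  expect_error(confusion(c(1, 0), c(1, 0, 1)), class = "fpscreen_error")
})

test_that("scalar metrics follow their definitions on hand-computed cases", {
  cm <- structure(list(tp = 9, fn = 1, tn = 90, fp = 0),
                  class = "confusion_matrix")
  expect_equal(balanced_accuracy(cm), (0.9 + 1) / 2)
  expect_equal(sensitivity(cm), 0.9)
  expect_equal(specificity(cm), 1)
  expect_equal(f1(cm), 2 * 9 / (2 * 9 + 0 + 1))
  perfect <- confusion(rep(c(1, 0), 5), rep(c(1, 0), 5))
  expect_equal(balanced_accuracy(perfect), 1)
  expect_equal(mcc(perfect), 1)
  constant <- confusion(rep(c(1, 0), 5), rep(0, 10))
  expect_equal(balanced_accuracy(constant), 0.5)
  # label-independent predictions (product margins) give MCC 0
  ind <- structure(list(tp = 20, fn = 20, fp = 30, tn = 30),
                   class = "confusion_matrix")
  expect_equal(mcc(ind), 0)
  expect_warning(mcc(constant), "degenerate")
  one_class <- structure(list(tp = 5, fn = 5, tn = 0, fp = 0),
                         class = "confusion_matrix")
  expect_error(balanced_accuracy(one_class), class = "fpscreen_metric_error")
})

test_that("the MCC-chi-square identity holds against stats::chisq.test", {
  set.seed(7)
  for (i in 1:200) {
    cm <- structure(as.list(stats::setNames(sample(1:40, 4, replace = TRUE),
                                            c("tp", "fp", "tn", "fn"))),
                    class = "confusion_matrix")
    tab <- matrix(c(cm$tp, cm$fn, cm$fp, cm$tn), 2)
    n <- sum(tab)
    x2 <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))$statistic
    expect_equal(abs(mcc(cm)), sqrt(unname(x2) / n), tolerance = 1e-12)
  }
})

test_that("AUC equals the all-pairs oracle and is rank-invariant", {
  set.seed(11)
  for (i in 1:10) {
    n <- sample(20:120, 1)
    labels <- rbinom(n, 1, 0.3)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    scores <- round(runif(n), 2)   # coarse grid forces ties
    expect_equal(auc(scores, labels), oracle_auc(scores, labels))
    # strictly monotone transform leaves AUC unchanged
    expect_equal(auc(exp(3 * scores) + 1, labels), auc(scores, labels))
  }
  expect_equal(auc(c(3, 2, 1, 0), c(1, 1, 0, 0)), 1)
  expect_error(auc(1:4, c(1, 1, 1, 1)), class = "fpscreen_metric_error")
})

test_that("binary cross-entropy is clipped and matches direct computation", {
  expect_lt(bce_loss(c(1, 0, 1), c(1, 0, 1)), 1e-5)
  p <- c(0.9, 0.2, 0.6)
  y <- c(1, 0, 0)
  expect_equal(bce_loss(p, y), -mean(c(log(0.9), log(0.8), log(0.4))))
  expect_true(is.finite(bce_loss(c(0, 1), c(1, 0))))
})

test_that("ranked screens order by descending score with stable ties", {
  d <- tibble::tibble(compound_id = c("a", "b", "c", "d"),
                      score = c(0.2, 0.9, 0.5, 0.5),
                      label = c("inactive", "active", "active", "inactive"))
  rs <- ranked_screen(d)
  expect_equal(rs$compound_id, c("b", "c", "d", "a"))
  expect_true(all(diff(rs$score) <= 0))
})

test_that("enrichment factor reproduces the worked table examples", {
  # 701-compound screen, 70 actives, 34 of the top 35 active
  d <- tibble::tibble(
    score = seq(1, 0, length.out = 701),
    label = rep("inactive", 701)
  )
  d$label[c(1:34, 36:71)] <- "active"   # 34 in window, 70 total
  ef <- enrichment_factor(ranked_screen(d), p = c(1, 2, 5))
  expect_equal(ef$window, c(7, 14, 35))
  expect_equal(ef$hits, c(7, 14, 34))
  expect_equal(ef$percent, c(100, 100, 100 * 34 / 35))
  # 3720-compound screen, 80 actives, 65 in the 2% window
  d2 <- tibble::tibble(score = seq(1, 0, length.out = 3720),
                       label = rep("inactive", 3720))
  d2$label[c(1:65, 80:94)] <- "active"
  ef2 <- enrichment_factor(ranked_screen(d2), p = c(1, 2))
  expect_equal(ef2$window, c(37, 74))
  expect_equal(ef2$hits[2], 65)
  expect_equal(round(ef2$percent[2], 2), 87.84)
})

test_that("enrichment factor matches the sort-slice-count oracle", {
  set.seed(5)
  for (i in 1:15) {
    n <- sample(200:10000, 1)
    scores <- runif(n)
    act <- rbinom(n, 1, 0.08) == 1
    d <- tibble::tibble(score = scores,
                        label = ifelse(act, "active", "inactive"))
    p <- sample(c(1, 2, 5, 10, 25), 1)
    got <- enrichment_factor(ranked_screen(d), p = p)
    want <- oracle_ef(scores, act, p)
    expect_equal(got$window, want$window)
    expect_equal(got$hits, want$hits)
    expect_equal(got$percent, want$percent)
  }
})

test_that("enrichment factor rejects empty windows and perfect rankings score 100", {
  d <- tibble::tibble(score = 10:1 / 10,
                      label = rep(c("active", "inactive"), c(3, 7)))
  expect_error(enrichment_factor(ranked_screen(d), p = 1),
               class = "fpscreen_validation_error")
  ef <- enrichment_factor(ranked_screen(d), p = 20)
  expect_equal(ef$percent, 100)
})

test_that("evaluate_scores assembles the full metric suite consistently", {
  set.seed(2)
  y <- rbinom(80, 1, 0.3)
  y[1:2] <- c(0, 1)
  p <- pmin(pmax(y * 0.6 + runif(80) * 0.4, 0.01), 0.99)
  rep <- evaluate_scores(y, p)
  cm <- confusion(y, as.numeric(p > 0.5))
  expect_equal(rep$bacc, balanced_accuracy(cm))
  expect_equal(rep$auc, auc(p, y))
  expect_equal(rep$loss, bce_loss(p, y))
  expect_equal(rep$n_active, sum(y))
})
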