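counts_to_vectors <- function(tp, tn, fp, fn) {
  list(
    truth = rep(c(1L, 0L, 0L, 1L), c(tp, tn, fp, fn)),
    pred = rep(c(1L, 0L, 1L, 0L), c(tp, tn, fp, fn))
  )
}

test_that("metrics match hand evaluation of the defining formulas", {
  v <- counts_to_vectors(tp = 90, tn = 85, fp = 15, fn = 10)
  m <- compute_metrics(v$truth, v$pred)
  expect_equal(m$acc, 87.5)
  expect_equal(m$sen, 90)
  expect_equal(m$spe, 85)
  expect_equal(m$f1, 180 / 205)
  expect_equal(m$mcc, (90 * 85 - 15 * 10) / sqrt(100 * 100 * 105 * 95))
  expect_equal(c(m$tp, m$tn, m$fp, m$fn), c(90, 85, 15, 10))
})

test_that("perfect prediction yields the identity values", {
  y <- rep(c(1L, 0L), 10)
  m <- compute_metrics(y, y, y_score = as.numeric(y))
  expect_equal(m$acc, 100)
  expect_equal(m$mcc, 1)
  expect_equal(m$f1, 1)
  expect_equal(m$auc, 1)
})

test_that("constant scores give AUC 0.5 by the tie convention", {
  y <- rep(c(1L, 0L), 20)
  m <- compute_metrics(y, y_score = rep(0.4, 40))
  expect_equal(m$auc, 0.5)
})

test_that("zero denominators map MCC to 0 and single-class truth warns for AUC", {
  m <- compute_metrics(c(1L, 1L, 0L, 0L), rep(1L, 4)) # no predicted negatives
  expect_equal(m$mcc, 0)
  expect_warning(
    m2 <- compute_metrics(rep(1L, 4), rep(1L, 4), y_score = runif(4)),
    "single class"
  )
  expect_true(is.na(m2$auc))
  expect_equal(m2$acc, 100)
})

test_that("metrics agree with a brute-force tally on 1000 random vectors", {
  results <- withr::with_seed(101, {
    replicate(1000, {
      n <- sample(10:60, 1)
      truth <- c(0L, 1L, sample(0:1, n - 2, replace = TRUE)) # both classes
      pred <- sample(0:1, n, replace = TRUE)
      score <- round(runif(n), 2) # coarse scores force ties
      m <- compute_metrics(truth, pred, score)
      tp <- sum(truth & pred); tn <- sum(!truth & !pred)
      fp <- sum(!truth & pred); fn <- sum(truth & !pred)
      den <- sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tp + fp) * sqrt(tn + fn)
      # independent AUC: pairwise comparison with half-credit for ties
      pos <- score[truth == 1L]; neg <- score[truth == 0L]
      cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
      c(
        acc = abs(m$acc - 100 * (tp + tn) / n),
        mcc = abs(m$mcc - if (den == 0) 0 else (tp * tn - fp * fn) / den),
        sen = if (tp + fn > 0) abs(m$sen - 100 * tp / (tp + fn)) else 0,
        auc = abs(m$auc - mean(cmp)),
        trap = abs(m6ager:::trapezoid_auc(m$roc) - m$auc)
      )
    })
  })
  expect_lt(max(results["acc", ]), 1e-10)
  expect_lt(max(results["mcc", ]), 1e-10)
  expect_lt(max(results["sen", ]), 1e-10)
  expect_lt(max(results["auc", ]), 1e-10)
  expect_lt(max(results["trap", ]), 1e-12)
})

test_that("AUC matches an established ROC implementation", {
  withr::with_seed(103, {
    truth <- sample(0:1, 200, replace = TRUE, prob = c(0.6, 0.4))
    truth[1:2] <- 0:1
    score <- runif(200) + 0.3 * truth
    m <- compute_metrics(truth, y_score = score)
    ref <- as.numeric(pROC::auc(pROC::roc(truth, score, quiet = TRUE)))
    expect_equal(m$auc, ref, tolerance = 1e-12)
  })
})

test_that("ROC curves start at (0,0), end at (1,1), are monotone", {
  withr::with_seed(105, {
    truth <- c(0L, 1L, sample(0:1, 98, replace = TRUE))
    score <- round(runif(100), 1)
    roc <- roc_curve(truth, score)
    expect_equal(c(roc$fpr[1], roc$tpr[1]), c(0, 0))
    expect_equal(c(roc$fpr[nrow(roc)], roc$tpr[nrow(roc)]), c(1, 1))
    expect_true(all(diff(roc$fpr) >= 0))
    expect_true(all(diff(roc$tpr) >= 0))
  })
})

test_that("perfect scores pass through (0,1) and reversal flips AUC", {
  y <- rep(c(1L, 0L), each = 10)
  s <- as.numeric(y)
  roc <- roc_curve(y, s)
  expect_true(any(roc$fpr == 0 & roc$tpr == 1))
  withr::with_seed(107, {
    s2 <- runif(20)
    a <- compute_metrics(y, y_score = s2)$auc
    b <- compute_metrics(y, y_score = -s2)$auc
    expect_equal(b, 1 - a, tolerance = 1e-12)
  })
})

test_that("random scores on balanced labels give AUC near 0.5", {
  withr::with_seed(109, {
    y <- rep(c(1L, 0L), each = 5000)
    s <- runif(10000)
    expect_lt(abs(compute_metrics(y, y_score = s)$auc - 0.5), 0.02)
  })
})

test_that("swapping the class convention maps SEN <-> SPE, keeps ACC and MCC", {
  withr::with_seed(111, {
    truth <- c(0L, 1L, sample(0:1, 98, replace = TRUE))
    pred <- sample(0:1, 100, replace = TRUE)
    a <- compute_metrics(truth, pred)
    b <- compute_metrics(1L - truth, 1L - pred)
    expect_equal(a$sen, b$spe)
    expect_equal(a$spe, b$sen)
    expect_equal(a$acc, b$acc)
    expect_equal(a$mcc, b$mcc)
  })
})

test_that("ROC and importance plots build without error", {
  withr::with_seed(113, {
    truth <- rep(c(1L, 0L), each = 25)
    score <- runif(50) + 0.5 * truth
    m <- compute_metrics(truth, y_score = score)
    p <- plot_roc(m)
    expect_s3_class(p, "ggplot")
    expect_s3_class(ggplot2::autoplot(m), "ggplot")
  })
})

test_that("tidy/glance expose the metrics as tibbles", {
  v <- counts_to_vectors(9, 8, 2, 1)
  m <- compute_metrics(v$truth, v$pred, y_score = seq(0, 1, length.out = 20))
  td <- tidy(m)
  expect_named(td, c("metric", "value"))
  expect_equal(nrow(td), 6L)
  expect_equal(glance(m)$tp, 9)
})
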