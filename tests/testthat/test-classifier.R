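make_block <- function(X, ids = NULL, block = "X") {
  m6ager:::new_feature_block(ids %||% sprintf("s%03d", seq_len(nrow(X))), X, block)
}

lin_sep <- function(n = 80, seed = 81) {
  withr::with_seed(seed, {
    y <- rep(c(0L, 1L), each = n / 2)
    X <- cbind(f1 = rnorm(n, mean = 2 * y), f2 = rnorm(n))
    X[, 1] <- X[, 1] + 10 * y # fully separable on f1
    colnames(X) <- c("X_f1", "X_f2")
    list(X = make_block(X), y = y)
  })
}

test_that("auto class weights are inversely proportional to class sizes", {
  y <- rep(c(1L, 0L), c(400, 100))
  cw <- m6ager:::resolve_class_weights("auto", y)
  expect_equal(unname(cw["1"]), 0.625)
  expect_equal(unname(cw["0"]), 2.5)
  # equal total weighted mass per class
  expect_equal(cw[["1"]] * 400, cw[["0"]] * 100)
})

test_that("a separable problem is fit to 100% training accuracy", {
  d <- lin_sep()
  m <- train_model(d$X, d$y, train_config(iterations = 50, seed = 1))
  pr <- predict(m, d$X)
  expect_equal(pr$label, d$y)
  expect_true(all(pr$score >= 0 & pr$score <= 1))
})

test_that("training and prediction are deterministic given the seed", {
  d <- lin_sep(seed = 83)
  m1 <- train_model(d$X, d$y, train_config(iterations = 30, seed = 5))
  m2 <- train_model(d$X, d$y, train_config(iterations = 30, seed = 5))
  expect_identical(predict(m1, d$X)$score, predict(m2, d$X)$score)
})

test_that("row permutations permute predictions identically", {
  d <- lin_sep(seed = 85)
  m <- train_model(d$X, d$y, train_config(iterations = 30, seed = 2))
  perm <- withr::with_seed(87, sample(nrow(d$X)))
  p1 <- predict(m, d$X)
  p2 <- predict(m, d$X[perm, ])
  expect_equal(p2$score, p1$score[perm])
})

test_that("prediction rejects mismatched columns naming the offenders", {
  d <- lin_sep()
  m <- train_model(d$X, d$y, train_config(iterations = 10))
  bad <- d$X
  names(bad)[2] <- "X_other"
  attr(bad, "block_map") <- stats::setNames(rep("X", 2), c("X_other", "X_f2"))
  expect_error(predict(m, bad), "X_f1")
})

test_that("single-class training labels are rejected", {
  d <- lin_sep()
  expect_error(train_model(d$X, rep(1L, nrow(d$X)), train_config()), "single class")
})

test_that("an informative column among noise ranks first in importance", {
  first_rank <- vapply(1:10, function(seed) {
    withr::with_seed(seed, {
      n <- 200
      y <- rep(c(0L, 1L), each = n / 2)
      X <- matrix(rnorm(n * 6), n, 6)
      X[, 4] <- y + rnorm(n, sd = 0.1) # the only informative column
      colnames(X) <- paste0("X_f", 1:6)
      m <- train_model(make_block(X), y, train_config(iterations = 50, seed = seed))
      feature_importance(m, top_n = 6)$features$feature[1]
    })
  }, character(1))
  expect_gte(sum(first_rank == "X_f4"), 6) # 10-seed majority
})

test_that("importance reports are ranked, clamped, and block fractions sum to 1", {
  d <- lin_sep()
  m <- train_model(d$X, d$y, train_config(iterations = 20))
  expect_warning(imp <- feature_importance(m, top_n = 50), "clamp")
  expect_equal(nrow(imp$features), 2L)
  expect_true(all(diff(imp$features$score) <= 0))
  expect_true(all(imp$features$score >= 0))
  expect_equal(sum(imp$blocks$fraction), 1)
})

test_that("block selection finds the informative block and honors overrides", {
  d <- random_samples(120, 21, seed = 91)
  withr::with_seed(93, {
    n <- nrow(d)
    signal <- matrix(rnorm(n * 4, mean = 2 * d$label), n, 4)
    noise <- matrix(rnorm(n * 4), n, 4)
    colnames(signal) <- paste0("SIG_f", 1:4)
    colnames(noise) <- paste0("NOI_f", 1:4)
    cand <- list(
      SIG = make_block(signal, ids = d$id, block = "SIG"),
      NOI = make_block(noise, ids = d$id, block = "NOI")
    )
    sel <- select_feature_blocks(d, cand, train_config(iterations = 40), n_keep = 1)
    expect_equal(sel, "SIG")
    expect_equal(
      select_feature_blocks(d, cand, n_keep = 1, override = c("NOI", "SIG")),
      c("NOI", "SIG")
    )
    expect_warning(
      sel_all <- select_feature_blocks(d, cand, train_config(iterations = 10), n_keep = 5),
      "n_keep"
    )
    expect_setequal(sel_all, c("SIG", "NOI"))
  })
})

test_that("save -> load -> predict round-trips bit-identically", {
  d <- lin_sep(seed = 95)
  m <- train_model(d$X, d$y, train_config(iterations = 30, seed = 3),
    encoders = list(bpb = fit_bpb(random_samples(20, 9, seed = 97)))
  )
  dir <- tempfile("bundle")
  save_model(m, dir)
  m2 <- load_model(dir)
  expect_identical(predict(m2, d$X)$score, predict(m, d$X)$score)
  expect_equal(m2$columns, m$columns)
  expect_equal(m2$encoders$bpb$f_pos, m$encoders$bpb$f_pos)
  expect_s3_class(m2$encoders$bpb, "bpb_model")
})

test_that("importance plots build from models and reports", {
  d <- lin_sep(seed = 101)
  m <- train_model(d$X, d$y, train_config(iterations = 20))
  expect_s3_class(plot_importance(m, top_n = 2), "ggplot")
  expect_s3_class(ggplot2::autoplot(feature_importance(m, top_n = 2)), "ggplot")
})

test_that("tidy and glance methods return well-formed tibbles", {
  d <- lin_sep(seed = 99)
  m <- train_model(d$X, d$y, train_config(iterations = 20))
  td <- tidy(m)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("feature", "score", "block"))
  gl <- glance(m)
  expect_equal(gl$iterations, 20L)
  expect_equal(gl$n_features, 2L)
})
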