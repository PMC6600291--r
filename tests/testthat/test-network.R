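test_that("shape arithmetic matches the fixed stack for all three maps", {
  # 19x19 angle map: 19 -> 15 (conv5) -> 7 (pool) -> 3 (conv5) -> 2 (conv2)
  expect_identical(validate_cnn_shape(c(19, 19, 23)), c(19L, 15L, 7L, 3L, 2L))
  expect_identical(validate_cnn_shape(c(20, 20, 25)), c(20L, 16L, 8L, 4L, 3L))
  expect_identical(validate_cnn_shape(c(23, 23, 8)), c(23L, 19L, 9L, 5L, 4L))

  # the paper-scale model flattens 2*2*500 features for the angle map
  m <- build_cnn(c(19, 19, 23), cnn_config("arch1"))
  dense <- m$layers[[length(m$layers)]]
  expect_identical(dense$type, "dense")
  expect_identical(dense$D, 2L * 2L * 500L)

  expect_error(build_cnn(c(4, 4, 1), cnn_config("desk")), "conv")
})

test_that("shape validator agrees with actually constructed models", {
  cfg <- cnn_config("desk", filters = c(2, 3, 4))
  withr::with_seed(41, {
    for (rep_i in 1:50) {
      h <- sample(16:40, 1)  # 16 is the smallest side the stack accepts
      tr <- validate_cnn_shape(c(h, h, 1), cfg)
      m <- build_cnn(c(h, h, 1), cfg)
      x <- list(array(rnorm(h * h), c(h, h, 1)))
      p <- predict_proba(m, x)
      expect_identical(dim(p), c(1L, 6L))
      dense <- m$layers[[length(m$layers)]]
      expect_identical(dense$D, as.integer(tr[5]^2 * 4))
    }
  })
})

test_that("softmax outputs are probability vectors even untrained", {
  m <- build_cnn(c(19, 19, 3), cnn_config("desk", filters = c(3, 4, 5)))
  x <- withr::with_seed(42, lapply(1:4, function(i) {
    array(rnorm(19 * 19 * 3), c(19, 19, 3))
  }))
  p <- predict_proba(m, x)
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 4), tolerance = 1e-6)
})

test_that("training separates linearly separable classes", {
  x <- withr::with_seed(43, lapply(1:24, function(i) {
    array(rnorm(19 * 19, mean = ifelse(i <= 12, -0.5, 0.5)), c(19, 19, 1))
  }))
  y <- rep(1:2, each = 12)
  cfg <- cnn_config("desk", filters = c(4, 8, 16), epochs = 20,
                    batch_size = 8, n_classes = 2, seed = 44)
  fit <- train_cnn(build_cnn(c(19, 19, 1), cfg), x, y)
  expect_gte(tail(fit$history$train_acc, 1), 0.95)
  expect_identical(nrow(fit$history), 20L)
  expect_true(all(fit$history$train_acc >= 0 & fit$history$train_acc <= 1))
})

test_that("shuffled labels give chance-level test accuracy", {
  withr::with_seed(45, {
    x <- lapply(1:40, function(i) array(rnorm(19 * 19), c(19, 19, 1)))
    y <- sample(1:2, 40, replace = TRUE)
    x_te <- lapply(1:40, function(i) array(rnorm(19 * 19), c(19, 19, 1)))
    y_te <- sample(1:2, 40, replace = TRUE)
  })
  cfg <- cnn_config("desk", filters = c(2, 4, 8), epochs = 5,
                    n_classes = 2, seed = 46)
  fit <- train_cnn(build_cnn(c(19, 19, 1), cfg), x, y, x_te, y_te)
  acc <- tail(fit$history$test_acc, 1)
  expect_gt(acc, 0.5 - 3 * sqrt(0.25 / 40))  # binomial noise around 1/l
  expect_lt(acc, 0.5 + 3 * sqrt(0.25 / 40))
})

test_that("training is bit-deterministic given the seed", {
  x <- withr::with_seed(47, lapply(1:12, function(i) {
    array(rnorm(19 * 19), c(19, 19, 1))
  }))
  y <- rep(1:3, 4)
  cfg <- cnn_config("desk", filters = c(2, 3, 4), epochs = 3,
                    n_classes = 3, seed = 48)
  f1 <- train_cnn(build_cnn(c(19, 19, 1), cfg), x, y)
  f2 <- train_cnn(build_cnn(c(19, 19, 1), cfg), x, y)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$layers[[1]]$W, f2$model$layers[[1]]$W)
})

test_that("full-batch descent on a tiny set decreases the loss", {
  x <- withr::with_seed(49, lapply(1:8, function(i) {
    array(rnorm(19 * 19, mean = ifelse(i <= 4, -1, 1)), c(19, 19, 1))
  }))
  y <- rep(1:2, each = 4)
  cfg <- cnn_config("desk", filters = c(2, 3, 4), epochs = 15,
                    batch_size = 8, dropout_rate = 0, momentum = 0,
                    n_classes = 2, seed = 50)
  fit <- train_cnn(build_cnn(c(19, 19, 1), cfg), x, y)
  # history is recorded in evaluation mode: tiny transient increases from
  # batch-norm running-statistic warm-up are tolerated
  dl <- diff(fit$history$train_loss)
  expect_true(all(dl <= 5e-3))
  expect_lt(tail(fit$history$train_loss, 1), fit$history$train_loss[1])
})

test_that("an overfit toy model reproduces its training labels", {
  x <- withr::with_seed(51, lapply(1:12, function(i) {
    array(rnorm(19 * 19, mean = (i %% 3) - 1, sd = 0.3), c(19, 19, 1))
  }))
  y <- (seq_len(12) %% 3) + 1L
  cfg <- cnn_config("desk", filters = c(4, 8, 16), epochs = 40,
                    batch_size = 12, dropout_rate = 0, n_classes = 3,
                    seed = 52)
  fit <- train_cnn(build_cnn(c(19, 19, 1), cfg), x, y)
  p <- predict_proba(fit$model, x)
  expect_gte(mean(apply(p, 1, which.max) == y), 0.95)
})

test_that("batch and one-at-a-time inference agree", {
  m <- build_cnn(c(19, 19, 2), cnn_config("desk", filters = c(3, 4, 5)))
  x <- withr::with_seed(53, lapply(1:5, function(i) {
    array(rnorm(19 * 19 * 2), c(19, 19, 2))
  }))
  p_batch <- predict_proba(m, x)
  p_single <- do.call(rbind, lapply(x, function(xi) predict_proba(m, list(xi))))
  expect_equal(p_batch, p_single, tolerance = 1e-12)
})

test_that("training rejects degenerate inputs", {
  x <- lapply(1:4, function(i) array(rnorm(19 * 19), c(19, 19, 1)))
  cfg <- cnn_config("desk", filters = c(2, 3, 4), epochs = 1, n_classes = 3,
                    seed = 54)
  m <- build_cnn(c(19, 19, 1), cfg)
  expect_error(train_cnn(m, x, c(1, 1, 2, 2)), "class")
  expect_error(predict_proba(m, list(array(0, c(5, 5, 1)))), "shape")
})
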