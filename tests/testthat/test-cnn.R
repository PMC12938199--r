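test_that("layer shapes follow the stride-1 no-padding arithmetic for every channel count", {
  dims <- oracle_layer_dims()
  for (ch in c(2L, 4L, 8L, 16L, 32L, 64L)) {
    shp <- cnn_shapes(cnn_config(ch))
    expect_equal(shp$height[-1], vapply(dims, `[`, numeric(1), 1))
    expect_equal(shp$width[-1], vapply(dims, `[`, numeric(1), 2))
    expect_equal(attr(shp, "flat_length"), ch * 17L * 13L)
  }
  expect_equal(attr(cnn_shapes(cnn_config(64L)), "flat_length"), 14144L)
  expect_warning(cnn_config(3L), "search set")
})

test_that("a 64-channel forward pass flattens to 14,144 values and a softmax pair", {
  model <- build_cnn(cnn_config(64L), seed = 2)
  x <- array(runif(36 * 32), c(36, 32, 1))
  fw <- ppigray:::cnn_forward(model, ppigray:::as_input_matrix(x), cache = TRUE)
  expect_equal(nrow(fw$cache$Xf), 14144L)
  expect_equal(colSums(fw$probs), 1)
  expect_true(all(fw$probs >= 0 & fw$probs <= 1))
  expect_equal(model$flat_length, 14144L)
})

test_that("analytic gradients match numerical differentiation", {
  model <- build_cnn(cnn_config(2L), seed = 3)
  set.seed(10)
  x <- matrix(runif(1152 * 3), 1152, 3)
  y <- c(1L, 0L, 1L)
  fw <- ppigray:::cnn_forward(model, x, cache = TRUE)
  onehot <- rbind(as.numeric(y == 1), as.numeric(y != 1))
  grads <- ppigray:::cnn_backward(model, fw$cache, (fw$probs - onehot) / 3)
  eps <- 1e-6
  for (nm in names(grads)) {
    for (k in sample(length(model$params[[nm]]), min(3, length(model$params[[nm]])))) {
      m2 <- model
      m2$params[[nm]][k] <- model$params[[nm]][k] + eps
      up <- ppigray:::ce_loss(ppigray:::cnn_forward(m2, x)$probs, y)
      m2$params[[nm]][k] <- model$params[[nm]][k] - eps
      dn <- ppigray:::ce_loss(ppigray:::cnn_forward(m2, x)$probs, y)
      num <- (up - dn) / (2 * eps)
      expect_equal(grads[[nm]][k], num, tolerance = 1e-4,
                   label = paste("grad", nm))
    }
  }
})

test_that("mean-reduced loss is invariant to duplicating a batch", {
  model <- build_cnn(cnn_config(2L), seed = 4)
  set.seed(20)
  x1 <- matrix(runif(1152), 1152, 1)
  x4 <- x1[, rep(1, 4)]
  l1 <- ppigray:::ce_loss(ppigray:::cnn_forward(model, x1)$probs, 1L)
  l4 <- ppigray:::ce_loss(ppigray:::cnn_forward(model, x4)$probs, rep(1L, 4))
  expect_equal(l1, l4)
})

separable_set <- function(n, seed) {
  # two template maps plus light noise: trivially separable
  set.seed(seed)
  t1 <- matrix(runif(1152), 36, 32)
  t0 <- matrix(runif(1152), 36, 32)
  x <- array(0, c(36, 32, n))
  y <- rep(c(1L, 0L), length.out = n)
  for (i in seq_len(n)) {
    x[, , i] <- (if (y[i] == 1) t1 else t0) + matrix(rnorm(1152, 0, 0.02), 36, 32)
  }
  list(x = x, y = y)
}

test_that("training overfits a small separable set and stops early on plateaus", {
  tr <- separable_set(64, 1)
  # validating on the training set itself: early stopping then only fires
  # once the model has stopped improving on what it can memorize
  tc <- cnn_train_config(lr = 1e-3, batch_size = 8L, max_epochs = 100L,
                         patience = 10L, seed = 5)
  model <- cnn_train(build_cnn(cnn_config(2L), seed = 6),
                     tr$x, tr$y, tr$x, tr$y, tc)
  train_acc <- mean((predict(model, tr$x) > 0.5) == (tr$y == 1))
  expect_equal(train_acc, 1)
  expect_lte(model$stopped_epoch, 100L)
  # after the best epoch, no more than `patience` non-improving epochs ran
  expect_lte(model$stopped_epoch - model$best_epoch, tc$patience)
  expect_equal(min(model$history$val_loss),
               model$history$val_loss[model$best_epoch])
})

test_that("training is bitwise reproducible under a fixed seed", {
  tr <- separable_set(32, 3)
  va <- separable_set(16, 4)
  tc <- cnn_train_config(lr = 5e-4, batch_size = 16L, max_epochs = 5L,
                         patience = 3L, seed = 7)
  m1 <- cnn_train(build_cnn(cnn_config(2L), seed = 8), tr$x, tr$y, va$x, va$y, tc)
  m2 <- cnn_train(build_cnn(cnn_config(2L), seed = 8), tr$x, tr$y, va$x, va$y, tc)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
})

test_that("training rejects empty inputs and records history", {
  tr <- separable_set(16, 5)
  expect_error(cnn_train(build_cnn(cnn_config(2L), seed = 1),
                         tr$x[, , 0], integer(0), tr$x, tr$y,
                         cnn_train_config(max_epochs = 2L, patience = 1L)),
               "empty")
  m <- cnn_train(build_cnn(cnn_config(2L), seed = 1), tr$x, tr$y, tr$x, tr$y,
                 cnn_train_config(max_epochs = 3L, patience = 2L, seed = 2))
  expect_named(m$history, c("epoch", "train_loss", "val_loss"))
  expect_gte(nrow(m$history), 1)
})

test_that("prediction thresholds are monotone and probabilities complementary", {
  tr <- separable_set(24, 6)
  model <- build_cnn(cnn_config(2L), seed = 9)
  pm <- predict(model, tr$x, type = "matrix")
  expect_equal(rowSums(pm), rep(1, 24))
  p <- predict(model, tr$x)
  strict <- which(p > 0.98)
  loose <- which(p > 0.5)
  expect_true(all(strict %in% loose))
})
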