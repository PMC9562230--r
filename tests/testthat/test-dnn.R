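# Network presets, normalisation, training behaviour and MAE evaluation.

test_that("presets encode the three published architectures", {
  d1 <- preset_spec("data1")
  expect_identical(d1$optimizer, "RMSprop")
  expect_identical(d1$input_dim, 14L)
  expect_identical(vapply(d1$layers, `[[`, integer(1), "units"),
                   c(64L, 64L, 32L, 16L, 1L))
  expect_identical(vapply(d1$layers, `[[`, character(1), "activation"),
                   c("RELU", "ELU", "ELU", "ELU", "linear"))
  d2 <- preset_spec("data2")
  expect_identical(d2$input_dim, 6L)
  expect_identical(d2$optimizer, "Adam")
  expect_true(all(vapply(d2$layers[1:4], `[[`, character(1), "activation") == "RELU"))
  d3 <- preset_spec("data3")
  expect_identical(d3$layers[[1]]$units, 128L)
  expect_identical(d3$layers[[1]]$activation, "RELU")
  for (spec in list(d1, d2, d3)) {
    last <- spec$layers[[length(spec$layers)]]
    expect_identical(last$units, 1L)
    expect_identical(last$activation, "linear")
    expect_identical(spec$max_epochs, 2000L)
    expect_identical(spec$loss, "MAE")
  }
  expect_error(preset_spec("data4"))
})

test_that("normalisation fits on training data only", {
  set.seed(1)
  train <- tibble::tibble(a = rnorm(50, 10, 3), b = runif(50, 0, 1))
  held <- tibble::tibble(a = rnorm(20, 30, 1), b = runif(20, 5, 6))
  norm <- normalize_features(train, apply_to = list(held = held))
  expect_equal(unname(colMeans(as.matrix(norm$train))), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(apply(as.matrix(norm$train), 2, sd)), c(1, 1),
               tolerance = 1e-9)
  # the held-out table is scaled with the training parameters, not its own:
  # its distribution sits far from the training one, so its own z-scores
  # (mean 0) must differ from the leakage-free scaling
  scaled_held <- as.matrix(norm$applied$held)
  expect_gt(abs(mean(scaled_held[, "a"])), 3)
  own <- scale(as.matrix(held))
  expect_false(isTRUE(all.equal(scaled_held, unclass(own), check.attributes = FALSE)))
  expect_warning(normalize_features(tibble::tibble(a = rep(2, 5), b = 1:5)),
                 regexp = "Constant")
  const <- suppressWarnings(normalize_features(tibble::tibble(a = rep(2, 5))))
  expect_true(all(const$train$a == 0))
})

test_that("MAE evaluation is plain mean absolute error", {
  spec <- network_spec(2, list(list(4L, "RELU")), max_epochs = 5)
  m <- train_dnn(spec, matrix(rnorm(20), 10, 2), rnorm(10), seed = 1,
                 validation_split = 0)
  X <- matrix(c(1, 0, 0, 1, 1, 1), 3, 2, byrow = TRUE)
  y <- predict(m, X)
  expect_equal(evaluate_mae(m, X, y), 0)
  expect_equal(evaluate_mae(m, X, y + 1), 1)
  # hand-computed oracle on a 3-row fixture
  t3 <- c(2.5, -1, 4)
  expect_equal(evaluate_mae(m, X, t3),
               (abs(y[1] - 2.5) + abs(y[2] + 1) + abs(y[3] - 4)) / 3)
  expect_error(evaluate_mae(m, X, 1:2), class = "winepi_error_config")
})

test_that("training fits a noiseless linear target to low MAE", {
  spec <- network_spec(6, list(list(16L, "RELU"), list(8L, "RELU")),
                       optimizer = "Adam", max_epochs = 600, patience = 60)
  for (seed in 1:3) {
    set.seed(100 + seed)
    X <- matrix(rnorm(1000 * 6), 1000, 6)
    w <- c(0.5, -0.3, 0.2, 0.1, -0.4, 0.25)
    y <- as.vector(X %*% w) + 5.5
    m <- train_dnn(spec, X, y, seed = seed)
    expect_lte(evaluate_mae(m, X, y), 0.05)
  }
})

test_that("a constant target is reproduced", {
  spec <- network_spec(3, list(list(8L, "RELU")), max_epochs = 300, patience = 50)
  X <- matrix(rnorm(200 * 3), 200, 3)
  m <- train_dnn(spec, X, rep(5.5, 200), seed = 2, learning_rate = 0.01)
  expect_true(all(abs(predict(m, X) - 5.5) <= 0.05))
})

test_that("the same seed reproduces the identical history", {
  spec <- network_spec(3, list(list(8L, "ELU")), max_epochs = 40)
  set.seed(5)
  X <- matrix(rnorm(120 * 3), 120, 3)
  y <- rnorm(120, 5, 1)
  m1 <- train_dnn(spec, X, y, seed = 7)
  m2 <- train_dnn(spec, X, y, seed = 7)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$weights, m2$weights)
  m3 <- train_dnn(spec, X, y, seed = 8)
  expect_false(identical(m1$history, m3$history))
})

test_that("early stopping restores the best epoch within the cap", {
  spec <- network_spec(3, list(list(8L, "RELU")), max_epochs = 500, patience = 20)
  set.seed(6)
  X <- matrix(rnorm(150 * 3), 150, 3)
  y <- rnorm(150)
  m <- train_dnn(spec, X, y, seed = 1)
  expect_lte(m$stopping_epoch, spec$max_epochs)
  expect_identical(nrow(m$history), m$stopping_epoch)
  expect_lte(m$best_epoch, m$stopping_epoch)
  expect_equal(m$best_metric, min(m$history$val_loss))
})

test_that("full-batch training is invariant to row permutation", {
  spec <- network_spec(3, list(list(8L, "RELU")), max_epochs = 60)
  set.seed(8)
  X <- matrix(rnorm(80 * 3), 80, 3)
  y <- as.vector(X %*% c(1, -1, 0.5)) + 5
  perm <- sample(80)
  m1 <- train_dnn(spec, X, y, seed = 3, batch_size = Inf,
                  validation_split = 0, shuffle = FALSE)
  m2 <- train_dnn(spec, X[perm, ], y[perm], seed = 3, batch_size = Inf,
                  validation_split = 0, shuffle = FALSE)
  expect_equal(evaluate_mae(m1, X, y), evaluate_mae(m2, X, y), tolerance = 1e-6)
})

test_that("input contracts are enforced", {
  spec <- network_spec(3, list(list(4L, "RELU")), max_epochs = 5)
  X <- matrix(rnorm(30), 10, 3)
  expect_error(train_dnn(spec, X, rnorm(9), seed = 1),
               class = "winepi_error_config")
  expect_error(train_dnn(spec, X[, 1:2], rnorm(10), seed = 1),
               class = "winepi_error_config")
  Xbad <- X; Xbad[1, 1] <- NA
  expect_error(train_dnn(spec, Xbad, rnorm(10), seed = 1),
               class = "winepi_error_domain")
})

test_that("tidiers and plots summarise a fitted network", {
  spec <- network_spec(3, list(list(4L, "RELU")), max_epochs = 30)
  set.seed(9)
  m <- train_dnn(spec, matrix(rnorm(150), 50, 3), rnorm(50, 5), seed = 1)
  h <- tidy(m)
  expect_identical(names(h), c("epoch", "loss", "val_loss"))
  g <- glance(m)
  expect_identical(g$stopping_epoch, m$stopping_epoch)
  expect_s3_class(autoplot(m), "ggplot")
})
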