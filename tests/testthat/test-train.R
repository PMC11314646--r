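test_that("cross-entropy equals minus log softmax, stably", {
  expect_equal(cross_entropy(c(0, 0), 1), log(2), tolerance = 1e-12)
  expect_equal(cross_entropy(c(2, 0), 0), log(1 + exp(-2)), tolerance = 1e-12)
  # saturated logits neither overflow nor go negative
  expect_equal(cross_entropy(c(1000, 0), 0), 0, tolerance = 1e-12)
  expect_gt(cross_entropy(c(0, 1000), 0), 900)
  expect_error(cross_entropy(c(Inf, 0), 0), "finite")

  set.seed(21)
  for (i in 1:200) {
    o <- rnorm(2, 0, 5)
    y <- sample(0:1, 1)
    expect_lt(abs(cross_entropy(o, y) + log(softmax_oracle(o)[y + 1])),
              1e-9)
  }
})

test_that("the SGD step moves against the gradient", {
  ctl <- train_control(learning_rate = 0.1)
  expect_equal(sgd_update(1, 2, ctl)$theta, 0.8)
  expect_equal(sgd_update(c(1, 2), c(0, 0), ctl)$theta, c(1, 2))
  # minimizing J(theta) = theta^2 contracts by 0.8 per step
  th <- 1
  J <- th^2
  for (i in 1:10) {
    th <- sgd_update(th, 2 * th, ctl)$theta
    expect_lt(th^2, J)
    J <- th^2
  }
  expect_equal(th, 0.8^10, tolerance = 1e-12)

  # classical momentum accumulates velocity
  ctl9 <- train_control(learning_rate = 0.1, momentum = 0.9)
  s1 <- sgd_update(1, 1, ctl9)
  s2 <- sgd_update(s1$theta, 1, ctl9, velocity = s1$velocity)
  expect_equal(s1$theta, 0.9)
  expect_equal(s2$theta, 0.9 - 0.1 * (0.9 * 1 + 1))

  # nested parameter lists update leaf-wise; shape mismatches are caught
  nest <- list(a = matrix(1, 2, 2), b = list(c = 1:3 * 1.0))
  gn <- list(a = matrix(1, 2, 2), b = list(c = rep(1, 3)))
  up <- sgd_update(nest, gn, ctl)
  expect_equal(up$theta$a, matrix(0.9, 2, 2))
  expect_equal(up$theta$b$c, 1:3 - 0.1)
  expect_error(sgd_update(nest, list(a = 1), ctl), "shape")
})

test_that("backpropagation matches finite-difference gradients", {
  set.seed(7)
  x <- matrix(runif(3 * 8, 0.4, 1.2), 3, 8)
  y <- c(0, 1, 1)
  for (case in list(c("se", "swish"), c("atac", "sine"), c("none", "relu"))) {
    cfg <- model_config(attention = case[1], activation = case[2],
                        channels = c(4L, 3L), input_length = 8L)
    m <- build_model(cfg, seed = 42)
    ga <- flat_grads(m, x, y)
    gn <- numeric_grads(m, x, y)
    expect_equal(length(ga), length(coef(m)))
    expect_equal(unname(ga), unname(gn), tolerance = 1e-4)
  }
})

test_that("fitting is reproducible and actually descends", {
  win <- toy_windows(100)
  cfg <- model_config(attention = "se")

  # zero epochs leave the initialized parameters untouched
  m0 <- build_model(cfg, seed = 3)
  f0 <- fit_model(m0, win, control = train_control(epochs = 0, seed = 3))
  expect_identical(coef(f0), coef(m0))

  ctl <- train_control(epochs = 2, batch_size = 50, momentum = 0.9, seed = 9)
  f1 <- af_cnn(win, config = cfg, control = ctl)
  f2 <- af_cnn(win, config = cfg, control = ctl)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$history$batch_loss, f2$history$batch_loss)
  expect_length(f1$history$batch_loss, 2 * 4)   # 200 windows / 50 per batch

  # mean epoch-1 loss improves on the loss of the frozen initialization,
  # measured under the identical minibatch order and dropout masks (a
  # vanishing learning rate keeps the parameters at their initial values)
  win_big <- toy_windows(200, seed = 31)
  for (seed in 1:5) {
    init <- build_model(cfg, seed = seed)
    frozen <- fit_model(init, win_big,
                        control = train_control(learning_rate = 1e-12,
                                                epochs = 1, batch_size = 50,
                                                seed = seed))
    fit1 <- fit_model(init, win_big,
                      control = train_control(epochs = 1, batch_size = 50,
                                              momentum = 0.9, seed = seed))
    expect_lt(mean(fit1$history$epoch_loss),
              mean(frozen$history$epoch_loss))
  }
})

test_that("k-fold partitions cover the data in near-equal disjoint folds", {
  win <- toy_windows(52)[1:103, ]      # odd size forces unequal folds
  ctl <- train_control(epochs = 1, batch_size = 50, seed = 2)
  cfg <- model_config(attention = "se", channels = c(6L, 4L))
  cv <- kfold_cv(cfg, ctl, win, k = 5, seed = 31)
  expect_length(cv$accuracy, 5)
  expect_identical(sort(as.integer(table(cv$folds)), decreasing = TRUE),
                   c(21L, 21L, 21L, 20L, 20L))
  expect_identical(length(cv$folds), 103L)
  expect_equal(cv$mean, mean(cv$accuracy))
  expect_true(all(cv$accuracy >= 0 & cv$accuracy <= 1))

  cv2 <- kfold_cv(cfg, ctl, toy_windows(5), k = 2, seed = 1)
  expect_identical(as.integer(table(cv2$folds)), c(5L, 5L))
  expect_error(kfold_cv(cfg, ctl, win, k = 1), "at least 2")
})
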