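test_that("length-preserving convolution matches the naive hand oracle", {
  # identity kernel
  expect_equal(conv1d_forward(c(3, -1, 2), 1), c(3, -1, 2))
  # hand-evaluated two-tap case with zero padding
  expect_equal(conv1d_forward(c(1, 2, 3), c(1, 1)), c(1, 3, 5))
  # bias-only with ReLU
  expect_equal(conv1d_forward(rep(0, 5), c(0.3, 0.3, 0.3), b = 2,
                              act = "relu"),
               rep(2, 5))
  set.seed(11)
  for (case in 1:25) {
    Cin <- sample(1:8, 1); Cout <- sample(1:8, 1)
    L <- sample(3:8, 1); M <- sample(1:min(8, L), 1)
    X <- matrix(rnorm(Cin * L), Cin, L)
    W <- array(rnorm(Cout * Cin * M), c(Cout, Cin, M))
    b <- rnorm(Cout)
    expect_equal(conv1d_forward(X, W, b), conv_oracle(X, W, b),
                 tolerance = 1e-12)
  }
  expect_error(conv1d_forward(matrix(1, 2, 5), array(1, c(1, 3, 2))),
               "channel")
})

test_that("activation kinds evaluate to their closed forms", {
  expect_equal(activation(c(-2, 3), "relu"), c(0, 3))
  expect_equal(activation(0, "swish"), 0)
  expect_equal(activation(0, "sine"), 0)
  expect_equal(activation(1, "swish"), 1 / (1 + exp(-1)), tolerance = 1e-9)
  expect_equal(activation(1, "swish"), 0.731059, tolerance = 1e-6)
  expect_equal(activation(pi / 2, "sine"), 1)
  expect_error(activation(1, "tanh"), "arg")
})

test_that("squeeze-excitation rescales each channel by one sigmoid scalar", {
  # zero weights -> every gate is sigmoid(0) = 0.5
  x <- matrix(rnorm(8), 2, 4)
  p0 <- list(W1 = matrix(0, 1, 2), b1 = 0, W2 = matrix(0, 2, 1),
             b2 = c(0, 0))
  expect_equal(se_forward(x, p0)$out, 0.5 * x)

  # hand-evaluated bottleneck
  p <- list(W1 = matrix(c(0.5, 0.5), 1, 2), b1 = 0,
            W2 = matrix(c(1, -1), 2, 1), b2 = c(0, 0))
  r <- se_forward(matrix(c(2, 0, 2, 4), 2, 2), p)
  expect_equal(r$s, c(0.88080, 0.11920), tolerance = 1e-5)
  expect_equal(r$out, matrix(c(2, 0, 2, 4), 2, 2) * r$s)

  # the per-channel ratio is constant wherever x is non-zero
  set.seed(3)
  x2 <- matrix(rnorm(30), 3, 10)
  pr <- list(W1 = matrix(rnorm(3), 1, 3), b1 = rnorm(1),
             W2 = matrix(rnorm(3), 3, 1), b2 = rnorm(3))
  rr <- se_forward(x2, pr)
  ratio <- rr$out / x2
  expect_equal(ratio, matrix(rr$s, 3, 10), tolerance = 1e-12)
  expect_true(all(rr$s > 0 & rr$s < 1))
  expect_error(se_forward(x2, p0), "shape")
})

test_that("attention-as-activation gates elementwise through the bottleneck", {
  x <- matrix(rnorm(12), 3, 4)
  p0 <- list(W1 = matrix(0, 1, 3), b1 = 0, W2 = matrix(0, 3, 1),
             b2 = rep(0, 3))
  expect_equal(atac_forward(x, p0)$out, 0.5 * x)

  # hand-evaluated scalar chain with identity normalization
  p1 <- list(W1 = matrix(1, 1, 1), b1 = 0, W2 = matrix(1, 1, 1), b2 = 0)
  r <- atac_forward(matrix(c(0, 2), 1, 2), p1)
  expect_equal(r$gate, matrix(c(0.5, 0.88080), 1, 2), tolerance = 1e-5)
  expect_equal(r$out, matrix(c(0, 1.76159), 1, 2), tolerance = 1e-5)

  # gate in (0,1): output never exceeds the input in magnitude
  set.seed(4)
  x2 <- matrix(rnorm(40), 4, 10)
  pr <- list(W1 = matrix(rnorm(4), 1, 4), b1 = rnorm(1),
             W2 = matrix(rnorm(4), 4, 1), b2 = rnorm(4))
  rr <- atac_forward(x2, pr)
  expect_true(all(rr$gate > 0 & rr$gate < 1))
  expect_true(all(abs(rr$out) <= abs(x2)))
  expect_identical(dim(rr$out), dim(x2))
})

test_that("built models are deterministic and produce probability outputs", {
  cfg <- model_config(attention = "se")
  m1 <- build_model(cfg, seed = 77)
  m2 <- build_model(cfg, seed = 77)
  expect_identical(coef(m1), coef(m2))
  expect_false(identical(coef(m1), coef(build_model(cfg, seed = 78))))

  set.seed(5)
  x <- matrix(runif(5 * 30, 0.4, 1.3), 5, 30)
  for (att in c("none", "se", "atac")) {
    m <- build_model(model_config(attention = att), seed = 1)
    P <- predict(m, x, type = "prob")
    expect_true(all(P >= 0 & P <= 1))
    expect_equal(unname(rowSums(P)), rep(1, 5), tolerance = 1e-12)
  }
})

test_that("the compressed forward pass traces the expected shapes", {
  m <- build_model(model_config(attention = "se"), seed = 1)
  fw <- afcnn:::nn_forward(m$layers, afcnn:::.as_input(matrix(0.8, 1, 30)))
  types <- vapply(m$layers, `[[`, "", "type")
  dims <- lapply(fw$acts[-1], dim)
  expect_identical(dims[[which(types == "conv")[1]]], c(20L, 30L, 1L))
  expect_identical(dims[[which(types == "conv")[2]]], c(10L, 30L, 1L))
  expect_identical(dims[[which(types == "se")]], c(10L, 30L, 1L))
  expect_identical(dims[[which(types == "pool")]], c(10L, 15L, 1L))
  expect_identical(dims[[which(types == "conv")[3]]], c(5L, 15L, 1L))
  expect_identical(dim(fw$logits), c(2L, 1L))
})

test_that("parameter counts match the closed-form per-layer sums", {
  base <- count_learnables(model_config("baseline", attention = "none"))
  # 1->60, 60->40, 40->20, 20->10 convs + BN pairs + FC(150 -> 2)
  expect_identical(base$exact,
                   (1L * 5L * 60L + 60L) + 2L * 60L +
                   (60L * 5L * 40L + 40L) + 2L * 40L +
                   (40L * 5L * 20L + 20L) + 2L * 20L +
                   (20L * 5L * 10L + 10L) + 2L * 10L +
                   (150L * 2L + 2L))
  expect_identical(base$exact, 17992L)
  expect_identical(base$truncated, 17900L)

  se <- count_learnables(model_config(attention = "se"))
  backbone <- (1L * 5L * 20L + 20L) + 2L * 20L +
    (20L * 5L * 10L + 10L) + 2L * 10L +
    (10L * 5L * 5L + 5L) + 2L * 5L + (75L * 2L + 2L)
  expect_identical(backbone, 1607L)
  expect_identical(se$exact, backbone + (10L * 3L + 3L) + (3L * 10L + 10L))
  expect_identical(se$exact, 1680L)
  expect_identical(se$truncated, 1600L)

  atac <- count_learnables(model_config(attention = "atac"))
  expect_identical(atac$exact,
                   backbone + (10L * 3L + 3L) + 2L * 3L +
                     (3L * 10L + 10L) + 2L * 10L)
  expect_identical(atac$exact, 1706L)
  expect_identical(atac$truncated, 1700L)
})

test_that("counted learnables equal the parameters a built model carries", {
  cfgs <- list(
    model_config("baseline", attention = "none"),
    model_config(attention = "se"),
    model_config(attention = "atac"),
    model_config(attention = "se", attention_layer = 1),
    model_config(attention = "atac", channels = c(8L, 6L, 4L),
                 reduction_ratio = 2, input_length = 20))
  for (cfg in cfgs) {
    m <- build_model(cfg, seed = 2)
    expect_identical(length(coef(m)), as.integer(count_learnables(cfg)$exact))
  }
})

test_that("compression keeps under a tenth of the baseline budget", {
  base <- count_learnables(model_config("baseline", attention = "none"))$exact
  for (att in c("none", "se", "atac")) {
    comp <- count_learnables(model_config(attention = att))$exact
    expect_lt(comp / base, 0.10)
  }
})
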