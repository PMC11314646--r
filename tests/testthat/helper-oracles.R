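# Independent oracles, kept deliberately naive.

# Hand evaluation of the neural convolution (x * w)[n] = sum_m x[n-m] w[M-1-m]
# over the full support, then the centred length-preserving slice.
conv_oracle_1d <- function(x, w) {
  L <- length(x); M <- length(w)
  full <- numeric(L + M - 1)
  for (n in 0:(L + M - 2)) {
    s <- 0
    for (m in 0:(M - 1)) {
      xi <- n - m
      if (xi >= 0 && xi < L) s <- s + x[xi + 1] * w[M - 1 - m + 1]
    }
    full[n + 1] <- s
  }
  start <- floor((M - 1) / 2)
  full[(start + 1):(start + L)]
}

# Multi-channel conv: sum the single-channel oracle over input channels.
conv_oracle <- function(X, W, b = rep(0, dim(W)[1])) {
  Cout <- dim(W)[1]; Cin <- dim(W)[2]
  out <- matrix(0, Cout, ncol(X))
  for (o in seq_len(Cout)) {
    for (c in seq_len(Cin))
      out[o, ] <- out[o, ] + conv_oracle_1d(X[c, ], W[o, c, ])
    out[o, ] <- out[o, ] + b[o]
  }
  out
}

softmax_oracle <- function(o) exp(o) / sum(exp(o))

# Brute-force recount of the four confusion metrics, in percent.
metrics_oracle <- function(pred, lab) {
  tp <- 0; fp <- 0; tn <- 0; fn <- 0
  for (i in seq_along(pred)) {
    if (lab[i] == 1) { if (pred[i] == 1) tp <- tp + 1 else fn <- fn + 1 }
    else { if (pred[i] == 1) fp <- fp + 1 else tn <- tn + 1 }
  }
  c(accuracy = 100 * (tp + tn) / (tp + fp + tn + fn),
    sensitivity = if (tp + fn == 0) NA else 100 * tp / (tp + fn),
    specificity = if (tn + fp == 0) NA else 100 * tn / (tn + fp),
    f1 = if (2 * tp + fp + fn == 0) NA else 100 * 2 * tp / (2 * tp + fp + fn))
}

# Small labeled window table without going through the generator.
toy_windows <- function(n_per_class, W = 30, seed = 1) {
  set.seed(seed)
  x0 <- matrix(0.85 + rnorm(n_per_class * W, 0, 0.02), n_per_class, W)
  x1 <- matrix(0.70 + rnorm(n_per_class * W, 0, 0.13), n_per_class, W)
  x <- pmax(rbind(x0, x1), 0.25)
  colnames(x) <- paste0("i", seq_len(W))
  cbind(data.frame(record_id = paste0("r", seq_len(2 * n_per_class)),
                   window_index = 1L,
                   label = rep(c(0L, 1L), each = n_per_class)),
        as.data.frame(x))
}

# Analytic-vs-numeric gradient comparison for a whole model on one batch.
flat_grads <- function(model, x, y) {
  X <- afcnn:::.as_input(x)
  fw <- afcnn:::nn_forward(model$layers, X, training = TRUE,
                           use_dropout = FALSE)
  lg <- afcnn:::.ce_loss_grad(fw$logits, y)
  bw <- afcnn:::nn_backward(fw$layers, fw, lg$dlogits)
  out <- c()
  for (i in seq_along(model$layers)) {
    g <- bw$grads[[i]]
    if (!is.null(g)) out <- c(out, unlist(g))
  }
  out
}

numeric_grads <- function(model, x, y, h = 1e-5) {
  X <- afcnn:::.as_input(x)
  theta <- afcnn:::model_get_flat(model)
  loss_at <- function(th) {
    mm <- afcnn:::model_set_flat(model, th)
    fw <- afcnn:::nn_forward(mm$layers, X, training = TRUE,
                             use_dropout = FALSE)
    afcnn:::.ce_loss_grad(fw$logits, y)$loss
  }
  vapply(seq_along(theta), function(i) {
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    (loss_at(tp) - loss_at(tm)) / (2 * h)
  }, numeric(1))
}
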