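# Architectures: baseline and compressed 1-D CNNs with pluggable channel
# attention (squeeze-excitation or attention-as-activation) and ReLU /
# Swish / sine activations.

#' Describe a CNN architecture
#'
#' The baseline network stacks four length-5 convolutions of 60/40/20/10
#' feature maps; the compressed network stacks three of 20/10/5 and may
#' carry one channel-attention module.  Every convolution uses
#' length-preserving ("same") zero padding and is followed by batch
#' normalization and the chosen activation; max-pooling (size 2, stride 2)
#' sits between the penultimate and final convolutions, and the final
#' convolution output is dropped out at 50% during training.  The head is
#' a 2-way fully connected layer with softmax.
#'
#' @param variant `"compressed"` (default) or `"baseline"`.
#' @param activation `"relu"`, `"swish"` or `"sine"`.
#' @param attention `"none"`, `"se"` or `"atac"`.  Attention modulates the
#'   output of one convolution layer only.
#' @param reduction_ratio Bottleneck reduction ratio `r` of the attention
#'   module (channel count shrinks to `floor(C / r)`); default 3.
#' @param attention_layer Index of the convolution layer whose output is
#'   modulated; default 2.
#' @param input_length Window length fed to the network; default 30.
#' @param channels Optional integer vector overriding the per-layer
#'   feature-map counts.
#' @param kernel Convolution filter length; default 5.
#' @param dropout Dropout rate on the final convolution layer; default
#'   0.5.
#' @return An object of class `af_cnn_config`.
#' @export
model_config <- function(variant = c("compressed", "baseline"),
                         activation = c("relu", "swish", "sine"),
                         attention = c("none", "se", "atac"),
                         reduction_ratio = 3L, attention_layer = 2L,
                         input_length = 30L, channels = NULL,
                         kernel = 5L, dropout = 0.5) {
  variant <- match.arg(variant)
  activation <- match.arg(activation)
  attention <- match.arg(attention)
  if (is.null(channels))
    channels <- if (variant == "baseline") c(60L, 40L, 20L, 10L)
                else c(20L, 10L, 5L)
  channels <- as.integer(channels)
  stopifnot(length(channels) >= 2, all(channels >= 1), kernel >= 1,
            reduction_ratio >= 1, input_length >= 4,
            input_length %% 2 == 0, dropout >= 0, dropout < 1)
  if (attention != "none" &&
      (attention_layer < 1 || attention_layer > length(channels)))
    stop("`attention_layer` must address an existing conv layer")
  cfg <- structure(list(variant = variant, activation = activation,
                        attention = attention,
                        reduction_ratio = as.integer(reduction_ratio),
                        attention_layer = as.integer(attention_layer),
                        input_length = as.integer(input_length),
                        channels = channels, kernel = as.integer(kernel),
                        pool_after = length(channels) - 1L,
                        dropout = dropout, n_classes = 2L),
                   class = "af_cnn_config")
  cfg
}

#' @export
print.af_cnn_config <- function(x, ...) {
  att <- if (x$attention == "none") "no attention"
         else sprintf("%s attention (r = %d) on conv layer %d",
                      toupper(x$attention), x$reduction_ratio,
                      x$attention_layer)
  cat(sprintf("<af_cnn_config> %s CNN: conv channels %s (kernel %d), %s activation, %s\n",
              x$variant, paste(x$channels, collapse = "/"), x$kernel,
              x$activation, att))
  invisible(x)
}

#' Activation functions
#'
#' `relu` is `max(0, x)`, `swish` is `x * sigmoid(x)` and `sine` is plain
#' `sin(x)` (no frequency scaling).
#'
#' @param x Numeric input (any shape).
#' @param kind `"relu"`, `"swish"` or `"sine"`.
#' @return Elementwise activation values, same shape as `x`.
#' @export
activation <- function(x, kind = c("relu", "swish", "sine")) {
  kind <- match.arg(kind)
  switch(kind,
         relu = pmax(x, 0),
         swish = x * sigmoid(x),
         sine = sin(x))
}

.activation_grad <- function(x, kind) {
  switch(kind,
         relu = (x > 0) + 0,
         swish = { s <- sigmoid(x); s * (1 + x * (1 - s)) },
         sine = cos(x))
}

# --- 1-D "same" convolution ------------------------------------------------
#
# out[o, n, s] = b[o] + sum_{c, j} W[o, c, j] * x[c, n + (j-1) - ctr, s]
# with ctr = ceiling((M - 1) / 2) and zeros outside 1..L.  Weight index j
# follows the neural-convolution orientation (kernel reversed relative to
# sliding correlation), so the hand formula
# (x * w)[n] = sum_m x[n - m] w[M - 1 - m] holds with centred padding.
.conv_taps <- function(L, M) {
  ctr <- ceiling((M - 1) / 2)
  lapply(seq_len(M), function(j) {
    p <- seq_len(L) + (j - 1L) - ctr
    ok <- p >= 1L & p <= L
    list(out_idx = seq_len(L)[ok], in_idx = p[ok])
  })
}

.conv_fwd <- function(X, W, b) {
  d <- dim(X); Cin <- d[1]; L <- d[2]; N <- d[3]
  Cout <- dim(W)[1]; M <- dim(W)[3]
  taps <- .conv_taps(L, M)
  out <- array(0, c(Cout, L, N))
  for (j in seq_len(M)) {
    tp <- taps[[j]]
    if (!length(tp$out_idx)) next
    Wj <- matrix(W[, , j], Cout, Cin)
    Xs <- X[, tp$in_idx, , drop = FALSE]
    dim(Xs) <- c(Cin, length(tp$in_idx) * N)
    contrib <- Wj %*% Xs
    dim(contrib) <- c(Cout, length(tp$out_idx), N)
    out[, tp$out_idx, ] <- out[, tp$out_idx, , drop = FALSE] + contrib
  }
  out + b    # b recycles along the channel (first) dimension
}

.conv_bwd <- function(dOut, X, W) {
  d <- dim(X); Cin <- d[1]; L <- d[2]; N <- d[3]
  Cout <- dim(W)[1]; M <- dim(W)[3]
  taps <- .conv_taps(L, M)
  dX <- array(0, dim(X))
  dW <- array(0, dim(W))
  for (j in seq_len(M)) {
    tp <- taps[[j]]
    if (!length(tp$out_idx)) next
    Wj <- matrix(W[, , j], Cout, Cin)
    dO <- dOut[, tp$out_idx, , drop = FALSE]
    dim(dO) <- c(Cout, length(tp$out_idx) * N)
    Xs <- X[, tp$in_idx, , drop = FALSE]
    dim(Xs) <- c(Cin, length(tp$in_idx) * N)
    dW[, , j] <- dO %*% t(Xs)
    back <- t(Wj) %*% dO
    dim(back) <- c(Cin, length(tp$in_idx), N)
    dX[, tp$in_idx, ] <- dX[, tp$in_idx, , drop = FALSE] + back
  }
  dOm <- dOut; dim(dOm) <- c(Cout, L * N)
  list(dX = dX, dW = dW, db = rowSums(dOm))
}

#' Length-preserving 1-D convolution with optional bias and activation
#'
#' Computes the neural convolution
#' \eqn{(x * w)[n] = \sum_m x[n-m]\, w[M-1-m]} with centred zero padding so
#' the output length equals the input length, then adds the bias and, if
#' requested, applies the activation (the single-neuron forward contract
#' of a convolution layer).
#'
#' @param x Numeric vector (single channel) or `C_in x L` matrix.
#' @param w Numeric vector of length `M` (single-in, single-out) or array
#'   of dim `c(C_out, C_in, M)`.
#' @param b Bias, length `C_out` (default 0).
#' @param act Optional activation kind (see [activation()]).
#' @return Vector (if `x` and `w` were vectors) or `C_out x L` matrix.
#' @export
conv1d_forward <- function(x, w, b = 0, act = NULL) {
  vec_in <- is.null(dim(x)) && is.null(dim(w))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (is.null(dim(w))) w <- array(w, c(1, 1, length(w)))
  if (length(dim(w)) != 3 || dim(w)[2] != nrow(x))
    stop("weight shape does not match input channel count")
  if (length(b) == 1) b <- rep(b, dim(w)[1])
  if (length(b) != dim(w)[1]) stop("bias length must equal C_out")
  X <- array(x, c(nrow(x), ncol(x), 1))
  out <- .conv_fwd(X, w, b)
  out <- matrix(out, dim(w)[1], ncol(x))
  if (!is.null(act)) out <- activation(out, act)
  if (vec_in) drop(out) else out
}

#' Squeeze-excitation channel attention, forward pass
#'
#' Squeezes each feature map to its global average `z_c`, passes `z`
#' through a two-layer bottleneck (`C -> floor(C/r) -> C`, ReLU then
#' sigmoid) and rescales each channel by the resulting scalar
#' `s_c \in (0, 1)`: `out[c, ] = s_c * x[c, ]`.
#'
#' @param x `C x L` feature-map matrix.
#' @param params List with `W1` (`H x C`), `b1`, `W2` (`C x H`), `b2`.
#' @return List with `out` (same shape as `x`) and `s` (per-channel
#'   gates).
#' @export
se_forward <- function(x, params) {
  x <- as.matrix(x)
  C <- nrow(x)
  W1 <- as.matrix(params$W1); W2 <- as.matrix(params$W2)
  if (ncol(W1) != C || nrow(W2) != C || nrow(W1) != ncol(W2))
    stop("SE parameter shapes do not match the channel count")
  z <- rowMeans(x)
  h <- pmax(drop(W1 %*% z) + (params$b1 %||% 0), 0)
  s <- sigmoid(drop(W2 %*% h) + (params$b2 %||% 0))
  list(out = x * s, s = s)
}

#' Attention-as-activation gating, forward pass
#'
#' Two point-wise (length-1) convolutions with batch normalization form a
#' channel bottleneck (`C -> floor(C/r) -> C`, ReLU between), and a
#' sigmoid turns the result into a gate in (0, 1) of the same shape as the
#' feature map; the output is the elementwise product gate * x.  Unlike
#' squeeze-excitation the gate varies across positions.
#'
#' @param x `C x L` feature-map matrix.
#' @param params List with `W1` (`H x C`), `b1`, `W2` (`C x H`), `b2`, and
#'   optional `bn1`, `bn2` (lists with `gamma`, `beta`, `mean`, `var`;
#'   identity normalization by default).
#' @return List with `out` and `gate` (both `C x L`).
#' @export
atac_forward <- function(x, params) {
  x <- as.matrix(x)
  C <- nrow(x)
  W1 <- as.matrix(params$W1); W2 <- as.matrix(params$W2)
  if (ncol(W1) != C || nrow(W2) != C || nrow(W1) != ncol(W2))
    stop("ATAC parameter shapes do not match the channel count")
  bn_apply <- function(v, bn) {
    if (is.null(bn)) return(v)
    g <- bn$gamma %||% 1; b <- bn$beta %||% 0
    m <- bn$mean %||% 0; s2 <- bn$var %||% 1
    g * (v - m) / sqrt(s2 + 1e-5) + b
  }
  v1 <- bn_apply(W1 %*% x + (params$b1 %||% 0), params$bn1)
  h <- pmax(v1, 0)
  v2 <- bn_apply(W2 %*% h + (params$b2 %||% 0), params$bn2)
  gate <- sigmoid(v2)
  list(out = gate * x, gate = gate)
}

# --- layer constructors and initialization ---------------------------------

.he_init <- function(dims, fan_in) array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)

.bn_layer <- function(C) list(type = "bn", gamma = rep(1, C), beta = rep(0, C),
                              rmean = rep(0, C), rvar = rep(1, C),
                              eps = 1e-5, momentum = 0.1)

.build_layers <- function(cfg) {
  layers <- list()
  Cin <- 1L
  nconv <- length(cfg$channels)
  for (i in seq_len(nconv)) {
    C <- cfg$channels[i]
    layers <- c(layers, list(
      list(type = "conv", W = .he_init(c(C, Cin, cfg$kernel), Cin * cfg$kernel),
           b = rep(0, C)),
      .bn_layer(C),
      list(type = "act", kind = cfg$activation)))
    if (cfg$attention != "none" && i == cfg$attention_layer) {
      H <- max(1L, C %/% cfg$reduction_ratio)
      if (cfg$attention == "se") {
        layers <- c(layers, list(list(
          type = "se",
          W1 = .he_init(c(H, C), C), b1 = rep(0, H),
          W2 = .he_init(c(C, H), H), b2 = rep(0, C))))
      } else {
        layers <- c(layers, list(list(
          type = "atac",
          W1 = .he_init(c(H, C), C), b1 = rep(0, H), bn1 = .bn_layer(H),
          W2 = .he_init(c(C, H), H), b2 = rep(0, C), bn2 = .bn_layer(C))))
      }
    }
    if (i == cfg$pool_after) layers <- c(layers, list(list(type = "pool")))
    if (i == nconv)
      layers <- c(layers, list(list(type = "dropout", p = cfg$dropout)))
    Cin <- C
  }
  L_out <- cfg$input_length %/% 2L
  n_in <- cfg$channels[nconv] * L_out
  layers <- c(layers, list(list(
    type = "fc", W = .he_init(c(cfg$n_classes, n_in), n_in),
    b = rep(0, cfg$n_classes))))
  layers
}

#' Build an (untrained) AF detection network
#'
#' Initializes all weights from `seed` (He-scaled normal draws; biases
#' zero, batch-norm scale 1 / offset 0 with identity running statistics).
#' The same seed and configuration always give bitwise-identical initial
#' parameters.
#'
#' @param config An [model_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `af_cnn` (untrained; see [af_cnn()] for the
#'   one-call fit interface).
#' @export
build_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "af_cnn_config"))
  layers <- with_seed(seed, .build_layers(config))
  structure(list(config = config, layers = layers, seed = as.integer(seed),
                 trained = FALSE, history = NULL, control = NULL),
            class = "af_cnn")
}

# --- parameter accounting ---------------------------------------------------

#' Count learnable parameters of an architecture
#'
#' Sums, in closed form, convolution weights and biases
#' (`C_in * M * C_out + C_out`), batch-norm scale/offset pairs (`2C`), the
#' fully connected head (`in * out + out`) and the attention module
#' (squeeze-excitation: two biased fully connected layers
#' `C -> floor(C/r) -> C`; attention-as-activation: two biased point-wise
#' convolutions plus their batch-norm pairs).  The truncated figure
#' rounds the exact count down to the nearest hundred, the convention
#' used when quoting model budgets.
#'
#' @param config An [model_config()].
#' @return List with `exact` and `truncated` integer counts.
#' @export
count_learnables <- function(config) {
  stopifnot(inherits(config, "af_cnn_config"))
  cfg <- config
  total <- 0L
  Cin <- 1L
  for (i in seq_along(cfg$channels)) {
    C <- cfg$channels[i]
    total <- total + (Cin * cfg$kernel * C + C) + 2L * C
    if (cfg$attention != "none" && i == cfg$attention_layer) {
      H <- max(1L, C %/% cfg$reduction_ratio)
      total <- total +
        if (cfg$attention == "se") (C * H + H) + (H * C + C)
        else (C * H + H) + 2L * H + (H * C + C) + 2L * C
    }
    Cin <- C
  }
  n_in <- cfg$channels[length(cfg$channels)] * (cfg$input_length %/% 2L)
  total <- total + n_in * cfg$n_classes + cfg$n_classes
  list(exact = as.integer(total),
       truncated = as.integer(100L * (total %/% 100L)))
}

# Trainable leaves of a layer, as a named list of arrays.
.layer_params <- function(layer) {
  switch(layer$type,
         conv = list(W = layer$W, b = layer$b),
         fc = list(W = layer$W, b = layer$b),
         bn = list(gamma = layer$gamma, beta = layer$beta),
         se = list(W1 = layer$W1, b1 = layer$b1,
                   W2 = layer$W2, b2 = layer$b2),
         atac = list(W1 = layer$W1, b1 = layer$b1,
                     bn1_gamma = layer$bn1$gamma, bn1_beta = layer$bn1$beta,
                     W2 = layer$W2, b2 = layer$b2,
                     bn2_gamma = layer$bn2$gamma, bn2_beta = layer$bn2$beta),
         NULL)
}

.set_layer_params <- function(layer, p) {
  for (nm in names(p)) {
    if (nm == "bn1_gamma") layer$bn1$gamma <- p[[nm]]
    else if (nm == "bn1_beta") layer$bn1$beta <- p[[nm]]
    else if (nm == "bn2_gamma") layer$bn2$gamma <- p[[nm]]
    else if (nm == "bn2_beta") layer$bn2$beta <- p[[nm]]
    else layer[[nm]] <- p[[nm]]
  }
  layer
}

# Flatten all trainable parameters into one named numeric vector.
model_param_vector <- function(model) {
  unlist(lapply(model$layers, .layer_params))
}
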