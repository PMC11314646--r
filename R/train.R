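# Cross-entropy loss, minibatch SGD and the model-fitting interface.

#' Training hyperparameters
#'
#' Defaults follow the reference training recipe for these networks:
#' initial learning rate 1e-4, minibatch size 100, 25 epochs, plain SGD.
#' `momentum` (classical momentum on the gradient) is available because
#' the original training environment's stochastic solver commonly applies
#' 0.9.
#'
#' @param learning_rate Step size eta (> 0).
#' @param batch_size Minibatch size n (>= 1); the last short minibatch of
#'   an epoch is used, not dropped.
#' @param epochs Number of passes over the training set (>= 0).
#' @param momentum Classical momentum coefficient in `[0, 1)`; default 0.
#' @param seed Integer seed governing shuffling and dropout; the same
#'   seed always reproduces the same fit.
#' @param shuffle Reshuffle the training windows every epoch.
#' @return An object of class `af_train_control`.
#' @export
train_control <- function(learning_rate = 1e-4, batch_size = 100L,
                          epochs = 25L, momentum = 0, seed = 1L,
                          shuffle = TRUE) {
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 0,
            momentum >= 0, momentum < 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), momentum = momentum,
                 seed = as.integer(seed), shuffle = isTRUE(shuffle)),
            class = "af_train_control")
}

#' Cross-entropy loss of a logit vector
#'
#' `-log softmax(o)[y]`, computed through log-sum-exp so it is stable for
#' arbitrarily large logits.
#'
#' @param o Finite numeric logit vector (one entry per class).
#' @param y 0-based true class index.
#' @return Non-negative loss in nats.
#' @export
cross_entropy <- function(o, y) {
  if (any(!is.finite(o))) stop("logits must be finite")
  stopifnot(length(y) == 1, y >= 0, y < length(o))
  logsumexp(o) - o[as.integer(y) + 1L]
}

#' One (momentum) SGD step
#'
#' Returns `theta - learning_rate * v` where
#' `v = momentum * velocity + grad`; with the default zero momentum this
#' is the plain update `theta - learning_rate * grad`.  `theta` and
#' `grad` may be numeric vectors/arrays or (nested) lists thereof; a new
#' value is returned, inputs are never modified in place.
#'
#' @param theta Current parameters.
#' @param grad Gradient, shaped like `theta`.
#' @param control An [train_control()].
#' @param velocity Previous velocity (same shape; defaults to zero).
#' @return List with updated `theta` and `velocity`.
#' @export
sgd_update <- function(theta, grad, control = train_control(),
                       velocity = NULL) {
  step <- function(th, g, v) {
    if (is.list(th)) {
      if (!is.list(g) || length(g) != length(th))
        stop("gradient shape does not match parameters")
      vs <- if (is.null(v)) vector("list", length(th)) else v
      out <- Map(step, th, g, vs)
      list(theta = lapply(out, `[[`, "theta"),
           velocity = lapply(out, `[[`, "velocity"))
    } else {
      if (length(g) != length(th))
        stop("gradient shape does not match parameters")
      v <- if (is.null(v)) g * 0 else v
      v <- control$momentum * v + g
      list(theta = th - control$learning_rate * v, velocity = v)
    }
  }
  step(theta, grad, velocity)
}

#' Fit a network to labeled windows
#'
#' Minibatch SGD on the mean cross-entropy: each epoch shuffles the
#' windows (seeded), sweeps them in minibatches, and applies one
#' (momentum) gradient step per minibatch.  Dropout is active only here;
#' batch-norm layers use batch statistics during fitting and their
#' running averages at prediction time.  The same seed, data and
#' configuration reproduce the fit exactly.
#'
#' @param model An untrained (or previously trained) `af_cnn` from
#'   [build_model()].
#' @param x Numeric matrix of windows (rows) or a window table data
#'   frame (then `y` is taken from its `label` column).
#' @param y 0/1 labels (1 = AF), when `x` is a matrix.
#' @param control An [train_control()].
#' @return The fitted `af_cnn`, with a `history` element holding
#'   per-minibatch and per-epoch mean losses.
#' @export
fit_model <- function(model, x, y = NULL, control = train_control()) {
  stopifnot(inherits(model, "af_cnn"))
  if (is.data.frame(x)) { xy <- windows_to_xy(x); x <- xy$x; y <- xy$y }
  x <- as.matrix(x)
  y <- as.integer(y)
  if (nrow(x) == 0) stop("no training windows")
  if (length(y) != nrow(x)) stop("`y` must have one label per window")
  if (ncol(x) != model$config$input_length)
    stop("window length does not match the model input length")
  layers <- model$layers
  n <- nrow(x)
  batch_losses <- numeric(0)
  epoch_losses <- numeric(0)
  velocity <- vector("list", length(layers))
  with_seed(control$seed, {
    for (ep in seq_len(control$epochs)) {
      ord <- if (control$shuffle) sample.int(n) else seq_len(n)
      ep_loss <- numeric(0)
      for (b0 in seq.int(1L, n, by = control$batch_size)) {
        idx <- ord[b0:min(b0 + control$batch_size - 1L, n)]
        Xb <- .as_input(x[idx, , drop = FALSE])
        fw <- nn_forward(layers, Xb, training = TRUE, use_dropout = TRUE)
        layers <- fw$layers
        lg <- .ce_loss_grad(fw$logits, y[idx])
        bw <- nn_backward(layers, fw, lg$dlogits)
        for (i in seq_along(layers)) {
          p <- .layer_params(layers[[i]])
          if (is.null(p) || is.null(bw$grads[[i]])) next
          up <- sgd_update(p, bw$grads[[i]], control, velocity[[i]])
          velocity[[i]] <- up$velocity
          layers[[i]] <- .set_layer_params(layers[[i]], up$theta)
        }
        ep_loss <- c(ep_loss, lg$loss)
      }
      batch_losses <- c(batch_losses, ep_loss)
      epoch_losses <- c(epoch_losses, mean(ep_loss))
    }
  })
  model$layers <- layers
  model$trained <- model$trained || control$epochs > 0
  model$control <- control
  model$history <- list(batch_loss = batch_losses,
                        epoch_loss = epoch_losses,
                        epochs = control$epochs)
  model
}

#' Fit a compressed attention CNN for AF detection
#'
#' The one-call modelling interface: builds the network described by
#' `config` (weights seeded from `control$seed`) and fits it to the
#' labeled windows with minibatch SGD.  Lower-level pieces are available
#' separately as [build_model()] and [fit_model()].
#'
#' @inheritParams fit_model
#' @param config An [model_config()].
#' @return An object of class `af_cnn` with `config`, `layers`,
#'   `history` and `control` elements; see [predict.af_cnn()].
#' @examples
#' win <- synth_windows(synth_config(n_windows = 40, seed = 7))
#' fit <- af_cnn(win, config = model_config(attention = "se"),
#'               control = train_control(epochs = 2, batch_size = 20))
#' table(predict(fit, win), win$label)
#' @export
af_cnn <- function(x, y = NULL, config = model_config(),
                   control = train_control()) {
  model <- build_model(config, seed = control$seed)
  fit_model(model, x, y, control)
}

#' Predict AF class or class probabilities
#'
#' @param object A fitted `af_cnn`.
#' @param newdata Matrix of windows (rows) or a window table.
#' @param type `"class"` for 0/1 labels (argmax of the softmax, i.e. a
#'   0.5 probability threshold) or `"prob"` for the two-column
#'   probability matrix.
#' @param ... Unused.
#' @return Integer vector of 0/1 predictions, or an `n x 2` matrix of
#'   probabilities with columns `non-AF` and `AF`.
#' @export
predict.af_cnn <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata)) newdata <- windows_to_xy(newdata)$x
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$config$input_length)
    stop("window length does not match the model input length")
  fw <- nn_forward(object$layers, .as_input(newdata), training = FALSE)
  P <- t(.softmax_cols(fw$logits))
  colnames(P) <- c("non-AF", "AF")
  if (type == "prob") P else as.integer(P[, 2] > P[, 1])
}

#' @export
print.af_cnn <- function(x, ...) {
  print(x$config)
  n <- count_learnables(x$config)
  cat(sprintf("  learnable parameters: %d (%s)\n", n$exact,
              if (x$trained) "trained" else "untrained"))
  if (!is.null(x$history) && length(x$history$epoch_loss))
    cat(sprintf("  final epoch mean cross-entropy: %.4f over %d epoch(s)\n",
                utils::tail(x$history$epoch_loss, 1), x$history$epochs))
  invisible(x)
}

#' @export
summary.af_cnn <- function(object, ...) {
  cnt <- count_learnables(object$config)
  types <- vapply(object$layers, `[[`, "", "type")
  per_layer <- vapply(object$layers, function(l) {
    p <- .layer_params(l)
    if (is.null(p)) 0L else as.integer(sum(lengths(p)))
  }, 0L)
  out <- list(config = object$config, trained = object$trained,
              parameters = cnt,
              layers = data.frame(type = types, params = per_layer),
              history = object$history)
  class(out) <- "summary.af_cnn"
  out
}

#' @export
print.summary.af_cnn <- function(x, ...) {
  print(x$config)
  cat(sprintf("  %d learnable parameters (%d truncated to hundreds)\n",
              x$parameters$exact, x$parameters$truncated))
  print(x$layers)
  invisible(x)
}

#' @export
coef.af_cnn <- function(object, ...) model_get_flat(object)

#' Plot the training loss history
#'
#' @param x A fitted `af_cnn`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.af_cnn <- function(x, ...) {
  h <- x$history
  if (is.null(h) || !length(h$batch_loss)) stop("model has no training history")
  graphics::plot(h$batch_loss, type = "l", col = "grey60",
                 xlab = "minibatch", ylab = "cross-entropy (nats)", ...)
  per_epoch <- length(h$batch_loss) / max(1, h$epochs)
  graphics::lines((seq_along(h$epoch_loss) - 0.5) * per_epoch, h$epoch_loss,
                  col = "red3", lwd = 2)
  invisible(x)
}

#' k-fold cross-validated accuracy
#'
#' Shuffles the windows with `seed`, partitions them into `k` folds whose
#' sizes differ by at most one, and trains a fresh model on each
#' complement, scoring accuracy on the held-out fold.
#'
#' @param config An [model_config()].
#' @param control An [train_control()]; fold `j` trains with seed
#'   `control$seed + j`.
#' @param windows A window table or matrix+label list.
#' @param k Number of folds (>= 2).
#' @param seed Seed for the fold partition.
#' @return List with `accuracy` (length-`k` vector), `mean`, and `folds`
#'   (the fold index of every window).
#' @export
kfold_cv <- function(config, control, windows, k = 5L, seed = 1L) {
  if (k < 2) stop("`k` must be at least 2")
  xy <- if (is.data.frame(windows)) windows_to_xy(windows) else windows
  n <- nrow(xy$x)
  if (n < k) stop("fewer windows than folds")
  ord <- with_seed(seed, sample.int(n))
  sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  fold_of <- integer(n)
  fold_of[ord] <- rep(seq_len(k), times = sizes)
  acc <- numeric(k)
  for (j in seq_len(k)) {
    tr <- fold_of != j
    ctl <- control
    ctl$seed <- control$seed + j
    fit <- af_cnn(xy$x[tr, , drop = FALSE], xy$y[tr], config, ctl)
    pred <- predict(fit, xy$x[!tr, , drop = FALSE])
    acc[j] <- mean(pred == xy$y[!tr])
  }
  list(accuracy = acc, mean = mean(acc), folds = fold_of)
}
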