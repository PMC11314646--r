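# 1-D Grad-CAM saliency over interval windows.

#' Grad-CAM saliency for one window
#'
#' Computes gradient-weighted class activation mapping over a chosen
#' convolution layer: the gradient of the target-class score (pre-softmax
#' logit) with respect to the layer's activation map is averaged over
#' positions to give one weight per channel; the rectified, weighted sum
#' of the maps is then linearly interpolated back to the window length
#' and max-normalized to `[0, 1]`.  An all-zero map stays all-zero
#' (the normalization guard never divides by zero).
#'
#' @param model A (trained or initialized) `af_cnn`.
#' @param window Numeric window (length `input_length`) or a one-row
#'   window table.
#' @param target_class 0 (non-AF) or 1 (AF); default 1.
#' @param layer Convolution-layer index whose feature maps are used;
#'   default the final convolution layer.
#' @return Object of class `saliency_trace`: list with `importance`
#'   (length `input_length`, values in `[0, 1]`), `target_class` and
#'   `layer`.
#' @export
grad_cam <- function(model, window, target_class = 1L, layer = NULL) {
  stopifnot(inherits(model, "af_cnn"))
  if (is.data.frame(window)) window <- windows_to_xy(window)$x[1, ]
  window <- as.numeric(window)
  W <- model$config$input_length
  if (length(window) != W) stop("window length does not match the model")
  if (!target_class %in% c(0, 1)) stop("`target_class` must be 0 or 1")
  types <- vapply(model$layers, `[[`, "", "type")
  conv_pos <- which(types == "conv")
  layer <- layer %||% length(conv_pos)
  if (layer < 1 || layer > length(conv_pos))
    stop("`layer` must index a convolution layer")
  # activation output of that conv block (conv -> bn -> act)
  act_idx <- conv_pos[layer] + 2L
  stopifnot(types[act_idx] == "act")
  fw <- nn_forward(model$layers, .as_input(matrix(window, 1)),
                   training = FALSE)
  A <- fw$acts[[act_idx + 1L]]
  C <- dim(A)[1]; Lf <- dim(A)[2]
  dlogits <- matrix(0, model$config$n_classes, 1)
  dlogits[as.integer(target_class) + 1L, 1] <- 1
  bw <- nn_backward(model$layers, fw, dlogits, upto = act_idx + 1L)
  grad <- bw$dacts[[act_idx + 1L]]
  alpha <- rowMeans(matrix(grad, C, Lf))
  cam <- pmax(colSums(matrix(A, C, Lf) * alpha), 0)
  imp <- if (Lf == W) cam
         else if (Lf == 1) rep(cam, W)
         else stats::approx(seq(1, W, length.out = Lf), cam, xout = seq_len(W))$y
  m <- max(imp)
  if (m > 0) imp <- imp / m
  structure(list(importance = imp, target_class = as.integer(target_class),
                 layer = layer),
            class = "saliency_trace")
}

#' @export
print.saliency_trace <- function(x, ...) {
  cat(sprintf("<saliency_trace> class %d, conv layer %d; peak at beat %d\n",
              x$target_class, x$layer, which.max(x$importance)))
  invisible(x)
}

#' Plot a saliency trace against the window it explains
#'
#' @param x A `saliency_trace`.
#' @param window Optional window (intervals, seconds) drawn above the
#'   saliency.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.saliency_trace <- function(x, window = NULL, ...) {
  graphics::plot(x$importance, type = "h", ylim = c(0, 1),
                 xlab = "beat index", ylab = "saliency", ...)
  if (!is.null(window)) {
    w <- as.numeric(window)
    graphics::lines(seq_along(w), (w - min(w)) / max(1e-12, diff(range(w))),
                    col = "steelblue")
  }
  invisible(x)
}

#' First difference of a window's intervals
#'
#' The interval derivative trace used to compare saliency against local
#' rhythm changes: `out[i] = values[i + 1] - values[i]`.
#'
#' @param window Numeric window or one-row window table.
#' @return Numeric vector one shorter than the window.
#' @export
rr_derivative <- function(window) {
  if (is.data.frame(window)) window <- windows_to_xy(window)$x[1, ]
  diff(as.numeric(window))
}

#' Export a per-window saliency table
#'
#' @param model A fitted `af_cnn`.
#' @param window Numeric window or one-row window table.
#' @param target_class See [grad_cam()].
#' @return Data frame with columns `beat`, `saliency`, `rr`,
#'   `rr_derivative` (the derivative is `NA` at the last beat).
#' @export
saliency_table <- function(model, window, target_class = 1L) {
  if (is.data.frame(window)) window <- windows_to_xy(window)$x[1, ]
  window <- as.numeric(window)
  tr <- grad_cam(model, window, target_class)
  data.frame(beat = seq_along(window), saliency = tr$importance,
             rr = window, rr_derivative = c(rr_derivative(window), NA))
}
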