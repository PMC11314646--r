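# Single-file JSON checkpoints: architecture, training state and all
# parameter arrays, inspectable and diff-able.

.enc_node <- function(x) {
  if (is.numeric(x) || is.logical(x))
    list(kind = "array", dim = as.integer(dim(x) %||% length(x)),
         data = as.vector(as.numeric(x)))
  else if (is.character(x)) list(kind = "char", data = x)
  else if (is.list(x)) list(kind = "list", items = lapply(x, .enc_node))
  else stop("cannot serialize field of class ", class(x)[1])
}

.dec_node <- function(x) {
  kind <- x$kind
  if (kind == "array") {
    v <- as.numeric(unlist(x$data))
    d <- as.integer(unlist(x$dim))
    if (length(d) > 1) dim(v) <- d
    v
  } else if (kind == "char") {
    as.character(unlist(x$data))
  } else {
    lapply(x$items, .dec_node)
  }
}

#' Save or load a model checkpoint
#'
#' A checkpoint is one JSON file holding the configuration, the training
#' control and history, and every parameter array (including batch-norm
#' running statistics) at full precision, so a reloaded model reproduces
#' the original's predictions exactly.
#'
#' @param model A fitted or initialized `af_cnn`.
#' @param path Checkpoint file path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the reconstructed `af_cnn`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "af_cnn"))
  payload <- list(
    format = "afcnn-checkpoint-1",
    config = unclass(model$config),
    seed = model$seed,
    trained = model$trained,
    control = if (!is.null(model$control)) unclass(model$control),
    history = model$history,
    layers = lapply(model$layers, .enc_node))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(payload$format, "afcnn-checkpoint-1"))
    stop("not an afcnn checkpoint: ", path)
  cf <- payload$config
  config <- model_config(variant = cf$variant, activation = cf$activation,
                         attention = cf$attention,
                         reduction_ratio = cf$reduction_ratio,
                         attention_layer = cf$attention_layer,
                         input_length = cf$input_length,
                         channels = unlist(cf$channels),
                         kernel = cf$kernel, dropout = cf$dropout)
  layers <- lapply(payload$layers, .dec_node)
  # restore scalar types the JSON round trip flattened
  for (i in seq_along(layers)) {
    layers[[i]]$type <- as.character(layers[[i]]$type)
    if (!is.null(layers[[i]]$kind))
      layers[[i]]$kind <- as.character(layers[[i]]$kind)
  }
  control <- NULL
  if (!is.null(payload$control)) {
    pc <- payload$control
    control <- train_control(pc$learning_rate, pc$batch_size, pc$epochs,
                             pc$momentum, pc$seed, pc$shuffle)
  }
  history <- NULL
  if (!is.null(payload$history))
    history <- list(batch_loss = as.numeric(unlist(payload$history$batch_loss)),
                    epoch_loss = as.numeric(unlist(payload$history$epoch_loss)),
                    epochs = as.integer(payload$history$epochs %||% NA))
  structure(list(config = config, layers = layers,
                 seed = as.integer(payload$seed %||% NA),
                 trained = isTRUE(payload$trained),
                 history = history, control = control),
            class = "af_cnn")
}
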