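# Forward/backward engine for the 1-D CNNs.  Activations travel as
# (channels, positions, batch) arrays; the fully connected head flattens
# channel-fastest (column-major), matching count_learnables' bookkeeping.

.bn_fwd <- function(Xm, ly, training) {
  if (training) {
    mu <- rowMeans(Xm)
    xc <- Xm - mu
    v <- rowMeans(xc * xc)
    invstd <- 1 / sqrt(v + ly$eps)
    xhat <- xc * invstd
    ly$rmean <- (1 - ly$momentum) * ly$rmean + ly$momentum * mu
    ly$rvar <- (1 - ly$momentum) * ly$rvar + ly$momentum * v
    list(out = ly$gamma * xhat + ly$beta, ly = ly,
         cache = list(xhat = xhat, invstd = invstd, training = TRUE))
  } else {
    invstd <- 1 / sqrt(ly$rvar + ly$eps)
    xhat <- (Xm - ly$rmean) * invstd
    list(out = ly$gamma * xhat + ly$beta, ly = ly,
         cache = list(xhat = xhat, invstd = invstd, training = FALSE))
  }
}

.bn_bwd <- function(dY, cache, ly) {
  dgamma <- rowSums(dY * cache$xhat)
  dbeta <- rowSums(dY)
  dXhat <- dY * ly$gamma
  dX <- if (cache$training)
    cache$invstd * (dXhat - rowMeans(dXhat) -
                      cache$xhat * rowMeans(dXhat * cache$xhat))
  else dXhat * cache$invstd
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# broadcast a C x N per-channel/per-sample matrix over L positions
.bcast_CLN <- function(m, C, L, N) aperm(array(m, c(C, N, L)), c(1, 3, 2))
# collapse a (C, L, N) array over positions -> C x N
.sum_over_L <- function(A) {
  d <- dim(A)
  colSums(aperm(A, c(2, 1, 3)))
}

nn_forward <- function(layers, X, training = FALSE, use_dropout = FALSE,
                       from = 1L) {
  n_layers <- length(layers)
  caches <- vector("list", n_layers)
  acts <- vector("list", n_layers + 1L)
  for (i in seq.int(from, n_layers)) {
    ly <- layers[[i]]
    acts[[i]] <- X
    d <- dim(X)
    if (ly$type == "conv") {
      caches[[i]] <- list()
      X <- .conv_fwd(X, ly$W, ly$b)
    } else if (ly$type == "bn") {
      Xm <- X; dim(Xm) <- c(d[1], d[2] * d[3])
      r <- .bn_fwd(Xm, ly, training)
      layers[[i]] <- r$ly
      caches[[i]] <- r$cache
      out <- r$out; dim(out) <- d
      X <- out
    } else if (ly$type == "act") {
      caches[[i]] <- list()
      X <- activation(X, ly$kind)
    } else if (ly$type == "se") {
      C <- d[1]; L <- d[2]; N <- d[3]
      z <- .sum_over_L(X) / L                      # C x N
      v <- ly$W1 %*% z + ly$b1
      h <- pmax(v, 0)
      u <- ly$W2 %*% h + ly$b2
      s <- sigmoid(u)                              # C x N
      S <- .bcast_CLN(s, C, L, N)
      caches[[i]] <- list(z = z, v = v, h = h, s = s, S = S)
      X <- X * S
    } else if (ly$type == "atac") {
      C <- d[1]; K <- d[2] * d[3]
      Xm <- X; dim(Xm) <- c(C, K)
      v1 <- ly$W1 %*% Xm + ly$b1
      r1 <- .bn_fwd(v1, ly$bn1, training)
      layers[[i]]$bn1 <- r1$ly
      h <- pmax(r1$out, 0)
      v2 <- ly$W2 %*% h + ly$b2
      r2 <- .bn_fwd(v2, ly$bn2, training)
      layers[[i]]$bn2 <- r2$ly
      g <- sigmoid(r2$out)
      caches[[i]] <- list(Xm = Xm, n1 = r1$out, c1 = r1$cache, h = h,
                          c2 = r2$cache, g = g)
      out <- g * Xm; dim(out) <- d
      X <- out
    } else if (ly$type == "pool") {
      L <- d[2]
      odd <- seq.int(1L, L, 2L)
      x1 <- X[, odd, , drop = FALSE]
      x2 <- X[, odd + 1L, , drop = FALSE]
      take1 <- x1 >= x2
      caches[[i]] <- list(take1 = take1, dims = d)
      X <- pmax(x1, x2)
    } else if (ly$type == "dropout") {
      if (training && use_dropout && ly$p > 0) {
        mask <- (array(stats::runif(length(X)), d) >= ly$p) / (1 - ly$p)
        caches[[i]] <- list(mask = mask)
        X <- X * mask
      } else caches[[i]] <- list(mask = NULL)
    } else if (ly$type == "fc") {
      Fm <- X; dim(Fm) <- c(d[1] * d[2], d[3])
      caches[[i]] <- list(Fm = Fm, dims = d)
      X <- ly$W %*% Fm + ly$b
    } else stop("unknown layer type: ", ly$type)
  }
  acts[[n_layers + 1L]] <- X
  list(logits = X, caches = caches, acts = acts, layers = layers)
}

nn_backward <- function(layers, fw, dlogits, upto = 1L) {
  n_layers <- length(layers)
  grads <- vector("list", n_layers)
  dacts <- vector("list", n_layers + 1L)
  G <- dlogits
  for (i in rev(seq.int(upto, n_layers))) {
    ly <- layers[[i]]
    ca <- fw$caches[[i]]
    Xin <- fw$acts[[i]]
    dacts[[i + 1L]] <- G
    if (ly$type == "conv") {
      r <- .conv_bwd(G, Xin, ly$W)
      grads[[i]] <- list(W = r$dW, b = r$db)
      G <- r$dX
    } else if (ly$type == "bn") {
      d <- dim(Xin)
      Gm <- G; dim(Gm) <- c(d[1], d[2] * d[3])
      r <- .bn_bwd(Gm, ca, ly)
      grads[[i]] <- list(gamma = r$dgamma, beta = r$dbeta)
      dX <- r$dX; dim(dX) <- d
      G <- dX
    } else if (ly$type == "act") {
      G <- G * .activation_grad(Xin, ly$kind)
    } else if (ly$type == "se") {
      d <- dim(Xin); C <- d[1]; L <- d[2]; N <- d[3]
      ds <- .sum_over_L(G * Xin)                   # C x N
      du <- ds * ca$s * (1 - ca$s)
      dW2 <- du %*% t(ca$h); db2 <- rowSums(du)
      dh <- t(ly$W2) %*% du
      dv <- dh * (ca$v > 0)
      dW1 <- dv %*% t(ca$z); db1 <- rowSums(dv)
      dz <- t(ly$W1) %*% dv
      grads[[i]] <- list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
      G <- G * ca$S + .bcast_CLN(dz / L, C, L, N)
    } else if (ly$type == "atac") {
      d <- dim(Xin); C <- d[1]; K <- d[2] * d[3]
      Gm <- G; dim(Gm) <- c(C, K)
      dgate <- Gm * ca$Xm
      dn2 <- dgate * ca$g * (1 - ca$g)
      r2 <- .bn_bwd(dn2, ca$c2, ly$bn2)
      dW2 <- r2$dX %*% t(ca$h); db2 <- rowSums(r2$dX)
      dh <- t(ly$W2) %*% r2$dX
      dn1 <- dh * (ca$n1 > 0)
      r1 <- .bn_bwd(dn1, ca$c1, ly$bn1)
      dW1 <- r1$dX %*% t(ca$Xm); db1 <- rowSums(r1$dX)
      dXm <- t(ly$W1) %*% r1$dX + Gm * ca$g
      grads[[i]] <- list(W1 = dW1, b1 = db1,
                         bn1_gamma = r1$dgamma, bn1_beta = r1$dbeta,
                         W2 = dW2, b2 = db2,
                         bn2_gamma = r2$dgamma, bn2_beta = r2$dbeta)
      dim(dXm) <- d
      G <- dXm
    } else if (ly$type == "pool") {
      d <- ca$dims
      L <- d[2]
      odd <- seq.int(1L, L, 2L)
      dX <- array(0, d)
      dX[, odd, ] <- G * ca$take1
      dX[, odd + 1L, ] <- G * !ca$take1
      G <- dX
    } else if (ly$type == "dropout") {
      if (!is.null(ca$mask)) G <- G * ca$mask
    } else if (ly$type == "fc") {
      grads[[i]] <- list(W = G %*% t(ca$Fm), b = rowSums(G))
      dF <- t(ly$W) %*% G
      dim(dF) <- ca$dims
      G <- dF
    }
  }
  dacts[[upto]] <- G
  list(grads = grads, dacts = dacts)
}

.softmax_cols <- function(logits) {
  mx <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, mx))
  sweep(e, 2, colSums(e), "/")
}

# Mean cross-entropy over a batch of logits (n_classes x N) and 0-based
# class labels, plus the gradient w.r.t. the logits.
.ce_loss_grad <- function(logits, y) {
  N <- ncol(logits)
  P <- .softmax_cols(logits)
  idx <- cbind(as.integer(y) + 1L, seq_len(N))
  loss <- -mean(log(pmax(P[idx], 1e-300)))
  dP <- P
  dP[idx] <- dP[idx] - 1
  list(loss = loss, dlogits = dP / N)
}

# x matrix (N x L) -> network input array (1, L, N)
.as_input <- function(x) {
  x <- as.matrix(x)
  array(t(x), c(1L, ncol(x), nrow(x)))
}

# Vector view of all trainables, and its inverse (for gradient checks).
model_get_flat <- function(model) unlist(lapply(model$layers, .layer_params))

model_set_flat <- function(model, theta) {
  pos <- 1L
  for (i in seq_along(model$layers)) {
    p <- .layer_params(model$layers[[i]])
    if (is.null(p)) next
    for (nm in names(p)) {
      n <- length(p[[nm]])
      v <- theta[pos:(pos + n - 1L)]
      dim(v) <- dim(p[[nm]])
      p[[nm]] <- v
      pos <- pos + n
    }
    model$layers[[i]] <- .set_layer_params(model$layers[[i]], p)
  }
  stopifnot(pos - 1L == length(theta))
  model
}
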