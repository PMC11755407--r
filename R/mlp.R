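# Compact dense feed-forward network for binary classification: four hidden
# ReLU layers trained with Adam on binary cross-entropy, glorot-uniform
# initialization, sigmoid output.  Written in base R matrix code; adequate
# for descriptor matrices of a few thousand molecules.

glorot_uniform <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

mlp_fit <- function(x, y01, hidden = c(50, 50, 50, 50), epochs = 500L,
                    batch_size = 36L, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                    eps = 1e-8, seed = 1L, class_weights = NULL,
                    verbose = FALSE) {
  with_seed(seed, {
    n <- nrow(x); p <- ncol(x)
    sizes <- c(p, hidden, 1L)
    L <- length(sizes) - 1L
    W <- lapply(seq_len(L), function(l) glorot_uniform(sizes[l], sizes[l + 1L]))
    b <- lapply(seq_len(L), function(l) numeric(sizes[l + 1L]))
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(bb) bb * 0); vb <- mb
    if (is.null(class_weights)) class_weights <- c(`0` = 1, `1` = 1)
    wts <- ifelse(y01 == 1, class_weights[["1"]], class_weights[["0"]])
    t_step <- 0L
    losses <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      idx <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1L, n, by = batch_size)) {
        bi <- idx[start:min(start + batch_size - 1L, n)]
        xb <- x[bi, , drop = FALSE]
        yb <- y01[bi]; wb <- wts[bi]
        acts <- list(xb)
        for (l in seq_len(L)) {
          z <- sweep(acts[[l]] %*% W[[l]], 2L, b[[l]], "+")
          acts[[l + 1L]] <- if (l < L) pmax(z, 0) else 1 / (1 + exp(-z))
        }
        phat <- pmin(pmax(acts[[L + 1L]][, 1L], 1e-12), 1 - 1e-12)
        ep_loss <- ep_loss - sum(wb * (yb * log(phat) + (1 - yb) * log(1 - phat)))
        delta <- matrix((phat - yb) * wb / length(bi), ncol = 1L)
        t_step <- t_step + 1L
        for (l in rev(seq_len(L))) {
          gW <- crossprod(acts[[l]], delta)
          gb <- colSums(delta)
          if (l > 1L) {
            delta <- (delta %*% t(W[[l]])) * (acts[[l]] > 0)
          }
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
          cor1 <- 1 - beta1^t_step; cor2 <- 1 - beta2^t_step
          W[[l]] <- W[[l]] - lr * (mW[[l]] / cor1) / (sqrt(vW[[l]] / cor2) + eps)
          b[[l]] <- b[[l]] - lr * (mb[[l]] / cor1) / (sqrt(vb[[l]] / cor2) + eps)
        }
      }
      losses[ep] <- ep_loss / n
      if (verbose && ep %% 50L == 0L) {
        message(sprintf("epoch %d: loss %.5f", ep, losses[ep]))
      }
    }
    list(W = W, b = b, losses = losses, hidden = hidden)
  })
}

mlp_predict <- function(fit, x) {
  a <- x
  L <- length(fit$W)
  for (l in seq_len(L)) {
    z <- sweep(a %*% fit$W[[l]], 2L, fit$b[[l]], "+")
    a <- if (l < L) pmax(z, 0) else 1 / (1 + exp(-z))
  }
  a[, 1L]
}
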