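#' Train a feed-forward multilayer perceptron
#'
#' Compact binary MLP classifier used for topologies with two or more hidden
#' layers and for the deep fully-connected meta-classifier: tanh hidden
#' units, sigmoid output, binary cross-entropy loss, Adam optimizer,
#' glorot-normal weight initialization, optional inverted dropout on hidden
#' activations. Inputs are standardized internally. Deterministic given
#' `seed`.
#'
#' @param x numeric matrix / data.frame of predictors.
#' @param y 0/1 labels.
#' @param hidden integer vector of hidden layer sizes; `integer(0)` gives a
#'   plain logistic unit.
#' @param epochs passes over the data (default 50).
#' @param lr Adam learning rate (default 1e-3).
#' @param batchSize minibatch size (default 128, capped at n).
#' @param dropout dropout rate on hidden activations in \[0, 1) (default 0).
#' @param seed RNG seed for initialization and batching.
#' @return an object of class `"netnetMLP"`; use [mlpPredict()] for scores.
#' @export
mlpTrain <- function(x, y, hidden = integer(0), epochs = 50L, lr = 1e-3,
                     batchSize = 128L, dropout = 0, seed = NULL) {
  x <- as.matrix(x); storage.mode(x) <- "double"
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)), nrow(x) == length(y))
  if (!is.null(seed)) set.seed(seed)
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd); scl[scl == 0 | !is.finite(scl)] <- 1
  xs <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")
  sizes <- c(ncol(x), as.integer(hidden), 1L)
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    sdw <- sqrt(2 / (sizes[l] + sizes[l + 1L]))   # glorot-normal
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L], sd = sdw),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- rep(0, sizes[l + 1L])
  }
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(v) v * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t <- 0L
  n <- nrow(xs)
  batchSize <- min(as.integer(batchSize), n)
  sigm <- function(z) 1 / (1 + exp(-z))
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = batchSize)) {
      idx <- ord[start:min(start + batchSize - 1L, n)]
      a <- xs[idx, , drop = FALSE]
      acts <- vector("list", L + 1L); acts[[1L]] <- a
      masks <- vector("list", L)
      for (l in seq_len(L)) {
        z <- sweep(acts[[l]] %*% W[[l]], 2L, b[[l]], "+")
        if (l < L) {
          h <- tanh(z)
          if (dropout > 0) {
            msk <- matrix(stats::rbinom(length(h), 1L, 1 - dropout) /
                            (1 - dropout), nrow(h), ncol(h))
            h <- h * msk
            masks[[l]] <- msk
          }
          acts[[l + 1L]] <- h
        } else acts[[l + 1L]] <- sigm(z)
      }
      m <- length(idx)
      delta <- (acts[[L + 1L]] - y[idx]) / m    # dL/dz at the sigmoid output
      t <- t + 1L
      for (l in rev(seq_len(L))) {
        gW <- crossprod(acts[[l]], delta)
        gb <- colSums(delta)
        if (l > 1L) {
          delta <- delta %*% t(W[[l]])
          h <- acts[[l]]
          delta <- delta * (1 - h * h)          # tanh'
          if (dropout > 0 && !is.null(masks[[l - 1L]]))
            delta <- delta * masks[[l - 1L]]
        }
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        corr1 <- 1 - beta1^t; corr2 <- 1 - beta2^t
        W[[l]] <- W[[l]] - lr * (mW[[l]] / corr1) /
          (sqrt(vW[[l]] / corr2) + eps)
        b[[l]] <- b[[l]] - lr * (mb[[l]] / corr1) /
          (sqrt(vb[[l]] / corr2) + eps)
      }
    }
  }
  structure(list(W = W, b = b, center = ctr, scale = scl, sizes = sizes),
            class = "netnetMLP")
}

#' Predict scores from a trained MLP
#'
#' @param model a `"netnetMLP"` from [mlpTrain()].
#' @param x predictor matrix with the training columns.
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
mlpPredict <- function(model, x) {
  x <- as.matrix(x); storage.mode(x) <- "double"
  a <- sweep(sweep(x, 2L, model$center), 2L, model$scale, "/")
  L <- length(model$W)
  for (l in seq_len(L)) {
    z <- sweep(a %*% model$W[[l]], 2L, model$b[[l]], "+")
    a <- if (l < L) tanh(z) else 1 / (1 + exp(-z))
  }
  as.numeric(a)
}
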