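# Compact fully-connected binary classifier used by the echo-classification
# ensemble: 483 -> 105 (ReLU) -> dropout 0.5 -> 50 (ReLU) -> 6 (ReLU) -> 1
# (sigmoid), trained with binary cross-entropy and Adam. Written directly
# on base-R matrix algebra; the network is small enough (~56k weights) that
# this trains in seconds.

mlp_init <- function(sizes = c(483, 105, 50, 6, 1), seed = 1L) {
  with_seed(seed, {
    layers <- lapply(seq_len(length(sizes) - 1), function(i) {
      fan_in <- sizes[i]
      list(W = matrix(stats::rnorm(sizes[i] * sizes[i + 1],
                                   sd = sqrt(2 / fan_in)),
                      sizes[i], sizes[i + 1]),
           b = numeric(sizes[i + 1]))
    })
    structure(list(layers = layers, sizes = sizes), class = "batsonar_mlp")
  })
}

relu <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

# Forward pass. `dropout` is the drop probability applied after layer 1
# (inverted dropout; only during training). Returns activations for
# backprop.
mlp_forward <- function(net, X, dropout = 0, masks = NULL) {
  L <- length(net$layers)
  acts <- vector("list", L + 1)
  acts[[1]] <- X
  drop_mask <- NULL
  for (i in seq_len(L)) {
    z <- sweep(acts[[i]] %*% net$layers[[i]]$W, 2, net$layers[[i]]$b, "+")
    a <- if (i == L) sigmoid(z) else relu(z)
    if (i == 1 && dropout > 0) {
      drop_mask <- matrix(stats::runif(length(a)) >= dropout,
                          nrow(a), ncol(a)) / (1 - dropout)
      a <- a * drop_mask
    }
    acts[[i + 1]] <- a
  }
  list(acts = acts, drop_mask = drop_mask)
}

mlp_predict <- function(net, X) {
  as.numeric(mlp_forward(net, X, dropout = 0)$acts[[length(net$layers) + 1]])
}

# One Adam update on a minibatch; binary cross-entropy loss.
mlp_train <- function(net, X, y, epochs = 100, batch = 32, lr = 1e-3,
                      dropout = 0.5, seed = 1L) {
  L <- length(net$layers)
  mW <- lapply(net$layers, function(l) l$W * 0)
  vW <- mW
  mb <- lapply(net$layers, function(l) l$b * 0)
  vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t_step <- 0
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      idx <- sample(nrow(X))
      for (start in seq(1, nrow(X), by = batch)) {
        ii <- idx[start:min(start + batch - 1, nrow(X))]
        Xi <- X[ii, , drop = FALSE]
        yi <- y[ii]
        fw <- mlp_forward(net, Xi, dropout = dropout)
        acts <- fw$acts
        # output delta for sigmoid + BCE
        delta <- (acts[[L + 1]] - yi) / length(ii)
        t_step <- t_step + 1
        for (i in L:1) {
          gW <- crossprod(acts[[i]], delta)
          gb <- colSums(delta)
          if (i > 1) {
            delta <- delta %*% t(net$layers[[i]]$W)
            delta <- delta * (acts[[i]] > 0)
            if (i - 1 == 1 && !is.null(fw$drop_mask)) {
              # gradient flows through the dropout scaling
              delta <- delta * (fw$drop_mask > 0) / (1 - dropout)
            }
          }
          mW[[i]] <- beta1 * mW[[i]] + (1 - beta1) * gW
          vW[[i]] <- beta2 * vW[[i]] + (1 - beta2) * gW^2
          mb[[i]] <- beta1 * mb[[i]] + (1 - beta1) * gb
          vb[[i]] <- beta2 * vb[[i]] + (1 - beta2) * gb^2
          mhW <- mW[[i]] / (1 - beta1^t_step)
          vhW <- vW[[i]] / (1 - beta2^t_step)
          mhb <- mb[[i]] / (1 - beta1^t_step)
          vhb <- vb[[i]] / (1 - beta2^t_step)
          net$layers[[i]]$W <- net$layers[[i]]$W - lr * mhW / (sqrt(vhW) + eps)
          net$layers[[i]]$b <- net$layers[[i]]$b - lr * mhb / (sqrt(vhb) + eps)
        }
      }
    }
  })
  net
}
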