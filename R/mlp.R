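# Compact multilayer perceptron (two hidden layers, ReLU, softmax output),
# trained full-batch with Adam on a weighted cross-entropy. Kept deliberately
# small: the pixel-classification problems here have tens of features and a
# few classes, where a light fully-connected net is sufficient.

mlp_init <- function(n_in, hidden, n_out) {
  sizes <- c(n_in, hidden, n_out)
  w <- list()
  for (l in seq_len(length(sizes) - 1)) {
    fan_in <- sizes[l]
    w[[paste0("W", l)]] <- matrix(rnorm(fan_in * sizes[l + 1],
                                        sd = sqrt(2 / fan_in)),
                                  fan_in, sizes[l + 1])
    w[[paste0("b", l)]] <- matrix(0, 1, sizes[l + 1])
  }
  w
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

mlp_forward <- function(weights, X) {
  n_layers <- length(weights) / 2
  a <- X
  acts <- list(a)
  for (l in seq_len(n_layers)) {
    z <- a %*% weights[[paste0("W", l)]] +
      matrix(weights[[paste0("b", l)]], nrow(a), ncol(weights[[paste0("b", l)]]),
             byrow = TRUE)
    a <- if (l < n_layers) pmax(z, 0) else z
    acts[[l + 1]] <- a
  }
  list(p = softmax_rows(acts[[n_layers + 1]]), acts = acts)
}

mlp_predict <- function(weights, X) mlp_forward(weights, X)$p

# y: integer class indices 1..K; w: per-sample weights.
mlp_train <- function(X, y, w, hidden = c(100, 50), n_classes = 3L,
                      maxit = 250L, lr = 0.01, tol = 1e-8, seed = NULL) {
  with_seed(seed, {
    n <- nrow(X)
    w <- w / sum(w)
    Y <- matrix(0, n, n_classes); Y[cbind(seq_len(n), y)] <- 1
    weights <- mlp_init(ncol(X), hidden, n_classes)
    n_layers <- length(weights) / 2
    m_adam <- lapply(weights, function(x) x * 0)
    v_adam <- lapply(weights, function(x) x * 0)
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    last_loss <- Inf
    for (it in seq_len(maxit)) {
      fw <- mlp_forward(weights, X)
      p <- pmax(fw$p, 1e-12)
      loss <- -sum(w * rowSums(Y * log(p)))
      grads <- list()
      delta <- (fw$p - Y) * w            # d loss / d logits
      for (l in rev(seq_len(n_layers))) {
        a_prev <- fw$acts[[l]]
        grads[[paste0("W", l)]] <- crossprod(a_prev, delta)
        grads[[paste0("b", l)]] <- matrix(colSums(delta), 1)
        if (l > 1) {
          delta <- delta %*% t(weights[[paste0("W", l)]])
          delta[fw$acts[[l]] <= 0] <- 0   # ReLU gate
        }
      }
      for (nm in names(weights)) {
        g <- grads[[nm]]
        m_adam[[nm]] <- b1 * m_adam[[nm]] + (1 - b1) * g
        v_adam[[nm]] <- b2 * v_adam[[nm]] + (1 - b2) * g^2
        mh <- m_adam[[nm]] / (1 - b1^it)
        vh <- v_adam[[nm]] / (1 - b2^it)
        weights[[nm]] <- weights[[nm]] - lr * mh / (sqrt(vh) + eps)
      }
      if (abs(last_loss - loss) < tol * (abs(last_loss) + tol)) break
      last_loss <- loss
    }
    weights
  })
}
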