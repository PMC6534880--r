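## Minimal dense feed-forward classifier used for the DNN QSAR variant:
## ReLU hidden layers with inverted dropout, sigmoid output, binary
## cross-entropy, Adam.  Kept in R (matrix ops hit BLAS) because no
## deep-learning framework is available in the target environment and
## scikit-learn's MLP has no dropout.

.dnn_init <- function(n_in, hidden, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dims <- c(n_in, hidden, 1L)
  params <- list()
  for (l in seq_len(length(dims) - 1L)) {
    k <- sqrt(2 / dims[l])   # He initialization for ReLU stacks
    params[[paste0("W", l)]] <- matrix(stats::rnorm(dims[l] * dims[l + 1L],
                                                    sd = k),
                                       dims[l], dims[l + 1L])
    params[[paste0("b", l)]] <- matrix(0, 1L, dims[l + 1L])
  }
  params
}

.dnn_forward <- function(params, X, dropout = 0, train = FALSE) {
  nl <- length(params) / 2L
  acts <- list(X)
  masks <- vector("list", nl)
  a <- X
  for (l in seq_len(nl)) {
    z <- sweep(a %*% params[[paste0("W", l)]], 2,
               params[[paste0("b", l)]], "+")
    if (l < nl) {
      a <- pmax(z, 0)
      if (train && dropout > 0) {
        m <- matrix(stats::runif(length(a)) >= dropout, nrow(a)) / (1 - dropout)
        a <- a * m
        masks[[l]] <- m
      }
    } else {
      a <- 1 / (1 + exp(-z))
    }
    acts[[l + 1L]] <- a
  }
  list(acts = acts, masks = masks)
}

.dnn_backward <- function(params, fwd, y) {
  nl <- length(params) / 2L
  n <- length(y)
  grads <- list()
  # BCE + sigmoid: dL/dz_out = (p - y)/n
  delta <- (fwd$acts[[nl + 1L]] - matrix(y, ncol = 1)) / n
  for (l in rev(seq_len(nl))) {
    a_in <- fwd$acts[[l]]
    grads[[paste0("W", l)]] <- crossprod(a_in, delta)
    grads[[paste0("b", l)]] <- matrix(colSums(delta), 1L)
    if (l > 1L) {
      delta <- delta %*% t(params[[paste0("W", l)]])
      if (!is.null(fwd$masks[[l - 1L]])) delta <- delta * fwd$masks[[l - 1L]]
      delta <- delta * (fwd$acts[[l]] > 0)
    }
  }
  grads
}

.dnn_fit <- function(X, y, hidden = c(8000L, 4000L, 2000L), dropout = 0.2,
                     epochs = 100L, lr = 1e-3, batch_size = 128L,
                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  params <- .dnn_init(ncol(X), hidden)
  opt <- adam_init(params, lr = lr)
  n <- nrow(X)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (s in seq(1L, n, by = batch_size)) {
      idx <- ord[s:min(s + batch_size - 1L, n)]
      fwd <- .dnn_forward(params, X[idx, , drop = FALSE], dropout,
                          train = TRUE)
      grads <- .dnn_backward(params, fwd, y[idx])
      params <- adam_update(opt, params, grads)
    }
  }
  params
}

.dnn_predict <- function(params, X) {
  p <- .dnn_forward(params, X, train = FALSE)$acts
  as.numeric(p[[length(p)]])
}
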