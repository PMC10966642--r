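# Minimal 1-D convolutional network engine on BLAS matrix operations.
#
# Activations are stored as (B * L, C) matrices with sample-major rows
# (row = (b - 1) * L + l).  Convolutions are im2col gathers followed by one
# GEMM; transposed convolutions are the exact adjoint (scatter-add of one
# GEMM), so a stride-2 transposed convolution doubles the length that the
# matching stride-2 convolution halves.  Every layer has a hand-derived
# backward pass; gradients are verified against finite differences in the
# test suite.

.nn_cache <- new.env(parent = emptyenv())

# gather-index matrix (B*L_out, K) into rbind(0, X); 0 entries hit the zero row
.im2col_idx <- function(L_in, K, stride, pad, B) {
  key <- paste(L_in, K, stride, pad, B, sep = "/")
  hit <- .nn_cache[[key]]
  if (!is.null(hit)) return(hit)
  L_out <- (L_in + 2L * pad - K) %/% stride + 1L
  pos <- outer((seq_len(L_out) - 1L) * stride - pad, seq_len(K), `+`)  # L_out x K
  g <- matrix(0L, B * L_out, K)
  boff <- rep((seq_len(B) - 1L) * L_in, each = L_out)
  for (k in seq_len(K)) {
    p <- rep(pos[, k], B)
    ok <- p >= 1L & p <= L_in
    gk <- integer(B * L_out)
    gk[ok] <- p[ok] + boff[ok]
    g[, k] <- gk
  }
  out <- list(idx = g, L_out = L_out)
  .nn_cache[[key]] <- out
  out
}

# gather and scatter-add run in compiled code (src/engine.cpp)
.gather <- function(X, g) .cpp_gather(X, g)

.scatter_add <- function(U, g, n_rows, C) .cpp_scatter_add(U, g, n_rows, C)

.layer_conv <- function(c_in, c_out, K = 4L, stride = 2L, pad = 1L, init_sd = NULL) {
  if (is.null(init_sd)) init_sd <- sqrt(2 / (K * c_in))
  list(type = "conv", K = K, stride = stride, pad = pad,
       c_in = c_in, c_out = c_out,
       W = matrix(stats::rnorm(K * c_in * c_out, 0, init_sd), K * c_in, c_out),
       b = numeric(c_out))
}

.layer_tconv <- function(c_in, c_out, K = 4L, stride = 2L, pad = 1L, init_sd = NULL) {
  if (is.null(init_sd)) init_sd <- sqrt(2 / (K * c_in))
  # adjoint of a conv mapping L_out -> L_in; weight is (c_in, K * c_out)
  list(type = "tconv", K = K, stride = stride, pad = pad,
       c_in = c_in, c_out = c_out,
       W = matrix(stats::rnorm(c_in * K * c_out, 0, init_sd), c_in, K * c_out),
       b = numeric(c_out))
}

.layer_bnorm <- function(c) {
  list(type = "bnorm", c = c, gamma = rep(1, c), beta = numeric(c),
       run_mean = numeric(c), run_var = rep(1, c), momentum = 0.9, eps = 1e-5)
}

.conv_fwd <- function(layer, X, L_in, B) {
  ii <- .im2col_idx(L_in, layer$K, layer$stride, layer$pad, B)
  cols <- .gather(X, ii$idx)
  Y <- cols %*% layer$W
  Y <- Y + rep(layer$b, each = nrow(Y))
  list(Y = Y, L_out = ii$L_out, cache = list(cols = cols, idx = ii$idx, L_in = L_in, B = B))
}

.conv_bwd <- function(layer, dY, cache) {
  dW <- crossprod(cache$cols, dY)
  db <- colSums(dY)
  dCols <- dY %*% t(layer$W)
  dX <- .scatter_add(dCols, cache$idx, cache$B * cache$L_in, layer$c_in)
  list(dX = dX, dW = dW, db = db)
}

.tconv_fwd <- function(layer, X, L_in, B) {
  L_out <- L_in * layer$stride   # adjoint geometry (exact for our K, pad)
  ii <- .im2col_idx(L_out, layer$K, layer$stride, layer$pad, B)
  stopifnot(ii$L_out == L_in)
  U <- X %*% layer$W
  Y <- .scatter_add(U, ii$idx, B * L_out, layer$c_out)
  Y <- Y + rep(layer$b, each = nrow(Y))
  list(Y = Y, L_out = L_out, cache = list(X = X, idx = ii$idx, L_out = L_out, B = B))
}

.tconv_bwd <- function(layer, dY, cache) {
  cols <- .gather(dY, cache$idx)
  dX <- cols %*% t(layer$W)
  dW <- crossprod(cache$X, cols)
  db <- colSums(dY)
  list(dX = dX, dW = dW, db = db)
}

.bnorm_fwd <- function(layer, X, training) {
  n <- nrow(X)
  if (training) {
    mu <- colMeans(X)
    xc <- X - rep(mu, each = n)
    va <- colMeans(xc * xc)
    layer$run_mean <- layer$momentum * layer$run_mean + (1 - layer$momentum) * mu
    layer$run_var  <- layer$momentum * layer$run_var  + (1 - layer$momentum) * va
  } else {
    mu <- layer$run_mean
    va <- layer$run_var
    xc <- X - rep(mu, each = n)
  }
  inv <- 1 / sqrt(va + layer$eps)
  xhat <- xc * rep(inv, each = n)
  Y <- xhat * rep(layer$gamma, each = n) + rep(layer$beta, each = n)
  list(Y = Y, layer = layer, cache = list(xhat = xhat, inv = inv))
}

.bnorm_bwd <- function(layer, dY, cache) {
  xhat <- cache$xhat
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  n <- nrow(dY)
  dxhat <- dY * rep(layer$gamma, each = n)
  dX <- (dxhat - rep(colMeans(dxhat), each = n) -
           xhat * rep(colMeans(dxhat * xhat), each = n)) * rep(cache$inv, each = n)
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

.lrelu_fwd <- function(X, slope) {
  pos <- X > 0
  list(Y = X * (slope + (1 - slope) * pos), cache = pos)
}
.lrelu_bwd <- function(dY, cache, slope) dY * (slope + (1 - slope) * cache)
.relu_fwd <- function(X) {
  pos <- X > 0
  list(Y = X * pos, cache = pos)
}
.relu_bwd <- function(dY, cache) dY * cache
.dropout_fwd <- function(X, rate, training) {
  if (!training || rate <= 0) return(list(Y = X, cache = NULL))
  keep <- 1 - rate
  m <- matrix((stats::runif(length(X)) < keep) / keep, nrow(X), ncol(X))
  list(Y = X * m, cache = m)
}
.dropout_bwd <- function(dY, cache) if (is.null(cache)) dY else dY * cache
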