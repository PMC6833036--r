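# Internal layer primitives. A batch is a 3-d array [width, channels, m];
# convolution/pooling kernels live in src/kernels.cpp, everything else is
# vectorized R. Batch norm operates on the (width x m, channels) matrix
# view of an array.

FILTER_WIDTH <- 16L

arr3 <- function(x) {
  if (is.matrix(x)) array(x, dim = c(nrow(x), 1L, ncol(x)))
  else if (is.array(x) && length(dim(x)) == 3L) x
  else abort("expected a [width, channels, m] array or [width, m] matrix")
}

# array [w, c, m] <-> matrix [w * m, c]
arr_to_cm <- function(A) {
  d <- dim(A)
  M <- aperm(A, c(1L, 3L, 2L))
  dim(M) <- c(d[1L] * d[3L], d[2L])
  M
}
cm_to_arr <- function(M, d) {
  dim(M) <- c(d[1L], d[3L], d[2L])
  aperm(M, c(1L, 3L, 2L))
}

bn_forward <- function(A, gamma, beta, running, momentum, eps, training) {
  d <- dim(A)
  X <- arr_to_cm(A)
  if (training) {
    mu <- colMeans(X)
    xc <- sweep(X, 2L, mu, "-")
    v <- colMeans(xc * xc)          # biased batch variance
    new_running <- list(mean = momentum * running$mean + (1 - momentum) * mu,
                        var = momentum * running$var + (1 - momentum) * v)
  } else {
    mu <- running$mean
    v <- running$var
    xc <- sweep(X, 2L, mu, "-")
    new_running <- running
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, invstd, "*")
  Y <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(Y = cm_to_arr(Y, d), running = new_running,
       cache = if (training) list(xhat = xhat, invstd = invstd, d = d))
}

bn_backward <- function(dY, gamma, cache) {
  dYm <- arr_to_cm(dY)
  xhat <- cache$xhat
  n <- nrow(dYm)
  dgamma <- colSums(dYm * xhat)
  dbeta <- colSums(dYm)
  dxhat <- sweep(dYm, 2L, gamma, "*")
  t1 <- colMeans(dxhat)
  t2 <- colMeans(dxhat * xhat)
  dX <- sweep(dxhat, 2L, t1, "-") - sweep(xhat, 2L, t2, "*")
  dX <- sweep(dX, 2L, cache$invstd, "*")
  list(dX = cm_to_arr(dX, cache$d), dgamma = dgamma, dbeta = dbeta)
}

# inverted dropout; mask drawn from the current RNG stream
dropout_forward <- function(A, rate) {
  mask <- array((runif(length(A)) >= rate) / (1 - rate), dim = dim(A))
  list(Y = A * mask, mask = mask)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}
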