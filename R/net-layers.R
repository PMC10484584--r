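# Layer primitives for the dilated temporal convolutional network.
#
# Feature maps are matrices (channels x time). Dilated 1-D convolutions are
# evaluated as sums of shifted matrix products, so all heavy lifting goes
# through BLAS; the backward passes mirror the forward algebra exactly.

# Y[, t] = X[, t + off], zero-padded outside the valid range
zshift <- function(X, off) {
  n <- ncol(X)
  if (off == 0) return(X)
  Z <- matrix(0, nrow(X), n)
  if (off > 0 && off < n) {
    Z[, 1:(n - off)] <- X[, (1 + off):n, drop = FALSE]
  } else if (off < 0 && -off < n) {
    Z[, (1 - off):n] <- X[, 1:(n + off), drop = FALSE]
  }
  Z
}

# conv parameters: list(W = list of K (Cout x Cin) matrices, b = Cout vector)
conv_init <- function(c_in, c_out, k, rng) {
  sdv <- sqrt(2 / (c_in * k))
  list(W = lapply(seq_len(k), function(i) {
    matrix(rng$rnorm(c_out * c_in, 0, sdv), c_out, c_in)
  }), b = rep(0, c_out))
}

conv_fwd <- function(X, p, dil) {
  k <- length(p$W)
  center <- (k + 1) / 2
  Y <- matrix(p$b, length(p$b), ncol(X))
  for (j in seq_len(k)) {
    off <- (j - center) * dil
    Y <- Y + p$W[[j]] %*% zshift(X, off)
  }
  Y
}

conv_bwd <- function(X, p, dil, dY) {
  k <- length(p$W)
  center <- (k + 1) / 2
  dX <- matrix(0, nrow(X), ncol(X))
  dW <- vector("list", k)
  for (j in seq_len(k)) {
    off <- (j - center) * dil
    dX <- dX + zshift(crossprod(p$W[[j]], dY), -off)
    dW[[j]] <- dY %*% t(zshift(X, off))
  }
  list(dX = dX, grad = list(W = dW, b = rowSums(dY)))
}

dense_init <- function(c_in, c_out, rng) {
  list(W = matrix(rng$rnorm(c_out * c_in, 0, sqrt(2 / c_in)), c_out, c_in),
       b = rep(0, c_out))
}

dense_fwd <- function(X, p) p$W %*% X + p$b

dense_bwd <- function(X, p, dY) {
  list(dX = crossprod(p$W, dY),
       grad = list(W = dY %*% t(X), b = rowSums(dY)))
}

maxpool_fwd <- function(X, pool) {
  if (pool == 1) return(list(Y = X, ridx = NULL, n_in = ncol(X)))
  n2 <- floor(ncol(X) / pool)
  X <- X[, seq_len(n2 * pool), drop = FALSE]
  Y <- X[, seq(1, n2 * pool, by = pool), drop = FALSE]
  ridx <- matrix(1L, nrow(X), n2)
  for (r in 2:pool) {
    Xr <- X[, seq(r, n2 * pool, by = pool), drop = FALSE]
    upd <- Xr > Y
    Y[upd] <- Xr[upd]
    ridx[upd] <- r
  }
  list(Y = Y, ridx = ridx, n_in = ncol(X))
}

maxpool_bwd <- function(cache_pool, pool, dY, n_orig) {
  if (pool == 1) return(dY)
  n2 <- ncol(dY)
  dX <- matrix(0, nrow(dY), n_orig)
  for (r in seq_len(pool)) {
    mask <- cache_pool$ridx == r
    tmp <- matrix(0, nrow(dY), n2)
    tmp[mask] <- dY[mask]
    dX[, seq(r, n2 * pool, by = pool)] <- tmp
  }
  dX
}

# residual convolutional block: stacked dilated convs (ReLU), a 1x1 dense
# combination, a residual connection (1x1 projection when widths differ),
# ReLU, then temporal max pooling
block_init <- function(c_in, c_out, dilations, kernel, rng) {
  convs <- vector("list", length(dilations))
  cin <- c_in
  for (j in seq_along(dilations)) {
    convs[[j]] <- conv_init(cin, c_out, kernel, rng)
    cin <- c_out
  }
  proj <- if (c_in != c_out) dense_init(c_in, c_out, rng) else NULL
  list(convs = convs, dense = dense_init(c_out, c_out, rng), proj = proj)
}

block_fwd <- function(X, p, dilations, pool) {
  H <- X
  conv_in <- vector("list", length(dilations))
  masks <- vector("list", length(dilations))
  for (j in seq_along(dilations)) {
    conv_in[[j]] <- H
    Z <- conv_fwd(H, p$convs[[j]], dilations[j])
    masks[[j]] <- Z > 0
    H <- Z * masks[[j]]
  }
  D <- dense_fwd(H, p$dense)
  R <- if (is.null(p$proj)) X else dense_fwd(X, p$proj)
  S <- D + R
  A <- S * (S > 0)
  pl <- maxpool_fwd(A, pool)
  list(Y = pl$Y,
       cache = list(X = X, conv_in = conv_in, masks = masks, H = H, S = S,
                    pool = pl))
}

block_bwd <- function(p, dilations, pool, cache, dY) {
  dA <- maxpool_bwd(cache$pool, pool, dY, ncol(cache$S))
  dS <- dA * (cache$S > 0)
  dd <- dense_bwd(cache$H, p$dense, dS)
  dH <- dd$dX
  grad <- list(dense = dd$grad, convs = vector("list", length(dilations)))
  if (is.null(p$proj)) {
    dX_res <- dS
    grad$proj <- NULL
  } else {
    dp <- dense_bwd(cache$X, p$proj, dS)
    dX_res <- dp$dX
    grad$proj <- dp$grad
  }
  for (j in rev(seq_along(dilations))) {
    dZ <- dH * cache$masks[[j]]
    cb <- conv_bwd(cache$conv_in[[j]], p$convs[[j]], dilations[j], dZ)
    grad$convs[[j]] <- cb$grad
    dH <- cb$dX
  }
  dH <- dH + dX_res
  list(dX = dH, grad = grad)
}

# ---- nested parameter-tree utilities (Adam lives on these) --------------

tree_map <- function(f, ...) {
  trees <- list(...)
  t1 <- trees[[1]]
  if (is.numeric(t1) || is.logical(t1)) return(do.call(f, trees))
  if (is.null(t1)) return(NULL)
  out <- vector("list", length(t1))
  names(out) <- names(t1)
  keys <- names(t1)
  by_name <- !is.null(keys) && all(nzchar(keys))
  for (i in seq_along(t1)) {
    key <- if (by_name) keys[i] else i
    out[[i]] <- do.call(tree_map, c(list(f), lapply(trees, `[[`, key)))
  }
  out
}

tree_zeros <- function(tree) tree_map(function(x) x * 0, tree)

tree_add <- function(a, b) tree_map(`+`, a, b)

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- tree_map(function(m, g) beta1 * m + (1 - beta1) * g,
                      state$m, grads)
  state$v <- tree_map(function(v, g) beta2 * v + (1 - beta2) * g^2,
                      state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- tree_map(function(p, m, v) {
    p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }, params, state$m, state$v)
  list(params = params, state = state)
}

adam_init <- function(params) {
  list(t = 0, m = tree_zeros(params), v = tree_zeros(params))
}
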