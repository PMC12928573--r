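# Minimal dense neural-network core: parameter trees, Glorot initialisation,
# multi-head attention, post-norm transformer layers, and AdamW. Every
# forward returns a cache; every backward consumes (upstream gradient, cache)
# and returns input gradients plus a gradient tree shaped like the parameter
# tree. Gradients are analytic and are validated against central finite
# differences in the test suite.

# --- parameter-tree utilities -----------------------------------------------

.tree_map <- function(f, tree) {
  if (is.list(tree)) return(lapply(tree, .tree_map, f = f))
  f(tree)
}

.tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    stopifnot(is.list(b), length(a) == length(b))
    out <- mapply(.tree_map2, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
    names(out) <- names(a)
    return(out)
  }
  f(a, b)
}

.tree_zeros_like <- function(tree) .tree_map(function(x) x * 0, tree)

.tree_add <- function(a, b) .tree_map2(`+`, a, b)

.tree_scale <- function(tree, s) .tree_map(function(x) x * s, tree)

# Leaf access by path (integer vector of [[ ]] indices), used by the
# finite-difference checks and the optimizer.
.tree_leaf_paths <- function(tree, prefix = integer(0)) {
  if (!is.list(tree)) return(list(prefix))
  out <- list()
  for (k in seq_along(tree)) {
    out <- c(out, .tree_leaf_paths(tree[[k]], c(prefix, k)))
  }
  out
}

.tree_get <- function(tree, path) {
  for (k in path) tree <- tree[[k]]
  tree
}

.tree_set <- function(tree, path, value) {
  if (length(path) == 1L) {
    tree[[path]] <- value
    return(tree)
  }
  tree[[path[1L]]] <- .tree_set(tree[[path[1L]]], path[-1L], value)
  tree
}

.glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

.relu <- function(x) x * (x > 0)

# Numerically stable row-wise softmax (max subtraction per row).
.softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# --- multi-head attention ----------------------------------------------------

#' @keywords internal
.mha_params <- function(d, d_out = d) {
  list(Wq = .glorot(d, d), Wk = .glorot(d, d), Wv = .glorot(d, d),
       Wo = .glorot(d, d_out))
}

# Scaled dot-product multi-head attention. Xq: nq x d queries, Xkv: nk x d
# keys/values. Heads are column blocks of width dk = d/h. No positional
# information is added here; token order carries no meaning for the graph
# view (set semantics).
.mha_forward <- function(Xq, Xkv, p, h) {
  d <- ncol(Xq)
  stopifnot(d %% h == 0L)
  dk <- d %/% h
  Q <- Xq %*% p$Wq
  K <- Xkv %*% p$Wk
  V <- Xkv %*% p$Wv
  nq <- nrow(Xq)
  O <- matrix(0, nq, d)
  A <- vector("list", h)
  for (i in seq_len(h)) {
    idx <- ((i - 1L) * dk + 1L):(i * dk)
    Ai <- .softmax_rows(Q[, idx, drop = FALSE] %*%
                          t(K[, idx, drop = FALSE]) / sqrt(dk))
    A[[i]] <- Ai
    O[, idx] <- Ai %*% V[, idx, drop = FALSE]
  }
  Y <- O %*% p$Wo
  list(Y = Y, cache = list(Xq = Xq, Xkv = Xkv, Q = Q, K = K, V = V,
                           A = A, O = O, h = h, dk = dk))
}

.mha_backward <- function(dY, cache, p) {
  h <- cache$h; dk <- cache$dk
  dO <- dY %*% t(p$Wo)
  dWo <- t(cache$O) %*% dY
  dQ <- matrix(0, nrow(cache$Q), ncol(cache$Q))
  dK <- matrix(0, nrow(cache$K), ncol(cache$K))
  dV <- matrix(0, nrow(cache$V), ncol(cache$V))
  for (i in seq_len(h)) {
    idx <- ((i - 1L) * dk + 1L):(i * dk)
    Ai <- cache$A[[i]]
    dOi <- dO[, idx, drop = FALSE]
    dAi <- dOi %*% t(cache$V[, idx, drop = FALSE])
    dV[, idx] <- t(Ai) %*% dOi
    dZ <- Ai * (dAi - rowSums(dAi * Ai))
    dZ <- dZ / sqrt(dk)
    dQ[, idx] <- dZ %*% cache$K[, idx, drop = FALSE]
    dK[, idx] <- t(dZ) %*% cache$Q[, idx, drop = FALSE]
  }
  list(dXq = dQ %*% t(p$Wq),
       dXkv = dK %*% t(p$Wk) + dV %*% t(p$Wv),
       grads = list(Wq = t(cache$Xq) %*% dQ,
                    Wk = t(cache$Xkv) %*% dK,
                    Wv = t(cache$Xkv) %*% dV,
                    Wo = dWo))
}

# --- layer normalization (row-wise) ------------------------------------------

.ln_params <- function(d) list(g = matrix(1, 1, d), b = matrix(0, 1, d))

.ln_forward <- function(X, p, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  Y <- sweep(xhat, 2L, p$g, `*`)
  Y <- sweep(Y, 2L, p$b, `+`)
  list(Y = Y, cache = list(xhat = xhat, inv = inv, g = p$g))
}

.ln_backward <- function(dY, cache) {
  xhat <- cache$xhat
  dxhat <- sweep(dY, 2L, cache$g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- cache$inv * (dxhat - m1 - xhat * m2)
  list(dX = dX,
       grads = list(g = matrix(colSums(dY * xhat), 1),
                    b = matrix(colSums(dY), 1)))
}

# --- transformer encoder layer (post-norm, as in the standard encoder block) --

.layer_params <- function(d, d_ff = 2L * d) {
  list(attn = .mha_params(d),
       ln1 = .ln_params(d),
       W1 = .glorot(d, d_ff), b1 = matrix(0, 1, d_ff),
       W2 = .glorot(d_ff, d), b2 = matrix(0, 1, d),
       ln2 = .ln_params(d))
}

.layer_forward <- function(X, p, h) {
  att <- .mha_forward(X, X, p$attn, h)
  r1 <- X + att$Y
  l1 <- .ln_forward(r1, p$ln1)
  pre <- sweep(l1$Y %*% p$W1, 2L, p$b1, `+`)
  hh <- .relu(pre)
  f <- sweep(hh %*% p$W2, 2L, p$b2, `+`)
  l2 <- .ln_forward(l1$Y + f, p$ln2)
  list(Y = l2$Y,
       cache = list(att = att$cache, l1 = l1$cache, l2 = l2$cache,
                    l1Y = l1$Y, pre = pre, hh = hh))
}

.layer_backward <- function(dY, cache, p) {
  b2g <- .ln_backward(dY, cache$l2)
  dr2 <- b2g$dX
  # feed-forward branch
  dhh <- dr2 %*% t(p$W2)
  dW2 <- t(cache$hh) %*% dr2
  db2 <- matrix(colSums(dr2), 1)
  dpre <- dhh * (cache$pre > 0)
  dW1 <- t(cache$l1Y) %*% dpre
  db1 <- matrix(colSums(dpre), 1)
  dl1 <- dr2 + dpre %*% t(p$W1)
  b1g <- .ln_backward(dl1, cache$l1)
  dr1 <- b1g$dX
  attg <- .mha_backward(dr1, cache$att, p$attn)
  dX <- dr1 + attg$dXq + attg$dXkv
  list(dX = dX,
       grads = list(attn = attg$grads, ln1 = b1g$grads,
                    W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
                    ln2 = b2g$grads))
}

.stack_forward <- function(X, layers, h) {
  caches <- vector("list", length(layers))
  for (l in seq_along(layers)) {
    st <- .layer_forward(X, layers[[l]], h)
    X <- st$Y
    caches[[l]] <- st$cache
  }
  list(Y = X, caches = caches)
}

.stack_backward <- function(dY, caches, layers) {
  grads <- vector("list", length(layers))
  for (l in rev(seq_along(layers))) {
    bk <- .layer_backward(dY, caches[[l]], layers[[l]])
    dY <- bk$dX
    grads[[l]] <- bk$grads
  }
  list(dX = dY, grads = grads)
}

# --- AdamW (decoupled weight decay) ------------------------------------------

.adamw_init <- function(params) {
  list(m = .tree_zeros_like(params), v = .tree_zeros_like(params), t = 0L)
}

.adamw_step <- function(params, grads, state, lr, weight_decay = 0,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- .tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                        state$m, grads)
  state$v <- .tree_map2(function(v, g) beta2 * v + (1 - beta2) * g * g,
                        state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  upd <- .tree_map2(function(m, v) (m / c1) / (sqrt(v / c2) + eps),
                    state$m, state$v)
  params <- .tree_map2(function(p, u) p - lr * u, params, upd)
  if (weight_decay > 0) {
    params <- .tree_map(function(p) p - lr * weight_decay * p, params)
  }
  list(params = params, state = state)
}

# Central finite-difference gradient of a scalar-valued function of a
# parameter tree, evaluated at a sample of coordinates per leaf. Used only by
# tests and diagnostics.
.fd_grad_check <- function(fn, params, analytic, n_coords = 4L,
                           h = 1e-6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paths <- .tree_leaf_paths(params)
  worst <- 0
  for (pt in paths) {
    leaf <- .tree_get(params, pt)
    aleaf <- .tree_get(analytic, pt)
    ncl <- length(leaf)
    coords <- if (ncl <= n_coords) seq_len(ncl) else sample.int(ncl, n_coords)
    for (ci in coords) {
      pp <- leaf; pp[ci] <- pp[ci] + h
      pm <- leaf; pm[ci] <- pm[ci] - h
      fp <- fn(.tree_set(params, pt, pp))
      fm <- fn(.tree_set(params, pt, pm))
      g_num <- (fp - fm) / (2 * h)
      g_ana <- aleaf[ci]
      rel <- abs(g_num - g_ana) / max(1, abs(g_num), abs(g_ana))
      if (rel > worst) worst <- rel
    }
  }
  worst
}
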