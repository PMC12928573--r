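# Analytic gradients of every block against central finite differences.
# Random projections turn matrix-valued outputs into scalars so the full
# Jacobian is probed along random directions.

fd_block <- function(fn, params, grads, seed = 1, tol = 1e-6) {
  worst <- crossddi:::.fd_grad_check(fn, params, grads, n_coords = 4, seed = seed)
  expect_lt(worst, tol)
}

test_that("layer-norm gradients are exact", {
  set.seed(21)
  X <- matrix(rnorm(15), 3, 5)
  P <- matrix(rnorm(15), 3, 5)           # random output projection
  p <- crossddi:::.ln_params(5)
  p$g <- p$g + rnorm(5) * 0.1
  fwd <- crossddi:::.ln_forward(X, p)
  bk <- crossddi:::.ln_backward(P, fwd$cache)
  fd_block(function(q) sum(crossddi:::.ln_forward(X, q)$Y * P), p, bk$grads)
  # input gradient via FD on X
  num <- X
  for (i in seq_along(X)) {
    Xp <- X; Xp[i] <- Xp[i] + 1e-6
    Xm <- X; Xm[i] <- Xm[i] - 1e-6
    num[i] <- (sum(crossddi:::.ln_forward(Xp, p)$Y * P) -
                 sum(crossddi:::.ln_forward(Xm, p)$Y * P)) / 2e-6
  }
  expect_lt(max(abs(num - bk$dX)), 1e-5)
})

test_that("attention and transformer-layer gradients are exact", {
  set.seed(22)
  d <- 8; h <- 2
  X <- matrix(rnorm(4 * d), 4, d)
  P <- matrix(rnorm(4 * d), 4, d)
  p <- crossddi:::.mha_params(d)
  fwd <- crossddi:::.mha_forward(X, X, p, h)
  bk <- crossddi:::.mha_backward(P, fwd$cache, p)
  fd_block(function(q) sum(crossddi:::.mha_forward(X, X, q, h)$Y * P),
           p, bk$grads)

  lp <- crossddi:::.layer_params(d)
  lf <- crossddi:::.layer_forward(X, lp, h)
  lb <- crossddi:::.layer_backward(P, lf$cache, lp)
  fd_block(function(q) sum(crossddi:::.layer_forward(X, q, h)$Y * P),
           lp, lb$grads, tol = 1e-5)
})

test_that("contrastive batch gradients are exact in both modes", {
  set.seed(23)
  Z <- matrix(rnorm(32), 4, 8)
  H <- matrix(rnorm(32), 4, 8)
  for (mode in c("pairwise_eq11", "batch")) {
    cfg <- contrastive_config(tau = 0.4, mode = mode)
    g <- crossddi:::.contrastive_batch_grad(Z, H, cfg)
    fd_block(function(q) crossddi:::.contrastive_batch_grad(q$Z, q$H, cfg)$loss,
             list(Z = Z, H = H), list(Z = g$dZ, H = g$dH))
  }
})

test_that("fusion and head gradients are exact", {
  set.seed(24)
  p <- cross_attention_params(8, d_f = 5, heads = 2)
  Z <- matrix(rnorm(24), 3); H <- matrix(rnorm(24), 3)
  P <- matrix(rnorm(15), 3, 5)
  fwd <- crossddi:::.fuse_all_forward(Z, H, p)
  bk <- crossddi:::.fuse_all_backward(P, fwd$cache, p)
  fd_block(function(q) {
    qq <- p; qq$attn <- q$attn; qq$Wf <- q$Wf; qq$bf <- q$bf
    sum(crossddi:::.fuse_all_forward(Z, H, qq)$Fm * P)
  }, list(attn = p$attn, Wf = p$Wf, bf = p$bf), bk$grads)
  fd_block(function(q) sum(crossddi:::.fuse_all_forward(q$Z, q$H, p)$Fm * P),
           list(Z = Z, H = H), list(Z = bk$dZ, H = bk$dH))

  hp <- prediction_head(5, hidden = 4)
  X <- matrix(rnorm(30), 6, 10)
  w <- rnorm(6)
  hf <- crossddi:::.head_forward(X, hp)
  hb <- crossddi:::.head_backward(w, hf$cache, hp)
  fd_block(function(q) sum(crossddi:::.head_forward(X, q)$logit * w),
           hp, hb$grads)
})

test_that("encoder gradients flow correctly through readout and embeddings", {
  set.seed(25)
  vocab <- build_token_vocab(tiny_drugs()$smiles)
  gp <- graph_encoder_params(12, 4, d = 8, heads = 2, layers = 2)
  spars <- seq_encoder_params(length(vocab), d = 8, heads = 2, layers = 2,
                              max_len = 64)
  feats <- lapply(
    brics_decompose(parse_smiles("CC(=O)Oc1ccccc1C(=O)O"))$pharmacophores,
    featurize_subgraph, vocab = feature_vocab())
  w <- rnorm(8)
  gf <- crossddi:::.graph_view_forward(feats, gp)
  gg <- crossddi:::.graph_view_backward(w, gf, gp)
  fd_block(function(q) {
    attributes(q) <- attributes(gp)
    sum(crossddi:::.graph_view_forward(feats, q)$z * w)
  }, unclass(gp), gg, tol = 1e-5)

  ids <- token_ids("CC(=O)Oc1ccccc1C(=O)O", vocab)
  sf <- crossddi:::.seq_view_forward(ids, spars)
  sg <- crossddi:::.seq_view_backward(w, sf, spars)
  fd_block(function(q) {
    attributes(q) <- attributes(spars)
    sum(crossddi:::.seq_view_forward(ids, q)$h * w)
  }, unclass(spars), sg, tol = 1e-5)
})
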