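# Method core: cosine similarity, contrastive loss, fusion, prediction head.

test_that("cosine similarity satisfies its defining identities", {
  v <- c(0.3, -1.2, 2)
  expect_equal(cosine_sim(v, v), 1)
  expect_equal(cosine_sim(v, -v), -1)
  expect_equal(cosine_sim(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_sim(2 * v, 7 * v), 1)
  expect_error(cosine_sim(c(0, 0), v[1:2]), "zero-norm")
  expect_error(cosine_sim(c(Inf, 1), c(1, 1)), "non-finite")
})

test_that("the pairwise contrastive loss reproduces the hand-derived values", {
  u <- c(1, 0)
  a <- list(z = u, h = u); b <- list(z = u, h = u)
  expect_equal(contrastive_loss_pair(a, b, contrastive_config(tau = 1)),
               log(2), tolerance = 1e-12)
  a2 <- list(z = c(1, 0), h = c(1, 0))
  b2 <- list(z = c(0, 1), h = c(0, 1))
  expect_equal(contrastive_loss_pair(a2, b2, contrastive_config(tau = 1)),
               log(2) - 1, tolerance = 1e-12)
  expect_equal(contrastive_loss_pair(a2, b2, contrastive_config(tau = 0.5)),
               log(2) - 2, tolerance = 1e-12)
  expect_error(contrastive_config(tau = 0), "positive")
})

test_that("the batch loss reduces to the printed pair loss and its mean", {
  set.seed(4)
  mk <- function(d) list(z = rnorm(d), h = rnorm(d))
  cfg <- contrastive_config(tau = 0.7)
  a <- mk(6); b <- mk(6); c_ <- mk(6)
  expect_equal(contrastive_loss_batch(list(a, b), cfg),
               contrastive_loss_pair(a, b, cfg), tolerance = 1e-12)
  want <- mean(c(contrastive_loss_pair(a, b, cfg),
                 contrastive_loss_pair(a, c_, cfg),
                 contrastive_loss_pair(b, c_, cfg)))
  expect_equal(contrastive_loss_batch(list(a, b, c_), cfg), want,
               tolerance = 1e-10)
  # A<->B symmetry and batch relabelling invariance
  expect_equal(contrastive_loss_pair(a, b, cfg),
               contrastive_loss_pair(b, a, cfg))
  expect_equal(contrastive_loss_batch(list(c_, a, b), cfg),
               contrastive_loss_batch(list(a, b, c_), cfg),
               tolerance = 1e-12)
  # NT-Xent-style mode agrees with the printed loss on two drugs
  cfgB <- contrastive_config(tau = 0.7, mode = "batch")
  expect_equal(contrastive_loss_batch(list(a, b), cfgB),
               contrastive_loss_pair(a, b, cfg), tolerance = 1e-12)
  expect_error(contrastive_loss_batch(list(a), cfg), "no negatives")
})

test_that("the loss is scale-invariant and monotone in positive similarity", {
  set.seed(9)
  cfg <- contrastive_config(tau = 0.5)
  for (r in 1:20) {
    a <- list(z = rnorm(8), h = rnorm(8))
    b <- list(z = rnorm(8), h = rnorm(8))
    base <- contrastive_loss_pair(a, b, cfg)
    a_s <- list(z = 3.7 * a$z, h = 0.2 * a$h)
    b_s <- list(z = 5 * b$z, h = 11 * b$h)
    expect_equal(contrastive_loss_pair(a_s, b_s, cfg), base, tolerance = 1e-6)
  }
  # raise sim(z_A, h_A) with the four cross-drug similarities pinned at 0:
  # A lives in the (e1, e2) plane, B in the (e3, e4) plane
  for (r in 1:100) {
    th <- sort(stats::runif(2, 0.1, 1.4))
    loss_at <- function(theta) {
      a <- list(z = c(1, 0, 0, 0), h = c(cos(theta), sin(theta), 0, 0))
      b <- list(z = c(0, 0, 1, 0), h = c(0, 0, cos(0.3), sin(0.3)))
      contrastive_loss_pair(a, b, contrastive_config(tau = 0.5))
    }
    expect_lt(loss_at(th[1]), loss_at(th[2]))  # smaller angle = higher sim
  }
})

test_that("cross-attention fusion passes the identity case and is deterministic", {
  d <- 4
  p <- cross_attention_params(d, d_f = d, heads = 1)
  p$attn$Wq <- diag(d); p$attn$Wk <- diag(d)
  p$attn$Wv <- diag(d); p$attn$Wo <- diag(d)
  p$Wf <- diag(d); p$bf <- matrix(0, 1, d)
  v <- c(0.4, -1, 2, 0.1)
  expect_equal(cross_attention_fuse(v, v, p), v, tolerance = 1e-12)

  set.seed(3)
  p2 <- cross_attention_params(6, d_f = 3, heads = 2)
  z <- rnorm(6); h <- rnorm(6)
  out <- cross_attention_fuse(z, h, p2)
  expect_length(out, 3L)
  expect_identical(out, cross_attention_fuse(z, h, p2))
  expect_error(cross_attention_fuse(z[1:3], h, p2), "expected two length-6")
})

test_that("vectorized fusion equals the per-drug path", {
  set.seed(13)
  p <- cross_attention_params(8, d_f = 5, heads = 2)
  Z <- matrix(rnorm(40), 5); H <- matrix(rnorm(40), 5)
  Fm <- crossddi:::.fuse_all_forward(Z, H, p)$Fm
  for (k in 1:5) {
    expect_equal(Fm[k, ], cross_attention_fuse(Z[k, ], H[k, ], p),
                 tolerance = 1e-12)
  }
})

test_that("the prediction head behaves like a sigmoid MLP", {
  set.seed(5)
  head <- prediction_head(4)
  head$W2 <- head$W2 * 0; head$b2 <- head$b2 * 0
  expect_equal(predict_interaction(rnorm(4), rnorm(4), head), 0.5)
  head2 <- prediction_head(4)
  for (r in 1:10) {
    y <- predict_interaction(rnorm(4), rnorm(4), head2)
    expect_gt(y, 0); expect_lt(y, 1)
  }
  expect_error(predict_interaction(c(1, NA, 1, 1), rnorm(4), head2),
               "non-finite")
  expect_error(prediction_head(4, lambda_cl = -1), "non-negative")
})

test_that("binary cross-entropy matches its closed forms", {
  expect_equal(supervised_loss(0.5, 1), log(2))
  expect_equal(supervised_loss(0.5, 0), log(2))
  expect_lt(supervised_loss(1 - 1e-9, 1), 1e-8)
  expect_equal(supervised_loss(c(0.5, 0.5), c(1, 0)), log(2))
  a <- supervised_loss(0.9, 1); b <- supervised_loss(0.2, 0)
  expect_equal(supervised_loss(c(0.9, 0.2), c(1, 0)), (a + b) / 2)
  expect_error(supervised_loss(1, 1), "strictly in")
  expect_silent(supervised_loss(1, 1, clamp = TRUE))
})

test_that("the combined objective follows its schedule", {
  expect_equal(total_objective(0.7, 0.3, lambda_cl = 0, schedule = "joint"), 0.7)
  expect_equal(total_objective(0.7, 0.3, lambda_cl = 1, schedule = "joint"), 1.0)
  expect_equal(total_objective(0.7, 0.3, schedule = "two_stage", phase = 1), 0.3)
  expect_equal(total_objective(0.7, 0.3, schedule = "two_stage", phase = 2), 0.7)
  expect_error(total_objective(0.7, 0.3, lambda_cl = -2, schedule = "joint"),
               "non-negative")
})
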