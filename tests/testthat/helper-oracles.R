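# Independent oracles and shared fixtures for the test suite. Every oracle
# is a deliberately naive implementation (nested loops, enumeration, scalar
# formulas) kept separate from the vectorized code paths it checks.

# Nested-loop scaled dot-product multi-head self-attention: literal
# per-element transcription of Q/K/V projection, row softmax, value mixing,
# head concatenation and output projection.
attention_loop_oracle <- function(X, Wq, Wk, Wv, Wo, h) {
  n <- nrow(X); d <- ncol(X); dk <- d %/% h
  O <- matrix(0, n, d)
  for (i in seq_len(h)) {
    idx <- ((i - 1) * dk + 1):(i * dk)
    Q <- X %*% Wq[, idx, drop = FALSE]
    K <- X %*% Wk[, idx, drop = FALSE]
    V <- X %*% Wv[, idx, drop = FALSE]
    for (q in seq_len(n)) {
      scores <- numeric(n)
      for (k in seq_len(n)) scores[k] <- sum(Q[q, ] * K[k, ]) / sqrt(dk)
      w <- exp(scores - max(scores))
      w <- w / sum(w)
      acc <- numeric(dk)
      for (k in seq_len(n)) acc <- acc + w[k] * V[k, ]
      O[q, idx] <- acc
    }
  }
  O %*% Wo
}

# Scalar, formula-literal cross-view contrastive loss for one drug pair.
eq11_scalar_oracle <- function(zA, hA, zB, hB, tau) {
  cs <- function(u, v) sum(u * v) / sqrt(sum(u * u) * sum(v * v))
  num <- exp(cs(zA, hA) / tau) + exp(cs(zB, hB) / tau)
  den <- exp(cs(zA, zB) / tau) + exp(cs(zA, hB) / tau) +
    exp(cs(hA, zB) / tau) + exp(cs(hA, hB) / tau)
  -log(num / den)
}

# O(n^2) pair-counting AUROC: fraction of (positive, negative) pairs where
# the positive outscores the negative, ties worth one half.
auroc_pair_oracle <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Exact two-sided Mann-Whitney p-value by full enumeration of group
# assignments (tie-free data only).
mw_exact_oracle <- function(x, y) {
  vals <- c(x, y)
  n1 <- length(x)
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- u_of(x, y)
  combs <- utils::combn(length(vals), n1)
  us <- apply(combs, 2, function(ix) u_of(vals[ix], vals[-ix]))
  pl <- mean(us <= u_obs + 1e-9)
  pg <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(pl, pg))
}

# Small reusable drug table (parsed fast, covers rings/aromatics/heteroatoms).
tiny_drugs <- function() {
  data.frame(
    drug_id = c("d1", "d2", "d3", "d4", "d5", "d6"),
    smiles = c("CCO", "CC(=O)Oc1ccccc1C(=O)O", "c1ccncc1CC", "CCOCC",
               "C1CCNCC1CC", "c1ccccc1OC"),
    stringsAsFactors = FALSE
  )
}

tiny_cfg <- function(...) {
  ddi_config(d = 8, graph = list(heads = 2, layers = 1),
             seq = list(heads = 2, layers = 1), fusion = list(d_f = 6),
             seed = 3, ...)
}
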