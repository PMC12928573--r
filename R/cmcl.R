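# Method core: cosine similarity, the cross-view contrastive loss, the
# cross-attention fusion of the two views, the sigmoid MLP prediction head,
# and the combined training objective.
#
# The pairwise contrastive loss is implemented exactly as printed: for drugs
# A and B the numerator holds the two positive (same-drug, cross-view) pairs
# and the denominator holds only the four cross-drug pairs -- the positive
# terms are NOT repeated in the denominator, unlike standard InfoNCE. An
# NT-Xent-style "batch" mode is available as a documented alternative and is
# never silently substituted.

#' Cosine similarity
#'
#' @param u,v Finite numeric vectors of equal length and positive norm.
#' @return `u . v / (|u| |v|)`, in `[-1, 1]`.
#' @export
cosine_sim <- function(u, v) {
  if (length(u) != length(v)) {
    stop("cosine_sim: vectors differ in length", call. = FALSE)
  }
  if (any(!is.finite(u)) || any(!is.finite(v))) {
    stop("cosine_sim: non-finite input", call. = FALSE)
  }
  nu <- sqrt(sum(u * u)); nv <- sqrt(sum(v * v))
  if (nu == 0 || nv == 0) {
    stop("cosine_sim: zero-norm vector has no direction", call. = FALSE)
  }
  sum(u * v) / (nu * nv)
}

#' Contrastive-loss configuration
#'
#' @param tau Temperature, strictly positive (default 0.5).
#' @param mode `"pairwise_eq11"` (the printed two-drug loss, averaged over
#'   all unordered in-batch drug pairs) or `"batch"` (NT-Xent-style pooled
#'   numerator/denominator; agrees with the printed loss on 2-drug batches).
#' @return A `contrastive_config` list.
#' @export
contrastive_config <- function(tau = 0.5, mode = c("pairwise_eq11", "batch")) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0) {
    stop("contrastive_config: tau must be a positive number", call. = FALSE)
  }
  structure(list(tau = tau, mode = match.arg(mode)),
            class = "contrastive_config")
}

#' Cross-view contrastive loss for one drug pair
#'
#' For drugs A and B with graph-view embeddings `z` and sequence-view
#' embeddings `h`, returns
#' `-log[(e^{s(zA,hA)/tau} + e^{s(zB,hB)/tau}) /
#'       (e^{s(zA,zB)/tau} + e^{s(zA,hB)/tau} + e^{s(hA,zB)/tau} + e^{s(hA,hB)/tau})]`
#' with `s` the cosine similarity. The value is finite and may be negative.
#'
#' @param a,b Lists with components `z` and `h` (the two view embeddings of
#'   one drug).
#' @param cfg A [contrastive_config()].
#' @return Scalar loss.
#' @export
contrastive_loss_pair <- function(a, b, cfg = contrastive_config()) {
  stopifnot(inherits(cfg, "contrastive_config"))
  tau <- cfg$tau
  num <- exp(cosine_sim(a$z, a$h) / tau) + exp(cosine_sim(b$z, b$h) / tau)
  den <- exp(cosine_sim(a$z, b$z) / tau) + exp(cosine_sim(a$z, b$h) / tau) +
    exp(cosine_sim(a$h, b$z) / tau) + exp(cosine_sim(a$h, b$h) / tau)
  -log(num / den)
}

# Row-normalize a matrix; rows must have positive norm.
.row_normalize <- function(X) {
  nrm <- sqrt(rowSums(X * X))
  if (any(nrm == 0)) {
    stop("contrastive loss: zero-norm embedding", call. = FALSE)
  }
  list(Xn = X / nrm, nrm = nrm)
}

# Vectorized batch contrastive loss with analytic gradients.
# Z, H: B x d matrices of the two views, row i = drug i.
# Returns list(loss, dZ, dH).
.contrastive_batch_grad <- function(Z, H, cfg) {
  B <- nrow(Z)
  if (B < 2L) {
    stop("contrastive loss: need at least 2 distinct drugs (no negatives exist)",
         call. = FALSE)
  }
  tau <- cfg$tau
  zn <- .row_normalize(Z); hn <- .row_normalize(H)
  Zn <- zn$Xn; Hn <- hn$Xn
  S_zh <- Zn %*% t(Hn)
  S_zz <- Zn %*% t(Zn)
  S_hh <- Hn %*% t(Hn)
  E_zh <- exp(S_zh / tau)
  E_zz <- exp(S_zz / tau)
  E_hh <- exp(S_hh / tau)
  pos <- diag(E_zh)                       # e^{s(z_i,h_i)/tau}
  D <- E_zz + E_zh + t(E_zh) + E_hh      # per-(i,j) denominator terms

  dS_zh <- matrix(0, B, B)
  dS_zz <- matrix(0, B, B)
  dS_hh <- matrix(0, B, B)

  if (cfg$mode == "pairwise_eq11") {
    P <- B * (B - 1L) / 2L
    loss <- 0
    for (i in seq_len(B - 1L)) {
      for (j in (i + 1L):B) {
        num <- pos[i] + pos[j]
        den <- D[i, j]
        loss <- loss + (-log(num / den)) / P
        cnum <- -1 / (tau * num * P)
        dS_zh[i, i] <- dS_zh[i, i] + cnum * pos[i]
        dS_zh[j, j] <- dS_zh[j, j] + cnum * pos[j]
        cden <- 1 / (tau * den * P)
        dS_zz[i, j] <- dS_zz[i, j] + cden * E_zz[i, j]
        dS_zh[i, j] <- dS_zh[i, j] + cden * E_zh[i, j]
        dS_zh[j, i] <- dS_zh[j, i] + cden * E_zh[j, i]
        dS_hh[i, j] <- dS_hh[i, j] + cden * E_hh[i, j]
      }
    }
  } else {
    # Pooled generalization: one ratio with all positives in the numerator
    # and all cross-drug view combinations in the denominator. Reduces to
    # the pairwise loss when B = 2.
    num <- sum(pos)
    off <- upper.tri(D)
    den <- sum(D[off])
    loss <- -log(num / den)
    diag(dS_zh) <- -pos / (tau * num)
    cden <- 1 / (tau * den)
    dS_zz[off] <- cden * E_zz[off]
    dS_hh[off] <- cden * E_hh[off]
    offdiag <- row(E_zh) != col(E_zh)   # both E_zh[i,j] and E_zh[j,i] appear
    dS_zh[offdiag] <- dS_zh[offdiag] + cden * E_zh[offdiag]
  }

  # Backprop through the similarity matrices into the normalized rows ...
  dZn <- dS_zh %*% Hn + (dS_zz + t(dS_zz)) %*% Zn
  dHn <- t(dS_zh) %*% Zn + (dS_hh + t(dS_hh)) %*% Hn
  # ... and through the row normalization x -> x / |x|.
  unnorm <- function(dXn, Xn, nrm) {
    (dXn - Xn * rowSums(dXn * Xn)) / nrm
  }
  list(loss = loss,
       dZ = unnorm(dZn, Zn, zn$nrm),
       dH = unnorm(dHn, Hn, hn$nrm))
}

#' Batch cross-view contrastive loss
#'
#' In mode `"pairwise_eq11"` (default), the mean of [contrastive_loss_pair()]
#' over all unordered drug pairs in the batch; in mode `"batch"`, a pooled
#' NT-Xent-style ratio with every drug's two views as the positives and all
#' cross-drug view combinations as negatives. The two modes coincide on
#' 2-drug batches.
#'
#' @param pairs List of drugs, each a list with `z` and `h` embeddings.
#' @param cfg A [contrastive_config()].
#' @return Scalar loss.
#' @export
contrastive_loss_batch <- function(pairs, cfg = contrastive_config()) {
  if (length(pairs) < 2L) {
    stop("contrastive_loss_batch: need >= 2 drugs (no negatives exist)",
         call. = FALSE)
  }
  Z <- do.call(rbind, lapply(pairs, function(p) as.numeric(p$z)))
  H <- do.call(rbind, lapply(pairs, function(p) as.numeric(p$h)))
  .contrastive_batch_grad(Z, H, cfg)$loss
}

# --- cross-attention fusion ---------------------------------------------------

#' Initialise cross-attention fusion parameters
#'
#' @param d View embedding width.
#' @param d_f Fused output width (default `d`).
#' @param heads Attention heads (default 1).
#' @return Parameter tree of class `cross_attention_params`.
#' @export
cross_attention_params <- function(d, d_f = d, heads = 1L) {
  if (d %% heads != 0L) {
    stop("cross_attention_params: heads must divide d", call. = FALSE)
  }
  p <- list(attn = .mha_params(d),
            Wf = .glorot(d, d_f),
            bf = matrix(0, 1, d_f))
  attr(p, "heads") <- heads
  attr(p, "d_f") <- d_f
  class(p) <- c("cross_attention_params", "list")
  p
}

# Forward with cache. z, h: length-d vectors. Bidirectional single-layer
# cross-attention: each view is a 1-token query attending over the 2-token
# set {z, h}; the two attended outputs are averaged and projected to d_f.
.fuse_forward <- function(z, h, p) {
  heads <- attr(p, "heads")
  Tkv <- rbind(z, h)
  a1 <- .mha_forward(matrix(z, 1), Tkv, p$attn, heads)
  a2 <- .mha_forward(matrix(h, 1), Tkv, p$attn, heads)
  u <- (a1$Y + a2$Y) / 2
  fused <- u %*% p$Wf
  fused <- sweep(fused, 2L, p$bf, `+`)
  list(fused = as.numeric(fused),
       cache = list(a1 = a1$cache, a2 = a2$cache, u = u))
}

.fuse_backward <- function(dfused, cache, p) {
  dfused <- matrix(dfused, 1)
  du <- dfused %*% t(p$Wf)
  gWf <- t(cache$u) %*% dfused
  gbf <- dfused
  b1 <- .mha_backward(du / 2, cache$a1, p$attn)
  b2 <- .mha_backward(du / 2, cache$a2, p$attn)
  dz <- as.numeric(b1$dXq) + b1$dXkv[1, ] + b2$dXkv[1, ]
  dh <- as.numeric(b2$dXq) + b1$dXkv[2, ] + b2$dXkv[2, ]
  list(dz = dz, dh = dh,
       grads = list(attn = .tree_add(b1$grads, b2$grads), Wf = gWf, bf = gbf))
}

# Vectorized fusion over n drugs at once: Z, H are n x d matrices of the two
# views. Identical math to .fuse_forward row by row (the 2-token attention
# reduces to a per-row binary softmax), verified against it in the tests.
.fuse_all_forward <- function(Z, H, p) {
  h <- attr(p, "heads")
  d <- ncol(Z)
  dk <- d %/% h
  Qz <- Z %*% p$attn$Wq; Qh <- H %*% p$attn$Wq
  Kz <- Z %*% p$attn$Wk; Kh <- H %*% p$attn$Wk
  Vz <- Z %*% p$attn$Wv; Vh <- H %*% p$attn$Wv
  n <- nrow(Z)
  Oz <- matrix(0, n, d); Oh <- matrix(0, n, d)
  A <- vector("list", h)
  for (i in seq_len(h)) {
    idx <- ((i - 1L) * dk + 1L):(i * dk)
    att <- function(Q) {
      s1 <- rowSums(Q[, idx, drop = FALSE] * Kz[, idx, drop = FALSE]) / sqrt(dk)
      s2 <- rowSums(Q[, idx, drop = FALSE] * Kh[, idx, drop = FALSE]) / sqrt(dk)
      m <- pmax(s1, s2)
      e1 <- exp(s1 - m); e2 <- exp(s2 - m)
      a1 <- e1 / (e1 + e2)
      list(a1 = a1, a2 = 1 - a1)
    }
    az <- att(Qz); ah <- att(Qh)
    Oz[, idx] <- az$a1 * Vz[, idx, drop = FALSE] + az$a2 * Vh[, idx, drop = FALSE]
    Oh[, idx] <- ah$a1 * Vz[, idx, drop = FALSE] + ah$a2 * Vh[, idx, drop = FALSE]
    A[[i]] <- list(az = az, ah = ah)
  }
  U <- (Oz %*% p$attn$Wo + Oh %*% p$attn$Wo) / 2
  Fm <- sweep(U %*% p$Wf, 2L, p$bf, `+`)
  list(Fm = Fm,
       cache = list(Z = Z, H = H, Qz = Qz, Qh = Qh, Kz = Kz, Kh = Kh,
                    Vz = Vz, Vh = Vh, Oz = Oz, Oh = Oh, U = U, A = A,
                    h = h, dk = dk))
}

.fuse_all_backward <- function(dF, cache, p) {
  h <- cache$h; dk <- cache$dk
  dU <- dF %*% t(p$Wf)
  gWf <- t(cache$U) %*% dF
  gbf <- matrix(colSums(dF), 1)
  dOz <- (dU / 2) %*% t(p$attn$Wo)
  dOh <- dOz                       # same projection, same upstream
  gWo <- t(cache$Oz) %*% (dU / 2) + t(cache$Oh) %*% (dU / 2)
  n <- nrow(dF); d <- ncol(cache$Z)
  dQz <- matrix(0, n, d); dQh <- matrix(0, n, d)
  dKz <- matrix(0, n, d); dKh <- matrix(0, n, d)
  dVz <- matrix(0, n, d); dVh <- matrix(0, n, d)
  for (i in seq_len(h)) {
    idx <- ((i - 1L) * dk + 1L):(i * dk)
    back_branch <- function(dO, a, Q) {
      dA1 <- rowSums(dO[, idx, drop = FALSE] * cache$Vz[, idx, drop = FALSE])
      dA2 <- rowSums(dO[, idx, drop = FALSE] * cache$Vh[, idx, drop = FALSE])
      dVz[, idx] <<- dVz[, idx] + a$a1 * dO[, idx, drop = FALSE]
      dVh[, idx] <<- dVh[, idx] + a$a2 * dO[, idx, drop = FALSE]
      s <- a$a1 * dA1 + a$a2 * dA2
      ds1 <- a$a1 * (dA1 - s) / sqrt(dk)
      ds2 <- a$a2 * (dA2 - s) / sqrt(dk)
      dKz[, idx] <<- dKz[, idx] + ds1 * Q[, idx, drop = FALSE]
      dKh[, idx] <<- dKh[, idx] + ds2 * Q[, idx, drop = FALSE]
      ds1 * cache$Kz[, idx, drop = FALSE] + ds2 * cache$Kh[, idx, drop = FALSE]
    }
    dQz[, idx] <- back_branch(dOz, cache$A[[i]]$az, cache$Qz)
    dQh[, idx] <- back_branch(dOh, cache$A[[i]]$ah, cache$Qh)
  }
  dZ <- dQz %*% t(p$attn$Wq) + dKz %*% t(p$attn$Wk) + dVz %*% t(p$attn$Wv)
  dH <- dQh %*% t(p$attn$Wq) + dKh %*% t(p$attn$Wk) + dVh %*% t(p$attn$Wv)
  grads <- list(attn = list(
    Wq = t(cache$Z) %*% dQz + t(cache$H) %*% dQh,
    Wk = t(cache$Z) %*% dKz + t(cache$H) %*% dKh,
    Wv = t(cache$Z) %*% dVz + t(cache$H) %*% dVh,
    Wo = gWo), Wf = gWf, bf = gbf)
  list(dZ = dZ, dH = dH, grads = grads)
}

# Single-view degenerate fusion (ablations): project the lone view to d_f.
.fuse_single_forward <- function(v, p) {
  fused <- matrix(v, 1) %*% p$Wf
  fused <- sweep(fused, 2L, p$bf, `+`)
  list(fused = as.numeric(fused), cache = list(v = v))
}

.fuse_single_backward <- function(dfused, cache, p) {
  dfused <- matrix(dfused, 1)
  list(dv = as.numeric(dfused %*% t(p$Wf)),
       grads = list(attn = .tree_zeros_like(p$attn),
                    Wf = matrix(cache$v, ncol = 1) %*% dfused,
                    bf = dfused))
}

#' Fuse the two view embeddings of a drug by cross-attention
#'
#' `z` attends as a 1-token query over the 2-token sequence `[z; h]`, and `h`
#' symmetrically; the two attended outputs are averaged and linearly
#' projected to width `d_f`. Deterministic in inputs and parameters.
#'
#' @param z,h Numeric vectors of length d (graph- and sequence-view
#'   embeddings).
#' @param params A [cross_attention_params()] tree.
#' @return Fused numeric vector of length `d_f`.
#' @export
cross_attention_fuse <- function(z, h, params) {
  if (length(z) != length(h) || length(z) != nrow(params$Wf)) {
    stop(sprintf(
      "cross_attention_fuse: expected two length-%d views, got %d and %d",
      nrow(params$Wf), length(z), length(h)), call. = FALSE)
  }
  .fuse_forward(z, h, params)$fused
}

# --- prediction head ----------------------------------------------------------

#' Initialise the MLP prediction head
#'
#' Widths `[2 d_f, hidden, 1]` with ReLU hidden activation; the final logit
#' is passed through the sigmoid by [predict_interaction()].
#'
#' @param d_f Fused embedding width.
#' @param hidden Hidden width (default `d_f`).
#' @param lambda_cl Non-negative weight of the contrastive term in the joint
#'   objective (default 1).
#' @return Parameter tree of class `prediction_head`.
#' @export
prediction_head <- function(d_f, hidden = d_f, lambda_cl = 1) {
  if (lambda_cl < 0) {
    stop("prediction_head: lambda_cl must be non-negative", call. = FALSE)
  }
  p <- list(W1 = .glorot(2L * d_f, hidden), b1 = matrix(0, 1, hidden),
            W2 = .glorot(hidden, 1L), b2 = matrix(0, 1, 1))
  attr(p, "lambda_cl") <- lambda_cl
  class(p) <- c("prediction_head", "list")
  p
}

# Batched head forward: X is m x (2 d_f) rows of concatenated fused pairs.
.head_forward <- function(X, p) {
  pre <- sweep(X %*% p$W1, 2L, p$b1, `+`)
  hh <- .relu(pre)
  logit <- as.numeric(hh %*% p$W2) + as.numeric(p$b2)
  list(logit = logit, cache = list(X = X, pre = pre, hh = hh))
}

.head_backward <- function(dlogit, cache, p) {
  dlogit <- matrix(dlogit, ncol = 1)
  dhh <- dlogit %*% t(p$W2)
  dpre <- dhh * (cache$pre > 0)
  list(dX = dpre %*% t(p$W1),
       grads = list(W1 = t(cache$X) %*% dpre,
                    b1 = matrix(colSums(dpre), 1),
                    W2 = t(cache$hh) %*% dlogit,
                    b2 = matrix(sum(dlogit), 1, 1)))
}

#' Predict the interaction probability of a fused drug pair
#'
#' `y_hat = sigmoid(MLP([d_A ; d_B]))`; the concatenation order is (first
#' argument, second argument).
#'
#' @param d_A,d_B Fused drug vectors of length `d_f`.
#' @param head A [prediction_head()].
#' @return Probability in (0, 1).
#' @export
predict_interaction <- function(d_A, d_B, head) {
  x <- c(as.numeric(d_A), as.numeric(d_B))
  if (length(x) != nrow(head$W1)) {
    stop(sprintf("predict_interaction: expected fused width %d, got %d",
                 nrow(head$W1) / 2L, length(d_A)), call. = FALSE)
  }
  if (any(!is.finite(x))) {
    stop("predict_interaction: non-finite input", call. = FALSE)
  }
  1 / (1 + exp(-.head_forward(matrix(x, 1), head)$logit))
}

#' Binary cross-entropy loss
#'
#' `-[y log(y_hat) + (1 - y) log(1 - y_hat)]`, averaged over a batch.
#' Probabilities outside the open interval (0, 1) are a domain error unless
#' `clamp = TRUE`, which clips at `1e-12`.
#'
#' @param y_hat Predicted probabilities.
#' @param y Labels in \{0, 1\}.
#' @param clamp Clip probabilities instead of erroring (default `FALSE`).
#' @return Mean non-negative loss.
#' @export
supervised_loss <- function(y_hat, y, clamp = FALSE) {
  if (length(y_hat) != length(y)) {
    stop("supervised_loss: length mismatch", call. = FALSE)
  }
  if (!all(y %in% c(0, 1))) {
    stop("supervised_loss: labels must be 0 or 1", call. = FALSE)
  }
  if (clamp) {
    y_hat <- pmin(pmax(y_hat, 1e-12), 1 - 1e-12)
  } else if (any(y_hat <= 0 | y_hat >= 1)) {
    stop("supervised_loss: probabilities must lie strictly in (0, 1)",
         call. = FALSE)
  }
  mean(-(y * log(y_hat) + (1 - y) * log(1 - y_hat)))
}

#' Combine the supervised and contrastive terms into the training objective
#'
#' Two schedules: `"two_stage"` (default) optimizes the contrastive loss
#' alone in phase 1 and the supervised loss alone in phase 2; `"joint"`
#' returns `bce + lambda_cl * cl`.
#'
#' @param bce Supervised (binary cross-entropy) term.
#' @param cl Contrastive term.
#' @param lambda_cl Non-negative contrastive weight (joint schedule).
#' @param schedule `"two_stage"` or `"joint"`.
#' @param phase Training phase for the two-stage schedule (1 or 2).
#' @return Scalar objective.
#' @export
total_objective <- function(bce, cl, lambda_cl = 1, schedule = c("two_stage", "joint"),
                            phase = 1L) {
  schedule <- match.arg(schedule)
  if (!is.finite(bce) || !is.finite(cl)) {
    stop("total_objective: non-finite inputs", call. = FALSE)
  }
  if (lambda_cl < 0) {
    stop("total_objective: lambda_cl must be non-negative", call. = FALSE)
  }
  if (schedule == "joint") return(bce + lambda_cl * cl)
  if (!phase %in% c(1L, 2L)) {
    stop("total_objective: phase must be 1 or 2", call. = FALSE)
  }
  if (phase == 1L) cl else bce
}
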