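# Model assembly: configuration, parameter initialisation, drug encoding in
# both views, and the end-to-end objective with analytic gradients for all
# parameter groups. Ablation variants reuse the same machinery with one view
# disabled (the disabled view's parameters then receive exactly zero
# gradient, and the fusion degenerates to a projection of the lone view).

#' Default run configuration
#'
#' Training defaults follow the published setup (300 epochs, learning rate
#' 1e-3, batch size 256, weight decay 4e-4, embedding width 64, 4 attention
#' heads); everything is overridable through `...` using nested lists.
#'
#' @param ... Named overrides, e.g. `d = 32`, `train = list(epochs = 40)`.
#' @return A nested configuration list of class `ddi_config`.
#' @export
ddi_config <- function(...) {
  cfg <- list(
    d = 64L,
    graph = list(heads = 4L, layers = 2L, readout = "mean"),
    seq = list(heads = 4L, layers = 2L, max_len = 256L),
    contrastive = list(tau = 0.5, mode = "pairwise_eq11"),
    fusion = list(d_f = NULL, heads = 1L),     # d_f NULL -> d
    predict = list(symmetrize = FALSE, threshold = 0.5, hidden = NULL),
    train = list(epochs = 300L, epochs_cl = 300L, lr = 1e-3,
                 batch_size = 256L, weight_decay = 4e-4,
                 schedule = "two_stage", lambda_cl = 1, freeze_encoders = TRUE,
                 negative_ratio = 1),
    variant = "full",
    seed = 1L
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]])) {
      for (k in names(over[[nm]])) cfg[[nm]][[k]] <- over[[nm]][[k]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  if (is.null(cfg$fusion$d_f)) cfg$fusion$d_f <- cfg$d
  stopifnot(cfg$d %% cfg$graph$heads == 0L, cfg$d %% cfg$seq$heads == 0L,
            cfg$train$lambda_cl >= 0, cfg$contrastive$tau > 0)
  if (!cfg$variant %in% c("full", "no_graph_view", "no_sequence_view")) {
    stop(sprintf("ddi_config: unknown variant '%s'", cfg$variant),
         call. = FALSE)
  }
  class(cfg) <- c("ddi_config", "list")
  cfg
}

#' Initialise a cross-view DDI model
#'
#' @param token_vocab SMILES token vocabulary from [build_token_vocab()].
#' @param feat_vocab A [feature_vocab()].
#' @param cfg A [ddi_config()].
#' @return A `ddi_model`: parameter trees for both encoders, the fusion
#'   module and the head, plus the vocabularies and resolved config.
#' @export
ddi_model <- function(token_vocab, feat_vocab = feature_vocab(),
                      cfg = ddi_config()) {
  set.seed(cfg$seed)
  params <- list(
    graph = graph_encoder_params(feat_vocab$D_V, feat_vocab$D_E, cfg$d,
                                 cfg$graph$heads, cfg$graph$layers),
    seq = seq_encoder_params(length(token_vocab), cfg$d, cfg$seq$heads,
                             cfg$seq$layers, cfg$seq$max_len),
    fusion = cross_attention_params(cfg$d, cfg$fusion$d_f, cfg$fusion$heads),
    head = prediction_head(cfg$fusion$d_f,
                           hidden = if (is.null(cfg$predict$hidden))
                             cfg$fusion$d_f else cfg$predict$hidden,
                           lambda_cl = cfg$train$lambda_cl)
  )
  structure(list(params = params, token_vocab = token_vocab,
                 feat_vocab = feat_vocab, cfg = cfg, feat_norm = NULL),
            class = "ddi_model")
}

#' @export
print.ddi_model <- function(x, ...) {
  cat(sprintf(
    "<ddi_model> d=%d, graph %d layers/%d heads, seq %d layers/%d heads, d_f=%d, variant=%s\n",
    x$cfg$d, x$cfg$graph$layers, x$cfg$graph$heads, x$cfg$seq$layers,
    x$cfg$seq$heads, x$cfg$fusion$d_f, x$cfg$variant))
  invisible(x)
}

# Precompute per-drug featurizations and token ids once per dataset.
# drugs: data.frame(drug_id, smiles). Returns named list of
# list(feats, ids).
.drug_cache <- function(drugs, model) {
  prepared <- prepare_drugs(drugs, model$feat_vocab)
  out <- vector("list", nrow(drugs))
  names(out) <- drugs$drug_id
  for (r in seq_len(nrow(drugs))) {
    out[[r]] <- list(
      feats = prepared[[r]]$features,
      ids = token_ids(drugs$smiles[r], model$token_vocab,
                      attr(model$params$seq, "max_len"))
    )
  }
  out
}

# Encode a set of drugs in both active views, with caches for backprop.
# Returns list(Z, H, gcaches, scaches); disabled views give NULL matrices.
.encode_batch <- function(model, cache, drug_ids) {
  n <- length(drug_ids)
  cfg <- model$cfg
  use_g <- cfg$variant != "no_graph_view"
  use_s <- cfg$variant != "no_sequence_view"
  Z <- if (use_g) matrix(0, n, cfg$d) else NULL
  H <- if (use_s) matrix(0, n, cfg$d) else NULL
  gcaches <- vector("list", n)
  scaches <- vector("list", n)
  for (k in seq_len(n)) {
    dc <- cache[[drug_ids[k]]]
    if (is.null(dc)) {
      stop(sprintf("unknown drug id '%s'", drug_ids[k]), call. = FALSE)
    }
    if (use_g) {
      gf <- .graph_view_forward(dc$feats, model$params$graph)
      Z[k, ] <- gf$z
      gcaches[[k]] <- gf
    }
    if (use_s) {
      sf <- .seq_view_forward(dc$ids, model$params$seq)
      H[k, ] <- sf$h
      scaches[[k]] <- sf
    }
  }
  list(Z = Z, H = H, gcaches = gcaches, scaches = scaches)
}

# Per-dimension standardization of frozen view embeddings. The statistics
# are estimated on the training drugs after the contrastive stage and applied
# unchanged to validation/test drugs; used only when the encoders are frozen
# (the supervised stage then trains on a fixed, well-scaled feature space).
.fit_feat_norm <- function(enc, rows) {
  stat <- function(M) {
    if (is.null(M)) return(NULL)
    Mt <- M[rows, , drop = FALSE]
    s <- apply(Mt, 2L, stats::sd)
    list(mu = colMeans(Mt), sd = pmax(s, 1e-8))
  }
  list(z = stat(enc$Z), h = stat(enc$H))
}

.apply_feat_norm <- function(enc, norm) {
  if (is.null(norm)) return(enc)
  if (!is.null(enc$Z) && !is.null(norm$z)) {
    enc$Z <- sweep(sweep(enc$Z, 2L, norm$z$mu), 2L, norm$z$sd, `/`)
  }
  if (!is.null(enc$H) && !is.null(norm$h)) {
    enc$H <- sweep(sweep(enc$H, 2L, norm$h$mu), 2L, norm$h$sd, `/`)
  }
  enc
}

# Fuse all drugs of a batch at once. enc as returned by .encode_batch.
# Returns list(Fm = n x d_f matrix, cache).
.fuse_batch <- function(model, enc) {
  p <- model$params$fusion
  if (model$cfg$variant == "full") {
    return(.fuse_all_forward(enc$Z, enc$H, p))
  }
  V <- if (model$cfg$variant == "no_graph_view") enc$H else enc$Z
  Fm <- sweep(V %*% p$Wf, 2L, p$bf, `+`)
  list(Fm = Fm, cache = list(V = V))
}

# Backward counterpart: dF is n x d_f. Returns dZ/dH (n x d, zero matrix for
# a disabled view) and fusion parameter gradients.
.fuse_batch_backward <- function(model, dF, cache) {
  p <- model$params$fusion
  if (model$cfg$variant == "full") {
    return(.fuse_all_backward(dF, cache, p))
  }
  dV <- dF %*% t(p$Wf)
  grads <- list(attn = .tree_zeros_like(p$attn),
                Wf = t(cache$V) %*% dF,
                bf = matrix(colSums(dF), 1))
  zero <- matrix(0, nrow(dF), ncol(dV))
  if (model$cfg$variant == "no_graph_view") {
    list(dZ = zero, dH = dV, grads = grads)
  } else {
    list(dZ = dV, dH = zero, grads = grads)
  }
}

# End-to-end objective and gradients on a batch of labelled pairs.
#   pairs: data.frame(a, b, y) with a/b indices into drug_ids.
#   phase: "joint" (bce + lambda*cl), "contrastive" (cl only),
#          "supervised" (bce only).
#   frozen_enc: skip encoder backprop (supervised phase of the two-stage
#          schedule with frozen encoders).
# Returns list(loss, bce, cl, logits, grads).
.model_objective <- function(model, cache, drug_ids, pairs,
                             phase = "joint", frozen_enc = FALSE,
                             enc = NULL) {
  cfg <- model$cfg
  ccfg <- contrastive_config(cfg$contrastive$tau, cfg$contrastive$mode)
  if (is.null(enc)) enc <- .encode_batch(model, cache, drug_ids)
  n <- length(drug_ids)
  grads <- .tree_zeros_like(lapply(model$params, unclass))

  use_cl <- phase %in% c("joint", "contrastive") && cfg$variant == "full" &&
    n >= 2L
  cl <- 0
  dZ_cl <- NULL; dH_cl <- NULL
  if (use_cl) {
    cg <- .contrastive_batch_grad(enc$Z, enc$H, ccfg)
    cl <- cg$loss
    lam <- if (phase == "contrastive") 1 else cfg$train$lambda_cl
    dZ_cl <- lam * cg$dZ
    dH_cl <- lam * cg$dH
  }

  bce <- 0
  dZ_sup <- matrix(0, n, cfg$d)
  dH_sup <- matrix(0, n, cfg$d)
  logits <- numeric(0)
  if (phase %in% c("joint", "supervised") && nrow(pairs) > 0L) {
    fus <- .fuse_batch(model, enc)
    X <- cbind(fus$Fm[pairs$a, , drop = FALSE], fus$Fm[pairs$b, , drop = FALSE])
    hf <- .head_forward(X, model$params$head)
    logits <- hf$logit
    m <- length(logits)
    # BCE with logits: softplus(l) - y l, numerically stable.
    bce <- mean(ifelse(logits > 0,
                       logits + log1p(exp(-logits)) - pairs$y * logits,
                       log1p(exp(logits)) - pairs$y * logits))
    dlogit <- (1 / (1 + exp(-logits)) - pairs$y) / m
    hb <- .head_backward(dlogit, hf$cache, model$params$head)
    grads$head <- .tree_add(grads$head, hb$grads)
    d_f <- attr(model$params$fusion, "d_f")
    dXa <- hb$dX[, seq_len(d_f), drop = FALSE]
    dXb <- hb$dX[, d_f + seq_len(d_f), drop = FALSE]
    dF <- matrix(0, n, d_f)
    agg_a <- rowsum(dXa, group = pairs$a)
    agg_b <- rowsum(dXb, group = pairs$b)
    dF[as.integer(rownames(agg_a)), ] <- dF[as.integer(rownames(agg_a)), , drop = FALSE] + agg_a
    dF[as.integer(rownames(agg_b)), ] <- dF[as.integer(rownames(agg_b)), , drop = FALSE] + agg_b
    fb <- .fuse_batch_backward(model, dF, fus$cache)
    dZ_sup <- if (!is.null(enc$Z)) fb$dZ else dZ_sup
    dH_sup <- if (!is.null(enc$H)) fb$dH else dH_sup
    grads$fusion <- .tree_add(grads$fusion, fb$grads)
  }

  dZ <- dZ_sup
  dH <- dH_sup
  if (use_cl) {
    dZ <- dZ + dZ_cl
    dH <- dH + dH_cl
  }

  if (!frozen_enc) {
    use_g <- cfg$variant != "no_graph_view"
    use_s <- cfg$variant != "no_sequence_view"
    for (k in seq_len(n)) {
      if (use_g && any(dZ[k, ] != 0)) {
        grads$graph <- .tree_add(
          grads$graph,
          .graph_view_backward(dZ[k, ], enc$gcaches[[k]], model$params$graph))
      }
      if (use_s && any(dH[k, ] != 0)) {
        grads$seq <- .tree_add(
          grads$seq,
          .seq_view_backward(dH[k, ], enc$scaches[[k]], model$params$seq))
      }
    }
  }

  lam <- cfg$train$lambda_cl
  loss <- switch(phase,
                 joint = bce + lam * cl,
                 contrastive = cl,
                 supervised = bce)
  list(loss = loss, bce = bce, cl = cl, logits = logits, grads = grads)
}

#' Score drug pairs with a trained model
#'
#' @param model A trained `ddi_model`.
#' @param drugs data.frame with `drug_id`, `smiles` covering every pair
#'   member.
#' @param pairs data.frame with `drug_a`, `drug_b`.
#' @param cache Optional precomputed drug cache (internal reuse).
#' @return Numeric vector of interaction probabilities; with
#'   `cfg$predict$symmetrize = TRUE` the scores of (A,B) and (B,A) are
#'   averaged.
#' @export
predict_pairs <- function(model, drugs, pairs, cache = NULL) {
  if (is.null(cache)) cache <- .drug_cache(drugs, model)
  ids <- unique(c(pairs$drug_a, pairs$drug_b))
  enc <- .apply_feat_norm(.encode_batch(model, cache, ids), model$feat_norm)
  fus <- .fuse_batch(model, list(Z = enc$Z, H = enc$H))
  ia <- match(pairs$drug_a, ids)
  ib <- match(pairs$drug_b, ids)
  score_of <- function(i1, i2) {
    X <- cbind(fus$Fm[i1, , drop = FALSE], fus$Fm[i2, , drop = FALSE])
    1 / (1 + exp(-.head_forward(X, model$params$head)$logit))
  }
  s <- score_of(ia, ib)
  if (isTRUE(model$cfg$predict$symmetrize)) s <- (s + score_of(ib, ia)) / 2
  s
}
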