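# Training loop: two-stage (contrastive alignment, then supervised head) or
# joint schedule, AdamW updates, per-epoch logging, best-validation
# checkpointing, and the ablation runner.

.empty_pairs <- function() data.frame(a = integer(0), b = integer(0),
                                      y = numeric(0))

# Resolve a split plan into train/validation/test triplet tables.
.split_sets <- function(split, test_fold = 1L, seed = 1L, val_frac = 0.1) {
  stopifnot(inherits(split, "split_plan"))
  tri <- split$triplets
  if (split$mode == "warm") {
    if (test_fold < 1L || test_fold > split$k) {
      stop("split_sets: test_fold out of range", call. = FALSE)
    }
    val_fold <- test_fold %% split$k + 1L
    list(train = tri[!split$fold %in% c(test_fold, val_fold), , drop = FALSE],
         val = tri[split$fold == val_fold, , drop = FALSE],
         test = tri[split$fold == test_fold, , drop = FALSE])
  } else {
    train_pool <- tri[split$train_idx, , drop = FALSE]
    test <- tri[split$test_idx, , drop = FALSE]
    if (!is.null(split$negatives)) {
      ntr <- split$negatives[split$negatives$split == "train",
                             c("drug_a", "drug_b", "label"), drop = FALSE]
      nte <- split$negatives[split$negatives$split == "test",
                             c("drug_a", "drug_b", "label"), drop = FALSE]
      ntr$stratum <- "0"; nte$stratum <- "0"
      train_pool <- rbind(train_pool, ntr)
      test <- rbind(test, nte)
    }
    set.seed(seed)
    n <- nrow(train_pool)
    n_val <- max(1L, round(val_frac * n))
    vidx <- sample.int(n, n_val)
    list(train = train_pool[-vidx, , drop = FALSE],
         val = train_pool[vidx, , drop = FALSE],
         test = test)
  }
}

# Score (probability) labelled pairs given encodings of all drugs.
.score_from_enc <- function(model, enc_all, master_ids, pairs_df) {
  fus <- .fuse_batch(model, enc_all)
  ia <- match(pairs_df$drug_a, master_ids)
  ib <- match(pairs_df$drug_b, master_ids)
  X <- cbind(fus$Fm[ia, , drop = FALSE], fus$Fm[ib, , drop = FALSE])
  1 / (1 + exp(-.head_forward(X, model$params$head)$logit))
}

#' Train a cross-view DDI model on a split plan
#'
#' Runs the configured schedule: by default contrastive view alignment first
#' (encoders only), then supervised training of the fusion/head on frozen
#' encoder embeddings; set `train$schedule = "joint"` for a single phase
#' optimizing `bce + lambda_cl * cl` end to end, or
#' `train$freeze_encoders = FALSE` to fine-tune the encoders in phase 2.
#' Training is deterministic given the config seed. The best-validation-AUROC
#' parameters are checkpointed and used for the final test evaluation.
#'
#' @param drugs data.frame with `drug_id`, `smiles`.
#' @param split A `split_plan` from [make_warm_split()] / [make_cold_split()].
#' @param cfg A [ddi_config()].
#' @param test_fold Warm mode: which fold is the test fold (its successor is
#'   the validation fold).
#' @param verbose Print per-epoch progress.
#' @return A `ddi_fit`: the trained `model`, per-epoch `history`, the test
#'   `metrics` (a [compute_metrics()] report) and the resolved triplet sets.
#' @export
train_model <- function(drugs, split, cfg = ddi_config(), test_fold = 1L,
                        verbose = FALSE) {
  sets <- .split_sets(split, test_fold, seed = cfg$seed)
  if (nrow(sets$train) == 0L || nrow(sets$test) == 0L) {
    stop("train_model: empty train or test set", call. = FALSE)
  }
  used_ids <- unique(c(sets$train$drug_a, sets$train$drug_b,
                       sets$val$drug_a, sets$val$drug_b,
                       sets$test$drug_a, sets$test$drug_b))
  drugs <- drugs[drugs$drug_id %in% used_ids, , drop = FALSE]
  if (!all(used_ids %in% drugs$drug_id)) {
    stop("train_model: triplets reference drugs missing from the drug table",
         call. = FALSE)
  }
  train_drug_ids <- unique(c(sets$train$drug_a, sets$train$drug_b))
  token_vocab <- build_token_vocab(
    drugs$smiles[drugs$drug_id %in% train_drug_ids])
  model <- ddi_model(token_vocab, feature_vocab(), cfg)
  cache <- .drug_cache(drugs, model)
  master_ids <- names(cache)

  tp <- cfg$train
  states <- lapply(model$params, function(p) .adamw_init(unclass(p)))
  step_groups <- function(grads, groups) {
    for (g in groups) {
      st <- .adamw_step(unclass(model$params[[g]]), grads[[g]], states[[g]],
                        lr = tp$lr, weight_decay = tp$weight_decay)
      p_new <- st$params
      attributes(p_new) <- attributes(model$params[[g]])
      model$params[[g]] <<- p_new
      states[[g]] <<- st$state
    }
  }
  enc_groups <- switch(cfg$variant,
                       full = c("graph", "seq"),
                       no_graph_view = "seq",
                       no_sequence_view = "graph")
  all_groups <- c(enc_groups, "fusion", "head")

  tr_pairs <- data.frame(a = match(sets$train$drug_a, master_ids),
                         b = match(sets$train$drug_b, master_ids),
                         y = sets$train$label)
  history <- list()
  set.seed(cfg$seed + 1L)

  # ---- phase 1: contrastive alignment of the two views (full model only) ----
  if (cfg$variant == "full" && tp$schedule == "two_stage" &&
      tp$epochs_cl > 0L && length(train_drug_ids) >= 2L) {
    for (e in seq_len(tp$epochs_cl)) {
      ord <- sample(train_drug_ids)
      losses <- c()
      for (start in seq(1L, length(ord), by = tp$batch_size)) {
        bids <- ord[start:min(start + tp$batch_size - 1L, length(ord))]
        if (length(bids) < 2L) next
        ob <- .model_objective(model, cache, bids, .empty_pairs(),
                               phase = "contrastive")
        step_groups(ob$grads, enc_groups)
        losses <- c(losses, ob$loss)
      }
      history[[length(history) + 1L]] <- data.frame(
        epoch = e, phase = "contrastive", loss = mean(losses),
        val_auroc = NA_real_)
      if (verbose) message(sprintf("[cl] epoch %d loss %.5f", e, mean(losses)))
    }
  }

  # ---- phase 2 / joint: supervised training ----------------------------------
  frozen <- tp$schedule == "two_stage" && isTRUE(tp$freeze_encoders)
  phase2 <- if (tp$schedule == "joint") "joint" else "supervised"
  enc_all <- NULL
  if (frozen) {
    enc_all <- .encode_batch(model, cache, master_ids)
    model$feat_norm <- .fit_feat_norm(enc_all,
                                      match(train_drug_ids, master_ids))
    enc_all <- .apply_feat_norm(enc_all, model$feat_norm)
  }

  best <- list(val = -Inf, params = model$params)
  val_ok <- nrow(sets$val) > 0L && length(unique(sets$val$label)) == 2L
  for (e in seq_len(tp$epochs)) {
    ord <- sample.int(nrow(tr_pairs))
    losses <- c()
    for (start in seq(1L, length(ord), by = tp$batch_size)) {
      bidx <- ord[start:min(start + tp$batch_size - 1L, length(ord))]
      bp <- tr_pairs[bidx, , drop = FALSE]
      sub <- sort(unique(c(bp$a, bp$b)))
      rel <- data.frame(a = match(bp$a, sub), b = match(bp$b, sub), y = bp$y)
      if (frozen) {
        enc_sub <- list(Z = if (!is.null(enc_all$Z)) enc_all$Z[sub, , drop = FALSE],
                        H = if (!is.null(enc_all$H)) enc_all$H[sub, , drop = FALSE])
        ob <- .model_objective(model, cache, master_ids[sub], rel,
                               phase = "supervised", frozen_enc = TRUE,
                               enc = enc_sub)
        step_groups(ob$grads, c("fusion", "head"))
      } else {
        ob <- .model_objective(model, cache, master_ids[sub], rel,
                               phase = phase2)
        step_groups(ob$grads, all_groups)
      }
      losses <- c(losses, ob$loss)
    }
    val_auroc <- NA_real_
    if (val_ok) {
      enc_eval <- if (frozen) enc_all else
        .apply_feat_norm(.encode_batch(model, cache, master_ids),
                         model$feat_norm)
      vs <- .score_from_enc(model, enc_eval, master_ids, sets$val)
      val_auroc <- auroc(sets$val$label, vs)
      if (val_auroc > best$val) {
        best$val <- val_auroc
        best$params <- model$params
      }
    }
    history[[length(history) + 1L]] <- data.frame(
      epoch = e, phase = phase2, loss = mean(losses), val_auroc = val_auroc)
    if (verbose) {
      message(sprintf("[%s] epoch %d loss %.5f val AUROC %s", phase2, e,
                      mean(losses),
                      if (is.na(val_auroc)) "-" else sprintf("%.4f", val_auroc)))
    }
  }
  if (val_ok) model$params <- best$params

  enc_final <- .apply_feat_norm(.encode_batch(model, cache, master_ids),
                                model$feat_norm)
  test_scores <- .score_from_enc(model, enc_final, master_ids, sets$test)
  metrics <- compute_metrics(sets$test$label, test_scores,
                             threshold = cfg$predict$threshold)

  structure(list(model = model, history = do.call(rbind, history),
                 metrics = metrics, sets = sets,
                 best_val_auroc = if (val_ok) best$val else NA_real_,
                 test_scores = test_scores),
            class = "ddi_fit")
}

#' @export
print.ddi_fit <- function(x, ...) {
  cat(sprintf("<ddi_fit> variant=%s | best val AUROC %s | test:\n",
              x$model$cfg$variant,
              if (is.na(x$best_val_auroc)) "-" else
                sprintf("%.4f", x$best_val_auroc)))
  print(x$metrics)
  invisible(x)
}

#' Evaluate a trained model on labelled pairs
#'
#' @param fit A `ddi_fit` (or a bare `ddi_model`).
#' @param drugs Drug table covering every pair member.
#' @param pairs data.frame with `drug_a`, `drug_b`, `label`.
#' @param threshold Decision threshold (default: the model config's).
#' @return A [compute_metrics()] report.
#' @export
evaluate_model <- function(fit, drugs, pairs, threshold = NULL) {
  model <- if (inherits(fit, "ddi_fit")) fit$model else fit
  stopifnot(inherits(model, "ddi_model"))
  if (is.null(threshold)) threshold <- model$cfg$predict$threshold
  scores <- predict_pairs(model, drugs, pairs)
  compute_metrics(pairs$label, scores, threshold = threshold)
}

#' Run one ablation variant on a shared split
#'
#' `no_graph_view` trains on the sequence view alone (fusion degenerates to a
#' projection of h_mol; the contrastive phase is skipped since only one view
#' exists, and graph-encoder parameters receive zero gradient);
#' `no_sequence_view` is symmetric; `full` is the complete model. All other
#' settings, including the split, are identical across variants.
#'
#' @param variant One of `"full"`, `"no_graph_view"`, `"no_sequence_view"`.
#' @param drugs Drug table.
#' @param split A shared `split_plan`.
#' @param cfg A [ddi_config()]; its `variant` field is overridden.
#' @param test_fold Warm-mode test fold.
#' @return A `ddi_fit`.
#' @export
run_ablation <- function(variant, drugs, split, cfg = ddi_config(),
                         test_fold = 1L) {
  if (!variant %in% c("full", "no_graph_view", "no_sequence_view")) {
    stop(sprintf("run_ablation: unknown variant '%s'", variant), call. = FALSE)
  }
  cfg$variant <- variant
  train_model(drugs, split, cfg, test_fold = test_fold)
}
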