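# Evaluation protocol: triplet canonicalisation, warm-start stratified k-fold
# splits, cold-start drug-disjoint splits, per-split negative sampling,
# confusion metrics, AUROC/AUPRC, and the Kruskal-Wallis / Mann-Whitney /
# Holm-Bonferroni model comparison.

#' Canonicalise a DDI triplet table
#'
#' Pairs are symmetric: each is stored once with `drug_a < drug_b`
#' (lexicographically). A `type` column, when present, is collapsed to binary
#' label 1 and retained as the stratification stratum. Self-pairs are an
#' error; duplicated pairs are dropped (first occurrence wins).
#'
#' @param triplets data.frame with `drug_a`, `drug_b` and either `label`
#'   (0/1) or `type`.
#' @return data.frame with `drug_a`, `drug_b`, `label`, `stratum`.
#' @export
canonical_triplets <- function(triplets) {
  stopifnot(is.data.frame(triplets),
            all(c("drug_a", "drug_b") %in% names(triplets)))
  a <- as.character(triplets$drug_a)
  b <- as.character(triplets$drug_b)
  if (any(a == b)) {
    stop("canonical_triplets: self-pairs (drug_a == drug_b) are invalid",
         call. = FALSE)
  }
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  if ("label" %in% names(triplets)) {
    label <- as.integer(triplets$label)
    if (!all(label %in% c(0L, 1L))) {
      stop("canonical_triplets: labels must be 0 or 1", call. = FALSE)
    }
    stratum <- as.character(label)
  } else if ("type" %in% names(triplets)) {
    label <- rep(1L, nrow(triplets))
    stratum <- as.character(triplets$type)
  } else {
    stop("canonical_triplets: need a 'label' or 'type' column", call. = FALSE)
  }
  out <- data.frame(drug_a = a, drug_b = b, label = label, stratum = stratum,
                    stringsAsFactors = FALSE)
  out[!duplicated(paste(out$drug_a, out$drug_b)), , drop = FALSE]
}

#' Warm-start stratified k-fold split
#'
#' Partitions the triplets into `k` folds, stratified so each fold's class
#' (or interaction-type) composition matches the global one within one item
#' per stratum. Deterministic given `seed`.
#'
#' @param triplets Canonical triplet table (see [canonical_triplets()]).
#' @param k Fold count (>= 2).
#' @param seed Integer RNG seed.
#' @return A `split_plan` with `mode = "warm"`, the per-triplet `fold`
#'   assignment (1..k) and the input table.
#' @export
make_warm_split <- function(triplets, k = 5L, seed = 1L) {
  triplets <- canonical_triplets(triplets)
  if (k < 2L) stop("make_warm_split: k must be >= 2", call. = FALSE)
  tab <- table(triplets$stratum)
  if (any(tab < k)) {
    stop(sprintf(
      "make_warm_split: stratum '%s' has %d members, fewer than k = %d",
      names(tab)[which.min(tab)], min(tab), k), call. = FALSE)
  }
  set.seed(seed)
  fold <- integer(nrow(triplets))
  for (s in unique(triplets$stratum)) {
    idx <- which(triplets$stratum == s)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  structure(list(mode = "warm", k = as.integer(k), seed = as.integer(seed),
                 fold = fold, triplets = triplets, negatives = NULL),
            class = "split_plan")
}

#' Cold-start drug-disjoint split
#'
#' Samples `round(frac_new * |G|)` drugs uniformly as the "new" set G_new.
#' Training triplets have both drugs in G_old. In `strict` mode (default)
#' test triplets have both drugs in G_new; in `one_new` mode a test triplet
#' needs at least one new drug. Triplets matching neither rule are dropped
#' and counted.
#'
#' @param triplets Canonical triplet table.
#' @param drugs Character vector of all drug ids (the drug universe G).
#' @param frac_new Fraction of drugs held out as new (0 < frac_new < 1).
#' @param seed Integer RNG seed.
#' @param test_mode `"strict"` or `"one_new"`.
#' @return A `split_plan` with `mode = "cold"`, the `new_drugs` / `old_drugs`
#'   sets, `train_idx` / `test_idx` row indices and the dropped count.
#' @export
make_cold_split <- function(triplets, drugs, frac_new = 0.2, seed = 1L,
                            test_mode = c("strict", "one_new")) {
  test_mode <- match.arg(test_mode)
  triplets <- canonical_triplets(triplets)
  drugs <- unique(as.character(drugs))
  if (frac_new <= 0 || frac_new >= 1) {
    stop("make_cold_split: frac_new must lie in (0, 1)", call. = FALSE)
  }
  n_new <- round(frac_new * length(drugs))
  if (n_new < 1L || n_new >= length(drugs)) {
    stop("make_cold_split: frac_new leaves an empty drug set", call. = FALSE)
  }
  set.seed(seed)
  new_drugs <- sort(sample(drugs, n_new))
  old_drugs <- sort(setdiff(drugs, new_drugs))
  a_new <- triplets$drug_a %in% new_drugs
  b_new <- triplets$drug_b %in% new_drugs
  train_idx <- which(!a_new & !b_new)
  test_idx <- if (test_mode == "strict") which(a_new & b_new) else
    which(a_new | b_new)
  n_dropped <- nrow(triplets) - length(train_idx) - length(test_idx)
  if (length(train_idx) == 0L || length(test_idx) == 0L) {
    stop(sprintf(
      "make_cold_split: empty %s set (|G_new| = %d, %d triplets, mode %s)",
      if (length(train_idx) == 0L) "training" else "test",
      n_new, nrow(triplets), test_mode), call. = FALSE)
  }
  structure(list(mode = "cold", test_mode = test_mode, seed = as.integer(seed),
                 frac_new = frac_new, new_drugs = new_drugs,
                 old_drugs = old_drugs, train_idx = train_idx,
                 test_idx = test_idx, n_dropped = n_dropped,
                 triplets = triplets, negatives = NULL),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  if (x$mode == "warm") {
    cat(sprintf("<split_plan> warm, k = %d folds over %d triplets (seed %d)\n",
                x$k, nrow(x$triplets), x$seed))
  } else {
    cat(sprintf(
      "<split_plan> cold (%s), %d new / %d old drugs; %d train, %d test, %d dropped (seed %d)\n",
      x$test_mode, length(x$new_drugs), length(x$old_drugs),
      length(x$train_idx), length(x$test_idx), x$n_dropped, x$seed))
  }
  invisible(x)
}

#' Sample negative drug pairs
#'
#' Draws `round(ratio * nrow(positives))` unordered pairs uniformly without
#' replacement from the pairs of `drug_pool`, excluding every positive pair
#' and all self-pairs, labelled 0.
#'
#' @param positives data.frame with `drug_a`, `drug_b` (canonical order not
#'   required).
#' @param drug_pool Character vector of candidate drugs (>= 2).
#' @param ratio Negatives per positive (default 1).
#' @param seed Integer RNG seed.
#' @return data.frame `drug_a`, `drug_b`, `label = 0` in canonical order.
#' @export
sample_negatives <- function(positives, drug_pool, ratio = 1, seed = 1L) {
  drug_pool <- sort(unique(as.character(drug_pool)))
  n <- length(drug_pool)
  if (n < 2L) stop("sample_negatives: drug_pool needs >= 2 drugs", call. = FALSE)
  if (ratio <= 0) stop("sample_negatives: ratio must be positive", call. = FALSE)
  want <- round(ratio * nrow(positives))
  a <- pmin(as.character(positives$drug_a), as.character(positives$drug_b))
  b <- pmax(as.character(positives$drug_a), as.character(positives$drug_b))
  pos_key <- paste(a, b, sep = "\r")
  total <- n * (n - 1) / 2
  set.seed(seed)
  if (total <= 2e6) {
    ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    key <- paste(drug_pool[ij[, 1]], drug_pool[ij[, 2]], sep = "\r")
    avail <- which(!key %in% pos_key)
    if (length(avail) < want) {
      stop(sprintf(
        "sample_negatives: requested %d negatives but only %d non-positive pairs exist",
        want, length(avail)), call. = FALSE)
    }
    pick <- avail[sample.int(length(avail), want)]
    out <- data.frame(drug_a = drug_pool[ij[pick, 1]],
                      drug_b = drug_pool[ij[pick, 2]],
                      label = 0L, stringsAsFactors = FALSE)
  } else {
    chosen <- character(0)
    guard <- 0L
    while (length(chosen) < want) {
      guard <- guard + 1L
      if (guard > 200L) {
        stop("sample_negatives: sampling did not converge", call. = FALSE)
      }
      m <- max(64L, 2L * (want - length(chosen)))
      i <- sample.int(n, m, replace = TRUE)
      j <- sample.int(n, m, replace = TRUE)
      ok <- i != j
      ka <- pmin(drug_pool[i[ok]], drug_pool[j[ok]])
      kb <- pmax(drug_pool[i[ok]], drug_pool[j[ok]])
      key <- paste(ka, kb, sep = "\r")
      key <- key[!key %in% pos_key]
      chosen <- unique(c(chosen, key))
    }
    chosen <- chosen[seq_len(want)]
    parts <- strsplit(chosen, "\r", fixed = TRUE)
    out <- data.frame(drug_a = vapply(parts, `[`, "", 1L),
                      drug_b = vapply(parts, `[`, "", 2L),
                      label = 0L, stringsAsFactors = FALSE)
  }
  swap <- out$drug_a > out$drug_b
  tmp <- out$drug_a[swap]; out$drug_a[swap] <- out$drug_b[swap]
  out$drug_b[swap] <- tmp
  out
}

#' Add per-split sampled negatives to a positives-only cold split
#'
#' Negatives are generated separately within the training and test drug
#' pools: training negatives from G_old pairs, test negatives from G_new
#' pairs (strict mode) or pairs touching G_new (one_new mode). The plan
#' records the provenance of every negative.
#'
#' @param plan A cold `split_plan` built from positives only.
#' @param ratio Negatives per positive in each split.
#' @param seed Integer RNG seed.
#' @return The plan with a `negatives` data.frame
#'   (`drug_a`, `drug_b`, `label`, `split`).
#' @export
add_split_negatives <- function(plan, ratio = 1, seed = 1L) {
  stopifnot(inherits(plan, "split_plan"), plan$mode == "cold")
  tr <- plan$triplets[plan$train_idx, , drop = FALSE]
  te <- plan$triplets[plan$test_idx, , drop = FALSE]
  tr_pos <- tr[tr$label == 1L, , drop = FALSE]
  te_pos <- te[te$label == 1L, , drop = FALSE]
  neg_tr <- sample_negatives(tr_pos, plan$old_drugs, ratio, seed)
  neg_te <- sample_negatives(te_pos, plan$new_drugs, ratio, seed + 1L)
  neg_tr$split <- "train"
  neg_te$split <- "test"
  plan$negatives <- rbind(neg_tr, neg_te)
  plan
}

# --- metrics ------------------------------------------------------------------

#' Area under the ROC curve (rank formulation)
#'
#' The probability that a uniformly chosen positive outscores a uniformly
#' chosen negative, with ties credited 0.5.
#'
#' @param labels 0/1 labels (both classes present).
#' @param scores Numeric scores.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(labels, scores) {
  if (length(labels) != length(scores)) {
    stop("auroc: length mismatch", call. = FALSE)
  }
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0L || nn == 0L) {
    stop("auroc: both classes must be present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve (step-wise, no interpolation)
#'
#' Scores are swept from high to low with tied scores processed as one block;
#' the area is the sum of recall increments times the precision at each
#' block.
#'
#' @inheritParams auroc
#' @return AUPRC in `(0, 1]`.
#' @export
auprc <- function(labels, scores) {
  if (length(labels) != length(scores)) {
    stop("auprc: length mismatch", call. = FALSE)
  }
  P <- sum(labels == 1)
  if (P == 0L || P == length(labels)) {
    stop("auprc: both classes must be present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  blocks <- cumsum(!duplicated(sc))
  tp <- cumsum(lab)
  npred <- seq_along(lab)
  last <- !duplicated(blocks, fromLast = TRUE)   # end of each tie block
  tp_b <- tp[last]; npred_b <- npred[last]
  rec <- tp_b / P
  prec <- tp_b / npred_b
  sum(diff(c(0, rec)) * prec)
}

#' Confusion-matrix metrics at a decision threshold
#'
#' Scores at or above the threshold are predicted positive. Recall,
#' accuracy, precision and F1 follow the standard confusion-count formulas;
#' a metric with a zero denominator is reported as 0 and flagged.
#'
#' @param labels 0/1 labels.
#' @param scores Probabilities in `[0, 1]`.
#' @param threshold Decision threshold (default 0.5).
#' @return A `metrics_report`: confusion counts, recall / accuracy /
#'   precision / f1 / auroc / auprc, the threshold, and `flags` naming any
#'   zero-denominator metrics.
#' @export
compute_metrics <- function(labels, scores, threshold = 0.5) {
  if (length(labels) != length(scores) || length(labels) < 1L) {
    stop("compute_metrics: labels and scores must have equal positive length",
         call. = FALSE)
  }
  if (any(scores < 0 | scores > 1)) {
    stop("compute_metrics: scores must lie in [0, 1]", call. = FALSE)
  }
  pred <- as.integer(scores >= threshold)
  TP <- sum(pred == 1 & labels == 1)
  FN <- sum(pred == 0 & labels == 1)
  FP <- sum(pred == 1 & labels == 0)
  TN <- sum(pred == 0 & labels == 0)
  flags <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) {
      flags <<- c(flags, name)
      return(0)
    }
    num / den
  }
  recall <- safe(TP, TP + FN, "recall")
  precision <- safe(TP, TP + FP, "precision")
  accuracy <- (TP + TN) / length(labels)
  f1 <- if (precision + recall == 0) {
    flags <- c(flags, "f1"); 0
  } else 2 * precision * recall / (precision + recall)
  both <- length(unique(labels)) == 2L
  structure(list(TP = TP, FN = FN, FP = FP, TN = TN,
                 recall = recall, accuracy = accuracy, precision = precision,
                 f1 = f1,
                 auroc = if (both) auroc(labels, scores) else NA_real_,
                 auprc = if (both) auprc(labels, scores) else NA_real_,
                 threshold = threshold, n = length(labels), flags = flags),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> n=%d @%.2f | TP=%d FN=%d FP=%d TN=%d | ACC=%.4f AUROC=%.4f AUPRC=%.4f F1=%.4f P=%.4f R=%.4f%s\n",
    x$n, x$threshold, x$TP, x$FN, x$FP, x$TN, x$accuracy, x$auroc, x$auprc,
    x$f1, x$precision, x$recall,
    if (length(x$flags)) paste0(" [zero-denominator: ",
                                paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' Compare models across runs (Kruskal-Wallis + Mann-Whitney + Holm)
#'
#' Runs the Kruskal-Wallis omnibus test over per-model metric samples; if
#' significant at `alpha`, all pairwise two-sided Mann-Whitney U tests are
#' performed (exact for small tie-free samples, normal approximation with
#' continuity correction otherwise) and Holm-Bonferroni adjusted.
#'
#' @param samples Named list of numeric vectors (one per model, each >= 2
#'   observations).
#' @param alpha Omnibus significance level (default 0.05).
#' @return List with `omnibus` (statistic, df, p.value), `significant`, and
#'   `pairwise` (data.frame with U, raw and Holm-adjusted p-values; `NULL`
#'   when the omnibus is not significant).
#' @export
stat_compare <- function(samples, alpha = 0.05) {
  if (!is.list(samples) || length(samples) < 2L) {
    stop("stat_compare: need >= 2 groups", call. = FALSE)
  }
  if (any(vapply(samples, length, 1L) < 2L)) {
    stop("stat_compare: each group needs >= 2 observations", call. = FALSE)
  }
  if (is.null(names(samples))) names(samples) <- paste0("g", seq_along(samples))
  values <- unlist(samples, use.names = FALSE)
  if (length(unique(values)) == 1L) {
    stop("stat_compare: all observations identical; ranks are degenerate",
         call. = FALSE)
  }
  groups <- factor(rep(names(samples), vapply(samples, length, 1L)),
                   levels = names(samples))
  kw <- stats::kruskal.test(values, groups)
  significant <- kw$p.value < alpha
  pairwise <- NULL
  if (significant) {
    nms <- names(samples)
    combs <- utils::combn(nms, 2L)
    rows <- vector("list", ncol(combs))
    for (c_ in seq_len(ncol(combs))) {
      g1 <- combs[1L, c_]; g2 <- combs[2L, c_]
      wt <- suppressWarnings(stats::wilcox.test(samples[[g1]], samples[[g2]],
                                                alternative = "two.sided",
                                                correct = TRUE))
      rows[[c_]] <- data.frame(group1 = g1, group2 = g2,
                               U = unname(wt$statistic),
                               p_raw = wt$p.value, stringsAsFactors = FALSE)
    }
    pairwise <- do.call(rbind, rows)
    pairwise$p_adj <- stats::p.adjust(pairwise$p_raw, method = "holm")
  }
  list(omnibus = list(statistic = unname(kw$statistic),
                      df = unname(kw$parameter), p.value = kw$p.value),
       alpha = alpha, significant = significant, pairwise = pairwise)
}
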