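# Splits, negative sampling, metrics and statistical comparison.

test_that("triplets are canonicalised symmetrically", {
  tri <- data.frame(drug_a = c("b", "a", "b"), drug_b = c("a", "c", "a"),
                    label = c(1, 0, 1))
  ct <- canonical_triplets(tri)
  expect_equal(nrow(ct), 2L)               # (b,a) and (a,b) collapse
  expect_true(all(ct$drug_a < ct$drug_b))
  expect_error(canonical_triplets(data.frame(drug_a = "a", drug_b = "a",
                                             label = 1)), "self-pairs")
  ty <- canonical_triplets(data.frame(drug_a = "a", drug_b = "b",
                                      type = "inhibition"))
  expect_equal(ty$label, 1L)
  expect_equal(ty$stratum, "inhibition")
})

test_that("warm splits are stratified partitions, deterministic in the seed", {
  tri <- data.frame(drug_a = sprintf("a%02d", 1:10),
                    drug_b = sprintf("b%02d", 1:10),
                    label = rep(c(0L, 1L), each = 5))
  sp <- make_warm_split(tri, k = 5, seed = 2)
  expect_equal(as.integer(table(sp$fold)), rep(2L, 5))
  for (f in 1:5) {
    expect_equal(sum(sp$triplets$label[sp$fold == f]), 1L)  # 1 positive each
  }
  expect_identical(make_warm_split(tri, k = 5, seed = 2)$fold, sp$fold)
  expect_false(identical(make_warm_split(tri, k = 5, seed = 3)$fold, sp$fold))
  expect_error(make_warm_split(tri, k = 6, seed = 1), "fewer than k")

  # exhaustive union/disjointness on a larger fixture
  set.seed(8)
  big <- data.frame(drug_a = sprintf("x%03d", 1:50),
                    drug_b = sprintf("y%03d", 1:50),
                    label = rbinom(50, 1, 0.4))
  spb <- make_warm_split(big, k = 5, seed = 4)
  expect_setequal(unlist(lapply(1:5, function(f) which(spb$fold == f))), 1:50)
  frac <- mean(spb$triplets$label)
  for (f in 1:5) {
    idx <- spb$fold == f
    expect_lte(abs(sum(spb$triplets$label[idx]) - frac * sum(idx)), 1)
  }
})

test_that("cold splits are drug-disjoint with the stated sizes", {
  drugs <- sprintf("d%02d", 1:10)
  grid <- t(utils::combn(drugs, 2))       # dense pair table: every new-drug
  tri <- data.frame(drug_a = grid[, 1],   # subset has test pairs
                    drug_b = grid[, 2], label = 1L)
  sp <- make_cold_split(tri, drugs, frac_new = 0.2, seed = 5)
  expect_length(sp$new_drugs, 2L)
  expect_length(intersect(sp$new_drugs, sp$old_drugs), 0L)
  expect_setequal(c(sp$new_drugs, sp$old_drugs), drugs)

  # a mixed old/new triplet is excluded from train always, and from test in
  # strict mode but not in one_new mode
  six <- c("a", "b", "c", "d", "e", "f")
  tri6 <- data.frame(drug_a = c("a", "a", "e"), drug_b = c("b", "e", "f"),
                     label = 1L)
  for (seed in 1:50) {
    spl <- tryCatch(make_cold_split(tri6, six, 1 / 3, seed = seed),
                    error = function(e) NULL)
    if (is.null(spl)) next
    mixed <- (spl$triplets$drug_a %in% spl$new_drugs) !=
      (spl$triplets$drug_b %in% spl$new_drugs)
    expect_false(any(which(mixed) %in% spl$train_idx))
    expect_false(any(which(mixed) %in% spl$test_idx))
    one <- make_cold_split(tri6, six, 1 / 3, seed = seed,
                           test_mode = "one_new")
    expect_true(all(which(mixed) %in% one$test_idx))
  }
})

test_that("cold strict splits never share a drug between train and test", {
  ds <- synth_dataset(n_drugs = 40, n_pairs = 250, noise = 0.1, seed = 17)
  for (seed in 1:100) {
    sp <- make_cold_split(ds$triplets, ds$drugs$drug_id, 0.2, seed = seed)
    tr <- sp$triplets[sp$train_idx, ]
    te <- sp$triplets[sp$test_idx, ]
    expect_length(intersect(unique(c(tr$drug_a, tr$drug_b)),
                            unique(c(te$drug_a, te$drug_b))), 0L)
    expect_length(sp$new_drugs, round(0.2 * 40))
  }
})

test_that("negative sampling avoids positives, self-pairs and repeats", {
  pool <- sprintf("d%02d", 1:12)
  pos <- data.frame(drug_a = pool[1:10], drug_b = pool[c(2:10, 1)])
  neg <- sample_negatives(pos, pool, ratio = 1, seed = 3)
  expect_equal(nrow(neg), 10L)
  expect_true(all(neg$label == 0L))
  expect_true(all(neg$drug_a < neg$drug_b))
  expect_false(any(duplicated(paste(neg$drug_a, neg$drug_b))))
  pos_key <- paste(pmin(pos$drug_a, pos$drug_b), pmax(pos$drug_a, pos$drug_b))
  expect_false(any(paste(neg$drug_a, neg$drug_b) %in% pos_key))
  expect_identical(sample_negatives(pos, pool, 1, seed = 3), neg)
  expect_error(sample_negatives(pos, pool[1:3], ratio = 10, seed = 1),
               "only .* non-positive pairs")
})

test_that("per-split cold negatives respect the split drug pools", {
  ds <- synth_dataset(n_drugs = 40, n_pairs = 200, noise = 0, seed = 31)
  pos_only <- ds$triplets[ds$triplets$label == 1L, ]
  sp <- make_cold_split(pos_only, ds$drugs$drug_id, 0.25, seed = 2)
  sp <- add_split_negatives(sp, ratio = 1, seed = 9)
  ntr <- sp$negatives[sp$negatives$split == "train", ]
  nte <- sp$negatives[sp$negatives$split == "test", ]
  expect_true(all(c(ntr$drug_a, ntr$drug_b) %in% sp$old_drugs))
  expect_true(all(c(nte$drug_a, nte$drug_b) %in% sp$new_drugs))
})

test_that("confusion metrics reproduce the hand-computed report", {
  labels <- c(rep(1, 10), rep(0, 10))
  scores <- c(rep(0.9, 8), rep(0.1, 2),   # TP = 8, FN = 2
              rep(0.9, 1), rep(0.1, 9))   # FP = 1, TN = 9
  m <- compute_metrics(labels, scores, threshold = 0.5)
  expect_equal(c(m$TP, m$FN, m$FP, m$TN), c(8, 2, 1, 9))
  expect_equal(m$TP + m$FN + m$FP + m$TN, m$n)
  expect_equal(m$recall, 0.8)
  expect_equal(m$precision, 8 / 9)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$f1, 2 * (8 / 9) * 0.8 / (8 / 9 + 0.8), tolerance = 1e-12)

  perfect <- compute_metrics(labels, labels, threshold = 0.5)
  expect_equal(c(perfect$recall, perfect$accuracy, perfect$precision,
                 perfect$f1), rep(1, 4))

  allneg <- compute_metrics(labels, rep(0, 20), threshold = 0.5)
  expect_equal(allneg$precision, 0)
  expect_true("precision" %in% allneg$flags)
})

test_that("AUROC and AUPRC match their definitions", {
  expect_equal(auroc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(auroc(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  expect_error(auroc(c(1, 1), c(0.1, 0.2)), "both classes")
  set.seed(31)
  for (r in 1:50) {
    n <- sample(4:12, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.5))
    scores <- sample(seq(0, 1, 0.25), n, replace = TRUE)
    expect_equal(auroc(labels, scores), auroc_pair_oracle(labels, scores))
  }
  # step-wise AUPRC, hand-evaluated: precision 1 at recall 1/2, 2/3 at recall 1
  expect_equal(auprc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.6)),
               0.5 * 1 + 0.5 * (2 / 3))
  expect_equal(auprc(c(1, 1, 0), c(0.9, 0.8, 0.1)), 1)
})

test_that("model comparison wires exact Mann-Whitney and Holm correctly", {
  res <- stat_compare(list(m1 = c(1, 2, 3), m2 = c(4, 5, 6)), alpha = 0.06)
  expect_true(res$significant)
  expect_equal(res$pairwise$U, 0)
  expect_equal(res$pairwise$p_raw, 0.1)    # exact two-sided 2 * 1/20

  set.seed(41)
  for (r in 1:10) {
    n1 <- sample(3:5, 1); n2 <- sample(3:5, 1)
    x <- sample(seq(1, 40), n1); y <- sample(seq(41, 80), n2) + 0.5
    w <- stats::wilcox.test(x, y, alternative = "two.sided")
    expect_equal(w$p.value, mw_exact_oracle(x, y), tolerance = 1e-12)
  }

  g1 <- c(0.95, 0.96, 0.94, 0.97)
  g2 <- c(0.80, 0.82, 0.81, 0.83)
  g3 <- c(0.60, 0.62, 0.61, 0.63)
  res3 <- stat_compare(list(a = g1, b = g2, c = g3))
  expect_true(res3$significant)
  expect_lt(res3$omnibus$p.value, 0.05)
  expect_equal(nrow(res3$pairwise), 3L)
  ord <- order(res3$pairwise$p_raw)
  expect_true(all(diff(res3$pairwise$p_adj[ord]) >= -1e-12))
  expect_true(all(res3$pairwise$p_adj <= 1))
  expect_true(all(res3$pairwise$p_adj >= res3$pairwise$p_raw))

  expect_error(stat_compare(list(a = c(1, 1), b = c(1, 1))), "identical")
  expect_error(stat_compare(list(a = 1:3)), ">= 2 groups")
})
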