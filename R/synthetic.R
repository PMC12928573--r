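# Synthetic benchmark generator: molecules assembled from a small fragment
# library (joined by single bonds at attachment positions, with every
# junction bond BRICS-cleavable so that planted fragments align with
# pharmacophore subgraphs), plus a symmetric interaction-label table driven
# by a plantable fragment-pair rule with label noise.

#' Default fragment library
#'
#' Chemically valid SMILES fragments with one attachment position at each
#' end (`last_attach` is the 0-based atom index that bonds to the next
#' fragment; the first atom bonds to the previous one). Two designated
#' signal fragments, a pyridine ring (`f1`) and a piperidine ring (`f2`),
#' are only inserted when a molecule is flagged to carry them. Heteroatom
#' junction fragments (`ether`, `amine`) are restricted to interior
#' positions.
#'
#' @return A `fragment_library` data.frame.
#' @export
fragment_library <- function() {
  lib <- data.frame(
    name = c("ethyl", "propyl", "isopropyl", "methoxymethyl", "benzene",
             "cyclohexyl", "acetyl", "amine", "ether", "pyridine",
             "piperidine"),
    smiles = c("CC", "CCC", "CC(C)", "COC", "c1ccccc1",
               "C1CCCCC1", "CC(=O)", "N(C)", "O", "c1ccncc1",
               "C1CCNCC1"),
    n_atoms = c(2L, 3L, 3L, 3L, 6L, 6L, 3L, 2L, 1L, 6L, 6L),
    last_attach = c(1L, 2L, 1L, 2L, 5L, 5L, 1L, 0L, 0L, 5L, 5L),
    interior_only = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                      TRUE, TRUE, FALSE, FALSE),
    hetero_junction = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                        TRUE, TRUE, FALSE, FALSE),
    signal = c(rep(FALSE, 9L), TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  for (s in lib$smiles) parse_smiles(s)  # every fragment must parse
  class(lib) <- c("fragment_library", "data.frame")
  lib
}

# Assemble one molecule from a fragment-name sequence by string
# concatenation (each fragment's ring labels close internally, so digits can
# be reused). Returns list(smiles, junctions), junctions = 0-based atom-index
# pairs of the assembly bonds.
.assemble <- function(frag_names, lib) {
  rows <- lib[match(frag_names, lib$name), , drop = FALSE]
  smiles <- paste(rows$smiles, collapse = "")
  offsets <- cumsum(c(0L, rows$n_atoms[-nrow(rows)]))
  junctions <- NULL
  if (nrow(rows) > 1L) {
    junctions <- cbind(offsets[-nrow(rows)] + rows$last_attach[-nrow(rows)],
                       offsets[-1L])
  }
  list(smiles = smiles, junctions = junctions)
}

# Is every assembly junction among the BRICS-cleaved bonds?
.junctions_cleavable <- function(smiles, junctions) {
  mol <- parse_smiles(smiles)
  cl <- find_brics_bonds(mol)
  if (is.null(junctions)) return(TRUE)
  key <- paste(pmin(mol$bonds$i[cl], mol$bonds$j[cl]),
               pmax(mol$bonds$i[cl], mol$bonds$j[cl]))
  want <- paste(pmin(junctions[, 1], junctions[, 2]),
                pmax(junctions[, 1], junctions[, 2]))
  all(want %in% key)
}

# Sample one fragment sequence honouring placement rules: interior-only
# fragments never at the ends, no two heteroatom-junction fragments adjacent,
# and forced inclusion of the requested signal fragments.
.sample_sequence <- function(n_frag, with_f1, with_f2, lib) {
  backbone <- lib$name[!lib$signal]
  seq_names <- sample(backbone, n_frag, replace = TRUE)
  forced <- c(if (with_f1) "pyridine", if (with_f2) "piperidine")
  if (length(forced) > 0L) {
    slots <- sample.int(n_frag, length(forced))
    seq_names[slots] <- forced
  }
  hj <- lib$hetero_junction[match(seq_names, lib$name)]
  io <- lib$interior_only[match(seq_names, lib$name)]
  if (io[1L] || io[n_frag]) return(NULL)
  if (n_frag > 1L && any(hj[-1L] & hj[-n_frag])) return(NULL)
  seq_names
}

#' Generate synthetic drug molecules
#'
#' Each molecule is assembled from `n_frag_range[1]`-`n_frag_range[2]`
#' library fragments joined by single bonds; assemblies whose junction bonds
#' are not all BRICS-cleavable are resampled, so planted fragments coincide
#' with pharmacophore subgraphs. A fraction `frac_f1` of molecules carries
#' the first signal fragment and `frac_f2` the second (independent flags).
#' Deterministic given `seed`.
#'
#' @param n Number of molecules (>= 2).
#' @param seed Integer RNG seed.
#' @param library A [fragment_library()].
#' @param frac_f1,frac_f2 Probability that a molecule carries each signal
#'   fragment (defaults 0.55, which balances the pair rule's positive rate).
#' @param n_frag_range Length-2 integer range of fragments per molecule.
#' @return data.frame `drug_id`, `smiles`, `has_f1`, `has_f2` with the
#'   fragment composition of every molecule in `attr(, "composition")`.
#' @export
gen_molecules <- function(n, seed = 1L, library = fragment_library(),
                          frac_f1 = 0.55, frac_f2 = 0.55,
                          n_frag_range = c(2L, 4L)) {
  if (n < 2L) stop("gen_molecules: n must be >= 2", call. = FALSE)
  set.seed(seed)
  smiles <- character(n)
  has_f1 <- stats::runif(n) < frac_f1
  has_f2 <- stats::runif(n) < frac_f2
  composition <- vector("list", n)
  seen <- character(0)
  for (m in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(200L)) {
      n_frag <- sample(seq.int(n_frag_range[1L], n_frag_range[2L]), 1L)
      n_sig <- has_f1[m] + has_f2[m]
      if (n_frag < n_sig) n_frag <- n_sig
      sq <- .sample_sequence(n_frag, has_f1[m], has_f2[m], library)
      if (is.null(sq)) next
      asm <- .assemble(sq, library)
      if (asm$smiles %in% seen) next
      if (!.junctions_cleavable(asm$smiles, asm$junctions)) next
      smiles[m] <- asm$smiles
      composition[[m]] <- sq
      seen <- c(seen, asm$smiles)
      ok <- TRUE
      break
    }
    if (!ok) {
      stop("gen_molecules: could not assemble a valid distinct molecule",
           call. = FALSE)  # never expected with the default library
    }
  }
  out <- data.frame(drug_id = sprintf("D%04d", seq_len(n)), smiles = smiles,
                    has_f1 = has_f1, has_f2 = has_f2, stringsAsFactors = FALSE)
  attr(out, "composition") <- stats::setNames(composition, out$drug_id)
  out
}

#' Generate a symmetric DDI label table from a fragment-pair rule
#'
#' The clean label of pair (A, B) is 1 iff (A carries `f1` and B carries
#' `f2`) or (A carries `f2` and B carries `f1`) -- symmetric by construction.
#' Each label is then independently flipped with probability `noise`. The
#' clean labels and flip mask are recorded as attributes (the generation
#' ground truth).
#'
#' @param drugs Output of [gen_molecules()] (needs `has_f1`, `has_f2`).
#' @param noise Flip probability, `0 <= noise < 0.5`.
#' @param n_pairs Number of distinct unordered pairs to sample.
#' @param seed Integer RNG seed.
#' @return data.frame `drug_a`, `drug_b`, `label` (canonical pair order),
#'   with attributes `clean_label` and `flipped`.
#' @export
gen_ddi_labels <- function(drugs, noise = 0.1, n_pairs, seed = 1L) {
  stopifnot(all(c("drug_id", "has_f1", "has_f2") %in% names(drugs)))
  if (noise < 0 || noise >= 0.5) {
    stop("gen_ddi_labels: noise must lie in [0, 0.5)", call. = FALSE)
  }
  n <- nrow(drugs)
  total <- n * (n - 1) / 2
  if (n_pairs > total) {
    stop(sprintf("gen_ddi_labels: n_pairs = %d exceeds the %d available pairs",
                 n_pairs, total), call. = FALSE)
  }
  if (!any(drugs$has_f1) || !any(drugs$has_f2)) {
    warning("gen_ddi_labels: a rule fragment is absent from the pool; all clean labels are 0",
            call. = FALSE)
  }
  set.seed(seed)
  pick <- sample.int(total, n_pairs)
  # map linear upper-triangle index -> (i, j), i < j
  j <- ceiling((1 + sqrt(1 + 8 * pick)) / 2)
  i <- pick - (j - 1) * (j - 2) / 2
  a <- drugs$drug_id[i]; b <- drugs$drug_id[j]
  clean <- as.integer((drugs$has_f1[i] & drugs$has_f2[j]) |
                        (drugs$has_f2[i] & drugs$has_f1[j]))
  flip <- stats::runif(n_pairs) < noise
  label <- ifelse(flip, 1L - clean, clean)
  out <- data.frame(drug_a = pmin(a, b), drug_b = pmax(a, b),
                    label = as.integer(label), stringsAsFactors = FALSE)
  attr(out, "clean_label") <- clean
  attr(out, "flipped") <- flip
  out
}

#' Generate a complete synthetic DDI benchmark
#'
#' @param n_drugs Number of molecules (default 300).
#' @param n_pairs Number of labelled pairs (default 3000).
#' @param noise Label flip probability (default 0.1).
#' @param seed Integer RNG seed.
#' @param ... Passed to [gen_molecules()].
#' @return List with `drugs`, `triplets`, and `truth` (rule fragments, noise,
#'   seed, clean labels, flip mask, per-drug composition).
#' @export
synth_dataset <- function(n_drugs = 300L, n_pairs = 3000L, noise = 0.1,
                          seed = 7L, ...) {
  drugs <- gen_molecules(n_drugs, seed = seed, ...)
  triplets <- gen_ddi_labels(drugs, noise = noise, n_pairs = n_pairs,
                             seed = seed + 1L)
  list(drugs = drugs, triplets = triplets,
       truth = list(f1 = "pyridine", f2 = "piperidine", noise = noise,
                    seed = seed,
                    clean_label = attr(triplets, "clean_label"),
                    flipped = attr(triplets, "flipped"),
                    composition = attr(drugs, "composition")))
}

#' Fragment-presence logistic baseline
#'
#' A reference classifier establishing that the planted pair signal is
#' recoverable before any representation learning: pair features are the
#' symmetrized fragment-presence indicators and their pairwise products
#' (`1[A has f] + 1[B has f]` and the symmetric cross products), fed to a
#' logistic regression trained on the (noisy) training labels of a split.
#'
#' @param dataset A [synth_dataset()] result.
#' @param split A `split_plan` over `dataset$triplets`.
#' @param test_fold Warm-mode test fold.
#' @param against `"noisy"` scores the observed test labels; `"clean"`
#'   scores the recorded noise-free rule labels (signal recovery).
#' @return List with the test `auroc` and the fitted `glm`.
#' @export
fragment_baseline <- function(dataset, split, test_fold = 1L,
                              against = c("clean", "noisy")) {
  against <- match.arg(against)
  comp <- dataset$truth$composition
  frag_names <- sort(unique(unlist(comp)))
  ind <- t(vapply(comp, function(fr) as.numeric(frag_names %in% fr),
                  numeric(length(frag_names))))
  colnames(ind) <- frag_names

  featurize <- function(tri) {
    A <- ind[tri$drug_a, , drop = FALSE]
    B <- ind[tri$drug_b, , drop = FALSE]
    X <- A + B
    inter <- list()
    for (f in seq_along(frag_names)) {
      for (g in f:length(frag_names)) {
        inter[[paste0("x", f, "_", g)]] <-
          A[, f] * B[, g] + A[, g] * B[, f]
      }
    }
    cbind(X, do.call(cbind, inter))
  }

  # clean labels are recorded per triplet row; track rows through the split
  tri <- split$triplets
  key_all <- paste(dataset$triplets$drug_a, dataset$triplets$drug_b)
  clean_of <- function(sub) {
    dataset$truth$clean_label[match(paste(sub$drug_a, sub$drug_b), key_all)]
  }
  sets <- .split_sets(split, test_fold, seed = split$seed)
  Xtr <- featurize(sets$train); Xte <- featurize(sets$test)
  df_tr <- data.frame(y = sets$train$label, Xtr)
  fit <- suppressWarnings(stats::glm(y ~ ., data = df_tr,
                                     family = stats::binomial()))
  scores <- suppressWarnings(
    stats::predict(fit, newdata = data.frame(Xte), type = "response"))
  y_te <- if (against == "clean") clean_of(sets$test) else sets$test$label
  list(auroc = auroc(y_te, scores), fit = fit)
}
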