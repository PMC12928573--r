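# One-hot featurization of pharmacophore subgraphs.

#' Atom/bond feature vocabulary
#'
#' The atom vocabulary keeps H, C, O, N in the leading slots and extends them
#' with the halogens and other elements common in small-molecule drugs, plus
#' two reserved slots: `OTHER` (any element outside the vocabulary) and
#' `ATTACH` (BRICS attachment pseudo-atoms). The bond vocabulary is
#' single/double/triple/aromatic.
#'
#' @param atom_symbols Ordered character vector of element symbols; `OTHER`
#'   and `ATTACH` are appended if absent.
#' @param bond_types Ordered character vector of bond types.
#' @return A `feature_vocab` object with `atom_symbols`, `bond_types`, and
#'   the feature widths `D_V` and `D_E`.
#' @export
feature_vocab <- function(atom_symbols = c("H", "C", "O", "N", "S", "P",
                                           "F", "Cl", "Br", "I"),
                          bond_types = c("single", "double", "triple",
                                         "aromatic")) {
  atom_symbols <- as.character(atom_symbols)
  if (!"OTHER" %in% atom_symbols) atom_symbols <- c(atom_symbols, "OTHER")
  if (!"ATTACH" %in% atom_symbols) atom_symbols <- c(atom_symbols, "ATTACH")
  if (anyDuplicated(atom_symbols) || anyDuplicated(bond_types)) {
    stop("feature_vocab: vocabulary entries must be unique", call. = FALSE)
  }
  structure(list(atom_symbols = atom_symbols,
                 bond_types = as.character(bond_types),
                 D_V = length(atom_symbols),
                 D_E = length(bond_types)),
            class = "feature_vocab")
}

#' One-hot featurize a pharmacophore subgraph
#'
#' Builds the node feature matrix `X_V` (one row per atom, one-hot over the
#' atom vocabulary; out-of-vocabulary elements map to `OTHER`, attachment
#' pseudo-atoms to `ATTACH`) and the edge feature matrix `X_E` (one row per
#' bond, one-hot over the bond-type vocabulary). Row order follows the
#' subgraph's atom/bond order.
#'
#' @param sub One pharmacophore from [brics_decompose()] (a list with `atoms`
#'   and `bonds` data.frames).
#' @param vocab A [feature_vocab()].
#' @return List with matrices `X_V` (`|V| x D_V`) and `X_E` (`|E| x D_E`;
#'   zero rows when the subgraph has no bonds).
#' @export
featurize_subgraph <- function(sub, vocab = feature_vocab()) {
  stopifnot(inherits(vocab, "feature_vocab"))
  atoms <- sub$atoms
  bonds <- sub$bonds
  if (is.null(atoms) || nrow(atoms) == 0L) {
    stop("featurize_subgraph: empty subgraph (|V| = 0) violates the N >= 1 invariant",
         call. = FALSE)
  }
  sym <- ifelse(atoms$is_attach, "ATTACH", atoms$symbol)
  col <- match(sym, vocab$atom_symbols)
  col[is.na(col)] <- match("OTHER", vocab$atom_symbols)
  X_V <- matrix(0, nrow = nrow(atoms), ncol = vocab$D_V,
                dimnames = list(NULL, vocab$atom_symbols))
  X_V[cbind(seq_len(nrow(atoms)), col)] <- 1

  X_E <- matrix(0, nrow = nrow(bonds), ncol = vocab$D_E,
                dimnames = list(NULL, vocab$bond_types))
  if (nrow(bonds) > 0L) {
    bcol <- match(bonds$order, vocab$bond_types)
    if (anyNA(bcol)) {
      stop(sprintf("featurize_subgraph: bond type(s) %s not in vocabulary",
                   paste(unique(bonds$order[is.na(bcol)]), collapse = ", ")),
           call. = FALSE)
    }
    X_E[cbind(seq_len(nrow(bonds)), bcol)] <- 1
  }
  list(X_V = X_V, X_E = X_E)
}

#' Parse, decompose and featurize a drug table
#'
#' Convenience wrapper running [parse_smiles()], [brics_decompose()] and
#' [featurize_subgraph()] over a drug table.
#'
#' @param drugs data.frame with columns `drug_id` and `smiles`.
#' @param vocab A [feature_vocab()].
#' @return Named list (by `drug_id`) of lists with the `decomposed_molecule`
#'   and `features` (per-pharmacophore `X_V`/`X_E`).
#' @export
prepare_drugs <- function(drugs, vocab = feature_vocab()) {
  stopifnot(is.data.frame(drugs), all(c("drug_id", "smiles") %in% names(drugs)))
  if (anyDuplicated(drugs$drug_id)) {
    stop("prepare_drugs: duplicate drug_id values", call. = FALSE)
  }
  out <- vector("list", nrow(drugs))
  names(out) <- drugs$drug_id
  for (r in seq_len(nrow(drugs))) {
    mol <- parse_smiles(drugs$smiles[r], drugs$drug_id[r])
    dec <- brics_decompose(mol)
    feats <- lapply(dec$pharmacophores, featurize_subgraph, vocab = vocab)
    out[[r]] <- list(decomposed = dec, features = feats)
  }
  out
}
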