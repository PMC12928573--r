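# Sequence-view encoder: a from-scratch BERT-style encoder over atom-level
# SMILES tokens. Each token is embedded, combined with a learned positional
# embedding, passed through a stack of self-attention layers (the same layer
# math as the graph view), and mean-pooled into the molecule embedding h_mol.
# No CLS token is added; pooling is an explicit mean over all tokens.

#' Build a SMILES token vocabulary
#'
#' Collects the distinct tokens of a SMILES corpus and prepends the reserved
#' `<unk>` token, to which unseen tokens map at encoding time.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector: the ordered token vocabulary (first entry
#'   `<unk>`).
#' @export
build_token_vocab <- function(smiles) {
  toks <- unique(unlist(lapply(smiles, tokenize_smiles)))
  c("<unk>", sort(toks))
}

#' Map a SMILES string to vocabulary token ids
#'
#' @param smiles SMILES string.
#' @param vocab Vocabulary from [build_token_vocab()].
#' @param max_len Maximum admissible length; longer sequences are an error
#'   (never silently truncated).
#' @return Integer vector of 1-based token ids.
#' @export
token_ids <- function(smiles, vocab, max_len = 256L) {
  toks <- tokenize_smiles(smiles)
  if (length(toks) > max_len) {
    stop(sprintf("token_ids: sequence of %d tokens exceeds max length %d",
                 length(toks), max_len), call. = FALSE)
  }
  ids <- match(toks, vocab)
  ids[is.na(ids)] <- 1L
  ids
}

#' Initialise sequence-view encoder parameters
#'
#' @param vocab_size Token vocabulary size.
#' @param d Embedding width (divisible by `heads`).
#' @param heads Attention heads.
#' @param layers Self-attention layers (`0` gives the degenerate
#'   embeddings-plus-positions encoder).
#' @param max_len Positional-table length.
#' @return Parameter tree of class `seq_encoder_params`.
#' @export
seq_encoder_params <- function(vocab_size, d = 64L, heads = 4L, layers = 2L,
                               max_len = 256L) {
  if (d %% heads != 0L) {
    stop(sprintf("seq_encoder_params: heads (%d) must divide d (%d)", heads, d),
         call. = FALSE)
  }
  p <- list(tok_emb = .glorot(vocab_size, d),
            pos_emb = .glorot(max_len, d),
            layers = lapply(seq_len(layers), function(l) .layer_params(d)))
  attr(p, "heads") <- heads
  attr(p, "d") <- d
  attr(p, "max_len") <- max_len
  class(p) <- c("seq_encoder_params", "list")
  p
}

#' Encode a token-id sequence into contextual embeddings H
#'
#' Row i of the pre-attention input is `tok_emb[ids[i], ] + pos_emb[i, ]`;
#' the layer stack then yields one contextual row per token.
#'
#' @param ids Integer token ids from [token_ids()].
#' @param params A [seq_encoder_params()] tree.
#' @return `n x d` matrix H of contextual token embeddings.
#' @export
encode_sequence <- function(ids, params) {
  n <- length(ids)
  if (n < 1L) stop("encode_sequence: empty token sequence", call. = FALSE)
  if (n > attr(params, "max_len")) {
    stop(sprintf("encode_sequence: %d tokens exceed positional table length %d",
                 n, attr(params, "max_len")), call. = FALSE)
  }
  X0 <- params$tok_emb[ids, , drop = FALSE] +
    params$pos_emb[seq_len(n), , drop = FALSE]
  .stack_forward(X0, params$layers, attr(params, "heads"))$Y
}

#' Mean-pool contextual token embeddings into h_mol
#'
#' @param H `n x d` matrix of token embeddings.
#' @return Numeric vector of length d: the row mean of `H`.
#' @export
sequence_readout <- function(H) {
  if (!is.matrix(H) || nrow(H) < 1L) {
    stop("sequence_readout: H must have at least one row", call. = FALSE)
  }
  colMeans(H)
}

# Forward with cache (training path).
.seq_view_forward <- function(ids, params) {
  n <- length(ids)
  X0 <- params$tok_emb[ids, , drop = FALSE] +
    params$pos_emb[seq_len(n), , drop = FALSE]
  st <- .stack_forward(X0, params$layers, attr(params, "heads"))
  list(h = colMeans(st$Y), caches = st$caches, ids = ids, n = n)
}

.seq_view_backward <- function(dh, fwd, params) {
  n <- fwd$n
  dY <- matrix(rep(dh / n, each = n), nrow = n)
  bk <- .stack_backward(dY, fwd$caches, params$layers)
  grads <- .tree_zeros_like(unclass(params))
  grads$layers <- bk$grads
  # scatter-add token gradients; positional rows map 1:1
  for (r in seq_len(n)) {
    grads$tok_emb[fwd$ids[r], ] <- grads$tok_emb[fwd$ids[r], ] + bk$dX[r, ]
  }
  grads$pos_emb[seq_len(n), ] <- grads$pos_emb[seq_len(n), , drop = FALSE] +
    bk$dX
  grads
}

#' Compute the sequence-view embedding of a SMILES string
#'
#' @param smiles SMILES string.
#' @param vocab Token vocabulary.
#' @param params A [seq_encoder_params()] tree.
#' @return `h_mol`, numeric vector of length d.
#' @export
sequence_view_embedding <- function(smiles, vocab, params) {
  sequence_readout(encode_sequence(
    token_ids(smiles, vocab, attr(params, "max_len")), params))
}
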