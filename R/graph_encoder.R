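# Graph-view encoder: per pharmacophore, node and edge one-hot features are
# projected into a common width d and stacked into a token matrix
# X' = [X_V' ; X_E']; the tokens are encoded by a stack of multi-head
# self-attention layers (no positional encoding -- the tokens form a set, so
# the molecule embedding is invariant to atom/bond ordering); finally a
# two-stage mean readout (rows within each pharmacophore, then across
# pharmacophores) yields the molecule-level embedding z_mol.

#' Initialise graph-view encoder parameters
#'
#' @param D_V,D_E Input feature widths for nodes and edges.
#' @param d Common embedding width (must be divisible by `heads`).
#' @param heads Number of attention heads.
#' @param layers Number of transformer layers.
#' @return A parameter tree (`graph_encoder_params` class) holding the node
#'   and edge projections and the per-layer attention/feed-forward/layer-norm
#'   weights.
#' @export
graph_encoder_params <- function(D_V, D_E, d = 64L, heads = 4L, layers = 2L) {
  if (d %% heads != 0L) {
    stop(sprintf("graph_encoder_params: heads (%d) must divide d (%d)",
                 heads, d), call. = FALSE)
  }
  p <- list(node_proj = .glorot(D_V, d),
            edge_proj = .glorot(D_E, d),
            layers = lapply(seq_len(layers), function(l) .layer_params(d)))
  attr(p, "heads") <- heads
  attr(p, "d") <- d
  class(p) <- c("graph_encoder_params", "list")
  p
}

#' Project node/edge features and stack them into pharmacophore tokens
#'
#' Row `i <= |V|` of the output is row i of `X_V` times the node projection;
#' row `|V| + j` is row j of `X_E` times the edge projection. Subgraphs
#' without bonds yield node rows only.
#'
#' @param X_V `|V| x D_V` node feature matrix.
#' @param X_E `|E| x D_E` edge feature matrix (0 rows allowed).
#' @param params A [graph_encoder_params()] tree.
#' @return `(|V|+|E|) x d` token matrix.
#' @export
project_and_concat <- function(X_V, X_E, params) {
  if (ncol(X_V) != nrow(params$node_proj)) {
    stop(sprintf("project_and_concat: X_V has %d columns, expected D_V = %d",
                 ncol(X_V), nrow(params$node_proj)), call. = FALSE)
  }
  if (nrow(X_E) > 0L && ncol(X_E) != nrow(params$edge_proj)) {
    stop(sprintf("project_and_concat: X_E has %d columns, expected D_E = %d",
                 ncol(X_E), nrow(params$edge_proj)), call. = FALSE)
  }
  nodes <- X_V %*% params$node_proj
  if (nrow(X_E) == 0L) return(nodes)
  rbind(nodes, X_E %*% params$edge_proj)
}

#' Encode one pharmacophore token matrix with multi-head self-attention
#'
#' Applies the encoder's transformer stack to a token matrix: per layer and
#' head i, `Q_i = X' Wq_i`, `K_i = X' Wk_i`, `V_i = X' Wv_i`,
#' `softmax(Q_i K_i^T / sqrt(d_k)) V_i`, heads concatenated and projected by
#' `W_O`, followed by the residual/feed-forward/layer-norm sublayers. Output
#' shape equals input shape.
#'
#' @param tokens `(|V|+|E|) x d` token matrix from [project_and_concat()].
#' @param params A [graph_encoder_params()] tree.
#' @return Encoded token matrix of the same shape.
#' @export
encode_pharmacophore <- function(tokens, params) {
  if (!is.matrix(tokens) || nrow(tokens) < 1L) {
    stop("encode_pharmacophore: token matrix must have at least one row",
         call. = FALSE)
  }
  if (any(!is.finite(tokens))) {
    stop("encode_pharmacophore: non-finite token values", call. = FALSE)
  }
  .stack_forward(tokens, params$layers, attr(params, "heads"))$Y
}

#' Pool pharmacophore embeddings into the molecule embedding z_mol
#'
#' Two-stage mean readout: each pharmacophore's token matrix is averaged over
#' its rows, and the per-pharmacophore vectors are averaged across
#' pharmacophores. The result is invariant to pharmacophore order and to row
#' order within each pharmacophore. `mode = "sum"` and `"max"` apply the
#' alternative pooling at both stages.
#'
#' @param embeddings Non-empty list of encoded token matrices.
#' @param mode One of `"mean"` (default), `"sum"`, `"max"`.
#' @return Numeric vector of length d.
#' @export
graph_readout <- function(embeddings, mode = c("mean", "sum", "max")) {
  mode <- match.arg(mode)
  if (!is.list(embeddings) || length(embeddings) == 0L) {
    stop("graph_readout: need at least one pharmacophore embedding (N >= 1)",
         call. = FALSE)
  }
  pool <- switch(mode,
                 mean = function(m) colMeans(m),
                 sum = function(m) colSums(m),
                 max = function(m) apply(m, 2L, max))
  pooled <- vapply(embeddings, pool, numeric(ncol(embeddings[[1L]])))
  pooled <- matrix(pooled, ncol = length(embeddings))
  switch(mode,
         mean = rowMeans(pooled),
         sum = rowSums(pooled),
         max = apply(pooled, 1L, max))
}

# Full graph-view forward with caches for backprop. feats: list over
# pharmacophores of list(X_V, X_E). Mean readout only on the training path.
.graph_view_forward <- function(feats, params) {
  h <- attr(params, "heads")
  N <- length(feats)
  caches <- vector("list", N)
  pooled <- NULL
  for (k in seq_len(N)) {
    Xp <- project_and_concat(feats[[k]]$X_V, feats[[k]]$X_E, params)
    st <- .stack_forward(Xp, params$layers, h)
    pk <- colMeans(st$Y)
    caches[[k]] <- list(stack = st$caches, n_rows = nrow(Xp),
                        n_nodes = nrow(feats[[k]]$X_V))
    pooled <- if (is.null(pooled)) pk / N else pooled + pk / N
  }
  list(z = pooled, caches = caches, feats = feats)
}

# dz: length-d gradient on z_mol. Returns gradient tree shaped like params.
.graph_view_backward <- function(dz, fwd, params) {
  h <- attr(params, "heads")
  N <- length(fwd$caches)
  grads <- .tree_zeros_like(unclass(params))
  for (k in seq_len(N)) {
    ck <- fwd$caches[[k]]
    nr <- ck$n_rows
    dY <- matrix(rep(dz / (N * nr), each = nr), nrow = nr)
    bk <- .stack_backward(dY, ck$stack, params$layers)
    grads$layers <- .tree_add(grads$layers, bk$grads)
    nV <- ck$n_nodes
    XV <- fwd$feats[[k]]$X_V
    XE <- fwd$feats[[k]]$X_E
    grads$node_proj <- grads$node_proj +
      t(XV) %*% bk$dX[seq_len(nV), , drop = FALSE]
    if (nr > nV) {
      grads$edge_proj <- grads$edge_proj +
        t(XE) %*% bk$dX[(nV + 1L):nr, , drop = FALSE]
    }
  }
  grads
}

#' Compute the graph-view embedding of a prepared drug
#'
#' Runs projection, attention encoding and readout over all pharmacophores of
#' one drug.
#'
#' @param prepared One element of [prepare_drugs()] output (list with
#'   `features`).
#' @param params A [graph_encoder_params()] tree.
#' @param readout Readout mode, see [graph_readout()].
#' @return `z_mol`, numeric vector of length d.
#' @export
graph_view_embedding <- function(prepared, params, readout = "mean") {
  embs <- lapply(prepared$features, function(f) {
    encode_pharmacophore(project_and_concat(f$X_V, f$X_E, params), params)
  })
  graph_readout(embs, mode = readout)
}
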