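## Message-passing feature learning on embedded trees.
##
## A FeatureNet runs T rounds of neighborhood aggregation (one of five
## convolution operators, in their original published formulations) over the
## Dirichlet-energy node embeddings, followed by a per-node 2-layer MLP.
## T = 0 skips message passing entirely (the "MLP" baseline). Undirected
## message passing: every tree edge carries messages in both directions.

glorot <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -s, s), nin, nout)
}

mlp2_params <- function(prefix, din, dhid, dout) {
  p <- list(glorot(din, dhid), matrix(0, 1L, dhid),
            glorot(dhid, dout), matrix(0, 1L, dout))
  names(p) <- paste0(prefix, c("W1", "b1", "W2", "b2"))
  p
}

mlp2_forward <- function(tp, ids, prefix, x) {
  h <- ad_elu(tp, ad_addbias(tp, ad_mm(tp, x, ids[[paste0(prefix, "W1")]]),
                             ids[[paste0(prefix, "b1")]]))
  ad_addbias(tp, ad_mm(tp, h, ids[[paste0(prefix, "W2")]]),
             ids[[paste0(prefix, "b2")]])
}

## scalar (1x1) parameter times matrix
ad_scalemul <- function(tp, s, a) {
  force(s); force(a)
  sv <- as.numeric(tp$vals[[s]]); A <- tp$vals[[a]]
  ad_push(tp, sv * A, c(s, a), function(g)
    list(matrix(sum(g * A), 1L, 1L), sv * g))
}

ad_oneminus <- function(tp, a) {
  force(a)
  ad_push(tp, 1 - tp$vals[[a]], a, function(g) list(-g))
}

#' Create a message-passing feature network
#'
#' @param variant One of \code{"gcn"}, \code{"gin"}, \code{"sage"},
#'   \code{"ggnn"}, \code{"edge"}, \code{"mlp"} (the last skips all
#'   message-passing iterations).
#' @param in_dim Input (embedding) dimension.
#' @param hidden Hidden width (default 100).
#' @param out_dim Output node-feature dimension (default \code{hidden}).
#' @param layers Number of message-passing layers T (default 2; ignored for
#'   \code{"mlp"}, which uses T = 0).
#' @param seed Integer seed for weight initialization.
#' @return An object of class \code{"feature_net"} holding the parameter
#'   list and architecture description.
#' @export
feature_net <- function(variant = c("gcn", "gin", "sage", "ggnn", "edge",
                                    "mlp"),
                        in_dim, hidden = 100L, out_dim = hidden,
                        layers = 2L, seed = 1L) {
  variant <- match.arg(variant)
  if (variant == "mlp") layers <- 0L
  with_seed(seed, {
    p <- list()
    din <- in_dim
    if (variant == "ggnn" && layers > 0L) {
      p <- c(p, list(ggnn_Win = glorot(in_dim, hidden),
                     ggnn_bin = matrix(0, 1L, hidden)))
      din <- hidden
    }
    if (layers > 0L) for (t in seq_len(layers)) {
      pre <- paste0("l", t, "_")
      p <- c(p, switch(variant,
        gcn = setNames(list(glorot(din, hidden), matrix(0, 1L, hidden)),
                       paste0(pre, c("W", "b"))),
        gin = c(setNames(list(matrix(0, 1L, 1L)), paste0(pre, "eps")),
                mlp2_params(pre, din, hidden, hidden)),
        sage = setNames(list(glorot(2L * din, hidden),
                             matrix(0, 1L, hidden)),
                        paste0(pre, c("W", "b"))),
        ggnn = setNames(list(glorot(din, hidden), matrix(0, 1L, hidden),
                             cbind(glorot(hidden, hidden),
                                   glorot(hidden, hidden)),
                             cbind(glorot(din, hidden), glorot(din, hidden)),
                             matrix(0, 1L, 2L * hidden),
                             glorot(hidden, hidden), glorot(din, hidden),
                             matrix(0, 1L, hidden)),
                        paste0(pre, c("Wm", "bm", "Uzr", "Vzr", "bzr",
                                      "Uh", "Vh", "bh"))),
        edge = mlp2_params(pre, 2L * din, hidden, hidden)))
      din <- hidden
    }
    p <- c(p, mlp2_params("mlp0_", din, hidden, out_dim))
    structure(list(variant = variant, in_dim = in_dim, hidden = hidden,
                   out_dim = out_dim, layers = layers, params = p),
              class = "feature_net")
  })
}

## ---- batched graph structure -------------------------------------------

## Per-tree cached pieces for fast minibatch assembly. X is stored stacked;
## per-tree rows are contiguous.
gnn_cache <- function(trees, X_list = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (is.null(X_list))
    X_list <- lapply(trees, function(tr) two_pass_embed(tr)$features)
  n_nodes <- vapply(X_list, nrow, integer(1L))
  row_off <- c(0L, cumsum(n_nodes))
  list(Xall = do.call(rbind, X_list),
       edges = lapply(trees, function(tr) tr$edge),
       n_nodes = n_nodes, row_off = row_off, n_trees = length(trees))
}

## Assemble the block-diagonal batch structure for trees cache[idx].
## `need`: which operator views to materialize ("ahat", "amean", "maxidx");
## the raw adjacency A and the readout R are always built.
gnn_assemble <- function(cache, idx = seq_len(cache$n_trees),
                         need = c("ahat", "amean", "maxidx")) {
  nn <- cache$n_nodes[idx]
  off <- c(0L, cumsum(nn))[seq_along(idx)]
  rows <- sequence(nn) + rep(cache$row_off[idx], nn)
  X <- cache$Xall[rows, , drop = FALSE]
  n <- nrow(X)
  ne <- vapply(cache$edges[idx], nrow, integer(1L))
  E <- do.call(rbind, cache$edges[idx])
  shift <- rep(off, ne)
  e1 <- E[, 1L] + shift; e2 <- E[, 2L] + shift
  src <- c(e1, e2); dst <- c(e2, e1)
  deg <- tabulate(dst, n)
  gs <- list(X = X, n = n, src = src, dst = dst,
             n_graphs = length(idx))
  if ("adj" %in% need)
    gs$A <- Matrix::sparseMatrix(i = dst, j = src, x = 1, dims = c(n, n))
  if ("ahat" %in% need) {
    dh <- 1 / sqrt(deg + 1)
    gs$Ahat <- Matrix::sparseMatrix(
      i = c(dst, seq_len(n)), j = c(src, seq_len(n)),
      x = c(dh[dst] * dh[src], dh^2), dims = c(n, n))
  }
  if ("amean" %in% need)
    gs$Amean <- Matrix::sparseMatrix(i = dst, j = src, x = 1 / deg[dst],
                                     dims = c(n, n))
  if ("maxidx" %in% need) {
    o <- order(dst)
    idxmat <- matrix(0L, n, max(deg))
    pos <- sequence(rle(dst[o])$lengths)
    idxmat[cbind(dst[o], pos)] <- o
    gs$idxmat <- idxmat
  }
  gs$gid <- rep(seq_along(idx), nn)
  gs
}

## operator views needed per variant
gnn_needs <- function(variant)
  switch(variant, gcn = "ahat", sage = "amean", edge = "maxidx",
         gin = , ggnn = "adj", mlp = character(0))

## Forward pass through the message-passing layers and MLP^(0).
## Returns list(H = tape id of node features, ids = tape ids of parameters).
gnn_node_forward <- function(net, gs, tp, ids = NULL) {
  if (is.null(ids)) ids <- lapply(net$params, function(v) ad_leaf(tp, v))
  H <- ad_leaf(tp, gs$X)
  v <- net$variant
  if (v == "ggnn" && net$layers > 0L)
    H <- ad_addbias(tp, ad_mm(tp, H, ids$ggnn_Win), ids$ggnn_bin)
  if (net$layers > 0L) for (t in seq_len(net$layers)) {
    pre <- paste0("l", t, "_")
    id <- function(nm) ids[[paste0(pre, nm)]]
    if (v == "gcn") {
      H <- ad_elu(tp, ad_addbias(tp, ad_mm(tp,
        ad_spmm(tp, gs$Ahat, H, St = gs$Ahat), id("W")), id("b")))
    } else if (v == "gin") {
      S <- ad_add(tp, ad_add(tp, H, ad_scalemul(tp, id("eps"), H)),
                  ad_spmm(tp, gs$A, H, St = gs$A))
      H <- mlp2_forward(tp, ids, pre, S)
    } else if (v == "sage") {
      H <- ad_elu(tp, ad_addbias(tp, ad_mm(tp,
        ad_cbind(tp, H, ad_spmm(tp, gs$Amean, H)), id("W")), id("b")))
    } else if (v == "ggnn") {
      ## gated recurrent update; the z and r gates share one fused matmul
      m <- ad_addbias(tp, ad_mm(tp, ad_spmm(tp, gs$A, H, St = gs$A),
                                id("Wm")), id("bm"))
      zr <- ad_sigmoid(tp, ad_addbias(tp,
        ad_add(tp, ad_mm(tp, m, id("Uzr")), ad_mm(tp, H, id("Vzr"))),
        id("bzr")))
      hd <- net$hidden
      z <- ad_cols(tp, zr, seq_len(hd))
      r <- ad_cols(tp, zr, hd + seq_len(hd))
      htil <- ad_tanh(tp, ad_addbias(tp,
        ad_add(tp, ad_mm(tp, m, id("Uh")),
               ad_mm(tp, ad_hadamard(tp, r, H), id("Vh"))), id("bh")))
      H <- ad_add(tp, ad_hadamard(tp, ad_oneminus(tp, z), H),
                  ad_hadamard(tp, z, htil))
    } else if (v == "edge") {
      ## message MLP on (h_dst, h_src - h_dst): algebraically
      ## Hd W1a + (Hs - Hd) W1b = Hd (W1a - W1b) + Hs W1b, so the wide
      ## matmul runs on the n-node matrix, not the 2|E|-row message stack
      W1 <- id("W1")
      din_t <- nrow(ad_value(tp, W1)) %/% 2L
      Wa <- ad_rows(tp, W1, seq_len(din_t))
      Wb <- ad_rows(tp, W1, din_t + seq_len(din_t))
      Pd <- ad_mm(tp, H, ad_sub(tp, Wa, Wb))
      Ps <- ad_mm(tp, H, Wb)
      pre1 <- ad_addbias(tp, ad_add(tp, ad_rows(tp, Pd, gs$dst),
                                    ad_rows(tp, Ps, gs$src)), id("b1"))
      M <- ad_addbias(tp, ad_mm(tp, ad_elu(tp, pre1), id("W2")), id("b2"))
      H <- ad_groupmax(tp, M, gs$idxmat)
    }
  }
  H <- mlp2_forward(tp, ids, "mlp0_", H)
  list(H = H, ids = ids)
}

#' Per-node learnable features for one tree
#'
#' Runs the message-passing network on a single tree and returns the
#' per-node output features (after the final MLP). Deterministic given the
#' network parameters.
#'
#' @param net A \code{"feature_net"}.
#' @param tree A \code{"phylo"} object.
#' @param embedding Optional precomputed \code{"node_embedding"}; defaults
#'   to the one-hot Dirichlet-energy embedding of \code{tree}.
#' @return Matrix of node features (rows in node-index order).
#' @export
forward_nodes <- function(net, tree, embedding = NULL) {
  X <- if (is.null(embedding)) two_pass_embed(tree)$features
       else embedding$features
  if (ncol(X) != net$in_dim)
    stop_input("embedding dimension ", ncol(X),
               " does not match network input dimension ", net$in_dim)
  cache <- gnn_cache(list(tree), list(X))
  gs <- gnn_assemble(cache, need = gnn_needs(net$variant))
  tp <- ad_tape()
  out <- gnn_node_forward(net, gs, tp)
  ad_value(tp, out$H)
}

#' Graph-level readout (elementwise sum)
#'
#' @param node_features Matrix of node feature vectors (rows = nodes).
#' @return Numeric vector: the permutation-invariant elementwise sum.
#' @export
readout_graph <- function(node_features) {
  if (is.null(dim(node_features))) node_features <- rbind(node_features)
  if (nrow(node_features) == 0L) stop_input("empty node set")
  colSums(node_features)
}

#' Edge-level readout (elementwise maximum)
#'
#' Symmetric in its two arguments, making edge features independent of edge
#' orientation on unrooted trees.
#'
#' @param u_feature,v_feature Feature vectors of the edge's endpoints.
#' @return Elementwise maximum.
#' @export
readout_edge <- function(u_feature, v_feature) {
  if (length(u_feature) != length(v_feature))
    stop_input("edge endpoint features must have equal dimension")
  pmax(u_feature, v_feature)
}

## ---- Adam ---------------------------------------------------------------

adam_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

adam_step <- function(state, params, grads, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in seq_along(params)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(state = state, params = params)
}
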