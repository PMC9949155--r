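## Interior node embedding by Dirichlet-energy minimization.
##
## Tip features are fixed; interior features minimize the Dirichlet energy
##   sum over edges (u,v) of ||x_u - x_v||^2,
## whose stationarity condition makes every interior feature the mean of its
## neighbors' features. On a tree the system is solved exactly in linear
## time by one postorder and one preorder sweep (a Thomas-algorithm
## analogue), instead of a dense solve.

#' One-hot tip features
#'
#' Identity features for the tips, with the one-hot axis ordered by
#' lexicographic taxon label (the package-wide taxon order convention).
#'
#' @param tree A \code{"phylo"} object.
#' @return An N x N matrix with rownames the tip labels.
#' @export
one_hot_tips <- function(tree) {
  labs <- tree$tip.label
  X <- diag(length(labs))
  rownames(X) <- sort(labs)
  X[labs, , drop = FALSE]
}

#' Interior node embedding via the linear-time two-pass algorithm
#'
#' Computes the Dirichlet-energy-minimizing interior node features given
#' fixed tip features. The first (postorder) pass expresses every non-root
#' node feature as \code{x_u = c_u * x_parent + d_u} with
#' \code{c_u = 1 / (|N(u)| - sum of children c)} and
#' \code{d_u = c_u * sum of children d}; the second (preorder) pass back
#' substitutes from the root. The result is independent of the traversal
#' root chosen and the coefficients satisfy \code{0 <= c_u <= 1/(lambda-1)}
#' where \code{lambda} is the minimum interior degree, which makes the
#' recursion numerically stable.
#'
#' @param tree A \code{"phylo"} object (multifurcations allowed).
#' @param tip_features Matrix of tip features with rownames equal to the tip
#'   labels; defaults to one-hot encoding in lexicographic taxon order.
#' @param root Node index used to direct the traversal; defaults to the
#'   first interior node. Any node may be chosen.
#' @return An object of class \code{"node_embedding"}: a list with
#'   \code{features} (all-node feature matrix, tips exactly equal to their
#'   prescribed features), \code{coef_c}, \code{coef_d} (first-pass
#'   coefficients, \code{NA} at the root), \code{is_tip}, \code{root}, and
#'   \code{n_visits} (traversal instrumentation).
#' @export
two_pass_embed <- function(tree, tip_features = one_hot_tips(tree),
                           root = NULL) {
  g <- tree_graph(tree)
  if (is.null(rownames(tip_features)))
    stop_input("tip_features must have taxon labels as rownames")
  missing <- setdiff(g$labels, rownames(tip_features))
  if (length(missing))
    stop_input("missing tip feature for: ", paste(missing, collapse = ", "))
  X_b <- tip_features[g$labels, , drop = FALSE]
  d <- ncol(X_b)
  if (is.null(root)) root <- if (g$n > g$ntip) g$ntip + 1L else 1L
  ro <- rooted_orders(g, root)

  cc <- rep(NA_real_, g$n)
  dd <- matrix(0, g$n, d)
  accC <- numeric(g$n)
  accD <- matrix(0, g$n, d)
  n_visits <- 0L

  ## first pass: postorder
  for (u in rev(ro$order)) {
    n_visits <- n_visits + 1L
    if (u == root) next
    p <- ro$parent[u]
    if (u <= g$ntip) {
      cc[u] <- 0
      dd[u, ] <- X_b[u, ]
    } else {
      deg <- length(g$adj[[u]])
      cu <- 1 / (deg - accC[u])
      cc[u] <- cu
      dd[u, ] <- cu * accD[u, ]
    }
    accC[p] <- accC[p] + cc[u]
    accD[p, ] <- accD[p, ] + dd[u, ]
  }

  ## second pass: preorder
  feats <- matrix(0, g$n, d)
  n_visits <- n_visits + 1L  # root evaluation opens the second pass
  if (root <= g$ntip) {
    feats[root, ] <- X_b[root, ]
  } else {
    deg <- length(g$adj[[root]])
    feats[root, ] <- accD[root, ] / (deg - accC[root])
  }
  for (u in ro$order[-1L]) {
    n_visits <- n_visits + 1L
    if (u <= g$ntip) {
      feats[u, ] <- X_b[u, ]
    } else {
      feats[u, ] <- cc[u] * feats[ro$parent[u], ] + dd[u, ]
    }
  }

  rn <- character(g$n)
  rn[seq_len(g$ntip)] <- g$labels
  rn[-seq_len(g$ntip)] <- paste0("node", (g$ntip + 1L):g$n)
  rownames(feats) <- rn
  structure(list(features = feats, coef_c = cc, coef_d = dd,
                 tip_features = X_b, is_tip = seq_len(g$n) <= g$ntip,
                 root = root, n_visits = n_visits),
            class = "node_embedding")
}

#' Dense linear-system oracle for the interior node embedding
#'
#' Solves the same stationarity system as \code{\link{two_pass_embed}} by a
#' generic dense factorization of the interior block of the graph
#' Laplacian. Intended as an independent test oracle; cost is cubic in the
#' interior count.
#'
#' @inheritParams two_pass_embed
#' @return A \code{"node_embedding"} (without two-pass coefficients).
#' @export
dense_embed_oracle <- function(tree, tip_features = one_hot_tips(tree)) {
  g <- tree_graph(tree)
  X_b <- tip_features[g$labels, , drop = FALSE]
  nint <- g$n - g$ntip
  if (nint > 500L) stop_input("dense oracle limited to <= 500 interior nodes")
  if (nint == 0L) {
    feats <- X_b
  } else {
    A <- matrix(0, g$n, g$n)
    for (u in seq_len(g$n)) A[u, g$adj[[u]]] <- 1
    deg <- rowSums(A)
    io <- (g$ntip + 1L):g$n
    ib <- seq_len(g$ntip)
    L_oo <- diag(deg[io], nint) - A[io, io, drop = FALSE]
    rhs <- A[io, ib, drop = FALSE] %*% X_b
    X_o <- solve(L_oo, rhs)
    feats <- rbind(X_b, X_o)
  }
  rn <- character(g$n)
  rn[seq_len(g$ntip)] <- g$labels
  if (nint > 0L) rn[-seq_len(g$ntip)] <- paste0("node", (g$ntip + 1L):g$n)
  rownames(feats) <- rn
  structure(list(features = feats, coef_c = NULL, coef_d = NULL,
                 tip_features = X_b, is_tip = seq_len(g$n) <= g$ntip,
                 root = NA_integer_, n_visits = NA_integer_),
            class = "node_embedding")
}

## Convex-combination coefficients a_{u,v} of interior features in terms of
## tip features (columns in lexicographic taxon order). For one-hot tips
## the coefficient of taxon v is simply component v of the feature.
interior_tip_coefficients <- function(embedding, coefficients = NULL) {
  if (!is.null(coefficients)) return(coefficients)
  X_b <- embedding$tip_features
  sorted <- sort(rownames(X_b))
  one_hot <- nrow(X_b) == ncol(X_b) &&
    all(X_b %in% c(0, 1)) && all(rowSums(X_b) == 1) && all(colSums(X_b) == 1)
  if (!one_hot)
    stop_input("tips are not one-hot; supply the coefficient decomposition")
  col_of <- apply(X_b[sorted, , drop = FALSE], 1L, which.max)
  A <- embedding$features[!embedding$is_tip, col_of, drop = FALSE]
  colnames(A) <- sorted
  A
}

#' Decode each tip's interior neighbor from the embedding
#'
#' In the convex-combination representation of the interior features, the
#' interior node with the largest coefficient on tip v is exactly v's
#' unique interior neighbor. This decodes tip attachments from the
#' embedding alone, without the topology.
#'
#' @param embedding A \code{"node_embedding"} from one-hot (or linearly
#'   independent, with \code{coefficients} supplied) tip features.
#' @param coefficients Optional interior x taxa coefficient matrix (columns
#'   in lexicographic taxon order) for non-one-hot tips.
#' @return Named integer vector: for each tip label, the decoded interior
#'   node index (ties broken by smallest node index).
#' @export
tip_neighbor_decode <- function(embedding, coefficients = NULL) {
  A <- interior_tip_coefficients(embedding, coefficients)
  interior_ids <- which(!embedding$is_tip)
  out <- vapply(colnames(A), function(v) interior_ids[which.max(A[, v])],
                integer(1L))
  out
}

#' Dirichlet energy of a node feature assignment
#'
#' @param tree A \code{"phylo"} object.
#' @param features All-node feature matrix in node-index order.
#' @return Scalar energy: sum over edges of squared feature differences.
#' @export
dirichlet_energy <- function(tree, features) {
  E <- tree$edge
  sum((features[E[, 1L], , drop = FALSE] -
         features[E[, 2L], , drop = FALSE])^2)
}

#' Identifiability check: are all embeddings distinct over a topology space?
#'
#' Embeds every enumerated unrooted topology on \code{N} taxa with one-hot
#' tips and reports whether the interior-feature multisets are pairwise
#' distinct (rows sorted, values rounded to \code{tol}). Distinct
#' embeddings over the whole space instantiate the identifiability of the
#' representation: no information about the topology is lost.
#'
#' @param N Taxon count (enumeration must be feasible; N <= 7 suggested).
#' @param tol Rounding tolerance for the comparison.
#' @return List with \code{distinct} (logical), \code{n_topologies},
#'   \code{n_distinct}.
#' @export
embeddings_distinct <- function(N, tol = 1e-9) {
  trees <- enumerate_unrooted(N)
  digits <- max(0L, ceiling(-log10(tol)))
  keys <- vapply(trees, function(tr) {
    emb <- two_pass_embed(tr)
    M <- round(emb$features[!emb$is_tip, , drop = FALSE], digits)
    rows <- apply(M, 1L, paste, collapse = ",")
    paste(sort(rows), collapse = ";")
  }, character(1L))
  list(distinct = !anyDuplicated(keys), n_topologies = length(trees),
       n_distinct = length(unique(keys)))
}
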