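## Minimal reverse-mode automatic differentiation over dense/sparse matrix
## operations. A tape records each primitive's output value and a backward
## closure; gradients are accumulated by a single reverse sweep. Only the
## primitives needed by the message-passing networks are provided. All
## values are dense base matrices; fixed (non-differentiated) sparse
## operators from the Matrix package may multiply tape values.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$vals <- list()
  tp$back <- list()
  tp$parents <- list()
  tp$n <- 0L
  tp
}

ad_push <- function(tp, value, parents = integer(0), backward = NULL) {
  tp$n <- tp$n + 1L
  tp$vals[[tp$n]] <- value
  tp$parents[[tp$n]] <- parents
  tp$back[[tp$n]] <- backward
  tp$n
}

ad_leaf <- function(tp, value) ad_push(tp, value)

ad_value <- function(tp, id) {
  force(id)
  tp$vals[[id]]
}

## Backward sweep from node `id` with seed gradient `seed` (same shape as
## the node's value). Returns nothing; per-node gradients afterwards via
## ad_grad().
ad_backward <- function(tp, id, seed) {
  force(id)
  grads <- vector("list", tp$n)
  grads[[id]] <- seed
  for (k in seq(id, 1L)) {
    g <- grads[[k]]
    if (is.null(g) || is.null(tp$back[[k]])) next
    pg <- tp$back[[k]](g)
    ps <- tp$parents[[k]]
    for (j in seq_along(ps)) {
      if (is.null(pg[[j]])) next
      p <- ps[[j]]
      grads[[p]] <- if (is.null(grads[[p]])) pg[[j]] else grads[[p]] + pg[[j]]
    }
  }
  tp$grads <- grads
  invisible(NULL)
}

ad_grad <- function(tp, id) {
  g <- tp$grads[[id]]
  if (is.null(g)) g <- array(0, dim(tp$vals[[id]]))
  g
}

ad_mm <- function(tp, a, b) {
  force(a); force(b)
  A <- tp$vals[[a]]; B <- tp$vals[[b]]
  ad_push(tp, A %*% B, c(a, b), function(g)
    list(tcrossprod(g, B), crossprod(A, g)))
}

ad_add <- function(tp, a, b) {
  force(a); force(b)
  ad_push(tp, tp$vals[[a]] + tp$vals[[b]], c(a, b), function(g) list(g, g))
}

ad_sub <- function(tp, a, b) {
  force(a); force(b)
  ad_push(tp, tp$vals[[a]] - tp$vals[[b]], c(a, b), function(g) list(g, -g))
}

ad_hadamard <- function(tp, a, b) {
  force(a); force(b)
  A <- tp$vals[[a]]; B <- tp$vals[[b]]
  ad_push(tp, A * B, c(a, b), function(g) list(g * B, g * A))
}

ad_scale <- function(tp, a, k) {
  force(a)
  ad_push(tp, k * tp$vals[[a]], a, function(g) list(k * g))
}

## add a bias row-vector (1 x d parameter) to every row
ad_addbias <- function(tp, a, b) {
  force(a); force(b)
  bv <- as.numeric(tp$vals[[b]])
  A <- tp$vals[[a]]
  ad_push(tp, A + rep(bv, each = nrow(A)), c(a, b),
          function(g) list(g, matrix(colSums(g), 1L)))
}

ad_elu <- function(tp, a) {
  force(a)
  X <- tp$vals[[a]]
  neg <- X < 0
  Y <- X
  Y[neg] <- exp(X[neg]) - 1
  ad_push(tp, Y, a, function(g) {
    dg <- g
    dg[neg] <- g[neg] * (Y[neg] + 1)
    list(dg)
  })
}

ad_sigmoid <- function(tp, a) {
  force(a)
  Y <- sigmoid(tp$vals[[a]])
  ad_push(tp, Y, a, function(g) list(g * Y * (1 - Y)))
}

ad_tanh <- function(tp, a) {
  force(a)
  Y <- tanh(tp$vals[[a]])
  ad_push(tp, Y, a, function(g) list(g * (1 - Y^2)))
}

## fixed sparse/dense operator S (not differentiated) times tape value;
## pass St = S for symmetric operators to skip the transpose
ad_spmm <- function(tp, S, a, St = NULL) {
  force(a)
  if (is.null(St)) St <- Matrix::t(S)
  ad_push(tp, as.matrix(S %*% tp$vals[[a]]), a,
          function(g) list(as.matrix(St %*% g)))
}

## column slice: value = X[, range]
ad_cols <- function(tp, a, range) {
  force(a)
  X <- tp$vals[[a]]
  nc <- ncol(X)
  ad_push(tp, X[, range, drop = FALSE], a, function(g) {
    out <- matrix(0, nrow(X), nc)
    out[, range] <- g
    list(out)
  })
}

## row gather: value = X[idx, ]; backward scatter-adds
ad_rows <- function(tp, a, idx) {
  force(a)
  X <- tp$vals[[a]]
  nr <- nrow(X)
  ad_push(tp, X[idx, , drop = FALSE], a, function(g) {
    rs <- rowsum(g, idx)
    out <- matrix(0, nr, ncol(g))
    out[as.integer(rownames(rs)), ] <- rs
    list(out)
  })
}

ad_cbind <- function(tp, a, b) {
  force(a); force(b)
  na <- ncol(tp$vals[[a]])
  ad_push(tp, cbind(tp$vals[[a]], tp$vals[[b]]), c(a, b), function(g)
    list(g[, seq_len(na), drop = FALSE],
         g[, -seq_len(na), drop = FALSE]))
}

ad_pmax2 <- function(tp, a, b) {
  force(a); force(b)
  A <- tp$vals[[a]]; B <- tp$vals[[b]]
  mask <- A >= B
  ad_push(tp, pmax(A, B), c(a, b), function(g)
    list(g * mask, g * !mask))
}

## Group max over rows of A: idxmat is n_out x K of row indices into A
## (0 = padding, treated as -Inf). value[i, j] = max_k A[idxmat[i,k], j].
## Backward scatters the gradient to the first attaining row.
ad_groupmax <- function(tp, a, idxmat) {
  force(a)
  A <- tp$vals[[a]]
  K <- ncol(idxmat)
  d <- ncol(A)
  n_out <- nrow(idxmat)
  slices <- vector("list", K)
  for (k in seq_len(K)) {
    idx <- idxmat[, k]
    S <- matrix(-Inf, n_out, d)
    ok <- idx > 0L
    S[ok, ] <- A[idx[ok], , drop = FALSE]
    slices[[k]] <- S
  }
  val <- slices[[1L]]
  argk <- matrix(1L, n_out, d)
  for (k in seq_len(K)[-1L]) {
    upd <- slices[[k]] > val
    val[upd] <- slices[[k]][upd]
    argk[upd] <- k
  }
  ad_push(tp, val, a, function(g) {
    out <- matrix(0, nrow(A), d)
    for (k in seq_len(K)) {
      idx <- idxmat[, k]
      ok <- idx > 0L
      gk <- g * (argk == k)
      if (!any(ok)) next
      rs <- rowsum(gk[ok, , drop = FALSE], idx[ok])
      rows <- as.integer(rownames(rs))
      out[rows, ] <- out[rows, ] + rs
    }
    list(out)
  })
}

ad_sum <- function(tp, a) {
  force(a)
  X <- tp$vals[[a]]
  ad_push(tp, matrix(sum(X), 1L, 1L), a, function(g)
    list(array(as.numeric(g), dim(X))))
}

## group sum over rows (graph readout): gid must be nondecreasing with
## groups 1..ngroups; backward is a row gather
ad_rowsum <- function(tp, a, gid, ngroups) {
  force(a)
  X <- tp$vals[[a]]
  val <- rowsum(X, gid, reorder = FALSE)
  ad_push(tp, val, a, function(g) list(g[gid, , drop = FALSE]))
}
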