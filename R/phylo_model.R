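## Phylogenetic likelihood under the JC69 substitution model.
##
## The likelihood of an alignment Y given (tau, q) is the product over
## sites of the sum over ancestral character assignments of the stationary
## probability at the root times the transition probabilities along every
## edge. It is computed by the pruning algorithm (postorder partial
## likelihoods with per-node scaling); a brute-force summation over all
## interior assignments serves as a test oracle. Site patterns are
## compressed (unique columns with weights) before any likelihood work.

DNA_STATES <- c("A", "C", "G", "T")

#' DNA alignment container
#'
#' @param taxa Character vector of taxon labels.
#' @param seqs N x M character matrix over A,C,G,T (anything else is
#'   treated as missing), or an integer matrix with values 1..4 (0 =
#'   missing).
#' @return A \code{"dna_alignment"}: list with \code{taxa}, integer matrix
#'   \code{seq} (rows = taxa), \code{n_sites}, plus compressed site
#'   \code{patterns} and \code{weights}.
#' @export
dna_alignment <- function(taxa, seqs) {
  if (is.character(seqs)) {
    seqs <- matrix(match(toupper(seqs), DNA_STATES, nomatch = 0L),
                   nrow = length(taxa))
  }
  storage.mode(seqs) <- "integer"
  if (nrow(seqs) != length(taxa))
    stop_input("sequence count does not match taxon count")
  rownames(seqs) <- taxa
  pat <- apply(seqs, 2L, paste, collapse = ",")
  first <- !duplicated(pat)
  w <- as.numeric(table(factor(pat, levels = pat[first])))
  structure(list(taxa = taxa, seq = seqs, n_sites = ncol(seqs),
                 patterns = seqs[, first, drop = FALSE], weights = w),
            class = "dna_alignment")
}

#' Read a FASTA DNA alignment
#'
#' @param path FASTA file (sequential or interleaved lines per record).
#' @return A \code{"dna_alignment"} (uppercase-normalized).
#' @export
read_fasta_alignment <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop_input("not a FASTA file: ", path)
  id <- cumsum(hdr)
  taxa <- sub("^>", "", sub("\\s.*$", "", lines[hdr]))
  seqs <- vapply(split(lines[!hdr], id[!hdr]),
                 function(x) paste(x, collapse = ""), character(1L))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop_input("unequal sequence lengths in ", path)
  mat <- matrix(unlist(strsplit(seqs, "")), nrow = length(taxa),
                byrow = TRUE)
  dna_alignment(taxa, matrix(match(toupper(mat), DNA_STATES, nomatch = 0L),
                             nrow = length(taxa)))
}

#' Write a FASTA DNA alignment
#'
#' @param aln A \code{"dna_alignment"}.
#' @param path Output file path.
#' @export
write_fasta_alignment <- function(aln, path) {
  ch <- matrix(c("N", DNA_STATES)[aln$seq + 1L], nrow = length(aln$taxa))
  out <- character(2L * length(aln$taxa))
  out[c(TRUE, FALSE)] <- paste0(">", aln$taxa)
  out[c(FALSE, TRUE)] <- apply(ch, 1L, paste, collapse = "")
  writeLines(out, path)
  invisible(path)
}

#' JC69 substitution model
#'
#' One-parameter DNA model with uniform stationary distribution;
#' \code{P_ii(t) = 1/4 + 3/4 exp(-4t/3)},
#' \code{P_ij(t) = 1/4 - 1/4 exp(-4t/3)}.
#'
#' @return A \code{"subst_model"} with the stationary distribution
#'   \code{eta}, transition function \code{P(t)} and its derivative
#'   \code{dP(t)}.
#' @export
jc69_model <- function() {
  structure(list(name = "JC69", eta = rep(0.25, 4L),
                 P = jc69_transition,
                 dP = function(t) {
                   e <- exp(-4 * t / 3)
                   M <- matrix(e / 3, 4L, 4L)
                   diag(M) <- -e
                   M
                 }),
            class = "subst_model")
}

#' JC69 transition probability matrix
#'
#' @param t Branch length (expected substitutions per site, >= 0).
#' @return 4 x 4 stochastic matrix.
#' @export
jc69_transition <- function(t) {
  if (t < 0) stop_input("negative branch length: ", t)
  e <- exp(-4 * t / 3)
  M <- matrix(0.25 - 0.25 * e, 4L, 4L)
  diag(M) <- 0.25 + 0.75 * e
  dimnames(M) <- list(DNA_STATES, DNA_STATES)
  M
}

## tip partial likelihoods (4 x P) for taxon row i over compressed patterns
tip_partial <- function(aln, i) {
  s <- aln$patterns[i, ]
  L <- matrix(0, 4L, length(s))
  miss <- s == 0L
  L[, miss] <- 1            # gaps/ambiguity: every state equally compatible
  L[cbind(s[!miss], which(!miss))] <- 1
  L
}

## internal: postorder partial likelihoods with per-node scaling.
## Returns list(part = list of 4 x P matrices, scale = P-vector of summed
## log scalers, order, parent, g).
pruning_partials <- function(tree, aln, model, root = NULL) {
  g <- tree_graph(tree)
  if (!setequal(g$labels, aln$taxa))
    stop_input("tree tip labels do not match alignment taxa")
  if (is.null(g$elen)) stop_input("tree has no branch lengths")
  if (is.null(root)) root <- if (g$n > g$ntip) g$ntip + 1L else 1L
  ro <- rooted_orders(g, root)
  P <- ncol(aln$patterns)
  row_of <- match(g$labels, aln$taxa)
  part <- vector("list", g$n)
  scale <- numeric(P)
  for (u in rev(ro$order)) {
    if (u <= g$ntip) {
      part[[u]] <- tip_partial(aln, row_of[u])
    } else {
      L <- matrix(1, 4L, P)
      for (v in g$adj[[u]]) {
        if (v == ro$parent[u]) next
        key <- paste(min(u, v), max(u, v), sep = "|")
        L <- L * (model$P(g$elen[[key]]) %*% part[[v]])
      }
      sc <- pmax(L[1L, ], pmax(L[2L, ], pmax(L[3L, ], L[4L, ])))
      sc[sc == 0] <- 1
      part[[u]] <- L / rep(sc, each = 4L)
      scale <- scale + log(sc)
    }
  }
  list(part = part, scale = scale, order = ro$order, parent = ro$parent,
       g = g, root = root)
}

#' Phylogenetic log-likelihood by the pruning algorithm
#'
#' Postorder partial-likelihood recursion with per-node scaling (safe for
#' thousands of sites). Under the reversible JC69 model the result is
#' invariant to the traversal root.
#'
#' @param tree A \code{"phylo"} tree with branch lengths.
#' @param aln A \code{"dna_alignment"} whose taxa match the tree tips.
#' @param model A \code{"subst_model"} (default JC69).
#' @param root Optional traversal root node.
#' @return Scalar log-likelihood.
#' @export
pruning_loglik <- function(tree, aln, model = jc69_model(), root = NULL) {
  pp <- pruning_partials(tree, aln, model, root)
  site <- log(as.numeric(model$eta %*% pp$part[[pp$root]])) + pp$scale
  sum(site * aln$weights)
}

#' Brute-force log-likelihood by summation over interior assignments
#'
#' Direct evaluation of the likelihood sum over all 4^k interior-node
#' character assignments. Test oracle only; limited to k <= 6.
#'
#' @inheritParams pruning_loglik
#' @return Scalar log-likelihood.
#' @export
brute_force_loglik <- function(tree, aln, model = jc69_model()) {
  g <- tree_graph(tree)
  if (!setequal(g$labels, aln$taxa))
    stop_input("tree tip labels do not match alignment taxa")
  nint <- g$n - g$ntip
  if (nint > 6L) stop_input("brute force limited to <= 6 interior nodes")
  E <- tree$edge
  Plist <- lapply(tree$edge.length, model$P)
  row_of <- match(g$labels, aln$taxa)
  P <- ncol(aln$patterns)
  sitelik <- numeric(P)
  states <- as.matrix(expand.grid(rep(list(1:4), nint)))
  for (k in seq_len(nrow(states))) {
    a <- integer(g$n)
    a[(g$ntip + 1L):g$n] <- states[k, ]
    term <- rep(0.25, P)  # eta at the (interior) root state
    for (i in seq_len(P)) {
      pr <- 1
      for (e in seq_len(nrow(E))) {
        u <- E[e, 1L]; v <- E[e, 2L]
        su <- if (u <= g$ntip) aln$patterns[row_of[u], i] else a[u]
        sv <- if (v <= g$ntip) aln$patterns[row_of[v], i] else a[v]
        if (su == 0L && sv == 0L) next
        if (su == 0L) pr <- pr * 1  # marginalized with the other endpoint
        else if (sv == 0L) pr <- pr * 1
        else pr <- pr * Plist[[e]][su, sv]
      }
      term[i] <- term[i] * pr
    }
    sitelik <- sitelik + term
  }
  sum(log(sitelik) * aln$weights)
}

## Analytic gradient of the log-likelihood with respect to every branch
## length. Returns a vector aligned with tree$edge rows. Uses downward
## partials plus an upward pass ("above" messages); scalers cancel in the
## per-site ratio.
loglik_branch_grad <- function(tree, aln, model = jc69_model(),
                               return_loglik = FALSE) {
  pp <- pruning_partials(tree, aln, model)
  g <- pp$g
  P <- ncol(aln$patterns)
  eta <- model$eta
  ## above[[v]]: 4 x P message arriving at v from the rest of the tree,
  ## excluding the transition along the edge (parent(v), v) itself
  above <- vector("list", g$n)
  above[[pp$root]] <- matrix(eta, 4L, P)
  site <- as.numeric(eta %*% pp$part[[pp$root]])
  grad_env <- numeric(nrow(tree$edge))
  ekey <- paste(pmin(tree$edge[, 1L], tree$edge[, 2L]),
                pmax(tree$edge[, 1L], tree$edge[, 2L]), sep = "|")
  for (u in pp$order) {
    kids <- g$adj[[u]]
    kids <- kids[kids != pp$parent[u]]
    if (!length(kids)) next
    ## transition-propagated child contributions
    tw <- lapply(kids, function(v) {
      key <- paste(min(u, v), max(u, v), sep = "|")
      model$P(g$elen[[key]]) %*% pp$part[[v]]
    })
    for (j in seq_along(kids)) {
      v <- kids[j]
      Ab <- above[[u]]
      for (l in seq_along(kids)) if (l != j) Ab <- Ab * tw[[l]]
      key <- paste(min(u, v), max(u, v), sep = "|")
      t_e <- g$elen[[key]]
      dnum <- colSums(Ab * (model$dP(t_e) %*% pp$part[[v]]))
      num <- colSums(Ab * tw[[j]])
      e_idx <- match(key, ekey)
      grad_env[e_idx] <- sum(aln$weights * dnum / num)
      above[[v]] <- crossprod(model$P(t_e), Ab)
    }
  }
  if (return_loglik)
    list(grad = grad_env, loglik = sum((log(site) + pp$scale) * aln$weights))
  else grad_env
}

#' Simulate an alignment along a tree
#'
#' Root state from the stationary distribution, states propagated edge-wise
#' through the transition matrices; sites i.i.d.
#'
#' @param tree A \code{"phylo"} tree with branch lengths.
#' @param M Number of sites.
#' @param model A \code{"subst_model"}.
#' @param seed Optional integer seed.
#' @return A \code{"dna_alignment"} for the tip taxa.
#' @export
simulate_alignment <- function(tree, M, model = jc69_model(), seed = NULL) {
  if (M < 1L) stop_input("need at least one site")
  g <- tree_graph(tree)
  root <- if (g$n > g$ntip) g$ntip + 1L else 1L
  ro <- rooted_orders(g, root)
  with_seed(seed, {
    states <- matrix(0L, g$n, M)
    states[root, ] <- sample.int(4L, M, replace = TRUE, prob = model$eta)
    for (u in ro$order[-1L]) {
      p <- ro$parent[u]
      key <- paste(min(u, p), max(u, p), sep = "|")
      Pm <- model$P(g$elen[[key]])
      cum <- t(apply(Pm, 1L, cumsum))
      r <- runif(M)
      sp <- states[p, ]
      states[u, ] <- 1L + rowSums(r > cum[sp, , drop = FALSE])
    }
    dna_alignment(g$labels, states[seq_len(g$ntip), , drop = FALSE])
  })
}
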