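## Subsplit Bayesian networks (SBNs) over unrooted bifurcating topologies.
##
## A subsplit of a clade is its bipartition into two child clades. An
## unrooted tree is decomposed by rooting it on each edge in turn: the root
## edge gives a root subsplit of the full taxon set, and every interior
## node below gives a parent-child subsplit pair. The SBN is the "simplest"
## variant: one conditional distribution per (parent subsplit, side) slot,
## shared across locations; Q(tau) is the sum of the rooted-tree
## probabilities over all 2N-3 edge rootings. Clades are encoded as integer
## bitmasks over taxa sorted lexicographically.

subsplit_key <- function(m1, m2) paste(min(m1, m2), max(m1, m2), sep = "|")
cond_key <- function(parent_key, clade) paste(parent_key, clade, sep = "/")

## Split key of a bipartition given the full-taxon mask: encode the side
## not containing taxon 1.
split_key_of <- function(mask, full) {
  if (bitwAnd(mask, 1L) == 1L) mask <- bitwXor(full, mask)
  as.character(mask)
}

## Directed clade masks for all edges: for edge row (u,v) of tree$edge,
## down[k] = tips on the v side; the u side is full - down[k].
directed_masks <- function(tree) {
  g <- tree_graph(tree)
  rank <- match(g$labels, sort(g$labels))
  root <- if (g$n > g$ntip) g$ntip + 1L else 1L
  ro <- rooted_orders(g, root)
  mask <- integer(g$n)
  for (u in rev(ro$order)) {
    if (u <= g$ntip) mask[u] <- bitwShiftL(1L, rank[u] - 1L)
    p <- ro$parent[u]
    if (p > 0L) mask[p] <- bitwOr(mask[p], mask[u])
  }
  full <- bitwShiftL(1L, g$ntip) - 1L
  E <- tree$edge
  child_is_2 <- ro$parent[E[, 2L]] == E[, 1L]
  down <- ifelse(child_is_2, mask[E[, 2L]], bitwXor(full, mask[E[, 1L]]))
  list(g = g, full = full, down = down, ro = ro, rank = rank)
}

## Decompose an unrooted tree into its rooted subsplit processes, one per
## edge rooting. Returns list(root_keys, pairs) where pairs[[r]] is a
## 2-column character matrix (cond slot, child subsplit) for rooting r.
## Shared across rootings, so also returns per-node subsplit info.
sbn_decompose <- function(tree) {
  dm <- directed_masks(tree)
  g <- dm$g
  E <- tree$edge
  full <- dm$full
  ## dirmask(u, v): tips strictly on the v side of edge u-v
  dmask <- new.env(parent = emptyenv())
  for (k in seq_len(nrow(E))) {
    assign(paste(E[k, 1L], E[k, 2L]), dm$down[k], envir = dmask)
    assign(paste(E[k, 2L], E[k, 1L]), bitwXor(full, dm$down[k]),
           envir = dmask)
  }
  dir_of <- function(u, v) get(paste(u, v), envir = dmask)
  ## subsplit of the clade headed by node u entered from neighbor v
  head_subsplit <- function(u, v) {
    kids <- g$adj[[u]]
    kids <- kids[kids != v]
    if (!length(kids)) return(NULL)
    if (length(kids) != 2L)
      stop_input("subsplit decomposition requires a bifurcating tree; ",
                 "node ", u, " has ", length(kids) + 1L, " neighbors")
    vapply(kids, function(w) dir_of(u, w), integer(1L))
  }
  harvest <- function(u, v, parent_key, clade, acc) {
    ## clade headed by u entered from v, with parent subsplit parent_key
    parts <- head_subsplit(u, v)
    if (is.null(parts)) return(acc)
    child <- subsplit_key(parts[1L], parts[2L])
    acc[[length(acc) + 1L]] <- c(cond_key(parent_key, clade), child)
    kids <- g$adj[[u]]
    kids <- kids[kids != v]
    for (j in seq_along(kids))
      acc <- harvest(kids[j], u, child, parts[j], acc)
    acc
  }
  root_keys <- character(nrow(E))
  pairs <- vector("list", nrow(E))
  for (k in seq_len(nrow(E))) {
    u <- E[k, 1L]; v <- E[k, 2L]
    mu <- dir_of(v, u); mv <- dir_of(u, v)
    s0 <- subsplit_key(mu, mv)
    root_keys[k] <- s0
    acc <- harvest(u, v, s0, mu, list())
    acc <- harvest(v, u, s0, mv, acc)
    pairs[[k]] <- do.call(rbind, c(acc, list(matrix(character(0), 0L, 2L))))
  }
  list(root_keys = root_keys, pairs = pairs, ntaxa = g$ntip)
}

## Split keys per edge (aligned with tree$edge rows).
edge_splits <- function(tree) {
  dm <- directed_masks(tree)
  vapply(dm$down, split_key_of, character(1L), full = dm$full)
}

## Primary subsplit pairs per edge: for each side of the edge that is an
## interior node, the subsplit of that side's clade. Keys are
## "<clade>-><m1>|<m2>"; pendant edges contribute one PSP.
edge_psps <- function(tree) {
  dm <- directed_masks(tree)
  g <- dm$g
  E <- tree$edge
  full <- dm$full
  dmaskv <- function(u, v) {
    k <- which(E[, 1L] == u & E[, 2L] == v)
    if (length(k)) return(dm$down[k])
    k <- which(E[, 1L] == v & E[, 2L] == u)
    bitwXor(full, dm$down[k])
  }
  side_psp <- function(u, v) {
    ## subsplit of the clade on u's side of edge u-v (headed by u)
    kids <- g$adj[[u]]
    kids <- kids[kids != v]
    if (!length(kids)) return(character(0))
    if (length(kids) != 2L)
      stop_input("PSPs require a bifurcating tree; node ", u, " has ",
                 length(kids) + 1L, " neighbors")
    parts <- vapply(kids, function(w) dmaskv(u, w), integer(1L))
    paste0(bitwXor(full, dmaskv(u, v)), "->", subsplit_key(parts[1L],
                                                           parts[2L]))
  }
  lapply(seq_len(nrow(E)), function(k)
    c(side_psp(E[k, 1L], E[k, 2L]), side_psp(E[k, 2L], E[k, 1L])))
}

#' Collect the SBN support and split/PSP sets from a tree sample
#'
#' Unions, over all trees and all edge rootings, the observed root
#' subsplits and parent-child subsplit slots; also collects the split set
#' and the primary-subsplit-pair (PSP) set used by the heuristic branch
#' parameterizations. Deterministic given the sample; duplicated trees do
#' not change the result.
#'
#' @param tree_sample List of \code{"phylo"} topologies on one taxon set.
#' @return An object of class \code{"sbn_support"}: list with \code{taxa},
#'   \code{root_keys}, \code{cond} (named list: slot -> child subsplit
#'   keys), \code{splits}, \code{psps}, \code{ntaxa}.
#' @export
collect_support <- function(tree_sample) {
  if (inherits(tree_sample, "phylo")) tree_sample <- list(tree_sample)
  if (!length(tree_sample)) stop_input("empty tree sample")
  taxa <- sort(tree_sample[[1L]]$tip.label)
  root_keys <- character(0)
  cond <- list()
  splits <- character(0)
  psps <- character(0)
  for (tr in tree_sample) {
    if (!setequal(sort(tr$tip.label), taxa))
      stop_input("trees in the sample have different taxon sets")
    dec <- sbn_decompose(tr)
    root_keys <- union(root_keys, dec$root_keys)
    for (p in dec$pairs) {
      for (k in seq_len(nrow(p))) {
        slot <- p[k, 1L]; child <- p[k, 2L]
        cond[[slot]] <- union(cond[[slot]], child)
      }
    }
    splits <- union(splits, edge_splits(tr))
    psps <- union(psps, unlist(edge_psps(tr)))
  }
  structure(list(taxa = taxa, ntaxa = length(taxa),
                 root_keys = sort(root_keys),
                 cond = cond[sort(names(cond))],
                 splits = sort(splits), psps = sort(psps)),
            class = "sbn_support")
}

#' Create an SBN model with softmax-parameterized CPTs
#'
#' Conditional probability tables are parameterized by unconstrained
#' logits, initialized at zero (uniform over each slot's support).
#'
#' @param support An \code{"sbn_support"}.
#' @return An \code{"sbn_model"}: support plus a parameter list with the
#'   root-subsplit logits and one logit vector per conditional slot.
#' @export
sbn_model <- function(support) {
  params <- c(list(root = setNames(numeric(length(support$root_keys)),
                                   support$root_keys)),
              lapply(support$cond, function(ch)
                setNames(numeric(length(ch)), ch)))
  names(params) <- c("root", paste0("c|", names(support$cond)))
  structure(list(support = support, params = params), class = "sbn_model")
}

log_softmax <- function(x) x - logsumexp(x)

#' SBN log-probability of an unrooted topology
#'
#' \code{log Q(tau)}: log-sum over the 2N-3 edge rootings of the product of
#' the root-subsplit probability and the parent-child conditional
#' probabilities. Topologies not composable from the support get
#' \code{-Inf} (with attribute \code{off_support = TRUE}).
#'
#' @param sbn An \code{"sbn_model"}.
#' @param tree A \code{"phylo"} unrooted bifurcating topology.
#' @param grad If \code{TRUE}, also return the gradient of log Q with
#'   respect to all CPT logits (same shapes as the parameter list).
#' @param dec Optional precomputed decomposition (internal caching).
#' @return Scalar log-probability (with attributes), or, with
#'   \code{grad = TRUE}, list(logprob, grads).
#' @export
sbn_logprob <- function(sbn, tree, grad = FALSE, dec = NULL) {
  if (is.null(dec)) dec <- sbn_decompose(tree)
  pms <- sbn$params
  lsm_root <- log_softmax(pms$root)
  lsm_cache <- list()
  nr <- length(dec$root_keys)
  lp <- numeric(nr)
  used <- vector("list", nr)
  for (r in seq_len(nr)) {
    s0 <- dec$root_keys[r]
    u <- list(c("root", s0))
    l <- if (s0 %in% names(lsm_root)) lsm_root[[s0]] else -Inf
    p <- dec$pairs[[r]]
    for (k in seq_len(nrow(p))) {
      slot <- paste0("c|", p[k, 1L]); child <- p[k, 2L]
      v <- pms[[slot]]
      if (is.null(v) || !(child %in% names(v))) { l <- -Inf; break }
      if (is.null(lsm_cache[[slot]]))
        lsm_cache[[slot]] <- log_softmax(v)
      l <- l + lsm_cache[[slot]][[child]]
      u[[length(u) + 1L]] <- c(slot, child)
    }
    lp[r] <- l
    used[[r]] <- u
  }
  logq <- logsumexp(lp)
  off <- !is.finite(logq)
  if (!grad) {
    attr(logq, "off_support") <- off
    return(logq)
  }
  grads <- lapply(pms, function(v) v * 0)
  if (!off) {
    w <- exp(lp - logq)
    for (r in seq_len(nr)) {
      if (w[r] == 0) next
      for (uk in used[[r]]) {
        slot <- uk[1L]; el <- uk[2L]
        sm <- exp(if (slot == "root") lsm_root else lsm_cache[[slot]])
        gi <- -sm * w[r]
        gi[[el]] <- gi[[el]] + w[r]
        grads[[slot]] <- grads[[slot]] + gi
      }
    }
  }
  list(logprob = logq, off_support = off, grads = grads)
}

## decode a bitmask to taxon labels
mask_taxa <- function(mask, taxa) {
  taxa[bitwAnd(bitwShiftR(mask, seq_along(taxa) - 1L), 1L) == 1L]
}

#' Sample a topology from an SBN
#'
#' Ancestral sampling: a root subsplit from its softmax distribution, then
#' child subsplits recursively down both sides.
#'
#' @param sbn An \code{"sbn_model"}.
#' @param seed Optional integer seed.
#' @return A \code{"phylo"} unrooted topology.
#' @export
sbn_sample <- function(sbn, seed = NULL) {
  with_seed(seed, parse_newick(sbn_sample_impl(sbn)$newick))
}

## sampling workhorse: returns the newick string plus the sampled clade
## masks (whose sorted set is a cache fingerprint of the rooted draw);
## parsing is left to the caller so repeated topologies can be cached
sbn_sample_impl <- function(sbn) {
  pms <- sbn$params
  taxa <- sbn$support$taxa
  pick <- function(logits) {
    p <- exp(log_softmax(logits))
    names(logits)[sample.int(length(logits), 1L, prob = p)]
  }
  clades <- integer(0)
  build <- function(parent_key, clade) {
    ## newick fragment for `clade` given its parent subsplit slot
    labs <- mask_taxa(clade, taxa)
    if (length(labs) == 1L) return(labs)
    slot <- paste0("c|", cond_key(parent_key, clade))
    v <- pms[[slot]]
    if (is.null(v)) stop_input("SBN support has no slot for clade ", clade)
    child <- pick(v)
    parts <- as.integer(strsplit(child, "|", fixed = TRUE)[[1L]])
    clades <<- c(clades, parts)
    paste0("(", build(child, parts[1L]), ",", build(child, parts[2L]), ")")
  }
  s0 <- pick(pms$root)
  parts <- as.integer(strsplit(s0, "|", fixed = TRUE)[[1L]])
  clades <- parts
  nwk <- paste0("(", build(s0, parts[1L]), ",", build(s0, parts[2L]), ");")
  list(clades = clades, newick = nwk,
       key = paste(sort(clades), collapse = ","))
}
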