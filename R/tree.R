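## Tree topology data model on top of ape's "phylo" class: newick I/O with
## validation, canonical form, exhaustive enumeration of small unrooted
## topology spaces, and uniform random topologies by sequential tip insertion.

default_taxa <- function(N) {
  if (N <= 26L) LETTERS[seq_len(N)] else sprintf("t%03d", seq_len(N))
}

## Undirected adjacency view of a phylo object.
## Returns list(n, ntip, labels, adj, elen) where elen is an n x n-keyed
## environment-free lookup implemented as a named vector on "i|j" (i < j).
tree_graph <- function(tree) {
  ntip <- length(tree$tip.label)
  n <- ntip + tree$Nnode
  adj <- vector("list", n)
  E <- tree$edge
  for (k in seq_len(nrow(E))) {
    a <- E[k, 1L]; b <- E[k, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  elen <- NULL
  if (!is.null(tree$edge.length)) {
    key <- paste(pmin(E[, 1L], E[, 2L]), pmax(E[, 1L], E[, 2L]), sep = "|")
    elen <- setNames(tree$edge.length, key)
  }
  list(n = n, ntip = ntip, labels = tree$tip.label, adj = adj, elen = elen)
}

## Rooted orders for traversal: returns list(order = preorder vector of
## nodes, parent = parent id per node (0 for root)). Root may be any node.
rooted_orders <- function(g, root) {
  n <- g$n
  parent <- integer(n)
  ord <- integer(n)
  ord[1L] <- root
  parent[root] <- 0L
  head_ <- 1L; tail_ <- 1L
  while (head_ <= tail_) {
    u <- ord[head_]
    for (v in g$adj[[u]]) {
      if (v != parent[u]) {
        tail_ <- tail_ + 1L
        ord[tail_] <- v
        parent[v] <- u
      }
    }
    head_ <- head_ + 1L
  }
  list(order = ord, parent = parent)
}

#' Parse a newick string into a phylogenetic tree
#'
#' Wraps \code{ape::read.tree} with strict validation: balanced parentheses,
#' unique non-empty tip labels, and non-negative branch lengths. By
#' convention a bifurcating root of degree 2 is collapsed (the unrooted
#' interpretation) when the tree has at least 3 tips.
#'
#' @param text A newick string (terminated by \code{";"}).
#' @param collapse_root Collapse a degree-2 root node (default \code{TRUE}).
#' @return An object of class \code{"phylo"}.
#' @export
parse_newick <- function(text, collapse_root = TRUE) {
  if (!is.character(text) || length(text) != 1L)
    stop_input("newick input must be a single character string")
  open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (open != close)
    stop_input("malformed newick: unbalanced parentheses in ", sQuote(text))
  if (!grepl(";\\s*$", text))
    stop_input("malformed newick: missing terminating ';'")
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop_input("malformed newick string: ", sQuote(text))
  if (any(tree$tip.label == "" | is.na(tree$tip.label)))
    stop_input("empty tip label in newick string")
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup))
    stop_input("duplicate tip label: ", sQuote(dup[1L]))
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    bad <- min(tree$edge.length)
    stop_input("negative branch length: ", format(bad))
  }
  if (collapse_root && length(tree$tip.label) >= 3L && ape::is.rooted(tree))
    tree <- ape::unroot(tree)
  tree
}

#' Write a tree to canonical newick form
#'
#' Deterministic output: for unrooted trees the traversal is rooted at the
#' interior node adjacent to the lexicographically smallest taxon, and at
#' every node children are ordered by the smallest taxon label contained in
#' their subtree. Two leaf-label-isomorphic trees with equal branch lengths
#' therefore produce identical strings.
#'
#' @param tree A \code{"phylo"} object.
#' @param digits Significant digits for branch lengths.
#' @return A newick string.
#' @export
write_newick <- function(tree, digits = 15L) {
  g <- tree_graph(tree)
  if (g$ntip < 2L) stop_input("tree must have at least 2 tips")
  if (ape::is.rooted(tree) && g$ntip >= 2L) {
    root <- g$ntip + 1L
  } else {
    small <- which(g$labels == sort(g$labels)[1L])
    root <- g$adj[[small]][1L]
    if (root <= g$ntip) root <- small  # 2-tip degenerate case
  }
  ro <- rooted_orders(g, root)
  ## smallest contained label per subtree, computed tips-up
  minlab <- rep(NA_character_, g$n)
  for (u in rev(ro$order)) {
    if (u <= g$ntip) lab <- g$labels[u] else lab <- minlab[u]
    p <- ro$parent[u]
    if (p > 0L && (is.na(minlab[p]) || lab < minlab[p])) minlab[p] <- lab
    if (u <= g$ntip) minlab[u] <- lab
  }
  fmt_len <- function(u, p) {
    if (is.null(g$elen)) return("")
    key <- paste(min(u, p), max(u, p), sep = "|")
    paste0(":", format(g$elen[[key]], digits = digits, trim = TRUE,
                       scientific = FALSE))
  }
  build <- function(u, p) {
    kids <- g$adj[[u]]
    kids <- kids[kids != p]
    if (!length(kids)) return(g$labels[u])
    kids <- kids[order(minlab[kids])]
    inner <- paste(vapply(kids, function(v)
      paste0(build(v, u), fmt_len(v, u)), character(1L)), collapse = ",")
    paste0("(", inner, ")")
  }
  paste0(build(root, 0L), ";")
}

## Split bitmasks: for every edge, the bitmask (over taxa in lexicographic
## label order, bit i = i-th smallest taxon) of the tips on the child side,
## normalized so the side NOT containing the smallest taxon is encoded.
edge_split_masks <- function(tree) {
  g <- tree_graph(tree)
  if (g$ntip > 30L) stop_input("split bitmask encoding supports at most 30 taxa")
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
  child <- ifelse(ro$parent[E[, 2L]] == E[, 1L], E[, 2L], E[, 1L])
  m <- mask[child]
  flip <- bitwAnd(m, 1L) == 1L
  m[flip] <- bitwXor(full, m[flip])
  m
}

#' Canonical topology key
#'
#' A hashable token equal for two trees if and only if they are
#' leaf-label-isomorphic as unrooted topologies. Built from the sorted set
#' of edge-induced taxon bipartitions (splits), which determine an unrooted
#' tree uniquely.
#'
#' @param tree A \code{"phylo"} object.
#' @return A character scalar.
#' @export
canonical_key <- function(tree) {
  m <- sort(unique(edge_split_masks(tree)))
  paste0(length(tree$tip.label), ":", paste(m, collapse = ","))
}

## Internal enumeration/building on raw integer edge matrices with tips
## 1..n and interior nodes n+1 .. 2n-2.
edges_to_newick <- function(E, labels) {
  n <- length(labels)
  nn <- max(E)
  adj <- vector("list", nn)
  for (k in seq_len(nrow(E))) {
    a <- E[k, 1L]; b <- E[k, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  build <- function(u, p) {
    kids <- adj[[u]]
    kids <- kids[kids != p]
    if (!length(kids)) return(labels[u])
    paste0("(", paste(vapply(kids, function(v) build(v, u), character(1L)),
                      collapse = ","), ")")
  }
  root <- if (nn > n) n + 1L else 1L
  paste0(build(root, 0L), ";")
}

insert_tip <- function(E, row, new_tip, new_int) {
  ## relabel interior ids >= new_tip by +1 to keep tips 1..n contiguous
  E2 <- E
  E2[E2 >= new_tip] <- E2[E2 >= new_tip] + 1L
  a <- E2[row, 1L]; b <- E2[row, 2L]
  rbind(E2[-row, , drop = FALSE],
        c(a, new_int), c(new_int, b), c(new_int, new_tip))
}

#' Enumerate all unrooted bifurcating topologies
#'
#' Exhaustive generation by sequential tip insertion: every topology on
#' \code{N} taxa arises from exactly one topology on \code{N - 1} taxa by
#' attaching the new tip to one of its \code{2N - 5} edges, so the space has
#' (2N-5)!! elements and is generated without duplicates.
#'
#' @param N Number of taxa, between 3 and 9.
#' @param labels Taxon labels (default \code{LETTERS[1:N]}).
#' @return A \code{"multiPhylo"} list of topologies.
#' @export
enumerate_unrooted <- function(N, labels = default_taxa(N)) {
  if (N < 3L || N > 9L)
    stop_input("enumeration supported for 3 <= N <= 9 (got ", N, ")")
  trees <- list(rbind(c(4L, 1L), c(4L, 2L), c(4L, 3L)))
  n <- 3L
  while (n < N) {
    n <- n + 1L
    out <- vector("list", length(trees) * (2L * n - 5L))
    j <- 0L
    for (E in trees) {
      for (row in seq_len(nrow(E))) {
        j <- j + 1L
        out[[j]] <- insert_tip(E, row, n, 2L * n - 2L)
      }
    }
    trees <- out
  }
  nwk <- vapply(trees, edges_to_newick, character(1L), labels = labels)
  res <- ape::read.tree(text = paste(nwk, collapse = "\n"))
  if (inherits(res, "phylo")) res <- c(res)  # N = 3: single star
  class(res) <- "multiPhylo"
  res
}

#' Random unrooted bifurcating topology
#'
#' Uniform over leaf-labelled unrooted bifurcating topologies, by sequential
#' insertion of each new tip into a uniformly chosen edge.
#'
#' @param N Number of taxa (>= 3).
#' @param seed Optional integer seed (caller's RNG state is restored).
#' @param labels Taxon labels.
#' @return A \code{"phylo"} topology without branch lengths.
#' @export
random_topology <- function(N, seed = NULL, labels = default_taxa(N)) {
  if (N < 3L) stop_input("need at least 3 taxa")
  with_seed(seed, {
    E <- rbind(c(4L, 1L), c(4L, 2L), c(4L, 3L))
    n <- 3L
    while (n < N) {
      n <- n + 1L
      row <- sample.int(nrow(E), 1L)
      E <- insert_tip(E, row, n, 2L * n - 2L)
    }
    ape::read.tree(text = edges_to_newick(E, labels))
  })
}
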