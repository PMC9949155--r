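## Deterministic synthetic-data generators: everything the tests, demos and
## experiments need, with no downloads. All generators are fully determined
## by their seed.

#' Synthetic VBPI fixture: alignment, support sample, and true tree
#'
#' Draws a true tree (uniform random topology, i.i.d. Exp(rate) branch
#' lengths), simulates a JC69 alignment of \code{M} sites along it, and
#' builds a support sample as the \code{m} topologies of the enumerated
#' space with the highest pruning log-likelihood at fixed branch lengths
#' (a deterministic, self-contained stand-in for bootstrap tree samples).
#'
#' @param N Taxon count (4..8; the space must be enumerable).
#' @param M Number of sites (default 500).
#' @param m Support size: number of top-ranked topologies (default 5;
#'   \code{Inf} takes the whole space).
#' @param rate Exponential branch-length rate (default 10, prior mean 0.1).
#' @param ranking_length Fixed branch length used when ranking topologies
#'   (default the prior mean \code{1 / rate}).
#' @param seed Integer seed.
#' @return List with \code{true_tree} (with branch lengths),
#'   \code{alignment}, \code{tree_sample} (list of topologies, best first),
#'   \code{support} (an \code{"sbn_support"}), and \code{ranked_keys}.
#' @export
make_vbpi_fixture <- function(N = 5L, M = 500L, m = 5L, rate = 10,
                              ranking_length = 1 / rate, seed = 1L) {
  if (N < 4L || N > 8L) stop_input("N must be in 4..8")
  with_seed(seed, {
    true_tree <- random_topology(N)
    true_tree$edge.length <- rexp(nrow(true_tree$edge), rate)
    aln <- simulate_alignment(true_tree, M)
    space <- enumerate_unrooted(N)
    ll <- vapply(space, function(tr) {
      tr$edge.length <- rep(ranking_length, nrow(tr$edge))
      pruning_loglik(tr, aln)
    }, numeric(1L))
    o <- order(ll, decreasing = TRUE)
    m_eff <- min(m, length(space))
    samp <- lapply(o[seq_len(m_eff)], function(i) space[[i]])
    list(true_tree = true_tree, alignment = aln, tree_sample = samp,
         support = collect_support(samp),
         ranked_keys = vapply(samp, canonical_key, character(1L)))
  })
}

#' Synthetic EBM fixture: Dirichlet target distribution
#'
#' Delegates to \code{\link{dirichlet_target}}; the topology order used for
#' the draw is the lexicographic canonical-key order stored in the result.
#'
#' @param N Taxon count (4..8).
#' @param beta Dirichlet concentration.
#' @param seed Integer seed.
#' @return A \code{"tree_distribution"}.
#' @export
make_ebm_fixture <- function(N = 7L, beta = 0.008 * 10395 / 945,
                             seed = 1L) {
  dirichlet_target(N, beta, seed)
}
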