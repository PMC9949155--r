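# shared helpers: small random instances built in code

random_phylo_with_lengths <- function(N, seed, rate = 10) {
  tr <- random_topology(N, seed = seed)
  tr$edge.length <- with_seed_helper(seed + 1000L, rexp(nrow(tr$edge), rate))
  tr
}

with_seed_helper <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# central finite-difference check of d D / d theta for an energy model on
# a tree set; returns the max relative error over `per_param` entries each
fd_relerr_energy <- function(model, trees, per_param = 2L, eps = 1e-5) {
  cache <- phylotopo:::gnn_cache(trees)
  gs <- phylotopo:::gnn_assemble(cache,
                                 need = phylotopo:::gnn_needs(model$net$variant))
  tp <- phylotopo:::ad_tape()
  fw <- phylotopo:::ebm_forward(model, gs, tp)
  ad_backward <- phylotopo:::ad_backward
  ad_backward(tp, fw$D, matrix(1, gs$n_graphs, 1L))
  grads <- lapply(fw$ids, function(i) phylotopo:::ad_grad(tp, i))
  worst <- 0
  for (pn in names(model$params)) {
    P <- model$params[[pn]]
    idx <- with_seed_helper(7L, sample(length(P), min(per_param, length(P))))
    for (i in idx) {
      mp <- model; mp$params[[pn]][i] <- P[i] + eps
      mm <- model; mm$params[[pn]][i] <- P[i] - eps
      fd <- sum(phylotopo:::ebm_dvalues(mp, cache) -
                  phylotopo:::ebm_dvalues(mm, cache)) / (2 * eps)
      an <- grads[[pn]][i]
      worst <- max(worst, abs(an - fd) / max(1e-8, abs(an) + abs(fd)))
    }
  }
  worst
}
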