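test_that("JC69 transition matrices behave like a Markov semigroup", {
  expect_equal(unname(jc69_transition(0)), diag(4), tolerance = 1e-15)
  expect_equal(unname(jc69_transition(500)), matrix(0.25, 4, 4),
               tolerance = 1e-12)
  ## frozen value cross-checked against the matrix exponential of the rate
  ## matrix (expm oracle)
  expect_equal(jc69_transition(0.1)[1, 1], 0.25 + 0.75 * exp(-0.4 / 3),
               tolerance = 1e-15)
  Q <- matrix(1 / 3, 4, 4); diag(Q) <- -1
  expect_lt(max(abs(as.matrix(Matrix::expm(Q * 0.37)) -
                      jc69_transition(0.37))), 1e-12)
  ## Chapman-Kolmogorov
  expect_lt(max(abs(jc69_transition(0.3) %*% jc69_transition(0.45) -
                      jc69_transition(0.75))), 1e-12)
  expect_error(jc69_transition(-0.1), "negative")
})

test_that("pruning matches the single-edge closed form", {
  tr <- ape::read.tree(text = "(A:0.05,B:0.05);")
  aln <- dna_alignment(c("A", "B"), matrix(c("A", "A"), nrow = 2))
  expect_equal(pruning_loglik(tr, aln),
               log(0.25 * (0.25 + 0.75 * exp(-4 * 0.1 / 3))),
               tolerance = 1e-12)
})

test_that("pruning equals brute-force summation over interior assignments", {
  worst <- 0
  for (i in 1:12) {
    N <- with_seed_helper(i, sample(4:6, 1L))
    tr <- random_phylo_with_lengths(N, seed = 500L + i)
    aln <- simulate_alignment(tr, 6, seed = 600L + i)
    l1 <- pruning_loglik(tr, aln)
    l2 <- brute_force_loglik(tr, aln)
    worst <- max(worst, abs(l1 - l2) / abs(l2))
  }
  expect_lt(worst, 1e-10)
})

test_that("the likelihood is invariant to root placement and child order", {
  tr <- random_phylo_with_lengths(6, seed = 77)
  aln <- simulate_alignment(tr, 50, seed = 78)
  base <- pruning_loglik(tr, aln)
  g <- phylotopo:::tree_graph(tr)
  for (r in (g$ntip + 1L):g$n)
    expect_lt(abs(pruning_loglik(tr, aln, root = r) - base), 1e-10)
  rewritten <- parse_newick(write_newick(tr))
  expect_lt(abs(pruning_loglik(rewritten, aln) - base), 1e-10)
})

test_that("pruning agrees with an independent implementation", {
  skip_if_not_installed("phangorn")
  tr <- random_phylo_with_lengths(6, seed = 42)
  aln <- simulate_alignment(tr, 120, seed = 43)
  pd <- phangorn::phyDat(matrix(c("a", "c", "g", "t")[aln$seq], nrow = 6,
                                dimnames = list(aln$taxa, NULL)),
                         type = "DNA")
  expect_equal(pruning_loglik(tr, aln), phangorn::pml(tr, pd)$logLik,
               tolerance = 1e-8)
})

test_that("degenerate cases follow the stationary law", {
  ## zero-length branches, one site, same character everywhere
  tr <- random_topology(5, seed = 3)
  tr$edge.length <- rep(0, nrow(tr$edge))
  aln <- dna_alignment(tr$tip.label, matrix("G", 5, 3))
  expect_equal(brute_force_loglik(tr, aln), 3 * log(0.25),
               tolerance = 1e-12)
  expect_equal(pruning_loglik(tr, aln), 3 * log(0.25), tolerance = 1e-12)
})

test_that("analytic branch gradients match central finite differences", {
  tr <- random_phylo_with_lengths(6, seed = 55)
  aln <- simulate_alignment(tr, 80, seed = 56)
  gr <- phylotopo:::loglik_branch_grad(tr, aln)
  for (e in seq_len(nrow(tr$edge))) {
    tp <- tr; tp$edge.length[e] <- tp$edge.length[e] + 1e-6
    tm <- tr; tm$edge.length[e] <- tm$edge.length[e] - 1e-6
    fd <- (pruning_loglik(tp, aln) - pruning_loglik(tm, aln)) / 2e-6
    expect_lt(abs(gr[e] - fd) / (abs(fd) + 1e-8), 1e-4)
  }
})

test_that("the simulator matches the model it simulates from", {
  tr <- random_topology(4, seed = 20)
  tr$edge.length <- rep(0, nrow(tr$edge))
  a0 <- simulate_alignment(tr, 30, seed = 21)
  expect_true(all(apply(a0$seq, 2L, function(x) length(unique(x))) == 1L))

  trl <- random_topology(4, seed = 22)
  trl$edge.length <- rep(8, nrow(trl$edge))
  al <- simulate_alignment(trl, 4000, seed = 23)
  freqs <- tabulate(al$seq, 4) / length(al$seq)
  se <- sqrt(0.25 * 0.75 / length(al$seq))
  expect_true(all(abs(freqs - 0.25) < 3 * se))

  ## likelihood consistency: the generating topology is preferred
  wins <- 0L
  for (s in 1:10) {
    true <- random_phylo_with_lengths(5, seed = 700L + s)
    aln <- simulate_alignment(true, 2000, seed = 800L + s)
    other <- random_topology(5, seed = 900L + s)
    while (canonical_key(other) == canonical_key(true))
      other <- random_topology(5, seed = 950L + s)
    other$edge.length <- true$edge.length
    if (pruning_loglik(true, aln) >= pruning_loglik(other, aln))
      wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("FASTA alignments round-trip through disk", {
  tr <- random_phylo_with_lengths(5, seed = 31)
  aln <- simulate_alignment(tr, 40, seed = 32)
  f <- tempfile(fileext = ".fasta")
  write_fasta_alignment(aln, f)
  back <- read_fasta_alignment(f)
  expect_identical(back$seq, aln$seq)
  expect_identical(back$taxa, aln$taxa)
  unlink(f)
})
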