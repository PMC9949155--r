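fx5 <- make_vbpi_fixture(N = 5, M = 300, m = 5, seed = 3)

test_that("support collection counts splits as expected", {
  s1 <- collect_support(list(parse_newick("((A,B),(C,D));")))
  expect_equal(length(s1$splits), 5L)  # 4 trivial + AB|CD

  s3 <- collect_support(as.list(enumerate_unrooted(4)))
  expect_equal(length(s3$splits), 7L)  # 4 trivial + 3 nontrivial

  q <- parse_newick("((A,B),(C,D));")
  expect_identical(collect_support(list(q, q, q)), collect_support(list(q)))

  expect_error(collect_support(list(q, parse_newick("((A,B),(C,E));"))),
               "taxon sets")

  ## multifurcations are fine for parsing and embedding but not for the
  ## subsplit machinery
  star <- parse_newick("(A,B,C,D);")
  expect_error(collect_support(list(star)), "bifurcating")
})

test_that("SBN probabilities normalize and concentrate correctly", {
  q <- parse_newick("((A,B),(C,D));")
  m1 <- sbn_model(collect_support(list(q)))
  expect_equal(as.numeric(sbn_logprob(m1, q)), 0, tolerance = 1e-12)

  ## uniform CPTs over the full quartet support treat the 3 topologies
  ## symmetrically
  quartets <- as.list(enumerate_unrooted(4))
  mq <- sbn_model(collect_support(quartets))
  lps <- vapply(quartets, function(tr) as.numeric(sbn_logprob(mq, tr)),
                numeric(1L))
  expect_lt(diff(range(lps)), 1e-12)
  expect_equal(sum(exp(lps)), 1, tolerance = 1e-8)

  ## randomized CPTs on a partial 5-taxon support still normalize over the
  ## enumerated space
  m <- sbn_model(fx5$support)
  m$params <- lapply(m$params, function(v)
    setNames(with_seed_helper(4L, rnorm(length(v))), names(v)))
  tot <- sum(vapply(enumerate_unrooted(5), function(tr)
    exp(as.numeric(sbn_logprob(m, tr))), numeric(1L)))
  expect_equal(tot, 1, tolerance = 1e-8)
})

test_that("off-support topologies are flagged with a -Inf sentinel", {
  m <- sbn_model(fx5$support)
  off <- NULL
  for (i in 1:100) {
    cand <- random_topology(5, seed = 1000L + i)
    if (!(canonical_key(cand) %in% fx5$ranked_keys)) { off <- cand; break }
  }
  lp <- sbn_logprob(m, off)
  expect_identical(as.numeric(lp), -Inf)
  expect_true(attr(lp, "off_support"))
})

test_that("SBN sampling follows the model distribution", {
  q <- parse_newick("((A,B),(C,D));")
  m1 <- sbn_model(collect_support(list(q)))
  for (i in 1:5)
    expect_identical(canonical_key(sbn_sample(m1, seed = i)),
                     canonical_key(q))
  expect_identical(canonical_key(sbn_sample(m1, seed = 9)),
                   canonical_key(sbn_sample(m1, seed = 9)))

  quartets <- as.list(enumerate_unrooted(4))
  mq <- sbn_model(collect_support(quartets))
  keys <- vapply(quartets, canonical_key, character(1L))
  draws <- with_seed_helper(11L, vapply(seq_len(3000), function(i)
    canonical_key(phylotopo:::parse_newick(
      phylotopo:::sbn_sample_impl(mq)$newick)), character(1L)))
  emp <- as.numeric(table(factor(draws, levels = keys))) / 3000
  se <- sqrt((1 / 3) * (2 / 3) / 3000)
  expect_true(all(abs(emp - 1 / 3) < 3 * se))
})

test_that("SBN log-probability gradients match finite differences", {
  m <- sbn_model(fx5$support)
  m$params <- lapply(m$params, function(v)
    setNames(with_seed_helper(5L, rnorm(length(v))), names(v)))
  tr <- fx5$tree_sample[[2L]]
  g <- sbn_logprob(m, tr, grad = TRUE)
  for (pn in names(m$params)[1:3]) {
    for (i in seq_len(min(2L, length(m$params[[pn]])))) {
      eps <- 1e-6
      mp <- m; mp$params[[pn]][i] <- mp$params[[pn]][i] + eps
      mm <- m; mm$params[[pn]][i] <- mm$params[[pn]][i] - eps
      fd <- (as.numeric(sbn_logprob(mp, tr)) -
               as.numeric(sbn_logprob(mm, tr))) / (2 * eps)
      expect_lt(abs(g$grads[[pn]][i] - fd), 1e-6)
    }
  }
})

test_that("PSP with zeroed refinements reduces exactly to split mode", {
  msp <- vbpi_model(fx5$support, "split")
  mps <- vbpi_model(fx5$support, "psp")
  for (tr in fx5$tree_sample)
    expect_identical(branch_mu_sigma(msp$branch, tr),
                     branch_mu_sigma(mps$branch, tr))

  ## all-zero split tables give mu = sigma-log = 0 on every edge
  z <- vbpi_model(fx5$support, "split", init_mu = 0, init_logsigma = 0)
  ms <- branch_mu_sigma(z$branch, fx5$tree_sample[[1L]])
  expect_true(all(ms$mu == 0) && all(ms$logsigma == 0))
})

test_that("split/psp lookups fail off support while gnn mode does not", {
  off <- NULL
  for (i in 1:100) {
    cand <- random_topology(5, seed = 2000L + i)
    if (!(canonical_key(cand) %in% fx5$ranked_keys)) { off <- cand; break }
  }
  msp <- vbpi_model(fx5$support, "split")
  expect_error(branch_mu_sigma(msp$branch, off), "support")
  mgn <- vbpi_model(fx5$support, "gnn", hidden = 8, seed = 4)
  ms <- branch_mu_sigma(mgn$branch, off)
  expect_true(all(is.finite(ms$mu)) && all(is.finite(ms$logsigma)))
})

test_that("learnable branch parameters are invariant to the written form", {
  mgn <- vbpi_model(fx5$support, "gnn", hidden = 8, seed = 5)
  tr1 <- fx5$tree_sample[[1L]]
  tr2 <- parse_newick(write_newick(tr1))  # same topology, other indexing
  s1 <- branch_mu_sigma(mgn$branch, tr1)
  s2 <- branch_mu_sigma(mgn$branch, tr2)
  k1 <- phylotopo:::edge_splits(tr1)
  k2 <- phylotopo:::edge_splits(tr2)
  expect_equal(s1$mu[order(k1)], s2$mu[order(k2)], tolerance = 1e-10)
  expect_equal(s1$logsigma[order(k1)], s2$logsigma[order(k2)],
               tolerance = 1e-10)
})

test_that("Lognormal branch density has the right analytic properties", {
  expect_equal(lognormal_branch_logq(1, 0, 0), -log(sqrt(2 * pi)),
               tolerance = 1e-12)
  expect_identical(as.numeric(lognormal_branch_logq(c(0.5, 0), c(0, 0),
                                                    c(0, 0))), -Inf)
  ## Monte-Carlo mean of the reparameterized sample
  mu <- -2; ls <- log(0.4)
  qs <- with_seed_helper(14L, exp(mu + exp(ls) * rnorm(40000)))
  m_th <- exp(mu + exp(ls)^2 / 2)
  se <- stats::sd(qs) / sqrt(length(qs))
  expect_lt(abs(mean(qs) - m_th), 3 * se)
  ## density integrates to one (quadrature oracle)
  ig <- stats::integrate(function(q)
    exp(vapply(q, function(x) lognormal_branch_logq(x, mu, ls),
               numeric(1L))), 0, Inf)
  expect_lt(abs(ig$value - 1), 1e-4)
})

test_that("reparameterization branch gradients match finite differences", {
  tr <- fx5$tree_sample[[1L]]
  aln <- fx5$alignment
  E <- nrow(tr$edge)
  mu <- rep(log(0.1), E); ls <- rep(-2, E)
  eps <- with_seed_helper(21L, rnorm(E))
  rate <- 10
  logw_of <- function(mu, ls) {
    q <- exp(mu + exp(ls) * eps)
    tq <- tr; tq$edge.length <- q
    pruning_loglik(tq, aln) + sum(dexp(q, rate, log = TRUE)) -
      lognormal_branch_logq(q, mu, ls)
  }
  q <- exp(mu + exp(ls) * eps)
  tq <- tr; tq$edge.length <- q
  gq <- phylotopo:::loglik_branch_grad(tq, aln) - rate
  dmu <- gq * q + 1
  dls <- (gq * q + 1) * exp(ls) * eps + 1
  h <- 1e-6
  for (e in seq_len(E)) {
    mp <- mu; mp[e] <- mp[e] + h
    mm <- mu; mm[e] <- mm[e] - h
    fd <- (logw_of(mp, ls) - logw_of(mm, ls)) / (2 * h)
    expect_lt(abs(dmu[e] - fd) / (abs(fd) + 1e-8), 1e-4)
    lp <- ls; lp[e] <- lp[e] + h
    lm <- ls; lm[e] <- lm[e] - h
    fd <- (logw_of(mu, lp) - logw_of(mu, lm)) / (2 * h)
    expect_lt(abs(dls[e] - fd) / (abs(fd) + 1e-8), 1e-4)
  }
})

test_that("VIMCO handles degenerate and K = 1 inputs", {
  vs <- phylotopo:::vimco_signals(c(2, 2, 2))
  expect_true(all(is.finite(vs$signal)))
  expect_lt(diff(range(vs$signal)), 1e-12)

  g1 <- list(list(root = c(a = 1, b = -1)))
  expect_warning(out <- vimco_topology_gradient(0.5, g1), "K >= 2")
  expect_equal(out$root, (0.5 - 1) * g1[[1L]]$root)
})

test_that("importance sampling of a single edge matches quadrature", {
  ## 2-taxon model: the likelihood depends on the total path length, whose
  ## prior is Gamma(2, rate); the evidence is a 1-D integral
  tr <- ape::read.tree(text = "(A:0.1,B:0.1);")
  aln <- with_seed_helper(31L, simulate_alignment(
    {t0 <- tr; t0$edge.length <- c(0.08, 0.08); t0}, 10))
  rate <- 10
  lik_of_total <- function(s) {
    vapply(s, function(si) {
      t2 <- tr; t2$edge.length <- c(si / 2, si / 2)
      exp(pruning_loglik(t2, aln))
    }, numeric(1L))
  }
  quad <- stats::integrate(function(s)
    lik_of_total(s) * stats::dgamma(s, 2, rate), 0, Inf, rel.tol = 1e-9)
  ## a deliberately wide proposal keeps the importance weights light-tailed
  mu <- c(log(0.08), log(0.08)); ls <- c(log(1.3), log(1.3))
  n <- 8000
  lw <- with_seed_helper(32L, vapply(seq_len(n), function(i) {
    q <- exp(mu + exp(ls) * rnorm(2))
    t2 <- tr; t2$edge.length <- q
    pruning_loglik(t2, aln) + sum(dexp(q, rate, log = TRUE)) -
      lognormal_branch_logq(q, mu, ls)
  }, numeric(1L)))
  m <- max(lw); w <- exp(lw - m)
  est <- m + log(mean(w))
  se <- stats::sd(w) / (mean(w) * sqrt(n))
  expect_lt(abs(est - log(quad$value)), 3 * se + 1e-6)
})

test_that("marginal-likelihood standard errors shrink with sample size", {
  m <- vbpi_model(fx5$support, "split", K = 5)
  fit <- train_vbpi(m, fx5$alignment, iters = 150, seed = 2)
  small <- marginal_likelihood_is(fit$model, fx5$alignment, 200, seed = 3)
  big <- marginal_likelihood_is(fit$model, fx5$alignment, 1800, seed = 4)
  expect_lt(big$se, small$se)
  expect_true(is.finite(small$logml) && is.finite(big$logml))
})

test_that("training is inert at zero learning rate and seeded otherwise", {
  m <- vbpi_model(fx5$support, "split", K = 3, anneal_steps = 500)
  fit0 <- train_vbpi(m, fx5$alignment, iters = 20, lr = 0, seed = 5)
  expect_identical(fit0$model$branch$params, m$branch$params)
  expect_identical(fit0$model$sbn$params, m$sbn$params)

  f1 <- train_vbpi(m, fx5$alignment, iters = 30, seed = 6)
  f2 <- train_vbpi(m, fx5$alignment, iters = 30, seed = 6)
  expect_identical(f1$trace, f2$trace)
})

test_that("the amortization gap vanishes with zero per-tree steps", {
  m <- vbpi_model(fx5$support, "split", K = 5)
  fit <- train_vbpi(m, fx5$alignment, iters = 100, seed = 7)
  g <- amortization_gap(fit$model, fx5$tree_sample[[1L]], fx5$alignment,
                        per_tree_opt_iters = 0, n_eval = 10, seed = 8)
  expect_equal(g$gap, 0)
})
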