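test_that("Dirichlet targets are valid, seeded, and concentration behaves", {
  d <- dirichlet_target(5, beta = 0.1, seed = 3)
  expect_equal(length(d$probs), 15L)
  expect_equal(sum(d$probs), 1, tolerance = 1e-12)
  expect_identical(d$probs, dirichlet_target(5, beta = 0.1, seed = 3)$probs)

  flat <- dirichlet_target(5, beta = 1e6, seed = 3)
  expect_lt(max(flat$probs) / min(flat$probs), 1.2)
})

test_that("a zero discriminator scores the coin-flip NCE loss", {
  m <- energy_model("mlp", N = 4, hidden = 4, seed = 1)
  m$params <- lapply(m$params, function(p) p * 0)
  trees <- enumerate_unrooted(4)
  loss <- nce_loss(m, trees, trees)
  expect_equal(loss, 2 * log(2), tolerance = 1e-12)
})

test_that("the exact log-ratio attains J*", {
  p <- dirichlet_target(5, beta = 0.5, seed = 11)
  pn <- uniform_over_space(p)
  Dstar <- log(p$probs) - log(pn$probs)
  loss <- phylotopo:::nce_loss_exact(Dstar, p$probs, pn$probs)
  expect_equal(loss, optimal_nce_loss(p, pn), tolerance = 1e-9)
})

test_that("optimal NCE loss follows the Jensen-Shannon divergence", {
  p <- dirichlet_target(4, beta = 1, seed = 1)
  expect_equal(optimal_nce_loss(p, p), 2 * log(2), tolerance = 1e-12)

  ## disjoint point masses: JSD = log 2, loss bottoms out at zero
  pm1 <- p; pm1$probs <- c(1, 0, 0)
  pm2 <- p; pm2$probs <- c(0, 1, 0)
  expect_equal(optimal_nce_loss(pm1, pm2), 0, tolerance = 1e-12)

  ## independent JSD summation oracle on random pairs
  for (i in 1:5) {
    a <- dirichlet_target(5, beta = 0.7, seed = 20L + i)
    b <- dirichlet_target(5, beta = 0.7, seed = 40L + i)
    kl <- function(x, y) sum(ifelse(x > 0, x * (log(x) - log(y)), 0))
    mm <- (a$probs + b$probs) / 2
    jsd <- (kl(a$probs, mm) + kl(b$probs, mm)) / 2
    expect_equal(optimal_nce_loss(a, b), 2 * log(2) - 2 * jsd,
                 tolerance = 1e-12)
  }
})

test_that("model probabilities normalize and reduce to noise for flat D", {
  p <- dirichlet_target(5, beta = 0.3, seed = 2)
  pn <- uniform_over_space(p)
  m <- energy_model("gcn", N = 5, hidden = 6, seed = 5)
  q <- model_probs(m, pn)
  expect_true(all(q$probs >= 0))
  expect_equal(sum(q$probs), 1, tolerance = 1e-9)

  mz <- m
  mz$params <- lapply(mz$params, function(x) x * 0)  # D constant (zero)
  qz <- model_probs(mz, p)
  expect_equal(qz$probs, p$probs, tolerance = 1e-12)
})

test_that("KL divergence matches direct summation and is nonnegative", {
  p <- dirichlet_target(4, beta = 1, seed = 1)
  expect_equal(kl_to_target(p, p), 0)

  pu <- p; pu$probs <- rep(1 / 3, 3)
  q <- p; q$probs <- c(1 / 2, 1 / 4, 1 / 4)
  direct <- sum(pu$probs * (log(pu$probs) - log(q$probs)))
  expect_equal(kl_to_target(pu, q), direct, tolerance = 1e-12)

  with_seed_helper(8L, for (i in 1:200) {
    a <- p; a$probs <- as.numeric(rmultinom(1, 50, rep(1, 3))) / 50
    b <- p; b$probs <- exp(rnorm(3)); b$probs <- b$probs / sum(b$probs)
    expect_gte(kl_to_target(a, b), 0)
  })
})

test_that("no discriminator beats the J* lower bound", {
  p <- dirichlet_target(5, beta = 0.3, seed = 13)
  pn <- uniform_over_space(p)
  jstar <- optimal_nce_loss(p, pn)
  cache <- phylotopo:::gnn_cache(p$trees)
  for (s in 1:5) {
    m <- energy_model("sage", N = 5, hidden = 6, seed = 30L + s)
    D <- phylotopo:::ebm_dvalues(m, cache)
    expect_gte(phylotopo:::nce_loss_exact(D, p$probs, pn$probs), jstar)
  }
})

test_that("NCE training on a uniform target stays at the coin-flip loss", {
  p0 <- dirichlet_target(5, beta = 1, seed = 6)
  p0 <- uniform_over_space(p0)
  m <- energy_model("gcn", N = 5, hidden = 8, seed = 2)
  fit <- train_nce(m, p0, steps = 300, batch = 32, seed = 3,
                   eval_every = 300)
  expect_lt(abs(fit$final_nce - 2 * log(2)), 0.02)
  expect_lt(fit$final_kl, 0.05)
})

test_that("training is reproducible given the seed", {
  p0 <- dirichlet_target(4, beta = 0.5, seed = 9)
  m <- energy_model("gin", N = 4, hidden = 6, seed = 4)
  f1 <- train_nce(m, p0, steps = 60, batch = 16, seed = 7, eval_every = 20)
  f2 <- train_nce(m, p0, steps = 60, batch = 16, seed = 7, eval_every = 20)
  expect_identical(f1$trace, f2$trace)
})
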