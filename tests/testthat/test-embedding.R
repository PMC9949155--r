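test_that("two-pass embedding solves the small cases exactly", {
  star <- parse_newick("(A,B,C);")
  emb <- two_pass_embed(star)
  expect_equal(unname(emb$features[4L, ]), rep(1 / 3, 3), tolerance = 1e-12)

  q <- parse_newick("((A,B),(C,D));")
  embq <- two_pass_embed(q)
  ## hand-solved stationarity system: 3 x_u = x_A + x_B + x_v,
  ## 3 x_v = x_C + x_D + x_u
  inter <- embq$features[!embq$is_tip, ]
  ab <- inter[which.max(inter[, 1L]), ]
  cd <- inter[which.min(inter[, 1L]), ]
  expect_equal(unname(ab), c(3, 3, 1, 1) / 8, tolerance = 1e-12)
  expect_equal(unname(cd), c(1, 1, 3, 3) / 8, tolerance = 1e-12)

  ## constant tip features give the constant solution
  tr <- random_topology(7, seed = 2)
  w <- matrix(rep(c(0.3, -1.2), each = 7), 7,
              dimnames = list(tr$tip.label, NULL))
  embc <- two_pass_embed(tr, w)
  expect_true(all(abs(sweep(embc$features, 2L, c(0.3, -1.2))) < 1e-12))
})

test_that("two-pass equals the dense oracle for one-hot and Gaussian tips", {
  worst <- 0
  for (i in 1:15) {
    N <- with_seed_helper(i, sample(4:30, 1L))
    tr <- random_topology(N, seed = i)
    e1 <- two_pass_embed(tr)
    e2 <- dense_embed_oracle(tr)
    worst <- max(worst, max(abs(e1$features - e2$features)))
    Xg <- with_seed_helper(100L + i,
      matrix(rnorm(N * 3), N, dimnames = list(tr$tip.label, NULL)))
    worst <- max(worst, max(abs(two_pass_embed(tr, Xg)$features -
                                  dense_embed_oracle(tr, Xg)$features)))
  }
  expect_lt(worst, 1e-8)
})

test_that("stationarity residuals vanish and traversal root does not matter", {
  tr <- random_topology(12, seed = 3)
  emb <- two_pass_embed(tr)
  g <- phylotopo:::tree_graph(tr)
  for (u in which(!emb$is_tip)) {
    res <- length(g$adj[[u]]) * emb$features[u, ] -
      colSums(emb$features[g$adj[[u]], , drop = FALSE])
    expect_lt(max(abs(res)), 1e-8 * ncol(emb$features))
  }
  base <- emb$features
  for (r in c(1L, 13L, 2L * 12L - 2L)) {
    expect_lt(max(abs(two_pass_embed(tr, root = r)$features - base)), 1e-10)
  }
})

test_that("one-hot interior rows are strict convex weights (extremum principle)", {
  for (i in 1:10) {
    N <- with_seed_helper(200L + i, sample(4:30, 1L))
    tr <- random_topology(N, seed = 300L + i)
    emb <- two_pass_embed(tr)
    inter <- emb$features[!emb$is_tip, , drop = FALSE]
    expect_true(all(inter > 0 & inter < 1))
    expect_true(all(abs(rowSums(inter) - 1) < 1e-9))
    ## first-pass coefficients stay in [0, 1/2] on bifurcating trees
    cc <- emb$coef_c[!emb$is_tip]
    cc <- cc[!is.na(cc)]
    expect_true(all(cc >= 0 & cc <= 0.5 + 1e-12))
    ## per-component extrema over all nodes are attained at tips
    for (d in seq_len(ncol(emb$features))) {
      col <- emb$features[, d]
      expect_equal(max(col), max(col[emb$is_tip]))
      expect_equal(min(col), min(col[emb$is_tip]))
    }
  }
})

test_that("the embedding minimizes the Dirichlet energy", {
  tr <- random_topology(10, seed = 9)
  emb <- two_pass_embed(tr)
  e0 <- dirichlet_energy(tr, emb$features)
  with_seed_helper(99L, {
    for (i in 1:50) {
      pert <- emb$features
      io <- which(!emb$is_tip)
      pert[io, ] <- pert[io, ] + matrix(rnorm(length(io) * 10, sd = 0.01),
                                        length(io))
      expect_gt(dirichlet_energy(tr, pert), e0)
    }
  })
})

test_that("tip neighbors are decodable from the embedding alone", {
  q <- parse_newick("((A,B),(C,D));")
  dec <- tip_neighbor_decode(two_pass_embed(q))
  g <- phylotopo:::tree_graph(q)
  for (tip in 1:4)
    expect_equal(unname(dec[[g$labels[tip]]]), g$adj[[tip]][1L])

  star <- parse_newick("(A,B,C);")
  expect_true(all(tip_neighbor_decode(two_pass_embed(star)) == 4L))

  for (i in 1:20) {
    tr <- random_topology(10, seed = 400L + i)
    dec <- tip_neighbor_decode(two_pass_embed(tr))
    g <- phylotopo:::tree_graph(tr)
    for (tip in seq_len(10))
      expect_equal(unname(dec[[g$labels[tip]]]), g$adj[[tip]][1L])
  }
})

test_that("non-one-hot tips without coefficients are rejected", {
  tr <- random_topology(5, seed = 1)
  Xg <- with_seed_helper(1L, matrix(rnorm(15), 5,
                                    dimnames = list(tr$tip.label, NULL)))
  expect_error(tip_neighbor_decode(two_pass_embed(tr, Xg)), "one-hot")
})

test_that("embeddings identify the topology over the whole 5-taxon space", {
  rep <- embeddings_distinct(5)
  expect_equal(rep$n_topologies, 15L)
  expect_true(rep$distinct)
})

test_that("the algorithm makes exactly two traversals", {
  for (N in c(5L, 20L, 40L)) {
    tr <- random_topology(N, seed = N)
    emb <- two_pass_embed(tr)
    expect_equal(emb$n_visits, 2L * (2L * N - 2L))
  }
})
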