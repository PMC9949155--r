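## Variational Bayesian phylogenetic inference (VBPI).
##
## The variational family is Q_phi(tau) * Q_psi(q | tau): an SBN over tree
## topologies and a diagonal Lognormal over branch lengths whose (mu,
## log sigma) parameters are amortized across topologies by one of three
## parameterizations: per-split tables, split + primary-subsplit-pair (PSP)
## refinements, or learnable features (Dirichlet-energy embedding ->
## message passing -> symmetric edge readout -> MLP heads). Training
## maximizes the K-sample lower bound with an annealed likelihood; topology
## parameters get VIMCO score-function gradients, branch parameters get
## reparameterization gradients. Priors: uniform over topologies, i.i.d.
## exponential branch lengths.

#' Branch-length parameterization
#'
#' @param mode \code{"split"} (one (mu, log sigma) pair per split),
#'   \code{"psp"} (split tables plus additive PSP refinements), or
#'   \code{"gnn"} (learnable features: embedding, message passing, max edge
#'   readout, MLP heads; needs no support lookup).
#' @param support An \code{"sbn_support"} (required for split/psp; for gnn
#'   only the taxon count is used).
#' @param variant,hidden,layers Network architecture for \code{"gnn"} mode.
#' @param init_mu,init_logsigma Initialization for the tables /
#'   head output biases (defaults weakly informative around the Exp(10)
#'   prior mean).
#' @param seed Weight initialization seed (gnn mode).
#' @return A \code{"branch_param"} object with a flat parameter list.
#' @export
branch_param <- function(mode = c("split", "psp", "gnn"), support,
                         variant = "edge", hidden = 32L, layers = 2L,
                         init_mu = log(0.1), init_logsigma = -2,
                         seed = 1L) {
  mode <- match.arg(mode)
  N <- support$ntaxa
  if (mode %in% c("split", "psp")) {
    params <- list(
      mu = setNames(rep(init_mu, length(support$splits)), support$splits),
      sigma = setNames(rep(init_logsigma, length(support$splits)),
                       support$splits))
    if (mode == "psp") {
      params$psp_mu <- setNames(numeric(length(support$psps)),
                                support$psps)
      params$psp_sigma <- setNames(numeric(length(support$psps)),
                                   support$psps)
    }
    net <- NULL
  } else {
    net <- feature_net(variant, in_dim = N, hidden = hidden,
                       out_dim = hidden, layers = layers, seed = seed)
    heads <- with_seed(seed + 1L, c(mlp2_params("mu_", hidden, hidden, 1L),
                                    mlp2_params("sg_", hidden, hidden, 1L)))
    heads$mu_b2[] <- init_mu
    heads$sg_b2[] <- init_logsigma
    params <- c(net$params, heads)
    net$params <- NULL
  }
  structure(list(mode = mode, params = params, net = net, ntaxa = N),
            class = "branch_param")
}

## static per-topology quantities used repeatedly during training
branch_statics <- function(branch, tree) {
  out <- list(tree = tree, n_edges = nrow(tree$edge))
  if (branch$mode %in% c("split", "psp")) {
    out$splits <- edge_splits(tree)
    if (branch$mode == "psp") out$psps <- edge_psps(tree)
  } else {
    X <- two_pass_embed(tree)$features
    out$X <- X
    cache <- gnn_cache(list(tree), list(X))
    out$gs <- gnn_assemble(cache, need = gnn_needs(branch$net$variant))
    E <- tree$edge
    out$eu <- E[, 1L]
    out$ev <- E[, 2L]
  }
  out
}

## batched tape forward over several topologies at once (gnn mode):
## statics is a list of branch_statics entries; returns stacked mu / sg
## tape ids plus per-entry edge offsets
branch_gnn_forward_batch <- function(branch, statics, tp) {
  K <- length(statics)
  bc <- list(Xall = do.call(rbind, lapply(statics, `[[`, "X")),
             edges = lapply(statics, function(s) s$tree$edge),
             n_nodes = vapply(statics, function(s) nrow(s$X), integer(1L)),
             n_trees = K)
  bc$row_off <- c(0L, cumsum(bc$n_nodes))
  gs <- gnn_assemble(bc, need = gnn_needs(branch$net$variant))
  node_off <- bc$row_off[seq_len(K)]
  eu <- unlist(lapply(seq_len(K), function(i)
    statics[[i]]$eu + node_off[i]))
  ev <- unlist(lapply(seq_len(K), function(i)
    statics[[i]]$ev + node_off[i]))
  ids <- lapply(branch$params, function(v) ad_leaf(tp, v))
  out <- gnn_node_forward(branch$net, gs, tp, ids)
  hu <- ad_rows(tp, out$H, eu)
  hv <- ad_rows(tp, out$H, ev)
  he <- ad_pmax2(tp, hu, hv)
  mu <- mlp2_forward(tp, ids, "mu_", he)
  sg <- mlp2_forward(tp, ids, "sg_", he)
  n_edges <- vapply(statics, `[[`, integer(1L), "n_edges")
  list(mu = mu, sg = sg, ids = ids,
       edge_off = c(0L, cumsum(n_edges)), n_edges = n_edges)
}

## tape forward for gnn mode: returns ids for the E x 1 mu and log-sigma
## columns plus the parameter leaf ids
branch_gnn_forward <- function(branch, st, tp) {
  ids <- lapply(branch$params, function(v) ad_leaf(tp, v))
  out <- gnn_node_forward(branch$net, st$gs, tp, ids)
  hu <- ad_rows(tp, out$H, st$eu)
  hv <- ad_rows(tp, out$H, st$ev)
  he <- ad_pmax2(tp, hu, hv)
  mu <- mlp2_forward(tp, ids, "mu_", he)
  sg <- mlp2_forward(tp, ids, "sg_", he)
  list(mu = mu, sg = sg, ids = ids)
}

#' Branch-length distribution parameters for a topology
#'
#' Returns the Lognormal location \code{mu} and log-scale \code{logsigma}
#' for every edge of \code{tree} (aligned with \code{tree$edge} rows).
#' Split mode reads the per-split tables; PSP mode adds the PSP
#' refinements; gnn mode runs the feature network (and therefore works for
#' topologies never seen in the support sample).
#'
#' @param branch A \code{"branch_param"}.
#' @param tree A \code{"phylo"} topology.
#' @return List with numeric vectors \code{mu} and \code{logsigma}.
#' @export
branch_mu_sigma <- function(branch, tree) {
  st <- branch_statics(branch, tree)
  branch_mu_sigma_st(branch, st)
}

branch_mu_sigma_st <- function(branch, st) {
  if (branch$mode %in% c("split", "psp")) {
    mu <- branch$params$mu[st$splits]
    sg <- branch$params$sigma[st$splits]
    if (anyNA(mu)) {
      bad <- st$splits[which(is.na(mu))[1L]]
      stop_input("edge split ", bad, " is outside the support")
    }
    if (branch$mode == "psp") {
      for (k in seq_along(st$psps)) {
        pk <- st$psps[[k]]
        if (!length(pk)) next
        pm <- branch$params$psp_mu[pk]
        ps <- branch$params$psp_sigma[pk]
        if (anyNA(pm))
          stop_input("edge PSP ", pk[which(is.na(pm))[1L]],
                     " is outside the support")
        mu[k] <- mu[k] + sum(pm)
        sg[k] <- sg[k] + sum(ps)
      }
    }
    list(mu = unname(mu), logsigma = unname(sg))
  } else {
    tp <- ad_tape()
    fw <- branch_gnn_forward(branch, st, tp)
    list(mu = as.numeric(ad_value(tp, fw$mu)),
         logsigma = as.numeric(ad_value(tp, fw$sg)))
  }
}

#' Diagonal Lognormal log-density of branch lengths
#'
#' @param q Positive branch-length vector.
#' @param mu,logsigma Per-edge location and log-scale.
#' @return Sum of Lognormal log-densities (-Inf if any length is
#'   non-positive).
#' @export
lognormal_branch_logq <- function(q, mu, logsigma) {
  if (any(q <= 0)) return(structure(-Inf, nonpositive = TRUE))
  sum(dlnorm(q, meanlog = mu, sdlog = exp(logsigma), log = TRUE))
}

#' VBPI model
#'
#' @param support An \code{"sbn_support"} built from a topology sample.
#' @param branch_mode \code{"split"}, \code{"psp"} or \code{"gnn"}.
#' @param K Number of samples in the multi-sample bound (default 10).
#' @param prior_rate Rate of the i.i.d. exponential branch-length prior
#'   (default 10; prior mean 0.1 substitutions/site).
#' @param anneal_init,anneal_steps Likelihood annealing schedule
#'   \code{lambda_n = min(1, anneal_init + n / anneal_steps)}.
#' @param ... Passed to \code{\link{branch_param}} (variant, hidden, seed,
#'   initialization).
#' @return A \code{"vbpi_model"} with components \code{sbn} and
#'   \code{branch}.
#' @export
vbpi_model <- function(support, branch_mode = "split", K = 10L,
                       prior_rate = 10, anneal_init = 0.001,
                       anneal_steps = 100000L, ...) {
  structure(list(sbn = sbn_model(support),
                 branch = branch_param(branch_mode, support, ...),
                 K = K, prior_rate = prior_rate,
                 anneal_init = anneal_init, anneal_steps = anneal_steps,
                 ntaxa = support$ntaxa),
            class = "vbpi_model")
}

## log prior over unrooted topologies: uniform over (2N-5)!!
log_topo_prior <- function(N) -sum(log(seq(2 * N - 5, 1, by = -2)))

vbpi_lambda <- function(model, n)
  min(1, model$anneal_init + n / model$anneal_steps)

## draw one (tau, q) joint sample plus everything needed for gradients
vbpi_draw <- function(model, aln, lambda, cache_env = NULL,
                      want_grad = FALSE) {
  s <- sbn_sample_impl(model$sbn)
  st <- if (!is.null(cache_env)) cache_env[[s$key]] else NULL
  if (is.null(st)) {
    tree <- parse_newick(s$newick)
    st <- branch_statics(model$branch, tree)
    st$dec <- sbn_decompose(tree)
    if (!is.null(cache_env)) cache_env[[s$key]] <- st
  }
  tp <- fw <- NULL
  if (model$branch$mode == "gnn" && want_grad) {
    tp <- ad_tape()
    fw <- branch_gnn_forward(model$branch, st, tp)
    ms <- list(mu = as.numeric(ad_value(tp, fw$mu)),
               logsigma = as.numeric(ad_value(tp, fw$sg)))
  } else {
    ms <- branch_mu_sigma_st(model$branch, st)
  }
  eps <- rnorm(st$n_edges)
  sigma <- exp(ms$logsigma)
  q <- exp(ms$mu + sigma * eps)
  tree_q <- st$tree
  tree_q$edge.length <- q
  if (want_grad) {
    lg <- loglik_branch_grad(tree_q, aln, return_loglik = TRUE)
    ll <- lg$loglik
    dll <- lg$grad
  } else {
    ll <- pruning_loglik(tree_q, aln)
    dll <- NULL
  }
  lqphi <- sbn_logprob(model$sbn, st$tree, grad = want_grad,
                       dec = st$dec)
  lqpsi <- lognormal_branch_logq(q, ms$mu, ms$logsigma)
  logprior <- log_topo_prior(model$ntaxa) +
    sum(dexp(q, rate = model$prior_rate, log = TRUE))
  logqphi <- if (want_grad) lqphi$logprob else as.numeric(lqphi)
  logw <- lambda * ll + logprior - logqphi - lqpsi
  list(st = st, ms = ms, eps = eps, sigma = sigma, q = q, loglik = ll,
       dll = dll, logw = logw, sbn_lp = lqphi, tape = tp, fw = fw)
}

#' Multi-sample variational lower bound
#'
#' Draws K joint samples (tau_i, q_i) from the variational distribution and
#' returns \code{log((1/K) sum_i w_i)} with importance weights
#' \code{w_i = p(Y|tau_i, q_i)^lambda p(tau_i, q_i) / (Q_phi Q_psi)},
#' computed in log space. Per-sample log-weights are retained for VIMCO.
#'
#' @param model A \code{"vbpi_model"}.
#' @param aln A \code{"dna_alignment"}.
#' @param K Sample count (default the model's K).
#' @param lambda Likelihood annealing factor in (0, 1].
#' @param seed Optional integer seed.
#' @return List with \code{bound} and \code{log_weights}.
#' @export
multisample_bound <- function(model, aln, K = model$K, lambda = 1,
                              seed = NULL) {
  with_seed(seed, {
    lw <- vapply(seq_len(K), function(i)
      vbpi_draw(model, aln, lambda)$logw, numeric(1L))
    list(bound = logsumexp(lw) - log(K), log_weights = lw)
  })
}

## VIMCO leave-one-out learning signals: for each sample, the bound minus
## the bound with that sample's weight replaced by the geometric mean of
## the others. Returns list(signal, wbar).
vimco_signals <- function(lw) {
  K <- length(lw)
  L <- logsumexp(lw) - log(K)
  wbar <- exp(lw - logsumexp(lw))
  sig <- numeric(K)
  for (i in seq_len(K)) {
    loo <- lw[-i]
    lhat <- mean(loo)                     # log geometric mean
    sig[i] <- L - (logsumexp(c(loo, lhat)) - log(K))
  }
  list(signal = sig, wbar = wbar)
}

#' VIMCO gradient contribution for the topology parameters
#'
#' Combines per-sample learning signals (leave-one-out control variates)
#' with the score-function gradients of \code{log Q_phi(tau_i)}:
#' \code{sum_i (signal_i - wbar_i) * grad_i}. With K = 1 no control
#' variate exists and the plain score-function estimator
#' \code{(log w - 1) * grad} is used, with a warning.
#'
#' @param per_sample_log_weights Numeric vector of K log-weights.
#' @param sbn_grads List of K gradients of \code{log Q_phi} (each a list of
#'   arrays shaped like the SBN parameters).
#' @return Gradient list shaped like the SBN parameters (ascent direction).
#' @export
vimco_topology_gradient <- function(per_sample_log_weights, sbn_grads) {
  lw <- per_sample_log_weights
  K <- length(lw)
  acc <- lapply(sbn_grads[[1L]], function(v) v * 0)
  if (K == 1L) {
    warning("VIMCO needs K >= 2; falling back to the plain score-function",
            " estimator")
    co <- lw[1L] - 1
    for (nm in names(acc)) acc[[nm]] <- co * sbn_grads[[1L]][[nm]]
    return(acc)
  }
  vs <- vimco_signals(lw)
  co <- vs$signal - vs$wbar
  for (i in seq_len(K))
    for (nm in names(acc))
      acc[[nm]] <- acc[[nm]] + co[i] * sbn_grads[[i]][[nm]]
  acc
}

## per-edge reparameterization gradients of log w with respect to mu and
## log sigma (see the methods vignette for the derivation):
##   d log w / d mu_e    = g_q * q + 1
##   d log w / d lsig_e  = (g_q * q + 1) * sigma * eps + 1
## where g_q = lambda * d loglik / d q - prior_rate.
branch_reparam_grads <- function(draw, lambda, prior_rate) {
  gq <- lambda * draw$dll - prior_rate
  dmu <- gq * draw$q + 1
  dls <- dmu * draw$sigma * draw$eps + 1
  list(dmu = dmu, dls = dls)
}

#' Train a VBPI model
#'
#' Joint Adam updates: VIMCO (score-function with leave-one-out control
#' variates) for the SBN topology parameters and reparameterization
#' gradients for the branch parameters, under the annealed likelihood
#' schedule.
#'
#' @param model A \code{"vbpi_model"}.
#' @param aln A \code{"dna_alignment"}.
#' @param iters Number of parameter updates.
#' @param lr Adam learning rate.
#' @param K Samples per update (default the model's K).
#' @param seed Integer seed.
#' @param trace_every Record the running bound estimate every so many
#'   iterations (every iteration's bound is always recorded).
#' @return List with the trained \code{model}, a \code{trace} data frame
#'   (iter, lambda, bound) and \code{final_bound} (mean bound over the
#'   last 100 iterations).
#' @export
train_vbpi <- function(model, aln, iters = 5000L, lr = 1e-3, K = model$K,
                       seed = 1L, trace_every = 1L) {
  with_gc_headroom(
    train_vbpi_impl(model, aln, iters, lr, K, seed, trace_every))
}

train_vbpi_impl <- function(model, aln, iters, lr, K, seed, trace_every) {
  cache_env <- new.env(parent = emptyenv())
  phi <- model$sbn$params
  psi <- model$branch$params
  opt_phi <- adam_init(phi)
  opt_psi <- adam_init(psi)
  bounds <- numeric(iters)
  lambdas <- numeric(iters)
  gnn_mode <- model$branch$mode == "gnn"
  with_seed(seed, {
    for (it in seq_len(iters)) {
      lambda <- vbpi_lambda(model, it)
      if (gnn_mode) {
        ## sample K topologies, then run one batched network pass for all
        ## of their branch parameters
        sts <- vector("list", K)
        for (i in seq_len(K)) {
          s <- sbn_sample_impl(model$sbn)
          st <- cache_env[[s$key]]
          if (is.null(st)) {
            tree <- parse_newick(s$newick)
            st <- branch_statics(model$branch, tree)
            st$dec <- sbn_decompose(tree)
            cache_env[[s$key]] <- st
          }
          sts[[i]] <- st
        }
        tp <- ad_tape()
        bf <- branch_gnn_forward_batch(model$branch, sts, tp)
        mu_all <- as.numeric(ad_value(tp, bf$mu))
        sg_all <- as.numeric(ad_value(tp, bf$sg))
      }
      draws <- vector("list", K)
      lw <- numeric(K)
      for (i in seq_len(K)) {
        if (gnn_mode) {
          st <- sts[[i]]
          sel <- bf$edge_off[i] + seq_len(bf$n_edges[i])
          ms <- list(mu = mu_all[sel], logsigma = sg_all[sel])
          eps <- rnorm(st$n_edges)
          sigma <- exp(ms$logsigma)
          q <- exp(ms$mu + sigma * eps)
          tree_q <- st$tree
          tree_q$edge.length <- q
          lg <- loglik_branch_grad(tree_q, aln, return_loglik = TRUE)
          lqphi <- sbn_logprob(model$sbn, st$tree, grad = TRUE,
                               dec = st$dec)
          lqpsi <- lognormal_branch_logq(q, ms$mu, ms$logsigma)
          logprior <- log_topo_prior(model$ntaxa) +
            sum(dexp(q, rate = model$prior_rate, log = TRUE))
          draws[[i]] <- list(st = st, ms = ms, eps = eps, sigma = sigma,
                            q = q, loglik = lg$loglik, dll = lg$grad,
                            logw = lambda * lg$loglik + logprior -
                              lqphi$logprob - lqpsi,
                            sbn_lp = lqphi)
        } else {
          draws[[i]] <- vbpi_draw(model, aln, lambda, cache_env,
                                  want_grad = TRUE)
        }
        lw[i] <- draws[[i]]$logw
      }
      bounds[it] <- logsumexp(lw) - log(K)
      lambdas[it] <- lambda
      vs <- vimco_signals(lw)
      ## ---- phi (ascent) ----
      gphi <- lapply(phi, function(v) v * 0)
      co <- vs$signal - vs$wbar
      for (i in seq_len(K)) {
        gr <- draws[[i]]$sbn_lp$grads
        for (nm in names(gphi))
          gphi[[nm]] <- gphi[[nm]] + co[i] * gr[[nm]]
      }
      ## ---- psi (ascent, reparameterized) ----
      gpsi <- lapply(psi, function(v) v * 0)
      if (gnn_mode) {
        wmu_all <- numeric(bf$edge_off[K + 1L])
        wls_all <- numeric(bf$edge_off[K + 1L])
      }
      for (i in seq_len(K)) {
        d <- draws[[i]]
        rg <- branch_reparam_grads(d, lambda, model$prior_rate)
        wmu <- vs$wbar[i] * rg$dmu
        wls <- vs$wbar[i] * rg$dls
        if (!gnn_mode) {
          sp <- d$st$splits
          gpsi$mu[sp] <- gpsi$mu[sp] + wmu
          gpsi$sigma[sp] <- gpsi$sigma[sp] + wls
          if (model$branch$mode == "psp") {
            for (k in seq_along(d$st$psps)) {
              pk <- d$st$psps[[k]]
              if (!length(pk)) next
              gpsi$psp_mu[pk] <- gpsi$psp_mu[pk] + wmu[k]
              gpsi$psp_sigma[pk] <- gpsi$psp_sigma[pk] + wls[k]
            }
          }
        } else {
          sel <- bf$edge_off[i] + seq_len(bf$n_edges[i])
          wmu_all[sel] <- wmu
          wls_all[sel] <- wls
        }
      }
      if (gnn_mode) {
        comb <- ad_cbind(tp, bf$mu, bf$sg)
        ad_backward(tp, comb, cbind(wmu_all, wls_all))
        for (nm in names(gpsi))
          gpsi[[nm]] <- ad_grad(tp, bf$ids[[nm]])
      }
      ## Adam minimizes, so negate the ascent directions
      up <- adam_step(opt_phi, phi, lapply(gphi, function(g) -g), lr = lr)
      opt_phi <- up$state; phi <- up$params
      model$sbn$params <- phi
      up <- adam_step(opt_psi, psi, lapply(gpsi, function(g) -g), lr = lr)
      opt_psi <- up$state; psi <- up$params
      model$branch$params <- psi
    }
  })
  keep <- seq(1L, iters, by = trace_every)
  trace <- data.frame(iter = keep, lambda = lambdas[keep],
                      bound = bounds[keep])
  list(model = model, trace = trace,
       final_bound = mean(bounds[max(1L, iters - 99L):iters]))
}

#' Importance-sampling estimate of the marginal likelihood
#'
#' \code{log p(Y)} estimated as the log of the average importance weight at
#' \code{lambda = 1}, with a delta-method standard error on the log scale.
#'
#' @param model A trained \code{"vbpi_model"}.
#' @param aln A \code{"dna_alignment"}.
#' @param n_samples Number of importance samples (the study uses 1000).
#' @param seed Optional integer seed.
#' @return List with \code{logml} and \code{se}.
#' @export
marginal_likelihood_is <- function(model, aln, n_samples = 1000L,
                                   seed = NULL) {
  cache_env <- new.env(parent = emptyenv())
  lw <- with_seed(seed, vapply(seq_len(n_samples), function(i)
    vbpi_draw(model, aln, 1, cache_env)$logw, numeric(1L)))
  m <- max(lw)
  w <- exp(lw - m)
  logml <- m + log(mean(w))
  se <- stats::sd(w) / (mean(w) * sqrt(n_samples))
  list(logml = logml, se = se)
}

## K-sample per-tree bound for a FIXED topology (branch terms only):
## log mean_i [ p(Y|tau,q_i) p(q_i) / Q(q_i) ]
fixed_tree_bound <- function(tree, aln, mu, logsigma, prior_rate, K) {
  sigma <- exp(logsigma)
  eps <- matrix(rnorm(length(mu) * K), length(mu), K)
  lw <- vapply(seq_len(K), function(i) {
    q <- exp(mu + sigma * eps[, i])
    tq <- tree
    tq$edge.length <- q
    pruning_loglik(tq, aln) + sum(dexp(q, prior_rate, log = TRUE)) -
      lognormal_branch_logq(q, mu, logsigma)
  }, numeric(1L))
  logsumexp(lw) - log(K)
}

#' Amortization gap on a fixed topology
#'
#' The gap between the per-tree bound after independently optimizing an
#' unamortized diagonal Lognormal (free mu and log sigma per edge,
#' initialized from the amortized parameters) and the bound at the shared
#' amortized parameters; both at lambda = 1 with the same K and common
#' random numbers for the final evaluation. Nonnegative up to Monte Carlo
#' error.
#'
#' @param model A trained \code{"vbpi_model"}.
#' @param tree Fixed \code{"phylo"} topology.
#' @param aln A \code{"dna_alignment"}.
#' @param per_tree_opt_iters Adam iterations for the per-tree fit.
#' @param K Samples per bound estimate (default the model's K).
#' @param n_eval Number of K-sample bound replicates in the evaluation.
#' @param lr Adam learning rate for the per-tree fit.
#' @param seed Integer seed.
#' @return List with \code{gap}, \code{amortized}, \code{optimized},
#'   \code{se} (of the paired difference).
#' @export
amortization_gap <- function(model, tree, aln, per_tree_opt_iters = 200L,
                             K = model$K, n_eval = 50L, lr = 0.01,
                             seed = 1L) {
  with_gc_headroom(amortization_gap_impl(model, tree, aln,
                                         per_tree_opt_iters, K, n_eval,
                                         lr, seed))
}

amortization_gap_impl <- function(model, tree, aln, per_tree_opt_iters,
                                  K, n_eval, lr, seed) {
  ms <- branch_mu_sigma(model$branch, tree)
  mu <- ms$mu; ls <- ms$logsigma
  rate <- model$prior_rate
  with_seed(seed, {
    ## per-tree optimization of the free parameters
    par <- list(mu = mu, ls = ls)
    opt <- adam_init(par)
    for (it in seq_len(per_tree_opt_iters)) {
      eps <- matrix(rnorm(length(mu) * K), length(mu), K)
      sigma <- exp(par$ls)
      lw <- numeric(K)
      dmu <- matrix(0, length(mu), K)
      dls <- matrix(0, length(mu), K)
      for (i in seq_len(K)) {
        q <- exp(par$mu + sigma * eps[, i])
        tq <- tree
        tq$edge.length <- q
        lg <- loglik_branch_grad(tq, aln, return_loglik = TRUE)
        lw[i] <- lg$loglik + sum(dexp(q, rate, log = TRUE)) -
          lognormal_branch_logq(q, par$mu, par$ls)
        gq <- lg$grad - rate
        dmu[, i] <- gq * q + 1
        dls[, i] <- (gq * q + 1) * sigma * eps[, i] + 1
      }
      wbar <- exp(lw - logsumexp(lw))
      g <- list(mu = -as.numeric(dmu %*% wbar),
                ls = -as.numeric(dls %*% wbar))
      up <- adam_step(opt, par, g, lr = lr)
      opt <- up$state; par <- up$params
    }
    ## paired evaluation with common random numbers
    eval_seed <- sample.int(.Machine$integer.max, 1L)
    b_am <- with_seed(eval_seed, vapply(seq_len(n_eval), function(r)
      fixed_tree_bound(tree, aln, mu, ls, rate, K), numeric(1L)))
    b_op <- with_seed(eval_seed, vapply(seq_len(n_eval), function(r)
      fixed_tree_bound(tree, aln, par$mu, par$ls, rate, K), numeric(1L)))
    d <- b_op - b_am
    list(gap = mean(d), amortized = mean(b_am), optimized = mean(b_op),
         se = stats::sd(d) / sqrt(n_eval))
  })
}
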