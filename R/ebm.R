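## Energy-based tree-probability estimation over an enumerated topology
## space, trained by noise-contrastive estimation (NCE).
##
## The network head outputs D(tau) = log q(tau) - log p_noise(tau) directly,
## so the partition function never needs estimating during training;
## explicit normalization over the enumerated space is done only for
## evaluation.

#' Explicit probability table over an enumerated topology space
#'
#' @param trees A \code{"multiPhylo"} list covering the space.
#' @param probs Probabilities aligned with \code{trees}.
#' @return A \code{"tree_distribution"}: list with \code{keys} (canonical
#'   keys, lexicographically sorted), \code{probs}, \code{trees}.
#' @export
tree_distribution <- function(trees, probs) {
  keys <- vapply(trees, canonical_key, character(1L))
  if (anyDuplicated(keys)) stop_input("duplicate topologies in space")
  if (length(probs) != length(keys))
    stop_input("probs length does not match space size")
  if (any(probs < 0)) stop_input("negative probability")
  o <- order(keys)
  structure(list(keys = keys[o], probs = probs[o] / sum(probs),
                 trees = trees[o]),
            class = "tree_distribution")
}

#' Dirichlet-sampled target distribution over all topologies
#'
#' Draws one sample from the symmetric Dirichlet distribution
#' Dir(beta * 1) of order (2N-5)!! over the enumerated unrooted topology
#' space, with topologies in a fixed (lexicographic canonical-key) order.
#' Small \code{beta} concentrates mass on few topologies.
#'
#' @param N Taxon count (4..8).
#' @param beta Dirichlet concentration (> 0).
#' @param seed Integer seed; the draw is reproducible per seed.
#' @return A \code{"tree_distribution"}.
#' @export
dirichlet_target <- function(N, beta, seed = NULL) {
  if (N < 4L || N > 8L) stop_input("N must be in 4..8")
  if (beta <= 0) stop_input("beta must be positive")
  trees <- enumerate_unrooted(N)
  d <- tree_distribution(trees, rep(1, length(trees)))
  g <- with_seed(seed, rgamma(length(d$keys), shape = beta, rate = 1))
  if (sum(g) == 0) g[] <- 1
  d$probs <- g / sum(g)
  d
}

#' Uniform distribution over the same space as another distribution
#'
#' @param dist A \code{"tree_distribution"}.
#' @return A \code{"tree_distribution"} with equal probabilities.
#' @export
uniform_over_space <- function(dist) {
  dist$probs <- rep(1 / length(dist$keys), length(dist$keys))
  dist
}

#' Energy-based model over tree topologies
#'
#' A message-passing network with sum graph readout and a scalar head; the
#' head output is the trained log-density ratio D(tau) against the noise
#' distribution.
#'
#' @param variant Convolution variant (see \code{\link{feature_net}}).
#' @param N Taxon count (embedding dimension = N for one-hot tips).
#' @param hidden Hidden width.
#' @param layers Message-passing layers.
#' @param seed Seed for weight initialization.
#' @return An object of class \code{"energy_model"}.
#' @export
energy_model <- function(variant, N, hidden = 100L, layers = 2L, seed = 1L) {
  net <- feature_net(variant, in_dim = N, hidden = hidden,
                     out_dim = hidden, layers = layers, seed = seed)
  head <- with_seed(seed + 1L, mlp2_params("mlp1_", hidden, hidden, 1L))
  params <- c(net$params, head)
  net$params <- NULL
  structure(list(net = net, params = params), class = "energy_model")
}

## forward to D values on an assembled graph structure; returns tape ids
ebm_forward <- function(model, gs, tp) {
  ids <- lapply(model$params, function(v) ad_leaf(tp, v))
  out <- gnn_node_forward(model$net, gs, tp, ids)
  hG <- ad_rowsum(tp, out$H, gs$gid, gs$n_graphs)
  D <- mlp2_forward(tp, ids, "mlp1_", hG)
  list(D = D, ids = ids)
}

## D values for trees cache[idx], evaluated in chunks (no gradient)
ebm_dvalues <- function(model, cache, idx = seq_len(cache$n_trees),
                        chunk = 2000L) {
  need <- gnn_needs(model$net$variant)
  out <- numeric(length(idx))
  for (s in split(seq_along(idx), ceiling(seq_along(idx) / chunk))) {
    gs <- gnn_assemble(cache, idx[s], need = need)
    tp <- ad_tape()
    out[s] <- as.numeric(ad_value(tp, ebm_forward(model, gs, tp)$D))
  }
  out
}

#' Monte-Carlo NCE loss
#'
#' \code{J = -(E_data log S(D) + E_noise log(1 - S(D)))} with the logistic
#' \code{S}; estimated on the two supplied batches.
#'
#' @param model An \code{"energy_model"}.
#' @param data_batch,noise_batch Lists of \code{"phylo"} topologies.
#' @return Scalar loss.
#' @export
nce_loss <- function(model, data_batch, noise_batch) {
  if (!length(data_batch) || !length(noise_batch))
    stop_input("batches must be nonempty")
  cache <- gnn_cache(c(data_batch, noise_batch))
  D <- ebm_dvalues(model, cache)
  nd <- length(data_batch)
  mean(softplus(-D[seq_len(nd)])) + mean(softplus(D[-seq_len(nd)]))
}

## exact (exhaustive-expectation) NCE loss from tabulated D values
nce_loss_exact <- function(D, p_data, p_noise)
  sum(p_data * softplus(-D)) + sum(p_noise * softplus(D))

#' Optimal NCE loss via the Jensen-Shannon divergence
#'
#' The attainable minimum of the NCE objective:
#' \code{J* = -2 JSD(p_data || p_noise) + 2 log 2}, computed by summation
#' over the enumerated space.
#'
#' @param p_data,p_noise \code{"tree_distribution"}s on the same space.
#' @return Scalar \code{J*}.
#' @export
optimal_nce_loss <- function(p_data, p_noise) {
  if (!identical(p_data$keys, p_noise$keys))
    stop_input("distributions are not on the same topology space")
  p <- p_data$probs; q <- p_noise$probs
  m <- (p + q) / 2
  klpm <- sum(ifelse(p > 0, p * (log(p) - log(m)), 0))
  klqm <- sum(ifelse(q > 0, q * (log(q) - log(m)), 0))
  jsd <- (klpm + klqm) / 2
  2 * log(2) - 2 * jsd
}

#' Normalized model distribution over the enumerated space
#'
#' \code{q(tau) = p_n(tau) exp(D(tau)) / Z} with the normalizer computed in
#' log space by max subtraction.
#'
#' @param model An \code{"energy_model"}.
#' @param p_noise A \code{"tree_distribution"} (also supplies the space).
#' @return A \code{"tree_distribution"} for the model.
#' @export
model_probs <- function(model, p_noise) {
  cache <- gnn_cache(p_noise$trees)
  D <- ebm_dvalues(model, cache)
  lg <- log(p_noise$probs) + D
  lg <- lg - logsumexp(lg)
  out <- p_noise
  out$probs <- exp(lg)
  out
}

#' KL divergence between two tree distributions
#'
#' \code{KL(p || q) = sum p log(p/q)} with \code{0 log 0 := 0}.
#'
#' @param p_target,q_model \code{"tree_distribution"}s on the same space.
#' @return Scalar divergence.
#' @export
kl_to_target <- function(p_target, q_model) {
  if (!identical(p_target$keys, q_model$keys))
    stop_input("distributions are not on the same topology space")
  p <- p_target$probs; q <- q_model$probs
  sum(ifelse(p > 0, p * (log(p) - log(q)), 0))
}

#' Train an energy-based model by noise-contrastive estimation
#'
#' Stochastic gradient (Adam) steps on the NCE loss, sampling fresh data
#' batches from the target table and noise batches from the noise
#' distribution at every step. The exact (exhaustive-expectation) loss and
#' the KL divergence to the target are recorded every \code{eval_every}
#' steps.
#'
#' @param model An \code{"energy_model"}.
#' @param p_target Target \code{"tree_distribution"}.
#' @param p_noise Noise distribution; defaults to uniform over the space.
#' @param steps Number of parameter updates.
#' @param batch Batch size per term (noise:data ratio 1:1).
#' @param lr Adam learning rate.
#' @param lr_schedule \code{"constant"} or \code{"cosine"} (cosine decay
#'   from \code{lr} to \code{lr / 10} over the run, which damps the
#'   stochastic-gradient noise floor late in training).
#' @param seed Integer seed (sampling and evaluation are reproducible).
#' @param eval_every Trace recording interval.
#' @return List with the trained \code{model}, \code{trace} data frame
#'   (step, nce, kl), \code{final_nce}, \code{final_kl}.
#' @export
train_nce <- function(model, p_target, p_noise = NULL, steps = 20000L,
                      batch = 128L, lr = 1e-3,
                      lr_schedule = c("constant", "cosine"), seed = 1L,
                      eval_every = 1000L) {
  lr_schedule <- match.arg(lr_schedule)
  return(with_gc_headroom(train_nce_impl(model, p_target, p_noise, steps,
                                         batch, lr, lr_schedule, seed,
                                         eval_every)))
}

train_nce_impl <- function(model, p_target, p_noise, steps, batch, lr,
                           lr_schedule, seed, eval_every) {
  if (is.null(p_noise)) p_noise <- uniform_over_space(p_target)
  if (!identical(p_target$keys, p_noise$keys))
    stop_input("target and noise are not on the same topology space")
  cache <- gnn_cache(p_target$trees)
  n <- length(p_target$keys)
  need <- gnn_needs(model$net$variant)
  opt <- adam_init(model$params)
  trace <- list()
  with_seed(seed, {
    for (step in seq_len(steps)) {
      id_d <- sample.int(n, batch, replace = TRUE, prob = p_target$probs)
      id_n <- sample.int(n, batch, replace = TRUE, prob = p_noise$probs)
      ## forward each distinct tree once; weight the loss gradient by the
      ## batch multiplicities
      cd <- tabulate(id_d, n); cn <- tabulate(id_n, n)
      idx <- which(cd + cn > 0L)
      gs <- gnn_assemble(cache, idx, need = need)
      tp <- ad_tape()
      fw <- ebm_forward(model, gs, tp)
      D <- as.numeric(ad_value(tp, fw$D))
      seed_grad <- matrix((-(1 - sigmoid(D)) * cd[idx] +
                             sigmoid(D) * cn[idx]) / batch, ncol = 1L)
      ad_backward(tp, fw$D, seed_grad)
      grads <- lapply(fw$ids, function(i) ad_grad(tp, i))
      lr_t <- if (lr_schedule == "cosine")
        lr / 10 + (lr - lr / 10) * (1 + cos(pi * step / steps)) / 2 else lr
      upd <- adam_step(opt, model$params, grads, lr = lr_t)
      opt <- upd$state
      model$params <- upd$params
      if (step %% eval_every == 0L || step == steps) {
        Dall <- ebm_dvalues(model, cache)
        nce <- nce_loss_exact(Dall, p_target$probs, p_noise$probs)
        lg <- log(p_noise$probs) + Dall
        lg <- lg - logsumexp(lg)
        kl <- sum(ifelse(p_target$probs > 0,
                         p_target$probs * (log(p_target$probs) - lg), 0))
        trace[[length(trace) + 1L]] <- c(step = step, nce = nce, kl = kl)
      }
    }
  })
  trace <- as.data.frame(do.call(rbind, trace))
  list(model = model, trace = trace,
       final_nce = trace$nce[nrow(trace)], final_kl = trace$kl[nrow(trace)])
}

#' Scaled-down simulated tree probability estimation experiment
#'
#' Builds a Dirichlet target over the full unrooted topology space on
#' \code{N} taxa (with the concentration scaled so that the total
#' concentration mass matches beta0 * 10395 of the 8-taxon study), trains
#' an NCE energy model against uniform noise, and reports the final exact
#' NCE loss, the attainable minimum J*, and the KL diagnostics.
#'
#' @param N Taxon count (default 7: 945 topologies).
#' @param variant Convolution variant.
#' @param beta0 Reference concentration at space size 10395.
#' @param steps,batch,lr,hidden Training configuration.
#' @param seed Integer seed.
#' @param eval_every Trace interval.
#' @return List with \code{final_nce}, \code{jstar}, \code{final_kl},
#'   \code{kl_uniform} (KL of the target from uniform), \code{trace}, and
#'   the trained \code{model}.
#' @export
run_ebm_experiment <- function(N = 7L, variant = "edge", beta0 = 0.008,
                               steps = 20000L, batch = 32L, lr = 2e-3,
                               hidden = 32L, seed = 1L,
                               eval_every = 1000L) {
  p0 <- dirichlet_target(N, beta = beta0 * 10395 /
                           prod(seq(2 * N - 5, 1, by = -2)), seed = seed)
  pn <- uniform_over_space(p0)
  model <- energy_model(variant, N = N, hidden = hidden, seed = seed)
  fit <- train_nce(model, p0, pn, steps = steps, batch = batch, lr = lr,
                   lr_schedule = "cosine", seed = seed + 1L,
                   eval_every = eval_every)
  kl_unif <- kl_to_target(p0, pn)
  list(final_nce = fit$final_nce, jstar = optimal_nce_loss(p0, pn),
       final_kl = fit$final_kl, kl_uniform = kl_unif, trace = fit$trace,
       model = fit$model)
}
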