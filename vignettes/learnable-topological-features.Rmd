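---
title: "Learnable topological features for phylogenetic inference: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learnable topological features for phylogenetic inference: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(phylotopo)
```

# The problem

Statistical phylogenetics infers evolutionary trees (a discrete topology
$\tau$ plus continuous branch lengths $q$) from aligned molecular
sequences. Many inference algorithms need numeric *features* of tree
topologies — for scoring topologies, for amortizing branch-length
distributions across topologies, or for learning probability models over
tree space. Classical features (clades, splits, primary subsplit pairs)
are hand-engineered and must be harvested from a pre-computed sample of
topologies. This package implements an alternative: raw node features
obtained by Dirichlet-energy minimization, refined by message-passing
networks, and plugged into two downstream tasks — energy-based tree
probability estimation and variational Bayesian phylogenetic inference
(VBPI).

# Interior node embedding by Dirichlet-energy minimization

Tip nodes get one-hot features $x_v \in \mathbb{R}^N$ (axes ordered by
lexicographic taxon label — the package-wide convention). Interior
features minimize the Dirichlet energy
$\ell(f,\tau) = \sum_{(u,v)\in E} \lVert f(u) - f(v)\rVert^2$, i.e. each
interior feature must equal the mean of its neighbors' features. On a
tree this linear system is solved exactly by a two-pass sweep
(`two_pass_embed()`): a postorder pass writes every non-root feature as
$\hat x_u = c_u \hat x_{\pi(u)} + d_u$ with

$$c_u = \frac{1}{|\mathcal N(u)| - \sum_{v \in ch(u)} c_v}, \qquad
  d_u = c_u \sum_{v \in ch(u)} d_v,$$

(leaves: $c_u = 0$, $d_u = x_u$), and a preorder pass back-substitutes
from the root, whose feature has the closed form
$\hat x_r = \sum_{v\in ch(r)} d_v / (|\mathcal N(r)| - \sum_{v\in ch(r)} c_v)$.
The cost is two traversals — linear in the node count — versus the cubic
dense solve that `dense_embed_oracle()` performs (kept as an independent
test oracle only).

Key properties, each instantiated as an executable test suite rather
than a proof:

* **Stability.** $0 \le c_u \le 1/(\lambda-1)$ where $\lambda$ is the
  minimum interior degree, so for bifurcating trees all $c_u \le 1/2$ and
  the recursion never amplifies rounding error. No pivoting machinery is
  needed; plain double precision suffices, and we test agreement with the
  dense oracle at $10^{-8}$ scaled by dimension.
* **Extremum principle / convexity.** With one-hot tips every interior
  row lies strictly in $(0,1)$ and sums to one; with linearly independent
  tips the interior features are strict convex combinations of tip
  features.
* **Decodability.** In the convex-combination representation, the
  interior node with the largest coefficient on tip $v$ is exactly $v$'s
  interior neighbor (`tip_neighbor_decode()`); ties are broken by
  smallest node index (ties occur with probability zero for generic
  inputs).
* **Identifiability.** Distinct topologies give distinct interior-feature
  multisets. We verify this by exhaustive enumeration
  (`embeddings_distinct()`, all 105 six-taxon and 945 seven-taxon
  topologies) rather than implementing the constructive inverse, which
  the decoding lemma does not supply beyond tip neighbors.

The traversal is rooted at an arbitrary node (default: the first
interior node); the solution is the unique minimizer, hence root-choice
invariant, which the suite checks to $10^{-10}$. Multifurcating trees and
degree-2 chains are accepted; the solver is not restricted to bifurcating
topologies. A 2-tip tree has no interior unknowns and tips are returned
unchanged.

# Message passing on embedded trees

`feature_net()` implements five standard convolution operators — GCN
(symmetric-normalized averaging with self-loops), GIN (sum aggregation
plus an MLP with learnable $\varepsilon$), GraphSAGE (mean aggregation,
concatenation), GGNN (gated recurrent update; the two gates share a fused
matrix multiply for speed), and EDGE (max-aggregated MLP on
$(h_u, h_v - h_u)$) — plus an "mlp" baseline that skips message passing
entirely ($T = 0$). Messages flow in both directions along every tree
edge. Architecture follows the study's fixed depth (2 message-passing
layers, all MLPs 2 layers); widths and activations are not specified
there, so the package declares its own defaults: hidden width 100
(configurable; the experiment drivers use smaller widths, see below) and
ELU activations. Graph-level readout is the elementwise sum over nodes;
edge-level readout is the elementwise maximum of the two endpoint
features, which makes edge features orientation-invariant — necessary on
unrooted trees.

Gradients come from a small reverse-mode tape (`R/autodiff.R`) over dense
and sparse matrix primitives, written for exactly the operations these
networks need. Every operator's analytic gradient is checked against
central finite differences at relative error $10^{-4}$ (in practice they
agree to $10^{-8}$).

# Energy-based tree probability estimation with NCE

Over an enumerable topology space (all $(2N-5)!!$ unrooted bifurcating
topologies; 10395 at $N = 8$), an energy model assigns each topology a
scalar through embedding, message passing, sum readout and a scalar head.
The head output is trained directly as the log-density ratio
$D(\tau) = \log q(\tau) - \log p_n(\tau)$ against a known noise
distribution $p_n$, so the partition function is never estimated during
training; `model_probs()` normalizes explicitly over the enumerated space
only for evaluation. The noise-contrastive estimation loss is

$$J = -\big(E_{p_{data}} \log S(D) + E_{p_n} \log(1 - S(D))\big),$$

with logistic $S$; its attainable minimum is
$J^* = -2\,\mathrm{JSD}(p_{data}\,\|\,p_n) + 2\log 2$
(`optimal_nce_loss()`), and $J = 2\log 2$ exactly when $D \equiv 0$.

**Study conditions.** The simulated study draws a target $p_0$ from a
symmetric Dirichlet over the enumerated space in a fixed (lexicographic
canonical-key) order, with concentration $\beta = 0.008$ at space size
10395, and uses uniform noise. `run_ebm_experiment()` reproduces this at
$N = 7$ (945 topologies) by scaling the concentration so the total
Dirichlet mass matches ($\beta \cdot 10395/945$), and trains for 20000
updates. Design choices for the scaled-down run, fixed in advance of any
comparison: the EDGE operator with hidden width 32, batch 32 per term
(noise:data ratio 1:1), Adam with initial rate $2\times10^{-3}$ decaying
by a cosine schedule to one tenth — the decay damps the stochastic
gradient noise floor so the exact exhaustive loss can approach $J^*$
closely. Training batches sample topologies with replacement from the
target table; each distinct topology in a batch is forwarded once and its
loss gradient weighted by its multiplicity, which is mathematically
identical and much faster on concentrated targets.

# Variational Bayesian phylogenetic inference

The variational family is $Q_\phi(\tau)\,Q_\psi(q\mid\tau)$.

**Topologies: a subsplit Bayesian network.** A subsplit of a clade is its
bipartition into two child clades (clades are integer bitmasks over
lexicographically sorted taxa, supporting up to 30 taxa). An unrooted
tree is decomposed by rooting it on each of its $2N-3$ edges: the rooting
edge yields a root subsplit, and every interior node below yields a
parent–child subsplit pair. We use the simplest SBN: one conditional
distribution per (parent subsplit, side) slot, softmax-parameterized and
shared across locations; $Q_\phi(\tau)$ is the sum of rooted-tree
probabilities over all rootings. The support of the conditional
probability tables is harvested from a topology sample
(`collect_support()`). Because ancestral sampling always produces a
rooted tree and rooted trees partition into unrooted trees with one term
per rooting, $\sum_\tau Q_\phi(\tau) = 1$ exactly — the suite checks this
by enumeration. Off-support topologies get probability zero and a
`-Inf` sentinel with an explicit flag; we fail loudly rather than fall
back silently so support-coverage bugs surface.

**Branch lengths: diagonal Lognormal with three amortizations.**
$\mu(e,\tau)$ and $\log\sigma(e,\tau)$ come from (i) *split* tables keyed
by the bipartition the edge induces; (ii) *psp* tables that add, to the
split values, the parameters of the edge's primary subsplit pairs — for
each endpoint of the edge that is interior, the subsplit describing how
that side's clade subdivides (pendant edges thus carry one PSP, internal
edges two). The referenced constructions leave some freedom in which
subsplit pairs count as primary; this package pins exactly the
reduction-to-split property (zero PSP tables reproduce split mode
identically — tested) and internal consistency. Or (iii) *gnn*: the
learnable route — embed, message-pass, take the elementwise max of the
two endpoint features, and map through separate MLP heads for $\mu$ and
$\log\sigma$. The gnn mode needs no support lookup, so it produces
parameters for topologies absent from the tree sample — the property the
heuristic parameterizations structurally lack; a test asserts the
split/psp modes raise off-support errors on inputs the gnn mode handles.
$\sigma$ is stored on log scale (unconstrained). Tables initialize at
$\mu = \log 0.1$, $\log\sigma = -2$, weakly informative around the
Exp(10) prior mean; the gnn heads initialize their output biases to the
same values.

**The bound and its gradients.** Training maximizes the K-sample lower
bound ($K = 10$) with importance weights
$w_i = p(Y\mid\tau_i,q_i)^{\lambda}\,p(\tau_i)p(q_i) / (Q_\phi Q_\psi)$
under the annealing schedule
$\lambda_n = \min(1, 0.001 + n/\texttt{anneal\_steps})$. The study's
schedule reaches 1 after 100000 iterations of a 400000-iteration run; the
scaled-down five-taxon experiments here run 5000 iterations and
proportionally set `anneal_steps = 2000` so that the same fraction of the
run is annealed. Only the likelihood is annealed, not the prior.
Priors are fixed: uniform over topologies, i.i.d. Exp(10) branch lengths
(rate configurable).

Topology parameters $\phi$ get VIMCO gradients: per-sample learning
signals $\hat L - \hat L_{-i}$, where $\hat L_{-i}$ replaces sample $i$'s
weight with the geometric mean of the others, combined as
$\sum_i (\mathrm{signal}_i - \bar w_i)\,\nabla_\phi \log Q_\phi(\tau_i)$
with $\bar w$ the normalized importance weights. A toy-model test checks
unbiasedness against an exhaustively enumerated exact gradient and
variance reduction against the plain score-function estimator. At
$K = 1$ no control variate exists; the plain estimator is used with a
warning.

Branch parameters $\psi$ get reparameterization gradients. With
$q_e = \exp(\mu_e + \sigma_e \varepsilon_e)$, $s_e = \log\sigma_e$, and
$g_e = \lambda\,\partial \log p(Y\mid\tau,q)/\partial q_e - \text{rate}$,
substituting the sample into $-\log Q_\psi$ collapses it to
$\mu_e + \sigma_e\varepsilon_e + s_e + \text{const}$, giving the compact
totals

$$\frac{\partial \log w}{\partial \mu_e} = g_e q_e + 1, \qquad
  \frac{\partial \log w}{\partial s_e} = (g_e q_e + 1)\sigma_e\varepsilon_e + 1.$$

These need $\partial \log p(Y)/\partial q_e$ for every edge, which the
pruning module provides analytically in two passes (downward partial
likelihoods plus upward "above" messages; scalers cancel in the per-site
ratio) — checked against central finite differences at $10^{-4}$. In gnn
mode the per-edge gradients are seeded into the tape and backpropagated
into the network weights.

**Diagnostics.** `marginal_likelihood_is()` estimates $\log p(Y)$ by
importance sampling at $\lambda = 1$ with a delta-method standard error
on the log scale. `amortization_gap()` operationalizes the per-tree
amortization gap as: the K-sample per-tree bound after independently
optimizing an unamortized diagonal Lognormal (free $\mu, \log\sigma$ per
edge, initialized from the amortized values) minus the bound at the
shared amortized parameters, both at $\lambda = 1$, same $K$, evaluated
with common random numbers so the paired difference is low-variance (and
exactly zero at zero optimization steps). The reference text leaves the
gap's precise definition to a footnote not reproduced here; this
operationalization is the package's own and is stated openly.

# The likelihood model

JC69 throughout (the substitution model of the study's experiments):
uniform stationary distribution,
$P_{ii}(t) = \tfrac14 + \tfrac34 e^{-4t/3}$,
$P_{ij}(t) = \tfrac14 - \tfrac14 e^{-4t/3}$. The model object carries a
generic interface (stationary distribution plus transition function and
derivative), so another reversible model could slot in. Site patterns are
compressed to unique columns with weights before any likelihood work;
partial likelihoods are rescaled per interior node, keeping thousands of
sites underflow-safe. Ambiguous characters and gaps are treated as
missing (partial likelihood 1 in every state). The pruning implementation
is validated against a brute-force sum over all interior-node character
assignments and against an independent implementation on random
instances.

# Synthetic data

All experiments run from internally generated data
(`make_vbpi_fixture()`, `make_ebm_fixture()`), fully determined by their
seeds. The VBPI fixture draws a true topology uniformly (by sequential
random tip insertion, which is exactly uniform over unrooted bifurcating
topologies), Exp(10) branch lengths, and a JC69 alignment; its default
scale — 5 taxa, 500 sites, support size 10 — keeps full enumeration (105
topologies at most for checks) and repeated pruning affordable while
leaving the inference problem non-trivial. The support sample is the
top-$m$ topologies by pruning log-likelihood at fixed branch lengths (the
prior mean), a deterministic, download-free stand-in for the bootstrap
tree samples used with real data; it emulates "a set of plausible
topologies containing the truth" but not the replicate-noise structure of
bootstrap samples. The EBM fixture is the Dirichlet target described
above. What passing these tests shows — and does not show — about real
data: the machinery (bounds, gradients, amortization) is correct and the
qualitative ordering of parameterizations reproduces at small scale;
real-data effect sizes, mixing over much larger supports, and
model-misspecification effects are out of scope here.

# Numerical choices and limitations

* Stationarity residual tolerance $10^{-8}$ scaled by feature dimension;
  identifiability comparisons round features to $10^{-9}$.
* Canonical topology identity is the sorted set of edge-induced
  bipartitions (unique for unrooted trees); canonical newick output roots
  at the interior neighbor of the smallest taxon and orders children by
  smallest contained label, giving byte-identical strings for isomorphic
  trees.
* The NCE loss is computed through `softplus` and the normalizers through
  max-subtracted log-sum-exp; no overflow paths remain.
* Training runs are seeded end to end and bit-reproducible; all RNG use
  goes through a helper that restores the caller's RNG state.
* Problem sizes used by the experiment drivers (945-topology NCE space;
  5-taxon, 500-site, support-10 VBPI fixture; hidden widths 32/16) are
  the package's scaled-down study conditions, chosen once so that the
  full suite — enumeration, training, and diagnostics — runs on a single
  CPU in minutes while preserving the qualitative results.
* Limitations: no rate heterogeneity or partition models; no tree
  rearrangement operators; tree probability estimation requires an
  enumerable space (no SBN-amortized estimation of non-enumerable
  spaces); bitmask clade encoding caps the SBN machinery at 30 taxa;
  the identifiability suite verifies distinctness by enumeration, not a
  reconstruction algorithm.
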