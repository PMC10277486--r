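---
title: "Neighborhood-constrained logistic matrix factorization for metabolite-disease interaction prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neighborhood-constrained logistic matrix factorization for metabolite-disease interaction prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(lmflnc)
```

## The problem

Metabolite levels are proximal readouts of physiological state, and many
diseases perturb characteristic sets of metabolites.  Experimentally
confirmed metabolite-disease interactions are sparse: a typical curated
corpus covers a few thousand interactions over hundreds of diseases and
over a thousand metabolites, so the observed binary interaction matrix is
more than 99% zeros, and most zeros are *unobserved* rather than
confirmed negatives.  The task is bipartite link prediction: score every
unobserved metabolite-disease pair with an interaction probability so
candidate pairs can be ranked for follow-up.

## The model

Let $Y \in \{0,1\}^{n \times m}$ be the observed interaction matrix over
$n$ metabolites and $m$ diseases.  Each metabolite $i$ and disease $j$
receives a latent vector $u_i, v_j \in \mathbb{R}^r$ with
$r \ll \min(n, m)$, and an interaction is Bernoulli with probability

$$p_{ij} = \sigma(u_i v_j^\top) = \frac{e^{u_i v_j^\top}}{1 + e^{u_i v_j^\top}}.$$

Observed interactions are more trustworthy than unobserved ones, so each
observed pair is counted as $c \ge 1$ positive observations.  With
$A$ the (possibly smoothed, see below) interaction matrix, the data term
of the objective is

$$\sum_{i,j} cA_{ij}\, u_i v_j^\top - (1 + cA_{ij} - A_{ij})
  \ln\!\big(1 + e^{u_i v_j^\top}\big),$$

which for binary $A$ and $c=1$ is exactly the Bernoulli log-likelihood
(a property the test suite asserts).  Two penalties are subtracted: a
Frobenius-norm penalty $\tfrac{\alpha}{2}(\lVert U\rVert_F^2 +
\lVert V\rVert_F^2)$ against overfitting, and a neighborhood penalty
$\tfrac{\lambda}{2}\big(\mathrm{tr}(U^\top vir_u U) +
\mathrm{tr}(V^\top vir_v V)\big)$ that pulls the latent vector of each
node toward a weighted combination of its neighbors' vectors.

A note on signs: the gradient expressions implemented in
`lmf_gradient_U()`/`lmf_gradient_V()` carry the penalty terms with the
sign of a *minimized* negative log-likelihood, so the package's
`lmf_objective()` consistently reports the log-likelihood with both
penalties subtracted, and training descends on the negative of that
quantity.  An objective that *added* the penalty terms to a maximized
likelihood would reward large norms and contradict its own gradients;
we treat the gradient forms as authoritative.

## The local spectral (Vicus) regularizer

The classical choice for the neighborhood penalty is the graph Laplacian
of a K-nearest-neighbor graph.  The local spectral alternative used here
replaces the global Laplacian with a matrix built from *per-node label
diffusion*:

1. For node $i$, extract the subnetwork over its $K$ nearest neighbors
   plus $i$ itself.  By convention node $i$ occupies the **last**
   position of the subnetwork, so the final coordinate of every derived
   vector refers to the node's self-weight.
2. Row-normalize the subnetwork to a transition matrix $S_i$ and compute
   the converged diffusion operator $(1-\alpha)(I - \alpha S_i)^{-1}$
   with diffusion constant $\alpha = 0.9$.  Its last row $\beta_i$ is a
   probability vector expressing node $i$'s converged label as a convex
   combination of subnetwork labels.
3. Renormalize over the neighbors:
   $B_{ij} = \beta_{ij} / (1 - \beta_{i,K+1})$ for $j \in N_i$, zero
   elsewhere.  Every row of $B$ sums to 1 and $B_{ii} = 0$.
4. The local spectral matrix is $vir = (I - B)^\top (I - B)$.

$vir$ shares the Laplacian's contract — symmetric, positive
semidefinite, smallest eigenvalue 0 with eigenvector $\mathbf{1}$ — and
its quadratic form $\mathrm{tr}(U^\top vir\, U) = \sum_k
\lVert (I - B) U_{:k} \rVert^2$ measures how badly each latent dimension
is reconstructed from neighbors.  The cluster-indicator machinery that
motivates the construction cancels out of the final matrix (only
$\beta_i$ survives), so indicators are not runtime inputs; the
reconstruction-residual identity $\lVert q - Bq \rVert^2 = q^\top vir\,
q$ is exercised in the tests instead.

Numerical choices, all asserted by tests:

* The per-node linear systems are $(K{+}1) \times (K{+}1)$ and solved by
  direct factorization; the contract is the exact inverse row, not an
  iterative approximation.
* Nodes with fewer than $K$ positive-similarity neighbors get a
  per-node shrunken $K$ (minimum one neighbor) — padding with
  zero-similarity neighbors would make transition rows degenerate.
* If a node's diffusion self-weight reaches 1 (isolated from its
  neighborhood), its $B$ row falls back to the uniform distribution over
  the neighbor set, keeping $B$ row-stochastic and $vir$ well defined.
* Neighbor ties are broken by ascending identifier so all constructions
  are deterministic and permutation-equivariant.

`knn_laplacian()` provides the classical combinatorial Laplacian of the
same K-NN graph behind the same interface, as an ablation baseline.

## Similarity networks

**Diseases.**  Disease terms live in a rooted hierarchy (a MeSH-style
DAG consumed as a simple child-parent TSV) with per-term annotation
counts.  A term's frequency is its own count plus the counts of its
descendant *set* — on a DAG a term reachable through several parents is
counted once; the naive per-parent recursion would double-count and push
probabilities above 1.  Probability is frequency relative to the root,
and pairwise similarity is Lin's information-content measure

$$score(t_1, t_2) = \max_{t \in CA(t_1,t_2)}
  \frac{2 \log prob(t)}{\log prob(t_1) + \log prob(t_2)},$$

maximized over common ancestors (probability is monotone toward the
root, so this equals the maximum over *least* common ancestors).  The
root carries no information content ($\log prob = 0$): it scores 0
against every other term and 1 against itself, which also resolves the
zero-denominator case without special-casing at call sites.

**Metabolites.**  From metabolite-gene and gene-GO tables: gene-gene
similarity is the Jaccard index of GO sets (defined 0 when both sets are
empty — no evidence is not evidence of similarity), gene-vs-set
similarity is the best match, and metabolite-metabolite similarity
averages best matches in both directions, which is symmetric by
construction rather than by post-hoc averaging.  Metabolites mapping to
no gene have no functional similarity and are dropped with a report,
mirroring the corpus-construction filter.

**Fusion.**  When several disease (or metabolite) similarity sources are
available they are combined by `fuse_similarities()`, a renormalized
weighted elementwise average with equal weights by default.  The
diffusion-based multi-network fusion used in some corpus pipelines is a
deliberate non-goal; the weighted average keeps the fusion rule
explicit, configurable and order-independent.

## Smoothing the interaction matrix (WKNNP)

Because most zeros are unobserved, the binary matrix is smoothed before
factorization by weighted K-nearest-known-neighbor profiles: entry
$(i,j)$ receives the decayed, similarity-weighted average of the $K$
most similar metabolites' profiles and, symmetrically, the $K$ most
similar diseases' profiles, the two sides are averaged, and the result
is combined with the original matrix by elementwise maximum — so
observed interactions are never attenuated and the output is a monotone
completion of the input.  Neighbor weights are $\eta^{k-1} s_k$ with
decay $\eta = 0.9$ and $K = 5$ by default; neighbors are restricted to
nodes with at least one known interaction (configurable), since an
all-zero profile carries no information to borrow.  Rows with no
positive neighbor similarity are left unchanged, which also makes the
operation exactly idempotent on degenerate input.

## Training

Defaults follow the method's published operating point: $c = 2$,
$\lambda = 8$, $\alpha = 4$, diffusion $K = 15$ and $\alpha_{diff} =
0.9$.  The latent dimension is not part of that operating point; the
package default is $r = 50$, with the constraint $r \le \min(n, m)$
enforced.  Optimization is AdaGrad — per-parameter steps
$\mathrm{lr}/\sqrt{G + 10^{-8}}$ on accumulated squared gradients, base
learning rate 0.01, at most 1000 iterations, stopping when the relative
objective change over a 10-iteration window falls below $10^{-6}$.
Initialization draws all latent entries from $\mathcal{N}(0, 1/r)$ under
the configuration seed, keeping initial inner products $O(1)$ and fits
bitwise reproducible.  When $A$ is smoothed its real values weight each
pair on a continuum between 1 and $c$; a flag restores binary
weighting.

## Cold-start projection

Nodes with no observed interaction in the *original binary* matrix (the
smoothed matrix would make almost every row nonzero and disable the
mechanism) get projected vectors before scoring: the similarity network
is masked to its K-NN structure by an or-rule ($K = 10$, symmetric by
construction), and an unknown node's vector is replaced by the decayed,
weight-normalized combination of its nearest *known* neighbors' vectors
(decay 0.9, neighbors ordered by descending constraint weight, ties by
identifier).  Restricting the donor pool to known nodes is what makes
the projection idempotent.  A node with no positively weighted known
neighbor keeps its trained vector, with a warning.  Pair scores are the
sigmoid of the projected inner products.

## Evaluation protocol

Five-fold cross-validation over the observed positives: each fold's
positives are zeroed in the training matrix and scored at test time
against **all** zeros of the original matrix, matching the extreme class
imbalance of deployment.  Three protocol rules prevent leakage and
are asserted programmatically in the tests:

* held-out positives are zero in the training matrix *before* smoothing,
  and smoothing is applied per fold to the training matrix only;
* the Vicus matrices depend only on the similarity networks, never on
  the interaction matrix, so they are shared across folds;
* folds are seeded exact partitions with sizes differing by at most one.

Metrics are AUPR (step-interpolated precision-recall area, the primary
metric under class imbalance), AUC (pairwise-comparison definition with
half credit for ties), and best F1 over thresholds (the thresholding
rule is not standardized in the literature; a fixed-cutoff variant is
available).  All three match exhaustive threshold-enumeration oracles in
the tests.  `grid_search()` sweeps $\alpha, \lambda \in \{2^{-3}, \dots,
2^3\}$ by cross-validated AUPR, breaking ties toward smaller $\lambda$
then smaller $\alpha$.

## The synthetic generator, and what passing tests do not show

`generate_bipartite()` emulates the structural assumption the model
exploits: metabolites and diseases fall into matched blocks, interaction
probability is elevated within matched blocks (0.9 within vs 0.05
background by default, giving low-rank structure), labels are flipped
symmetrically with probability 0.05, and the similarity networks echo
the block identity with configurable strength (default: within-block
mean similarity exceeds between-block by 0.45, with Gaussian jitter of
sd 0.1, unit diagonal).  Setting the similarity signal to 0 yields a
negative control in which neighborhood regularization has no structure
to exploit.  Defaults of 20 metabolites and 15 diseases keep every
routine exercised in seconds.

Real corpora differ in ways the generator deliberately does not
emulate: heavy-tailed degree distributions, far more extreme sparsity
(order $10^{-2}$ density), block-free covariance structure, and
annotation biases.  Passing recovery tests therefore demonstrates
correctness of the machinery, not expected field performance.

One property of the generator deserves emphasis.  Conditional on the
block labels, cells are independent Bernoulli draws, so any score
computed from the training data assigns exchangeable scores to test
cells of the same block; the best achievable ranking is the generative
block-probability oracle.  With flip noise and background interactions
included in the evaluation, that oracle's AUC on this protocol sits in
the high 0.80s — an information-theoretic ceiling that no method can
exceed in expectation at these settings.  Recovery tests on the default
spec should be read against that ceiling, and the noise-free planted
configurations (within-probability 1, background 0, no flips) are the
ones where near-perfect recovery is the correct expectation.

## Problem sizes used by the tests

Unit and property tests run on 2-60 node networks where brute-force
oracles (dense inversions, exhaustive ancestor enumeration, full
threshold sweeps) are exact and instant.  Cross-validation tests use the
default 20x15 generator spec with $r = 5$, AdaGrad learning rate 0.05
and up to 1000 iterations, and diffusion $K = 5$ — at 15-20 nodes a
15-neighbor subnetwork would swallow the whole graph and the per-node
shrink rule would make the larger $K$ a fiction.  These are the
package's reference desk-scale settings; corpus-scale runs should
restore the published operating point.

## Known limitations

* Training is full-batch; the gradient cost is $O(nm r)$ per iteration.
  At corpus scale (hundreds by thousands) this is still modest, but
  minibatch or alternating schemes are out of scope.
* The gene-network variant of metabolite similarity (propagating over a
  human gene interaction network instead of GO Jaccard) is not
  implemented; the annotation-based path is.
* The fusion rule is a weighted average, not a diffusion-based
  integration; sources with very different scales should be normalized
  upstream.
* F1's threshold maximization makes it optimistic relative to a
  deployment threshold chosen on validation data.
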