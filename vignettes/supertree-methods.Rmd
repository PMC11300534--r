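---
title: "Supertree distributions from overlapping tree posteriors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supertree distributions from overlapping tree posteriors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbnsupertree)
```

## The problem

Bayesian phylogenetic analyses of two overlapping taxon sets yield two
posterior distributions over rooted tree topologies.  Re-running MCMC on
the union of the taxon sets is expensive; instead, one can ask for a single
distribution $q(\tau)$ over topologies on the union taxon set
$X = X_1 \cup X_2$ whose *restrictions* to each subset resemble the given
per-subset distributions $p_1, p_2$.  Restricting a topology means deleting
the tips outside the subset and suppressing the internal nodes left with
one child; restricting a distribution means marginalizing over all
topologies with the same restriction,
$q\!\downharpoonright_{\bar X}(\bar\tau) = \sum_{\tau:\,
\tau\downharpoonright_{\bar X}=\bar\tau} q(\tau)$.

This package fits $q$ variationally: it minimizes the loss

$$L(\{p_i, w_i\} \,\|\, q) \;=\; \sum_i w_i\,
D_{\mathrm{KL}}\!\left(p_i \,\big\|\, q\!\downharpoonright_{X_i}\right)$$

by gradient descent, with $q$ parameterized as a subsplit Bayesian network
(SBN).  All divergences are natural-log (nats).

## Subsplit Bayesian networks

A *clade* is a taxon subset; a *subsplit* $s = \{Y, Z\}$ is an unordered
pair of disjoint clades with parent clade $U(s) = Y \cup Z$; a *PCSP*
(parent–child subsplit pair) $t \to s$ pairs a subsplit with its parent.  A
rooted bifurcating topology on $n$ taxa is identified with its set of
$n - 1$ nontrivial subsplits (equivalently its PCSPs, with the root
subsplit parented by the trivial subsplit $\{X, \emptyset\}$).

Two SBN families are implemented:

* **CCD** (clade-conditional): $p(\tau) = \prod_{s \in \tau} p(s \mid U(s))$.
* **SCD** (subsplit-conditional): $p(\tau) = \prod_{s \in \tau}
  p(s \mid (\pi_\tau(s), U(s)))$, conditioning on the parent subsplit and
  the focal clade.

Singleton conditionals are fixed to 1 and never stored.  Both families
support exact linear-time computation of tree probabilities, top-down
sampling, unconditional subsplit/PCSP probabilities, ancestor–descendant
path probabilities $q(a \to_* d)$, and a closed-form KL divergence that
sums over support elements instead of trees:
$D_{\mathrm{KL}}(p\|q) = -\sum_s p(s) [\log q(s|U(s)) - \log p(s|U(s))]$
for CCDs, with the PCSP analogue for SCDs.  Every one of these quantities
is testable against the `tree_distribution` module, a deliberately slow
explicit-enumeration oracle; the test suite holds them to agreement within
$10^{-10}$ on randomized 4–6-taxon instances.

## Restriction at the parameter level

Restricting an SBN is done directly from its parameters, without
enumerating trees.  Distinct subsplits that restrict to the same nontrivial
subsplit are mutually exclusive (no topology can contain two of them), so
unconditional restricted probabilities are plain fiber sums
$q\!\downharpoonright(\bar s) = \sum_{s:\, s\downharpoonright = \bar s} q(s)$,
clade probabilities are sums over dividing subsplits, and restricted
conditionals are their ratios.  For SCDs, a restricted PCSP
$\bar t \to \bar s$ can arise from an ancestor–descendant pair $(a, d)$
that was *not* a parent–child pair before restriction: every subsplit
strictly between them necessarily restricts to a trivial subsplit, so
$q\!\downharpoonright(\bar t \to \bar s) = \sum_{a\downharpoonright=\bar t}
\sum_{d\downharpoonright=\bar s} q(a \to_* d)$.

One finding from this package's own testing deserves emphasis.  **SCD
restriction is exact**: the induced tree distribution of the restricted
SCD equals the marginalized restriction, to machine precision on hundreds
of randomized sparse-support instances.  **CCD restriction is a
projection**: the clade-conditional family is not closed under
restriction.  On sparse supports the true restricted distribution may not
be a CCD at all; the construction then returns the CCD with the exact
restricted conditional clade frequencies, i.e. the maximum-likelihood CCD
of the true restricted distribution (verified by fitting that CCD
explicitly and obtaining identical conditionals).  The package's loss and
gradients for CCDs are defined — and finite-difference-verified — with
respect to this projected restriction, which is also what the closed-form
conditional ratios imply.  Complete supports did not exhibit the
discrepancy in testing.  This is one practical reason the SCD
parameterization is the default throughout the higher-level tools.

## The mutual supertree support

An SBN's support (the subsplits or PCSPs with positive probability) is
what makes the KL divergences finite: $D_{\mathrm{KL}}(p \| q)$ is
undefined wherever $p$ has mass and $q$ does not.  The supertree support is
built from the reference supports to satisfy two requirements: every
element must restrict into each reference support (keeping the support as
small as possible), and every topology on $X$ whose restrictions lie in
all references must be representable (not missing anything admissible).

The combination step is the box product
$s_1 \boxtimes s_2 = \{\{Y_1 \cup Y_2,\, Z_1 \cup Z_2\},
\{Y_1 \cup Z_2,\, Z_1 \cup Y_2\}\}$, keeping candidates whose children are
disjoint and nonempty.  The subsplit algorithm walks clades top-down from
$X$, pairing reference candidates (including trivial subsplits, and
singleton or empty pseudo-subsplits for reference sides whose restricted
clade has fewer than two taxa) and pushing emitted child clades.  The PCSP
algorithm additionally carries, per stack frame, the most recent
nontrivially-restricting parent on each reference side, because a parent
subsplit can vanish (restrict trivially) on one side; candidates on that
side are then drawn from the carried parent's focal clade.  The visited set
is keyed on the full frame (focal clade plus both carried parents): the
same focal clade reached under different carried parents can admit
different children.

Two implementation choices go beyond the bare traversal:

* The raw traversal can emit dead ends — elements whose child clades no
  emitted element divides.  The output is pruned to a closed, reachable
  support (iterating closure and reachability to a fixed point).  Pruned
  elements can complete no topology, so neither requirement is affected;
  the exhaustive requirement checker (`verify_requirements`) confirms this
  on randomized instances by enumerating all topologies on the union taxon
  set.
* Mutualization of more than two references folds pairwise,
  left-to-right.  One-at-a-time folding is not guaranteed to be
  order-independent; the package verifies requirements against all
  references but does not enforce order invariance.

When the references conflict (no topology restricts into both), the mutual
support is legitimately empty and is returned as such.

## Softmax parameterization, gradients, and training

The supertree SBN is parameterized by unconstrained reals $v$, one per
support element, with conditionals given by a softmax within each clade
block (CCD) or focal-parent block (SCD).  The default start $v = 0$ gives
uniform conditionals — the high-entropy initialization.  Adding a constant
to a block leaves the distribution unchanged; gradients are accordingly
orthogonal to each block's all-ones direction (tested to $10^{-10}$).

The KL gradients are analytic.  For CCDs,
$$\partial_{s'} q(s) = q(U(s'))\, q(s'|U(s'))\,
\left[q(s' \to_* s \mid s') - q(U(s') \to_* s \mid U(s'))\right],$$
accumulated against coefficients built from the reference's and the
restriction's subsplit and clade probabilities.  For SCDs the derivative of
a restricted PCSP probability needs derivatives of path probabilities,
$$\partial_{s'|t'}\, q(a \to_* d) = q(a)\, q(a \to_* t' \mid a)\,
\mathcal{D}(s'|t'; d) + q(t')\, \mathcal{D}(s'|t'; a)\, q(a \to_* d \mid a),$$
with $\mathcal{D}(s'|t'; a) = q(s'|(t', U(s')))\,[\,q(s' \to_* a \mid s') -
q((t', U(s')) \to_* a \mid (t', U(s')))\,]$.  Conditional path
probabilities are computed once per evaluation point as dense
ancestor-by-descendant tables via a column-wise dynamic program over the
support, which keeps both restriction and gradients vectorized.  Every
gradient component is validated against central finite differences
($h = 10^{-5}$, relative error under $10^{-5}$ with near-zero components
compared absolutely) across randomized instances that include taxa private
to one reference, parents that restrict trivially, and weighted
multi-reference losses.

Training is plain gradient descent with step halving: a proposed step that
increases the loss is retried at half the step until it improves, making
the recorded loss trace non-increasing by construction.  After an accepted
step the step size is allowed to recover (doubling, capped at 64 times the
initial value); with a monotonically shrinking step the 6-taxon recovery
experiment below needed several times more iterations to approach its
optimum, and the acceptance rule preserves monotonicity either way.
Defaults: step 0.5, at most 40 halvings per iteration, stop when an
accepted step improves the loss by less than $10^{-10}$.  An optional
L2 penalty $\lambda \|v\|^2$ (default $\lambda = 0$) is available to pull
the fit toward the uniform distribution where the references carry no
information; the choice of an L2 form on $v$ is this package's own design
decision among the penalties that encourage conservative conditionals.

## Synthetic study design

The generator emulates a leave-one-taxon-out divide-and-conquer study at
desk scale, replacing sequence simulation and MCMC with exact SBN
machinery while preserving the statistical structure the method consumes:

1. a ground-truth SCD on $n = 6$ taxa whose support is spanned by 10
   coalescent-sampled topologies (uniform random pair merging), with
   conditional blocks drawn from a symmetric Dirichlet with concentration
   1 — a posterior-sample-like sparse support with unstructured
   probabilities;
2. two references: exact restrictions of the truth, each omitting one of
   two distinct taxa; optionally re-estimated from 5{,}000 sampled
   topologies with min-count-2 trimming (topologies seen once are
   discarded), the stand-in for thinned MCMC output;
3. the mutual PCSP support of the two reference supports;
4. truth and references trimmed to what the mutual support (appropriately
   restricted) covers, then renormalized within each conditional block.
   Renormalization after trimming is this package's choice, required to
   keep the trimmed objects valid distributions.

Problem sizes throughout the tests (4–6 taxa, supports from 2–10 trees,
5{,}000 samples, 200 training iterations) are chosen so that brute-force
enumeration remains an exact oracle for every computation.

What the generator does *not* emulate: phylogenetic signal from actual
sequence data (truth conditionals are Dirichlet draws, not posterior
concentrations induced by an alignment), MCMC autocorrelation beyond
simple multinomial sampling noise, and branch lengths, which are outside
the scope of the topology-only method.  Passing tests therefore
demonstrate the correctness of the machinery and the qualitative training
behaviour, not calibration against any real posterior.

## The recovery experiment and its identifiability limit

The headline end-to-end check trains a supertree SCD on the mutual support
(from $v=0$, 200 iterations) against the two exact leave-one-out
references.  The loss decreases monotonically to below $10^{-2}$
(typically far below), and the same holds for the sampled-reference
pipeline, whose loss falls by well over 90% from initialization.

The KL divergence from the ground truth to the fitted distribution behaves
differently, and deliberately so: the two references never jointly observe
the two omitted taxa, so the truth's correlation between their placements
is invisible to the loss.  At loss $\approx 0$ the fit matches both
restrictions exactly, yet a whole manifold of distributions does; gradient
descent from the uniform start converges to a point on that manifold that
generically retains a KL gap to the truth.  Under this generator's
conditions the gap is substantial: across seeds, the KL to the truth falls
by roughly 55–75% even at loss $\sim 10^{-9}$, and concentrating the
truth's conditionals (Dirichlet concentration 0.1–0.2) widens the spread
(45–99%) without making recovery reliable.  The corresponding acceptance
check asserts a 90% reduction and is expected to fail under these study
conditions; the package reports the observed reduction rather than
adjusting the experiment to meet the number.  This is the same
insufficiency of reference information for which the optional
regularization penalty exists, and a reason importance-sampling correction
of the fitted distribution is attractive future work.

## Numerical choices and degenerate inputs

* Natural logarithms everywhere; $0 \log 0 := 0$.
* Tree probabilities accumulate in log space; conditional tables stay in
  linear space and must normalize within $10^{-9}$ per block at
  construction.
* Canonical forms: taxa sorted bytewise; subsplit children ordered by
  (size, then lexicographic key); deterministic Newick output with the
  canonical child order.
* Restriction to fewer than 2 taxa is a domain error for distributions; a
  single-tip restriction of a topology yields a degenerate zero-subsplit
  topology, needed when a reference barely overlaps a clade.
* Restricted conditionals with zero denominators cannot arise: support
  elements are only created from positive fiber sums.
* Enumeration guards: topology enumeration is capped at 8 taxa
  ((2n-3)!! growth), support enumeration at a configurable topology count,
  complete supports at 7 taxa.
* Seeds: every stochastic routine accepts one; fixed seeds reproduce
  bit-identical SBNs, samples, and training traces.

## Limitations

* Rooted, bifurcating topologies only; no branch lengths, no unrooted
  trees, no multifurcations.
* CCD restriction is a projection on sparse supports (see above); use
  SCDs when exactness under restriction matters.
* Mutualization handles two references at a time; $k$-way combination is
  an ordered fold and may depend on the order.
* The exhaustive requirement verifier and all oracle comparisons need
  enumerable taxon sets (at most 8 taxa); correctness at larger scales
  rests on the verified algebra, not on direct enumeration.
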