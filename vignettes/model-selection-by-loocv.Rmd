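---
title: "Selecting the number of clusters in sparse networks by analytic LOOCV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting the number of clusters in sparse networks by analytic LOOCV}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbmcv)
```

## The model and the inference problem

The stochastic block model (SBM) assigns each vertex a latent cluster label
$\sigma_i \in \{1,\dots,q\}$ drawn with probabilities $\gamma_\sigma$, and
connects each unordered pair independently with probability
$\omega_{\sigma_i\sigma_j}$. In sparse networks $\omega = O(1/N)$, so the
likelihood

$$p(A,\sigma\mid\gamma,\omega) = \prod_i \gamma_{\sigma_i}
  \prod_{i<j} \omega_{\sigma_i\sigma_j}^{A_{ij}}
  (1-\omega_{\sigma_i\sigma_j})^{1-A_{ij}}$$

is dominated by the edge factors; the non-edge factors act collectively as
a weak external field. The degree-corrected variant multiplies the edge
probability by per-vertex propensities, $\theta_i \omega \theta_j$, which
lets clusters carry heterogeneous degree distributions; we identify
$\theta$ by fixing its mean to 1 within each cluster, so $\omega$ keeps the
block-pair scale.

Given $A$ and a trial $q$, the engine runs EM: the E-step estimates
marginals by belief propagation (BP), the M-step re-estimates
$(\gamma,\omega)$ from the marginals. BP tracks cavity biases
$\psi^{i\to j}_\sigma$ — the marginal of $i$ computed while ignoring $j$ —
and treats all non-edges through a mean-field term $h_\sigma =
\sum_k \theta_k \sum_{\sigma_k}\psi^k_{\sigma_k}\omega_{\sigma_k\sigma}$,
with vertex $i$ feeling $e^{-\theta_i h_\sigma}$. This replaces the exact
$(1-\omega)$ product — valid when $\omega = O(1/N)$ — and gives $O(N+L)$
cost per sweep.

## Why cross-validation, and why it is free here

Model selection by minimum prediction error does not require the model to
be the true generator of the data, unlike marginal-likelihood or BIC-style
criteria. The natural data unit for a network is the pair observation
$A_{ij}$; leave-one-out cross-validation hides one pair at a time. Naively
that means refitting $O(N^2)$ times, but the cavity bias is precisely the
posterior with one pair's information removed:
$p(\sigma_i,\sigma_j\mid A^{\backslash(i,j)}) =
\psi^{i\to j}_{\sigma_i}\psi^{j\to i}_{\sigma_j}$. Every LOOCV error
therefore has a closed form in BP quantities, evaluated after a single fit.
The per-pair predictive of an edge is the pair normalizer
$Z^{ij} = \sum \psi^{i\to j}\omega\,\psi^{j\to i}$, and for sparse networks
the non-edge contributions to each error reduce to a constant (the leading
"1" in the reports; the tables also carry the constant-stripped convention
used for plotting).

Four errors are computed per edge (nats): Bayes
($1 - \overline{\log Z^{ij}}$), Gibbs (score at assignments drawn from the
leave-one-out posterior), its MAP variant (argmax assignments, ties to the
lowest index), and the training error (average over the full-data
posterior — goodness of fit). Two exact relations hold at *any* message
state, and the test suite asserts them on random states:

* $E_\text{training} \le E_\text{Bayes} \le E_\text{Gibbs}$, from Bayes'
  rule plus non-negativity of KL divergence (the gaps *are* KL
  divergences, an identity the enumeration oracle checks term by term);
* $f_\text{Bethe} = \frac{c}{2}(E^v_\text{Bayes} + 1 - E_\text{Bayes}) -
  \frac{c}{2}$, where $E^v_\text{Bayes} = -\frac1L\sum_i\log Z^i$ is the
  leave-one-vertex-out error and $c = 2L/N$.

The selected $q$ uses the one-standard-error rule on per-edge standard
errors: the smallest model within one SE of the best. Diagnostics flag
solutions worth discarding: BP sweep counts growing by more than a
configurable factor (default 3) over smaller $q$, fewer populated clusters
than $q$, non-convergence, and criteria whose minimum sits at the edge of
the sweep ("no saturation") — in that case the result is an explicit flag,
not a confident selection.

## Engine choices and numerical details

* **Updates.** Sweeps are asynchronous and vertex-blocked: vertices are
  visited in a seeded random order and all outgoing messages of a vertex
  are refreshed together. This allows forming the product over incoming
  messages once and dividing out each factor ($O(Lq^2)$ per sweep); a
  near-degenerate divisor (entry below $10^{-12}$ of the max) triggers a
  direct exclusion product instead. The field $h$ is updated incrementally
  as marginals change.
* **Defaults.** Message tolerance $10^{-6}$ (max absolute entry change),
  500 BP sweeps, 100 EM iterations (parameter change below $10^{-6}$,
  with $\omega$ measured on the $N\omega$ scale), 10 restarts, damping 0.
  These are conventional for BP on sparse graphs; restarts are ranked by
  Bethe free energy, which is always the criterion for the *inference*
  step — the cross-validation errors arbitrate only across $q$.
* **Initialization.** Cavity messages start uniform with multiplicative
  noise (default 0.1) and renormalization; parameters start from random
  cluster fractions and a random planted-partition-shaped affinity at the
  observed mean degree. Zero noise reproduces the symmetric factorized
  point exactly, which is useful for studying the undetectable regime.
* **Floors.** Messages are floored at $10^{-12}$ before renormalization to
  avoid $\log 0$; underflowing updates reset to uniform and are counted. A
  cluster whose fraction falls below $10^{-8}$ in the M-step is declared
  empty and its affinity rows frozen, so the *effective* number of clusters
  can be smaller than $q$ (and is reported).
* **$q=1$.** Returned in closed form: all errors coincide at
  $1-\log\omega$. The reporting baseline uses $\omega = 2L/N(N-1)$, while
  the M-step fixed point is $2L/N^2$; the difference is $O(1/N)$ and the
  baseline convention wins in reports. The degree-corrected null uses
  $p_{ij} = d_id_j/2L$, giving $1 - \frac1L\sum_i d_i\log d_i + \log 2L$.

## The synthetic generator and the detectability threshold

`planted_partition_params()` builds the equal-affinity community structure:
$\omega_\text{in}$ on the diagonal, $\omega_\text{out} =
\epsilon\,\omega_\text{in}$ elsewhere, scaled so the *expected* mean degree
equals $c$ (the realized degree then fluctuates binomially; we fix the
expectation, not the realization). Sampling draws a binomial edge count per
block pair and places that many distinct pairs, so a network with $N=4000$
costs $O(N+L)$; degree-corrected sampling thins a bounding proposal, and
collapses to the standard stream when $\theta\equiv 1$. For $q$ equal
blocks the planted structure becomes undetectable above
$\epsilon^* = c_\text{out}/c_\text{in}$ solving $c_\text{in}-c_\text{out} =
q\sqrt c$; for $q=4$, $c=8$ this is $\approx 0.31$. The threshold formula
assumes equal block sizes; unequal blocks are allowed everywhere else.

What the generator emulates is exactly the model the engine assumes — that
is the point of the benchmark (detectability is a property of the model
class), but it means passing tests on synthetic data say nothing about
model mismatch on real networks: no degree heterogeneity beyond the
planted $\theta$, no clustering/transitivity, no metadata. The
degree-corrected errors and the diagnostics exist precisely because real
networks violate these assumptions.

## The enumeration oracle and what "exact on trees" means

For $N\le 10$ the oracle enumerates all $q^N$ assignments under the full
dense likelihood and produces exact marginals, pair posteriors, the free
energy, and exact leave-one-out predictives (parameters fixed, no refit —
refitting changes parameters by $O(1/N)$ only). BP with the mean-field
non-edge term is *not* exactly the dense model even on trees: the field
sums over all vertices (including neighbours and the vertex itself) and
$e^{-\omega}$ differs from $1-\omega$ at second order. Both effects vanish
with the affinity scale, so the tree-equivalence tests run at
$\omega \sim 10^{-10}$, where agreement is required at $10^{-8}$. One
constant needs care: the $-c/2$ in the Bethe free energy is the
sparse-regime non-edge mass, which is $\approx 0$ on tiny-$\omega$
fixtures, so the oracle comparison is
$f_\text{Bethe} + c/2 \approx f_\text{exact}$ there. On loopy graphs BP is
approximate; a triangle fixture quantifies the loop correction (it depends
on the affinity *contrast*, not the scale).

## Holdout and K-fold

Both are provided for comparison with the analytic LOOCV: the held-out
edges are removed from the training network (so their cavity messages
never enter any product; their endpoints still feel the generic non-edge
field — the held-out pair is treated as unobserved, not as a non-edge) and
scored with the marginals their endpoints send into the pair. The holdout
can be constrained to pairwise non-adjacent edges; K-fold deliberately
ignores the dependence among connected held-out edges and reports the
number of adjacent held-out pairs per fold so the approximation can be
judged. On tree fixtures at fixed parameters, single-edge holdout equals
the analytic per-edge LOOCV term and $K=L$ K-fold equals the analytic
LOOCV, which the acceptance tests verify at $10^{-8}$.

## Problem sizes used in the tests

The suite runs the full study conditions where they are cheap enough to be
routine: the planted-partition benchmark at $N = 4000$ ($q^*=4$, blocks of
1000, $c=8$, $\epsilon = 0.1$ and five seeds at $0.25$) with 5 restarts;
parameter recovery at $N = 2000$; twenty tree fixtures at $N \le 9$ for
the enumeration comparisons; smaller planted networks ($N \le 1200$)
elsewhere. These sizes were chosen so the whole suite is a coffee-break
run on one core while keeping every stochastic check comfortably away from
its threshold.

## Known limitations

* Directed, weighted, bipartite and signed networks are out of scope, as
  are dense graphs (the $e^{-h}$ approximation assumes $\omega = O(1/N)$).
* The degree-corrected BP uses the minimal substitution
  $\theta_i\omega\theta_j$ in the messages, the analogous
  $\theta$-weighted field, and identifies $\theta$ from degrees within
  argmax blocks; a full joint M-step over $\theta$ is not attempted.
* The information-monotonicity ordering of selected $q$ across criteria
  ($q^*_\text{training} \ge q^*_\text{Bayes} \ge q^*_\text{Gibbs}$) rests
  on a hierarchy assumption that numerical fits only approximate, so the
  package *reports* violations of the ordering rather than asserting it.
* "Saturation" of an error curve has no formal definition; only the
  one-standard-error rule is implemented as a selector, and the curve, the
  SEs and the flags are all exposed for judgment.
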