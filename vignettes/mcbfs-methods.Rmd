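---
title: "Multi-scale clustering-based feature selection: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale clustering-based feature selection: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcbfs)
```

## The model

MCBFS is a supervised gene-weighting method for labeled expression
matrices. The classes are treated as known clusters: the center of class
$i$ is the per-gene mean $v_{ik}$ of its samples. Dissimilarity between an
expression value and its class center is measured by a bank of $m$ bounded
Gaussian-style kernels

$$d_n(x, v) = 1 - e^{-\gamma_n (x - v)^2}, \qquad n = 1, \dots, m,$$

whose bandwidths share one data-derived scale: with $u_k$ the range of
gene $k$ over all samples, $\gamma_n = \sigma_n\,(\max_k u_k + \min_k
u_k)/2$. Because the class centers depend only on the labels, the summed
per-gene, per-kernel dissimilarities

$$A_{nk} = \sum_i \sum_{j \in c_i} d_n(x_{jk}, v_{ik})$$

are computed once per fit and never change afterwards. Each $A_{nk}$ lies
in $[0, s)$ for $s$ samples, and measures the within-class scatter of gene
$k$ at length scale $1/\sqrt{\gamma_n}$.

Two weight vectors are estimated: gene weights $W \in \Delta^{p}$ and
kernel weights $P \in \Delta^{m}$, by minimizing

$$J = \sum_n P_n \sum_k W_k A_{nk} \;+\; \delta \sum_k W_k^2
      \;+\; \rho \sum_n P_n \log P_n ,$$

subject to both vectors lying on their probability simplices. The first
term rewards concentrating weight on genes (and kernels) with compact
within-class expression; the ridge term spreads $W$; the negative-entropy
term keeps $P$ from collapsing onto a single kernel. Eliminating the
Lagrange multipliers gives closed-form updates:

* $W_k = \tfrac1p + \tfrac1{2\delta}\big(\tfrac1p\sum_{k'} b_{k'} - b_k\big)$
  with $b_k = \sum_n P_n A_{nk}$ — the equality-constrained ridge solution;
* $P_n \propto \exp(-B_n/\rho)$ with $B_n = \sum_k W_k A_{nk}$ — a softmax,
  computed with a max-shift ($-1$ inside the exponent cancels in the
  normalization).

Both regularization strengths are re-estimated each iteration so that they
stay on the scale of the scatter term:
$\delta = \alpha \sum_n P_n B_n / \sum_k W_k^2$ and
$\rho = \beta \sum_n P_n B_n / \lvert\sum_n P_n \log P_n\rvert$. Both
vectors start uniform. Genes are ranked by their final weight.

### Why the entropy denominator is taken in absolute value

$\sum_n P_n \log P_n$ is non-positive, so the printed temperature formula
would give $\rho \le 0$, while the softmax update and the objective need
$\rho > 0$ to *penalize* concentration of $P$. We take the absolute value,
preserving the magnitude and the intended role of the term. A one-hot $P$
(zero entropy) is an error unless $m = 1$, where the configured
`rho_fallback` (default 1) is returned and $P$ stays $(1)$.

### Why genes are standardized before fitting

$A_{nk}$ measures *absolute* within-class scatter. On raw data a flat,
uninformative gene with small variance beats a discriminative gene whose
within-class noise is larger in absolute units — the objective cannot see
between-class separation at all. Standardizing every gene to unit total
variance (the `scale_genes = TRUE` default) turns the score into a
*relative* within-class compactness: for gene $k$ it approaches
$1 - \eta_k^2$, the complement of the between-class variance fraction, so
small scatter now means exactly "much of this gene's variance is
between-class". This is what makes the ranking discriminative, and it also
makes the ranking exactly invariant to rescaling the expression matrix.
Fitting raw values remains available with `scale_genes = FALSE`; note that
the bandwidth rule makes $\gamma_n$ proportional to the data scale, so the
raw-value fit is not scale-invariant. Zero-range (constant) genes would be
ranked best for the same reason — zero scatter — and are dropped with a
warning before fitting. Whether to log-transform counts first is left to
the user (`transform_log()`), as is any other pre-processing: loading
applies no normalization.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `m` | 50 | number of kernels; more kernels give a finer bandwidth ladder, with accuracy saturating for large `m` |
| `sigma_grid` | geometric, $10^{-2}$–$10^{2}$ | bandwidth multipliers; spans sub-range to super-range length scales as in multi-kernel practice |
| `alpha`, `beta` | 0.5 | keep $\delta$, $\rho$ on the scatter term's order of magnitude |
| `max_iter` | 100 | iteration cap; fits on the reference scenario converge in about 10 |
| `tol` | $10^{-6}$ | stop when both $\max\lvert\Delta W\rvert$ and $\max\lvert\Delta P\rvert$ fall below it |
| `scale_genes` | `TRUE` | per-gene standardization before fitting (see above) |

### Numerical choices

* Update order within an iteration: $\delta$ and $\rho$ from the previous
  iterate, then $W$, then $P$, then the objective. With $\delta, \rho$
  frozen this W-then-P sweep from the uniform initialization never
  increases $J$ (each update is the exact minimizer of its subproblem);
  the suite checks this numerically.
* The equality-constrained $W$ can leave the box; negative entries are
  clipped to zero and the vector renormalized, the standard projection
  heuristic in attribute-weighting clustering. The projection is reported
  via a message and can, on adversarial banks, cost the strict descent
  guarantee at later iterations — in practice the fit converges in a few
  iterations with $W$ near the simplex interior.
* Ranking ties break by input gene order (stable sort), so the fit is
  fully deterministic; no random numbers are drawn anywhere in it.
* Natural logarithms throughout; $0 \log 0 := 0$.

## The hub-gene ensemble

Rankings from two independent datasets are intersected at the top $k$
(`shared_genes()`, default $k = 200$, ordered by rank sum), the shared
genes' interaction subnetwork is loaded from an edge list, and every node
is scored by ten centrality measures: degree, maximal clique centrality
(MCC, $\sum (\lvert C\rvert - 1)!$ over maximal cliques, enumerated
exactly), maximum neighborhood component (MNC), closeness, BottleNeck,
eccentricity (as its reciprocal, so larger is central everywhere),
radiality, edge percolated component (EPC; seeded Monte-Carlo, 1000
trials, retain probability 0.5), betweenness and stress. Path-based
scores are computed per connected component; singleton components score 0.

The ensemble converts each method's scores to fractional ranks (ties
averaged) and averages them with uniform weights by default — ranks,
because the ten scales are incommensurable, which also makes the ensemble
invariant to monotone rescaling of any one method. The top 10 nodes are
reported as hub genes.

BottleNeck builds one BFS shortest-path tree per root with a deterministic
lowest-node-id parent rule and awards a point to any node whose proper
descendants exceed a quarter of the component. Determinism has a price:
on even cycles the antipodal vertex must attach to one of two equally
short branches, so the fixed tie rule is not label-symmetric there. The
other nine measures are exactly symmetric on vertex-transitive graphs.

## The wrapper

Gene subsets are evaluated classifier-in-the-loop. The default classifier
is kNN with $k = 5$, Euclidean distance, and fully deterministic ties
(equal distances resolve to the lower training index; vote ties to the
tied class seen earliest in the neighbor order). Evaluation modes:

* `repeated_cv()` — stratified 10-fold cross-validation repeated 10
  times, folds reshuffled each repeat from a seeded generator. Gene
  subsets are taken as given and never re-fit inside folds; this matches
  evaluating a pre-computed ranking and keeps the CV honest about the
  subset, though not about the ranking step itself.
* `best_prefix()` — nested prefixes top-1 … top-`max_k` of a ranking;
  linear in `max_k`, ties toward the smaller prefix.
* `exhaustive_search()` — all $2^g - 1$ subsets of at most 15 candidates,
  trained on one dataset and scored on an independent test set; ties
  toward smaller subsets, then lexicographic gene order.

Metrics: accuracy and Cohen's kappa for any number of classes;
sensitivity, specificity, F-score and the Matthews correlation
coefficient for binary problems, with the positive class defaulting to
the lexicographically larger label. Zero-denominator cases report 0 with
a warning. Per-gene differential expression uses the two-sample t-test
(Welch by default; pooled variance optional) at $p \le 0.05$ with no
multiplicity correction by default, Benjamini–Hochberg behind a flag.
Survival screening is an interface only: `filter_key_genes()` applies the
$p < 0.05$ log-rank rule to externally supplied p-values and orders the
survivors by p-value.

## What the synthetic generator does and does not emulate

`simulate_expression()` produces microarray-style continuous values:
Gaussian noise for every gene, plus class-specific mean offsets on a
planted subset, equally spaced so adjacent classes differ by
`effect_size * noise_sd`. The reference scenario — 60 samples, 500 genes,
20 informative, 2 balanced classes, effect size 2, unit noise — stands in
for a small two-class cohort study. A log-normal option adds RNA-seq-like
heavy tails. `simulate_graph()` plants a single high-degree hub in a
sparse Erdős–Rényi background (defaults: 100 nodes, hub degree 20, edge
probability 0.02).

The generator deliberately omits gene–gene correlation, batch effects,
heteroscedastic per-gene variances, dropout, and hub structure beyond a
single planted node. Passing the recovery tests therefore shows the
estimator does what its model says under its own assumptions — clean
separation of shifted-mean genes from null genes — not that it is robust
to correlated or batch-confounded real cohorts.

## Problem sizes used by the tests

The suite runs the update-rule oracle checks on 100 random instances
($p \le 6$, $m \le 4$) against a KKT quadratic-program solve and a damped
Newton entropy minimizer; the descent sweep on 100 random banks; gene
recovery on ten seeds of the reference scenario; the centrality oracles on
200 random connected graphs of up to 7 nodes against exhaustive path and
clique enumeration; and the planted-hub ensemble on ten graph seeds. These
sizes were chosen so each property is exercised well past its edge cases
while the whole suite stays interactive.

## Known limitations

* The objective sees only within-class compactness; standardization is
  what injects between-class information. Genes informative through
  variance differences rather than mean shifts rank poorly.
* $m = 50$ kernels on very wide matrices cost $m \times s \times p$
  kernel evaluations per fit; the bank is built once, so this is usually
  seconds, but memory is $O(mp)$.
* Maximal-clique enumeration is exponential in the worst case; the hub
  workflow targets networks of a few hundred nodes.
* The wrapper's exhaustive search is capped at 15 candidates by design;
  use the prefix search beyond that.
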