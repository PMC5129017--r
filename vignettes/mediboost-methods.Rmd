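---
title: "Boosting rewritten as a single interpretable tree: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boosting rewritten as a single interpretable tree: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Clinical decision making runs on decision trees: a stratification a
physician can read is a conjunction of if–then conditions on a handful of
measurements. Greedy tree inducers (CART, ID3) produce exactly that object
but are consistently out-performed by ensembles — boosted stumps, random
forests — which are not readable. This package implements a family of tree
inducers that keep the tree form while borrowing the accuracy mechanism of
boosting.

The starting observation is that an additive ensemble of $T$ decision
stumps,

$$ H(x) = \operatorname{sign}\Big(\sum_{t=1}^{T} \alpha_t h_t(x)\Big),
   \qquad h_t(x) = \begin{cases} s^L_t & x_{j_t} \le \theta_t \\
                                 s^R_t & \text{otherwise}, \end{cases} $$

can be rewritten *exactly* as a depth-$T$ binary tree: give every level of
the tree the stump $h_t$, route left on $x_{j_t} \le \theta_t$, and let each
branch carry the constant contribution of its side. A root-to-leaf path then
accumulates the path score

$$ G = \sum_{t=1}^{T} \nu\, \alpha_t\, s_t^{(b_t)}, $$

whose sign is the ensemble's prediction for every $x$ routed to that leaf.
The tree has up to $2^T$ leaves, but two mechanisms shrink it drastically:
conjunctions of thresholds with empty feasible regions ("impossible paths")
never need to be built, and any subtree whose leaves all agree can be
collapsed after training without changing a single prediction.

## Growth with a membership function

A literal rewriting refits the *same* stump everywhere at depth $t$. The
algorithms here interpolate between that and classical recursive
partitioning through a per-instance **membership** $m_i \ge 0$. Growth
starts at the root with $m_i = 1$, working score $F_i = 0$ and path score
$G = 0$, and recurses:

1. fit a stump to the whole training set under weights that combine
   boosting emphasis with membership;
2. update every instance's working score with its own stump output,
   $F_i \leftarrow F_i + \nu\,\delta(x_i)$;
3. descend into each branch $b$ with $G_b = G + \nu\,\delta_b$, and damp the
   membership of instances routed *against* the branch:
   $m_i \leftarrow m_i e^{-\gamma}$.

The **acceleration parameter** $\gamma \ge 0$ is the interpolation knob. At
$\gamma = 0$ membership never decays, every node at a given depth sees the
same problem, and the tree is literally the rewritten ensemble (this
equivalence is asserted exactly in the test suite, against independently
coded AdaBoost and gradient-boosting references). As
$\gamma \to \infty$ off-branch instances vanish, recovering hard recursive
partitioning; the suite checks that $\gamma = 30$ reproduces, node for node,
a reference grower that drops off-branch instances outright. In between,
off-branch instances act as a soft prior that regularises deep nodes, which
is why training error falls and trees shrink as $\gamma$ grows while test
error stays flat — a property asserted (within a 0.01 band averaged over ten
simulated data sets) for both engines.

Two engines share this recursion:

* **MAB** (exponential loss). Node weights are
  $w_i \propto m_i e^{-y_i F_i}$; the stump minimises the weighted 0/1
  error $\varepsilon$ over all features, midpoint thresholds and both
  polarities; its coefficient is
  $\alpha = \tfrac12 \log\{(1-\varepsilon')/\varepsilon'\}$ with
  $\varepsilon'$ clipped to $[\varepsilon_{\min}, 1-\varepsilon_{\min}]$.
  Branches stop when $\alpha \le 0$ (no weak-learnable structure remains).
* **LMB** (binomial log-likelihood, usually the more accurate). With loss
  $\log(1 + e^{-2yF})$ the pseudo-residuals are
  $r_i = 2y_i/(1 + e^{2 y_i F_i}) \in (-2, 2)$; the stump minimises the
  membership-weighted squared error to $r$; each side gets one Newton step
  $$ c = \frac{\sum m_i r_i}{\sum m_i |r_i| (2 - |r_i|) + \lambda}, $$
  whose denominator is the weighted second derivative $4p(1-p)$ plus a
  ridge term $\lambda$.

A leaf predicts $\operatorname{sign}(G)$; $|G|$ is kept as a real-valued
margin and is what AUC computations rank by (hard labels would make AUC
degenerate).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `depth` | 15 | boosting rounds per path; the unpruned tree has up to $2^{\text{depth}}$ leaves. The default suits a grow-deep-then-prune workflow; tuned fits typically use 2–6. |
| `gamma` | 2 | membership decay per off-branch step (dimensionless, in $e^{-\gamma}$); 0 = pure ensemble, $\gtrsim 30$ = hard partition. |
| `learning_rate` | 0.1 | shrinkage $\nu$ on every additive update. |
| `lambda` | 0 | ridge penalty in the Newton denominator (LMB). |
| `eps_min` | $10^{-6}$ | clipping floor for stump errors before $\alpha$. |
| `min_membership` | $10^{-4}$ | a branch stops once $\sum_i m_i / n$ falls below this; at large $\gamma$ this is what terminates empty branches. |

`depth` and `gamma` are the two parameters worth tuning, which
`tune_nested()` does by inner stratified 5-fold cross-validation on the
balanced error, breaking ties towards the smaller depth and then the
smaller `gamma` (the more interpretable model).

## Numerical choices

* **Routing ties.** `x <= threshold` goes left, everywhere (growth,
  prediction, serialised models). Feasible regions are half-open intervals
  `(lo, hi]`.
* **Candidate thresholds** are midpoints between consecutive distinct
  values, a standard CART convention. Candidates are proposed only by
  instances whose weight exceeds `max(w) * 1e-9`; all instances still score
  every candidate. The cutoff makes the hard-partition limit exact instead
  of perturbed by $e^{-30}$-sized weights.
* **Split ties.** The chosen split is the first candidate in canonical
  order (feature index, then threshold, then negative-left polarity) whose
  objective lies within a relative $10^{-10}$ of the optimum. Exact ties
  are common (integer error counts under uniform weights), and a
  tolerance-free argmin would resolve them by last-ulp rounding noise;
  the tolerance makes trees reproducible bit-for-bit.
* **Impossible paths.** The split search itself is unconstrained by the
  path's feasible region; if the best stump's threshold falls outside the
  region, one branch would be infeasible, so no internal node is recorded —
  the stump's contribution on the surviving side is folded into $F$ and $G$
  and growth continues (the round still counts towards `depth`). This is
  what makes the $\gamma = 0$ tree replay the ensemble exactly even when a
  later round reuses an ancestor's feature, while every *recorded*
  threshold still lies strictly inside its path's feasible interval.
* **Leaf ties.** $|G| \le 10^{-10}$ counts as a zero path score and takes
  the tie label (the training majority class, `+1` under exact balance).
  Without the floor, an overwhelming ridge penalty ($\lambda = 10^{12}$)
  would leave sign noise of order $10^{-11}$ in the leaves instead of the
  tie label.
* **Overflow.** Boosting weights are computed on the log scale;
  pseudo-residuals go through `plogis()`, so $|F| \sim 10^4$ is safe.
* **Stopping.** A branch becomes a leaf at `depth` rounds, when no feasible
  split exists, when $\alpha \le 0$ (MAB), when both Newton coefficients
  are below $10^{-12}$ in magnitude (LMB), or when mean membership drops
  below `min_membership`.

## Pruning

`prune_sign()` collapses, bottom-up to a fixpoint, every internal node whose
descendant leaves carry the same label. Predictions are provably unchanged;
the merged leaf keeps the common label and the largest $|G|$ among the
merged leaves (signed by the label) so that score rankings inside the merged
region are preserved. The operation is idempotent and never increases the
leaf count. On depth-8 likelihood trees over the four-region generator it
typically removes well over half of the leaves; the acceptance script
recomputes the exact figure.

## Evaluation protocol

The harness mirrors the evaluation design the method was published with:

* **balanced error** $1 - (\text{sens} + \text{spec})/2$ on every held-out
  fold, so class imbalance cannot flatter a constant classifier;
* **AUC** in the Mann–Whitney form with ties counted one half, computed
  from mid-ranks (and checked against $O(n^2)$ pair counting in the tests);
* **5 trials of stratified 5-fold cross-validation** (25 fold results),
  with imputation statistics re-fitted on each training portion so nothing
  leaks from test folds;
* **nested tuning**: an additional stratified 5-fold loop on each training
  portion over a (depth, gamma) grid;
* **permutation test**: labels permuted $B = 100$ times, the whole CV
  protocol re-run on each copy, and
  $\hat p = (1 + \#\{\text{AUC}_\text{perm} \ge \text{AUC}_\text{obs}\})/(B+1)$.
  The add-one estimator is a valid p-value under the null and differs from
  the raw frequency by at most $1/101$; the smallest attainable value is
  $1/101 \approx 0.0099$.
* **comparison harness**: per-dataset mean balanced error and AUC per
  learner, pairwise win/loss/tie counts (differences under $10^{-10}$ are
  ties) and a two-sided sign test.

## Synthetic data: what it does and does not show

`sim_four_region()` draws $x$ uniformly on the unit square and labels it
with a fixed depth-2 tree — split $x_1$ at 0.5, then $x_2$ at 0.3 (left)
and 0.7 (right) — flipping each label with probability `flip_noise`. The
label assignment is deliberately checkerboard-like: left of $x_1 = 0.5$ the
positive region is $x_2 \le 0.3$, right of it $x_2 > 0.7$, so the $x_1$
marginal is uninformative and the classes form a true interaction. A
depth-2 tree that reproduces the labels exists by construction, but *no*
impurity- or residual-driven grower can find it greedily from the root
(an $x_2$ split always has more marginal gain), which makes the fixture a
useful stress test: the likelihood engine first reaches zero training error
at depth 6 with the default learning rate. This is also why the tuning
grids used in the tests and the acceptance script extend to depth 6 — a
shallower grid would handicap the boosted trees structurally rather than
measure their accuracy.

`sim_additive_logistic()` draws $x$ uniform on $[0,1]^d$ and labels with
$P(y\!=\!+1\,|\,x) = \operatorname{logistic}\{\sum_j \beta_j
\operatorname{sign}(x_j - t_j)\}$, so the Bayes rule is itself an additive
stump ensemble — the model class the engines assume. Defaults
($\beta_j = 2 \cdot 0.75^{\,j-1}$, $t_j = 0.5$) give a few informative
features of decaying strength; the exact Bayes error is attached by
enumerating the $2^d$ sign patterns. With $\beta = 0$ the generator yields
pure label noise, the null configuration used to calibrate the permutation
test.

Problem sizes in the tests and the acceptance script (n of 150–400,
$d \le 6$, depths up to 8, ten seeds per experiment) were chosen as the
smallest at which the asserted properties are stable across seeds; they
exercise every code path at desk scale. What passing them shows is that the
implementation is faithful to the model — exact ensemble equivalence, exact
hard-partition limit, lossless pruning, calibrated permutation p-values.
What they cannot show is performance on real clinical tables, whose
correlated features, informative missingness and non-uniform marginals none
of the generators emulate; the missingness generator in particular is MCAR
by design, and mean/mode imputation with indicator columns is the only
missing-data strategy implemented.

## Design choices where the design was open

* **Preprocessing.** Categorical columns are one-hot expanded *after* mode
  imputation so the stump search only ever sees numeric thresholds;
  imputation statistics are computed per training fold in the CV harness.
  Indicator columns are appended one per original feature regardless of
  expansion.
* **MAB working score.** The per-instance score uses the instance's own
  stump output while the path constant uses the branch constant; this is
  the unique combination under which the $\gamma = 0$ tree is literally
  the rewritten ensemble. The learning rate enters both identically, and
  the node weights use the shrunk score — so with $\nu \ne 1$ the stump
  *sequence* (not just its scale) depends on $\nu$ beyond the first round.
* **Positive class.** The larger label value (numeric or alphabetical) is
  positive unless overridden, and the mapping is stored in the model and
  its JSON form.
* **Pruned-leaf scores.** Merged leaves keep the maximal $|G|$; an
  alternative (membership-weighted average) would also preserve labels but
  not the within-region ranking.
* **Baseline for comparisons.** `learner_greedy_tree()` is CART via
  `rpart` with the complexity penalty and minimum node sizes switched off,
  i.e. a pure depth-limited greedy partitioner — the hard-partition
  counterpart of a depth-limited boosted tree, with depth as its only
  capacity control.

## Limitations

Binary classification only — no multi-class, regression or survival
variants; axis-aligned stumps only, so interactions are represented through
depth and acceleration rather than within a node; no surrogate splits
(missingness is handled by imputation plus indicators); deep unpruned trees
are exponential objects — `depth = 15` with small `gamma` can allocate tens
of thousands of nodes, so deep growth is best paired with larger `gamma`
and pruning. The permutation test re-runs the full CV protocol per
permutation and is the most expensive operation in the package.
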