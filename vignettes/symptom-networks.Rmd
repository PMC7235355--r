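---
title: "Estimating and interpreting symptom networks with symptomnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and interpreting symptom networks with symptomnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symptomnet)
```

## The model

symptomnet analyzes item-level questionnaire data as a **Gaussian graphical
model** (GGM): each item is a node, and an edge between two items is their
*partial correlation* — the association that remains after conditioning on
every other item. If $\Theta = \Sigma^{-1}$ is the precision matrix of the
latent multivariate-normal trait vector, the edge weights are

$$ w_{ij} = -\frac{\Theta_{ij}}{\sqrt{\Theta_{ii}\,\Theta_{jj}}}, $$

so a zero in $\Theta$ means conditional independence. Because a saturated
GGM on $p$ items has $p(p-1)/2$ free edges, the precision matrix is
estimated with the **graphical lasso**: maximize

$$ \log\det\Theta - \operatorname{tr}(S\Theta) - \lambda \sum_{i \ne j} |\Theta_{ij}| $$

over positive-definite $\Theta$, where $S$ is the item correlation matrix.
The $\ell_1$ penalty sets small partial correlations exactly to zero,
keeping only associations strong enough to survive shrinkage. The diagonal
is unpenalized.

The penalty level is chosen by the **extended Bayesian information
criterion** (EBIC) over a descending path of 100 log-spaced penalties from
$\lambda_{\max}$ (the smallest penalty giving an empty graph) down to
$\lambda_{\max}/100$:

$$ \mathrm{EBIC}_\gamma = -n\,(\log\det\Theta - \operatorname{tr}(S\Theta))
   + E \log n + 4 E \gamma \log p, $$

with $E$ the number of edges. The hyperparameter $\gamma$ is conventionally
set between 0 and 0.5; larger values yield sparser models. The package
default is $\gamma = 0.25$. A **fixed-penalty mode**
(`estimate_network(..., lambda = 0.25)`) is also provided for analyses that
set the tuning parameter a priori rather than selecting it; the run report
records which mode was used via `selected_lambda` and `lambda_path`.

### Ordinal items and correlations

Questionnaire responses are ordinal (here, a seven-point 0–6 frequency
scale and a four-point 1–4 agreement scale). The default correlation is
**Spearman**: it is invariant to the unknown monotone link between the
latent trait and the response categories, deterministic, and dependency
light. Pearson is available by flag. Polychoric correlations are a
reasonable alternative that this package deliberately does not implement.
Missing cells are handled pairwise-complete, mirroring the practice of
retaining respondents with a handful of missing answers; if pairwise
deletion leaves the matrix indefinite it is projected to the nearest
correlation matrix by eigenvalue clipping at $10^{-8}$ (with a warning).
Reverse-coded items are flipped at load time from the scale metadata —
never inferred from the data — so that higher always means more symptoms.

## Redundant-item screening

Networks assume each node measures a distinct construct, but questionnaires
often contain near-duplicate items. `find_bad_pairs()` implements the
dependent overlapping-correlations screen: for a candidate pair (A, B) and
every third item C, it tests $H_0: \rho_{AC} = \rho_{BC}$ with the
back-transformed-average Fisher-z test for two dependent correlations
sharing one variable. If fewer than $1 -$ `share_threshold` (default: 25%)
of those comparisons are significant at `p_threshold` (default 0.05), the
two items' correlation profiles are statistically indistinguishable and the
pair is flagged redundant. `reduce_nodes()` then removes one member per
pair — the one in the most flagged pairs, breaking ties toward keeping the
item with more total correlation, then lexicographically.

Two details matter in small samples:

* **The multicollinearity gate.** Only pairs with zero-order
  $|r| \ge$ `min_correlation` (default 0.5) are candidates. The profile
  test asks "could these two items measure the same construct?", which is
  only a sensible question for strongly correlated items. Without the gate
  the procedure degenerates: any two items with *equally unrelated*
  profiles — including perfectly independent ones — are "indistinguishable"
  and would be flagged, and at $n \approx 100$ the comparisons have so
  little power that most pairs are. Setting `min_correlation = 0` recovers
  the ungated behavior.
* **Degenerate correlations.** The covariance term of the test is an
  approximation that can stray above 1 for extreme inputs; it is clipped
  just below 1, where the test correctly reports any real profile
  difference as overwhelming. Literal duplicate columns (profile
  correlations of exactly $\pm 1$) are nudged inside the Fisher-transformable
  range during screening.

## Centrality and bridge centrality

Interpretation uses **expected influence** rather than strength, because
edges can be negative:

* $EI_1(i) = \sum_j w_{ij}$ — one-step expected influence;
* $EI_2(i) = EI_1(i) + \sum_j w_{ij}\, EI_1(j)$ — two-step, adding each
  neighbor's own influence weighted by the connecting edge.

With items partitioned into two communities (the two instruments), the
**bridge** variants restrict the one-step sum to cross-community edges:
$BEI_1(i) = \sum_{c(j) \ne c(i)} w_{ij}$, and
$BEI_2(i) = BEI_1(i) + \sum_{j \ne i} w_{ij}\, BEI_1(j)$. Bridge nodes are
symptoms that connect the two disorders' clusters. Two conventions are
worth stating because the two-step definition admits variants: the
neighbor's influence includes its edge back to $i$ (no back-edge
exclusion), and z-scores — the reported scale — are computed within each
metric across all nodes, with the exact decomposition
$EI_1 = BEI_1 + \text{within-community } EI_1$ holding for every node and
any labeling. The decomposition and both brute-force summation oracles are
asserted in the test suite.

## Bootstrap accuracy and stability

* `nonparametric_bootstrap()` resamples respondents with replacement,
  re-runs the full estimator, and reports per-edge 95% percentile intervals
  whose endpoints are order statistics of the stored draws. The item set is
  reduced **once** on the full sample and held fixed across replicates —
  re-running item selection inside replicates would change the node set and
  make statistic vectors non-comparable.
* `case_dropping_bootstrap()` re-estimates on subsets containing
  $1 - \ell$ of the respondents for drop levels
  $\ell \in \{0.1, \dots, 0.9\}$ and correlates each subset's statistic
  vector (expected influence, bridge expected influence, or edge weights)
  with the full-sample vector. The **correlation-stability (CS)
  coefficient** is the largest tested $\ell$ at which that correlation
  stays $\ge 0.7$ with probability $\ge 0.95$. The guideline for
  interpretation: below 0.25 the statistic should not be interpreted;
  above 0.5 is preferable. Replicates whose subset statistic is constant
  (typically an empty re-estimated network) count *against* the stability
  probability — an empty re-estimate is evidence of instability, not
  missing data. Levels whose subsets would fall below $p/2$ respondents are
  skipped with a warning.
* `difference_test()` compares two edges or two nodes' centralities via the
  percentile interval of their paired bootstrap difference at
  $\alpha = 0.05$; at the degenerate boundary $\alpha = 1$ the interval
  collapses to the median and any nonzero median difference is "significant"
  (documented for completeness, not for use).

Every resampling function derives one sub-seed per replicate from its
master seed, so results are bit-reproducible and independent of execution
order. Default replicate counts are $B = 1000$ (both per-level and for the
edge bootstrap); the examples and the acceptance script scale down to
$B = 200$, which the stability literature treats as adequate for CS
estimation and which keeps a full study-scale run around a minute in
fixed-penalty mode.

## The synthetic-data generator

No participant data ship with the package; every pipeline stage is
validated against a generator with known ground truth
(`synthetic_spec()` / `simulate_study_data()`):

1. **Structure.** A sparse precision matrix with two diagonal blocks
   (within-community edges at `within_density`) and `n_bridge_edges`
   planted cross-community edges. Magnitudes are uniform in `weight_range`;
   signs are negative with probability `prob_negative` (default for the
   study preset: 0.1, since symptom items keyed in the same direction are
   predominantly positively associated — random signs would cancel the
   marginal-correlation structure real questionnaires show). Positive
   definiteness is enforced by a Gershgorin budget — edges are rescaled so
   each node's total absolute off-diagonal mass stays below 0.9 — with
   uniform diagonal loading only as a backstop. The budget preserves strong
   edges on low-degree nodes (the near-duplicate-item phenomenon), which
   uniform loading would flatten; neither step changes a planted sign.
2. **Responses.** $n$ latent Gaussian vectors with covariance
   $\Theta^{-1}$, discretized per item through normal-quantile thresholds
   (equal-probability by default; `threshold_skew > 0` piles mass on low
   categories, the floor effect typical of symptom inventories).
3. **Perturbations.** `n_redundant_pairs` near-duplicate items (latent copy
   plus Gaussian noise, re-discretized), `n_reverse_coded` items stored in
   reversed orientation with the metadata flag set, and
   missing-completely-at-random cells at `missing_rate`.

The defaults (20 + 20 items, $n = 2000$, magnitudes 0.2–0.4) define the
reference fixture at which the estimator's operating characteristics are
measured: edge sensitivity $\ge 0.8$, specificity $\ge 0.9$, and perfect
sign agreement on recovered edges across seeds. Bridge detection is scored
by whether a planted bridge node reaches the top 3 by $|BEI_1|$ — magnitude
rather than signed value, because a planted *negative* bridge edge makes
its endpoints the most negative entries while bridging the communities all
the same.

`study_like_spec()` emulates the shape of a two-questionnaire clinical
study: 22 seven-point items plus 65 four-point items (including two planted
near-duplicate pairs per instrument, so reduction is exercised), $n = 101$,
one reverse-coded item in the second community, missing rate 0.08%.

### What the stand-in does and does not show

The generator is a structural stand-in, not a calibrated emulation of any
real instrument pair. One consequence is worth understanding before
interpreting study-scale runs. With $n = 101$ and $p \approx 80$, an edge
survives EBIC selection only if its likelihood gain exceeds
$\log n + 4\gamma\log p \approx 9$ nats — after lasso shrinkage, roughly an
empirical partial correlation of 0.5. But in sparse latent-GGM data, any
pair that strong has a zero-order correlation above the redundancy gate and
a correlation profile the small-sample screen cannot tell apart, so item
selection removes one member first. The two stages together leave the
EBIC-selected network empty or nearly so at this scale. Real questionnaire
data escape the pincer because their correlation profiles are dense and
differentiated in a way a sparse random GGM is not. For this reason the
package's study-scale demonstration runs the estimator in fixed-penalty
mode ($\lambda = 0.25$), which exercises every downstream stage on a
non-degenerate network; EBIC-$\gamma$ selection remains the default for
data analysis, and its operating characteristics are demonstrated at the
reference scale, where they are excellent. Passing tests therefore show
that the machinery is correct and stable under known ground truth — not
that a particular clinical dataset's network is recoverable at $n = 101$.

## Numerical choices

* **Solver.** Block coordinate descent over columns of the working
  covariance (the standard graphical-lasso scheme), in C++. Column
  subproblems exit on their own KKT residual, with an exact active-set
  Cholesky solve as a fallback where coordinate descent grinds.
  Convergence of the full problem is declared only when the KKT conditions
  hold for the *exact inverse of the recovered precision matrix* —
  $|\Sigma_{ij} - S_{ij}| \le \lambda$ on zero entries and
  $\Sigma_{ij} - S_{ij} = \lambda\,\mathrm{sign}(\Theta_{ij})$ on edges,
  to tolerance `tol` $= 10^{-4}$ — not when a surrogate stops changing.
  The working covariance alone satisfies per-column stationarity by
  construction, so certifying on it would be vacuous; the certificate is
  re-derived every outer cycle and an adaptive per-column slack tightens
  whenever the certified residual stalls.
* **Paths.** 100 points, `min_ratio` 0.01, warm-started downward. A fit of
  the full path at $p \approx 83$, $n = 101$ takes well under a second,
  which is what makes $10^3$-replicate bootstraps practical.
* **Degenerate inputs.** Zero-variance items, insufficient pairwise
  overlap, non-positive-definite inputs at zero penalty, unlabeled nodes,
  and constant statistic vectors are all explicit errors or counted
  exclusions rather than silent propagation.
* **Problem sizes in the checks.** The test suite validates calibration of
  the redundancy test at $n = 101$ with $10^4$ replicates, recovery on ten
  seeds of the reference fixture, stability monotonicity across
  $n \in \{100, 400, 1600\}$ at $B = 200$, and byte-identical reruns of the
  full study-scale pipeline at $B = 200$ — sizes chosen so the full suite
  exercises every claim at meaningful scale.

## Limitations

* Polychoric correlations, nonparanormal transforms, and mixed graphical
  models are out of scope; Spearman input is a pragmatic, monotone-invariant
  default, slightly attenuated relative to latent correlations for
  few-category items.
* The redundancy screen's power at $n \approx 100$ is low; its false-flag
  behavior on genuinely connected strong pairs is a property of the method,
  not of this implementation, and is why removal decisions are logged in
  full.
* CS coefficients and centrality orderings from any single small-sample run
  carry the uncertainty the bootstrap itself reveals; the package reports
  that uncertainty rather than hiding it.
* No graphical layout/plotting: exports (edge list, adjacency, GraphML with
  community and sign attributes) are meant for dedicated graph tools.
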