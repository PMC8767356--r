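---
title: "Methods: cost-sensitive gain-ratio trees for fitness-test cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cost-sensitive gain-ratio trees for fitness-test cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fittree)
```

## The problem

National student fitness testing scores each student's body mass index (BMI)
against grade- and gender-specific bands (low weight / normal / overweight /
obesity, worth 80 / 100 / 80 / 60 points) and analyses the resulting records
with decision trees. Classes are imbalanced — obesity is rare — and errors
are not exchangeable: missing a student in the high-stakes band costs more
than misbanding one near the centre of the distribution. `fittree`
implements the standard gain-ratio tree, a cost-weighted variant of the same
criterion, the scoring standard, a synthetic cohort generator, and a
cost-stratified evaluation report.

## The split criterion and its cost-weighted variant

The standard criterion is classical C4.5: entropy in bits
($I = -\sum_i p_i \log_2 p_i$, with $0 \log_2 0 = 0$), size-weighted
conditional entropy over the subsets of a split, information gain, and gain
divided by the split information (the entropy of the subset sizes).

The cost-sensitive variant changes only the probabilities. A cost matrix
$cost(i,j) \ge 0$ (diagonal fixed at 0) yields row sums
$C(i) = \sum_j cost(i,j)$ and class weights

$$w(i) = \frac{C(i)\,n}{\sum_k C(k)\,n_k},$$

normalized so $\sum_i w(i) n_i = n$; probabilities become
$p_i = w_i n_i / \sum_k w_k n_k$ at the node and $p_{ij}$ analogously inside
each subset. Design choices made where the formulation left room:

- **Weight mass.** The per-class mass $W_i$ entering the weighted
  probabilities is taken as $W_i = w_i n_i$, the reading under which the two
  published forms of the weighted probability coincide.
- **Split information stays unweighted.** It is defined over subset *sizes*
  only, so cost weighting does not touch it. A consequence worth knowing:
  only the numerator of the gain ratio is cost-aware.
- **Weights are fixed at the root.** $w(i)$ is computed once from the full
  training distribution and held constant down the tree, so a node's
  criterion reflects global class costs rather than drifting with local
  class frequencies. (Recomputing per node would make the uniform-cost
  reduction hold node-wise too, but makes weights of empty classes
  undefined; the root convention avoids that degeneracy.)
- **Leaf labels** are the class of maximum *weighted* probability, which is
  where cost sensitivity acts on impure leaves.
- **Uniform reduction.** With all off-diagonal costs equal, $w(i) \equiv 1$
  and criterion, chosen splits, and the grown tree are identical to the
  standard path; this is enforced by property tests and an acceptance
  criterion, and is why the default off-diagonal cost is 1.

## Tree induction

- **Continuous splits** test $x \le t$ (left branch; a record exactly at the
  threshold goes left, matching the "$\le$" convention of the printed band
  table). Candidate thresholds are midpoints between consecutive distinct
  values, kept only where the adjacent value-groups differ in class
  (boundary-point reduction — interior midpoints of a one-class run cannot
  improve an entropy criterion).
- **Categorical splits** branch on every value observed at the node. At
  prediction time an unseen value is routed to the node's majority branch
  with a warning; a missing tested attribute is an error (no surrogate
  splits, no fractional instances — records with missing declared columns
  are rejected before training).
- **Zero-gain splits are allowed.** Greedy positive-gain search cannot start
  on XOR-style structure, and a fully grown tree is required to fit any
  label-consistent dataset exactly; termination is still guaranteed because
  every branch is non-empty and strictly smaller. Candidates with vanishing
  split information (all mass on one side) are rejected outright.
- **Stopping**: purity, `min_samples_to_split` (default 2), `max_depth`
  (default unlimited). **No pruning** is implemented, deliberately: the
  method being reproduced does not prune, and the evaluation compares two
  unpruned arms.
- **Determinism**: criterion ties within `tie_tol = 1e-9` are resolved by
  attribute declaration order, then by the smaller threshold; identical
  inputs give byte-identical serialized trees.

Trees serialize to a versioned JSON document (`fittree-1`); loading
validates the schema and names the offending path on corruption.

## The scoring standard

The shipped standard (`inst/extdata/bmi_standard.json`) transcribes the
national BMI band table: exactly four strata — male bands for freshman
(13.4 / 18.1 / 20.3), sophomore (13.6 / 18.4 / 20.4) and junior
(17.8 / 23.9 / 27.9), female bands for senior (17.1 / 23.9 / 27.9) — each
with scores 80 / 100 / 80 / 60. Two decisions:

- **One-decimal resolution.** The printed bands leave one-decimal gaps
  (e.g. 20.3 next to ≥ 20.4), so values are rounded to one decimal before
  lookup; validation then proves the bands cover the whole axis with no
  overlap, and an exhaustive scan over 5.0–60.0 in 0.1 steps is part of the
  test suite.
- **No invented strata.** The table prints only one gender per grade; the
  default standard defines exactly those four keys, and scoring any other
  stratum fails loudly ("no standard for stratum"). Whether the same bands
  apply to the unlisted gender is unstated, so it is not assumed here.

Vital capacity scoring is supported by the same configurable band-table
schema, but no default bands ship because none are published.

## The synthetic cohort generator

The generator emulates the *structure* of the study population — a
four-grade, two-gender university cohort split into tested and untested
groups with tested boys > tested girls > untested boys > untested girls —
not its numbers, which were never published machine-readably. Defaults,
chosen once:

- **Stratum proportions** 0.40 / 0.30 / 0.18 / 0.12 across gender × tested,
  uniform over grades: a synthetic mimicry of the published ordering only.
- **BMI** per grade from a truncated normal centred in the "normal" band
  (freshman 16.0 ± 2.6 on [8, 30], sophomore 16.2 ± 2.6, junior 21.5 ± 3.6
  on [10, 40], senior 21.0 ± 3.6), recorded at one decimal like test-entry
  forms. These means and spreads put roughly 5% of records in the obesity
  band, giving the class imbalance the cost-sensitive comparison needs.
  Height is drawn per gender (1.72/1.61 ± 0.06 m) and weight back-computed
  from BMI, so records are physically coherent; vital capacity is drawn per
  gender (3600/2700 ± 500 mL) and carried along untouched.
- **Labels** are the BMI band of the record under a *synthetic* standard
  that applies each grade's printed bands to both genders
  (`synthetic_bmi_standard()`) — the generator must label every stratum,
  while the shipped scoring standard deliberately keeps only the printed
  four. The band class is the default target; a binary relabelling can be
  applied downstream if a pass/fail target is wanted.
- **Label noise** flips a label to a uniformly chosen other band with
  probability 0.05 by default — a realistic entry/measurement error rate;
  recovery tests set it to 0 explicitly.
- **Reproducibility**: everything is drawn under the config seed (the
  caller's RNG state is restored), and the written CSV + manifest are
  byte-identical across runs.

What a green test on this generator does **not** establish: agreement with
the original study cohort (unavailable), realistic BMI–vital-capacity
correlation (none is modelled), or the published population percentages
(figure values were not machine-readable and are deliberately not imitated).

## Cost-stratified evaluation

The published comparison reports total / high-cost / general-cost / low-cost
error rates for a "newly built" and an "adjusted" model, without defining
the strata. Interpretations adopted, prominently recorded:

- **Strata** group *classes* by their row-sum cost $C(i)$: the distinct
  $C(i)$ values are ranked and spread evenly over low / general / high
  (all-equal costs put every class in "general", whose rate then equals the
  total rate). An explicit class→stratum mapping can override the default.
  A stratum's error rate is the misclassification rate among records whose
  true class lies in it, so the stratum rates weighted by stratum sizes
  recover the total rate exactly.
- **Arms**: "newly built" = standard criterion, "adjusted" = cost-weighted
  criterion; the "error value" is newly built − adjusted, sign preserved
  (negative means the adjusted model is worse there — expected on the
  low-cost stratum, which it sacrifices).
- **Split**: seeded stratified random modeling/test split, default 70/30.
- Rates are computed exactly and only rounded to two decimals for display.

## Numerical conventions and limitations

- Entropies in bits (log base 2); $0\log 0 = 0$; criterion tie tolerance
  1e−9; split-information guard 1e−12; band-bound comparisons use a 1e−9
  cushion after one-decimal rounding.
- The inducer is quadratic-ish in records per attribute at each node
  (thresholds × tabulation); fine for cohort-scale data (10⁴ records), not
  tuned for millions.
- No pruning, ensembles, surrogate splits, Gini/misclassification
  impurities, ROC/AUC, or significance tests on rate differences — all out
  of scope by design.
- Acceptance-grade empirical behaviour (threshold recovery on noiseless
  cohorts; the high-cost error rate dropping in a majority of 50 seeded
  replicates while the low-cost rate may rise) is computed by the test
  suite itself; no result is asserted here that the tests do not compute.
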