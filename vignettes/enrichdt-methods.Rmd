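---
title: "Methods: classifying disease genes from network-neighborhood enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying disease genes from network-neighborhood enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enrichdt)
```

## The problem

Given a set of genes known to be associated with a disease (for example, a
disease-gene catalog entry for a cancer) and the bulk of other protein-coding
genes as the contrast class, which *functional annotations* — GO biological
processes, cellular components, molecular functions, and pathway memberships —
distinguish the two groups? `enrichdt` answers this by classifying genes from
functional-enrichment features of their interaction-network neighborhoods,
then reading the discriminative annotations and quantitative decision rules
off the model.

The pipeline has five stages:

1. **Featurize** — encode every gene as a vector of neighborhood enrichment
   scores, one per annotation term.
2. **Filter** — keep all-relevant features with the Boruta shadow-feature
   algorithm.
3. **Rank** — order surviving features by max-relevance/min-redundancy (mRMR)
   mutual information.
4. **Select** — incremental feature selection (IFS): sweep nested prefixes of
   the ranking with a SMOTE-balanced CART decision tree under stratified
   10-fold cross-validation and keep the prefix with the best F1.
5. **Explain** — refit the tree on all samples with the chosen features and
   extract mutually exclusive, exhaustive IF–THEN rules.

## Feature encoding

For a gene $g$, let $G$ be the set of its direct interaction partners (the
gene itself excluded; `include_self` reverses this for sensitivity analysis).
For an annotation term with gene set of size $M$ in a universe of $N$ genes,
with $n = |G|$ and $m = |G \cap \text{term}|$, the feature value is

$$\mathrm{ES}(g, \text{term}) = -\log_{10} \; P(X \ge m), \qquad
X \sim \mathrm{Hypergeom}(N, M, n),$$

the upper tail being $\sum_{k=m}^{\min(n,M)} \binom{M}{k}\binom{N-M}{n-k} /
\binom{N}{n}$. The sum's upper limit is clamped to $\min(n, M)$; terms beyond
$M$ successes are identically zero, so the clamp changes nothing
mathematically but keeps the routine defined. Numerically the tail is
evaluated through the hypergeometric survival function on the log scale, so
deep tails do not underflow; scores are capped at 300 (a p-value of
$10^{-300}$, near the double-precision floor) and an exactly underflowed
p-value of 0 maps to the cap. Genes with no neighbors get an all-zero row —
they carry no neighborhood information, and zero is the "no enrichment"
value. $N$ is always the size of the loaded universe, never a hard-coded
human gene count. No term-size filter and no score threshold are applied by
default; both are configurable (`min_score` follows the STRING 0–1000 score
convention).

The column order of the matrix is the catalog order — GO namespaces first,
pathways last — and is part of the contract: every downstream stage refers to
features by these ids.

## Boruta filtering

Boruta asks, for each feature, whether it carries *any* information about the
label beyond what an uninformative feature of the same marginal distribution
would. Each iteration appends one freshly permuted "shadow" copy per feature,
fits a random forest (500 trees, impurity importance, class-balanced weights
so the minority disease class is not ignored), and scores a *hit* for every
real feature whose importance exceeds the maximum shadow importance
(`percentile = 100`; lower percentiles relax the reference). Hits across
iterations feed a two-sided binomial test with hit probability 0.5,
Bonferroni-corrected over the still-undecided features: significantly many
hits confirms a feature, significantly few rejects and drops it.

Two design choices depart from the textbook loop, both forced by calibration:

* **Per-iteration subsampling.** The binomial hit model treats iterations as
  independent replicates. If every iteration reuses the full fixed dataset,
  they are not: the noise feature whose chance association with the label
  happens to be the strongest realized in the data beats the freshly drawn
  shadows round after round — its importance is a fixed upper-tail draw while
  the max-shadow reference is redrawn — and the test happily "confirms" pure
  noise. Each iteration therefore runs on a fresh 50% stratified subsample
  drawn *without* replacement (`subsample = 0.5`), so the chance association
  itself is resampled. Sampling *with* replacement is not an option:
  duplicated (features, label) rows inflate the apparent association of every
  real column relative to shadows permuted after resampling. The test suite
  verifies the resulting operating characteristics: on iid noise features the
  filter confirms nothing, while a feature equal to the label is confirmed in
  every run.
* **Full-width shadow pool.** Shadows are generated for all original
  features even after some are rejected. A pool that shrank with the active
  set would weaken the max-shadow reference over time and let chance
  survivors accumulate spurious hits.

Features still undecided at `max_iter` are resolved by comparing their median
importance across iterations against the median best-shadow importance
(confirmed if above, rejected otherwise); `resolve_tentative = FALSE` keeps
them as a separate tentative class instead. Only confirmed features continue
to the ranking stage.

## mRMR ranking

Relevance and redundancy are plug-in mutual information (base 2; the base
does not affect the ordering) on discretized features: three bins at
$\mu \pm t\sigma$ with $t = 1$, the documented default of the classical mRMR
program; a constant feature (zero variance) maps entirely to the middle bin.
The greedy ordering picks first the feature maximizing $I(f; y)$ and then
repeatedly

$$\arg\max_f \; I(f; y) - \frac{1}{|S|} \sum_{s \in S} I(f; s),$$

the additive MID criterion ($S$ = already selected; the quotient form MIQ is
available by option). Ties within a float tolerance of $10^{-12}$ go to the
smaller original column index, which makes the ordering reproducible and
comparable against an independently coded brute-force implementation of the
same criterion — the test suite checks exact order agreement on hundreds of
random small instances. The binary label is used as categories directly.

## IFS with a SMOTE-balanced CART

Disease-gene problems are heavily imbalanced, so each training fold is
rebalanced with SMOTE before the tree sees it: synthetic minority samples
$x_i + u (x_{nn} - x_i)$, $u \sim U(0,1)$, with $x_{nn}$ one of the $k = 5$
nearest minority neighbors of a uniformly chosen minority row $x_i$
(Euclidean metric, $k$ clamped to the minority size minus one). Every
synthetic coordinate lies between its parents' coordinates. Oversampling
brings the minority to exact parity with the majority — no ratio being an
obviously better default — and happens **strictly inside the training
portion of each fold**: the held-out fold never contains synthetic samples,
so the cross-validation estimate is free of oversampling leakage. The
alternative order (balance first, then split) is simpler but lets synthetic
near-copies of test points into training sets and inflates every metric;
`enrichdt` does not offer it.

The classifier is CART with the Gini criterion grown essentially
unrestricted (`minsplit = 2`, `minbucket = 1`, complexity penalty 0, depth
cap 30 — the implementation's structural maximum). Folds are stratified:
each class is shuffled and dealt round-robin, so per-class fold counts
differ by at most one. Confusion counts are pooled over folds and the
metrics — accuracy, sensitivity, specificity, precision, F1 on the positive
class, and the Matthews correlation coefficient — are computed once from the
pooled table; pooling keeps MCC well-defined when single folds hold few
positives (per-fold averaging is available by recomputing from the per-fold
counts). Any metric with a zero denominator is defined as 0.

IFS evaluates prefixes of the ranking of sizes $5, 10, 15, \dots$ (step
configurable), including a final ragged prefix when the feature count is not
a multiple of the step, reusing one fold assignment across prefixes so curve
points differ only in the features. The best prefix maximizes F1, ties going
to the smaller prefix — the cheaper model wins when performance is equal.

## Rule extraction

The final tree is trained on all samples, SMOTE-balanced with the same
recipe as the cross-validation folds (mirroring the classifier the metrics
describe), but rule *supports* are counted on real samples only, so the
reported per-rule class counts are interpretable as data. Each leaf yields
one rule: the conjunction of its root-to-leaf conditions, simplified per
feature to the tightest lower/upper bound. Rules are mutually exclusive and
exhaustive by construction — the tests verify that exactly one rule matches
each of thousands of random probes and that rule predictions agree with the
tree everywhere. Thresholds are reported at full precision in the JSON
artifact and at 4 significant digits in the text report; rules are ordered
by descending real-sample support.

## The synthetic benchmark

Real inputs for this problem are database snapshots (a disease-gene catalog,
an interaction network, GO/pathway annotation sets). The generator emulates
their structure at desk scale so every stage is testable offline:

* a gene universe (default 500 genes) with overlapping term annotations in
  four namespaces (default 25 BP / 10 CC / 10 MF / 5 PATHWAY terms, sizes
  uniform on 10–40 genes);
* an Erdős–Rényi background network with edge probability
  $\bar{d}/(n-1)$ (default mean degree 8) — the simplest exchangeable null;
  no downstream test requires degree heterogeneity;
* planted positives (default 75) and causal terms (default 3, drawn from BP,
  mirroring the biological-process dominance typical of such analyses):
  each positive gene receives `mean_degree` candidate extra edges, each
  realized with probability `effect_strength` toward a uniformly chosen
  member of a uniformly chosen causal term.

The signal is planted **through edges**, not by annotating the positives
directly, because the feature encoding scores the neighbor set, not the
gene. At `effect_strength = 0` no extra edge is created, so positives and
negatives follow the identical generation law — the null case is exactly
null, which the calibration tests rely on. A truth sidecar (causal term ids
and the universe, as JSON) is written next to the GMT/edge-list/label files
so recovery tests need no hidden state; the universe lives in the sidecar
because GMT and edge lists cannot represent isolated, unannotated genes.

What the generator does *not* emulate: the GO term hierarchy (no
parent–child annotation propagation), STRING's per-channel confidence
structure, degree heterogeneity of real interactomes, and identifier
mapping between nomenclatures. Passing tests therefore demonstrate the
pipeline's statistical behavior under a clean planted-signal model, not
performance on any real disease dataset.

## Reference problem sizes

The test suite and the acceptance script run the full pipeline at 500 genes,
50 terms, 75 positives, 3 causal terms, and 5 replicate seeds — small enough
to run in minutes on one CPU, large enough that cross-validated F1 and MCC
are stable to a few percent. Module tests use smaller instances (hundreds of
samples, up to 20 features) chosen so each property is measurable without
simulation noise dominating.

## Determinism

Every stochastic step — generation, shadow permutation, subsampling, fold
assignment, SMOTE — derives its seed from one user-facing seed through a
fixed fan-out, and the random-forest fits pin their own seeds and run
single-threaded, so a pipeline run is reproducible bit for bit, including
the written artifacts.

## Known limitations

* Boruta's subsampled iterations trade some power for calibration: weak but
  real features need more iterations to accumulate significant hits than
  they would with full-data iterations.
* Plug-in MI on three bins is coarse; features whose relevance lives in fine
  distributional detail may rank lower than a continuous estimator would
  place them. The discretization is configurable but deliberately simple.
* An unrestricted CART on hundreds of features memorizes its training set;
  the cross-validated IFS curve, not training fit, is the performance claim.
* With no confirmed features (null data), the pipeline warns and ranks all
  features rather than stopping, so null calibration can be measured on a
  real IFS run; downstream numbers in that regime are noise by design.
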