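# enrichdt

Classifies disease-associated genes against the background of other genes
using **functional-enrichment features of their interaction-network
neighborhoods**, and explains the classifier as quantitative IF–THEN rules.
Intended for computational biologists who have (or want to simulate) three
inputs: an annotation catalog (GO-like terms and pathways, GMT format), an
undirected gene/protein interaction network (STRING-style edge list), and a
positive gene list.

## The method

A gene `g` is encoded by one feature per annotation term: the upper-tail
hypergeometric enrichment of its direct network neighbors `G` against the
term's gene set,

```
ES(g, term) = −log10  Σ_{k=m}^{min(n,M)}  C(M,k) C(N−M, n−k) / C(N, n)
```

with `N` the universe size, `M` the term size, `n = |G|`, and
`m = |G ∩ term|`. On this genes × terms matrix the pipeline runs:

1. **Boruta** — all-relevant filtering against permuted shadow features
   (random forests, binomial hit tests, per-iteration stratified
   subsampling for calibration);
2. **mRMR** — greedy max-relevance/min-redundancy ranking by mutual
   information, `I(f; y) − mean_{s∈S} I(f; s)`;
3. **IFS** — incremental feature selection: nested prefixes of the ranking
   evaluated with a CART (Gini) decision tree under stratified 10-fold
   cross-validation, each training fold rebalanced with SMOTE; best prefix
   by F1;
4. **Rules** — the final tree, refit on all samples, is read out as
   mutually exclusive, exhaustive IF–THEN rules with per-class support.

Performance is reported as ACC, SN (recall), SP, precision, F1 and MCC from
fold-pooled confusion counts. A synthetic-data generator with planted
neighborhood enrichment (`synthetic_config()` / `generate_dataset()`)
makes the whole pipeline testable without any database download. See the
methods vignette (`vignettes/enrichdt-methods.Rmd`) for the model,
calibration design, and limitations.

## Worked example

```r
library(enrichdt)

report <- run_pipeline(pipeline_config(
  synthetic = synthetic_config(seed = 42),   # 500 genes, 3 causal BP terms
  out_dir   = "demo_out",
  seed      = 42))
print(report)
#> pipeline_report
#>   Boruta confirmed: 13 features
#>   best prefix: 5 features
#>   metrics: ACC 0.978  SN 0.960  SP 0.981  precision 0.900  F1 0.929  MCC 0.917
#>   rules: 14
#>   namespaces: BP=5 CC=0 MF=0 PATHWAY=0
#>   causal terms confirmed: 3 of 3
```

Reading the report: Boruta retained 13 of the 50 annotation features; the
cross-validated F1 over nested mRMR prefixes peaked at 5 features (F1 0.929,
MCC 0.917 — strong planted signal at the default effect strength 0.9); all
3 planted causal terms were among the confirmed features, and the selected
features are all biological-process terms, as planted. The final tree
yields 14 rules, e.g. from `demo_out/rules.txt`:

```
RULE 1 (support: 0 positive, 358 negative)
IF
  BP0003 <= 1.128
  BP0014 <= 0.4531
  BP0017 <= 1.56
THEN class = negative
```

— genes whose neighborhoods show enrichment below ~1.1–1.6 (−log10 p) for
the three causal processes are classified negative; 358 real negatives and
no positives reach this leaf. Every stage artifact (enrichment matrix,
Boruta partition, mRMR ranking, IFS curve, rules) is written to `out_dir`
in plain-text formats and reloads with the corresponding `read_*`
functions. Real inputs run the same way with
`pipeline_config(paths = list(catalog = ..., network = ..., positives = ...))`,
or from a shell via `inst/scripts/run_pipeline.R`.

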