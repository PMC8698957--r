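---
title: "Single-gene network expansion: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-gene network expansion: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seednet)
```

## The problem

Co-expression networks connect genes whose expression profiles correlate, but
correlation mixes direct regulatory relationships with indirect ones mediated
by third genes. Causal-discovery methods address this by testing conditional
independence: an edge between two genes survives only if no conditioning set
of other genes explains their association away. `seednet` implements a
single-gene variant of this idea. Instead of expanding a known local network,
it expands *one seed gene at a time* against the whole gene universe, so that
precomputed per-gene results can later be combined freely into networks for
any gene set of interest.

## The expansion procedure

One expansion of a seed gene consists of `n_iterations` independent
iterations. In each iteration the non-seed genes are randomly partitioned
into `ceiling((n_genes - 1) / (tile_size - 1))` chunks of at most
`tile_size - 1` genes, and the seed is prepended to every chunk ("tiles").
On each tile, the undirected skeleton of a causal graph is estimated with the
PC algorithm's skeleton phase (below). Two counters accumulate per gene:

* `input_count` — iterations in which the gene shared a tile with the seed
  (with exact partitions this equals `n_iterations`);
* `output_count` — tiles in whose estimated skeleton the gene remained
  adjacent to the seed.

The score is the relative frequency `f_rel = output_count / input_count`,
in `[0, 1]`; genes are ranked by descending `f_rel`. A gene that is only
marginally correlated with the seed through intermediaries is separated in
most tiles and scores low; a direct neighbour resists separation under many
random conditioning contexts and scores high. At production scale
(a 28,013-gene universe, tiles of 1000, 2000 iterations) one expansion
schedules 29 skeleton runs per iteration; expanding every gene gives
`28013 * 29 * 2000 = 1,624,754,000` runs — the arithmetic reproduced by
`num_tiles()` and `total_runs()`.

Tiles are **resampled at every iteration**. The denominator of `f_rel`
("times the gene was in the input") is only informative when tile membership
varies across iterations; a fixed tiling would make it constant and the
conditioning contexts identical. A `resample_tiles = FALSE` switch retains
the fixed variant for comparison. The last tile of an iteration is left
smaller rather than padded: padding would inflate `input_count`
asymmetrically for the padded genes, while the per-gene denominator already
absorbs unequal tile sizes.

Ties in `f_rel` are broken by larger `|pearson_r|` (the gene's full-sample
Pearson correlation with the seed), then lexicographic gene ID, so ranking is
fully deterministic. The Pearson correlation is computed once over all
samples — not per tile — and stored with each record, because its *sign*
travels downstream to color network edges as correlated or anticorrelated.

### Reproducibility and parallelism

All randomness derives from one root seed. Iteration `i` uses the stream
seed `(rng_seed + 11400714 * i) mod (2^31 - 1)`, so any iteration can be
recomputed independently; iterations may therefore run concurrently
(`cores > 1`) with results byte-identical to sequential execution. Gene IDs
are canonically sorted before each shuffle, which makes expansion lists
invariant to the row order of the input matrix.

## The skeleton search

`estimate_skeleton()` implements the *stable* (order-independent) variant of
the PC skeleton phase. Starting from the complete graph, conditioning sets of
size 0, 1, 2, ... are enumerated from the neighbourhoods of each edge's
endpoints, with the neighbourhoods snapshotted at the start of each level;
an edge is deleted as soon as one set yields independence, and the separating
set is recorded. The stable snapshot is what makes the result independent of
variable order — essential here, because millions of runs are aggregated and
run-to-run comparability matters more than the marginally smaller graphs the
classic sequential variant can produce. Subsets are enumerated
lexicographically and the search stops at the first independence; only the
skeleton (not edge orientations) is consumed downstream, so the choice of
separating set is immaterial but kept deterministic.

With data, conditional independence is judged by the Fisher-z test:
`z = sqrt(n - |S| - 3) * atanh(rho)` with `rho` the partial correlation
computed by precision-matrix inversion on the `(i, j, S)` submatrix of the
correlation matrix, clamped to `±(1 - 1e-12)`. The pair is called
independent when `|z| <= qnorm(1 - alpha/2)`; the default `alpha = 0.05`.
When `n - |S| - 3 <= 0` the test is unavailable and the edge is *retained* —
the conservative direction, since an unavailable test must not fabricate
independence. `max_order` is unlimited by default; the structural stopping
rule (no neighbourhood large enough to supply the next conditioning size)
terminates the search.

The hot path is compiled (RcppArmadillo); an R-level loop with identical
semantics accepts any conditional-independence closure. The two paths are
cross-checked against each other in the tests, and the R path is used with an
exact d-separation oracle (`dsep_oracle()`): under faithfulness, PC with a
perfect oracle must return exactly the generating DAG's skeleton, and the
test suite verifies this exhaustively for *every* labeled DAG on up to five
nodes (29,281 graphs on five nodes alone).

## Building networks from expansion lists

`create_network()` connects a set of input genes using their expansion
lists. Each list is first trimmed at a user-chosen relative-frequency
threshold `f_min` (0.5 focuses on the most direct connections). An edge is
drawn between two input genes when each appears in the other's trimmed list
— the **mutual presence** rule — with weight the mean of the two `f_rel`
values and a negative sign when either direction's stored Pearson
correlation is negative. Mutual presence is the stricter reading of the
rule and is the default; `one_sided = TRUE` relaxes it (the edge takes the
single available `f_rel`), which can be useful when some nodes lack their
own expansion lists. Sign discordances between the two directions are
possible in principle (the stored correlations are estimates of a symmetric
quantity) and are resolved conservatively toward flagging anticorrelation,
with a message.

Edge weights in the displayed band `[f_min, 1]` are binned into equal thirds
as solid / dashed / dotted line classes — with the default band the cut
points are 0.8333 and 0.6667. Only the band's endpoints are inherent to the
display convention; equal thirds is this package's choice.

`expand_network()` aggregates lists into a candidate table by one of four
criteria: a relative-frequency floor (`frel`), a rank ceiling (`rank`), a
functional-category prefix (`pattern`, e.g. a transcription-factor category
code), or the number of input lists sharing the candidate (`shared`).
Candidates are ordered by the best `f_rel` across sources (`max_f_rel`);
the mean is also reported. The combiner is deliberately `max` — "best
evidence from any seed" — because aggregation across seeds has no canonical
definition and `max` is the least destructive for downstream triage.

## GO enrichment and promoters

`go_enrichment()` is the classic per-term one-sided Fisher
(hypergeometric-tail) test over a study set versus a population, after
true-path propagation of annotations (`propagate_annotations()`: each gene
inherits all ancestors of its directly annotated terms through is_a/part_of;
the operation is idempotent, counts diamond ancestors once, and rejects
cyclic term graphs). Decorrelation variants (weight/elim) are deliberately
not implemented: the classic test is exactly reproducible against
brute-force enumeration, which the test suite does for every 2x2 table with
population up to 30. Rows are ranked by raw p-value; a Benjamini–Hochberg
adjusted column is added but does not affect the ranking.

`extract_promoters()` cuts the `length` bases (default 1000) upstream of the
annotated gene start — plus strand: `[start - length, start - 1]`; minus
strand: reverse complement of `[end + 1, end + length]` — clipped at
chromosome boundaries, preserving soft-masked lowercase. The anchor is the
annotated feature start with no TSS refinement, which is the only
information a plain GFF provides. The FASTA output is intended as input to
external motif-discovery tools; motif discovery itself is out of scope.

## The synthetic benchmark

`random_dag()` and `sample_expression()` generate ground-truthed data from a
linear-Gaussian structural model: `X_j = sum_{i in pa(j)} w_ij X_i + eps_j`,
sampled in topological order with unit-variance Gaussian noise by default.
This model is chosen deliberately: the Fisher-z test is exactly calibrated
for it, so the engine is tested first under its own assumptions. Edge
coefficients are drawn from `±[0.5, 1.5]`; the magnitude floor of 0.5 avoids
near-unfaithful cancellations that would make small-sample recovery
unstable. The analytic covariance `(I - W)^{-T} D (I - W)^{-1}` is exposed
for convergence checks.

Named fixtures with hard-coded seeds (`tiny-collider`, `chain-5`, `dag-20`,
`dag-50`) make every statistical test reproducible. The standard benchmark
is `dag-50` (50 genes, edge probability 0.08 — average degree about 4, the
sparse regime the method targets) sampled at 1000 observations and expanded
with 200 iterations of tiles of 25: a desk-scale proportional shrinkage of
the production geometry (the production 28,013/1000/2000 setting is far
beyond a single machine, and these sizes already give stable recovery
statistics). On this benchmark the relative frequency ranks true seed
neighbours at AUROC above 0.8 and separates neighbour from non-neighbour
mean `f_rel` by an order of magnitude.

What the generator does *not* emulate: the mixed microarray/RNA-seq noise of
a real expression compendium — batch effects, heteroscedasticity, count
overdispersion, missing annotations. Passing the benchmark therefore shows
the machinery is correct under the model's assumptions, not that any
particular biological network will be recovered at these rates.

## Numerical and degenerate-input choices

* Partial correlations: submatrix inversion is the production route; the
  classical recursion is kept as an independently implemented cross-check.
  Singular submatrices raise a degenerate-input error rather than silently
  returning a value.
* Zero-variance genes cannot enter correlation-based tests: readers flag
  them, `expand_gene()` excludes them with a warning, and
  `estimate_skeleton()` refuses them by name.
* Archives are written with a byte-reproducible ZIP writer (stored entries,
  fixed timestamps), so identical inputs give identical archive bytes —
  which the round-trip tests assert literally.
* `f_rel` values are serialized at full precision (`%.17g`); all write/read
  pairs round-trip field-for-field.

## Known limitations

* The skeleton search is exponential in the worst case; dense graphs or very
  liberal `alpha` make it slow. `max_order` caps the conditioning size when
  speed matters more than exactness.
* `f_rel` is a stability score, not a probability of direct interaction; its
  scale depends on tile size, iteration count and sample size, so thresholds
  (e.g. the 0.5 trimming default) are conventions, not calibrated error
  rates.
* Aggregation (`expand_network`) unions *records*, so its `shared` criterion
  counts containment in lists as supplied — trim lists first if containment
  should mean "strong candidate" rather than "scored at all".
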