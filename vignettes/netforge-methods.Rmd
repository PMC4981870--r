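---
title: "netforge: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{netforge: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

netforge builds probabilistic functional gene networks from heterogeneous
evidence and mines them for candidate genes. This vignette records the
statistical model, the tunable parameters and their defaults, the numerical
choices made where the method leaves room, what the synthetic-data generator
does and does not emulate, and the known limitations. Nothing here states an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## Gold standard

Positive pairs are unordered pairs of genes sharing at least one annotation
term; negative pairs are annotated genes sharing none. Together they
partition the pairs of annotated genes — a property the test suite asserts
by brute force. Two filters precede pairing:

* **Term size** (`max_term_size`, default 300 genes). A term with *k* genes
  contributes C(*k*, 2) positives, so a single broad term can swamp the
  training set with generic-biology pairs; oversized terms are dropped.
* **Term depth** (`min_level` 2 to `max_level` 10), applied only when the
  source provides depth metadata (typically GO Biological Process).
  Pathway-style sources without a hierarchy are filtered on size alone.

When several annotation sources are merged, a pair positive in any source
is positive overall: a shared annotation anywhere is positive evidence, and
conflicting sources should not cancel it. The merge therefore takes the
union of positives and subtracts it from the union of negatives. This
precedence rule is our policy; nothing in the method constrains it.

## LLS calibration

Each evidence channel yields a scored pair table. The gold-overlapping
pairs are ranked by raw score (ties broken by canonical pair order, for
determinism) and cut into consecutive equal-count bins (`bin_size`, default
1000 gold pairs; the small synthetic worlds in the tests use 100–2000). Per
bin,

$$LLS = \ln\frac{P(I\mid D)/P(\neg I\mid D)}{P(I)/P(\neg I)},$$

with the dataset-cell odds taken from the bin counts and the prior odds
from the *entire* gold standard. A Haldane pseudocount of 0.5 is added to
the two bin cells only, so a bin with zero positives (or negatives) still
maps to a finite score; the perturbation is bounded by
$\ln((n+0.5)/n)$ per cell and vanishes for well-populated bins.

The score-to-LLS **mapping** is fit through the per-bin (mean score, LLS)
points. The method family is unstated in the literature this follows, so we
chose isotonic regression with linear interpolation between the fitted
nodes and constant extrapolation beyond them: a calibration should never
invert the score order within one dataset, and isotonic regression is the
least-committal monotone fit. With fewer than five bins a monotone fit is
under-determined and an ordinary linear fit on (mean score, LLS) is used
instead. `apply_lls_model()` maps *every* pair through this function —
generalization to non-gold pairs is the point of the continuous mapping —
and keeps edges with positive LLS at or above `min_lls`.

**0.632 bootstrap.** In-sample bin LLS is optimistic. With `B` resamples
(default 100) of the labeled pairs, each bin's final value is
`0.368 * in-sample + 0.632 * mean(out-of-bag)`, where out-of-bag pairs are
assigned to the in-sample bins and a bin left empty in a resample is
skipped for that resample (and kept in-sample if that happens in every
resample). The 0.632 rule is applied per bin, because bins are the
estimation unit. Resampling is deterministic for a fixed seed.

## Weighted-sum integration

Evidence channels are correlated (two co-expression compendia are not two
independent observations), so LLS values are not summed naively. Supporting
values at or above the threshold `T` are ranked $L_0 \ge L_1 \ge \dots$ and
combined as

$$WS = L_0 + \sum_{i \ge 1} L_i / D^i, \qquad D \ge 1.$$

`D = 1` recovers the naive sum; `D \to \infty` keeps only the best channel.
Edges whose supporters all fall below `T` are *absent*, not zero-weighted:
whether `T` filters before or after identifying $L_0$ is ambiguous in
prose, and we filter first — an edge must have at least one supporter worth
keeping to exist at all. The algebra (WS ≥ L0, monotonicity in each input
and in support count, the geometric bound $WS \le L_0 D/(D-1)$, and the
equal-supporter closed form $L(2-2^{1-k})$ at D = 2) is asserted on random
inputs in the acceptance checks.

**Choosing (D, T).** `optimize_ws_params()` scores each grid point (default
D ∈ {1, 1.5, 2, 3, 4}, T ∈ {0, 0.5, 1, 1.5, 2}) by the area under the curve
of cumulative benchmark LLS versus cumulative pair count, evaluated per bin
of ranked edges with the same binning as the precision–recall analysis, and
integrated by the trapezoid rule from zero (holding the first bin's value
constant down to zero — a stated convention, since the curve has no natural
value at zero pairs). Ties prefer smaller D, then larger T. One property of
this metric is worth knowing: if the benchmark is fully contained in the
network, cumulative LLS can approach but never cross zero, and extra junk
edges never reduce the area. The metric only penalizes noise when the
benchmark extends beyond the network (as a genome-wide gold standard does),
which is how the optimizer tests are constructed.

## Evidence channels

* **Mutual information** (profiles): equal-width discretization into
  `n_bins` (default 4) bins per vector, natural logarithm (nats); vectors
  with at most two distinct values are used as-is (binary bypass); constant
  vectors carry zero information. The base and binning are unstated in the
  source methods; these defaults are documented choices, checked against a
  brute-force joint-histogram oracle to 1e-9.
* **Domain co-occurrence**: presence of a domain is encoded as the inverse
  of its proteome frequency (`universe_size / n_genes_with_domain`), absence
  as 0, so sharing a rare domain moves the MI more than sharing a common
  one.
* **Gene neighborhood**, two variants that concretize the two classic
  approaches (both are our instantiations — the originals are not restated
  in the source — and both are flagged as approximations):
  the *distance* variant scores a pair by the mean over co-occurrence
  genomes of $1/(1+\Delta)$ (0 when on different contigs); the
  *probability* variant scores $-\ln P$ where $P$ is the one-tailed
  binomial tail of observing at least *k* within-`window` proximities in
  *m* genomes, with per-genome proximity chance
  $q = \min(1, 2\,\mathrm{window}/(L-1))$ on a single contig of *L* genes,
  summed over contigs and averaged across genomes when contig structure
  differs (the binomial requires one *q*; the mean is our documented
  simplification).
* **Co-expression**: Pearson correlation with a two-sided exact *t* test
  ($t = r\sqrt{(n-2)/(1-r^2)}$, df = n−2) at confidence `conf` (default
  0.99). The exact distribution matters because the minimum dataset size is
  small (12 samples); datasets below `min_samples = 12` are rejected
  outright rather than scored, and constant-expression genes are skipped
  with a message. Whether the filter should be one- or two-sided is
  unstated; two-sided is the default since strong negative correlation is
  also retained evidence (the type-I calibration in the acceptance suite
  measures the two-sided rate).

## Orthology transfer

`bbh()` links genes that are mutually best hits, with ties resolved
deterministically (highest score, then lexicographic subject) and logged.
`inparanoid_clusters()` reduces the full InParanoid machinery (bootstrap
confidence, overlap-rule cluster merging) to a seed-plus-ratio scheme:
cluster seeds are the BBH pairs at confidence 1; a same-species gene joins
a cluster when its similarity to the seed gene reaches at least
`overlap_cut` (default 0.5) of the seed pair's cross-species score, with
confidence `min(1, ratio)`. A gene claimed by several clusters keeps only
its links in the cluster with the strongest seed. The graded-ratio rule is
what makes "multiplying two inparalog scores" testable: a duplicate at 80%
of the seed similarity carries confidence 0.8, one as similar as the seed
carries 1.0.

Transferred edges are scored by IWLLS: the source LLS multiplied by the two
link confidences, so a transferred edge never outweighs its source, and
identity orthology is a no-op (both asserted). Where several source edges
map onto one target pair, the maximum is kept — summing would double-count
paralog fan-out. Whether the InParanoid score should multiply the LLS value
or its exponent is ambiguous in the source's prose; we multiply the value
and note that multiplying the exponent would compress rather than scale
transferred weights.

## Prioritization and benchmarking

*Neighborhood* scoring ranks every non-guide gene by its summed edge weight
to the guide set (ties lexicographic); guides are never candidates. The
leave-one-out AUC holds out each guide, rescores everything against the
reduced guide set, and averages the Mann–Whitney probability that the
held-out guide outranks a random non-guide (ties credited 0.5). The
comparison set is all network genes outside the guide set; guides absent
from the network are dropped with a logged count. AUC is reported raw (it
can fall below 0.5 on anti-correlated inputs) rather than clamped at the
0.5 random-expectation guard, so null calibrations are unbiased; the
`> 0.7` good-predictive-power flag is attached to the result.

*Context* scoring tests each hub (degree ≥ `min_degree`, default 50) for
enrichment of its neighborhood in the DEG set by the one-tailed Fisher's
exact test — computed directly as the hypergeometric tail — over the
network's gene universe excluding the hub itself. One-tailed because
depletion of DEGs in a neighborhood is uninformative for prioritization.
No multiple-testing correction is applied by default, matching the
single-cutoff usage this follows (`p <= 0.01`); a Benjamini–Hochberg flag
is available. DEGs are an unweighted set.

`gba_benchmark()` / `term_recovery_auc()` run the leave-one-out AUC with
each qualifying annotation term's members (≥ `min_term`, default 5, present
in the network) as guides, and summarise the median AUC with a one-sided
Wilcoxon signed-rank test against 0.5.

## Topology diagnostics

Global clustering is the mean local clustering coefficient with nodes of
degree < 2 contributing 0 (the convention is unstated in the source; this
one keeps the mean over all genes well-defined). The null model is
degree-preserving double-edge-swap rewiring, 10·|E| swaps per replicate,
with the degree sequence asserted unchanged every replicate. The power-law
fit is an ordinary least-squares line on log10(count) versus log10(degree)
— a transparent descriptive statistic, deliberately not a maximum-likelihood
scale-free test. Shortest-path profiles are BFS lengths over pairs sampled
uniformly from connected pairs, seeded.

## The synthetic world

`generate_world()` plants `n_modules` (default 6) modules of `module_size`
(default 20) genes in a universe of `n_genes` (default 300) and emits every
input format: module-mates share an expression latent factor (mixing weight
`1 - noise`), a binary phylogenetic profile (bits flipped with probability
`noise`), three rare family domains (each membership dropped with
probability `noise`) on top of two background-pool domains per gene,
contiguous placement in each of `n_genomes` (default 8) synthetic genomes
(scattered with probability `noise`), and one annotation term per module
plus decoy terms over background genes. A second species is a renamed copy
with paralog duplicates at `dup_rate` (default 0.1) for orthology tests.
`noise = 0.2` is the default study condition; each component draws from its
own sub-seeded stream so regenerating one never perturbs another (asserted).

What the generator does **not** emulate: microarray platform artifacts,
realistic BLAST score distributions, unequal module sizes, genes in
multiple pathways, or annotation bias. Passing the end-to-end checks shows
the machinery is correct and calibrated on its stated model, not that any
particular real dataset would reach the same recovery.

Two fixture-design points deserve explicit record:

* **Guilt-by-association null.** Under a degree-preserving rewired null,
  the leave-one-out AUC is ~0.5 only when guide genes are degree-typical.
  In an evidence-derived world, module genes end up with systematically
  different degrees than background genes (the neighborhood channels alone
  see to that), and the rewired null inherits the confound — the null AUC
  is then a property of the degree gap, not of the scoring. The
  null-calibration checks therefore run on `planted_module_network()`, a
  direct generator whose background random edges are allocated so module
  and background genes have equal expected degree and whose edge weights
  are i.i.d.; there the rewired-null AUC is an honest ~0.5 while the intact
  network benchmarks near 1.
* **Hub enrichment type-I rate.** Fisher's exact test is conservative: its
  attained size sits below the nominal level by an amount set by the
  discreteness of the hypergeometric tail. With small margins the attained
  size can be half the nominal 1%, which would say nothing about the
  implementation. The calibration fixture (20 hubs of degree 120 over an
  820-gene universe, 300 DEGs drawn uniformly over that universe) keeps the
  tail steps fine enough that the attained size is close to 1%, so the
  measured pass rate tests the p-value computation rather than the
  conservativeness of exact tests.

## Problem sizes

The test suite and acceptance script run at desk scale by design: worlds of
60–300 genes, gold standards of 10,000 pairs, 1,000-instance oracle sweeps,
10,000-trial type-I calibrations, 500-instance algebra sweeps, and networks
of up to ~20,000 edges. The full suite completes in about two minutes on
one CPU; the acceptance script in about one.

## Limitations

* Scores flow only through direct neighbors; no diffusion or propagation.
* (D, T) are the only learned integration parameters; no per-dataset
  weights or dependence modeling beyond the rank discount.
* The isotonic mapping extrapolates as a constant beyond the observed bin
  range; scores far outside the calibration range keep the boundary LLS.
* Orthology clustering is the reduced seed-plus-ratio scheme, not full
  InParanoid; similarity tables are consumed, never computed.
* GO term depths are consumed as metadata; the ontology DAG is not
  traversed.
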