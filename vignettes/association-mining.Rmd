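---
title: "Mining associated genes from multiple evidence types"
author: "AssocMiner authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining associated genes from multiple evidence types}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AssocMiner)
```

## The model

Two genes are "associated" under an evidence type when they share more of
that type's attributes than chance would predict. For a type with
attribute universe of size $N$, genes $a$ and $b$ carrying $n$ and $m$
attributes and overlapping in $k$, the raw score is the hypergeometric
upper tail on the $-\log_{10}$ scale:

$$H_i(a,b) = -\log_{10} \sum_{x = k}^{\min(n, m)}
  \frac{\binom{n}{x}\binom{N-n}{m-x}}{\binom{N}{m}}.$$

What plays the role of attributes — and hence of $N$ — depends on the
type. For TF binding and TF regulation the attributes are TFs and $N$ is
the number of distinct TFs in the catalog; for mutant phenotypes,
functional annotations and literature links they are phenotypes,
annotation terms and publications; for physical and genetic interactions
the attributes are the interaction partners themselves and $N$ is the
size of the gene universe. Expression-profile (EP) association is not
scored here at all: those scores come precomputed from an expression
compendium and are imported as a pair–score table.

Raw scores of different types live on incomparable scales (they depend on
$N$ and on annotation density), so for a query $a$ each type is min–max
normalized over all candidates $b$,
$S_i(a,b) = (H_i - \min_b H_i)/(\max_b H_i - \min_b H_i)$, and the chosen
types are summed into the overall association score
$\mathrm{OAS}(a,b) = \sum_{i \in \text{chosen}} S_i(a,b)$. Candidates are
ranked by descending OAS. Separately, a pair carries *evidence* of type
$i$ when its raw score strictly exceeds the genome-wide 95th percentile
of that type's scores over all unordered gene pairs — a population
property of the raw score distribution, deliberately independent of
which types a user chose to rank with.

### Assumptions

The hypergeometric tail treats each gene's attribute set as a uniform
random draw of its observed size; annotation biases (well-studied genes
carry more publications and phenotypes) violate this and inflate scores
for heavily annotated pairs, which is one reason scores are only
interpreted relative to the per-query normalization and the genome-wide
percentile rather than as calibrated p-values. Interaction files are
treated as undirected; a row $(x, y)$ adds each gene to the other's
partner set, and self-interactions are dropped because self-membership
would add a constant to every overlap a gene takes part in.

## Parameters and conventions

* **Log base** (`logBase`, default 10). The tail could equally be
  reported in nats; normalization makes every downstream quantity
  invariant to the base, so the choice only affects raw score displays.
* **Probability floor** (`probFloor`, default 1e−300). The tail is
  computed in log space via `stats::phyper`, and the probability is
  clamped from below before the log so that extreme overlaps give large
  finite scores (≈300) instead of infinities that would break min–max
  normalization. The tail is mathematically symmetric in $(n, m)$ and is
  evaluated with the ordered pair so swapping the genes is bit-identical.
* **Percentile** (`percentile`, default 95) with the *nearest-rank*
  convention: the value at position $\lceil 0.95 M \rceil$ of the
  ascending multiset of all $M = \binom{G}{2}$ pair scores, implicit
  values included. Nearest-rank (rather than interpolation) stays
  well-defined on the heavily tied, zero-inflated distributions sparse
  catalogs produce. The evidence comparison is strict (`>`), so in types
  where the 95th percentile is 0 any positive score counts as evidence.
* **Implicit pairs.** A pair with no shared attributes has tail
  probability 1 and scores exactly 0; score tables only store pairs with
  $k \ge 1$. For EP, absent pairs count as the minimum observed score —
  compendium coverage is partial and absence is treated as non-evidence,
  which after normalization is equivalent to $S = 0$.
* **Degenerate normalization.** When all candidates score equally
  (e.g. an empty catalog), all $S$ are defined as 0, not 0.5: an
  uninformative type should contribute nothing to the OAS. The query
  gene itself is excluded from the candidate set, since its trivial
  self-association would otherwise dominate the max and compress
  everything else.
* **Tie-breaking.** Equal OAS values rank by ascending gene identifier.
  This makes rankings, exports and overlap averages deterministic; in
  particular a query with no annotations under a selection yields the
  $k$ lexicographically smallest candidates, and such queries are kept
  in overlap averages rather than excluded.
* **EP inside the OAS.** Imported EP scores are passed through the same
  min–max normalization as the seven computed types before entering the
  OAS, and the same percentile rule for flags. Treating the imported
  type uniformly keeps the OAS bounds and the evidence semantics
  identical across types.

## Ranked-list overlap analysis

To measure how much two evidence selections agree, the top-$k$ lists
(default $k = 50$) under each selection are compared per query gene and
the overlap count is averaged over every gene of the universe as query,
with standard error $\mathrm{sd}/\sqrt{G}$. For two independent random
rankings the expected overlap is $k^2/G$, which is the calibration the
test suite checks. Identical input catalogs for two types (the situation
of strongly redundant regulon evidence, e.g. binding vs regulation data
derived from the same underlying TF sets) force identical rankings and
hence a mean overlap of exactly $\min(k, G-1)$ — the construction-level
analogue of the empirical finding that binding and regulation lists
agree far more with each other than any other pair of types does.
Single-type rankings use the normalized score, which is a monotone
transform of the raw score, so the two orderings coincide except in the
all-tied degenerate case, where both collapse to the same lexicographic
order.

## What the synthetic generator emulates

`syntheticSpec()` defaults encode the validation condition used by the
tests and the acceptance script: a universe of 100 genes, 50 attributes
per attribute-style type, background membership (and interaction-edge)
probability 0.05 — matching the sparse, weakly structured background of
real annotation catalogs — and one planted pair sharing 10 of the 50
attributes per type. EP background pairs draw scores uniformly on
$[0,1]$ and planted pairs get $1 + \mathrm{Unif}(0,1)$, a deliberately
simple monotone-separable construction, since the engine imports EP
scores opaquely and only their ordering matters. A planted overlap of 10
against a background expectation of $\approx 0.125$ shared attributes
puts the planted pair far in the tail of every type simultaneously, so
recovery at rank 1 is the expected outcome and failures indicate an
engine defect rather than sampling noise.

One integer seed drives a single pseudo-random stream through a fixed
generation order (TFB, TFR, MP, FA, PI, GI, LE, EP), so identical specs
give byte-identical files. One subtlety: the files carry memberships
only, so a catalog loaded back from disk derives $N$ from the attributes
that were actually drawn, while the generator's returned catalogs carry
the full drawn attribute universe (an attribute that happens never to be
sampled still belongs to the universe). At the default background the
two rarely differ; at background 0 the distinction is what keeps planted
overlaps properly surprising.

What the generator does *not* emulate: the heavy-tailed per-gene
annotation-count distributions of real catalogs, correlations between
evidence types (beyond the planted module), study bias, or the marginal
pair counts of any real snapshot. Passing tests therefore demonstrate
the correctness and calibration of the machinery, not biological
performance on any particular organism's data.

## Problem sizes

The test suite and acceptance script run on universes of 8–100 genes for
property checks, 20 seeded 100-gene genomes for planted-pair recovery,
2,000 Monte-Carlo replicates for the random-overlap calibration, and one
1,000-gene, seven-type end-to-end pipeline; the exhaustive
subset-enumeration oracle covers every $(N, n, m, k)$ grid up to
$N = 12$. These sizes were chosen so every property is exercised at a
scale where the independent oracles are exact.

## Known limitations

* Scores are association screens, not significance tests: no
  multiple-testing control is applied or implied.
* Attribute identifiers are compared verbatim (genes are upper-cased,
  attributes are not), so mixed-case attribute vocabularies must be
  normalized upstream.
* The engine recomputes per-query normalization lazily; this is cheap
  (one sparse row extraction per type) but means genome-wide normalized
  matrices are never materialized, by design.
* Native dump formats of specific databases are out of scope; inputs are
  the two/three-column tabular forms documented in `loadCatalog()`,
  `importExternalScores()` and `loadGeneUniverse()`.
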