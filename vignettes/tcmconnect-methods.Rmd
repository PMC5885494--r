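---
title: "Methods: permutation-tested overlap of compound signatures and disease gene sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: permutation-tested overlap of compound signatures and disease gene sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the statistical model, the parameter choices and
their rationale, the behaviour of the synthetic-data generator, and the
numerical decisions made in `tcmconnect`. It is a design document: no
chunk is evaluated, and no empirical claim is made here beyond what the
package's test suite and `scripts/acceptance.R` actually compute.

## 1. Model and procedure

The package connects two bipartite gene networks and tests their
pairwise overlaps.

**Compound signature network.** Input is a probe x sample matrix of
log2 intensities, a probe-to-gene map, and a sample annotation
(`sample_id`, `compound`, `role`, `replicate`). Processing order is
fixed: collapse probes to genes first, then average replicates, then
call fold changes. Collapsing takes, per sample, the maximum over a
gene's probes — the convention that preserves sensitivity to a single
responsive probe set; probes mapping to no gene or to more than one gene
are dropped rather than double-counted. Replicates are averaged
arithmetically on the log2 scale (i.e. a geometric mean of intensities),
all vehicle samples pooling into one reserved `"VEHICLE"` column. A gene
enters compound *c*'s signature as "up" iff its linear fold change
versus vehicle is `>= t` and as "down" iff `<= 1/t`, inclusive at both
cuts, with default `t = 1.5`. A compound's *target genes* are the union
of its up and down sets.

**Disease gene network.** Input is a GWAS-catalog-dialect association
table and a trait-to-MeSH mapping. `MAPPED_GENE` cells are split on
`","` and on `" - "` (the intergenic dash), and `intergenic`/`NR`/empty
tokens are discarded. Traits are grouped by truncating their MeSH
Disease (category C) tree numbers to level 3 (e.g. `C14.280.067` stays;
`C14.280.067.845` maps to it); a trait with several category-C ancestors
contributes its genes to each of them, and a disease's gene set is the
union over its traits' records. Optionally each disease set is expanded
with one-hop neighbours from a STRING-dialect edge list: only edges with
combined score *strictly* above 0.9 qualify, at most 100 genes are
appended per disease, and candidates are ranked by their best edge score
to a seed gene (ties broken alphabetically). Expansion always restarts
from the catalog-derived seed genes, so it is idempotent.

**Prioritization.** For a pair with `K` compound target genes, `n`
disease genes, observed overlap `G`, and measured universe of size `N`,
the null is Monte-Carlo: draw `n_perm` uniform random `n`-subsets of the
universe and record their overlap `G(p)` with the compound's target set.
Then

- `P = #{ G(p) > G } / n_perm` — strict inequality, so `P = 0` is
  possible and honest ("no permutation beat the observation");
  `pseudocount = TRUE` switches to `(#exceed + 1)/(n_perm + 1)` for
  users who need strictly positive estimates;
- `Z = (G - mu) / sigma`, with `mu` and `sigma` the mean and *sample*
  standard deviation (denominator `n_perm - 1`) of the permuted
  overlaps;
- `q` = Benjamini–Hochberg adjustment over all tested pairs jointly
  (delegated to `stats::p.adjust`), significance declared at `q < 0.2`.

Pairs are ranked by `q`, then `p`, then `Z` descending. The permutation
is the *disease-side* one: the compound signature is held fixed and the
disease set is randomized, which is the natural choice when the
signature is the experimentally measured object and disease sets vary in
provenance. Under uniform sampling the two sides are exchangeable, so
the exact null is Hypergeometric(N, K, n) either way.

## 2. Dual route: sampled null versus closed form

`permutation_test()` genuinely samples gene subsets — a compiled partial
Fisher–Yates shuffle with swap-undo, `O(n)` per permutation, driven by
R's RNG so `set.seed()` governs it. `hypergeometric_oracle()` computes
the same tail, mean and standard deviation in closed form via
`stats::phyper`. The two are kept deliberately separate: the sampler is
the product (it generalizes to nulls with structure the closed form
cannot absorb), the oracle is its validator. The test suite compares
them across a parameter grid at three-standard-error tolerance and pins
one small case (`N = 10, K = 4, n = 3`) against exhaustive enumeration
of all 120 subsets.

## 3. Parameters, defaults, rationale

| Parameter | Default | Why |
|---|---|---|
| `fc_threshold` | 1.5 | conventional microarray fold-change cut; must be `> 1`; inclusive boundaries so "FC = t" counts |
| `ppi_score_threshold` | 0.9 | high-confidence STRING regime; strict `>` so 0.900 itself is excluded |
| `ppi_max_added` | 100 | caps dilution of a disease set by its interactome |
| `n_perm` | 100,000 | resolves p down to 1e-5; Monte-Carlo SE of a p near 0.05 is ~7e-4 |
| `q_threshold` | 0.2 | screening-stage FDR: candidates feed downstream validation, so a liberal cut is appropriate |
| `min_overlap` | 0 | pairs can be pre-filtered by observed overlap before testing; 0 tests everything |
| `universe_size` | measured universe | can be overridden (e.g. 20,462 for a genome-wide scale) when sets are drawn from a larger frame than the chip measures |
| `seed` | 1 | master seed; every compound–disease pair derives its own substream from `(seed, compound, disease)` via a platform-stable string hash, so results are independent of pair evaluation order |

All gene symbols are uppercased and trimmed on entry, everywhere.

## 4. The synthetic generator: what it emulates, what it does not

`synthetic_config()` / `simulate_study()` produce a full study: truth
(planted signatures, disease sets, and compound–disease pairs with exact
overlaps), a probe-level expression matrix, annotation, a
catalog-dialect association table, a trait-to-MeSH map, and a
STRING-dialect PPI table. Defaults: 2,000 genes x 2 probes, 20 compounds
x 2 replicates (+2 vehicle), 30 diseases of 30–60 genes, signatures of
80–120 genes, 5 planted pairs of overlap 10, effect size 1 on the log2
scale, noise SD 0.1, PPI density 0.01 with 25% high-confidence edges.

It **emulates**: baseline log2 intensities Uniform(4, 12) with per-probe
offsets; additive differential expression of random sign with magnitude
`de_log2_effect` (which must exceed `log2(fc_threshold)` so planted
signal is recoverable); Gaussian measurement noise; catalog quirks
(multi-gene cells, `" - "` separators, an `intergenic` token, `NR`
reported genes, multiple traits per disease); MeSH tree numbers one
level below their level-3 ancestor; an Erdős–Rényi PPI with a
high-score edge fraction. Planted overlaps are exact by construction:
overlap genes are chosen inside the planted signature and outside every
other planted signature, filler genes outside all planted signatures.

It does **not** emulate: probe-level cross-hybridization, batch or array
effects, correlated noise across genes, realistic degree distributions
in the PPI, linkage between traits, or signature size depending on
expression level. Conclusions about those phenomena cannot be drawn from
this generator.

Each artifact draws from its own RNG substream of the master seed
(`"truth"`, `"expression"`, `"catalog"`, `"ppi"`), so changing, say, the
PPI density leaves the expression matrix and catalog byte-identical.

## 5. Numerical choices

- **Fold-change cuts on the log2 scale.** `FC >= t` is evaluated as
  `log2 difference >= log2(t)`. Comparing `2^(diff)` to `1/t` in floating
  point makes the inclusive lower boundary inexact (`2^(-log2(1.5)) !=
  1/1.5` exactly); the log-space comparison keeps both boundaries exact.
- **Strict-inequality p with optional pseudocount** (section 1); the
  number of exceeding and tying permutations is stored on the result so
  any downstream recalibration is possible without re-running.
- **Sample SD** (`n_perm - 1`) for `sigma`, matching how a practitioner
  estimates a null SD from draws; `Z` is `NA` when `sigma = 0`
  (degenerate nulls, e.g. `n = N`), never infinite.
- **Uniformity checking of discrete p-values.** Permutation p-values sit
  on atoms, so the test suite checks background uniformity through the
  exact randomized PIT `u = (#exceed + V * (#tie + 1)) / (n_perm + 1)`
  with `V ~ U(0,1)`, which is exactly Uniform(0,1) when the observed
  overlap is exchangeable with the permuted ones. This is the principled
  version of "KS test allowing for discreteness".
- **Rounding of summary averages** (genes per compound/disease) is
  half-away-from-zero, matching how such tables are conventionally
  printed, not banker's rounding.
- **Determinism of artifacts.** No wall-clock or host path enters any
  emitted file; the configuration echo omits the output directory.
  Re-running a pipeline with identical inputs and seed reproduces every
  artifact byte for byte (asserted by the suite).
- **Tie-breaks** are always total and content-based (score descending,
  then symbol ascending for PPI candidates; `q`, `p`, `-Z` for pair
  ranking), never dependent on input row order: the suite asserts
  invariance under row/column permutations of the inputs.

## 6. Problem sizes and cost

The compiled kernel makes a single pair at `n_perm = 100,000` take
milliseconds for typical sizes (`N ~ 2,000`, `n ~ 50`); a 600-pair study
at `n_perm = 10,000` runs in seconds. Memory is `O(N)` per test. At
genome scale (`N ~ 20,000`, hundreds of compounds x diseases,
`n_perm = 100,000`) a full run is minutes on one core; pairs are
independent, so the loop parallelizes trivially if ever needed.

## 7. Limitations

- The permutation null assumes disease genes are exchangeable with
  uniformly drawn universe genes; real disease sets carry ascertainment
  structure (gene length, LD, study bias) that uniform sampling ignores.
- Up/down direction is recorded but the overlap statistic is
  direction-blind: a compound that *mimics* and one that *reverses* a
  disease profile score identically. Directional scoring is a natural
  extension, not implemented.
- BH correction treats pair tests as independent or positively
  dependent; pairs sharing a compound or disease are correlated.
- MeSH level-3 grouping is coarse: distinct diseases under one level-3
  ancestor are merged, and their gene sets unioned.
- PPI expansion trusts the score threshold; no topology beyond one hop
  is used.
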