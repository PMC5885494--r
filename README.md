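# tcmconnect

Connecting disease genes with compound expression signatures by
permutation-tested gene-set overlap.

## The scientific problem

Genome-wide association studies assign genes to diseases; compound
perturbation experiments on expression microarrays assign genes to
compounds (the genes a compound up- or down-regulates). If a compound's
target genes overlap a disease's associated genes more than chance
allows, the compound is a candidate modulator of that disease. This
package builds both gene networks from their raw inputs and tests every
compound–disease pair:

1. **Compound signatures** — probe-level log2 expression is collapsed to
   genes (per-sample maximum over a gene's probes), replicates are
   averaged per condition, and a gene enters a compound's signature when
   its fold change versus vehicle satisfies `FC >= 1.5` (up) or
   `FC <= 1/1.5` (down), inclusive at both cuts.
2. **Disease gene sets** — a GWAS-catalog-dialect table is parsed
   (`MAPPED_GENE` cells split on `","` and `" - "`, intergenic and
   not-reported entries dropped), traits are grouped under their MeSH
   Disease (category C) level-3 ancestors, and each disease set can be
   expanded with up to 100 one-hop neighbours from a STRING-dialect
   protein–protein interaction table at combined score strictly above
   0.9.
3. **Prioritization** — for a pair with `K` compound target genes, `n`
   disease genes and observed overlap `G`, the null is built by drawing
   `n_perm` random `n`-gene subsets of the measured universe (size `N`)
   and counting their overlap `G(p)` with the compound's targets:

   - `P = #{ G(p) > G } / n_perm` (strict inequality, so `P` can be 0),
   - `Z = (G − μ) / σ` with `μ`, `σ` the mean and sample standard
     deviation of the permuted overlaps,
   - Benjamini–Hochberg `q` across all pairs, significance at `q < 0.2`.

   The permutation machinery genuinely samples subsets (compiled via
   Rcpp); the closed-form hypergeometric distribution is kept separate
   as an independent cross-check (`hypergeometric_oracle()`), never as
   the production path.

A seeded synthetic-data generator produces complete studies (expression
matrix, probe map, annotation, catalog, MeSH map, PPI table) with known
planted compound–disease overlaps, so the whole pipeline can be
validated against ground truth.

## Worked example

Simulate a default study (2,000 genes, 20 compounds, 30 diseases, 5
planted compound–disease pairs of overlap 10) and run the pipeline:

```r
library(tcmconnect)
cfg <- synthetic_config(seed = 42)
sim <- simulate_study(cfg, file.path(tempdir(), "study"))
p <- sim$paths
run <- run_pipeline(pipeline_config(
  expression = p[["expression"]], probe_map = p[["probe_map"]],
  annotation = p[["annotation"]], catalog = p[["catalog"]],
  mesh_map = p[["mesh_map"]],
  output_dir = file.path(tempdir(), "out"),
  n_perm = 10000, seed = 42))
#> stage signatures: 20 compounds, 1988 compound-gene pairs
#> stage disease-net: parsing catalog
#> stage disease-net: 30 diseases, 1296 disease-gene pairs
#> stage prioritize: testing all pairs at n_perm = 10000
#> pipeline done: 16 significant pairs at q < 0.2
```

The five planted pairs occupy the top five of the 600 ranked pairs:

```r
res <- read.delim(file.path(tempdir(), "out", "ranked_pairs.tsv"))
head(res[, c("compound", "disease_id", "K", "n", "overlap", "z", "p", "q")], 5)
#>   compound  disease_id   K  n overlap     z p q
#> 1   CMPD04 C01.004.500  99 35      10 6.594 0 0
#> 2   CMPD03 C01.003.500 103 39      10 5.856 0 0
#> 3   CMPD05 C01.005.500 119 34      10 5.801 0 0
#> 4   CMPD02 C01.002.500 105 47      10 5.000 0 0
#> 5   CMPD01 C01.001.500 115 44      10 4.884 0 0
```

The core statistic in isolation, against its exact reference:

```r
permutation_test(K = 4, n = 3, g = 2, universe = 10,
                 n_perm = 100000, seed = 1)
#> Permutation null (N=10, K=4, n=3, 100000 permutations)
#>   observed overlap: 2
#>   mu = 1.2013, sigma = 0.7492
#>   p = 0.03448 (3448 exceed, 29814 tie)
hypergeometric_oracle(4, 3, 2, 10)$tail   # exact: 1/30 = 0.03333
```

Artifacts written per run: `signatures.gmt`,
`compound_gene_edges.tsv`, `disease_gene_edges.tsv`,
`disease_gene_network.sif`, `ranked_pairs.tsv`,
`significant_pairs.sif`, `heatmap_z.tsv`, `run_summary.txt`,
`config_echo.yaml`. Rerunning with the same inputs and seed reproduces
every file byte for byte.

A thin command-line front end lives at `inst/cli/tcmconnect.R` with
subcommands `simulate`, `run` and `query` (rank compounds against a
submitted disease gene list; `query_disease_genes()` is the underlying
function).

## License

MIT (see `LICENSE`).
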