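# hicdeconv

Species-level deconvolution of metagenome assemblies from Hi-C
proximity-ligation data.

## The problem

A shotgun assembly of a mixed microbial community yields thousands of
contigs with no record of which genome each one came from. Hi-C read pairs
carry exactly that missing signal: crosslinking happens inside intact
cells, so the two ends of a proximity-ligation pair almost always derive
from the same cell — and therefore the same genome. Tallying Hi-C links
between contigs turns genome binning into a graph clustering problem that
needs no reference genomes, no coverage profile across multiple samples,
and no sequence-composition model.

`hicdeconv` is for microbiologists and bioinformaticians who have a draft
metagenome assembly (FASTA) and a Hi-C library aligned to it (a 4DN-style
`.pairs` table, a name-grouped SAM/BAM, or a precomputed link-count table)
and want per-species contig bins, an estimate of how many species are
present, and honest diagnostics about what could not be binned.

## The method

1. **Site-proximity filtering.** Hi-C junctions form at restriction sites
   (HindIII `AAGCTT` or NcoI `CCATGG`), so a read pair is kept only if both
   5′ alignment positions lie within 500 bp of a site on their contig.
   Contigs with no site cannot produce signal and are reported as
   unclustered, with that reason.
2. **Normalized contact graph.** Nodes are site-bearing contigs; an edge
   carries the raw link count n(u,v) and the weight
   w(u,v) = n(u,v) / (s(u) · s(v)), where s(·) is the contig's
   restriction-site count — the number of ligatable fragment ends it
   exposes. Only the largest connected component is clustered.
3. **Jarvis–Patrick reweighting** (k = 100). Each node's neighborhood
   NN(v) is its top-k neighbors by normalized weight. An edge (u,v) is
   kept only if |NN(u) ∩ NN(v)| ≥ 1 and is reweighted to
   |NN(u) ∩ NN(v)| / k. Because neighborhoods depend only on weight ranks,
   the clustering tolerates species that are more abundant or lyse more
   easily and therefore contribute disproportionately many pairs.
4. **Average-linkage agglomeration** down to N clusters, with
   linkage(A,B) = Σ w(a,b) / (|A|·|B|). N can be supplied (the expected
   species count) or predicted from the intracluster link enrichment curve
   E(N) — the fraction of Hi-C links that fall within rather than between
   clusters at the N-cluster stage — via the sharp drop in per-merge link
   density at the first species–species merge.
5. **Evaluation and stability.** Against a contig→species truth table
   (multi-membership allowed, as produced by aligning contigs to reference
   genomes), the package computes length-weighted cluster purity matrices
   and placement accuracies, plus a pair-resampling bootstrap that scores
   each contig's stability.

A synthetic community generator (`sim_config()`, `simulate_genomes()`,
`simulate_hic()`) produces multi-species genomes, shared segments,
configurable abundance/lysis heterogeneity, power-law cis contact decay
and inter-cellular noise, so the entire pipeline is testable offline.

## Worked example

```r
library(hicdeconv)

cfg <- sim_config(
  species = tibble::tibble(
    label = c("S_cerevisiae", "K_wickerhamii", "P_stipitis"),
    genome_length = 200000, abundance = c(1, 2, 1),
    lysis_efficiency = c(1, 1, 0.5)
  ),
  n_pairs = 50000, noise_fraction = 0.01, seed = 101
)
community <- simulate_genomes(cfg)
pairs     <- simulate_hic(cfg, community)

result <- deconvolve(pairs, community$contigs, n_clusters = 3, k = 15)
result
#> <hic_clusters> 3 cluster(s), 54 contig(s) clustered, 6 unclustered
#>   sizes: 19, 19, 16

filter_report(result)
#> # A tibble: 1 × 5
#>   total  kept dropped dropped_zero_site site_window
#>   <int> <int>   <int>             <int>       <dbl>
#> 1 50000 45157    4843              1962         500

clustering_accuracy(result, community$truth, community$contigs)[, 1:2]
#> # A tibble: 1 × 2
#>   length_weighted_accuracy count_weighted_accuracy
#>                      <dbl>                   <dbl>
#> 1                        1                       1

round(as.matrix(purity_matrix(result, community$truth, community$contigs)), 3)
#>            K_wickerhamii P_stipitis S_cerevisiae
#> cluster_01             0          1            0
#> cluster_02             0          0            1
#> cluster_03             1          0            0

unclustered_report(result, community$contigs)
#> <unclustered_report> total unclustered length: 60000 bp; fraction on zero-site contigs: 1
```

Reading the output: all 54 contigs that carry a restriction site were
placed, every cluster maps to exactly one species (purity rows are unit
vectors), both accuracies are 1.0, and the 6 unclustered contigs are
precisely the ones without a HindIII site — which can never produce Hi-C
signal. The filter dropped 9.7% of pairs, of which 1962 touched a
zero-site contig.

The same workflow is available from the shell via the installed
`exec/hicdeconv` script (`sites`, `filter`, `graph`, `cluster`,
`estimate-k`, `evaluate`, `bootstrap`, `simulate`, `run-all` subcommands).

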