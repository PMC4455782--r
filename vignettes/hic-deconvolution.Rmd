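---
title: "Deconvolving metagenome assemblies with Hi-C: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvolving metagenome assemblies with Hi-C: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Hi-C crosslinks chromatin inside intact cells before lysis, so the two
reads of a proximity-ligation pair derive, with high probability, from the
same cell. In a mixed community this is a species label in disguise: links
between contigs of different genomes arise only from inter-cellular
ligation noise, while links within a genome are abundant and, for cis
contacts, decay with genomic separation. `hicdeconv` exploits exactly this
contrast and nothing else — no sequence composition, no coverage profiles,
no references.

The pipeline makes three modeling assumptions:

1. **Informative read ends start near restriction sites.** Ligation
   junctions form at the enzyme's recognition sites, so a read pair is
   kept only when both 5′ positions fall within `site_window` of the
   nearest site on their contig. Contigs without a single site cannot
   participate and are reported as unclustered with reason `zero_sites`
   rather than being given a pseudo-count: inventing signal for them would
   only contaminate clusters.
2. **Expected link counts scale with ligatable ends.** The number of
   fragment-end pairs available for ligation between two contigs grows as
   the product of their site counts, so edge weights are
   `raw_links / (s1 * s2)` (`normalization = "product"`, the default;
   `"sum"` is available for users who prefer a milder correction).
3. **Within-species link density exceeds between-species density by a
   large factor.** Everything downstream — shared-neighbor pruning, the
   agglomeration order, the cluster-count elbow — consumes only relative
   link densities, which is what makes the method robust to global and
   per-species scaling of the library.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `site_window` | 500 | bp | proximity filter radius; inclusive (`distance <= window`), measured from a read's 5′ position to the first base of the nearest motif occurrence |
| `normalization` | `"product"` | — | site-count denominator for edge weights |
| `k` | 100 | neighbors | Jarvis–Patrick neighborhood size |
| `min_shared` | 1 | neighbors | minimum shared-neighbor count for an edge to survive |
| `jp weight_mode` | `"fraction"` | — | surviving edges reweighted to shared/k (or the raw shared count) |
| `n_clusters` | `"auto"` | clusters | agglomeration target; `"auto"` uses the enrichment elbow |

`k = 100` is the published operating point for assemblies with thousands
of contigs. It must be read against the graph: when a species contributes
fewer than `k` linkable contigs, every neighbor — including spurious
cross-species ones — enters the neighborhood lists and the shared-neighbor
filter loses its discriminative power. On small benchmark communities we
therefore pass `k` below the per-species contig count (the test suite uses
`k` of 5–15 on 20–100-contig communities). A rough rule: `k` somewhat
below the typical number of linkable contigs per species.

The 500-bp window is inclusive because "within" reads naturally as `<=`;
boundary pairs are rare and a fixed convention matters more than the
choice. Site positions are the offset of the motif's first base — the
reference point had to be fixed somewhere, and the first base is the
simplest reproducible choice. Overlapping motif occurrences are each
counted, and occurrences of a non-palindromic motif's reverse complement
are merged in; IUPAC ambiguity codes never match, which keeps the
normalization denominators conservative.

Duplicate read pairs are kept by default (`dedup = FALSE`): PCR-duplicate
handling belongs upstream, and removing coordinate duplicates here would
silently alter counts for users whose pipelines already deduplicate.

## The clustering machinery

**Largest component.** Real metagenome contact graphs consist of one giant
component plus debris — isolated contigs with too little signal.
`deconvolve()` clusters only the largest component (ties broken by total
sequence length, then by smallest member id) and reports the rest as
`outside_component`.

**Jarvis–Patrick.** Neighborhood lists are ranked on the site-normalized
weights (normalization precedes clustering), ties broken by contig id so
that reruns are bit-identical. A node is never its own neighbor. Edges
whose endpoints share no neighbors are removed; nodes stripped of every
edge are reported `jp_isolated`, not force-merged — they mirror the
non-signal contigs of real data. Because the lists depend only on ranks,
multiplying all links that touch one species by any constant leaves the
reweighted graph unchanged; this is the mechanism behind the method's
tolerance of unequal abundance and lysis efficiency, and the test suite
asserts it directly.

**Average-linkage agglomeration.** Linkage between clusters is the sum of
reweighted edge weights divided by `|A| * |B|`, absent edges contributing
zero. Merging is deterministic: among equal linkages, the pair whose
smallest member id is lexicographically least merges first. Merging stops
when the number of clusters reaches the target or no positive-linkage
pair remains. Only nodes with at least one surviving edge enter the
agglomeration, so the target is never consumed by edgeless debris; a
disconnected component that merges to completion stays a cluster in its
own right and counts toward the target. We chose to count *all* active
clusters rather than only those retaining inter-cluster linkage: on
cleanly separable data the graph decomposes into one component per
species, and under the narrower rule a completed component would stop
counting while another was still split — leaving species fragmented for
purely bookkeeping reasons.

**Choosing N.** A full agglomeration is run once and the intracluster link
enrichment `E(N)` — intra-cluster raw links over all raw links — is read
off the merge trace. Raw links on Jarvis–Patrick-removed edges still count
as intra when their endpoints co-cluster: the curve describes the observed
library, not the pruned graph. The predicted count is an elbow, but not on
`E` itself: single-merge gains are incomparable because a late merge of a
two-contig straggler adds little however real it is. Instead each merge is
scored by its raw-link *density* (links joined / contig pairs joined).
Within-species merges run at roughly the within-species density whatever
their size; the first species–species merge drops to the between-species
density, so the ratio of successive densities spikes at the boundary and
its argmax is the prediction (ties resolved toward the finer clustering).
The full curve is always returned so users can override N.

**Bootstrap.** Stability resamples the filtered pair multiset with
replacement, rebuilds the graph and reclusters at the same N. The
bootstrap deliberately skips the largest-component restriction: resampling
perturbs component membership at the margins, and discarding components
would conflate sampling variance with membership churn (on separable data
it would discard entire species). Replicate clusters are matched to
original clusters by greatest shared contig length; a contig is stable in
a replicate when it lands in the cluster matched to its own. All
randomness flows from one integer seed through R's RNG; no global state
survives the call.

## What the simulator does and does not emulate

`simulate_genomes()` + `simulate_hic()` generate: uniform random genomes
(several chromosomes and an optional plasmid per species); exact-copy
shared segments whose overlapping contigs carry both species labels — on
the source and the destination genome, since alignment-based truth would
flag both; fixed 10-kb binning (the reference community design) or
lognormal contig lengths; per-species sampling weights proportional to
abundance x lysis efficiency x genome size; cis contacts with power-law
separation decay (inverse-CDF sampling on [1 kb, replicon length],
exponent 1 by default, verified against the closed-form CDF in the test
suite); uniform trans contacts within the cell; inter-cellular noise pairs
between distinct species; and endpoint snapping to within `site_window` of
a restriction site so that the filter's behavior is controllable.

Defaults mirror the reference designs: 10-kb bins, HindIII motif, 500-bp
window, 90% cis, equal abundances unless a test exercises heterogeneity.
The minimum cis separation of 1 kb avoids self-ligation artifacts that the
model does not attempt to describe.

Not emulated: read-level sequences and sequencing error, mappability and
multi-mapping (simulated endpoints always resolve to the true contig),
GC/codon composition, assembler behavior beyond binning, restriction-site
biases of real genomes, and strain-level sequence divergence (shared
segments are exact copies). Passing tests therefore demonstrate the
clustering machinery under the method's own statistical assumptions; they
do not certify performance on real libraries, where alignment artifacts
and chimeric contigs add failure modes the simulator cannot produce.

## Numerical and degenerate-input choices

- Coordinates are 0-based half-open internally; `.pairs` files are 1-based
  and converted at the I/O boundary, as is SAM input.
- Cluster labels are assigned by decreasing total sequence length (ties by
  smallest member id), so outputs are stable across runs.
- The purity matrix's `unknown` column absorbs contigs missing from the
  truth table; accuracies are reported both with them counted and with
  them excluded (`unknown = "include"/"exclude"`), since the denominator
  convention for unplaceable sequence is genuinely ambiguous.
- Empty graphs, empty truth tables, star graphs that Jarvis–Patrick
  empties completely, and targets exceeding the linkable node count all
  fail fast with explicit errors rather than returning half-meaningful
  objects.
- Outputs are written to a temporary file and renamed, so readers never
  observe partial files.

## Problem sizes

The test suite and the acceptance script run the full pipeline on
communities of 10 species x 1 Mb (1,000 contigs, 200,000 pairs) across
many seeds, plus smaller 2–5-species communities for the bootstrap and CLI
checks; oracle-equivalence properties use graphs of up to 30 nodes where
brute-force references are exact. These sizes exercise every code path at
full statistical fidelity while keeping a complete run in minutes on one
core; the implementation itself is vectorized (dense-matrix agglomeration
with a row-maximum cache, sparse crossproducts for shared-neighbor counts)
and handles assemblies in the low tens of thousands of contigs.

## Known limitations

- Strain-level resolution is out of scope: closely related strains merge
  into one cluster, and splitting them needs machinery this package does
  not provide.
- Contigs within a cluster are not ordered or oriented; scaffolding is a
  separate problem.
- The cluster-count elbow assumes a separation between within- and
  between-species link densities; on libraries where noise approaches
  within-species density the curve flattens and N must be supplied.
- `k` must be chosen against the assembly's granularity (see above); there
  is no universal default for small communities.
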